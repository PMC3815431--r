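# Drug-class map: key<TAB>drug_class
# A key matches a medication code exactly (case-insensitive) or the
# medication display name as a case-insensitive substring.
key	drug_class
simvastatin	antihyperlipidemics
atorvastatin	antihyperlipidemics
rosuvastatin	antihyperlipidemics
pravastatin	antihyperlipidemics
lisinopril	antihypertensives
ramipril	antihypertensives
furosemide	antihypertensives
amlodipine	antihypertensives
losartan	antihypertensives
metformin	oral_hypoglycemics
glipizide	oral_hypoglycemics
glyburide	oral_hypoglycemics
pioglitazone	oral_hypoglycemics
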