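patient_id,medication_id,medication_name,fill_date,days_supply,age_at_first_fill
demo-1,rx-ramipril,Ramipril,2021-12-20,30,62
demo-1,rx-ramipril,Ramipril,2022-01-19,30,62
demo-1,rx-ramipril,Ramipril,2022-02-18,30,62
demo-1,rx-ramipril,Ramipril,2022-03-20,30,62
demo-1,rx-ramipril,Ramipril,2022-04-19,30,62
demo-1,rx-ramipril,Ramipril,2022-05-19,30,62
demo-1,rx-ramipril,Ramipril,2022-06-18,30,62
demo-1,rx-ramipril,Ramipril,2022-07-18,30,62
demo-1,rx-ramipril,Ramipril,2022-08-17,30,62
demo-1,rx-ramipril,Ramipril,2022-09-16,30,62
demo-1,rx-ramipril,Ramipril,2022-10-16,30,62
demo-1,rx-ramipril,Ramipril,2022-11-15,30,62
demo-1,rx-ramipril,Ramipril,2022-12-15,30,62
demo-1,rx-ramipril,Ramipril,2023-01-14,30,62
demo-1,rx-furosemide,Furosemide,2022-07-15,30,62
demo-1,rx-furosemide,Furosemide,2022-08-24,30,62
demo-1,rx-furosemide,Furosemide,2022-10-13,30,62
demo-1,rx-furosemide,Furosemide,2022-12-02,30,62
demo-1,rx-cyclobenzaprine,Cyclobenzaprine,2022-09-01,30,62
demo-1,rx-cyclobenzaprine,Cyclobenzaprine,2022-10-01,30,62
demo-1,rx-cyclobenzaprine,Cyclobenzaprine,2022-10-31,30,62
demo-1,rx-cyclobenzaprine,Cyclobenzaprine,2022-11-30,30,62
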