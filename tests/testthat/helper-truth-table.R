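# Recipes constructing a history for each reachable combination of
# {gap alert} x {current MPR < 0.8} x {1-year observation: absent/ok/low}.
# Supplies are 30 days per fill throughout; horizons 200 (year absent)
# or 400 (year observed). Targets were derived by hand from the fill
# arithmetic and are re-verified against the component checks below.
truth_table_cases <- function() {
  list(
    list(gap = FALSE, curlow = FALSE, year = "absent",
         h = med_history(seq(0, 180, 30), rep(30L, 7), 200)),
    list(gap = FALSE, curlow = TRUE, year = "absent",
         h = med_history(seq(0, 160, 40), rep(30L, 5), 200)),
    list(gap = TRUE, curlow = FALSE, year = "absent",
         h = med_history(c(0, 70, 100, 101, 102, 103, 104), rep(30L, 7), 200)),
    list(gap = TRUE, curlow = TRUE, year = "absent",
         h = med_history(0, 30, 200)),
    list(gap = FALSE, curlow = FALSE, year = "ok",
         h = med_history(seq(0, 360, 30), rep(30L, 13), 400)),
    list(gap = FALSE, curlow = TRUE, year = "ok",
         h = med_history(c(0, 40, 80, 120, 160, 200, 240, 280, 310, 340),
                         rep(30L, 10), 400)),
    list(gap = TRUE, curlow = FALSE, year = "ok",
         h = med_history(c(0, seq(70, 340, 30)), rep(30L, 11), 400)),
    list(gap = TRUE, curlow = TRUE, year = "ok",
         h = med_history(c(0, seq(70, 310, 30)), rep(30L, 10), 400)),
    list(gap = FALSE, curlow = FALSE, year = "low",
         h = med_history(c(0, 42, 84, 126, 168, 210, 252, 294, 336, 370, 371),
                         rep(30L, 11), 400)),
    list(gap = FALSE, curlow = TRUE, year = "low",
         h = med_history(c(0, 50, 100, 150, 190, 230, 270, 310, 340),
                         rep(30L, 9), 400)),
    list(gap = TRUE, curlow = FALSE, year = "low",
         h = med_history(c(0, 70, 112, 154, 196, 238, 280, 322, 366, 367, 368),
                         rep(30L, 11), 400)),
    list(gap = TRUE, curlow = TRUE, year = "low",
         h = med_history(0, 30, 400))
  )
}

# the documented combination rule, written independently of the package
expected_status <- function(gap, curlow, year, pred) {
  if (gap || curlow) return("RED")
  if (year == "ok") return("GREEN")
  switch(pred, poor = "YELLOW", ok = "GREEN", none = "NONE")
}

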