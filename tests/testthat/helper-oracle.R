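# Brute-force day-by-day possession oracle, kept independent of the
# package's interval arithmetic: a daily supply counter that gains the
# fill's days of supply on each fill day and loses one unit per covered
# day (carryover), or per-fill coverage windows unioned (no carryover).
oracle_covered <- function(fill_days, supplies, horizon, carryover = TRUE) {
  if (horizon < 1L) return(logical(0))
  covered <- logical(horizon)
  if (carryover) {
    adds <- numeric(horizon)
    in_range <- fill_days < horizon
    adds[fill_days[in_range] + 1L] <- supplies[in_range]
    supply <- 0
    for (d in seq_len(horizon)) {
      supply <- supply + adds[d]
      if (supply > 0) {
        covered[d] <- TRUE
        supply <- supply - 1
      }
    }
  } else {
    for (i in seq_along(fill_days)) {
      dd <- fill_days[i]:(fill_days[i] + supplies[i] - 1L)
      dd <- dd[dd < horizon]
      covered[dd + 1L] <- TRUE
    }
  }
  covered
}

# maximal runs of `value` in a logical day vector, as [start, end) intervals
oracle_runs <- function(covered, value = TRUE) {
  if (length(covered) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(
    start = as.integer(starts[r$values == value]),
    end = as.integer(ends[r$values == value])
  )
}

oracle_mpr <- function(fill_days, supplies, day) {
  vapply(day, function(d) sum(supplies[fill_days <= d]) / d, numeric(1))
}

# a random but valid history under the current RNG stream
random_history <- function(max_fills = 10L) {
  n <- sample.int(max_fills, 1L)
  fd <- cumsum(c(0L, if (n > 1L) sample(1:60, n - 1L, replace = TRUE)))
  sup <- sample(1:90, n, replace = TRUE)
  hz <- max(fd[n] + sample(0:120, 1L), 1L)
  med_history(fd, sup, hz)
}
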