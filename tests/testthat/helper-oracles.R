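# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: closed-form survivor evaluations, hand summation,
# and exhaustive scans.

# Weibull survivor function evaluated directly
surv_oracle <- function(t, shape = 4.07, scale = 23.5) {
  exp(-(t / scale)^shape)
}

# discrete lifespan pmf implied by the truncated daily hazard: death in
# [i, i + 1) for i < max - 1, with the whole tail mass at max - 1
lifespan_pmf_oracle <- function(max_age = 30L, shape = 4.07, scale = 23.5) {
  i <- 0:(max_age - 1L)
  pmf <- surv_oracle(i, shape, scale) - surv_oracle(i + 1L, shape, scale)
  pmf[max_age] <- surv_oracle(max_age - 1L, shape, scale)
  pmf
}

# brute-force scan for the first run of `r` consecutive zeros: checks every
# window explicitly
extinction_scan_oracle <- function(counts, r) {
  n <- length(counts)
  if (n >= r) {
    for (start in 1:(n - r + 1L)) {
      if (all(counts[start:(start + r - 1L)] == 0L)) return(start)
    }
  }
  NA_integer_
}

# build a population_state with given counts at given ages
make_state <- function(wt = c(), tg = c(), wt_ages = c(), tg_ages = c(),
                       day = 0L, params = life_history()) {
  aw <- numeric(params$max_adult_age)
  at <- numeric(params$max_adult_age)
  aw[wt_ages + 1L] <- wt
  at[tg_ages + 1L] <- tg
  population_state(day, aw, at, NULL, params)
}
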