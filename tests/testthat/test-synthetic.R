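p0 <- life_history()

test_that("extinction week matches an exhaustive window scan", {
  # stated examples
  x <- data.frame(week = 1:4, n_transgenic = c(40, 20, 0, 0))
  expect_identical(extinction_week(x, 2), 3L)
  y <- data.frame(week = 1:4, n_transgenic = c(40, 0, 20, 10))
  expect_identical(extinction_week(y, 2), NA_integer_)
  expect_error(extinction_week(x, 0), "required_consecutive")
  expect_error(extinction_week(x[0, ], 2), "empty")

  # random 0/1 series against the brute-force oracle
  set.seed(5)
  for (i in 1:200) {
    counts <- rbinom(12, 1, 0.4)
    r <- sample(1:3, 1)
    obs <- data.frame(week = seq_along(counts), n_transgenic = counts)
    expect_identical(extinction_week(obs, r),
                     {
                       e <- extinction_scan_oracle(counts, r)
                       if (is.na(e)) NA_integer_ else as.integer(e)
                     })
  }
})

test_that("synthetic experiments are deterministic and follow the design", {
  d <- experiment_design(seeding_levels = c(0.2, 0.5), replicates_per_level = 2,
                         max_weeks = 8)
  a <- generate_experiment(d, p0, seed = 13)
  b <- generate_experiment(d, p0, seed = 13)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_setequal(unique(a$seeding_fraction), c(0.2, 0.5))
  expect_true(all(a$n_transgenic <= a$n_sampled))
  expect_true(all(a$n_sampled == 200))
  expect_true(all(table(a$seeding_fraction, a$replicate) > 0))

  # zero seeding with zero loads: all-zero series, terminated by the rule
  d0 <- experiment_design(seeding_levels = 0, replicates_per_level = 1,
                          true_loads = fitness_loads(0, 0), max_weeks = 10)
  z <- generate_experiment(d0, p0, seed = 1)
  expect_true(all(z$n_transgenic == 0))
  expect_identical(nrow(z), d0$termination_rule)
})

test_that("full transgenic seeding screens about half transgenic in week one", {
  d <- experiment_design(seeding_levels = 1, replicates_per_level = 100,
                         max_weeks = 1, true_loads = fitness_loads(0, 0),
                         termination_rule = 5)
  obs <- generate_experiment(d, p0, seed = 17)
  wk1 <- obs$n_transgenic[obs$week == 1]
  # var(n_obs) = screening binomial + harvest binomial, both ~ Bin(200, 1/2)
  se <- sqrt(2 * 200 * 0.25 / 100)
  expect_lt(abs(mean(wk1) - 100), 3 * se)
})

test_that("binomial screening adds variance but no bias", {
  d <- experiment_design(seeding_levels = 0.5, replicates_per_level = 100,
                         max_weeks = 4, termination_rule = 10)
  obs <- generate_experiment(d, p0, seed = 23)
  harvest <- attr(obs, "harvest_proportion")
  diffs <- obs$n_transgenic / obs$n_sampled - harvest
  se <- sqrt(mean(harvest * (1 - harvest) / 200) / length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("hypergeometric screening of the whole cohort reproduces it exactly", {
  d <- experiment_design(seeding_levels = 0.5, replicates_per_level = 1,
                         max_weeks = 4, sampling = "hypergeometric",
                         termination_rule = 10)
  obs <- generate_experiment(d, p0, seed = 29)
  # sample_size equals the cohort, so the screen is a census of the harvest
  expect_equal(obs$n_transgenic / obs$n_sampled,
               attr(obs, "harvest_proportion"))
})

test_that("heavier loads shift extinction stochastically earlier", {
  ext_weeks <- function(loads, seed0) {
    d <- experiment_design(seeding_levels = 0.5, replicates_per_level = 150,
                           max_weeks = 30, true_loads = loads)
    obs <- generate_experiment(d, p0, seed = seed0)
    vapply(split(obs, obs$replicate), extinction_week, integer(1))
  }
  e0 <- ext_weeks(fitness_loads(0, 0), 1)
  e4 <- ext_weeks(fitness_loads(0.4, 0), 2)
  # compare where extinction was reached; unreached cages sit at the top
  e0[is.na(e0)] <- 31L
  e4[is.na(e4)] <- 31L
  expect_lt(median(e4), median(e0))
  expect_lt(mean(e4), mean(e0))
  # empirical CDF dominance at the quartiles of the pooled sample
  qs <- quantile(c(e0, e4), c(0.25, 0.5, 0.75))
  expect_true(all(ecdf(e4)(qs) >= ecdf(e0)(qs)))
})

test_that("observation CSVs round-trip bit-identically with provenance headers", {
  d <- experiment_design(replicates_per_level = 1, max_weeks = 6)
  obs <- generate_experiment(d, p0, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cage_observations(obs, f, seed = 3, params = p0)
  expect_match(readLines(f, n = 1), "^# cageload .* seed=3 config=[0-9a-f]{8}$")
  back <- read_cage_observations(f)
  expect_equal(as.data.frame(obs), as.data.frame(back), ignore_attr = TRUE)
  # malformed files are rejected
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("week,n_sampled", "1,200"), bad)
  expect_error(read_cage_observations(bad), "lacks columns")
})

test_that("trajectory CSVs round-trip through the long format", {
  ens <- run_ensemble(0.2, p0, n_weeks = 4, n_replicates = 3, seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(ens, f, params = p0)
  df <- read_trajectories(f)
  expect_equal(nrow(df), 12)
  expect_equal(df$tg_proportion[df$replicate == 2],
               ens$trajectories[[2]]$tg_proportion)
})
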