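p0 <- life_history()
l0 <- fitness_loads()

test_that("egg transgenic probability is half the load-weighted transgenic fraction", {
  # all eligible females transgenic -> exactly one half
  s <- make_state(tg = 80, tg_ages = 5)
  expect_equal(egg_transgenic_probability(s, p0, l0), 0.5)

  # equal counts -> half of one half
  s <- make_state(wt = 50, tg = 50, wt_ages = 4, tg_ages = 6)
  expect_equal(egg_transgenic_probability(s, p0, l0), 0.25)

  # egg-batch load down-weights transgenic mothers: (TG 40, WT 160, Le 0.5)
  s <- make_state(wt = 160, tg = 40, wt_ages = 5, tg_ages = 5)
  expect_equal(egg_transgenic_probability(s, p0, fitness_loads(0.5, 0)),
               0.5 * 20 / 180)

  # females below the oviposition age do not count
  s <- make_state(wt = 100, tg = 100, wt_ages = 5, tg_ages = 1)
  expect_equal(egg_transgenic_probability(s, p0, l0), 0)

  # no eligible females is a distinct condition, not a zero
  s <- make_state(wt = 10, tg = 10, wt_ages = 0, tg_ages = 1)
  expect_error(egg_transgenic_probability(s, p0, l0),
               class = "cageload_no_eligible_females")
})

test_that("weekly harvest conserves the cohort and is binomial in the egg probability", {
  s <- make_state(wt = 160, tg = 40, wt_ages = 5, tg_ages = 5)
  set.seed(1)
  draws <- t(replicate(10000, {
    h <- weekly_oviposition(s, p0, l0)
    c(h$n_wt, h$n_tg)
  }))
  expect_true(all(rowSums(draws) == 200L))
  # fraction 0.2 transgenic -> p = 0.1, mean 20; 3-SE binomial moment check
  se <- sqrt(200 * 0.1 * 0.9 / 10000)
  expect_lt(abs(mean(draws[, 2]) - 20), 3 * se)

  # no transgenic females: absorbing, n_tg = 0 surely
  s0 <- make_state(wt = 100, wt_ages = 5)
  expect_identical(weekly_oviposition(s0, p0, l0)$n_tg, 0L)

  # no eligible females: empty harvest, not an error
  s1 <- make_state(wt = 10, wt_ages = 0)
  h <- weekly_oviposition(s1, p0, l0)
  expect_identical(h$n_wt + h$n_tg, 0L)
})

test_that("emergence is scheduled 10-12 days after harvest with genotype-specific delays", {
  h <- structure(list(day = 14L, n_wt = 134L, n_tg = 66L), class = "egg_harvest")
  set.seed(2)
  for (i in 1:200) {
    sched <- schedule_emergence(h, p0)
    expect_true(all(sched[, "emergence_day"] >= 24 &
                    sched[, "emergence_day"] <= 26))
    # female share taken deterministically as half the harvest per genotype
    expect_equal(sum(sched[, "n_tg"]), 33)
    expect_equal(sum(sched[, "n_wt"]), 67)
  }

  # degenerate delay vector: everyone emerges exactly base + 1 days later
  pdet <- life_history(phi_wt = c(1, 0, 0))
  sched <- schedule_emergence(h, pdet)
  expect_equal(unname(sched[sched[, "n_wt"] > 0, "emergence_day"]), 24)

  # transgenics stochastically slower: mean delay ordered as the phis
  big <- structure(list(day = 0L, n_wt = 20000L, n_tg = 20000L),
                   class = "egg_harvest")
  set.seed(3)
  sched <- schedule_emergence(big, p0)
  mean_day <- function(g) sum(sched[, "emergence_day"] * sched[, g]) / sum(sched[, g])
  expect_gt(mean_day("n_tg"), mean_day("n_wt"))
  # and both match the exact multinomial means within 3 SE
  ed <- function(phi) 9 + sum(phi * 1:3)
  se_wt <- sqrt(sum(p0$phi_wt * (9 + 1:3 - ed(p0$phi_wt))^2) / 20000)
  expect_lt(abs(mean_day("n_wt") - ed(p0$phi_wt)), 3 * se_wt)
})

test_that("step_day kills, ages, emerges and harvests in the documented order", {
  # adults at the truncation boundary are all gone the next day
  s <- make_state(wt = 50, tg = 50, wt_ages = 29, tg_ages = 29)
  s2 <- step_day(s, p0, l0)
  expect_equal(sum(s2$aw) + sum(s2$at), 0)

  # the empty cage is absorbing, across oviposition days too
  s <- make_state()
  for (d in 1:15) s <- step_day(s, p0, l0)
  expect_equal(sum(s$aw) + sum(s$at) + nrow(s$pending), 0)
  expect_equal(s$day, 15L)

  # survivor counts are Binomial(n, 1 - mu_age): 5000 replicate single days
  mu5 <- daily_death_probability(5, p0, l0, "WT")
  set.seed(4)
  surv <- replicate(5000, {
    s <- make_state(wt = 100, wt_ages = 5)
    sum(step_day(s, p0, l0)$aw)
  })
  se <- sqrt(100 * mu5 * (1 - mu5) / 5000)
  expect_lt(abs(mean(surv) - 100 * (1 - mu5)), 3 * se)
  # survivors aged by one day
  s <- make_state(wt = 100, wt_ages = 5)
  s2 <- step_day(s, p0, l0)
  expect_equal(which(s2$aw > 0), 7L)  # age 6, 1-based index 7

  # pending cohorts join the adult pool at age 0 on their emergence day
  pend <- cbind(emergence_day = 1, n_wt = 10, n_tg = 5)
  s <- population_state(0L, numeric(30), numeric(30), pend, p0)
  s2 <- step_day(s, p0, l0)
  expect_equal(s2$aw[1], 10)
  expect_equal(s2$at[1], 5)
  expect_equal(nrow(s2$pending), 0L)
})

test_that("run_replicate seeds, iterates and records reproducibly", {
  # no transgenes seeded -> no source of transgenes, ever
  tr <- run_replicate(0, p0, l0, n_weeks = 8, seed = 5)
  expect_true(all(tr$tg_proportion == 0))
  expect_true(all(tr$n_wt == 200))

  # full transgenic seeding: first harvest is Binomial(200, 1/2)
  set.seed(6)
  first <- vapply(1:300, function(s)
    run_replicate(1, p0, l0, n_weeks = 1, seed = s)$tg_proportion[1],
    numeric(1))
  se <- sqrt(0.25 / 200 / 300)
  expect_lt(abs(mean(first) - 0.5), 3 * se)

  # determinism: identical seeds give bitwise-identical trajectories
  a <- run_replicate(0.5, p0, fitness_loads(0.2, 0.1), n_weeks = 10, seed = 77)
  b <- run_replicate(0.5, p0, fitness_loads(0.2, 0.1), n_weeks = 10, seed = 77)
  expect_identical(a, b)

  # invalid inputs
  expect_error(run_replicate(1.2), "init_tg_fraction")
  expect_error(run_replicate(0.5, n_weeks = 0), "n_weeks")
})

test_that("seeded transgenic counts round half up and are exact at the study levels", {
  for (f in c(0.2, 0.5, 1.0)) {
    tr <- run_replicate(f, p0, l0, n_weeks = 1, seed = 1)
    expect_equal(tr$seeding_fraction, f)
  }
  # round-half-up at an awkward fraction: 0.125 * 100 = 12.5 -> 13
  s <- cageload:::seed_state(0.125, p0)
  expect_equal(sum(s$at), 13)
  expect_equal(sum(s$aw), 87)
  expect_equal(which(s$at > 0) - 1L, p0$initial_age)
})
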