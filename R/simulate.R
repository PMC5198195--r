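#' Construct a cage population state
#'
#' The state of the female population on a given day: adult counts by age and
#' genotype, plus juvenile cohorts scheduled to emerge on later days.
#'
#' @param day Non-negative integer day.
#' @param adults_wt,adults_tg Non-negative integer vectors of adult female
#'   counts indexed by age `0 .. max_adult_age - 1` (short vectors are
#'   zero-padded).
#' @param pending Matrix (or NULL) with columns `emergence_day`, `n_wt`,
#'   `n_tg`; every emergence day must be strictly after `day`.
#' @param params A [life_history()] object.
#' @return An object of class `population_state`.
#' @export
population_state <- function(day = 0L, adults_wt = integer(), adults_tg = integer(),
                             pending = NULL, params = life_history()) {
  m <- params$max_adult_age
  pad <- function(x) {
    x <- as.numeric(x)
    if (length(x) > m) stop("no adult may be aged >= max_adult_age", call. = FALSE)
    c(x, numeric(m - length(x)))
  }
  aw <- pad(adults_wt); at <- pad(adults_tg)
  if (any(aw < 0) || any(at < 0) || any(aw != round(aw)) || any(at != round(at)))
    stop("adult counts must be non-negative integers", call. = FALSE)
  if (is.null(pending))
    pending <- matrix(numeric(0), ncol = 3,
                      dimnames = list(NULL, c("emergence_day", "n_wt", "n_tg")))
  if (nrow(pending) && any(pending[, "emergence_day"] <= day))
    stop("pending emergence days must be strictly after the current day",
         call. = FALSE)
  structure(list(day = as.integer(day), aw = aw, at = at, pending = pending,
                 last_harvest = NULL),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Cage state, day %d: %d WT + %d TG adult females, %d pending juveniles\n",
              x$day, sum(x$aw), sum(x$at),
              if (nrow(x$pending)) sum(x$pending[, c("n_wt", "n_tg")]) else 0L))
  invisible(x)
}

eligible_counts <- function(state, params) {
  idx <- (params$min_oviposition_age + 1L):params$max_adult_age
  c(wt = sum(state$aw[idx]), tg = sum(state$at[idx]))
}

#' Probability that a harvested egg is transgenic
#'
#' Every viable egg has a wild-type father (transgenic males are sterile), so
#' an egg is transgenic only if its mother is, with probability one half by
#' Mendelian transmission of a hemizygous insert.  The mother is transgenic
#' with probability equal to the transgenic share of oviposition-eligible
#' females, weighted down by the egg-batch load: the returned value is
#' `0.5 * (1 - load_egg) * T / ((1 - load_egg) * T + W)` over females aged at
#' least `min_oviposition_age`.
#'
#' @param state A [population_state()].
#' @param params A [life_history()] object.
#' @param loads A [fitness_loads()] object.
#' @return A probability in `[0, 0.5]`.  If no eligible female exists, an
#'   error of class `cageload_no_eligible_females` is signalled (distinct
#'   from a zero probability).
#' @export
egg_transgenic_probability <- function(state, params = life_history(),
                                       loads = fitness_loads()) {
  el <- eligible_counts(state, params)
  w_tg <- (1 - loads$load_egg) * el[["tg"]]
  w_wt <- el[["wt"]]
  if (w_tg + w_wt <= 0)
    stop(structure(class = c("cageload_no_eligible_females", "error", "condition"),
                   list(message = "no oviposition possible: no eligible females",
                        call = sys.call(-1))))
  0.5 * w_tg / (w_tg + w_wt)
}

#' Weekly egg harvest
#'
#' Eggs are non-limiting: enough are always harvested that `cohort_size`
#' adults emerge and are restocked.  The only random element is the genotype
#' mix: the transgenic count is a single binomial draw of size `cohort_size`
#' with success probability [egg_transgenic_probability()].  With no eligible
#' females the harvest is empty (a zero cohort that week).
#'
#' @inheritParams egg_transgenic_probability
#' @return An object of class `egg_harvest`: list with `day`, `n_wt`, `n_tg`.
#' @export
weekly_oviposition <- function(state, params = life_history(),
                               loads = fitness_loads()) {
  el <- eligible_counts(state, params)
  if (sum(el) == 0)
    return(structure(list(day = state$day, n_wt = 0L, n_tg = 0L),
                     class = "egg_harvest"))
  p <- egg_transgenic_probability(state, params, loads)
  n_tg <- rbinom(1L, params$cohort_size, p)
  structure(list(day = state$day, n_wt = params$cohort_size - n_tg,
                 n_tg = n_tg),
            class = "egg_harvest")
}

#' Schedule emergence of a harvested cohort
#'
#' The female share of the restocked cohort is taken deterministically as half
#' the harvest (per genotype, rounded).  Each female emerges as an age-0 adult
#' `juvenile_base_days + D` days after the harvest, with delay `D` in
#' `{1, 2, 3}` drawn multinomially from `phi_wt` or `phi_tg`; with the default
#' base of 9 days, emergence falls 10--12 days after oviposition.  If
#' `pupal_mortality > 0`, each female is first removed independently with that
#' probability.
#'
#' @param harvest An `egg_harvest`.
#' @param params A [life_history()] object.
#' @return A pending-cohort matrix with columns `emergence_day`, `n_wt`,
#'   `n_tg` (zero rows dropped).
#' @export
schedule_emergence <- function(harvest, params = life_history()) {
  total <- harvest$n_wt + harvest$n_tg
  if (total == 0)
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("emergence_day", "n_wt", "n_tg"))))
  f_total <- round(total / 2)
  f_tg <- round(harvest$n_tg / 2)
  f_wt <- f_total - f_tg
  if (params$pupal_mortality > 0) {
    f_tg <- rbinom(1L, f_tg, 1 - params$pupal_mortality)
    f_wt <- rbinom(1L, f_wt, 1 - params$pupal_mortality)
  }
  d_wt <- drop(rmultinom(1L, f_wt, params$phi_wt))
  d_tg <- drop(rmultinom(1L, f_tg, params$phi_tg))
  days <- harvest$day + params$juvenile_base_days + 1:3
  keep <- (d_wt + d_tg) > 0
  cbind(emergence_day = days, n_wt = d_wt, n_tg = d_tg)[keep, , drop = FALSE]
}

#' Advance the cage population by one day
#'
#' In order: (1) every adult of age `i` dies independently with probability
#' `mu_i` from [daily_death_probability()] and survivors age one day;
#' (2) pending juveniles whose emergence day equals the new day join the adult
#' pool at age 0; (3) if the new day is an oviposition day (a multiple of
#' `oviposition_interval_days`), a [weekly_oviposition()] harvest is drawn and
#' its emergence scheduled via [schedule_emergence()].  The harvest, when one
#' occurred, is stored in the returned state's `last_harvest` field.
#'
#' @inheritParams egg_transgenic_probability
#' @param hazards Optional list with precomputed elements `wt` and `tg` (the
#'   full daily hazard vectors); computed from `params` and `loads` if NULL.
#' @return The new `population_state`.
#' @export
step_day <- function(state, params = life_history(), loads = fitness_loads(),
                     hazards = NULL) {
  if (is.null(hazards))
    hazards <- list(wt = hazard_vector(params, loads, "WT"),
                    tg = hazard_vector(params, loads, "TG"))
  m <- params$max_adult_age
  day <- state$day + 1L

  if (sum(state$aw) + sum(state$at) > 0) {
    surv <- rbinom(2L * m, c(state$aw, state$at),
                   1 - c(hazards$wt, hazards$tg))
    aw <- c(0, surv[seq_len(m - 1L)])
    at <- c(0, surv[m + seq_len(m - 1L)])
  } else {
    aw <- state$aw
    at <- state$at
  }

  pending <- state$pending
  if (nrow(pending)) {
    due <- pending[, "emergence_day"] == day
    if (any(due)) {
      aw[1L] <- aw[1L] + sum(pending[due, "n_wt"])
      at[1L] <- at[1L] + sum(pending[due, "n_tg"])
      pending <- pending[!due, , drop = FALSE]
    }
  }

  new <- state
  new$day <- day
  new$aw <- aw
  new$at <- at
  new$pending <- pending
  new$last_harvest <- NULL

  if (day %% params$oviposition_interval_days == 0L) {
    harvest <- weekly_oviposition(new, params, loads)
    sched <- schedule_emergence(harvest, params)
    if (nrow(sched)) new$pending <- rbind(new$pending, sched)
    new$last_harvest <- harvest
  }
  new
}

seed_state <- function(init_tg_fraction, params) {
  n_f <- params$cohort_size %/% 2L
  n_tg <- floor(init_tg_fraction * n_f + 0.5)  # round half up
  aw <- numeric(params$max_adult_age)
  at <- numeric(params$max_adult_age)
  aw[params$initial_age + 1L] <- n_f - n_tg
  at[params$initial_age + 1L] <- n_tg
  population_state(0L, aw, at, NULL, params)
}

#' Simulate one cage replicate
#'
#' Seeds `cohort_size / 2` adult females at age `initial_age`, of which
#' `round(init_tg_fraction * cohort_size / 2)` are transgenic, then iterates
#' [step_day()] for `7 * n_weeks` days, recording the transgenic proportion of
#' each weekly harvest.  Deterministic given `seed`.
#'
#' @param init_tg_fraction Initial transgenic fraction among seeded females,
#'   in `[0, 1]`.
#' @param params A [life_history()] object.
#' @param loads A [fitness_loads()] object.
#' @param n_weeks Number of weekly harvests to simulate (>= 1).
#' @param seed Integer RNG seed for this replicate.
#' @return An object of class `cage_trajectory`: list with
#'   `seeding_fraction`, `week` (1-based), `tg_proportion`, `n_tg`, `n_wt`,
#'   `tg_alive_end` (transgenic females alive or pending when the run ends;
#'   0 means the transgene is extinct), `seed`.  A week with no harvest (no
#'   eligible females) is recorded with zero counts and proportion 0.
#' @param engine `"compiled"` (default; the C++ daily loop) or `"reference"`
#'   (the pure-R [step_day()] loop).  The two engines implement the same
#'   update rules and are statistically exchangeable, but consume the RNG
#'   stream differently, so identical seeds give different (equally valid)
#'   realizations across engines.
#' @examples
#' tr <- run_replicate(0.5, n_weeks = 5, seed = 1)
#' tr$tg_proportion
#' @export
run_replicate <- function(init_tg_fraction, params = life_history(),
                          loads = fitness_loads(), n_weeks = 20L,
                          seed = 1L, engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  if (!is.finite(init_tg_fraction) || init_tg_fraction < 0 || init_tg_fraction > 1)
    stop("init_tg_fraction must lie in [0, 1]", call. = FALSE)
  if (n_weeks < 1L) stop("n_weeks must be >= 1", call. = FALSE)
  set.seed(seed)
  hz <- list(wt = hazard_vector(params, loads, "WT"),
             tg = hazard_vector(params, loads, "TG"))
  state <- seed_state(init_tg_fraction, params)
  n_days <- 7L * n_weeks
  ivl <- params$oviposition_interval_days
  n_harvest <- n_days %/% ivl
  if (engine == "compiled") {
    res <- cpp_sim_weeks(state$aw, state$at, hz$wt, hz$tg,
                         params$phi_wt, params$phi_tg,
                         params$cohort_size, params$min_oviposition_age,
                         params$juvenile_base_days, ivl, n_days,
                         1 - loads$load_egg, params$pupal_mortality)
    n_tg <- res$n_tg; n_wt <- res$n_wt
    tg_alive_end <- res$tg_alive_end
  } else {
    n_tg <- integer(n_harvest); n_wt <- integer(n_harvest)
    k <- 0L
    for (d in seq_len(n_days)) {
      state <- step_day(state, params, loads, hazards = hz)
      if (!is.null(state$last_harvest)) {
        k <- k + 1L
        n_tg[k] <- state$last_harvest$n_tg
        n_wt[k] <- state$last_harvest$n_wt
      }
    }
    tg_alive_end <- sum(state$at) +
      (if (nrow(state$pending)) sum(state$pending[, "n_tg"]) else 0)
  }
  tot <- n_tg + n_wt
  prop <- ifelse(tot > 0, n_tg / tot, 0)
  structure(list(seeding_fraction = init_tg_fraction,
                 week = seq_len(n_harvest),
                 tg_proportion = prop, n_tg = n_tg, n_wt = n_wt,
                 tg_alive_end = tg_alive_end,
                 seed = as.integer(seed)),
            class = "cage_trajectory")
}

#' @export
print.cage_trajectory <- function(x, ...) {
  cat(sprintf("Cage trajectory: seeding %.0f%%, %d weeks, seed %d\n",
              100 * x$seeding_fraction, length(x$week), x$seed))
  print(data.frame(week = x$week, tg_proportion = round(x$tg_proportion, 4),
                   n_tg = x$n_tg, n_wt = x$n_wt), row.names = FALSE)
  invisible(x)
}

#' Simulate an ensemble of replicate cages
#'
#' Runs [run_replicate()] `n_replicates` times with replicate seeds
#' `seed, seed + 1, ...` (a fixed-increment derivation, so any replicate can
#' be reproduced in isolation).
#'
#' @inheritParams run_replicate
#' @param n_replicates Number of replicate runs.
#' @param seed Base seed; replicate `r` uses `seed + r - 1`.
#' @return An object of class `cage_ensemble`: list with `seeding_fraction`,
#'   `n_replicates`, `trajectories` (list of `cage_trajectory`).
#' @export
run_ensemble <- function(init_tg_fraction, params = life_history(),
                         loads = fitness_loads(), n_weeks = 20L,
                         n_replicates = 1000L, seed = 1L) {
  trajectories <- lapply(seq_len(n_replicates), function(r)
    run_replicate(init_tg_fraction, params, loads, n_weeks, seed + r - 1L))
  structure(list(seeding_fraction = init_tg_fraction,
                 n_replicates = as.integer(n_replicates),
                 trajectories = trajectories),
            class = "cage_ensemble")
}

#' @export
print.cage_ensemble <- function(x, ...) {
  cat(sprintf("Cage ensemble: %d replicates at seeding %.0f%%, %d weeks\n",
              x$n_replicates, 100 * x$seeding_fraction,
              length(x$trajectories[[1]]$week)))
  invisible(x)
}

# weeks x replicates matrix of weekly transgenic proportions
ensemble_matrix <- function(ensemble) {
  vapply(ensemble$trajectories, `[[`, numeric(length(ensemble$trajectories[[1]]$week)),
         "tg_proportion")
}

#' Deterministic expectation recursion of the cage model
#'
#' Applies the same daily update rules as the stochastic simulator to expected
#' (real-valued) counts, with no sampling: survival multiplies each age class
#' by `1 - mu_i`, the weekly harvest's expected transgenic count is
#' `cohort_size` times the egg transgenic probability evaluated at the
#' expected eligible counts, and pupation delays split each cohort in the
#' exact proportions `phi_wt` / `phi_tg`.  Useful as an independent
#' deterministic reference for ensemble means (the two agree up to the
#' nonlinearity of the egg-probability ratio, which is negligible at cage
#' scale).
#'
#' @inheritParams run_replicate
#' @return Numeric vector of expected weekly transgenic proportions.
#' @export
expected_trajectory <- function(init_tg_fraction, params = life_history(),
                                loads = fitness_loads(), n_weeks = 20L) {
  mu_wt <- hazard_vector(params, loads, "WT")
  mu_tg <- hazard_vector(params, loads, "TG")
  m <- params$max_adult_age
  n_f <- params$cohort_size %/% 2L
  n_tg0 <- floor(init_tg_fraction * n_f + 0.5)
  aw <- numeric(m); at <- numeric(m)
  aw[params$initial_age + 1L] <- n_f - n_tg0
  at[params$initial_age + 1L] <- n_tg0
  n_days <- 7L * n_weeks
  ivl <- params$oviposition_interval_days
  # expected emergences indexed by absolute day
  em_wt <- numeric(n_days + params$juvenile_base_days + 4L)
  em_tg <- numeric(n_days + params$juvenile_base_days + 4L)
  idx_el <- (params$min_oviposition_age + 1L):m
  surv_p <- 1 - params$pupal_mortality
  prop <- numeric(n_days %/% ivl)
  k <- 0L
  for (d in seq_len(n_days)) {
    aw <- c(0, (aw * (1 - mu_wt))[-m])
    at <- c(0, (at * (1 - mu_tg))[-m])
    aw[1L] <- em_wt[d]
    at[1L] <- em_tg[d]
    if (d %% ivl == 0L) {
      k <- k + 1L
      w_tg <- (1 - loads$load_egg) * sum(at[idx_el])
      w_wt <- sum(aw[idx_el])
      if (w_tg + w_wt > 0) {
        p <- 0.5 * w_tg / (w_tg + w_wt)
        prop[k] <- p
        e_tg <- params$cohort_size * p / 2 * surv_p
        e_wt <- params$cohort_size * (1 - p) / 2 * surv_p
        days <- d + params$juvenile_base_days + 1:3
        em_wt[days] <- em_wt[days] + e_wt * params$phi_wt
        em_tg[days] <- em_tg[days] + e_tg * params$phi_tg
      } else {
        prop[k] <- 0
      }
    }
  }
  prop
}
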