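#' Prior specification for the ABC fit
#'
#' Uniform priors over the two loads and the rejection-sampling budget.  The
#' defaults are the analysis' standard choices: egg-batch load uniform on
#' `[0, 1)`, longevity load uniform on `[0, 0.7]` (the cap keeps transgenic
#' female life expectancy above one week), 10,000 prior draws, and a
#' tolerance equal to the 1\% quantile of the distance sample -- implemented
#' as rank-based acceptance of the `floor(n_prior * tolerance_quantile)`
#' smallest distances, which fixes the number of posterior points exactly.
#'
#' @param egg_load_range Length-2 interval inside `[0, 1)`.
#' @param longevity_load_range Length-2 interval inside `[0, 0.7]`.
#' @param n_prior Number of prior draws (>= 1).
#' @param tolerance_quantile Acceptance quantile in `(0, 1)`;
#'   `n_prior * tolerance_quantile` must be at least 1.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(egg_load_range = c(0, 1),
                       longevity_load_range = c(0, 0.7),
                       n_prior = 10000L,
                       tolerance_quantile = 0.01) {
  if (length(egg_load_range) != 2L || egg_load_range[1] < 0 ||
      egg_load_range[2] > 1 || diff(egg_load_range) <= 0)
    stop("egg_load_range must be an increasing interval inside [0, 1)",
         call. = FALSE)
  if (length(longevity_load_range) != 2L || longevity_load_range[1] < 0 ||
      longevity_load_range[2] > 0.7 || diff(longevity_load_range) <= 0)
    stop("longevity_load_range must be an increasing interval inside [0, 0.7]",
         call. = FALSE)
  if (n_prior < 1L) stop("n_prior must be >= 1", call. = FALSE)
  if (tolerance_quantile <= 0 || tolerance_quantile >= 1)
    stop("tolerance_quantile must lie in (0, 1)", call. = FALSE)
  if (n_prior * tolerance_quantile < 1)
    stop("n_prior * tolerance_quantile must be >= 1", call. = FALSE)
  structure(list(egg_load_range = as.numeric(egg_load_range),
                 longevity_load_range = as.numeric(longevity_load_range),
                 n_prior = as.integer(n_prior),
                 tolerance_quantile = as.numeric(tolerance_quantile)),
            class = "prior_spec")
}

#' Sum-of-squares distance between observed and simulated series
#'
#' The ABC discrepancy: the sum over seeding levels, replicates and weeks of
#' the squared difference between the observed transgenic proportion among
#' screened larvae (`n_transgenic / n_sampled`) and the simulated weekly
#' harvest proportion.  Comparison runs over the weeks present in each
#' observed series (terminated cages are never padded with zeros); simulated
#' trajectories must cover every observed week of their seeding level.
#'
#' @param observed A `cage_observations` data frame.
#' @param simulated A single `cage_trajectory` or a list of them; matched to
#'   observations by `seeding_fraction`.
#' @return A non-negative number.
#' @examples
#' obs <- data.frame(seeding_fraction = 0.2, replicate = 1, week = 1,
#'                   n_sampled = 200, n_transgenic = 80)
#' tr <- list(seeding_fraction = 0.2, week = 1, tg_proportion = 0.1)
#' class(tr) <- "cage_trajectory"
#' ss_distance(obs, tr)  # (0.4 - 0.1)^2 = 0.09
#' @export
ss_distance <- function(observed, simulated) {
  if (inherits(simulated, "cage_trajectory")) simulated <- list(simulated)
  total <- 0
  matched <- FALSE
  for (tr in simulated) {
    sub <- observed[observed$seeding_fraction == tr$seeding_fraction, ,
                    drop = FALSE]
    if (!nrow(sub)) next
    if (max(sub$week) > length(tr$tg_proportion))
      stop("simulated trajectory shorter than the observed series",
           call. = FALSE)
    matched <- TRUE
    p_obs <- sub$n_transgenic / sub$n_sampled
    total <- total + sum((p_obs - tr$tg_proportion[sub$week])^2)
  }
  if (!matched)
    stop("no overlapping seeding levels/weeks between observed and simulated",
         call. = FALSE)
  total
}

#' Overall genetic load from the two component loads
#'
#' Combines the egg-batch and longevity loads multiplicatively:
#' `1 - (1 - load_egg) * (1 - load_longevity)`.  Symmetric in its arguments
#' and confined to `[0, 1)` on the valid domain.
#'
#' @param load_egg Value(s) in `[0, 1)`.
#' @param load_longevity Value(s) in `[0, 0.7]`.
#' @return The overall load, vectorized.
#' @examples
#' overall_load(0.5, 0.5)  # 0.75
#' @export
overall_load <- function(load_egg, load_longevity) {
  if (any(load_egg < 0) || any(load_egg >= 1))
    stop("load_egg must lie in [0, 1)", call. = FALSE)
  if (any(load_longevity < 0) || any(load_longevity > 0.7))
    stop("load_longevity must lie in [0, 0.7]", call. = FALSE)
  1 - (1 - load_egg) * (1 - load_longevity)
}

# rank-based acceptance: indices of the m smallest distances, ties broken by
# draw order (order() is stable for ties)
accept_by_rank <- function(distances, m) {
  order(distances)[seq_len(m)]
}

#' Fit the transgene fitness loads by ABC rejection sampling
#'
#' Estimates the additional loads on egg-batch size (`load_egg`) and adult
#' longevity (`load_longevity`) from observed weekly transgene-proportion
#' series.  The sampler (i) draws `n_prior` parameter pairs from the uniform
#' priors, (ii) simulates one stochastic cage trajectory per observed seeding
#' level for each pair (more via `sims_per_level`), (iii) computes the
#' sum-of-squares distance [ss_distance()] to the observations, and
#' (iv) accepts exactly the `floor(n_prior * tolerance_quantile)`
#' lowest-distance pairs.  The accepted set is the joint posterior sample;
#' the overall load of each accepted pair is `1 - (1 - Le)(1 - Ll)`.
#' Deterministic given `seed`.
#'
#' @param observed A `cage_observations` data frame (see
#'   [read_cage_observations()] for the schema).
#' @param params A [life_history()] object.
#' @param prior A [prior_spec()].
#' @param sims_per_level Stochastic replicates simulated per seeding level
#'   per prior draw (default 1).
#' @param seed Integer seed governing both the prior draws and every
#'   simulation.
#' @param verbose Print progress every 1000 draws.
#' @return An object of class `cage_abc` with components `accepted` (data
#'   frame of `load_egg`, `load_longevity`, `distance`, `overall_load`),
#'   `distances` (all draws), `prior`, `params`, `observed`, `seed`, `call`.
#' @seealso [summary.cage_abc()], [predict.cage_abc()]
#' @export
fit_loads <- function(observed, params = life_history(), prior = prior_spec(),
                      sims_per_level = 1L, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(prior, "prior_spec"))
  if (!nrow(observed)) stop("observed series is empty", call. = FALSE)
  if (all(observed$n_transgenic == 0L))
    warning("observed data contain no transgenic larvae at any week; ",
            "the fit is driven by the all-zero series only")

  levels <- sort(unique(observed$seeding_fraction))
  obs_by_level <- lapply(levels, function(l) {
    sub <- observed[observed$seeding_fraction == l, , drop = FALSE]
    list(week = sub$week, p_obs = sub$n_transgenic / sub$n_sampled,
         n_weeks = max(sub$week))
  })

  n <- prior$n_prior
  set.seed(seed)
  le <- runif(n, prior$egg_load_range[1], prior$egg_load_range[2])
  ll <- runif(n, prior$longevity_load_range[1], prior$longevity_load_range[2])

  distances <- numeric(n)
  counter <- 0L
  for (i in seq_len(n)) {
    loads_i <- fitness_loads(le[i], ll[i])
    d <- 0
    for (j in seq_along(levels)) {
      ob <- obs_by_level[[j]]
      for (s in seq_len(sims_per_level)) {
        counter <- counter + 1L
        tr <- run_replicate(levels[j], params, loads_i, n_weeks = ob$n_weeks,
                            seed = seed + 101L + counter)
        d <- d + sum((ob$p_obs - tr$tg_proportion[ob$week])^2)
      }
    }
    distances[i] <- d
    if (verbose && i %% 1000L == 0L)
      message("  ", i, " / ", n, " prior draws")
  }

  m <- floor(n * prior$tolerance_quantile)
  idx <- accept_by_rank(distances, m)
  accepted <- data.frame(load_egg = le[idx], load_longevity = ll[idx],
                         distance = distances[idx])
  accepted$overall_load <- overall_load(accepted$load_egg,
                                        accepted$load_longevity)
  structure(list(accepted = accepted, distances = distances, prior = prior,
                 params = params, observed = observed,
                 sims_per_level = as.integer(sims_per_level),
                 seed = as.integer(seed), call = match.call()),
            class = "cage_abc")
}

#' Write an ABC posterior to CSV (+ optional JSON summary)
#'
#' @param fit A `cage_abc` object.
#' @param path CSV path for the accepted parameter sets.
#' @param json_path Optional path for a JSON summary with the overall-load
#'   posterior median and central 95\% interval.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(fit, path, json_path = NULL) {
  stopifnot(inherits(fit, "cage_abc"))
  header <- sprintf("# cageload %s seed=%d config=%s",
                    as.character(utils::packageVersion("cageload")),
                    fit$seed, config_hash(fit$params))
  con <- file(path, "w")
  writeLines(header, con)
  write.csv(fit$accepted, con, row.names = FALSE, quote = FALSE)
  close(con)
  if (!is.null(json_path)) {
    ol <- fit$accepted$overall_load
    q <- unname(quantile(ol, c(0.025, 0.975), type = 7))
    jsonlite::write_json(list(overall_load_median = median(ol),
                              ci95_low = q[1], ci95_high = q[2],
                              n_prior = fit$prior$n_prior,
                              n_accepted = nrow(fit$accepted)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
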