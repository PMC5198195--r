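#' @export
print.cage_abc <- function(x, ...) {
  cat("ABC rejection fit of transgene fitness loads\n")
  cat(sprintf("  %d accepted of %d prior draws (tolerance quantile %.3g)\n",
              nrow(x$accepted), x$prior$n_prior, x$prior$tolerance_quantile))
  cat(sprintf("  posterior medians: load_egg = %.3f, load_longevity = %.3f, overall = %.3f\n",
              median(x$accepted$load_egg), median(x$accepted$load_longevity),
              median(x$accepted$overall_load)))
  invisible(x)
}

#' Summarize an ABC fit
#'
#' Posterior medians and central 95\% credible intervals for the egg-batch
#' load, the longevity load, and the overall load
#' `1 - (1 - Le)(1 - Ll)`, plus the implied relative genetic fitness
#' `0.5 * (1 - overall load)` (the baseline 0.5 reflects complete male
#' sterility alone).
#'
#' @param object A `cage_abc` object.
#' @param level Credible level for the central interval (default 0.95).
#' @param ... Unused.
#' @return An object of class `summary.cage_abc`.
#' @export
summary.cage_abc <- function(object, level = 0.95, ...) {
  a <- object$accepted
  probs <- c((1 - level) / 2, 0.5, (1 + level) / 2)
  qs <- function(v) setNames(quantile(v, probs, type = 7, names = FALSE),
                             c("lower", "median", "upper"))
  tab <- rbind(load_egg = qs(a$load_egg),
               load_longevity = qs(a$load_longevity),
               overall_load = qs(a$overall_load))
  structure(list(table = tab, level = level,
                 fitness = 0.5 * (1 - qs(a$overall_load)),
                 n_accepted = nrow(a), n_prior = object$prior$n_prior),
            class = "summary.cage_abc")
}

#' @export
print.summary.cage_abc <- function(x, ...) {
  cat(sprintf("Posterior summary (%d accepted / %d prior draws), central %.0f%% intervals\n",
              x$n_accepted, x$n_prior, 100 * x$level))
  print(round(x$table, 4))
  f <- x$fitness
  cat(sprintf("Implied relative genetic fitness: %.3f (%.3f-%.3f); baseline 0.5 without extra load\n",
              f[["median"]], f[["upper"]], f[["lower"]]))
  invisible(x)
}

#' @export
coef.cage_abc <- function(object, ...) {
  c(load_egg = median(object$accepted$load_egg),
    load_longevity = median(object$accepted$load_longevity))
}

#' Plot an ABC posterior
#'
#' Scatter of the accepted (egg-batch load, longevity load) pairs over the
#' prior rectangle, with posterior medians marked.
#'
#' @param x A `cage_abc` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cage_abc <- function(x, ...) {
  a <- x$accepted
  plot(a$load_egg, a$load_longevity,
       xlim = x$prior$egg_load_range, ylim = x$prior$longevity_load_range,
       xlab = "egg-batch load", ylab = "longevity load",
       main = "ABC posterior sample", pch = 19,
       col = grDevices::adjustcolor("steelblue", 0.5), ...)
  abline(v = median(a$load_egg), h = median(a$load_longevity),
         lty = 2, col = "grey40")
  invisible(x)
}

#' Posterior-predictive envelope from an ABC fit
#'
#' Simulates one cage trajectory per accepted parameter pair (or a subsample)
#' at each requested seeding level and returns the central quantile band of
#' the predictive ensemble, week by week.
#'
#' @param object A `cage_abc` object.
#' @param seeding Seeding fractions to predict at; defaults to the levels of
#'   the fitted observations.
#' @param n_weeks Horizon; defaults to the longest observed series per level.
#' @param coverage Central coverage of the band (default 0.95).
#' @param max_draws At most this many accepted pairs are simulated per level.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A named list (one element per seeding level) of `quantile_band`
#'   data frames.
#' @export
predict.cage_abc <- function(object, seeding = NULL, n_weeks = NULL,
                             coverage = 0.95, max_draws = 200L, seed = 1L,
                             ...) {
  if (is.null(seeding)) seeding <- sort(unique(object$observed$seeding_fraction))
  a <- object$accepted
  take <- seq_len(min(nrow(a), max_draws))
  out <- list()
  counter <- 0L
  for (l in seeding) {
    nw <- if (!is.null(n_weeks)) n_weeks else {
      sub <- object$observed[object$observed$seeding_fraction == l, ]
      if (nrow(sub)) max(sub$week) else max(object$observed$week)
    }
    mat <- vapply(take, function(i) {
      counter <<- counter + 1L
      run_replicate(l, object$params,
                    fitness_loads(a$load_egg[i], a$load_longevity[i]),
                    n_weeks = nw, seed = seed + counter)$tg_proportion
    }, numeric(nw))
    out[[as.character(l)]] <- ensemble_quantile_band(mat, coverage)
  }
  out
}

#' Simulate cage trajectories from an ABC posterior
#'
#' Draws `nsim` parameter pairs from the accepted set (with replacement) and
#' simulates one trajectory per pair at the given seeding level.
#'
#' @param object A `cage_abc` object.
#' @param nsim Number of trajectories.
#' @param seed Integer seed.
#' @param seeding Seeding fraction (default: first fitted level).
#' @param n_weeks Horizon (default: longest observed series at that level).
#' @param ... Unused.
#' @return A list of `cage_trajectory` objects.
#' @export
simulate.cage_abc <- function(object, nsim = 1L, seed = 1L, seeding = NULL,
                              n_weeks = NULL, ...) {
  if (is.null(seeding)) seeding <- min(object$observed$seeding_fraction)
  if (is.null(n_weeks)) {
    sub <- object$observed[object$observed$seeding_fraction == seeding, ]
    n_weeks <- if (nrow(sub)) max(sub$week) else max(object$observed$week)
  }
  set.seed(seed)
  idx <- sample.int(nrow(object$accepted), nsim, replace = TRUE)
  lapply(seq_len(nsim), function(k) {
    i <- idx[k]
    run_replicate(seeding, object$params,
                  fitness_loads(object$accepted$load_egg[i],
                                object$accepted$load_longevity[i]),
                  n_weeks = n_weeks, seed = seed + k)
  })
}

#' Residuals of an ABC fit
#'
#' Observed weekly transgenic proportions minus the posterior-predictive
#' median of the matching week and seeding level.
#'
#' @param object A `cage_abc` object.
#' @param max_draws,seed Passed to [predict.cage_abc()].
#' @param ... Unused.
#' @return A numeric vector aligned with the rows of `object$observed`.
#' @export
residuals.cage_abc <- function(object, max_draws = 100L, seed = 1L, ...) {
  bands <- predict(object, max_draws = max_draws, seed = seed)
  obs <- object$observed
  p_obs <- obs$n_transgenic / obs$n_sampled
  pred <- mapply(function(l, w) {
    b <- bands[[as.character(l)]]
    b$center[match(w, b$week)]
  }, obs$seeding_fraction, obs$week)
  p_obs - pred
}

#' Plot a prediction envelope with observations overlaid
#'
#' @param x A `quantile_band` data frame.
#' @param obs Optional `cage_observations` to overlay as points.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.quantile_band <- function(x, obs = NULL, ...) {
  plot(x$week, x$center, type = "n", ylim = c(0, max(x$upper, 0.6)),
       xlab = "week", ylab = "transgenic proportion", ...)
  polygon(c(x$week, rev(x$week)), c(x$lower, rev(x$upper)),
          col = "grey85", border = NA)
  lines(x$week, x$center, lwd = 2)
  if (!is.null(obs))
    points(obs$week, obs$n_transgenic / obs$n_sampled, pch = 19,
           col = "firebrick")
  invisible(x)
}
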