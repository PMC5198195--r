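#' Central quantile bands of a trajectory ensemble
#'
#' Per week, the empirical `(1 - coverage) / 2`, `0.5` and
#' `(1 + coverage) / 2` quantiles of the transgenic proportion across
#' replicates, using the linear-interpolation quantile definition
#' (`stats::quantile` type 7).  With `coverage = 0.95` these are the 95\%
#' central quantile intervals drawn as the prediction envelope around the
#' ensemble median.
#'
#' @param ensemble A `cage_ensemble` (from [run_ensemble()]) or a
#'   weeks-by-replicates numeric matrix of proportions.
#' @param coverage Central coverage in `(0, 1)`; default 0.95.
#' @return A data frame of class `quantile_band` with columns `week`,
#'   `lower`, `center`, `upper`.
#' @examples
#' ens <- run_ensemble(0.5, n_weeks = 5, n_replicates = 50, seed = 1)
#' ensemble_quantile_band(ens)
#' @export
ensemble_quantile_band <- function(ensemble, coverage = 0.95) {
  if (coverage <= 0 || coverage >= 1)
    stop("coverage must lie in (0, 1)", call. = FALSE)
  mat <- if (inherits(ensemble, "cage_ensemble")) ensemble_matrix(ensemble)
         else as.matrix(ensemble)
  if (!length(mat) || !ncol(mat)) stop("empty ensemble", call. = FALSE)
  probs <- c((1 - coverage) / 2, 0.5, (1 + coverage) / 2)
  q <- t(apply(mat, 1L, quantile, probs = probs, type = 7, names = FALSE))
  out <- data.frame(week = seq_len(nrow(mat)), lower = q[, 1],
                    center = q[, 2], upper = q[, 3])
  class(out) <- c("quantile_band", "data.frame")
  out
}

#' Fraction of observed points inside a prediction envelope
#'
#' Quantifies the visual observation-vs-model comparison: the fraction of
#' observed weekly transgenic proportions that fall inside the
#' `[lower, upper]` band of the matching week.
#'
#' @param obs A `cage_observations` data frame (any number of cages; all
#'   rows are pooled).
#' @param bands A `quantile_band` data frame.
#' @return A fraction in `[0, 1]`.
#' @export
envelope_coverage <- function(obs, bands) {
  idx <- match(obs$week, bands$week)
  ok <- !is.na(idx)
  if (!any(ok))
    stop("no overlapping weeks between observations and bands", call. = FALSE)
  p <- obs$n_transgenic[ok] / obs$n_sampled[ok]
  lo <- bands$lower[idx[ok]]
  hi <- bands$upper[idx[ok]]
  mean(p >= lo & p <= hi)
}

#' Write / read quantile-band CSV files
#'
#' @param bands A `quantile_band` data frame.
#' @param path File path.
#' @param seed,params Optional provenance recorded in the header comment.
#' @return `write_bands` returns `path` invisibly; `read_bands` returns a
#'   `quantile_band` data frame.
#' @export
write_bands <- function(bands, path, seed = NA, params = NULL) {
  header <- sprintf("# cageload %s seed=%s config=%s",
                    as.character(utils::packageVersion("cageload")),
                    as.character(seed),
                    if (is.null(params)) "NA" else config_hash(params))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.csv(as.data.frame(bands), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bands
#' @export
read_bands <- function(path) {
  out <- read.csv(path, comment.char = "#")
  class(out) <- c("quantile_band", "data.frame")
  out
}
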