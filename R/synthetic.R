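#' Design of a synthetic cage experiment
#'
#' Describes the layout the generator emulates: seeding levels, replicates per
#' level, the weekly larval screen (200 larvae by default), the termination
#' rule (a cage stops after a run of consecutive transgene-free screens), and
#' the true fitness loads driving the underlying dynamics.
#'
#' @param seeding_levels Vector of initial transgenic fractions, each in
#'   `[0, 1]`; default the 20\% and 50\% release proportions.
#' @param replicates_per_level Cages per seeding level (default 3).
#' @param sample_size Larvae screened for fluorescence each week (default 200).
#' @param max_weeks Hard cap on series length.
#' @param termination_rule Number of consecutive transgene-free screens after
#'   which a cage is terminated (default 2).
#' @param true_loads A [fitness_loads()] object used to generate the data;
#'   the default `(0.3, 0.2)` represents a strain with substantial extra load
#'   beyond male sterility.
#' @param sampling `"binomial"` (default; with-replacement screen of the
#'   weekly harvest proportion) or `"hypergeometric"` (without replacement
#'   from the harvested cohort itself).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(seeding_levels = c(0.2, 0.5),
                              replicates_per_level = 3L,
                              sample_size = 200L,
                              max_weeks = 30L,
                              termination_rule = 2L,
                              true_loads = fitness_loads(0.3, 0.2),
                              sampling = c("binomial", "hypergeometric")) {
  sampling <- match.arg(sampling)
  if (any(seeding_levels < 0) || any(seeding_levels > 1))
    stop("seeding_levels must lie in [0, 1]", call. = FALSE)
  if (sample_size < 1L) stop("sample_size must be >= 1", call. = FALSE)
  if (termination_rule < 1L) stop("termination_rule must be >= 1", call. = FALSE)
  if (max_weeks < 1L) stop("max_weeks must be >= 1", call. = FALSE)
  stopifnot(inherits(true_loads, "fitness_loads"))
  structure(list(seeding_levels = as.numeric(seeding_levels),
                 replicates_per_level = as.integer(replicates_per_level),
                 sample_size = as.integer(sample_size),
                 max_weeks = as.integer(max_weeks),
                 termination_rule = as.integer(termination_rule),
                 true_loads = true_loads,
                 sampling = sampling),
            class = "experiment_design")
}

#' Generate synthetic cage observations
#'
#' For every seeding level and replicate, simulates a cage with
#' [run_replicate()] under the design's true loads, then screens
#' `sample_size` larvae each week: the observed transgenic count is a
#' binomial draw on the weekly harvest proportion (or a hypergeometric draw
#' from the harvested cohort).  Each series is truncated at the first run of
#' `termination_rule` consecutive transgene-free screens (the run itself is
#' kept, as those screens were performed) or at `max_weeks`.  Weeks are
#' 1-based: week 1 is the first post-seeding oviposition.  Deterministic
#' given `seed`.
#'
#' @param design An [experiment_design()].
#' @param params A [life_history()] object.
#' @param seed Integer base seed; each cage derives its own seed by a fixed
#'   increment.
#' @return A data frame of class `cage_observations` with columns
#'   `seeding_fraction`, `replicate`, `week`, `n_sampled`, `n_transgenic`.
#'   The per-cage underlying harvest proportions are attached as attribute
#'   `harvest_proportion` (a numeric column aligned with the rows).
#' @examples
#' obs <- generate_experiment(experiment_design(max_weeks = 10), seed = 11)
#' head(obs)
#' @export
generate_experiment <- function(design = experiment_design(),
                                params = life_history(), seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  rows <- list()
  harv <- list()
  cage <- 0L
  for (li in seq_along(design$seeding_levels)) {
    level <- design$seeding_levels[li]
    for (r in seq_len(design$replicates_per_level)) {
      cage <- cage + 1L
      cage_seed <- seed + 1000L * (cage - 1L)
      tr <- run_replicate(level, params, design$true_loads,
                          n_weeks = design$max_weeks, seed = cage_seed)
      # screening draws continue the replicate's RNG stream, so the whole
      # cage is a deterministic function of cage_seed
      n_obs <- switch(design$sampling,
        binomial = rbinom(length(tr$week), design$sample_size,
                          tr$tg_proportion),
        hypergeometric = {
          k <- pmin(design$sample_size, tr$n_tg + tr$n_wt)
          ifelse(k > 0, rhyper(length(tr$week), tr$n_tg, tr$n_wt, k), 0L)
        })
      last <- series_end(n_obs, design$termination_rule)
      keep <- seq_len(last)
      rows[[cage]] <- data.frame(seeding_fraction = level, replicate = r,
                                 week = tr$week[keep],
                                 n_sampled = design$sample_size,
                                 n_transgenic = as.integer(n_obs[keep]))
      harv[[cage]] <- tr$tg_proportion[keep]
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cage_observations", "data.frame")
  attr(out, "harvest_proportion") <- unlist(harv)
  out
}

# last retained week index under the termination rule: the series stops at
# the end of the first run of `rule` consecutive zero screens
series_end <- function(n_obs, rule) {
  run <- 0L
  for (i in seq_along(n_obs)) {
    run <- if (n_obs[i] == 0L) run + 1L else 0L
    if (run >= rule) return(i)
  }
  length(n_obs)
}

#' Week at which a cage reaches transgene extinction
#'
#' Scans an observed series for the earliest run of `required_consecutive`
#' weeks with zero transgenic larvae and returns the (1-based) index of the
#' first week of that run, or `NA_integer_` if the rule is never met.
#'
#' @param obs A `cage_observations` data frame holding a single cage
#'   (one seeding level and replicate), or any data frame with `week` and
#'   `n_transgenic` columns.
#' @param required_consecutive Length of the transgene-free run (>= 1).
#' @return Integer week index, or `NA_integer_` if not reached.
#' @examples
#' x <- data.frame(week = 1:4, n_transgenic = c(40, 20, 0, 0))
#' extinction_week(x)  # 3
#' @export
extinction_week <- function(obs, required_consecutive = 2L) {
  if (required_consecutive < 1L)
    stop("required_consecutive must be >= 1", call. = FALSE)
  if (!nrow(obs)) stop("empty observation series", call. = FALSE)
  o <- obs[order(obs$week), , drop = FALSE]
  zero <- o$n_transgenic == 0L
  run <- 0L
  for (i in seq_along(zero)) {
    run <- if (zero[i]) run + 1L else 0L
    if (run >= required_consecutive)
      return(o$week[i - required_consecutive + 1L])
  }
  NA_integer_
}

#' Read / write cage observation CSV files
#'
#' The on-disk schema has columns `seeding_fraction`, `replicate`, `week`,
#' `n_sampled`, `n_transgenic` and is shared between the synthetic generator
#' and the ABC fitter, so synthetic data round-trips losslessly into the
#' inference.  Files carry a `#`-prefixed provenance header (package version,
#' seed, config hash) which the reader skips.
#'
#' @param obs A `cage_observations` data frame.
#' @param path File path.
#' @param seed,params Optional provenance recorded in the header comment.
#' @return `write_cage_observations` returns `path` invisibly;
#'   `read_cage_observations` returns a `cage_observations` data frame.
#' @export
write_cage_observations <- function(obs, path, seed = NA, params = NULL) {
  header <- sprintf("# cageload %s seed=%s config=%s",
                    as.character(utils::packageVersion("cageload")),
                    as.character(seed),
                    if (is.null(params)) "NA" else config_hash(params))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.csv(as.data.frame(obs), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cage_observations
#' @export
read_cage_observations <- function(path) {
  out <- read.csv(path, comment.char = "#")
  need <- c("seeding_fraction", "replicate", "week", "n_sampled", "n_transgenic")
  missing <- setdiff(need, names(out))
  if (length(missing))
    stop("observation file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(out$n_transgenic > out$n_sampled) || any(out$n_sampled <= 0))
    stop("invalid observation counts", call. = FALSE)
  class(out) <- c("cage_observations", "data.frame")
  out
}

#' Write / read trajectory CSV files
#'
#' Long-format schema: `replicate`, `seed`, `seeding_fraction`, `week`,
#' `tg_proportion`, `n_tg`, `n_wt`; one block per trajectory.
#'
#' @param x A `cage_trajectory` or `cage_ensemble`.
#' @param path File path.
#' @param params Optional [life_history()] recorded in the header comment.
#' @return `write_trajectories` returns `path` invisibly;
#'   `read_trajectories` returns a data frame.
#' @export
write_trajectories <- function(x, path, params = NULL) {
  trs <- if (inherits(x, "cage_ensemble")) x$trajectories else list(x)
  df <- do.call(rbind, lapply(seq_along(trs), function(i) {
    tr <- trs[[i]]
    data.frame(replicate = i, seed = tr$seed,
               seeding_fraction = tr$seeding_fraction, week = tr$week,
               tg_proportion = tr$tg_proportion, n_tg = tr$n_tg,
               n_wt = tr$n_wt)
  }))
  header <- sprintf("# cageload %s seed=%s config=%s",
                    as.character(utils::packageVersion("cageload")),
                    as.character(trs[[1]]$seed),
                    if (is.null(params)) "NA" else config_hash(params))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  read.csv(path, comment.char = "#")
}
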