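#' Life-history parameters of the cage model
#'
#' Collects every fixed constant of the cage simulation: the Weibull adult
#' survival fit, the truncation age, oviposition eligibility, juvenile
#' development, the weekly restocked cohort, and the oviposition schedule.
#'
#' Defaults follow the published fit of caged \emph{An. gambiae} adult female
#' survival (shape 4.07, scale 23.5 days, all adults dead before day 30) and
#' the standard cage protocol: a cohort of 200 adults restocked weekly,
#' oviposition from age 3 days, juveniles emerging 10--12 days after
#' oviposition.  The pupation-delay vectors `phi_wt` and `phi_tg` give the
#' probability that emergence falls 1, 2 or 3 days after `juvenile_base_days`;
#' their numeric defaults are package defaults (the underlying empirical
#' distributions are not tabulated), chosen so that wild-type mass is
#' concentrated in the first interval and transgenics develop more slowly.
#' Both are fully configurable.
#'
#' @param weibull_shape Weibull shape parameter `k` (dimensionless, > 0).
#' @param weibull_scale Weibull scale parameter `lambda` (days, > 0).
#' @param max_adult_age Age in days at which death is certain; no adult of
#'   this age is ever present.
#' @param min_oviposition_age Minimum age (days) at which a female may
#'   oviposit.
#' @param juvenile_base_days Days from oviposition to the earliest possible
#'   emergence minus one; with the default 9 and delays 1--3, emergence falls
#'   10--12 days after oviposition.
#' @param phi_wt,phi_tg Probability 3-vectors of a pupation delay of 1, 2 or 3
#'   days for wild-type and transgenic juveniles; each must sum to 1.
#' @param cohort_size Number of adults restocked into the cage each week.
#' @param oviposition_interval_days Days between oviposition opportunities.
#' @param initial_age Age (days) at which seeded adults enter the cage; the
#'   default 3 makes them immediately oviposition-eligible, mirroring seeding
#'   with 2--4 day-old virgins.
#' @param pupal_mortality Probability that a restocked female dies between
#'   screening and emergence (independent thinning); 0 by default, as the
#'   model proper ignores it.
#'
#' @return An object of class `life_history` (a validated named list).
#' @examples
#' p <- life_history()
#' p$weibull_scale
#' @export
life_history <- function(weibull_shape = 4.07,
                         weibull_scale = 23.5,
                         max_adult_age = 30L,
                         min_oviposition_age = 3L,
                         juvenile_base_days = 9L,
                         phi_wt = c(0.65, 0.25, 0.10),
                         phi_tg = c(0.45, 0.35, 0.20),
                         cohort_size = 200L,
                         oviposition_interval_days = 7L,
                         initial_age = 3L,
                         pupal_mortality = 0) {
  p <- list(
    weibull_shape = as.numeric(weibull_shape),
    weibull_scale = as.numeric(weibull_scale),
    max_adult_age = as.integer(max_adult_age),
    min_oviposition_age = as.integer(min_oviposition_age),
    juvenile_base_days = as.integer(juvenile_base_days),
    phi_wt = as.numeric(phi_wt),
    phi_tg = as.numeric(phi_tg),
    cohort_size = as.integer(cohort_size),
    oviposition_interval_days = as.integer(oviposition_interval_days),
    initial_age = as.integer(initial_age),
    pupal_mortality = as.numeric(pupal_mortality)
  )
  class(p) <- "life_history"
  validate_life_history(p)
}

validate_life_history <- function(p) {
  stopifnot(inherits(p, "life_history"))
  if (!is.finite(p$weibull_shape) || p$weibull_shape <= 0)
    stop("weibull_shape must be a positive real", call. = FALSE)
  if (!is.finite(p$weibull_scale) || p$weibull_scale <= 0)
    stop("weibull_scale must be a positive real (days)", call. = FALSE)
  for (nm in c("phi_wt", "phi_tg")) {
    phi <- p[[nm]]
    if (length(phi) != 3L || any(phi < 0) || abs(sum(phi) - 1) > 1e-12)
      stop(nm, " must be a length-3 non-negative vector summing to 1",
           call. = FALSE)
  }
  if (!(p$min_oviposition_age > 0L && p$min_oviposition_age < p$max_adult_age))
    stop("need 0 < min_oviposition_age < max_adult_age", call. = FALSE)
  if (p$cohort_size < 1L)
    stop("cohort_size must be >= 1", call. = FALSE)
  if (p$oviposition_interval_days < 1L)
    stop("oviposition_interval_days must be >= 1", call. = FALSE)
  if (p$juvenile_base_days < 0L)
    stop("juvenile_base_days must be >= 0", call. = FALSE)
  if (p$initial_age < 0L || p$initial_age >= p$max_adult_age)
    stop("initial_age must lie in [0, max_adult_age)", call. = FALSE)
  if (p$pupal_mortality < 0 || p$pupal_mortality >= 1)
    stop("pupal_mortality must lie in [0, 1)", call. = FALSE)
  p
}

#' @export
print.life_history <- function(x, ...) {
  cat("Cage life-history parameters\n")
  cat(sprintf("  adult survival : Weibull(shape = %.3g, scale = %.3g days), death certain by day %d\n",
              x$weibull_shape, x$weibull_scale, x$max_adult_age))
  cat(sprintf("  oviposition    : weekly (every %d days) from age %d days\n",
              x$oviposition_interval_days, x$min_oviposition_age))
  cat(sprintf("  cohort         : %d adults restocked per week (females = %d)\n",
              x$cohort_size, x$cohort_size %/% 2L))
  cat(sprintf("  juveniles      : emerge %d-%d days after oviposition\n",
              x$juvenile_base_days + 1L, x$juvenile_base_days + 3L))
  cat(sprintf("  pupation delay : WT (%s)  TG (%s)\n",
              paste(format(x$phi_wt), collapse = ", "),
              paste(format(x$phi_tg), collapse = ", ")))
  invisible(x)
}

#' Fitness loads of the transgene
#'
#' The two additional genetic loads the ABC analysis infers, beyond the
#' intrinsic cost of complete male sterility: `load_egg` scales down the
#' relative egg-batch contribution of transgenic females, and `load_longevity`
#' scales down their longevity (by shrinking the Weibull scale parameter to
#' `lambda * (1 - load_longevity)`).  The longevity load is capped at 0.7,
#' which keeps transgenic female life expectancy above one week so a seeded
#' cage cannot lose all its females before the first oviposition.
#'
#' @param load_egg Egg-batch load in `[0, 1)`.
#' @param load_longevity Longevity load in `[0, 0.7]`.
#' @return An object of class `fitness_loads`.
#' @examples
#' fitness_loads(0.3, 0.2)
#' @seealso [overall_load()] for the combined load.
#' @export
fitness_loads <- function(load_egg = 0, load_longevity = 0) {
  if (!is.finite(load_egg) || load_egg < 0 || load_egg >= 1)
    stop("load_egg must lie in [0, 1)", call. = FALSE)
  if (!is.finite(load_longevity) || load_longevity < 0 || load_longevity > 0.7)
    stop("load_longevity must lie in [0, 0.7]", call. = FALSE)
  structure(list(load_egg = as.numeric(load_egg),
                 load_longevity = as.numeric(load_longevity)),
            class = "fitness_loads")
}

#' @export
print.fitness_loads <- function(x, ...) {
  cat(sprintf("Fitness loads: egg batch %.3f, longevity %.3f (overall %.3f)\n",
              x$load_egg, x$load_longevity,
              overall_load(x$load_egg, x$load_longevity)))
  invisible(x)
}

#' Read a model configuration from JSON or YAML
#'
#' Reads every [life_history()] field (and optionally `load_egg` /
#' `load_longevity`) from a configuration file.  Unknown keys are an error, so
#' typos cannot silently fall back to defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `params` (a `life_history`) and `loads`
#'   (a `fitness_loads`, defaults if absent from the file).
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml", call. = FALSE))
  if (!is.list(raw)) stop("config must be a mapping of fields", call. = FALSE)
  lh_fields <- names(formals(life_history))
  load_fields <- c("load_egg", "load_longevity")
  unknown <- setdiff(names(raw), c(lh_fields, load_fields))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- do.call(life_history, raw[intersect(names(raw), lh_fields)])
  loads <- do.call(fitness_loads, raw[intersect(names(raw), load_fields)])
  list(params = params, loads = loads)
}

#' Write a model configuration to JSON
#'
#' @param params A [life_history()] object.
#' @param loads A [fitness_loads()] object, or `NULL` to omit.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(params, loads = NULL, path) {
  x <- unclass(params)
  if (!is.null(loads)) x <- c(x, unclass(loads))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# FNV-1a over the serialized config, for provenance headers in output files.
config_hash <- function(params, loads = NULL) {
  x <- unclass(params)
  if (!is.null(loads)) x <- c(x, unclass(loads))
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}
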