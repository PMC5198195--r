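#' Weibull survivor function for adult females
#'
#' `S(t) = exp(-(t / lambda_g)^k)` where the genotype-specific scale is
#' `lambda` for wild type and `lambda * (1 - load_longevity)` for transgenics.
#'
#' @param t Age in days (vectorized, >= 0).
#' @param params A [life_history()] object.
#' @param loads A [fitness_loads()] object.
#' @param genotype `"WT"` or `"TG"`.
#' @return Survival probabilities in `[0, 1]`.
#' @export
weibull_survival <- function(t, params = life_history(),
                             loads = fitness_loads(), genotype = c("WT", "TG")) {
  genotype <- match.arg(genotype)
  if (any(t < 0)) stop("age must be non-negative", call. = FALSE)
  lam <- genotype_scale(params, loads, genotype)
  exp(-(t / lam)^params$weibull_shape)
}

genotype_scale <- function(params, loads, genotype) {
  if (genotype == "TG") params$weibull_scale * (1 - loads$load_longevity)
  else params$weibull_scale
}

#' Daily death probability from the discretized Weibull hazard
#'
#' The continuous survival fit is discretized to the day granularity of the
#' simulation: the probability that a female alive at integer age `i` dies
#' before age `i + 1` is `mu_i = (S(i) - S(i + 1)) / S(i)`.  Death is forced
#' (`mu = 1`) at `max_adult_age - 1`, so no adult ever reaches the truncation
#' age -- the discrete counterpart of truncating the fitted survival curve.
#' For shape `k > 1` the hazard is non-decreasing in age.
#'
#' @inheritParams weibull_survival
#' @param age Integer age(s) in days, `0 <= age < max_adult_age`.
#' @return Death probabilities in `(0, 1]`.
#' @examples
#' daily_death_probability(5, life_history(), fitness_loads(), "WT")
#' daily_death_probability(29)  # certain death at the truncation boundary
#' @export
daily_death_probability <- function(age, params = life_history(),
                                    loads = fitness_loads(),
                                    genotype = c("WT", "TG")) {
  genotype <- match.arg(genotype)
  age <- as.integer(age)
  if (any(age < 0L) || any(age >= params$max_adult_age))
    stop("age must lie in [0, max_adult_age)", call. = FALSE)
  s0 <- weibull_survival(age, params, loads, genotype)
  s1 <- weibull_survival(age + 1L, params, loads, genotype)
  mu <- (s0 - s1) / s0
  mu[age == params$max_adult_age - 1L] <- 1
  mu
}

# Full hazard vector mu_0 .. mu_{max-1} for one genotype; the inner loop of
# the simulator uses this instead of repeated calls.
hazard_vector <- function(params, loads, genotype) {
  daily_death_probability(0:(params$max_adult_age - 1L), params, loads,
                          genotype)
}
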