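#' Fitness-effect distribution for a hemizygote pool
#'
#' Describes the spike-and-tails distribution of fitness effects used when
#' drawing a synthetic pool: a point mass of strains with no effect, a
#' half-normal tail of deleterious (haploinsufficient-like) effects and a
#' half-normal tail of beneficial (haploproficient-like) effects. The default
#' spectrum is HI-heavy, with a wider negative than positive tail, as seen in
#' genome-wide hemizygote competitions.
#'
#' @param frac_null Proportion of strains with exactly zero fitness effect.
#' @param frac_neg Proportion of strains with a negative effect.
#' @param frac_pos Proportion of strains with a positive effect.
#' @param sd_neg Half-normal scale of negative effects (h^-1).
#' @param sd_pos Half-normal scale of positive effects (h^-1).
#' @return An object of class `effect_distribution`.
#' @examples
#' effect_distribution()                 # default HI-heavy spectrum
#' effect_distribution(frac_null = 1, frac_neg = 0, frac_pos = 0)  # neutral pool
#' @export
effect_distribution <- function(frac_null = 0.5, frac_neg = 0.25,
                                frac_pos = 0.25, sd_neg = 0.02,
                                sd_pos = 0.01) {
  fr <- c(frac_null, frac_neg, frac_pos)
  if (any(!is.finite(fr)) || any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    stop("frac_null + frac_neg + frac_pos must equal 1 and all be >= 0",
         call. = FALSE)
  if (sd_neg < 0 || sd_pos < 0)
    stop("effect spreads must be >= 0", call. = FALSE)
  structure(list(frac_null = frac_null, frac_neg = frac_neg,
                 frac_pos = frac_pos, sd_neg = sd_neg, sd_pos = sd_pos),
            class = "effect_distribution")
}

#' Draw a synthetic hemizygote pool
#'
#' Samples per-strain specific growth rates `mu = mu_ref + effect`, where the
#' effect is drawn from an [effect_distribution()]: zero for the null
#' fraction, minus the absolute value of a normal draw (scale `sd_neg`) for
#' the deleterious tail and plus the absolute value of a normal draw (scale
#' `sd_pos`) for the beneficial tail. Growth rates are truncated at zero.
#' Initial proportions are uniform unless `p0` is supplied.
#'
#' @param n_strains Number of strains (>= 2).
#' @param effects An [effect_distribution()].
#' @param mu_ref Reference specific growth rate (h^-1), > 0.
#' @param seed Integer seed; the draw is reproducible.
#' @param p0 Optional vector of initial proportions (recycled/normalised).
#' @return A `strain_pool` data frame with columns `strain_id`, `mu`, `p0`,
#'   `true_effect` (the drawn effect before truncation) and `excluded`.
#' @examples
#' pool <- sample_pool(100, effect_distribution(), mu_ref = 0.32, seed = 1)
#' head(pool)
#' @export
sample_pool <- function(n_strains, effects = effect_distribution(),
                        mu_ref = 0.32, seed, p0 = NULL) {
  if (!inherits(effects, "effect_distribution"))
    stop("`effects` must be an effect_distribution()", call. = FALSE)
  if (n_strains < 2) stop("n_strains must be >= 2", call. = FALSE)
  if (mu_ref <= 0) stop("mu_ref must be > 0", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(as.integer(seed))
  comp <- sample(c("null", "neg", "pos"), n_strains, replace = TRUE,
                 prob = c(effects$frac_null, effects$frac_neg,
                          effects$frac_pos))
  eff <- numeric(n_strains)
  n_neg <- sum(comp == "neg"); n_pos <- sum(comp == "pos")
  if (n_neg > 0) eff[comp == "neg"] <- -abs(stats::rnorm(n_neg, 0, effects$sd_neg))
  if (n_pos > 0) eff[comp == "pos"] <-  abs(stats::rnorm(n_pos, 0, effects$sd_pos))
  mu <- pmax(mu_ref + eff, 0)
  if (is.null(p0)) {
    p0 <- rep(1 / n_strains, n_strains)
  } else {
    p0 <- rep_len(as.numeric(p0), n_strains)
    if (any(p0 < 0)) stop("p0 entries must be >= 0", call. = FALSE)
    p0 <- p0 / sum(p0)
  }
  pool <- data.frame(
    strain_id = sprintf("strain%05d", seq_len(n_strains)),
    mu = mu, p0 = p0, true_effect = eff, excluded = FALSE,
    stringsAsFactors = FALSE)
  class(pool) <- c("strain_pool", "data.frame")
  validate_strain_pool(pool)
  pool
}

validate_strain_pool <- function(pool) {
  stopifnot(is.data.frame(pool),
            all(c("strain_id", "mu", "p0") %in% names(pool)))
  if (anyDuplicated(pool$strain_id))
    stop("duplicate strain ids", call. = FALSE)
  if (any(!is.finite(pool$mu)) || any(pool$mu < 0))
    stop("mu entries must be finite and >= 0", call. = FALSE)
  if (any(pool$p0 < 0) || abs(sum(pool$p0) - 1) > 1e-9)
    stop("p0 entries must be >= 0 and sum to 1", call. = FALSE)
  invisible(pool)
}

#' Doubling time of a culture at dilution rate D
#'
#' At steady state the population mean specific growth rate equals the
#' dilution rate, so the population doubling time is `ln(2) / D`.
#'
#' @param D Dilution rate (h^-1), > 0.
#' @return Doubling time in hours.
#' @examples
#' doubling_time(0.2)  # ~3.5 h
#' doubling_time(0.1)  # ~7 h
#' @export
doubling_time <- function(D) {
  if (any(!is.finite(D)) || any(D <= 0))
    stop("D must be > 0", call. = FALSE)
  log(2) / D
}

#' Number of generations elapsed under a dilution-rate trace
#'
#' Integrates `D(t) / ln(2)` over the sampled span (trapezoidal rule), giving
#' the number of population doublings. `D` may be a scalar (constant rate) or
#' a vector matching `times`.
#'
#' @param times Sample times in hours, strictly increasing, length >= 2.
#' @param D Dilution rate trace (h^-1): scalar or vector of `length(times)`.
#' @return Number of generations (population doublings).
#' @examples
#' generations_elapsed(c(0, 65), 0.32)  # about 30 generations
#' @export
generations_elapsed <- function(times, D) {
  if (length(times) < 2)
    stop("need at least two time points", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  D <- rep_len(as.numeric(D), length(times))
  if (any(!is.finite(D)) || any(D < 0))
    stop("D trace must be finite and >= 0", call. = FALSE)
  sum(diff(times) * (utils::head(D, -1) + utils::tail(D, -1)) / 2) / log(2)
}
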