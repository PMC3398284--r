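#' Continuous-culture sampling design
#'
#' Configuration of a chemostat or turbidostat competition: sampling times,
#' replicate structure, measurement depth and noise. In a chemostat the
#' dilution rate is fixed by the operator; in a turbidostat it is feedback
#' controlled and equals the population mean growth rate, so it drifts upward
#' as faster strains take over. The default design is the one used throughout
#' the package: five continuous-culture samples at 24 h spacing, two
#' biological and two technical replicates.
#'
#' @param mode `"turbidostat"` or `"chemostat"`.
#' @param dilution_rate Fixed dilution rate (h^-1); required for chemostat
#'   mode, ignored otherwise.
#' @param sample_times Sampling times in hours, strictly increasing; the
#'   continuous culture starts at 0 h.
#' @param n_bio_reps,n_tech_reps Biological and technical replicate counts.
#' @param depth Cells/reads sampled per measurement (multinomial size), >= 1.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise, >= 0.
#' @param seed Integer base seed; replicate seeds are spawned from it
#'   deterministically.
#' @return An object of class `culture_config`.
#' @export
culture_config <- function(mode = c("turbidostat", "chemostat"),
                           dilution_rate = NULL,
                           sample_times = c(0, 24, 48, 72, 96),
                           n_bio_reps = 2, n_tech_reps = 2,
                           depth = 1e6, noise_cv = 0.2, seed) {
  mode <- match.arg(mode)
  if (length(sample_times) < 2 || any(diff(sample_times) <= 0))
    stop("sample_times must be strictly increasing, length >= 2",
         call. = FALSE)
  if (length(sample_times) < 4)
    warning("fewer than 4 continuous-culture samples; slope estimates will ",
            "have very few residual degrees of freedom")
  if (mode == "chemostat") {
    if (is.null(dilution_rate) || dilution_rate <= 0)
      stop("chemostat mode requires dilution_rate > 0", call. = FALSE)
  }
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (n_bio_reps < 1 || n_tech_reps < 1)
    stop("replicate counts must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  structure(list(mode = mode, dilution_rate = dilution_rate,
                 sample_times = as.numeric(sample_times),
                 n_bio_reps = as.integer(n_bio_reps),
                 n_tech_reps = as.integer(n_tech_reps),
                 depth = depth, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "culture_config")
}

# one base seed deterministically spawns independent sub-seeds (< 2^31)
spawn_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate true strain proportions under replicator dynamics
#'
#' In continuous culture the per-strain abundance obeys dX/dt = (mu - D) X,
#' with D equal to the population mean growth rate at steady state. On
#' proportions this is the replicator equation, whose closed-form solution is
#' `p_i(t) = p_i(0) exp(mu_i t) / sum_j p_j(0) exp(mu_j t)`. The proportion
#' trajectories are the same in both culture modes under this closure; the
#' modes differ only in the reported dilution-rate trace (fixed for a
#' chemostat, population mean `sum_i mu_i p_i(t)` for a turbidostat).
#'
#' @param pool A `strain_pool`.
#' @param config A [culture_config()].
#' @return A `proportion_trajectory`: list with `props` (strain x time matrix,
#'   columns summing to 1), `times`, `D_trace` and `mode`.
#' @export
simulate_proportions <- function(pool, config) {
  validate_strain_pool(pool)
  stopifnot(inherits(config, "culture_config"))
  times <- config$sample_times
  # log-space for numerical stability at long times / large mu spread
  lp <- outer(ifelse(pool$p0 > 0, log(pool$p0), -Inf), rep(1, length(times))) +
    outer(pool$mu, times)
  m <- apply(lp, 2, max)
  w <- exp(sweep(lp, 2, m, "-"))
  props <- sweep(w, 2, colSums(w), "/")
  dimnames(props) <- list(pool$strain_id, paste0("t", times))
  D_trace <- if (config$mode == "turbidostat") {
    as.numeric(crossprod(pool$mu, props))
  } else {
    rep(config$dilution_rate, length(times))
  }
  structure(list(props = props, times = times, D_trace = D_trace,
                 mode = config$mode),
            class = "proportion_trajectory")
}

#' Observe a proportion trajectory with sampling and measurement noise
#'
#' Generates an [abundance_dataset()] from true proportions: for every
#' biological replicate (independent noise seed spawned from the base seed)
#' and technical replicate, counts are drawn from a multinomial of size
#' `depth` at each sample time, then multiplied by lognormal noise with unit
#' mean and coefficient of variation `noise_cv` (emulating hybridisation /
#' measurement variability on top of counting noise).
#'
#' @param traj A `proportion_trajectory` from [simulate_proportions()], or a
#'   strain x time matrix with columns summing to 1 (rownames = strain ids).
#' @param config A [culture_config()].
#' @param experiment Experiment label recorded in the sample sheet.
#' @return An [abundance_dataset()].
#' @export
observe <- function(traj, config, experiment = "SIM") {
  stopifnot(inherits(config, "culture_config"))
  props <- if (inherits(traj, "proportion_trajectory")) traj$props else traj
  if (any(abs(colSums(props) - 1) > 1e-6))
    stop("columns of true proportions must sum to 1", call. = FALSE)
  times <- if (inherits(traj, "proportion_trajectory")) traj$times
           else config$sample_times
  n_s <- nrow(props); n_t <- length(times)
  strains <- rownames(props)
  if (is.null(strains)) strains <- sprintf("strain%05d", seq_len(n_s))
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  bio_seeds <- spawn_seeds(config$seed, config$n_bio_reps)
  cols <- list(); meta <- list(); k <- 0L
  for (b in seq_len(config$n_bio_reps)) {
    set.seed(bio_seeds[b])
    for (j in seq_len(n_t)) {
      for (r in seq_len(config$n_tech_reps)) {
        counts <- as.numeric(stats::rmultinom(1, size = config$depth,
                                              prob = props[, j]))
        if (config$noise_cv > 0)
          counts <- counts * stats::rlnorm(n_s, -sdlog^2 / 2, sdlog)
        k <- k + 1L
        cols[[k]] <- counts
        meta[[k]] <- data.frame(
          sample_id = sprintf("%s_b%d_r%d_%03dh", experiment, b, r, times[j]),
          experiment = experiment, bio_rep = b, tech_rep = r,
          time_h = times[j], stringsAsFactors = FALSE)
      }
    }
  }
  mat <- do.call(cbind, cols)
  samples <- do.call(rbind, meta)
  rownames(mat) <- strains
  colnames(mat) <- samples$sample_id
  abundance_dataset(mat, samples)
}
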