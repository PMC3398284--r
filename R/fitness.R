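#' Fit a single strain's relative growth rate
#'
#' Ordinary least-squares fit of log relative abundance on time with a shared
#' slope and one intercept per replicate series. The slope estimates
#' `mu - D`, the strain's growth-rate deviation from the population average,
#' i.e. its modified flux control coefficient (FCC'). The two-sided P-value
#' for slope != 0 comes from the t distribution with the residual degrees of
#' freedom.
#'
#' @param times Sample times (hours).
#' @param log_abundances Natural log of relative abundance, same length.
#' @param grouping Optional replicate labels (one intercept per level).
#' @return List with `slope`, `stderr`, `p_value`, `n_points`, `df`. A
#'   degenerate design (fewer than 3 finite points, or all times equal, or no
#'   residual degrees of freedom) yields an all-`NA` result, not an error.
#' @examples
#' fit_strain(c(0, 24, 48, 72, 96), 0.02 * c(0, 24, 48, 72, 96))
#' @export
fit_strain <- function(times, log_abundances, grouping = NULL) {
  na_result <- list(slope = NA_real_, stderr = NA_real_, p_value = NA_real_,
                    n_points = 0L, df = NA_real_)
  ok <- is.finite(times) & is.finite(log_abundances)
  if (!is.null(grouping)) ok <- ok & !is.na(grouping)
  t <- times[ok]; y <- log_abundances[ok]
  g <- if (is.null(grouping)) rep(1L, length(t)) else factor(grouping[ok])
  n <- length(t)
  if (n < 3 || length(unique(t)) < 2)
    return(within_n(na_result, n))
  fit <- if (nlevels(factor(g)) > 1)
    stats::lm(y ~ 0 + factor(g) + t) else stats::lm(y ~ t)
  # summary() warns on zero-residual fits; that case is handled explicitly
  sm <- suppressWarnings(summary(fit))$coefficients
  row <- rownames(sm) == "t"
  if (!any(row) || fit$df.residual < 1) return(within_n(na_result, n))
  slope <- unname(sm[row, 1]); se <- unname(sm[row, 2])
  # an (effectively) zero-residual fit: a nonzero slope is unambiguous and a
  # zero slope unremarkable; the threshold only absorbs floating-point noise
  if (se < 1e-12) {
    if (abs(slope) < 1e-12) slope <- 0
    p <- if (slope != 0) 0 else 1
  } else {
    p <- 2 * stats::pt(-abs(slope / se), fit$df.residual)
  }
  list(slope = slope, stderr = se, p_value = p, n_points = n,
       df = fit$df.residual)
}

within_n <- function(res, n) { res$n_points <- as.integer(n); res }

#' Estimate FCC' for every strain in a dataset
#'
#' Per experiment, relative abundances are computed with a pseudocount
#' (default 0.5) and log-transformed; each strain's slope of log relative
#' abundance versus time is then fitted with replicate-specific intercepts
#' (one per biological x technical replicate series) and a shared slope.
#' Samples where the raw abundance is zero are dropped from that strain's
#' regression; strains with fewer than `min_points` nonzero samples in an
#' experiment are flagged insufficient (`NA` class). P-values are adjusted
#' per experiment by Benjamini-Hochberg, and strains are classified
#' haploinsufficient (HI, negative slope), haploproficient (HP, positive
#' slope) or not significant (NS) at FDR < `alpha`.
#'
#' The regression is computed with closed-form within-replicate centering,
#' vectorised over strains; it is algebraically identical to the per-strain
#' [fit_strain()] linear model.
#'
#' @param dataset An [abundance_dataset()] of raw (count-like) abundances.
#' @param pseudocount Added to every cell before normalisation and log.
#' @param min_points Minimum nonzero raw samples required per strain and
#'   experiment.
#' @param alpha FDR threshold for the HI/HP calls.
#' @return A `fitness_result` data frame: `strain_id`, `experiment`,
#'   `fcc_prime`, `stderr`, `n_points`, `df` (residual degrees of freedom),
#'   `p_value`, `fdr`, `hfc_class`.
#' @export
fit_fitness <- function(dataset, pseudocount = 0.5, min_points = 3,
                        alpha = 0.05) {
  stopifnot(inherits(dataset, "abundance_dataset"))
  out <- list()
  for (exp_id in unique(dataset$samples$experiment)) {
    sel <- dataset$samples$experiment == exp_id
    sub <- abundance_dataset(dataset$matrix[, sel, drop = FALSE],
                             dataset$samples[sel, , drop = FALSE])
    res <- fit_experiment(sub, pseudocount, min_points)
    res$experiment <- exp_id
    res$fdr <- bh_fdr(res$p_value)
    out[[exp_id]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- classify(res, alpha = alpha)
  class(res) <- c("fitness_result", "data.frame")
  res
}

# shared-slope, replicate-intercept OLS for all strains at once via
# within-replicate centering
fit_experiment <- function(dataset, pseudocount, min_points) {
  raw <- dataset$matrix
  norm <- normalize_relative(dataset, pseudocount)
  Y <- log(norm$matrix)
  M <- (raw > 0) * 1
  Y[M == 0] <- 0
  tt <- dataset$samples$time_h
  grp <- interaction(dataset$samples$bio_rep, dataset$samples$tech_rep,
                     drop = TRUE)
  Gm <- stats::model.matrix(~ 0 + grp)           # samples x groups
  n_sg <- M %*% Gm
  St_sg <- M %*% (Gm * tt)
  Sy_sg <- Y %*% Gm                              # Y already masked
  inv_n <- ifelse(n_sg > 0, 1 / n_sg, 0)
  Sxx <- as.numeric(M %*% tt^2) - rowSums(St_sg^2 * inv_n)
  Sxy <- as.numeric(Y %*% tt)  - rowSums(St_sg * Sy_sg * inv_n)
  Syy <- rowSums(Y^2 * M)      - rowSums(Sy_sg^2 * inv_n)
  n_i <- rowSums(M)
  g_i <- rowSums(n_sg > 0)
  df <- n_i - g_i - 1
  usable <- n_i >= max(3, min_points) & Sxx > 1e-12 & df >= 1
  slope <- ifelse(usable, Sxy / Sxx, NA_real_)
  rss <- pmax(Syy - Sxy^2 / ifelse(Sxx > 0, Sxx, NA_real_), 0)
  se <- ifelse(usable, sqrt(rss / df / Sxx), NA_real_)
  tval <- slope / se
  p <- ifelse(usable & se > 0, 2 * stats::pt(-abs(tval), df), NA_real_)
  # (effectively) zero residuals, i.e. noiseless data: a nonzero slope is
  # then unambiguous (p -> 0) and a zero slope unremarkable (p -> 1)
  noiseless <- usable & !is.na(se) & se < 1e-12
  slope[noiseless & abs(slope) < 1e-12] <- 0
  p[noiseless & slope != 0] <- 0
  p[noiseless & slope == 0] <- 1
  data.frame(strain_id = dataset$strains,
             fcc_prime = slope, stderr = se,
             n_points = as.integer(n_i), df = ifelse(usable, df, NA_real_),
             p_value = p, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted P-values
#'
#' Step-up false-discovery-rate adjustment across a vector of P-values
#' (wrapper around [stats::p.adjust()] with `method = "BH"`; `NA`s are kept).
#'
#' @param p_values Numeric vector in \[0, 1\] (NA allowed).
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  pv <- p_values[!is.na(p_values)]
  if (any(pv < 0 | pv > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Classify strains as haploinsufficient, haploproficient or neutral
#'
#' HP: positive FCC' with FDR < `alpha`; HI: negative FCC' with FDR <
#' `alpha`; NS otherwise; `NA` where the slope could not be fitted. An exact
#' zero slope is NS regardless of FDR. Summary counts are reported via
#' `message()`.
#'
#' @param results A data frame with columns `fcc_prime` and `fdr`.
#' @param alpha FDR threshold (default 0.05).
#' @return `results` with an `hfc_class` column added/refreshed.
#' @export
classify <- function(results, alpha = 0.05) {
  stopifnot(all(c("fcc_prime", "fdr") %in% names(results)))
  cls <- ifelse(is.na(results$fcc_prime) | is.na(results$fdr), NA_character_,
         ifelse(results$fdr < alpha & results$fcc_prime > 0, "HP",
         ifelse(results$fdr < alpha & results$fcc_prime < 0, "HI", "NS")))
  results$hfc_class <- cls
  message(sprintf("classify: %d HI, %d HP, %d NS, %d NA (alpha = %g)",
                  sum(cls == "HI", na.rm = TRUE),
                  sum(cls == "HP", na.rm = TRUE),
                  sum(cls == "NS", na.rm = TRUE), sum(is.na(cls)), alpha))
  results
}

#' Deviation index: scaled approximate flux control coefficient
#'
#' Scales the fitted growth-rate deviation (`slope = mu - D`) into the
#' deviation index `DI = A * slope` with `A = copy_number / D`, a
#' finite-perturbation approximation to a flux control coefficient. Sign
#' convention: the slope is measured for the copy-number reduction 2 -> 1,
#' so a haploinsufficient strain (negative FCC') indicates *positive* flux
#' control by the gene when copy number is raised from 1 to 2, and a
#' haploproficient strain indicates negative flux control.
#'
#' @param slope Fitted slope `mu - D` (h^-1).
#' @param copy_number Initial gene copy number (> 0; 2 for a diploid).
#' @param D Dilution rate (h^-1), > 0.
#' @return List with `di` and `scaling_a`.
#' @examples
#' deviation_index(-0.01, copy_number = 2, D = 0.32)  # di = -0.0625
#' @export
deviation_index <- function(slope, copy_number, D) {
  if (any(D <= 0)) stop("D must be > 0", call. = FALSE)
  if (any(copy_number <= 0)) stop("copy_number must be > 0", call. = FALSE)
  a <- copy_number / D
  list(di = a * slope, scaling_a = a)
}

#' Write per-strain fitness results as a wide TSV
#'
#' One row per strain, one column group per experiment:
#' `<experiment>.FCC'`, `<experiment>.P`, `<experiment>.FDR`,
#' `<experiment>.class`.
#'
#' @param results A `fitness_result` data frame from [fit_fitness()].
#' @param path Output TSV path.
#' @return The wide data frame, invisibly.
#' @export
write_fitness <- function(results, path) {
  strains <- unique(results$strain_id)
  wide <- data.frame(ORF = strains, stringsAsFactors = FALSE)
  for (exp_id in unique(results$experiment)) {
    sub <- results[results$experiment == exp_id, ]
    idx <- match(strains, sub$strain_id)
    wide[[paste0(exp_id, ".FCC'")]] <- sub$fcc_prime[idx]
    wide[[paste0(exp_id, ".P")]] <- sub$p_value[idx]
    wide[[paste0(exp_id, ".FDR")]] <- sub$fdr[idx]
    wide[[paste0(exp_id, ".class")]] <- sub$hfc_class[idx]
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(wide)
}
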