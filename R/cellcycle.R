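#' Generate a synthetic DNA-content histogram
#'
#' Samples flow-cytometry-like DNA-content events from a three-component
#' mixture: a G1 Gaussian at `g1_mean`, a G2/M Gaussian at `2 * g1_mean`
#' and an S phase whose true DNA content is uniform between the two,
#' broadened by the same proportional measurement CV. Events are binned into
#' a fixed 256-bin histogram.
#'
#' @param frac_g1,frac_s,frac_g2 Phase percentages, summing to 100.
#' @param g1_mean G1 peak position in fluorescence units.
#' @param cv Proportional measurement coefficient of variation (> 0).
#' @param n_events Total events to draw.
#' @param seed Integer seed.
#' @param n_bins Number of histogram bins (default 256).
#' @return A `dna_histogram`: list with `bin_centers`, `counts`, `n_events`.
#' @examples
#' h <- generate_histogram(60, 30, 10, seed = 1)
#' @export
generate_histogram <- function(frac_g1, frac_s, frac_g2, g1_mean = 100,
                               cv = 0.05, n_events = 20000, seed,
                               n_bins = 256) {
  fr <- c(frac_g1, frac_s, frac_g2)
  if (any(fr < 0) || abs(sum(fr) - 100) > 1e-6)
    stop("phase fractions must be >= 0 and sum to 100", call. = FALSE)
  if (cv <= 0) stop("cv must be > 0", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(as.integer(seed))
  n_phase <- as.numeric(stats::rmultinom(1, n_events, fr / 100))
  x <- c(
    stats::rnorm(n_phase[1], g1_mean, cv * g1_mean),
    { u <- stats::runif(n_phase[2], g1_mean, 2 * g1_mean)
      stats::rnorm(n_phase[2], u, cv * u) },
    stats::rnorm(n_phase[3], 2 * g1_mean, cv * 2 * g1_mean))
  breaks <- seq(0, 2.6 * g1_mean, length.out = n_bins + 1)
  x <- pmin(pmax(x, 0), max(breaks))
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  dna_histogram((breaks[-1] + breaks[-length(breaks)]) / 2, counts)
}

#' DNA-content histogram container
#'
#' @param bin_centers Strictly increasing fluorescence bin centres.
#' @param counts Nonnegative event counts per bin.
#' @return A `dna_histogram` object.
#' @export
dna_histogram <- function(bin_centers, counts) {
  if (length(bin_centers) != length(counts))
    stop("bin_centers and counts differ in length", call. = FALSE)
  if (any(diff(bin_centers) <= 0))
    stop("bins must be strictly increasing", call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(list(bin_centers = as.numeric(bin_centers),
                 counts = as.numeric(counts), n_events = sum(counts)),
            class = "dna_histogram")
}

#' Read a DNA-content histogram from a two-column TSV
#'
#' Columns: bin centre, event count (header row expected).
#'
#' @param path TSV path.
#' @return A [dna_histogram()].
#' @export
read_histogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path)
  dna_histogram(tab[[1]], tab[[2]])
}

# smoothed local maxima used to initialise the fit
find_peaks <- function(hist, k = 5) {
  s <- stats::filter(hist$counts, rep(1 / k, k), sides = 2)
  s[is.na(s)] <- 0
  n <- length(s)
  is_max <- c(FALSE, s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n],
              FALSE)
  idx <- which(is_max & s > 0.01 * max(s))
  idx[order(s[idx], decreasing = TRUE)]
}

#' Fit the Dean-Jett-Fox model to a DNA-content histogram
#'
#' Decomposes a DNA-content histogram into a G1 Gaussian, a G2/M Gaussian
#' (mean constrained to `[1.85, 2.15]` times the G1 mean) and an S-phase
#' component modelled as a second-degree polynomial event density over DNA
#' content between the G1 and G2 means, convolved with the proportional
#' measurement Gaussian. Shape parameters (G1 mean, CVs, G2/G1 ratio) are
#' optimised by bounded quasi-Newton search; at each step the component
#' amplitudes solve a linear least-squares problem. Phase fractions are the
#' component areas as percentages of the total model area, so they sum to
#' 100 by construction.
#'
#' Initialisation uses the two largest smoothed local maxima with a position
#' ratio near 2. If no plausible G2 peak exists the fit falls back to a
#' single Gaussian and the result is flagged `degenerate` with %G1 = 100.
#'
#' @param hist A [dna_histogram()] with >= 64 bins and >= 2000 events.
#' @param model `"djf"` (default, with the polynomial S component) or
#'   `"two_gauss"` (G1 + G2 Gaussians only).
#' @return A `dna_fit`: list with `g1_mean`, `g1_cv`, `g2_ratio`, `g2_cv`,
#'   `s_coeffs`, `fractions` (named %G1/%S/%G2M summing to 100),
#'   `fit_residual` (residual sum of squares), `degenerate`, `model`.
#' @export
djf_fit <- function(hist, model = c("djf", "two_gauss")) {
  model <- match.arg(model)
  stopifnot(inherits(hist, "dna_histogram"))
  if (length(hist$bin_centers) < 64)
    stop("histogram needs >= 64 bins", call. = FALSE)
  if (hist$n_events < 2000)
    stop("histogram needs >= 2000 events", call. = FALSE)
  x <- hist$bin_centers; y <- hist$counts
  peaks <- find_peaks(hist)
  if (length(peaks) == 0) stop("no peak found in histogram", call. = FALSE)
  m1_0 <- x[peaks[1]]
  # candidate G2 peak: local max whose position ratio to the other is ~2
  r0 <- NA
  for (p in peaks[-1]) {
    r <- x[p] / m1_0
    if (r > 1.6 && r < 2.5) { r0 <- min(max(r, 1.86), 2.14); break }
    if (r > 0.4 && r < 0.625) {  # picked G2 first; swap
      m1_0 <- x[p]; r0 <- min(max(1 / r, 1.86), 2.14); break
    }
  }
  if (is.na(r0)) {
    fit1 <- fit_single_gaussian(x, y, m1_0)
    return(structure(list(g1_mean = fit1$m, g1_cv = fit1$cv, g2_ratio = NA,
                          g2_cv = NA, s_coeffs = NULL,
                          fractions = c(G1 = 100, S = 0, G2M = 0),
                          fit_residual = fit1$rss, degenerate = TRUE,
                          model = "single_gauss"),
                     class = "dna_fit"))
  }
  obj <- function(th) djf_rss(th, x, y, model)$rss
  th0 <- c(m1 = m1_0, cv1 = 0.06, r = r0, cv2 = 0.06)
  lower <- c(0.85 * m1_0, 0.01, 1.85, 0.01)
  upper <- c(1.15 * m1_0, 0.25, 2.15, 0.25)
  opt <- stats::optim(th0, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper)
  sol <- djf_rss(opt$par, x, y, model)
  areas <- sol$areas
  frac <- 100 * areas / sum(areas)
  structure(list(g1_mean = unname(opt$par[1]), g1_cv = unname(opt$par[2]),
                 g2_ratio = unname(opt$par[3]), g2_cv = unname(opt$par[4]),
                 s_coeffs = sol$s_coeffs,
                 fractions = c(G1 = unname(frac[1]), S = unname(frac[2]),
                               G2M = unname(frac[3])),
                 fit_residual = sol$rss, degenerate = FALSE, model = model),
            class = "dna_fit")
}

# basis construction + linear amplitude solve for fixed shape parameters
djf_rss <- function(th, x, y, model) {
  m1 <- th[1]; cv1 <- th[2]; r <- th[3]; cv2 <- th[4]
  b1 <- stats::dnorm(x, m1, cv1 * m1)
  b2 <- stats::dnorm(x, r * m1, cv2 * r * m1)
  if (model == "djf") {
    u <- seq(m1, r * m1, length.out = 32)
    du <- u[2] - u[1]
    # Gaussian-broadened monomial bases over DNA content u (u scaled by m1
    # for conditioning); columns are bins, rows content grid
    kern <- outer(u, x, function(ui, xi) stats::dnorm(xi, ui, cv1 * ui)) * du
    s0 <- colSums(kern)
    s1 <- colSums(kern * (u / m1))
    s2 <- colSums(kern * (u / m1)^2)
    B <- cbind(b1, b2, s0, s1, s2)
  } else {
    B <- cbind(b1, b2)
  }
  a <- tryCatch(stats::lsfit(B, y, intercept = FALSE)$coefficients,
                error = function(e) rep(0, ncol(B)))
  # Gaussian amplitudes must be nonnegative; refit with an offender removed
  for (i in 1:2) if (a[i] < 0) {
    keep <- setdiff(seq_len(ncol(B)), i)
    a[] <- 0
    a[keep] <- stats::lsfit(B[, keep, drop = FALSE], y,
                            intercept = FALSE)$coefficients
  }
  fitv <- as.numeric(B %*% a)
  rss <- sum((y - fitv)^2)
  # component areas on the bin grid (proportional to event counts)
  area_g1 <- a[1] * sum(b1)
  area_g2 <- a[2] * sum(b2)
  area_s <- if (model == "djf") {
    sdens <- as.numeric(B[, 3:5, drop = FALSE] %*% a[3:5])
    sum(pmax(sdens, 0))
  } else 0
  areas <- pmax(c(area_g1, area_s, area_g2), 0)[c(1, 2, 3)]
  list(rss = rss, areas = c(areas[1], areas[2], areas[3]),
       s_coeffs = if (model == "djf") unname(a[3:5]) else NULL)
}

fit_single_gaussian <- function(x, y, m0) {
  obj <- function(th) {
    b <- stats::dnorm(x, th[1], th[2] * th[1])
    a <- sum(b * y) / sum(b * b)
    sum((y - a * b)^2)
  }
  opt <- stats::optim(c(m0, 0.06), obj, method = "L-BFGS-B",
                      lower = c(0.5 * m0, 0.01), upper = c(1.5 * m0, 0.3))
  list(m = opt$par[1], cv = opt$par[2], rss = opt$value)
}

#' Summarise %G1 across replicates and strains
#'
#' Per-strain mean, standard deviation (sample sd, `NA` for a single
#' replicate) and replicate count of the G1 fraction, plus the grand mean
#' and sd across strain means and a flag for strains deviating from the
#' grand mean by more than one grand sd.
#'
#' @param g1_table Data frame with columns `strain` and `pct_g1` (one row
#'   per replicate fit).
#' @return Data frame `strain`, `mean_g1`, `sd_g1`, `n`, `deviant`, with
#'   attributes `grand_mean` and `grand_sd`.
#' @export
g1_summary <- function(g1_table) {
  stopifnot(all(c("strain", "pct_g1") %in% names(g1_table)))
  sp <- split(g1_table$pct_g1, g1_table$strain)
  out <- data.frame(
    strain = names(sp),
    mean_g1 = vapply(sp, mean, numeric(1)),
    sd_g1 = vapply(sp, function(v) if (length(v) > 1) stats::sd(v)
                   else NA_real_, numeric(1)),
    n = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  gm <- mean(out$mean_g1); gs <- stats::sd(out$mean_g1)
  out$deviant <- if (is.na(gs)) FALSE else abs(out$mean_g1 - gm) > gs
  attr(out, "grand_mean") <- gm
  attr(out, "grand_sd") <- gs
  out
}
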