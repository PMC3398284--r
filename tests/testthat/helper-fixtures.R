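# shared fixture builders; all randomness is seeded by the caller

neutral_effects <- function() {
  effect_distribution(frac_null = 1, frac_neg = 0, frac_pos = 0)
}

# pool with explicit growth rates, uniform p0 unless given
make_pool <- function(mu, p0 = NULL) {
  n <- length(mu)
  if (is.null(p0)) p0 <- rep(1 / n, n)
  pool <- data.frame(strain_id = sprintf("s%04d", seq_len(n)),
                     mu = mu, p0 = p0 / sum(p0), excluded = FALSE,
                     stringsAsFactors = FALSE)
  class(pool) <- c("strain_pool", "data.frame")
  pool
}

# minimal dataset: given matrix and per-sample times, single replicate series
make_dataset <- function(mat, times, experiment = "E1", bio = 1, tech = 1) {
  n <- ncol(mat)
  samples <- data.frame(
    sample_id = sprintf("%s_b%d_r%d_s%d", experiment,
                        rep_len(bio, n), rep_len(tech, n), seq_len(n)),
    experiment = experiment, bio_rep = rep_len(bio, n),
    tech_rep = rep_len(tech, n), time_h = times,
    stringsAsFactors = FALSE)
  colnames(mat) <- samples$sample_id
  abundance_dataset(mat, samples)
}

# brute-force BH step-up: adjusted_i = min_{j >= i} p_(j) * m / j, monotone
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(ps[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force hypergeometric tail by enumeration of the overlap pmf
brute_hyper <- function(k, n, K, N, tail) {
  supp <- max(0, n + K - N):min(n, K)
  pmf <- vapply(supp, function(x)
    choose(K, x) * choose(N - K, n - x) / choose(N, n), numeric(1))
  if (tail == "lower") sum(pmf[supp <= k]) else sum(pmf[supp >= k])
}
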