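test_that("replicator proportions are column-stochastic and seed-stable", {
  for (s in 1:5) {
    pool <- sample_pool(50, effect_distribution(), seed = s)
    cfg <- culture_config(seed = s, sample_times = c(0, 24, 48, 72, 96, 150))
    traj <- simulate_proportions(pool, cfg)
    expect_lt(max(abs(colSums(traj$props) - 1)), 1e-9)
  }
})

test_that("pairwise log-ratio law holds exactly for any two strains", {
  pool <- make_pool(mu = c(0.32, 0.33, 0.1, 0.45), p0 = c(0.4, 0.3, 0.2, 0.1))
  cfg <- suppressWarnings(culture_config(seed = 1, sample_times = c(0, 100)))
  pr <- simulate_proportions(pool, cfg)$props
  # d ln(p_i/p_j)/dt = mu_i - mu_j independent of the rest of the pool
  for (i in 1:3) for (j in (i + 1):4) {
    lr <- log(pr[i, 2] / pr[j, 2]) - log(pr[i, 1] / pr[j, 1])
    expect_equal(lr, (pool$mu[i] - pool$mu[j]) * 100, tolerance = 1e-9)
  }
  # the worked two-strain case: mu = {0.32, 0.33}, equal start, t = 100 h
  two <- make_pool(mu = c(0.32, 0.33), p0 = c(0.5, 0.5))
  p2 <- simulate_proportions(two, cfg)$props
  expect_equal(log(p2[2, 2] / p2[1, 2]) - log(p2[2, 1] / p2[1, 1]), 1.0,
               tolerance = 1e-10)
})

test_that("neutral pools are static and zero-proportion strains stay absorbed", {
  pool <- make_pool(mu = rep(0.3, 6))
  cfg <- culture_config(seed = 1)
  traj <- simulate_proportions(pool, cfg)
  expect_true(all(abs(traj$props - 1 / 6) < 1e-12))
  expect_true(all(abs(traj$D_trace - 0.3) < 1e-12))
  pool0 <- make_pool(mu = c(0.5, 0.3, 0.3), p0 = c(0, 0.5, 0.5))
  traj0 <- simulate_proportions(pool0, cfg)
  expect_true(all(traj0$props[1, ] == 0))
})

test_that("turbidostat dilution trace rises toward the dominant growth rate", {
  pool <- make_pool(mu = c(0.40, 0.32, 0.30, 0.25))
  cfg <- culture_config(seed = 1, sample_times = seq(0, 400, by = 50))
  traj <- simulate_proportions(pool, cfg)
  expect_true(all(diff(traj$D_trace) >= -1e-12))
  expect_equal(traj$D_trace[length(traj$D_trace)], 0.40, tolerance = 1e-3)
})

test_that("chemostat and turbidostat share proportion trajectories", {
  pool <- sample_pool(30, effect_distribution(), seed = 4)
  turb <- culture_config("turbidostat", seed = 2)
  chem <- culture_config("chemostat", dilution_rate = 0.3, seed = 2)
  expect_equal(simulate_proportions(pool, turb)$props,
               simulate_proportions(pool, chem)$props)
  expect_equal(simulate_proportions(pool, chem)$D_trace, rep(0.3, 5))
})

test_that("closed form matches fourth-order numerical integration", {
  skip_if_not_installed("deSolve")
  for (s in 1:3) {
    pool <- sample_pool(10, effect_distribution(), seed = s)
    cfg <- culture_config(seed = s)
    closed <- simulate_proportions(pool, cfg)$props
    rhs <- function(t, p, parms) {
      mu <- parms$mu
      list(p * (mu - sum(mu * p)))
    }
    num <- deSolve::ode(y = pool$p0, times = cfg$sample_times, func = rhs,
                        parms = list(mu = pool$mu), method = "rk4",
                        hini = 0.01)
    numv <- t(num[, -1])
    expect_lt(max(abs(numv - closed) / pmax(closed, 1e-300)), 1e-6)
  }
})

test_that("observation is reproducible and converges in the noiseless limit", {
  pool <- sample_pool(40, effect_distribution(), seed = 5)
  cfg <- culture_config(seed = 11, depth = 1e7, noise_cv = 0)
  traj <- simulate_proportions(pool, cfg)
  a <- observe(traj, cfg, "E1")
  b <- observe(traj, cfg, "E1")
  expect_identical(a$matrix, b$matrix)
  props <- sweep(a$matrix, 2, colSums(a$matrix), "/")
  idx <- match(a$samples$time_h, traj$times)
  expect_lt(max(abs(props - traj$props[, idx])), 1e-3)
  # sample sheet covers the full design
  expect_equal(nrow(a$samples), 5 * 2 * 2)
  expect_setequal(unique(a$samples$bio_rep), 1:2)
  expect_setequal(unique(a$samples$tech_rep), 1:2)
})

test_that("low depth produces zeros at the multinomial-expected rate", {
  pool <- sample_pool(5800, neutral_effects(), seed = 6)
  cfg <- culture_config(seed = 12, depth = 1000, noise_cv = 0)
  ds <- observe(simulate_proportions(pool, cfg), cfg, "E1")
  nonzero <- mean(ds$matrix > 0)
  expected <- mean(1 - (1 - pool$p0)^1000)
  expect_gt(sum(ds$matrix == 0), 0)
  expect_equal(nonzero, expected, tolerance = 0.02)
})

test_that("culture_config rejects invalid designs", {
  expect_error(culture_config(depth = 0, seed = 1), "depth")
  expect_error(culture_config(noise_cv = -1, seed = 1), "noise_cv")
  expect_error(culture_config(sample_times = c(0, 0, 24), seed = 1),
               "increasing")
  expect_error(culture_config("chemostat", seed = 1), "dilution_rate")
  expect_warning(culture_config(sample_times = c(0, 24, 48), seed = 1),
                 "fewer than 4")
})
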