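test_that("a noiseless exponential series is fitted exactly", {
  tt <- c(0, 24, 48, 72, 96)
  fit <- fit_strain(tt, 0.02 * tt - 3)
  expect_equal(fit$slope, 0.02, tolerance = 1e-12)
  expect_lt(fit$stderr, 1e-12)
  expect_lt(fit$p_value, 1e-10)
  # constant series: zero slope, uninformative p
  flat <- fit_strain(tt, rep(-2.5, 5))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$p_value, 1)
})

test_that("degenerate designs return NA results rather than erroring", {
  expect_true(is.na(fit_strain(c(0, 24), c(1, 2))$slope))
  expect_true(is.na(fit_strain(rep(24, 5), rnorm(5))$slope))
  expect_true(is.na(fit_strain(c(0, 24, 48), c(1, NA, NA))$slope))
})

test_that("replicate-intercept pooling recovers a shared slope", {
  tt <- rep(c(0, 24, 48, 72), 2)
  grp <- rep(c("b1", "b2"), each = 4)
  y <- 0.015 * tt + ifelse(grp == "b1", -1, -4)   # offset replicate series
  fit <- fit_strain(tt, y, grp)
  expect_equal(fit$slope, 0.015, tolerance = 1e-12)
  expect_equal(fit$df, 8 - 3)
})

test_that("vectorised dataset fit is identical to the per-strain linear model", {
  pool <- sample_pool(60, effect_distribution(), seed = 21)
  cfg <- culture_config(seed = 22, depth = 5e3)  # low depth -> zero counts
  ds <- observe(simulate_proportions(pool, cfg), cfg, "E1")
  res <- suppressMessages(fit_fitness(ds))
  norm <- normalize_relative(ds, 0.5)
  grp <- interaction(ds$samples$bio_rep, ds$samples$tech_rep)
  for (i in seq_len(nrow(ds$matrix))) {
    sel <- ds$matrix[i, ] > 0
    if (sum(sel) < 3) {
      expect_true(is.na(res$fcc_prime[i]))
      next
    }
    ref <- fit_strain(ds$samples$time_h[sel], log(norm$matrix[i, sel]),
                      grp[sel])
    if (is.na(ref$slope)) {
      expect_true(is.na(res$fcc_prime[i]))
    } else {
      expect_equal(res$fcc_prime[i], ref$slope, tolerance = 1e-9)
      expect_equal(res$stderr[i], ref$stderr, tolerance = 1e-9)
      expect_equal(res$p_value[i], ref$p_value, tolerance = 1e-9)
    }
  }
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(-0.1), "\\[0, 1\\]")
  # adjusted values never fall below the raw p-values
  set.seed(7)
  p <- runif(50)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("classification follows sign and FDR threshold", {
  res <- data.frame(fcc_prime = c(0.01, -0.01, 0.01, 0, NA),
                    fdr = c(0.001, 0.001, 0.2, 0.001, NA))
  out <- suppressMessages(classify(res, alpha = 0.05))
  expect_equal(out$hfc_class, c("HP", "HI", "NS", "NS", NA))
})

test_that("deviation index scales the slope by copy number over D", {
  di <- deviation_index(-0.01, copy_number = 2, D = 0.32)
  expect_equal(di$scaling_a, 6.25)
  expect_equal(di$di, -0.0625)
  expect_equal(deviation_index(0, 2, 0.32)$di, 0)
  half <- deviation_index(-0.01, 2, 0.64)
  expect_equal(half$di, di$di / 2)
  expect_error(deviation_index(0.1, 2, 0), "D must be")
  expect_error(deviation_index(0.1, 0, 0.32), "copy_number")
})

test_that("fitness tables are written one column group per experiment", {
  pool <- sample_pool(30, effect_distribution(), seed = 31)
  cfg <- culture_config(seed = 32)
  ds1 <- observe(simulate_proportions(pool, cfg), cfg, "N01")
  cfg2 <- culture_config(seed = 33)
  ds2 <- observe(simulate_proportions(pool, cfg2), cfg2, "N02")
  both <- abundance_dataset(cbind(ds1$matrix, ds2$matrix),
                            rbind(ds1$samples, ds2$samples))
  res <- suppressMessages(fit_fitness(both))
  expect_setequal(unique(res$experiment), c("N01", "N02"))
  p <- withr::local_tempfile(fileext = ".tsv")
  wide <- write_fitness(res, p)
  expect_true(all(c("ORF", "N01.FCC'", "N01.P", "N01.FDR", "N01.class",
                    "N02.FCC'") %in% names(wide)))
  expect_equal(nrow(wide), 30)
  expect_true(file.exists(p))
})
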