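test_that("hypergeometric tails match brute-force enumeration", {
  # worked small case: N=10, K=5, n=4, P(X <= 1) = 55/210
  expect_equal(hypergeom_overlap(1, 4, 5, 10, "lower"), 55 / 210,
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:50) {
    N <- sample(2:25, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    expect_equal(hypergeom_overlap(k, n, K, N, "lower"),
                 brute_hyper(k, n, K, N, "lower"), tolerance = 1e-12)
    expect_equal(hypergeom_overlap(k, n, K, N, "upper"),
                 brute_hyper(k, n, K, N, "upper"), tolerance = 1e-12)
  }
})

test_that("adjacent tails are complementary and edge cases are total", {
  set.seed(12)
  for (i in 1:20) {
    N <- sample(5:200, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(max(0, n + K - N):(min(n, K) - 1), 1)
    expect_equal(hypergeom_overlap(k, n, K, N, "lower") +
                 hypergeom_overlap(k + 1, n, K, N, "upper"), 1,
                 tolerance = 1e-12)
  }
  expect_equal(hypergeom_overlap(0, 4, 5, 10, "upper"), 1)
  expect_equal(hypergeom_overlap(min(4, 5), 4, 5, 10, "lower"), 1)
  expect_error(hypergeom_overlap(6, 4, 5, 10, "lower"), "inconsistent")
  expect_error(hypergeom_overlap(1, 11, 5, 10, "lower"), "inconsistent")
})

test_that("logistic enrichment finds no signal in random sets", {
  set.seed(21)
  scores <- setNames(rnorm(1000, 0, 0.02), sprintf("g%04d", 1:1000))
  sets <- lapply(1:8, function(i) sample(names(scores), 50))
  names(sets) <- paste0("null", 1:8)
  res <- lr_enrichment(scores, sets)
  expect_equal(nrow(res), 8)
  expect_true(all(res$fdr > 0.05))
  expect_lt(max(abs(res$coeff)), 1)
})

test_that("a top-scoring set is called enriched in the HP direction", {
  set.seed(22)
  scores <- setNames(rnorm(1000, 0, 0.02), sprintf("g%04d", 1:1000))
  top <- names(sort(scores, decreasing = TRUE))[1:20]
  res <- lr_enrichment(scores, list(top20 = top))
  expect_gt(res$coeff, 0)
  expect_lt(res$p_value, 0.01)
  # direction cross-check: rank-separation (Mann-Whitney) on the same data
  w <- wilcox.test(scores[top], scores[setdiff(names(scores), top)],
                   alternative = "greater")
  expect_lt(w$p.value, 0.001)
  # a bottom-scoring set points the other way
  bot <- names(sort(scores))[1:20]
  res2 <- lr_enrichment(scores, list(bot = bot))
  expect_lt(res2$coeff, 0)
})

test_that("beta sign tracks the set-vs-complement mean FCC' difference", {
  set.seed(23)
  scores <- setNames(rnorm(800, 0, 0.02), sprintf("g%04d", 1:800))
  for (i in 1:10) {
    memb <- sample(names(scores), 60)
    res <- lr_enrichment(scores, list(s = memb))
    d <- mean(scores[memb]) - mean(scores[setdiff(names(scores), memb)])
    pooled_se <- sqrt(var(scores[memb]) / 60 +
                      var(scores[setdiff(names(scores), memb)]) / 740)
    if (abs(d) > pooled_se) expect_equal(sign(res$coeff), sign(d))
  }
})

test_that("balanced symmetric membership has a near-zero coefficient", {
  scores <- setNames(seq(-0.03, 0.03, length.out = 200),
                     sprintf("g%03d", 1:200))
  memb <- names(scores)[c(1:50, 151:200)]   # both extremes, symmetric
  res <- lr_enrichment(scores, list(sym = memb))
  expect_lt(abs(res$coeff), 0.1)
})

test_that("universe handling: small sets skipped, outside members warned", {
  scores <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  sets <- list(tiny = names(scores)[1:2],
               stray = c(names(scores)[1:10], "not_a_gene"))
  expect_warning(res <- lr_enrichment(scores, sets), "dropped")
  expect_equal(res$set_id, "stray")
  expect_equal(res$n_genes, 10)
  expect_error(lr_enrichment(setNames(numeric(0), character(0)), sets),
               "empty universe")
})

test_that("GMT round trip preserves sets and descriptions", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("GO:1\tribosome biogenesis\tg1\tg2\tg3",
               "GO:2\ttransport\tg2\tg4"), p)
  sets <- read_gmt(p)
  expect_equal(names(sets), c("GO:1", "GO:2"))
  expect_equal(as.character(sets[["GO:1"]]), c("g1", "g2", "g3"))
  expect_equal(attr(sets[["GO:2"]], "description"), "transport")
})

test_that("class frequency table reproduces category HI percentages", {
  # universe of 5713 scored genes, 1932 HI; a 123-gene category with 31 HI
  # and a 502-gene category with 167 HI
  N <- 5713; K <- 1932
  cls <- rep("NS", N)
  cls[1:K] <- "HI"
  ids <- sprintf("g%05d", 1:N)
  names(cls) <- ids
  part <- rep("other", N)
  part[c(1:31, (K + 1):(K + 92))] <- "comp"         # 123 genes, 31 HI
  part[c(32:198, (K + 93):(K + 427))] <- "nocomp"   # 502 genes, 167 HI
  names(part) <- ids
  tab <- class_frequency_table(cls, part)
  comp <- tab[tab$category == "comp", ]
  nocomp <- tab[tab$category == "nocomp", ]
  expect_equal(comp$n, 123); expect_equal(comp$n_hi, 31)
  expect_equal(round(comp$pct_hi), 25)
  expect_equal(nocomp$n, 502); expect_equal(nocomp$n_hi, 167)
  expect_equal(round(nocomp$pct_hi), 33)
  expect_equal(round(attr(tab, "universe_pct_hi")), 34)
  expect_equal(comp$p_hi_deplete,
               hypergeom_overlap(31, 123, 1932, 5713, "lower"))
  # a category equal to the whole universe has the genome-wide frequency and
  # its depletion tail covers the full distribution
  whole <- class_frequency_table(cls, setNames(rep("all", N), ids))
  expect_equal(whole$pct_hi, 100 * K / N)
  expect_equal(whole$p_hi_deplete, 1)
  expect_error(class_frequency_table(cls, part[-1]), "align")
})
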