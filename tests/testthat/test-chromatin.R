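# TF-IDF, gene-peak links, openness, classification and binding scores.

test_that("TF-IDF normalization matches the log-smoothed variant", {
  counts <- rbind(c(2, 0, 1), c(1, 1, 1), c(0, 2, 1))
  out <- tfidf_normalize(counts)
  n <- 3
  idf <- log(1 + n / (1 + c(2, 2, 3)))
  expect_equal(out[1, ], (counts[1, ] / 3) * idf)
  expect_equal(out[counts == 0], c(0, 0))
  # peak-column order irrelevant
  expect_equal(tfidf_normalize(counts[, c(3, 1, 2)]), out[, c(3, 1, 2)])
  # ubiquitous peak tends to log(2)
  big <- matrix(1, 500, 1)
  expect_equal(tfidf_normalize(big)[1, 1], log(1 + 500 / 501), tolerance = 1e-3)
  # sparse input agrees with dense
  sp <- tfidf_normalize(Matrix::Matrix(counts, sparse = TRUE))
  expect_equal(as.matrix(sp), out, ignore_attr = TRUE)
  expect_error(tfidf_normalize(rbind(c(0, 0), c(1, 1))), "all-zero")
})

test_that("gene-peak links retain strong positive correlations only", {
  set.seed(10)
  m <- 60
  e <- rnorm(m)
  access <- cbind(p_pos = e + rnorm(m, sd = 1e-3),
                  p_neg = -e + rnorm(m, sd = 1e-3),
                  p_null = rnorm(m))
  expr <- cbind(g = e)
  pairs <- data.frame(gene = "g", peak = colnames(access))
  links <- gene_peak_correlation(expr, access, pairs, B = 199, seed = 1)
  expect_gt(links$corr[1], 0.99)
  expect_equal(links$p[1], 1 / 200)
  expect_true(links$linked[1])
  expect_lt(links$corr[2], -0.99)  # anti-correlated: excluded by the one-sided rule
  expect_false(links$linked[2])
})

test_that("the permutation null is calibrated on independent data", {
  set.seed(20)
  reps <- 60
  kept <- vapply(seq_len(reps), function(r) {
    e <- cbind(g = rnorm(50))
    a <- cbind(p = rnorm(50))
    l <- gene_peak_correlation(e, a, data.frame(gene = "g", peak = "p"),
                               B = 199, seed = r)
    l$linked
  }, logical(1))
  expect_lte(mean(kept), 0.15)
})

test_that("Poisson openness matches a term-summation oracle", {
  counts <- setNames(c(7, 5, 0, 12), paste0("p", 1:4))
  # 10 peaks at 100k fragments: effective length 50k, lambda 2
  open <- peak_openness(c(counts, rep(24994, 4)), num_peaks = 10)
  lambda <- 100000 / 50000
  oracle <- vapply(counts, function(n)
    (1 - sum(dpois(0:n, lambda))) < 1e-2, logical(1))
  expect_identical(open[1:4], oracle)
  expect_true(open[["p1"]])   # P(X > 7 | lambda 2) ~ 0.0011
  expect_false(open[["p2"]])  # P(X > 5 | lambda 2) ~ 0.0166
  expect_error(peak_openness(c(0, 0)), "zero total")
})

test_that("peak classification follows the openness-in-reference logic", {
  links <- data.frame(gene = "g", peak = c("a", "b", "c", "d"),
                      corr = c(0.5, 0.5, 0.5, 0.05),
                      p = 0.01, linked = c(TRUE, TRUE, TRUE, FALSE))
  cls <- classify_peaks(links, lineage_relevant = c("a", "b", "d"),
                        reference_open = c(a = TRUE, b = FALSE, c = TRUE, d = TRUE))
  expect_equal(cls$class, c("primed", "lineage_specific", "excluded", "excluded"))
})

test_that("accessibility scores are correlation-weighted averages", {
  links <- data.frame(gene = "g", peak = c("p1", "p2"), corr = c(0.2, 0.6),
                      p = 0.01, linked = TRUE, class = "primed")
  access <- matrix(c(0.4, 0.8), 1, dimnames = list("c1", c("p1", "p2")))
  expect_equal(unname(accessibility_scores(access, links, "g", "primed")),
               (0.4 * 0.2 + 0.8 * 0.6) / 0.8)
  one <- links[1, ]
  expect_equal(unname(accessibility_scores(access, one, "g", "primed")), 0.4)
  # weight rescaling cancels
  links2 <- links; links2$corr <- links$corr * 7
  expect_equal(accessibility_scores(access, links2, "g", "primed"),
               accessibility_scores(access, links, "g", "primed"))
  expect_message(na_out <- accessibility_scores(access, links, "g", "lineage_specific"),
                 "no lineage_specific")
  expect_true(all(is.na(na_out)))
})

test_that("in-silico ChIP reproduces the worked example and its invariances", {
  s <- matrix(c(5, 10), 2, 1)
  rho <- matrix(c(0.5, 0.8), 2, 1)
  x <- insilico_chip(rho, s, max_access = c(1, 1))
  expect_equal(drop(x), c(0, 0.8))
  # negative correlation on the top peak propagates as repressive
  x2 <- insilico_chip(matrix(c(0.5, -0.8), 2, 1), s, c(1, 1))
  expect_equal(x2[2, 1], -0.8)
  # motif-score rescaling cancels in the minmax
  expect_equal(insilico_chip(rho, s * 13, c(1, 1)), x)
  # sub-threshold magnitudes are exactly zero
  x3 <- insilico_chip(matrix(c(0.5, 0.14), 2, 1), s, c(1, 1))
  expect_identical(x3[2, 1], 0)
  expect_warning(insilico_chip(matrix(0.5), matrix(3), 1), "degenerate")
})
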