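# The three frozen samples below were checked against an independent
# implementation of the composite Anderson-Darling test (estimated mean and
# variance, size-corrected p approximation); the p-values are frozen here.
test_that("Anderson-Darling statistic and p match the frozen oracle", {
  x1 <- c(0.1, 0.5, 0.9, 1.3, 2.2, 2.4, 3.1, 3.3, 4.0, 4.6)
  x2 <- c(0.05, 0.1, 0.2, 0.25, 0.4, 0.7, 1.1, 1.9, 3.5, 6.0, 7.2, 9.9)
  g1 <- normality_test(x1)
  g2 <- normality_test(x2)
  g3 <- normality_test(1:25)
  expect_equal(g1$statistic, 0.18372923, tolerance = 1e-6)
  expect_equal(g1$p, 0.88063419, tolerance = 1e-6)
  expect_true(g1$is_normal)
  expect_equal(g2$p, 0.00393617, tolerance = 1e-5)
  expect_false(g2$is_normal)
  expect_equal(g3$p, 0.64822798, tolerance = 1e-6)
})

test_that("the gate defaults to nonparametric when it cannot decide", {
  expect_warning(g <- normality_test(c(1, 2, 3, 4, 5)), "fewer than 8")
  expect_false(g$is_normal)
  expect_warning(gc <- normality_test(rep(2, 12)), "constant")
  expect_false(gc$is_normal)
})

test_that("gate routes clearly normal and clearly skewed data correctly", {
  set.seed(11)
  expect_true(normality_test(rnorm(500))$is_normal)
  expect_false(normality_test(rexp(500))$is_normal)
})

test_that("summaries format per the gate and round-trip", {
  expect_equal(as.character(summarize_sample(c(1, 2, 3), normal = TRUE)),
               "2.00 ± 1.00")
  expect_equal(as.character(summarize_sample(1:9, normal = FALSE)),
               "5.00 (3.00;7.00)")
  expect_error(summarize_sample(numeric(0)), "empty")
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(20, mean = runif(1, -50, 50), sd = runif(1, 0.1, 10))
    for (nrm in c(TRUE, FALSE)) {
      s <- summarize_sample(x, normal = nrm, digits = 2)
      v <- parse_summary(s)
      expect_equal(unname(v), round(attr(s, "values"), 2))
    }
  }
})

test_that("independent comparisons pick the gated test", {
  set.seed(21)
  a <- rnorm(50); b <- rnorm(50, 3)
  r <- compare_independent(a, b)
  expect_equal(r$test_used, "two_sample_t")
  expect_true(r$significant)
  r0 <- compare_independent(a, a)
  expect_gt(r0$p_value, 0.9)
  e1 <- rexp(50); e2 <- rexp(50) + 2
  rs <- compare_independent(e1, e2)
  expect_equal(rs$test_used, "mann_whitney")
  expect_true(rs$significant)
  expect_error(compare_independent(c(1, 2), b), "at least 3")
})

test_that("paired comparisons gate on the differences", {
  set.seed(31)
  a <- rnorm(30, 10)
  r_same <- compare_paired(a, a)
  expect_false(r_same$significant)
  r_shift <- compare_paired(a, a + rnorm(30, 0.5, 0.1))
  expect_equal(r_shift$test_used, "paired_t")
  expect_true(r_shift$significant)
  # strongly skewed differences take the signed-rank path
  r_skew <- compare_paired(a, a + rexp(30)^2)
  expect_equal(r_skew$test_used, "wilcoxon_signed_rank")
  names(a) <- paste0("s", 1:30)
  b <- a; names(b)[30] <- "zz"
  expect_error(compare_paired(a, b), "zz")
  expect_error(compare_paired(a[1:5], a[1:4]), "length")
})

test_that("spearman correlation recovers monotone relations", {
  x <- 1:20
  expect_equal(spearman_correlation(x, x^3)$rho, 1)
  expect_equal(spearman_correlation(x, -sqrt(x))$rho, -1)
  expect_error(spearman_correlation(x, rep(1, 20)), "constant")
  expect_error(spearman_correlation(1:4, 1:4), "at least 5")
})

test_that("protocol merge requires all six parameters and no significance", {
  mk <- function(p) {
    r <- compare_independent(rnorm(20), rnorm(20), "x")
    r$p_value <- p
    r$significant <- p < 0.05
    r
  }
  params <- c("thickness", "opening_angle", "inner_curvature",
              "outer_curvature", "inner_length", "outer_length")
  res <- setNames(lapply(rep(0.3, 6), mk), params)
  m <- protocol_merge_decision(res)
  expect_true(m$merge)
  res$inner_curvature <- mk(0.01)
  m2 <- protocol_merge_decision(res)
  expect_false(m2$merge)
  expect_equal(m2$offending, "inner_curvature")
  expect_error(protocol_merge_decision(res[-2]), "opening_angle")
})

test_that("holm adjustment only increases p-values", {
  set.seed(9)
  res <- lapply(1:4, function(i)
    compare_independent(rnorm(20), rnorm(20, i / 4)))
  adj <- holm_adjust(res)
  for (i in 1:4) {
    expect_gte(adj[[i]]$p_value, res[[i]]$p_value)
  }
})
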