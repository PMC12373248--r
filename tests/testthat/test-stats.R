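test_that("descriptive statistics match the closed form", {
  d <- descriptive_stats(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  half <- stats::qt(0.975, 2) / sqrt(3)
  expect_equal(d$ci_low, 2 - half, tolerance = 1e-12)
  expect_equal(d$ci_high, 2 + half, tolerance = 1e-12)
  expect_equal(round(c(d$ci_low, d$ci_high), 3), c(-0.484, 4.484))
  dc <- descriptive_stats(rep(5, 4))
  expect_equal(c(dc$sd, dc$ci_low, dc$ci_high), c(0, 5, 5))
  expect_error(descriptive_stats(1), "n >= 2")
})

test_that("paired t matches the brute-force formula", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    a <- stats::rnorm(n, sd = 3)
    b <- a + stats::rnorm(n, mean = 0.4)
    res <- paired_t(a, b)
    d <- a - b
    t_or <- mean(d) / (stats::sd(d) / sqrt(n))
    p_or <- 2 * stats::pt(-abs(t_or), n - 1)
    expect_equal(res$t, t_or, tolerance = 1e-12)
    expect_equal(res$df, n - 1)
    expect_equal(res$p, p_or, tolerance = 1e-12)
    # sign symmetry
    res2 <- paired_t(b, a)
    expect_equal(res2$t, -res$t, tolerance = 1e-12)
    expect_equal(res2$p, res$p, tolerance = 1e-12)
  }
  expect_equal(paired_t(c(1, 2, 3), c(1, 2, 3)), list(t = 0, df = 2, p = 1))
  r3 <- paired_t(c(1, 2, 3), c(0, 0, 0))  # d = (1, 2, 3)
  expect_equal(r3$t, sqrt(3) * 2, tolerance = 1e-9)  # t = 2/(1/sqrt(3))
  expect_equal(r3$df, 2)
  expect_error(paired_t(1, 1), "n >= 2")
  expect_error(paired_t(c(1, 2), c(0, 1)), "constant and nonzero")
})

test_that("Welch t matches the closed form and is antisymmetric", {
  set.seed(12)
  for (i in 1:200) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    g1 <- stats::rnorm(n1, 1, 2); g2 <- stats::rnorm(n2, 0, 0.5)
    res <- independent_t(g1, g2)
    v1 <- stats::var(g1) / n1; v2 <- stats::var(g2) / n2
    t_or <- (mean(g1) - mean(g2)) / sqrt(v1 + v2)
    df_or <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    expect_equal(res$t, t_or, tolerance = 1e-12)
    expect_equal(res$df, df_or, tolerance = 1e-9)
    expect_equal(res$p, 2 * stats::pt(-abs(t_or), df_or), tolerance = 1e-12)
    sw <- independent_t(g2, g1)
    expect_equal(sw$t, -res$t, tolerance = 1e-12)
    expect_equal(sw$p, res$p, tolerance = 1e-12)
  }
  expect_equal(independent_t(c(1, 1), c(1, 1))$p, 1)
  expect_error(independent_t(1, c(1, 2)), "n >= 2")
})

test_that("Pearson correlation matches the covariance formula", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    a <- stats::rnorm(n)
    b <- 0.5 * a + stats::rnorm(n)
    res <- pearson_r(a, b)
    r_or <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    t_or <- r_or * sqrt((n - 2) / (1 - r_or^2))
    expect_equal(res$r, r_or, tolerance = 1e-12)
    expect_equal(res$p, 2 * stats::pt(-abs(t_or), n - 2), tolerance = 1e-12)
  }
  a <- c(1, 3, 7, 9)
  expect_equal(pearson_r(a, 2 * a + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(a, -a)$r, -1, tolerance = 1e-12)
  expect_error(pearson_r(a, rep(2, 4)), "constant")
  expect_error(pearson_r(c(1, 2), c(3, 4)), "n >= 3")
})

# independent enumeration oracle over all 2^n sign assignments
enumerate_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

test_that("exact Wilcoxon signed-rank p equals full sign enumeration", {
  # all-positive textbook case: one-tailed 1/32, two-sided 1/16
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(0, 0, 0, 0, 0))
  expect_equal(res$W, 15)
  expect_equal(res$p, 1 / 16)
  expect_true(res$exact)

  set.seed(14)
  for (n in 5:12) {
    for (rep in 1:3) {
      # draws with deliberate ties and zeros
      a <- sample(seq(-3, 6, by = 0.5), n, replace = TRUE)
      b <- sample(seq(-2, 2, by = 0.5), n, replace = TRUE)
      d <- a - b
      if (sum(d != 0) < 5) next
      res <- wilcoxon_signed_rank(a, b)
      expect_equal(res$p, enumerate_signrank_p(d), tolerance = 1e-12)
    }
  }
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 4), c(1, 2, 3, 4)),
               "nonzero differences")
})

test_that("signed-rank test agrees with the reference implementation", {
  set.seed(15)
  # tie-free exact regime
  for (i in 1:20) {
    n <- sample(6:20, 1)
    a <- stats::rnorm(n); b <- stats::rnorm(n)
    res <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(res$W, unname(ref$statistic))
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  }
  # large-sample normal approximation with continuity correction
  for (i in 1:10) {
    n <- 40
    a <- stats::rnorm(n); b <- stats::rnorm(n, 0.3)
    res <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                              correct = TRUE)
    expect_false(res$exact)
    expect_equal(res$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("antisymmetric differences give a p value of 1", {
  a <- c(1, 2, 3, -1, -2, -3)
  res <- wilcoxon_signed_rank(a, rep(0, 6))
  expect_equal(res$p, 1)
})

test_that("ME and MAE obey their defining laws", {
  ve <- validity_errors(c(1, 0), c(0, 1))   # d = (1, -1)
  expect_equal(ve$me_mean, 0)
  expect_equal(ve$mae_mean, 1)
  ve2 <- validity_errors(c(2, -1, -1), c(0, 0, 0))
  expect_equal(ve2$me_mean, 0)
  expect_equal(ve2$mae_mean, 4 / 3)
  ve3 <- validity_errors(c(1, 2), c(1, 2))
  expect_equal(c(ve3$me_mean, ve3$mae_mean), c(0, 0))

  set.seed(16)
  for (i in 1:100) {
    n <- sample(2:30, 1)
    a <- stats::rnorm(n); b <- stats::rnorm(n)
    ve <- validity_errors(a, b)
    expect_gte(ve$mae_mean, abs(ve$me_mean) - 1e-12)
    expect_gte(ve$mae_mean, 0)
    expect_lte(ve$me_min, ve$me_max)
    expect_lte(ve$mae_min, ve$mae_max)
    d <- a - b
    same_sign <- all(d >= 0) || all(d <= 0)
    expect_equal(isTRUE(all.equal(ve$mae_mean, abs(ve$me_mean))), same_sign)
  }
})

test_that("Bonferroni threshold reproduces the published decision rule", {
  expect_equal(bonferroni_threshold(analysis_config(mode = "published")), 0.01)
  expect_equal(bonferroni_threshold(analysis_config(mode = "exact")), 0.0125)
  expect_equal(bonferroni_threshold(analysis_config(n_tests = 1,
                                                    mode = "exact")), 0.05)
  expect_error(analysis_config(alpha = 1.5), "alpha")
  expect_error(analysis_config(n_tests = 0), "n_tests")
})
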