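#' Descriptive statistics with 95% confidence interval
#'
#' Sample mean, sample SD (n-1 denominator) and the t-based 95% CI
#' `mean +/- t(0.975, n-1) * sd / sqrt(n)`.
#'
#' @param values Numeric vector, n >= 2.
#' @return List with `n`, `mean`, `sd`, `ci_low`, `ci_high`.
#' @export
descriptive_stats <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("descriptive statistics require n >= 2", call. = FALSE)
  m <- mean(values); s <- stats::sd(values)
  half <- stats::qt(0.975, df = n - 1) * s / sqrt(n)
  list(n = n, mean = m, sd = s, ci_low = m - half, ci_high = m + half)
}

check_paired <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("paired series must have equal length", call. = FALSE)
  if (length(a) < 2) stop("paired tests require n >= 2", call. = FALSE)
  list(a = a, b = b)
}

#' Paired t test
#'
#' Two-sided paired t test, `t = mean(d) / (sd(d)/sqrt(n))` with `d = a - b`
#' and `df = n - 1`. If the differences are all zero (to within 1e-12,
#' far below measurement resolution) the degenerate convention
#' `t = 0, p = 1` is returned; a constant nonzero difference has no finite
#' t statistic and raises an error.
#'
#' @param a,b Paired numeric vectors, aligned by subject.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t <- function(a, b) {
  s <- check_paired(a, b)
  d <- s$a - s$b
  n <- length(d)
  if (all(abs(d) < 1e-12)) return(list(t = 0, df = n - 1, p = 1))
  if (stats::sd(d) == 0) {
    stop("differences are constant and nonzero: paired t is undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(s$a, s$b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Welch independent-samples t test
#'
#' Two-sided unequal-variance (Welch) t test with Welch-Satterthwaite
#' degrees of freedom. Two identical constant groups return the degenerate
#' convention `t = 0, p = 1`.
#'
#' @param group1,group2 Numeric vectors, each n >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
independent_t <- function(group1, group2) {
  g1 <- as.numeric(group1); g2 <- as.numeric(group2)
  if (length(g1) < 2 || length(g2) < 2)
    stop("both groups need n >= 2", call. = FALSE)
  if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
    if (mean(g1) == mean(g2))
      return(list(t = 0, df = length(g1) + length(g2) - 2, p = 1))
    stop("both groups constant with different means: t is undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(g1, g2, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson product-moment correlation
#'
#' Two-sided p via `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param a,b Paired numeric vectors, n >= 3, both non-constant.
#' @return List with `r`, `n`, `p`.
#' @export
pearson_r <- function(a, b) {
  s <- check_paired(a, b)
  if (length(s$a) < 3) stop("correlation requires n >= 3", call. = FALSE)
  if (stats::sd(s$a) == 0 || stats::sd(s$b) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  ht <- stats::cor.test(s$a, s$b, method = "pearson")
  list(r = unname(ht$estimate), n = length(s$a), p = unname(ht$p.value))
}

# Exact null distribution of the signed-rank statistic W+ for given
# (possibly tied, average) ranks, via the generating function
# prod_i (1 + z^(2 r_i)) / 2^n over doubled ranks (doubling makes .5 average
# ranks integral). Returns P(W+ = w/2) on the support w = 0..2*sum(r).
signrank_exact_dist <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  f / 2^length(r2)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' The paired-sample Wilcoxon test (the dependent-sample analogue of the
#' rank-sum test): zero differences are dropped, ties receive average ranks,
#' and `W` is the sum of ranks of the positive differences. The two-sided p
#' value uses the exact null distribution (computed by convolution over the
#' realized ranks, so it remains exact under ties) for n <= `exact_limit`,
#' and a continuity-corrected normal approximation with tie-corrected
#' variance above.
#'
#' @param a,b Paired numeric vectors, aligned by subject.
#' @param exact_limit Largest number of nonzero differences for which the
#'   exact distribution is used (default 25).
#' @return List with `W`, `n` (nonzero differences), `p`, `exact`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 25) {
  s <- check_paired(a, b)
  d <- s$a - s$b
  d <- d[d != 0]
  n <- length(d)
  if (n < 5)
    stop("fewer than 5 nonzero differences: the signed-rank null ",
         "distribution is too coarse to be meaningful", call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    dist <- signrank_exact_dist(r)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(dist[seq_len(w2 + 1)])
    p_ge <- sum(dist[(w2 + 1):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(W = W, n = n, p = p, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(W = W, n = n, p = p, exact = FALSE)
}

#' Method-agreement error summary (ME / MAE)
#'
#' Mean error and mean absolute error between two measurement series,
#' conventionally ACP-based minus MCP-based: `d = a - b`, ME = mean(d) with
#' the SD/min/max of d, MAE = mean(|d|) with the SD/min/max of |d|. MAE is
#' non-negative by construction and always at least |ME|, with equality
#' exactly when all differences share one sign.
#'
#' @param a,b Paired numeric vectors (e.g. ACP-based and MCP-based values).
#' @return List with `me_mean`, `me_sd`, `me_min`, `me_max`, `mae_mean`,
#'   `mae_sd`, `mae_min`, `mae_max`.
#' @export
validity_errors <- function(a, b) {
  s <- check_paired(a, b)
  d <- s$a - s$b
  ad <- abs(d)
  list(me_mean = mean(d), me_sd = stats::sd(d),
       me_min = min(d), me_max = max(d),
       mae_mean = mean(ad), mae_sd = stats::sd(ad),
       mae_min = min(ad), mae_max = max(ad))
}

#' Analysis configuration
#'
#' @param alpha Nominal significance level (default 0.05, two-sided).
#' @param n_tests Number of comparisons entering the Bonferroni adjustment
#'   (default 4: the four lip variables).
#' @param mode `"published"` reproduces the printed decision threshold 0.01 for
#'   the default `alpha = 0.05, n_tests = 4`; `"exact"` returns
#'   `alpha / n_tests` (0.0125 for the defaults).
#' @param aesthetic_window Half-width of the aesthetic window in mm.
#' @param target_angle Convexity criterion in degrees.
#' @return An `"analysis_config"` list.
#' @export
analysis_config <- function(alpha = 0.05, n_tests = 4,
                            mode = c("published", "exact"),
                            aesthetic_window = 2, target_angle = 170) {
  mode <- match.arg(mode)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, n_tests = n_tests, mode = mode,
                 aesthetic_window = aesthetic_window,
                 target_angle = target_angle),
            class = "analysis_config")
}

#' Bonferroni-adjusted decision threshold
#'
#' In `"exact"` mode returns `alpha / n_tests`. In `"published"` mode the
#' division is rounded down to two decimals, reproducing the published
#' decision rule (0.01 for alpha 0.05 over 4 tests) while `"exact"` exposes
#' the unrounded 0.0125.
#'
#' @param config An [analysis_config()].
#' @return The decision threshold for p values.
#' @export
bonferroni_threshold <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  exact <- config$alpha / config$n_tests
  if (config$mode == "exact") return(exact)
  thr <- floor(exact * 100) / 100
  if (thr <= 0) exact else thr
}
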