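# Synthetic paired-cohort generator.
#
# Each synthetic subject is built in a canonical upright frame: Sn at the
# origin, G straight above it (so line A is vertical and line M leaves Sn at
# (180 - target) degrees from vertical on the posterior side), the chin at a
# drawn vertical depth and a drawn signed chin angle, the nose anchors (Pn,
# Col) at fixed offsets, and the lips placed so that their signed distances
# to the ACP-based S and E lines equal the drawn lip offsets. Isotropic
# landmark jitter and lateral (out-of-plane) noise are added last. The
# measurement pipeline refits the midsagittal frame from the emitted
# coordinates, so generator and measurer share no state.

#' Per-sex lip offset targets
#'
#' @param ul_s,ll_s,ul_e,ll_e Numeric `c(mean, sd)` in mm for the signed
#'   distance of the upper/lower lip to the S and E lines (ACP-based,
#'   anterior-positive).
#' @return A 4 x 2 matrix with rows `ul_s, ll_s, ul_e, ll_e`.
#' @export
lip_targets <- function(ul_s, ll_s, ul_e, ll_e) {
  m <- rbind(ul_s = ul_s, ll_s = ll_s, ul_e = ul_e, ll_e = ll_e)
  colnames(m) <- c("mean", "sd")
  if (any(m[, "sd"] < 0)) stop("lip offset sd must be >= 0", call. = FALSE)
  m
}

# Moments of the folded normal |N(mu, sigma^2)|.
folded_moments <- function(mu, sigma) {
  if (sigma <= 0) return(c(mean = abs(mu), sd = 0))
  z <- mu / sigma
  m <- sigma * sqrt(2 / pi) * exp(-z^2 / 2) + mu * (1 - 2 * stats::pnorm(-z))
  v <- mu^2 + sigma^2 - m^2
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Moment-match a folded normal to a target |x| mean/sd. If mu_fix is given
# only sigma is fit (to the folded mean). Returns c(mu, sigma) with mu <= 0:
# the sign encodes a modified chin point posterior to the actual chin point
# on average.
fit_folded_normal <- function(abs_mean, abs_sd, mu_fix = NULL) {
  if (!is.null(mu_fix)) {
    f <- function(sigma) folded_moments(mu_fix, sigma)[["mean"]] - abs_mean
    sigma <- stats::uniroot(f, c(1e-6, 10 * (abs_mean + abs_sd)))$root
    return(c(mu = -abs(mu_fix), sigma = sigma))
  }
  obj <- function(par) {
    mm <- folded_moments(abs(par[1]), exp(par[2]))
    (mm[["mean"]] - abs_mean)^2 + (mm[["sd"]] - abs_sd)^2
  }
  fit <- stats::optim(c(abs_mean, log(abs_sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mu = -abs(fit$par[1]), sigma = exp(fit$par[2]))
}

# Translate a signed ACP-to-MCP offset distribution x ~ N(mu_x, sd_x) into a
# chin-angle (convexity) distribution, for chin depth D ~ N(mean, sd) and a
# vertical line A. With theta the signed chin angle from the downward
# vertical (anterior-positive) and dev = 180 - target the line-M deviation,
# x = -D * (tan(dev) + tan(theta)); first-order propagation gives the
# convexity mean/SD in degrees.
convexity_from_x <- function(mu_x, sd_x, chin_drop, target_angle = 170) {
  dev <- deg2rad(180 - target_angle)
  mu_d <- chin_drop[1]; sd_d <- chin_drop[2]
  tan_theta <- -mu_x / mu_d - tan(dev)
  theta0 <- atan(tan_theta)
  var_from_depth <- sd_d^2 * (mu_x / mu_d)^2
  var_theta <- (sd_x^2 - var_from_depth) / (mu_d^2 * (1 / cos(theta0))^4)
  if (var_theta <= 0)
    stop("chin-depth variance alone exceeds the requested x variance; ",
         "reduce chin_drop sd", call. = FALSE)
  c(mean = 180 + rad2deg(theta0), sd = rad2deg(sqrt(var_theta)))
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the statistical structure of the validation study
#' cohort: 68 patients (28 male, 40 female) measured pre- (T0) and
#' post-surgery (T1); ACP-based lip-offset targets from the published
#' pre-surgery table and the sex-stratified post-surgery table; chin-angle
#' distributions derived from the published unsigned ACP-to-MCP distance
#' summaries (8.53 +/- 5.37 mm at T0, 3.87 +/- 2.58 mm at T1) by folded
#' normal moment matching (see the methods vignette for the sign
#' convention and the T1 constraint).
#'
#' The `convexity_*` means are interior facial-convexity angles in degrees;
#' the generator places the mean chin on the posterior side of the
#' glabella-subnasale line, with anterior chins arising through the spread.
#' Draws are truncated to geometric feasibility (convexity > 120 degrees,
#' chin depth > 20 mm).
#'
#' @param n_subjects Number of subjects (each gets a T0 and a T1 record).
#' @param male_fraction Proportion of male subjects.
#' @param seed Integer seed driving all randomness in [generate_cohort()].
#' @param convexity_t0,convexity_t1 `c(mean, sd)` in degrees.
#' @param chin_drop `c(mean, sd)` vertical Sn-to-chin distance in mm.
#' @param nose_geometry List with `pn` and `col` offsets `c(anterior,
#'   superior)` of pronasale and columella from Sn, in mm.
#' @param lip_offsets_t0,lip_offsets_t1 Lists with `male` and `female`
#'   [lip_targets()] matrices (mm).
#' @param lateral_noise_sd SD of out-of-plane landmark noise (mm).
#' @param landmark_jitter_sd SD of isotropic landmark jitter (mm).
#' @param subject_correlation Within-subject T0/T1 correlation of the latent
#'   chin, depth and lip draws (shared random effect).
#' @param face_height_mm Vertical Sn-to-G distance (mm).
#' @param max_retries Resampling cap for infeasible draws.
#' @return A `"cohort_config"` list.
#' @export
cohort_config <- function(
    n_subjects = 68,
    male_fraction = 28 / 68,
    seed = 1L,
    convexity_t0 = NULL,
    convexity_t1 = NULL,
    chin_drop = c(60, 5),
    nose_geometry = list(pn = c(18, 10), col = c(10, 4)),
    lip_offsets_t0 = NULL,
    lip_offsets_t1 = NULL,
    lateral_noise_sd = 0.5,
    landmark_jitter_sd = 0.25,
    subject_correlation = 0.5,
    face_height_mm = 65,
    max_retries = 100) {
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (male_fraction < 0 || male_fraction > 1)
    stop("male_fraction must lie in [0, 1]", call. = FALSE)
  if (lateral_noise_sd < 0 || landmark_jitter_sd < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  if (subject_correlation < 0 || subject_correlation > 1)
    stop("subject_correlation must lie in [0, 1]", call. = FALSE)
  if (is.null(convexity_t0)) {
    fx <- fit_folded_normal(8.53, 5.37)
    convexity_t0 <- convexity_from_x(fx[["mu"]], fx[["sigma"]], chin_drop)
  }
  if (is.null(convexity_t1)) {
    fx <- fit_folded_normal(3.87, 2.58, mu_fix = 0.2)
    convexity_t1 <- convexity_from_x(fx[["mu"]], fx[["sigma"]], chin_drop)
  }
  for (cv in list(convexity_t0, convexity_t1)) {
    if (!(cv[1] > 90 && cv[1] < 180))
      stop("convexity mean must lie in (90, 180) degrees", call. = FALSE)
    if (cv[2] < 0) stop("convexity sd must be >= 0", call. = FALSE)
  }
  if (is.null(lip_offsets_t0)) {
    t0 <- lip_targets(ul_s = c(0.96, 2.78), ll_s = c(6.02, 2.80),
                      ul_e = c(-2.87, 3.41), ll_e = c(3.54, 3.12))
    lip_offsets_t0 <- list(male = t0, female = t0)
  }
  if (is.null(lip_offsets_t1)) {
    lip_offsets_t1 <- list(
      male = lip_targets(ul_s = c(1.17, 1.61), ll_s = c(2.95, 2.50),
                         ul_e = c(-2.15, 1.78), ll_e = c(0.85, 2.55)),
      female = lip_targets(ul_s = c(1.04, 1.80), ll_s = c(1.63, 2.88),
                           ul_e = c(-2.14, 2.13), ll_e = c(-0.38, 3.05)))
  }
  structure(list(
    n_subjects = as.integer(n_subjects), male_fraction = male_fraction,
    seed = as.integer(seed),
    convexity_t0 = unname(convexity_t0), convexity_t1 = unname(convexity_t1),
    chin_drop = chin_drop, nose_geometry = nose_geometry,
    lip_offsets_t0 = lip_offsets_t0, lip_offsets_t1 = lip_offsets_t1,
    lateral_noise_sd = lateral_noise_sd,
    landmark_jitter_sd = landmark_jitter_sd,
    subject_correlation = subject_correlation,
    face_height_mm = face_height_mm, max_retries = as.integer(max_retries),
    target_angle = 170), class = "cohort_config")
}

#' Study-default synthetic cohort configuration
#'
#' The configuration whose targets are the published cohort summaries:
#' n = 68 subjects with 28 males, pre-surgery ACP-based lip offsets and
#' sex-stratified post-surgery lip offsets from the printed tables, and
#' chin-angle distributions calibrated to the printed ACP-to-MCP distance
#' summaries.
#'
#' @param seed Integer seed.
#' @return A `"cohort_config"`.
#' @export
study_default_config <- function(seed = 1L) {
  cohort_config(seed = seed)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: n = %d (%.0f%% male), seed = %d\n",
              x$n_subjects, 100 * x$male_fraction, x$seed))
  cat(sprintf("  convexity T0: %.2f +/- %.2f deg;  T1: %.2f +/- %.2f deg\n",
              x$convexity_t0[1], x$convexity_t0[2],
              x$convexity_t1[1], x$convexity_t1[2]))
  cat(sprintf("  chin drop: %.1f +/- %.1f mm; jitter %.2g mm; lateral %.2g mm\n",
              x$chin_drop[1], x$chin_drop[2],
              x$landmark_jitter_sd, x$lateral_noise_sd))
  invisible(x)
}

# Place a lip point from its signed perpendicular distances to the
# ACP-based S and E lines (two line constraints, one 2x2 solve).
solve_lip_point <- function(col, pn, acp, d_s, d_e) {
  s_line <- line_through(col, acp)
  e_line <- line_through(pn, acp)
  n_s <- anterior_normal(s_line)
  n_e <- anterior_normal(e_line)
  A <- rbind(n_s, n_e)
  det <- n_s[1] * n_e[2] - n_s[2] * n_e[1]
  if (abs(det) < 1e-8) return(NULL)  # S and E lines (near-)parallel
  b <- c(d_s + sum(n_s * col), d_e + sum(n_e * pn))
  p <- solve(A, b)
  c(a = p[1], s = p[2])
}

#' Generate a synthetic paired landmark cohort
#'
#' Draws per-subject chin angles, chin depths and ACP-based lip offsets from
#' the configured distributions (T0 and T1 correlated through a shared
#' subject-level random effect), constructs landmark coordinates realizing
#' those draws exactly, then adds isotropic jitter and lateral noise. The
#' emitted cohort passes [as_cohort()] validation and carries its ground
#' truth alongside.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return List with `cohort` (a `"chin_cohort"`), `ground_truth`
#'   (data.frame of the drawn values and the implied noiseless ACP-to-MCP
#'   offsets), and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(seed)) seed <- config$seed

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  n <- config$n_subjects
  n_male <- round(config$male_fraction * n)
  sexes <- rep(c("male", "female"), c(n_male, n - n_male))
  ids <- sprintf("S%03d", seq_len(n))
  rho <- config$subject_correlation
  dev <- 180 - config$target_angle  # line M deviation from line A, degrees

  draw_corr <- function(z, mean, sd) {
    mean + sd * (sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(1))
  }
  draw_trunc <- function(z, mean, sd, ok) {
    for (i in seq_len(config$max_retries)) {
      v <- draw_corr(z, mean, sd)
      if (ok(v)) return(v)
    }
    stop("could not draw a feasible value within the retry cap", call. = FALSE)
  }

  cohort_rows <- vector("list", 2L * n)
  truth_rows <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    # subject-level random effects, one per latent variable family
    z <- list(theta = stats::rnorm(1), depth = stats::rnorm(1),
              ul_s = stats::rnorm(1), ll_s = stats::rnorm(1),
              ul_e = stats::rnorm(1), ll_e = stats::rnorm(1))
    for (tp in c("T0", "T1")) {
      conv_par <- if (tp == "T0") config$convexity_t0 else config$convexity_t1
      lips_par <- (if (tp == "T0") config$lip_offsets_t0
                   else config$lip_offsets_t1)[[sexes[i]]]
      # signed chin angle from the downward vertical, anterior-positive;
      # the configured convexity mean sits on the posterior side
      theta0 <- conv_par[1] - 180
      theta <- draw_trunc(z$theta, theta0, conv_par[2],
                          function(v) abs(v) < 60)
      depth <- draw_trunc(z$depth, config$chin_drop[1], config$chin_drop[2],
                          function(v) v > 20)
      point <- NULL
      for (try in seq_len(config$max_retries)) {
        offs <- c(ul_s = draw_corr(z$ul_s, lips_par["ul_s", 1], lips_par["ul_s", 2]),
                  ll_s = draw_corr(z$ll_s, lips_par["ll_s", 1], lips_par["ll_s", 2]),
                  ul_e = draw_corr(z$ul_e, lips_par["ul_e", 1], lips_par["ul_e", 2]),
                  ll_e = draw_corr(z$ll_e, lips_par["ll_e", 1], lips_par["ll_e", 2]))
        g <- c(0, config$face_height_mm)
        sn <- c(0, 0)
        acp <- c(depth * tan(deg2rad(theta)), -depth)
        pn <- config$nose_geometry$pn
        col <- config$nose_geometry$col
        ul <- solve_lip_point(col, pn, acp, offs[["ul_s"]], offs[["ul_e"]])
        ll <- solve_lip_point(col, pn, acp, offs[["ll_s"]], offs[["ll_e"]])
        if (!is.null(ul) && !is.null(ll)) { point <- list(ul = ul, ll = ll); break }
      }
      if (is.null(point))
        stop("infeasible lip constraints for subject ", ids[i],
             " after ", config$max_retries, " resampling attempts",
             call. = FALSE)

      coords <- rbind(G = c(g, 0), Sn = c(sn, 0), Pn = c(pn, 0),
                      Col = c(col, 0), UL = c(point$ul, 0),
                      LL = c(point$ll, 0), ACP = c(acp, 0))
      jit <- matrix(stats::rnorm(21, sd = config$landmark_jitter_sd),
                    nrow = 7, ncol = 3)
      lat <- stats::rnorm(7, sd = config$lateral_noise_sd)
      coords <- coords + jit
      coords[, 3] <- coords[, 3] + lat

      x_true <- -depth * (tan(deg2rad(dev)) + tan(deg2rad(theta)))
      k <- k + 1L
      cohort_rows[[k]] <- data.frame(
        subject_id = ids[i], sex = sexes[i], timepoint = tp,
        landmark = rownames(coords),
        anterior_mm = coords[, 1], superior_mm = coords[, 2],
        lateral_mm = coords[, 3], stringsAsFactors = FALSE)
      truth_rows[[k]] <- data.frame(
        subject_id = ids[i], sex = sexes[i], timepoint = tp,
        theta_deg = theta, convexity_deg = 180 - abs(theta),
        chin_drop_mm = depth, x_signed_mm = x_true,
        ul_s = offs[["ul_s"]], ll_s = offs[["ll_s"]],
        ul_e = offs[["ul_e"]], ll_e = offs[["ll_e"]],
        stringsAsFactors = FALSE)
    }
  }
  cohort <- as_cohort(do.call(rbind, cohort_rows))
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(cohort = cohort, ground_truth = truth, config = config)
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates cohorts, runs the measurement pipeline and compares
#' its estimates to the drawn ground truth and to the configured targets:
#' per-sex T1 ACP-based lip-offset means (bias against the ground-truth
#' draws and the configured mean, plus whether the 95% CI covers the
#' configured mean) and the unsigned ACP-to-MCP distance summaries per
#' timepoint.
#'
#' @param config A [cohort_config()].
#' @param n_reps Number of replicates.
#' @param seed Integer seed for the replicate seed stream.
#' @return List with `lip` (per replicate x sex x variable), `chin` (per
#'   replicate x timepoint), and `coverage` (per sex x variable coverage
#'   fraction of the configured mean).
#' @export
recovery_experiment <- function(config = cohort_config(), n_reps = 20,
                                seed = 1L) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2147483646L, n_reps)

  lip_rows <- list(); chin_rows <- list()
  for (r in seq_len(n_reps)) {
    sim <- generate_cohort(config, seed = rep_seeds[r])
    meas <- measure_cohort(sim$cohort, target_angle = config$target_angle)
    truth <- sim$ground_truth
    t1 <- meas[meas$timepoint == "T1", ]
    tr1 <- truth[truth$timepoint == "T1", ]
    for (sx in intersect(c("male", "female"), unique(t1$sex))) {
      ms <- t1[t1$sex == sx, ]; ts <- tr1[tr1$sex == sx, ]
      if (nrow(ms) < 2) next
      for (v in LIP_VARIABLES) {
        est <- descriptive_stats(ms[[wide_col("ACP", v)]])
        target <- config$lip_offsets_t1[[sx]][v, "mean"]
        lip_rows[[length(lip_rows) + 1L]] <- data.frame(
          rep = r, sex = sx, variable = v,
          est_mean = est$mean, est_sd = est$sd,
          truth_mean = mean(ts[[v]]), target_mean = target,
          bias_vs_truth = est$mean - mean(ts[[v]]),
          bias_vs_target = est$mean - target,
          covered = est$ci_low <= target & target <= est$ci_high,
          stringsAsFactors = FALSE)
      }
    }
    for (tp in c("T0", "T1")) {
      mx <- meas$x_abs_mm[meas$timepoint == tp]
      tx <- abs(truth$x_signed_mm[truth$timepoint == tp])
      chin_rows[[length(chin_rows) + 1L]] <- data.frame(
        rep = r, timepoint = tp,
        est_mean = mean(mx), est_sd = stats::sd(mx),
        truth_mean = mean(tx), bias_vs_truth = mean(mx) - mean(tx),
        stringsAsFactors = FALSE)
    }
  }
  lip <- do.call(rbind, lip_rows)
  chin <- do.call(rbind, chin_rows)
  coverage <- stats::aggregate(covered ~ sex + variable, data = lip, FUN = mean)
  list(lip = lip, chin = chin, coverage = coverage,
       n_reps = n_reps, config = config)
}
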