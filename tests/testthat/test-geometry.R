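test_that("frame fitting recovers an exact coordinate plane", {
  lm <- embed3(canonical_profile())
  frame <- fit_midsagittal_frame(lm)
  expect_lt(max(abs(lateral_offsets(lm, frame))), 1e-9)
  prof <- project_landmarks(lm, frame)
  expect_equal(unname(prof["Sn", ]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(prof["G", ]), c(0, 65), tolerance = 1e-9)
  expect_gt(prof["Pn", "a"], 0)
})

test_that("projection respects the origin and axis conventions", {
  lm <- embed3(canonical_profile())
  frame <- fit_midsagittal_frame(lm)
  # a point 5 mm along the anterior axis from the origin projects to (5, 0)
  p <- frame$origin + 5 * frame$anterior
  a <- sum((p - frame$origin) * frame$anterior)
  s <- sum((p - frame$origin) * frame$superior)
  expect_equal(c(a, s), c(5, 0), tolerance = 1e-12)
  # frame is right-handed orthonormal
  ax <- rbind(frame$anterior, frame$superior, frame$lateral)
  expect_equal(ax %*% t(ax), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(det(ax), 1, tolerance = 1e-9)
})

test_that("projections are invariant under rigid 3D transforms", {
  set.seed(101)
  lm <- embed3(canonical_profile())
  prof0 <- project_landmarks(lm, fit_midsagittal_frame(lm))
  for (i in 1:20) {
    lm2 <- apply_rigid(lm, random_rotation(), stats::rnorm(3, sd = 50))
    prof2 <- project_landmarks(lm2, fit_midsagittal_frame(lm2))
    expect_profiles_equal(prof0, prof2, tol = 1e-6)
  }
})

test_that("collinear landmark sets are rejected", {
  coords <- cbind(anterior = seq(0, 6), superior = 2 * seq(0, 6),
                  lateral = rep(0, 7))
  rownames(coords) <- c("G", "Sn", "Pn", "Col", "UL", "LL", "ACP")
  expect_error(fit_midsagittal_frame(landmark_set(coords)), "collinear")
})

test_that("plane stability under lateral noise matches error propagation", {
  # Independent oracle: linearized TLS tilt variance. For lateral noise of
  # sd sigma on points with in-plane scatter sums Sa, Ss about the
  # centroid, the normal tilts with RMS angle sigma * sqrt(1/Sa + 1/Ss).
  # Seven midline landmarks are nearly collinear in the anterior direction,
  # so 0.5 mm of noise moves the plane by over a degree.
  set.seed(202)
  lm <- embed3(canonical_profile())
  lat0 <- fit_midsagittal_frame(lm)$lateral
  prof <- unclass(lm)[, 1:2]
  Sa <- sum((prof[, 1] - mean(prof[, 1]))^2)
  Ss <- sum((prof[, 2] - mean(prof[, 2]))^2)
  sigma <- 0.5
  predicted_rms <- sigma * sqrt(1 / Sa + 1 / Ss) * 180 / pi
  angs <- replicate(300, {
    coords <- unclass(lm)
    coords[, "lateral"] <- coords[, "lateral"] + stats::rnorm(7, sd = sigma)
    latn <- fit_midsagittal_frame(landmark_set(coords))$lateral
    acos(min(1, abs(sum(lat0 * latn)))) * 180 / pi
  })
  observed_rms <- sqrt(mean(angs^2))
  expect_lt(abs(observed_rms - predicted_rms) / predicted_rms, 0.3)
  expect_true(all(angs < 10))
})

test_that("facial convexity angle matches hand-checked values", {
  expect_equal(facial_convexity_angle(c(0, 80), c(0, 0), c(0, -60)), 180)
  expect_equal(facial_convexity_angle(c(0, 10), c(0, 0), c(10, 0)), 90)
  # arccos oracle: u = (0,80), v = (-8,-55)
  expected <- acos(-55 / sqrt(64 + 55^2)) * 180 / pi
  expect_equal(facial_convexity_angle(c(0, 80), c(0, 0), c(-8, -55)),
               expected, tolerance = 1e-12)
  expect_equal(round(expected, 2), 171.72)
  expect_error(facial_convexity_angle(c(0, 0), c(0, 0), c(1, 1)),
               "zero-length")
})

test_that("convexity angle is symmetric in its rays and scale invariant", {
  set.seed(303)
  for (i in 1:50) {
    sn <- stats::rnorm(2, sd = 10)
    g <- sn + stats::rnorm(2, sd = 30)
    pog <- sn + stats::rnorm(2, sd = 30)
    a1 <- facial_convexity_angle(g, sn, pog)
    expect_equal(facial_convexity_angle(pog, sn, g), a1, tolerance = 1e-9)
    k <- stats::runif(1, 0.2, 5)
    expect_equal(facial_convexity_angle(sn + k * (g - sn), sn,
                                        sn + k * (pog - sn)),
                 a1, tolerance = 1e-9)
  }
})

test_that("signed point-to-line distance follows the anterior-positive convention", {
  vert <- sagittal_line(c(0, 0), c(0, -1))
  expect_equal(signed_distance_to_line(c(3, -50), vert), 3)
  expect_equal(signed_distance_to_line(c(-2, 10), vert), -2)
  ln <- line_through(c(12, -5), c(8, -65))
  # 2D cross-product oracle
  d <- c(8 - 12, -65 + 5) / sqrt(16 + 3600)
  expected <- abs(d[1] * (-20 + 5) - d[2] * (14 - 12))
  expect_equal(signed_distance_to_line(c(14, -20), ln), expected,
               tolerance = 1e-12)
  expect_equal(round(expected, 2), 2.99)
  # any point on the line measures zero
  p_on <- c(12, -5) + 0.37 * (c(8, -65) - c(12, -5))
  expect_equal(signed_distance_to_line(p_on, ln), 0, tolerance = 1e-9)
})

test_that("signed distance agrees with a brute-force search over line samples", {
  set.seed(404)
  for (i in 1:20) {
    p0 <- stats::rnorm(2, sd = 20)
    dirv <- stats::rnorm(2)
    ln <- sagittal_line(p0, dirv)
    p <- stats::rnorm(2, sd = 30)
    tgrid <- seq(-200, 200, by = 0.001)
    pts_a <- ln$p0[1] + tgrid * ln$direction[1]
    pts_s <- ln$p0[2] + tgrid * ln$direction[2]
    brute <- min(sqrt((pts_a - p[1])^2 + (pts_s - p[2])^2))
    d <- signed_distance_to_line(p, ln)
    expect_equal(abs(d), brute, tolerance = 1e-3)
    n <- c(-ln$direction[2], ln$direction[1])
    if (n[1] < 0 || (n[1] == 0 && n[2] < 0)) n <- -n
    expect_equal(sign(d), sign(sum((p - ln$p0) * n)))
  }
})
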