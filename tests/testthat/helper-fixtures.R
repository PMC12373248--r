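# Fixture builders shared across tests. Everything is generated in code;
# no data files.

# A plausible upright profile: Sn at the origin, G above, nose anterior,
# lips between the nose anchors and the chin.
canonical_profile <- function(acp = c(-2, -60)) {
  rbind(G = c(0, 65), Sn = c(0, 0), Pn = c(18, 10), Col = c(10, 4),
        UL = c(12, -12), LL = c(13, -28), ACP = acp)
}

# Embed a 2D profile (rows: landmark, cols a, s) as 3D landmarks with zero
# lateral coordinate.
embed3 <- function(profile2d, lateral = 0) {
  coords <- cbind(profile2d, lateral)
  colnames(coords) <- c("anterior", "superior", "lateral")
  landmark_set(coords)
}

# Random 3D rotation matrix (uniform via QR of a Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(landmarks, R, shift) {
  coords <- unclass(landmarks) %*% t(R)
  coords <- sweep(coords, 2, -shift)
  colnames(coords) <- c("anterior", "superior", "lateral")
  rownames(coords) <- rownames(landmarks)
  landmark_set(coords)
}

# Random 2D rigid transform applied to a profile matrix.
apply_rigid2 <- function(profile2d, angle, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(profile2d %*% t(R), 2, -shift)
}

# Long-format cohort data.frame from a list of landmark sets.
cohort_df <- function(sets, ids, sexes, timepoints) {
  do.call(rbind, lapply(seq_along(sets), function(i) {
    coords <- unclass(sets[[i]])
    data.frame(subject_id = ids[i], sex = sexes[i], timepoint = timepoints[i],
               landmark = rownames(coords),
               anterior_mm = coords[, 1], superior_mm = coords[, 2],
               lateral_mm = coords[, 3], stringsAsFactors = FALSE)
  }))
}

# Small two-subject paired cohort with mild geometric variation.
small_cohort <- function() {
  sets <- list(
    embed3(canonical_profile(c(-4, -58))),   # s1 T0
    embed3(canonical_profile(c(-1, -59))),   # s1 T1
    embed3(canonical_profile(c(-7, -62))),   # s2 T0
    embed3(canonical_profile(c(-3, -61))))   # s2 T1
  as_cohort(cohort_df(sets, ids = c("s1", "s1", "s2", "s2"),
                      sexes = c("male", "male", "female", "female"),
                      timepoints = c("T0", "T1", "T0", "T1")))
}

# Noise-free config helper: small cohort, no jitter, fixed distributions.
noiseless_config <- function(n = 10, convexity = c(170, 3), seed = 1,
                             chin = c(60, 4)) {
  cohort_config(n_subjects = n, seed = seed,
                convexity_t0 = convexity, convexity_t1 = convexity,
                chin_drop = chin,
                lateral_noise_sd = 0, landmark_jitter_sd = 0)
}

expect_profiles_equal <- function(p1, p2, tol = 1e-6) {
  expect_lt(max(abs(p1[rownames(p1), ] - p2[rownames(p1), ])), tol)
}
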