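# Canonical landmark codes. G, Sn, Pn are the primed soft-tissue landmarks
# (glabella, subnasale, pronasale); Col the columella midpoint; UL/LL the
# most anterior upper/lower lip points; ACP the actual chin point (soft
# tissue pogonion in the midsagittal plane).
LANDMARK_NAMES <- c("G", "Sn", "Pn", "Col", "UL", "LL", "ACP")

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (!is.finite(n) || n < 1e-12) {
    stop("cannot normalize degenerate ", what, " (near-zero length)",
         call. = FALSE)
  }
  v / n
}

#' Create a 3D point in anatomical coordinates
#'
#' Coordinates are in millimetres: `anterior` positive toward the front of
#' the face, `superior` positive toward the top of the head, `lateral`
#' positive toward the subject's left.
#'
#' @param anterior,superior,lateral Finite numeric scalars (mm).
#' @return A named numeric vector of length 3 with class `"point3"`.
#' @export
point3 <- function(anterior, superior, lateral = 0) {
  p <- c(anterior = as.numeric(anterior), superior = as.numeric(superior),
         lateral = as.numeric(lateral))
  if (!all(is.finite(p))) stop("point3 coordinates must be finite", call. = FALSE)
  class(p) <- "point3"
  p
}

#' Assemble a validated landmark set
#'
#' A landmark set holds the seven midline soft-tissue landmarks used by the
#' modified-chin-point analysis: G (glabella), Sn (subnasale), Pn
#' (pronasale), Col (columella point), UL, LL (upper/lower lip) and ACP
#' (actual chin point / soft-tissue pogonion).
#'
#' @param coords A 7 x 3 numeric matrix with rownames from
#'   `c("G","Sn","Pn","Col","UL","LL","ACP")` and columns
#'   (anterior, superior, lateral), in mm.
#' @return A `"landmark_set"`: the validated coordinate matrix.
#' @export
landmark_set <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3)
    stop("landmark coordinates must have 3 columns (anterior, superior, lateral)",
         call. = FALSE)
  missing <- setdiff(LANDMARK_NAMES, rownames(coords))
  if (length(missing) > 0)
    stop("missing required landmark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(rownames(coords), LANDMARK_NAMES)
  if (length(extra) > 0)
    stop("unknown landmark name(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(rownames(coords)))
    stop("duplicated landmark names", call. = FALSE)
  coords <- coords[LANDMARK_NAMES, , drop = FALSE]
  colnames(coords) <- c("anterior", "superior", "lateral")
  if (!all(is.finite(coords)))
    stop("all landmark coordinates must be finite", call. = FALSE)
  if (vnorm(coords["G", ] - coords["Sn", ]) <= 1e-6)
    stop("G and Sn must be distinct (> 1e-6 mm apart)", call. = FALSE)
  if (vnorm(coords["ACP", ] - coords["Sn", ]) <= 1e-6)
    stop("ACP and Sn must be distinct (> 1e-6 mm apart)", call. = FALSE)
  structure(coords, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Midline soft-tissue landmark set (mm):\n")
  print(unclass(x), digits = 4)
  invisible(x)
}

#' Fit the midsagittal measurement frame
#'
#' Fits the total-least-squares plane through the seven midline landmarks
#' (minimizing the sum of squared out-of-plane distances), then orients an
#' orthonormal right-handed frame inside it: the superior axis is the
#' in-plane direction best aligned with Sn -> G, the anterior axis is the
#' in-plane direction orthogonal to it signed so that Pn has a positive
#' anterior coordinate, and the lateral axis completes the right-handed
#' triad. The origin is Sn. The frame operationalizes natural head position
#' for subjects supplied in an arbitrary scanner frame.
#'
#' @param landmarks A [landmark_set()].
#' @return A `"sagittal_frame"`: list with `origin` and unit `anterior`,
#'   `superior`, `lateral` axes (3-vectors).
#' @export
fit_midsagittal_frame <- function(landmarks) {
  landmarks <- landmark_set(landmarks)
  X <- unclass(landmarks)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  # smallest right-singular vector = plane normal; next-smallest detects
  # collinearity (all points on a line -> two near-zero singular values)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate landmark configuration: points are collinear, ",
         "midsagittal plane is undefined", call. = FALSE)
  normal <- sv$v[, 3]

  proj_inplane <- function(v) v - sum(v * normal) * normal
  sup <- proj_inplane(X["G", ] - X["Sn", ])
  if (vnorm(sup) < 1e-9)
    stop("Sn->G direction is orthogonal to the fitted plane; ",
         "cannot orient the superior axis", call. = FALSE)
  sup <- unitize(sup, "superior axis")
  ant <- c(sup[2] * normal[3] - sup[3] * normal[2],
           sup[3] * normal[1] - sup[1] * normal[3],
           sup[1] * normal[2] - sup[2] * normal[1])
  ant <- unitize(ant, "anterior axis")
  if (sum((X["Pn", ] - X["Sn", ]) * ant) < 0) ant <- -ant
  lat <- c(ant[2] * sup[3] - ant[3] * sup[2],
           ant[3] * sup[1] - ant[1] * sup[3],
           ant[1] * sup[2] - ant[2] * sup[1])
  structure(list(origin = unname(X["Sn", ]), anterior = unname(ant),
                 superior = unname(sup), lateral = unname(lat)),
            class = "sagittal_frame")
}

#' @export
print.sagittal_frame <- function(x, ...) {
  cat("Midsagittal frame\n  origin  :", format(x$origin, digits = 4), "\n")
  cat("  anterior:", format(x$anterior, digits = 4), "\n")
  cat("  superior:", format(x$superior, digits = 4), "\n")
  cat("  lateral :", format(x$lateral, digits = 4), "\n")
  invisible(x)
}

is_orthonormal_frame <- function(frame, tol = 1e-6) {
  ax <- rbind(frame$anterior, frame$superior, frame$lateral)
  g <- ax %*% t(ax)
  max(abs(g - diag(3))) < tol
}

#' Project landmarks into the sagittal plane
#'
#' Expresses each landmark in frame coordinates and drops the lateral
#' component, yielding 2D profile points (a = anterior mm, s = superior mm).
#'
#' @param landmarks A [landmark_set()].
#' @param frame A frame from [fit_midsagittal_frame()].
#' @return A matrix with one row per landmark and columns `a`, `s`.
#' @export
project_landmarks <- function(landmarks, frame) {
  landmarks <- landmark_set(landmarks)
  stopifnot(inherits(frame, "sagittal_frame"))
  X <- sweep(unclass(landmarks), 2, frame$origin)
  out <- cbind(a = as.numeric(X %*% frame$anterior),
               s = as.numeric(X %*% frame$superior))
  rownames(out) <- rownames(landmarks)
  out
}

#' Lateral (out-of-plane) landmark coordinates
#'
#' Companion to [project_landmarks()]: the signed lateral offset of each
#' landmark from the fitted midsagittal plane, used for the chin-deviation
#' quality check.
#'
#' @inheritParams project_landmarks
#' @return Named numeric vector of lateral offsets (mm).
#' @export
lateral_offsets <- function(landmarks, frame) {
  landmarks <- landmark_set(landmarks)
  stopifnot(inherits(frame, "sagittal_frame"))
  X <- sweep(unclass(landmarks), 2, frame$origin)
  stats::setNames(as.numeric(X %*% frame$lateral), rownames(landmarks))
}

profile_point <- function(a, s) {
  p <- c(a = as.numeric(a), s = as.numeric(s))
  if (!all(is.finite(p))) stop("profile point must be finite", call. = FALSE)
  p
}

#' Construct a line in the sagittal plane
#'
#' @param p0 Anchor point, numeric `(a, s)` in mm.
#' @param direction Direction vector `(a, s)`; normalized internally.
#' @return A `"sagittal_line"`: list with `p0` and unit `direction`.
#' @export
sagittal_line <- function(p0, direction) {
  p0 <- profile_point(p0[1], p0[2])
  d <- unitize(c(as.numeric(direction[1]), as.numeric(direction[2])),
               "line direction")
  structure(list(p0 = p0, direction = c(a = d[1], s = d[2])),
            class = "sagittal_line")
}

#' Line through two profile points
#'
#' @param from,to Profile points `(a, s)`; direction runs from `from`
#'   toward `to`.
#' @return A [sagittal_line()].
#' @export
line_through <- function(from, to) {
  d <- c(to[1] - from[1], to[2] - from[2])
  if (vnorm(d) < 1e-9)
    stop("cannot draw a line through coincident points", call. = FALSE)
  sagittal_line(from, d)
}

#' Angle of facial convexity
#'
#' Interior angle at subnasale between the rays Sn -> G and Sn -> pogonion,
#' in degrees. 180 degrees is a straight profile; smaller angles indicate a
#' more convex profile. Invariant under uniform scaling about `sn` and under
#' exchanging the two rays.
#'
#' @param g,sn,pog Profile points `(a, s)` in mm.
#' @return Angle in degrees, in (0, 180].
#' @export
facial_convexity_angle <- function(g, sn, pog) {
  u <- c(g[1] - sn[1], g[2] - sn[2])
  v <- c(pog[1] - sn[1], pog[2] - sn[2])
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-9 || nv < 1e-9)
    stop("zero-length ray: g and pog must differ from sn", call. = FALSE)
  cosang <- sum(u * v) / (nu * nv)
  rad2deg(acos(min(1, max(-1, cosang))))
}

# Anterior-pointing unit normal of a sagittal line: the perpendicular with
# positive anterior component (ties broken toward positive superior).
anterior_normal <- function(line) {
  d <- line$direction
  n <- c(-d[2], d[1])
  if (n[1] < 0 || (n[1] == 0 && n[2] < 0)) n <- -n
  c(a = n[1], s = n[2])
}

#' Signed perpendicular distance from a point to a line
#'
#' Distance of a profile point from an infinite line in the sagittal plane,
#' signed positive when the point lies on the anterior side of the line (the
#' side its anterior-pointing normal faces). Lips ahead of a reference line
#' therefore measure positive, behind it negative.
#'
#' @param p Profile point `(a, s)` in mm.
#' @param line A [sagittal_line()].
#' @return Signed distance in mm.
#' @export
signed_distance_to_line <- function(p, line) {
  stopifnot(inherits(line, "sagittal_line"))
  n <- anterior_normal(line)
  as.numeric((p[1] - line$p0[1]) * n[1] + (p[2] - line$p0[2]) * n[2])
}

# Horizontal (anteroposterior) offset from a point to a line: difference in
# anterior coordinate between p and the line at p's superior level. Provided
# as a sensitivity alternative to the perpendicular convention.
horizontal_distance_to_line <- function(p, line) {
  stopifnot(inherits(line, "sagittal_line"))
  d <- line$direction
  if (abs(d[2]) < 1e-9)
    stop("horizontal offset undefined for a horizontal line", call. = FALSE)
  t <- (p[2] - line$p0[2]) / d[2]
  a_line <- line$p0[1] + t * d[1]
  as.numeric(p[1] - a_line)
}
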