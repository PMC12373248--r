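#' Construct line A (glabella-subnasale line)
#'
#' The facial reference line through glabella and subnasale, directed from
#' G toward Sn (i.e. pointing inferiorly on a normally oriented face).
#'
#' @param g,sn Profile points `(a, s)` in mm.
#' @return A [sagittal_line()] anchored at `g`.
#' @export
construct_line_a <- function(g, sn) {
  line_through(g, sn)
}

#' Construct line M at the target convexity angle
#'
#' The ray from subnasale whose angle with the ray Sn -> G equals the target
#' facial-convexity angle (170 degrees by default), rotated to the posterior
#' side of line A and pointing inferiorly. A chin point on this ray realizes
#' the target angle of facial convexity exactly. Returned as an infinite
#' line anchored at `sn`.
#'
#' @param line_a Line A from [construct_line_a()].
#' @param g,sn Profile points; `sn` must lie on `line_a`.
#' @param target_angle Target convexity angle in degrees, in (90, 180].
#' @return A [sagittal_line()] anchored at `sn`.
#' @export
construct_line_m <- function(line_a, g, sn, target_angle = 170) {
  stopifnot(inherits(line_a, "sagittal_line"))
  if (!is.finite(target_angle) || target_angle <= 90 || target_angle > 180)
    stop("target_angle must lie in (90, 180] degrees", call. = FALSE)
  if (abs(signed_distance_to_line(sn, line_a)) > 1e-6)
    stop("sn does not lie on line A", call. = FALSE)
  u <- unitize(c(g[1] - sn[1], g[2] - sn[2]), "Sn->G ray")
  th <- deg2rad(target_angle)
  rot <- function(v, t) c(cos(t) * v[1] - sin(t) * v[2],
                          sin(t) * v[1] + cos(t) * v[2])
  cand <- list(rot(u, th), rot(u, -th))
  if (target_angle == 180) return(sagittal_line(sn, -u))
  nA <- anterior_normal(line_a)
  post <- vapply(cand, function(d) sum(d * nA), numeric(1))
  d <- cand[[which.min(post)]]  # posterior branch: negative anterior-normal component
  sagittal_line(sn, d)
}

#' Project the actual chin point onto line M
#'
#' Horizontally translates the actual chin point (ACP, the soft-tissue
#' pogonion) onto line M: the modified chin point (MCP) is the unique
#' intersection of the horizontal line through ACP with line M, and `x` is
#' the signed anterior-positive horizontal offset MCP - ACP. Negative `x`
#' means the MCP lies posterior to the ACP.
#'
#' @param acp Profile point `(a, s)` of the actual chin point, mm.
#' @param line_m Line M from [construct_line_m()].
#' @param line_a Optionally, line A (stored in the result).
#' @param target_angle The convexity criterion used to build `line_m`
#'   (stored in the result).
#' @return A `"chin_construction"`: list with `line_a`, `line_m`, `acp`,
#'   `mcp`, signed `x` (mm) and `target_angle`.
#' @export
compute_mcp <- function(acp, line_m, line_a = NULL, target_angle = NA_real_) {
  stopifnot(inherits(line_m, "sagittal_line"))
  d <- line_m$direction
  if (abs(d[2]) < sin(deg2rad(1)))
    stop(sprintf(
      "line M is within 1 degree of horizontal (direction angle %.3f deg); ",
      rad2deg(atan2(d[2], d[1]))),
      "the horizontal projection of ACP is ill-conditioned", call. = FALSE)
  t <- (acp[2] - line_m$p0[2]) / d[2]
  mcp <- c(a = as.numeric(line_m$p0[1] + t * d[1]), s = as.numeric(acp[2]))
  structure(list(line_a = line_a, line_m = line_m,
                 acp = c(a = as.numeric(acp[1]), s = as.numeric(acp[2])),
                 mcp = mcp,
                 x = as.numeric(mcp[1] - acp[1]),
                 target_angle = target_angle),
            class = "chin_construction")
}

#' @export
print.chin_construction <- function(x, ...) {
  cat("Modified chin point construction",
      if (is.finite(x$target_angle))
        sprintf("(target convexity %.6g deg)", x$target_angle), "\n")
  cat(sprintf("  ACP: (%.3f, %.3f) mm\n", x$acp[1], x$acp[2]))
  cat(sprintf("  MCP: (%.3f, %.3f) mm\n", x$mcp[1], x$mcp[2]))
  cat(sprintf("  horizontal offset x = %.3f mm (|x| = %.3f)\n", x$x, abs(x$x)))
  invisible(x)
}

#' Full chin construction from profile landmarks
#'
#' Convenience wrapper: builds line A from G and Sn, line M at the target
#' convexity angle, and projects the ACP onto it.
#'
#' @param g,sn,acp Profile points `(a, s)` in mm.
#' @param target_angle Convexity criterion in degrees (default 170).
#' @return A `"chin_construction"`; see [compute_mcp()].
#' @export
chin_construct <- function(g, sn, acp, target_angle = 170) {
  la <- construct_line_a(g, sn)
  lm <- construct_line_m(la, g, sn, target_angle)
  compute_mcp(acp, lm, line_a = la, target_angle = target_angle)
}

#' Unsigned ACP-to-MCP distance
#'
#' The horizontal distance between the actual and modified chin points,
#' reported unsigned; the signed offset is retained in the construction.
#'
#' @param construction A `"chin_construction"` from [compute_mcp()].
#' @return |x| in mm.
#' @export
acp_mcp_distance <- function(construction) {
  stopifnot(inherits(construction, "chin_construction"))
  abs(construction$x)
}
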