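#' Steiner S line
#'
#' Reference line from the columella point (Col) to the supplied soft-tissue
#' pogonion — either the actual chin point or the modified chin point.
#'
#' @param col Columella profile point `(a, s)`, mm.
#' @param pog Pogonion profile point (ACP or MCP).
#' @return A [sagittal_line()].
#' @export
build_s_line <- function(col, pog) {
  line_through(col, pog)
}

#' Ricketts E line
#'
#' Reference line from pronasale (Pn, nose tip) to the supplied soft-tissue
#' pogonion.
#'
#' @param pn Pronasale profile point `(a, s)`, mm.
#' @param pog Pogonion profile point (ACP or MCP).
#' @return A [sagittal_line()].
#' @export
build_e_line <- function(pn, pog) {
  line_through(pn, pog)
}

#' Lip position against the S and E lines under both chin points
#'
#' For each pogonion source (ACP and MCP) builds the Steiner S line (Col to
#' pogonion) and Ricketts E line (Pn to pogonion) and measures the signed
#' distance of the upper and lower lip from each, anterior-positive. The two
#' sources share the Col and Pn anchors and differ only in the chin anchor,
#' so measurements coincide exactly when the ACP-MCP offset x is zero.
#'
#' @param profile Matrix of projected landmarks from [project_landmarks()]
#'   (rows must include Col, Pn, UL, LL).
#' @param construction A `"chin_construction"` from [chin_construct()].
#' @param method `"perpendicular"` (default, standard cephalometric
#'   convention) or `"horizontal"` for pure anteroposterior offsets.
#' @return A data.frame with one row per pogonion source and columns
#'   `source`, `ul_s`, `ll_s`, `ul_e`, `ll_e` (signed mm).
#' @export
measure_subject <- function(profile, construction,
                            method = c("perpendicular", "horizontal")) {
  method <- match.arg(method)
  stopifnot(inherits(construction, "chin_construction"))
  need <- c("Col", "Pn", "UL", "LL")
  if (!all(need %in% rownames(profile)))
    stop("profile must contain rows: ", paste(need, collapse = ", "),
         call. = FALSE)
  distfun <- if (method == "perpendicular") signed_distance_to_line
             else horizontal_distance_to_line
  one_source <- function(pog) {
    s_line <- build_s_line(profile["Col", ], pog)
    e_line <- build_e_line(profile["Pn", ], pog)
    c(ul_s = distfun(profile["UL", ], s_line),
      ll_s = distfun(profile["LL", ], s_line),
      ul_e = distfun(profile["UL", ], e_line),
      ll_e = distfun(profile["LL", ], e_line))
  }
  out <- rbind(one_source(construction$acp), one_source(construction$mcp))
  data.frame(source = c("ACP", "MCP"), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Flag lip distances against the aesthetic window
#'
#' Lip positions within approximately +/- 2 mm of the S or E line are rated
#' most aesthetic in the population the method was calibrated for; this
#' flags each measurement as inside or outside that (closed) window.
#'
#' @param measurements Numeric vector (or one row of [measure_subject()]
#'   output) of signed lip distances in mm.
#' @param window Half-width of the aesthetic window in mm (default 2).
#' @return Character vector of `"within"` / `"outside"`, same names.
#' @export
aesthetic_flag <- function(measurements, window = 2) {
  if (!is.finite(window) || window <= 0)
    stop("window must be a positive number of mm", call. = FALSE)
  if (is.data.frame(measurements)) {
    if (nrow(measurements) != 1)
      stop("pass a single row of measurements", call. = FALSE)
    measurements <- unlist(measurements[setdiff(names(measurements), "source")])
  }
  nms <- names(measurements)
  m <- as.numeric(measurements)
  stats::setNames(ifelse(abs(m) <= window, "within", "outside"), nms)
}
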