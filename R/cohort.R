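# Cohort container: a long data.frame, one row per landmark, with columns
# subject_id, sex, timepoint, landmark, anterior_mm, superior_mm, lateral_mm.
# This is also the on-disk CSV schema (one row per landmark is robust to
# schema growth); the JSON format mirrors it as an array of records.

COHORT_COLUMNS <- c("subject_id", "sex", "timepoint", "landmark",
                    "anterior_mm", "superior_mm", "lateral_mm")

#' Default sex label aliases
#'
#' Labels are matched case-insensitively; unknown labels are rejected rather
#' than coerced.
#'
#' @return Named character vector mapping lowercase aliases to canonical
#'   `"male"` / `"female"`.
#' @export
default_sex_aliases <- function() {
  c(male = "male", m = "male", female = "female", f = "female")
}

normalize_sex <- function(sex, aliases = default_sex_aliases()) {
  key <- tolower(trimws(as.character(sex)))
  out <- unname(aliases[key])
  bad <- unique(sex[is.na(out)])
  if (length(bad) > 0)
    stop("unknown sex label(s): ", paste(bad, collapse = ", "),
         "; extend the alias map to accept them", call. = FALSE)
  out
}

#' Assemble and validate a landmark cohort
#'
#' @param df Data.frame in long format with columns `subject_id`, `sex`,
#'   `timepoint` (`"T0"`/`"T1"`), `landmark` (G, Sn, Pn, Col, UL, LL, ACP)
#'   and coordinates `anterior_mm`, `superior_mm`, `lateral_mm`.
#' @param sex_aliases Alias map as in [default_sex_aliases()].
#' @return A validated `"chin_cohort"` data.frame.
#' @export
as_cohort <- function(df, sex_aliases = default_sex_aliases()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- df[COHORT_COLUMNS]
  df$subject_id <- as.character(df$subject_id)
  if (any(!nzchar(df$subject_id) | is.na(df$subject_id)))
    stop("subject_id must be nonempty", call. = FALSE)
  df$sex <- normalize_sex(df$sex, sex_aliases)
  df$timepoint <- as.character(df$timepoint)
  bad_tp <- setdiff(unique(df$timepoint), c("T0", "T1"))
  if (length(bad_tp) > 0)
    stop("unknown timepoint(s): ", paste(bad_tp, collapse = ", "),
         call. = FALSE)
  bad_lm <- setdiff(unique(df$landmark), LANDMARK_NAMES)
  if (length(bad_lm) > 0)
    stop("unknown landmark name(s): ", paste(bad_lm, collapse = ", "),
         call. = FALSE)
  for (col in c("anterior_mm", "superior_mm", "lateral_mm")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.finite(df[[col]])))
      stop("non-finite coordinates in column ", col, call. = FALSE)
  }

  key <- paste(df$subject_id, df$timepoint, sep = "\r")
  for (k in unique(key)) {
    rows <- df[key == k, ]
    id <- rows$subject_id[1]; tp <- rows$timepoint[1]
    dup <- rows$landmark[duplicated(rows$landmark)]
    if (length(dup) > 0)
      stop(sprintf("duplicate landmark(s) %s for subject %s at %s",
                   paste(unique(dup), collapse = ", "), id, tp), call. = FALSE)
    miss <- setdiff(LANDMARK_NAMES, rows$landmark)
    if (length(miss) > 0)
      stop(sprintf("subject %s at %s is missing landmark(s): %s",
                   id, tp, paste(miss, collapse = ", ")), call. = FALSE)
    if (length(unique(rows$sex)) != 1)
      stop("inconsistent sex for subject ", id, call. = FALSE)
    landmark_set(`rownames<-`(as.matrix(rows[c("anterior_mm", "superior_mm",
                                               "lateral_mm")]), rows$landmark))
  }
  df <- df[order(df$subject_id, df$timepoint,
                 match(df$landmark, LANDMARK_NAMES)), ]
  rownames(df) <- NULL
  class(df) <- c("chin_cohort", "data.frame")
  df
}

#' @export
print.chin_cohort <- function(x, ...) {
  rec <- unique(x[c("subject_id", "timepoint")])
  cat(sprintf("Landmark cohort: %d subjects, %d records (T0: %d, T1: %d)\n",
              length(unique(x$subject_id)), nrow(rec),
              sum(rec$timepoint == "T0"), sum(rec$timepoint == "T1")))
  NextMethod()
}

#' Extract one subject/timepoint landmark set
#'
#' @param cohort A `"chin_cohort"`.
#' @param subject_id,timepoint Record to extract.
#' @return A [landmark_set()].
#' @export
cohort_landmarks <- function(cohort, subject_id, timepoint) {
  rows <- cohort[cohort$subject_id == subject_id &
                 cohort$timepoint == timepoint, ]
  if (nrow(rows) == 0)
    stop("no record for subject ", subject_id, " at ", timepoint, call. = FALSE)
  landmark_set(`rownames<-`(as.matrix(rows[c("anterior_mm", "superior_mm",
                                             "lateral_mm")]), rows$landmark))
}

#' Read a landmark cohort from CSV or JSON
#'
#' @param path File path. Format is inferred from the extension unless given.
#' @param format `"csv"` or `"json"`.
#' @param sex_aliases Alias map as in [default_sex_aliases()].
#' @return A validated `"chin_cohort"`.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json"),
                        sex_aliases = default_sex_aliases()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  as_cohort(df, sex_aliases = sex_aliases)
}

#' Write a landmark cohort to CSV or JSON
#'
#' Coordinates are written at full precision (15 significant digits) so that
#' a read/write round trip reproduces every coordinate to well below 1e-9 mm.
#'
#' @param cohort A `"chin_cohort"`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (inferred from extension by default).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- as.data.frame(cohort)
  if (format == "csv") {
    out <- df
    for (col in c("anterior_mm", "superior_mm", "lateral_mm"))
      out[[col]] <- sprintf("%.15g", out[[col]])
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Chin-deviation quality check
#'
#' Mirrors the cohort exclusion rule for clinically apparent facial
#' asymmetry: a record fails when the soft-tissue chin deviates from the
#' midsagittal plane by strictly more than the threshold (default 3 mm).
#' The deviation is the absolute lateral coordinate of the ACP in the
#' fitted frame, so the decision is invariant under rigid motion of the
#' whole landmark set.
#'
#' @param landmarks A [landmark_set()].
#' @param frame Optional [fit_midsagittal_frame()] result (refit if omitted).
#' @param threshold Exclusion threshold in mm; strictly-greater comparison.
#' @return List with `pass` (logical) and `deviation` (mm).
#' @export
chin_deviation_qc <- function(landmarks, frame = NULL, threshold = 3) {
  landmarks <- landmark_set(landmarks)
  if (is.null(frame)) frame <- fit_midsagittal_frame(landmarks)
  if (!is_orthonormal_frame(frame))
    stop("frame axes are not orthonormal", call. = FALSE)
  dev <- abs(unname(lateral_offsets(landmarks, frame)["ACP"]))
  list(pass = !(dev > threshold), deviation = dev)
}

#' Measure a full cohort
#'
#' Runs the complete per-record measurement pipeline: fit the midsagittal
#' frame, project the landmarks, run the chin-deviation QC, perform the
#' modified-chin-point construction, and measure the four lip distances
#' under both the ACP- and MCP-based reference lines.
#'
#' @param cohort A `"chin_cohort"` (see [read_cohort()], [as_cohort()]).
#' @param target_angle Convexity criterion in degrees (default 170).
#' @param lip_method `"perpendicular"` or `"horizontal"`; see
#'   [measure_subject()].
#' @param qc_threshold Chin-deviation threshold in mm.
#' @return Data.frame with one row per subject/timepoint: geometry columns
#'   (`convexity_deg`, `acp_a`, `acp_s`, `mcp_a`, `mcp_s`, `x_signed_mm`,
#'   `x_abs_mm`, `chin_deviation_mm`, `qc_pass`) and lip distances for both
#'   sources (`acp_ul_s`, ..., `mcp_ll_e`).
#' @export
measure_cohort <- function(cohort, target_angle = 170,
                           lip_method = c("perpendicular", "horizontal"),
                           qc_threshold = 3) {
  lip_method <- match.arg(lip_method)
  cohort <- as_cohort(cohort)
  if (nrow(cohort) == 0) stop("no paired subjects", call. = FALSE)
  rec <- unique(as.data.frame(cohort)[c("subject_id", "sex", "timepoint")])
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    lm <- cohort_landmarks(cohort, rec$subject_id[i], rec$timepoint[i])
    frame <- fit_midsagittal_frame(lm)
    prof <- project_landmarks(lm, frame)
    qc <- chin_deviation_qc(lm, frame, threshold = qc_threshold)
    conv <- facial_convexity_angle(prof["G", ], prof["Sn", ], prof["ACP", ])
    cons <- chin_construct(prof["G", ], prof["Sn", ], prof["ACP", ],
                           target_angle = target_angle)
    lips <- measure_subject(prof, cons, method = lip_method)
    acp <- lips[lips$source == "ACP", c("ul_s", "ll_s", "ul_e", "ll_e")]
    mcp <- lips[lips$source == "MCP", c("ul_s", "ll_s", "ul_e", "ll_e")]
    data.frame(subject_id = rec$subject_id[i], sex = rec$sex[i],
               timepoint = rec$timepoint[i],
               convexity_deg = conv,
               acp_a = cons$acp[["a"]], acp_s = cons$acp[["s"]],
               mcp_a = cons$mcp[["a"]], mcp_s = cons$mcp[["s"]],
               x_signed_mm = cons$x, x_abs_mm = abs(cons$x),
               chin_deviation_mm = qc$deviation, qc_pass = qc$pass,
               acp_ul_s = acp$ul_s, acp_ll_s = acp$ll_s,
               acp_ul_e = acp$ul_e, acp_ll_e = acp$ll_e,
               mcp_ul_s = mcp$ul_s, mcp_ll_s = mcp$ll_s,
               mcp_ul_e = mcp$ul_e, mcp_ll_e = mcp$ll_e,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$timepoint), ]
  rownames(out) <- NULL
  out
}
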