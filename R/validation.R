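# Variable labels used throughout the result tables.
LIP_VARIABLES <- c("ul_s", "ll_s", "ul_e", "ll_e")
LIP_LABELS <- c(ul_s = "UL / S line", ll_s = "LL / S line",
                ul_e = "UL / E line", ll_e = "LL / E line")

wide_col <- function(source, var) paste0(tolower(source), "_", var)

desc_row <- function(values) {
  d <- descriptive_stats(values)
  c(mean = d$mean, sd = d$sd, ci_low = d$ci_low, ci_high = d$ci_high)
}

#' Run the full cohort validation analysis
#'
#' Measures every record, applies the chin-deviation QC (failing subjects
#' are excluded in full, with a log message), checks T0/T1 pairing, and
#' assembles the method-validation tables:
#'
#' * `table2` — per lip variable and timepoint, descriptives of the ACP- and
#'   MCP-based measurements and the paired t test between them;
#' * `table3` — the unsigned ACP-to-MCP distance |x| at T0 and T1
#'   (mean, SD, median, IQR) with the paired Wilcoxon signed-rank p for the
#'   T0 vs T1 comparison;
#' * `table4` — ME / MAE method-agreement summaries of ACP minus MCP at T1;
#' * `table5` — sex-stratified T1 MCP-based lip descriptives with the Welch
#'   t test between sexes;
#' * `correlations` — Pearson r per variable for ACP(T1) vs MCP(T1) and for
#'   MCP(T0) vs MCP(T1);
#' * `normality` — Shapiro-Wilk p per variable/timepoint/source (logged as a
#'   gate; it does not switch tests);
#' * `aesthetic` — per variable, the proportion of T1 MCP-based lip
#'   positions inside the aesthetic window.
#'
#' @param cohort A `"chin_cohort"`, or a measurement data.frame from
#'   [measure_cohort()] (recognized by its columns).
#' @param config An [analysis_config()].
#' @param lip_method Passed to [measure_cohort()].
#' @param quiet Suppress log messages.
#' @return A `"cohort_results"` list with the tables above plus
#'   `measurements`, `config`, `n_subjects`, `excluded`.
#' @export
run_validation <- function(cohort, config = analysis_config(),
                           lip_method = c("perpendicular", "horizontal"),
                           quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  lip_method <- match.arg(lip_method)
  say <- function(...) if (!quiet) message(...)

  meas <- if (is.data.frame(cohort) && all(c("x_signed_mm", "acp_ul_s")
                                           %in% names(cohort))) {
    cohort
  } else {
    measure_cohort(cohort, target_angle = config$target_angle,
                   lip_method = lip_method)
  }

  excluded <- unique(meas$subject_id[!meas$qc_pass])
  if (length(excluded) > 0) {
    say("excluding ", length(excluded),
        " subject(s) failing the chin-deviation QC: ",
        paste(excluded, collapse = ", "))
    meas <- meas[!meas$subject_id %in% excluded, ]
  }

  t0 <- meas[meas$timepoint == "T0", ]
  t1 <- meas[meas$timepoint == "T1", ]
  ids <- intersect(t0$subject_id, t1$subject_id)
  unpaired <- setdiff(union(t0$subject_id, t1$subject_id), ids)
  if (length(unpaired) > 0)
    stop("unpaired subject(s) (present at only one timepoint): ",
         paste(unpaired, collapse = ", "), call. = FALSE)
  if (length(ids) == 0) stop("no paired subjects", call. = FALSE)
  ids <- sort(ids)
  t0 <- t0[match(ids, t0$subject_id), ]
  t1 <- t1[match(ids, t1$subject_id), ]

  # Shapiro-Wilk normality gate, logged per variable/timepoint/source
  normality <- do.call(rbind, lapply(c("T0", "T1"), function(tp) {
    tab <- if (tp == "T0") t0 else t1
    do.call(rbind, lapply(c("ACP", "MCP"), function(src) {
      do.call(rbind, lapply(LIP_VARIABLES, function(v) {
        x <- tab[[wide_col(src, v)]]
        p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
        data.frame(timepoint = tp, source = src, variable = v,
                   shapiro_p = p, stringsAsFactors = FALSE)
      }))
    }))
  }))
  n_nonnormal <- sum(normality$shapiro_p < 0.05, na.rm = TRUE)
  say("Shapiro-Wilk gate: ", n_nonnormal, " of ", nrow(normality),
      " variable distributions depart from normality at p < 0.05")

  # table2: ACP vs MCP lip positions per timepoint
  table2 <- do.call(rbind, lapply(c("T0", "T1"), function(tp) {
    tab <- if (tp == "T0") t0 else t1
    do.call(rbind, lapply(LIP_VARIABLES, function(v) {
      a <- tab[[wide_col("ACP", v)]]
      b <- tab[[wide_col("MCP", v)]]
      da <- desc_row(a); db <- desc_row(b)
      tt <- paired_t(a, b)
      data.frame(timepoint = tp, variable = v, label = LIP_LABELS[[v]],
                 n = length(a),
                 acp_mean = da[["mean"]], acp_sd = da[["sd"]],
                 acp_ci_low = da[["ci_low"]], acp_ci_high = da[["ci_high"]],
                 mcp_mean = db[["mean"]], mcp_sd = db[["sd"]],
                 mcp_ci_low = db[["ci_low"]], mcp_ci_high = db[["ci_high"]],
                 t = tt$t, p = tt$p, stringsAsFactors = FALSE)
    }))
  }))

  # table3: |x| per timepoint, Wilcoxon T0 vs T1 (p is NA when there are
  # too few nonzero differences for the signed-rank null to be meaningful)
  wx <- tryCatch(wilcoxon_signed_rank(t0$x_abs_mm, t1$x_abs_mm),
                 error = function(e) list(p = NA_real_))
  table3 <- do.call(rbind, lapply(c("T0", "T1"), function(tp) {
    x <- if (tp == "T0") t0$x_abs_mm else t1$x_abs_mm
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(timepoint = tp, n = length(x),
               mean = mean(x), sd = stats::sd(x),
               median = q[2], iqr_25 = q[1], iqr_75 = q[3],
               wilcoxon_p = wx$p, stringsAsFactors = FALSE)
  }))

  # table4: ME / MAE of ACP(T1) - MCP(T1)
  table4 <- do.call(rbind, lapply(LIP_VARIABLES, function(v) {
    ve <- validity_errors(t1[[wide_col("ACP", v)]], t1[[wide_col("MCP", v)]])
    data.frame(variable = v, label = LIP_LABELS[[v]],
               me_mean = ve$me_mean, me_sd = ve$me_sd,
               me_min = ve$me_min, me_max = ve$me_max,
               mae_mean = ve$mae_mean, mae_sd = ve$mae_sd,
               mae_min = ve$mae_min, mae_max = ve$mae_max,
               stringsAsFactors = FALSE)
  }))

  # table5: sex-stratified T1 MCP-based lip positions, Welch t between sexes
  males <- t1[t1$sex == "male", ]
  females <- t1[t1$sex == "female", ]
  table5 <- if (nrow(males) >= 2 && nrow(females) >= 2) {
    do.call(rbind, lapply(LIP_VARIABLES, function(v) {
      gm <- males[[wide_col("MCP", v)]]
      gf <- females[[wide_col("MCP", v)]]
      dm <- desc_row(gm); df_ <- desc_row(gf)
      tt <- independent_t(gm, gf)
      data.frame(variable = v, label = LIP_LABELS[[v]],
                 male_n = length(gm), female_n = length(gf),
                 male_mean = dm[["mean"]], male_sd = dm[["sd"]],
                 male_ci_low = dm[["ci_low"]], male_ci_high = dm[["ci_high"]],
                 female_mean = df_[["mean"]], female_sd = df_[["sd"]],
                 female_ci_low = df_[["ci_low"]],
                 female_ci_high = df_[["ci_high"]],
                 t = tt$t, p = tt$p, stringsAsFactors = FALSE)
    }))
  } else {
    say("fewer than 2 subjects in a sex stratum: table5 skipped")
    NULL
  }

  # correlations: ACP(T1) vs MCP(T1) and MCP(T0) vs MCP(T1)
  na_cor <- list(r = NA_real_, p = NA_real_, n = NA_integer_)
  safe_cor <- function(a, b) tryCatch(pearson_r(a, b),
                                      error = function(e) na_cor)
  correlations <- do.call(rbind, lapply(LIP_VARIABLES, function(v) {
    c1 <- safe_cor(t1[[wide_col("ACP", v)]], t1[[wide_col("MCP", v)]])
    c2 <- safe_cor(t0[[wide_col("MCP", v)]], t1[[wide_col("MCP", v)]])
    data.frame(variable = v, label = LIP_LABELS[[v]],
               comparison = c("ACP_T1_vs_MCP_T1", "MCP_T0_vs_MCP_T1"),
               r = c(c1$r, c2$r), p = c(c1$p, c2$p),
               n = c(c1$n, c2$n), stringsAsFactors = FALSE)
  }))

  aesthetic <- do.call(rbind, lapply(LIP_VARIABLES, function(v) {
    x <- t1[[wide_col("MCP", v)]]
    data.frame(variable = v, label = LIP_LABELS[[v]],
               window_mm = config$aesthetic_window,
               prop_within = mean(abs(x) <= config$aesthetic_window),
               stringsAsFactors = FALSE)
  }))

  structure(list(table2 = table2, table3 = table3, table4 = table4,
                 table5 = table5, correlations = correlations,
                 normality = normality, aesthetic = aesthetic,
                 measurements = meas, config = config,
                 n_subjects = length(ids), excluded = excluded),
            class = "cohort_results")
}

#' @export
print.cohort_results <- function(x, ...) {
  thr <- bonferroni_threshold(x$config)
  cat(sprintf(
    "Modified-chin-point validation: %d paired subjects (threshold p < %g)\n",
    x$n_subjects, thr))
  cat("\nACP-to-MCP distance |x| (mm):\n")
  print(format(x$table3, digits = 3), row.names = FALSE)
  cat("\nLip position ACP vs MCP (paired t):\n")
  print(format(x$table2[c("timepoint", "label", "acp_mean", "mcp_mean", "p")],
               digits = 3), row.names = FALSE)
  cat("\nMethod agreement at T1 (ACP - MCP):\n")
  print(format(x$table4[c("label", "me_mean", "me_sd", "mae_mean", "mae_sd")],
               digits = 3), row.names = FALSE)
  invisible(x)
}

#' Write validation results to disk
#'
#' Writes one CSV per table (`table2.csv` ... `table5.csv`,
#' `correlations.csv`, `measurements.csv`) plus `summary.json`, all with a
#' deterministic column order and full numeric precision; any display
#' rounding is left to human reports.
#'
#' @param results A `"cohort_results"` from [run_validation()].
#' @param path Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(inherits(results, "cohort_results"))
  if (is.null(results$n_subjects) || results$n_subjects == 0)
    stop("no paired subjects", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path,
                              call. = FALSE)
  write_one <- function(df, name) {
    file <- file.path(path, paste0(name, ".csv"))
    out <- df
    for (col in names(out)) {
      if (is.numeric(out[[col]])) out[[col]] <- sprintf("%.15g", out[[col]])
    }
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
    file
  }
  files <- c(write_one(results$table2, "table2"),
             write_one(results$table3, "table3"),
             write_one(results$table4, "table4"))
  if (!is.null(results$table5))
    files <- c(files, write_one(results$table5, "table5"))
  files <- c(files,
             write_one(results$correlations, "correlations"),
             write_one(results$measurements, "measurements"))
  summary_file <- file.path(path, "summary.json")
  jsonlite::write_json(
    list(n_subjects = results$n_subjects,
         excluded = as.list(results$excluded),
         threshold = bonferroni_threshold(results$config),
         aesthetic = results$aesthetic,
         normality = results$normality),
    summary_file, digits = NA, auto_unbox = TRUE)
  files <- c(files, summary_file)
  invisible(files)
}
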