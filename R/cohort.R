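COHORT_CSV_MD5 <- "8929152b0a985d3ce1999b315011c242"

#' Load the packaged clinical cohort table
#'
#' Reads the packaged transcription of the 25-tumor clinical cohort: per
#' tumor, patient age, laterality, breast quadrant, mammographic density
#' category (PF/SF/HD/ED), histology (ADH/DCIS/IDC/ILC/LCIS), grade
#' (X/1/2/3), actual and thermally estimated tumor size (cm), concomitant
#' in-situ component, TNM staging, receptor status, and MRI-derived tumor
#' depth (cm). Fields printed as an em-dash in the source table are kept
#' missing (`NA`), including one record's MRI depth. The fixture is
#' integrity-checked against its transcription checksum.
#'
#' @param path optional override of the packaged CSV (for testing).
#' @return a `cohort_table` data frame with 25 rows.
#' @examples
#' cohort <- load_cohort_table()
#' nrow(cohort)
#' @export
load_cohort_table <- function(path = NULL) {
  file <- path %||% system.file("extdata", "table1_cohort.csv",
                                package = "thermoscreen", mustWork = TRUE)
  if (is.null(path) && !identical(unname(tools::md5sum(file)), COHORT_CSV_MD5)) {
    stop("packaged cohort fixture failed its checksum", call. = FALSE)
  }
  df <- read.csv(file, stringsAsFactors = FALSE, na.strings = "",
                 colClasses = c(age = "integer", actual_size_cm = "numeric",
                                estimated_size_cm = "numeric",
                                depth_mri_cm = "numeric", grade = "character"))
  validate_cohort(df)
  class(df) <- c("cohort_table", "data.frame")
  df
}

validate_cohort <- function(df) {
  if (nrow(df) != 25) stop("cohort table must have exactly 25 rows", call. = FALSE)
  stopifnot(
    all(df$actual_size_cm > 0),
    all(df$estimated_size_cm > 0),
    all(df$laterality %in% c("L", "R")),
    all(df$quadrant %in% c("UOQ", "UIQ", "LOQ", "LIQ")),
    all(df$density %in% c("PF", "SF", "HD", "ED")),
    all(df$histology %in% c("ADH", "DCIS", "IDC", "ILC", "LCIS")),
    all(df$grade %in% c("X", "1", "2", "3"))
  )
  invisible(df)
}

#' Summarize the cohort
#'
#' Computes the descriptive statistics of the tumor cohort: median and range
#' of age, counts by density, laterality, quadrant, histology and grade, the
#' range of actual tumor sizes, and the maximum absolute difference between
#' actual and thermally estimated sizes. Statistics are over the 25 tumor
#' rows (one patient is bilateral; row-to-patient linkage is not recorded).
#'
#' @param records a `cohort_table` from [load_cohort_table()].
#' @return a `cohort_summary` list.
#' @examples
#' summarize_cohort(load_cohort_table())
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty cohort table", call. = FALSE)
  }
  size_diff <- abs(records$actual_size_cm - records$estimated_size_cm)
  structure(list(
    n_tumors = nrow(records),
    median_age = median(records$age),
    age_range = range(records$age),
    density_counts = table(factor(records$density, c("PF", "SF", "HD", "ED"))),
    laterality_counts = table(factor(records$laterality, c("L", "R"))),
    quadrant_counts = table(factor(records$quadrant, c("UOQ", "UIQ", "LOQ", "LIQ"))),
    histology_counts = table(factor(records$histology,
                                    c("ADH", "DCIS", "IDC", "ILC", "LCIS"))),
    grade_counts = table(factor(records$grade, c("X", "1", "2", "3"))),
    min_actual_size_cm = min(records$actual_size_cm),
    max_actual_size_cm = max(records$actual_size_cm),
    max_size_discrepancy_cm = max(size_diff),
    n_missing_depth = sum(is.na(records$depth_mri_cm)),
    depth_range_cm = range(records$depth_mri_cm, na.rm = TRUE)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d tumor rows (statistics are per tumor, not per patient)\n",
              x$n_tumors))
  cat(sprintf("  age: median %g, range %g-%g\n", x$median_age,
              x$age_range[1], x$age_range[2]))
  cat("  density:", paste(sprintf("%s=%d", names(x$density_counts),
                                  x$density_counts), collapse = " "), "\n")
  cat("  quadrant:", paste(sprintf("%s=%d", names(x$quadrant_counts),
                                   x$quadrant_counts), collapse = " "), "\n")
  cat("  histology:", paste(sprintf("%s=%d", names(x$histology_counts),
                                    x$histology_counts), collapse = " "), "\n")
  cat(sprintf("  actual size: %.1f-%.1f cm; max |actual - estimated| = %.1f cm\n",
              x$min_actual_size_cm, x$max_actual_size_cm,
              x$max_size_discrepancy_cm))
  cat(sprintf("  note: the source text reports a 7 mm maximum size error; the\n"))
  cat(sprintf("  tabulated maximum |actual - estimated| is %.0f mm (flagged, not resolved)\n",
              10 * x$max_size_discrepancy_cm))
  cat(sprintf("  MRI depth: %.2f-%.2f cm (%d missing)\n",
              x$depth_range_cm[1], x$depth_range_cm[2], x$n_missing_depth))
  invisible(x)
}

#' Score a validation batch of inverse fits against ground truth
#'
#' For each case, the true tumor parameters (or tumor-free status) are
#' compared with the classified inverse fit: size error `|D_true - D_hat|`,
#' location error `||center_true - center_hat||`, and the detection call.
#' Aggregates: sensitivity = detected present / truly present, specificity =
#' classified absent / truly absent (percent), plus maximum and mean errors
#' over detected tumor-bearing cases.
#'
#' @param truths list with one element per case: a [tumor_params()] for
#'   tumor-bearing cases or `NULL` for tumor-free cases.
#' @param results list of classified `inverse_result`s (same length/order).
#' @return a `validation_report` with a per-case data frame `$cases` and
#'   aggregate fields (`$sensitivity`, `$specificity` in percent — `NA` when
#'   the corresponding class is empty — and size/location error summaries
#'   in mm).
#' @export
score_validation <- function(truths, results) {
  if (length(truths) == 0) stop("empty validation batch", call. = FALSE)
  if (length(truths) != length(results)) {
    stop("truths and results must have the same length", call. = FALSE)
  }
  rows <- lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]
    res <- results[[i]]
    stop_if_not_class(res, "inverse_result")
    if (is.na(res$detected)) {
      stop("case ", i, " has not been classified (run classify_detection)",
           call. = FALSE)
    }
    present <- !is.null(tr)
    th <- res$theta_hat
    data.frame(
      case = i,
      truth_present = present,
      detected = res$detected,
      true_d_mm = if (present) 1000 * tr$diameter else NA_real_,
      est_d_mm = 1000 * th$diameter,
      size_error_mm = if (present) 1000 * abs(tr$diameter - th$diameter) else NA_real_,
      location_error_mm = if (present)
        1000 * sqrt(sum((tr$center - th$center)^2)) else NA_real_,
      residual_rms = res$residual_rms,
      decision_reason = res$decision_reason
    )
  })
  cases <- do.call(rbind, rows)
  pres <- cases$truth_present
  correct_pos <- cases$detected & pres
  sens <- if (any(pres)) 100 * sum(correct_pos) / sum(pres) else NA_real_
  spec <- if (any(!pres)) 100 * sum(!cases$detected & !pres) / sum(!pres) else NA_real_
  scored <- cases[correct_pos, , drop = FALSE]
  structure(list(
    cases = cases,
    n_present = sum(pres),
    n_absent = sum(!pres),
    sensitivity = sens,
    specificity = spec,
    max_size_error_mm = if (nrow(scored)) max(scored$size_error_mm) else NA_real_,
    mean_size_error_mm = if (nrow(scored)) mean(scored$size_error_mm) else NA_real_,
    max_location_error_mm = if (nrow(scored)) max(scored$location_error_mm) else NA_real_,
    mean_location_error_mm = if (nrow(scored)) mean(scored$location_error_mm) else NA_real_
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d tumor-bearing + %d tumor-free cases\n",
              x$n_present, x$n_absent))
  cat(sprintf("  sensitivity %s, specificity %s\n",
              if (is.na(x$sensitivity)) "undefined" else sprintf("%.0f%%", x$sensitivity),
              if (is.na(x$specificity)) "undefined" else sprintf("%.0f%%", x$specificity)))
  if (!is.na(x$max_size_error_mm)) {
    cat(sprintf("  size error: max %.1f mm, mean %.1f mm\n",
                x$max_size_error_mm, x$mean_size_error_mm))
    cat(sprintf("  location error: max %.1f mm, mean %.1f mm\n",
                x$max_location_error_mm, x$mean_location_error_mm))
  }
  invisible(x)
}
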