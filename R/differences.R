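#' Per-fraction metric differences between dose distributions
#'
#' For every valid metric of every fraction, computes the three pairwise
#' contrasts between the reference (REF), scheduled (SCH) and adapted (ADP)
#' dose values: `sch_ref = SCH - REF`, `adp_ref = ADP - REF`,
#' `adp_sch = ADP - SCH`. Differences are in the metric's native unit (Gy for
#' D-metrics, percentage points for V-metrics). Rows whose metric is not
#' valid, or that are missing any of the three values, are dropped (with a
#' warning for incomplete valid rows); a partial set of contrasts is never
#' emitted.
#'
#' @param metric_table A metric table as produced by [evaluate_fraction()] or
#'   [generate_metric_cohort()].
#' @return A difference table: `patient_id`, `fraction_index`, `site`,
#'   `structure`, `metric_id`, `unit`, `sch_ref`, `adp_ref`, `adp_sch`.
#' @export
compute_differences <- function(metric_table) {
  required <- c("patient_id", "fraction_index", "site", "structure",
                "metric_id", "status", "unit", "ref_value", "sch_value",
                "adp_value")
  missing <- setdiff(required, names(metric_table))
  if (length(missing) > 0L) {
    stop("metric table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  valid <- dplyr::filter(metric_table, .data$status == "valid")
  complete <- !is.na(valid$ref_value) & !is.na(valid$sch_value) &
    !is.na(valid$adp_value)
  if (any(!complete)) {
    warning(sum(!complete), " valid metric row(s) with missing values skipped",
            call. = FALSE)
    valid <- valid[complete, ]
  }
  out <- dplyr::transmute(
    valid,
    .data$patient_id, .data$fraction_index, .data$site, .data$structure,
    .data$metric_id, .data$unit,
    sch_ref = .data$sch_value - .data$ref_value,
    adp_ref = .data$adp_value - .data$ref_value
  )
  # ADP-SCH is (ADP-REF) - (SCH-REF) by the algebraic identity; assert that
  # this agrees with the direct ADP - SCH subtraction to rounding
  out$adp_sch <- out$adp_ref - out$sch_ref
  direct <- valid$adp_value - valid$sch_value
  stopifnot(max(abs(out$adp_sch - direct), 0) < 1e-9)
  out
}

table2_structure_order <- c("ptv", "ctv", "bowel", "bladder", "rectum", "femurs")

#' Summarize difference distributions by site, metric and contrast
#'
#' Produces the descriptive summary of the per-fraction difference
#' distributions: the median and interquartile range of each contrast
#' (SCH-REF, ADP-REF, ADP-SCH) per site and metric, pooling fractions across
#' patients (optionally summarizing per-patient medians instead). Quantiles
#' use linear interpolation between closest ranks (R type 7); IQR is Q3 - Q1
#' under the same convention.
#'
#' @param differences A difference table from [compute_differences()].
#' @param per_patient If `TRUE`, fractions are first collapsed to per-patient
#'   medians and the summary describes patients rather than pooled fractions.
#'   Default `FALSE` (pooled fractions).
#' @return A tibble with one row per site x metric x contrast: `site`,
#'   `structure`, `metric_id`, `unit`, `contrast` (one of `SCH_REF`,
#'   `ADP_REF`, `ADP_SCH`), `median`, `iqr`, `n`. Rows are ordered by
#'   structure block (PTV, CTV, bowel, bladder, rectum, femurs), metric, then
#'   contrast.
#' @export
summarize_cohort <- function(differences, per_patient = FALSE) {
  long <- tidyr::pivot_longer(
    differences,
    cols = c("sch_ref", "adp_ref", "adp_sch"),
    names_to = "contrast", values_to = "value"
  ) |>
    dplyr::mutate(contrast = toupper(.data$contrast))

  if (per_patient) {
    long <- long |>
      dplyr::group_by(.data$site, .data$structure, .data$metric_id,
                      .data$unit, .data$contrast, .data$patient_id) |>
      dplyr::summarise(value = stats::median(.data$value), .groups = "drop")
  }

  out <- long |>
    dplyr::group_by(.data$site, .data$structure, .data$metric_id,
                    .data$unit, .data$contrast) |>
    dplyr::summarise(
      median = stats::median(.data$value),
      iqr = unname(diff(stats::quantile(.data$value, c(0.25, 0.75), type = 7))),
      n = dplyr::n(),
      .groups = "drop"
    )

  slot_order <- metric_slots()$metric_id
  out |>
    dplyr::arrange(
      .data$site,
      match(.data$structure, table2_structure_order),
      match(.data$metric_id, slot_order),
      match(.data$contrast, c("SCH_REF", "ADP_REF", "ADP_SCH"))
    )
}
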