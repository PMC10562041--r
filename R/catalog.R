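#' Pelvic site and prescription registry
#'
#' The four standardized pelvic treatment regimens the analysis covers:
#' hypofractionated bladder (55 Gy in 20 fractions), post-operative prostate
#' fossa sequential boost (19.8 Gy in 11), hypofractionated prostate plus
#' proximal seminal vesicles (70.2 Gy in 26), and prostate SBRT (40 Gy in 5).
#'
#' @return A tibble with columns `site`, `total_dose_gy`, `n_fractions`,
#'   `dose_per_fraction_gy`, `description`.
#' @export
site_registry <- function() {
  tibble::tribble(
    ~site,                  ~total_dose_gy, ~n_fractions, ~description,
    "bladder_hypofx",       55,             20L,          "hypofractionated bladder",
    "prostate_fossa_boost", 19.8,           11L,          "post-operative prostate fossa sequential boost",
    "prostate_sv_hypofx",   70.2,           26L,          "hypofractionated prostate + proximal seminal vesicles",
    "prostate_sbrt",        40,             5L,           "prostate stereotactic body radiotherapy"
  ) |>
    dplyr::mutate(dose_per_fraction_gy = .data$total_dose_gy / .data$n_fractions,
                  .after = "n_fractions")
}

#' Prescription for a treatment site
#'
#' @param site One of `"bladder_hypofx"`, `"prostate_fossa_boost"`,
#'   `"prostate_sv_hypofx"`, `"prostate_sbrt"`.
#' @return An object of class `rt_prescription` with fields `site`,
#'   `total_dose_gy`, `n_fractions`, `dose_per_fraction_gy`.
#' @export
prescription <- function(site) {
  reg <- site_registry()
  row <- reg[reg$site == site, ]
  if (nrow(row) != 1L) {
    stop("unknown site '", site, "'; known sites: ",
         paste(reg$site, collapse = ", "), call. = FALSE)
  }
  stopifnot(abs(row$dose_per_fraction_gy * row$n_fractions - row$total_dose_gy) < 0.01)
  structure(as.list(row[, c("site", "total_dose_gy", "n_fractions",
                            "dose_per_fraction_gy")]),
            class = "rt_prescription")
}

#' @export
print.rt_prescription <- function(x, ...) {
  cat("<rt_prescription> ", x$site, ": ", x$total_dose_gy, " Gy in ",
      x$n_fractions, " fx (", round(x$dose_per_fraction_gy, 3), " Gy/fx)\n",
      sep = "")
  invisible(x)
}

# The 16 standardized metric slots. The two femoral heads are reported as a
# single combined slot evaluated on the union of the left and right masks.
metric_slots <- function() {
  tibble::tribble(
    ~metric_id,        ~structure, ~kind,        ~parameter, ~unit,      ~direction,      ~scale_per_fraction,
    "ptv_d99",         "ptv",      "D_relvol",   99,         "Gy",       "higher_better", FALSE,
    "ptv_d95",         "ptv",      "D_relvol",   95,         "Gy",       "higher_better", FALSE,
    "ptv_d0.03cc",     "ptv",      "D_absvol",   0.03,       "Gy",       "lower_better",  FALSE,
    "ctv_d99",         "ctv",      "D_relvol",   99,         "Gy",       "higher_better", FALSE,
    "ctv_v100",        "ctv",      "V_reldose",  100,        "percent",  "higher_better", FALSE,
    "ctv_d0.03cc",     "ctv",      "D_absvol",   0.03,       "Gy",       "lower_better",  FALSE,
    "bowel_d2cc",      "bowel",    "D_absvol",   2,          "Gy",       "lower_better",  FALSE,
    "bowel_v55gy",     "bowel",    "V_absdose",  55,         "percent",  "lower_better",  TRUE,
    "bowel_d0.03cc",   "bowel",    "D_absvol",   0.03,       "Gy",       "lower_better",  FALSE,
    "bladder_v65gy",   "bladder",  "V_absdose",  65,         "percent",  "lower_better",  TRUE,
    "bladder_v40gy",   "bladder",  "V_absdose",  40,         "percent",  "lower_better",  TRUE,
    "bladder_d0.03cc", "bladder",  "D_absvol",   0.03,       "Gy",       "lower_better",  FALSE,
    "rectum_v65gy",    "rectum",   "V_absdose",  65,         "percent",  "lower_better",  TRUE,
    "rectum_v40gy",    "rectum",   "V_absdose",  40,         "percent",  "lower_better",  TRUE,
    "rectum_d0.03cc",  "rectum",   "D_absvol",   0.03,       "Gy",       "lower_better",  FALSE,
    "femurs_d0.03cc",  "femurs",   "D_absvol",   0.03,       "Gy",       "lower_better",  FALSE
  )
}

# Site-specific metric statuses. "not_appropriate": the constraint makes no
# sense for the target (the bladder is the target of bladder_hypofx);
# "inadequate_dose": the absolute threshold exceeds the dose the regimen can
# reach, so the metric is identically degenerate and excluded from comparison.
metric_status_for_site <- function(site) {
  slots <- metric_slots()$metric_id
  status <- stats::setNames(rep("valid", length(slots)), slots)
  if (site == "bladder_hypofx") {
    status[c("bladder_v65gy", "bladder_v40gy", "bladder_d0.03cc")] <- "not_appropriate"
    status["rectum_v65gy"] <- "inadequate_dose"
  } else if (site == "prostate_sbrt") {
    status[c("bowel_v55gy", "bladder_v65gy", "rectum_v65gy")] <- "inadequate_dose"
  }
  status
}

#' Standardized dose-metric set for a prescription
#'
#' Returns the 16 standardized metric slots (PTV D99%/D95%/D0.03cc, CTV
#' D99%/V100%/D0.03cc, bowel D2cc/V55Gy/D0.03cc, bladder and rectum
#' V65Gy/V40Gy/D0.03cc, combined femoral heads D0.03cc) with their
#' site-specific applicability status. Non-valid slots (`not_appropriate`,
#' `inadequate_dose`) are carried through analyses as status only, never as
#' values.
#'
#' @param rx An [prescription()] object or a site string.
#' @return A tibble with one row per metric slot: `metric_id`, `structure`,
#'   `kind` (one of `D_relvol`, `D_absvol`, `V_reldose`, `V_absdose`),
#'   `parameter`, `unit`, `direction`, `scale_per_fraction`, `status`.
#' @export
standard_metric_set <- function(rx) {
  if (is.character(rx)) rx <- prescription(rx)
  stopifnot(inherits(rx, "rt_prescription"))
  slots <- metric_slots()
  status <- metric_status_for_site(rx$site)
  slots$status <- unname(status[slots$metric_id])
  slots
}

#' Per-fraction scaling of a cumulative dose limit
#'
#' Absolute-dose volume metrics (V55Gy, V65Gy, V40Gy) are defined against
#' course-level dose limits; since every analyzed dose distribution is a
#' single-fraction dose, the limit is scaled by the number of treatments to
#' obtain the corresponding per-fraction threshold.
#'
#' @param threshold_gy Course-level dose limit in Gy (> 0).
#' @param rx An [prescription()] object or site string.
#' @return Per-fraction threshold in Gy (`threshold_gy / n_fractions`).
#' @export
per_fraction_threshold <- function(threshold_gy, rx) {
  if (is.character(rx)) rx <- prescription(rx)
  stopifnot(inherits(rx, "rt_prescription"))
  if (!is.numeric(threshold_gy) || length(threshold_gy) != 1L || threshold_gy <= 0) {
    stop("`threshold_gy` must be a single positive dose (Gy)", call. = FALSE)
  }
  threshold_gy / rx$n_fractions
}

#' Convert a relative-dose threshold to Gy
#'
#' For Vx% metrics: x percent of the per-fraction prescription dose, in Gy.
#'
#' @param x Percent of prescription dose (> 0).
#' @param rx An [prescription()] object or site string.
#' @return Threshold in Gy.
#' @export
relative_dose_threshold <- function(x, rx) {
  if (is.character(rx)) rx <- prescription(rx)
  stopifnot(inherits(rx, "rt_prescription"))
  if (!is.numeric(x) || length(x) != 1L || x <= 0) {
    stop("`x` must be a single positive percentage", call. = FALSE)
  }
  x / 100 * rx$dose_per_fraction_gy
}

metric_value_from_curve <- function(curve, slot, rx) {
  switch(slot$kind,
    D_relvol  = dose_at_relative_volume(curve, slot$parameter),
    D_absvol  = dose_at_absolute_volume(curve, slot$parameter),
    V_reldose = volume_at_dose(curve, relative_dose_threshold(slot$parameter, rx)),
    V_absdose = volume_at_dose(curve, per_fraction_threshold(slot$parameter, rx)),
    stop("unknown metric kind '", slot$kind, "'", call. = FALSE)
  )
}

#' Evaluate the standardized metric set on one treatment fraction
#'
#' Computes every valid standardized metric on each of the three dose
#' distributions of a fraction: the reference dose (original plan on the
#' planning anatomy, REF), the scheduled dose (original plan on the daily
#' anatomy, SCH) and the adapted dose (re-optimized plan on the daily
#' anatomy, ADP). Non-valid metrics are emitted with their status and `NA`
#' values.
#'
#' @param grids Named list with elements `REF`, `SCH`, `ADP`, each a
#'   [dose_grid()].
#' @param masks Either a named list of [structure_mask()] objects (same
#'   anatomy for all three distributions), or a named list with elements
#'   `REF`, `SCH`, `ADP`, each itself a named list of masks (daily anatomy
#'   differing from the planning anatomy).
#' @param rx An [prescription()] object or site string.
#' @param patient_id,fraction_index Identifiers copied into the output rows.
#' @param bin_width DVH bin width in Gy passed to [compute_cumulative_dvh()].
#' @return A metric table: one row per metric slot with columns `patient_id`,
#'   `fraction_index`, `site`, `structure`, `metric_id`, `status`, `unit`,
#'   `ref_value`, `sch_value`, `adp_value`.
#' @export
evaluate_fraction <- function(grids, masks, rx, patient_id = "p01",
                              fraction_index = 1L, bin_width = 0.01) {
  if (is.character(rx)) rx <- prescription(rx)
  dists <- c("REF", "SCH", "ADP")
  if (!all(dists %in% names(grids))) {
    stop("`grids` must contain REF, SCH and ADP dose grids", call. = FALSE)
  }
  per_dist_masks <- all(dists %in% names(masks))
  mask_set <- function(dist) if (per_dist_masks) masks[[dist]] else masks

  slots <- standard_metric_set(rx)
  needed <- unique(slots$structure[slots$status == "valid"])
  for (dist in dists) {
    missing <- setdiff(needed, names(mask_set(dist)))
    if (length(missing) > 0L) {
      stop("missing structure mask(s) for valid metrics: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  curves <- lapply(dists, function(dist) {
    ms <- mask_set(dist)
    stats::setNames(
      lapply(needed, function(s) compute_cumulative_dvh(grids[[dist]], ms[[s]], bin_width)),
      needed
    )
  })
  names(curves) <- dists

  vals <- lapply(dists, function(dist) {
    vapply(seq_len(nrow(slots)), function(i) {
      slot <- slots[i, ]
      if (slot$status != "valid") return(NA_real_)
      metric_value_from_curve(curves[[dist]][[slot$structure]], slot, rx)
    }, numeric(1))
  })
  names(vals) <- dists

  tibble::tibble(
    patient_id = as.character(patient_id),
    fraction_index = as.integer(fraction_index),
    site = rx$site,
    structure = slots$structure,
    metric_id = slots$metric_id,
    status = slots$status,
    unit = slots$unit,
    ref_value = vals$REF,
    sch_value = vals$SCH,
    adp_value = vals$ADP
  )
}
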