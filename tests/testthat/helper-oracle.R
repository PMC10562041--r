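# Brute-force oracles on the sorted voxel-dose multiset, independent of the
# DVH-curve code path.

bf_dose_at_relative_volume <- function(doses, x) {
  n <- length(doses)
  k <- ceiling(x / 100 * n - 1e-9)
  sort(doses, decreasing = TRUE)[max(k, 1L)]
}

bf_dose_at_absolute_volume <- function(doses, x, voxel_cc) {
  if (x == 0) return(max(doses))
  n <- length(doses)
  k <- min(ceiling(x / voxel_cc - 1e-9), n)
  sort(doses, decreasing = TRUE)[max(k, 1L)]
}

bf_volume_at_dose <- function(doses, threshold) {
  100 * mean(doses >= threshold)
}

# Random toy phantom: grid up to max_dim^3 voxels with a random non-empty mask.
random_grid_mask <- function(max_dim = 20, max_dose = 10) {
  dims <- sample(2:max_dim, 3, replace = TRUE)
  vals <- array(stats::runif(prod(dims), 0, max_dose), dim = dims)
  occ <- array(stats::runif(prod(dims)) < 0.4, dim = dims)
  if (!any(occ)) occ[sample(prod(dims), 1)] <- TRUE
  list(
    grid = dose_grid(vals, spacing = stats::runif(3, 1, 4)),
    mask = structure_mask(occ, "s", "target")
  )
}

# Minimal single-metric difference table for trigger tests.
make_diffs <- function(sch_ref, adp_ref, metric_id = "ptv_d95",
                       site = "prostate_sv_hypofx", unit = "Gy") {
  n <- length(sch_ref)
  tibble::tibble(
    patient_id = rep("p01", n),
    fraction_index = seq_len(n),
    site = site, structure = sub("_.*", "", metric_id),
    metric_id = metric_id, unit = unit,
    sch_ref = sch_ref, adp_ref = adp_ref,
    adp_sch = adp_ref - sch_ref
  )
}

# Independent single-value trigger evaluation (loop, no vectorization shared
# with the package path).
bf_sweep_point <- function(diffs, value, direction, contrast = "SCH_REF") {
  d <- diffs[[tolower(contrast)]]
  n <- nrow(diffs)
  adapt <- logical(n)
  for (i in seq_len(n)) {
    fired <- if (direction == "higher_better") d[i] <= value else d[i] >= value
    pref <- if (direction == "higher_better") diffs$adp_sch[i] > 0 else diffs$adp_sch[i] < 0
    adapt[i] <- fired && pref
  }
  cf <- ifelse(adapt, diffs$adp_ref, diffs$sch_ref)
  list(proportion = mean(adapt), cf = cf)
}
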