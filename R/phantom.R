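#' Geometric phantom specification
#'
#' A toy pelvic phantom on a regular dose grid: a spherical clinical target
#' volume (CTV) expanded isotropically by a safety margin to the planning
#' target volume (PTV), surrounded by spherical stand-ins for the rectum
#' (posterior), bladder (anterior), bowel (superior) and the two femoral
#' heads (lateral, reported as one combined structure). The reference dose is
#' the per-fraction prescription, uniform inside the PTV with a Gaussian
#' penumbra fall-off outside. Daily anatomic change is a rigid displacement
#' of all structures; the adapted dose is the reference dose field rigidly
#' re-centred on the displaced target (a caricature of replanning, not an
#' optimizer).
#'
#' @param shape Grid shape (z, y, x) in voxels.
#' @param spacing Voxel edge lengths in mm (z, y, x).
#' @param ctv_radius_mm CTV sphere radius (mm).
#' @param margin_mm CTV-to-PTV margin (mm); clinical range 3-5 mm.
#' @param penumbra_mm Gaussian penumbra standard deviation (mm).
#' @param oar_radius_mm OAR sphere radius (mm).
#' @param oar_offset_mm Centre-to-centre distance from target to each OAR (mm).
#' @param displacement_sd_mm Per-axis SD of the daily rigid displacement (mm).
#' @param rx An [prescription()] object or site string; sets the per-fraction
#'   dose.
#' @param seed Master seed for per-fraction displacement substreams.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(30L, 30L, 30L), spacing = c(2, 2, 2),
                         ctv_radius_mm = 8, margin_mm = 4, penumbra_mm = 4,
                         oar_radius_mm = 6, oar_offset_mm = 16,
                         displacement_sd_mm = 3,
                         rx = "prostate_sv_hypofx", seed = 1L) {
  if (is.character(rx)) rx <- prescription(rx)
  stopifnot(margin_mm >= 0, ctv_radius_mm > 0, penumbra_mm > 0,
            displacement_sd_mm >= 0, all(shape >= 4L), all(spacing > 0))
  structure(
    list(shape = as.integer(shape), spacing = as.numeric(spacing),
         ctv_radius_mm = ctv_radius_mm, margin_mm = margin_mm,
         penumbra_mm = penumbra_mm, oar_radius_mm = oar_radius_mm,
         oar_offset_mm = oar_offset_mm,
         displacement_sd_mm = displacement_sd_mm,
         rx = rx, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Physical coordinates (mm) of voxel centres along each axis.
axis_coords <- function(spec) {
  lapply(1:3, function(a) (seq_len(spec$shape[a]) - 1) * spec$spacing[a])
}

# Squared distance field (mm^2) from a physical point.
distance2_field <- function(spec, centre) {
  cs <- axis_coords(spec)
  dz2 <- (cs[[1]] - centre[1])^2
  dy2 <- (cs[[2]] - centre[2])^2
  dx2 <- (cs[[3]] - centre[3])^2
  outer(outer(dz2, dy2, `+`), dx2, `+`)
}

sphere_mask <- function(spec, centre, radius, name, role) {
  structure_mask(distance2_field(spec, centre) <= radius^2, name, role)
}

phantom_centre <- function(spec) {
  (spec$shape - 1) * spec$spacing / 2
}

# OAR centres relative to the (possibly displaced) target centre.
phantom_oar_centres <- function(spec, target_centre) {
  off <- spec$oar_offset_mm
  list(
    rectum  = target_centre + c(0, off, 0),
    bladder = target_centre + c(0, -off, 0),
    bowel   = target_centre + c(off, 0, 0),
    femur_l = target_centre + c(0, 0, off),
    femur_r = target_centre + c(0, 0, -off)
  )
}

phantom_dose <- function(spec, target_centre) {
  r <- sqrt(distance2_field(spec, target_centre))
  ptv_r <- spec$ctv_radius_mm + spec$margin_mm
  dose <- ifelse(
    r <= ptv_r, spec$rx$dose_per_fraction_gy,
    spec$rx$dose_per_fraction_gy * exp(-(r - ptv_r)^2 / (2 * spec$penumbra_mm^2))
  )
  dose_grid(dose, spec$spacing)
}

phantom_masks <- function(spec, target_centre) {
  oars <- phantom_oar_centres(spec, target_centre)
  femur <- sphere_mask(spec, oars$femur_l, spec$oar_radius_mm, "femurs", "oar")
  femur_r <- sphere_mask(spec, oars$femur_r, spec$oar_radius_mm, "femurs", "oar")
  femur$occupancy <- femur$occupancy | femur_r$occupancy
  list(
    ctv = sphere_mask(spec, target_centre, spec$ctv_radius_mm, "ctv", "target"),
    ptv = sphere_mask(spec, target_centre,
                      spec$ctv_radius_mm + spec$margin_mm, "ptv", "target"),
    rectum = sphere_mask(spec, oars$rectum, spec$oar_radius_mm, "rectum", "oar"),
    bladder = sphere_mask(spec, oars$bladder, spec$oar_radius_mm, "bladder", "oar"),
    bowel = sphere_mask(spec, oars$bowel, spec$oar_radius_mm, "bowel", "oar"),
    femurs = femur
  )
}

#' Generate one phantom treatment fraction
#'
#' Produces the REF/SCH/ADP dose grids and per-distribution structure masks
#' for one fraction. REF: dose and anatomy at the planning position. SCH: the
#' same dose field with all structures rigidly displaced (the anatomy moved
#' under the old plan). ADP: the dose field re-centred on the displaced
#' target (plan re-conformed), with the displaced structures. A displacement
#' that would push the PTV outside the grid raises an error.
#'
#' @param spec A [phantom_spec()].
#' @param fraction_index Fraction number; selects the displacement substream.
#' @param displacement Optional fixed displacement vector (z, y, x) in mm;
#'   when `NULL`, drawn as independent normals with SD
#'   `spec$displacement_sd_mm` from the fraction's substream.
#' @return List with elements `grids` (named `REF`, `SCH`, `ADP`), `masks`
#'   (named `REF`, `SCH`, `ADP`, each a named mask list), and `displacement`.
#' @export
generate_phantom_fraction <- function(spec, fraction_index = 1L,
                                      displacement = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(displacement)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed((spec$seed + 7919L * as.integer(fraction_index)) %%
               .Machine$integer.max)
    displacement <- stats::rnorm(3, 0, spec$displacement_sd_mm)
  }
  stopifnot(length(displacement) == 3L, all(is.finite(displacement)))

  c0 <- phantom_centre(spec)
  c1 <- c0 + displacement
  ptv_r <- spec$ctv_radius_mm + spec$margin_mm
  extent <- (spec$shape - 1) * spec$spacing
  if (any(c1 - ptv_r < 0) || any(c1 + ptv_r > extent)) {
    stop("displacement pushes the PTV outside the phantom grid", call. = FALSE)
  }

  ref_dose <- phantom_dose(spec, c0)
  ref_masks <- phantom_masks(spec, c0)
  day_masks <- phantom_masks(spec, c1)

  list(
    grids = list(REF = ref_dose, SCH = ref_dose, ADP = phantom_dose(spec, c1)),
    masks = list(REF = ref_masks, SCH = day_masks, ADP = day_masks),
    displacement = displacement
  )
}

#' Evaluate a course of phantom fractions into a metric table
#'
#' Convenience wrapper: generates `n_fractions` phantom fractions and runs
#' [evaluate_fraction()] on each.
#'
#' @param spec A [phantom_spec()].
#' @param n_fractions Number of fractions; defaults to the prescription's.
#' @param patient_id Identifier for the output rows.
#' @param bin_width DVH bin width (Gy).
#' @return A metric table (schema of [evaluate_fraction()]).
#' @export
phantom_course <- function(spec, n_fractions = NULL, patient_id = "phantom01",
                           bin_width = 0.01) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(n_fractions)) n_fractions <- spec$rx$n_fractions
  rows <- lapply(seq_len(n_fractions), function(fx) {
    fr <- generate_phantom_fraction(spec, fx)
    evaluate_fraction(fr$grids, fr$masks, spec$rx, patient_id = patient_id,
                      fraction_index = fx, bin_width = bin_width)
  })
  dplyr::bind_rows(rows)
}
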