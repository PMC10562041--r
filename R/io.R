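metric_table_cols <- c("patient_id", "fraction_index", "site", "structure",
                       "metric_id", "status", "unit", "ref_value",
                       "sch_value", "adp_value")

validate_metric_table <- function(tbl) {
  missing <- setdiff(metric_table_cols, names(tbl))
  if (length(missing) > 0L) {
    stop("metric table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_status <- setdiff(unique(tbl$status),
                        c("valid", "not_appropriate", "inadequate_dose"))
  if (length(bad_status) > 0L) {
    stop("metric table integrity error: unknown status value(s) ",
         paste(bad_status, collapse = ", "), call. = FALSE)
  }
  nonvalid <- tbl$status != "valid"
  has_value <- !is.na(tbl$ref_value) | !is.na(tbl$sch_value) |
    !is.na(tbl$adp_value)
  if (any(nonvalid & has_value)) {
    i <- which(nonvalid & has_value)[1L]
    stop("metric table integrity error: row ", i, " has status '",
         tbl$status[i], "' but carries values", call. = FALSE)
  }
  # the reference dose is fixed at planning: it may not vary across a
  # patient's fractions
  ref_var <- tbl |>
    dplyr::filter(.data$status == "valid") |>
    dplyr::group_by(.data$patient_id, .data$metric_id) |>
    dplyr::summarise(spread = max(.data$ref_value) - min(.data$ref_value),
                     .groups = "drop")
  if (any(ref_var$spread > 1e-6)) {
    bad <- ref_var[which.max(ref_var$spread), ]
    stop("metric table integrity error: reference value of ", bad$metric_id,
         " varies across fractions of patient ", bad$patient_id,
         call. = FALSE)
  }
  invisible(tbl)
}

#' Write / read a per-fraction metric table
#'
#' CSV dialect: UTF-8, comma-separated, `.` decimal, header required, the
#' unit carried per row. Values are serialized with 4 decimal places. Reading
#' validates the schema and the table's integrity invariants: known status
#' vocabulary, values present only for `valid` rows, and reference values
#' constant across each patient's fractions.
#'
#' @param metric_table A metric table ([evaluate_fraction()] /
#'   [generate_metric_cohort()] schema).
#' @param path CSV file path.
#' @return `write_metric_table` returns `path` invisibly; `read_metric_table`
#'   returns the validated tibble.
#' @export
write_metric_table <- function(metric_table, path) {
  validate_metric_table(metric_table)
  out <- metric_table |>
    dplyr::mutate(dplyr::across(c("ref_value", "sch_value", "adp_value"),
                                ~ round(.x, 4)))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      fraction_index = readr::col_integer(),
      site = readr::col_character(),
      structure = readr::col_character(),
      metric_id = readr::col_character(),
      status = readr::col_character(),
      unit = readr::col_character(),
      ref_value = readr::col_double(),
      sch_value = readr::col_double(),
      adp_value = readr::col_double(),
      .default = readr::col_guess()
    )
  )
  validate_metric_table(tbl)
  tbl
}

#' Serialize a phantom dose grid and its structures
#'
#' Writes a documented plain-text array container: `<prefix>.json` holds the
#' header (shape in (z, y, x) axis order, spacing and origin in mm, dose unit
#' Gy, structure names and roles); `<prefix>.dose.txt` holds the dose values,
#' one per line, flattened in R's column-major order; each structure mask is
#' `<prefix>.mask.<name>.txt` with 0/1 lines in the same order.
#'
#' @param grid A [dose_grid()].
#' @param masks Named list of [structure_mask()] objects.
#' @param prefix Path prefix (without extension).
#' @return `write_dose_grid` returns `prefix` invisibly; `read_dose_grid`
#'   returns `list(grid = , masks = )`.
#' @export
write_dose_grid <- function(grid, masks, prefix) {
  stopifnot(inherits(grid, "dose_grid"))
  header <- list(
    format = "arttrigger dose grid v1",
    axis_order = "zyx",
    shape = dim(grid$values),
    spacing_mm = grid$spacing,
    origin_mm = grid$origin,
    dose_unit = "Gy",
    structures = lapply(names(masks), function(nm) {
      list(name = nm, role = masks[[nm]]$role,
           file = paste0(basename(prefix), ".mask.", nm, ".txt"))
    })
  )
  jsonlite::write_json(header, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  readr::write_lines(sprintf("%.6g", as.vector(grid$values)),
                     paste0(prefix, ".dose.txt"))
  for (nm in names(masks)) {
    check_congruent(grid, masks[[nm]])
    readr::write_lines(as.integer(masks[[nm]]$occupancy),
                       paste0(prefix, ".mask.", nm, ".txt"))
  }
  invisible(prefix)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(prefix) {
  header <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  shape <- as.integer(header$shape)
  vals <- as.numeric(readr::read_lines(paste0(prefix, ".dose.txt")))
  if (length(vals) != prod(shape)) {
    stop("dose grid container corrupt: ", length(vals), " values for shape ",
         paste(shape, collapse = "x"), call. = FALSE)
  }
  grid <- dose_grid(array(vals, dim = shape), header$spacing_mm,
                    header$origin_mm)
  masks <- list()
  if (length(header$structures) > 0L) {
    sdf <- header$structures
    for (i in seq_len(nrow(sdf))) {
      occ <- as.integer(readr::read_lines(
        file.path(dirname(prefix), sdf$file[i])))
      masks[[sdf$name[i]]] <- structure_mask(array(occ == 1L, dim = shape),
                                             sdf$name[i], sdf$role[i])
    }
  }
  list(grid = grid, masks = masks)
}

#' Export a DVH curve as CSV
#'
#' Two columns: `dose_Gy`, `cum_volume_fraction`.
#'
#' @param curve A `dvh_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(curve, path) {
  stopifnot(inherits(curve, "dvh_curve"))
  readr::write_csv(
    tibble::tibble(dose_Gy = curve$dose_edges,
                   cum_volume_fraction = curve$cum_volume_fraction),
    path
  )
  invisible(path)
}

#' Tidy a trigger sweep for export
#'
#' @param sweep A `trigger_sweep` from [sweep_trigger()].
#' @return A tibble with one row per grid value x percentile level:
#'   `site`, `metric_id`, `contrast`, `value`, `proportion_adapted`, `level`,
#'   `band`.
#' @export
tidy_sweep <- function(sweep) {
  stopifnot(inherits(sweep, "trigger_sweep"))
  tidyr::pivot_longer(
    tibble::as_tibble(sweep),
    cols = dplyr::starts_with("p", ignore.case = FALSE) &
      !dplyr::any_of(c("proportion_adapted")),
    names_to = "level", values_to = "band",
    names_transform = list(level = ~ as.integer(sub("^p", "", .x)))
  ) |>
    dplyr::mutate(
      site = attr(sweep, "site"),
      metric_id = attr(sweep, "metric_id"),
      contrast = attr(sweep, "contrast"),
      .before = 1
    )
}

#' Write a trigger sweep as JSON
#'
#' @param sweep A `trigger_sweep`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sweep_json <- function(sweep, path) {
  stopifnot(inherits(sweep, "trigger_sweep"))
  band_cols <- grep("^p[0-9]+$", names(sweep), value = TRUE)
  payload <- list(
    metric_id = attr(sweep, "metric_id"),
    contrast = attr(sweep, "contrast"),
    site = attr(sweep, "site"),
    unit = attr(sweep, "unit"),
    direction = attr(sweep, "direction"),
    n_fractions = attr(sweep, "n_fractions"),
    grid = sweep$value,
    proportion_adapted = sweep$proportion_adapted,
    bands = stats::setNames(lapply(band_cols, function(cl) sweep[[cl]]),
                            band_cols)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
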