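#' Adaptive trigger parameter-value pair
#'
#' A trigger is a monitored difference contrast for one metric (the
#' *parameter*) together with an action level (the *value*). For coverage
#' metrics (direction `higher_better`), a more negative difference means more
#' compromised dose, so the trigger fires when the difference falls to or
#' below the value and *raising* the value makes the trigger stricter. For
#' OAR metrics (`lower_better`), a more positive difference means more excess
#' dose, the trigger fires at or above the value, and *lowering* the value
#' makes it stricter. Comparisons are inclusive: a difference exactly equal
#' to the value fires.
#'
#' @param metric_id Metric identifier (see [standard_metric_set()]).
#' @param value Action level in the metric's native unit.
#' @param direction `"higher_better"` (coverage) or `"lower_better"` (OAR);
#'   looked up from the metric catalog when omitted.
#' @param contrast Which difference is monitored: `"SCH_REF"` (compromise of
#'   the original plan) or `"ADP_REF"` (residual deviation of the adapted
#'   plan).
#' @return An object of class `trigger_policy`.
#' @export
trigger_policy <- function(metric_id, value,
                           direction = NULL,
                           contrast = c("SCH_REF", "ADP_REF")) {
  contrast <- match.arg(contrast)
  if (is.null(direction)) {
    slots <- metric_slots()
    if (!metric_id %in% slots$metric_id) {
      stop("unknown metric '", metric_id,
           "'; pass `direction` explicitly for custom metrics", call. = FALSE)
    }
    direction <- slots$direction[slots$metric_id == metric_id]
  }
  direction <- match.arg(direction, c("higher_better", "lower_better"))
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(
    list(metric_id = metric_id, value = value, direction = direction,
         contrast = contrast),
    class = "trigger_policy"
  )
}

#' @export
print.trigger_policy <- function(x, ...) {
  op <- if (x$direction == "higher_better") "<=" else ">="
  cat("<trigger_policy> ", x$metric_id, " ", x$contrast, " ", op, " ",
      x$value, "\n", sep = "")
  invisible(x)
}

#' Does a trigger fire for a given difference?
#'
#' @param difference Numeric vector of observed differences (the policy's
#'   contrast, native metric unit).
#' @param policy A [trigger_policy()].
#' @return Logical vector: `TRUE` where the trigger fires (inclusive
#'   comparison).
#' @export
trigger_fires <- function(difference, policy) {
  stopifnot(inherits(policy, "trigger_policy"), all(is.finite(difference)))
  if (policy$direction == "higher_better") {
    difference <= policy$value
  } else {
    difference >= policy$value
  }
}

#' Fraction-level adaptation decisions under a trigger policy
#'
#' A fraction is adapted when the trigger fires *and* the adapted dose is
#' dosimetrically preferred over the scheduled dose for the trigger metric:
#' `adp_sch > 0` for coverage metrics, `adp_sch < 0` for OAR metrics. Ties
#' (`adp_sch` exactly 0) are not preferred: there is no dosimetric gain to
#' justify adapting. The preference condition is why the proportion of
#' treatments adapted need not reach 100% even under an arbitrarily strict
#' trigger.
#'
#' @param differences Difference table rows for the policy's metric (one row
#'   per fraction; see [compute_differences()]).
#' @param policy A [trigger_policy()].
#' @return A tibble of decisions: `patient_id`, `fraction_index`, `fired`,
#'   `preferred`, `adapt` (`fired & preferred`).
#' @export
adaptation_decision <- function(differences, policy) {
  stopifnot(inherits(policy, "trigger_policy"))
  if (!all(differences$metric_id == policy$metric_id)) {
    stop("difference rows must all carry the policy metric '",
         policy$metric_id, "'", call. = FALSE)
  }
  d <- differences[[tolower(policy$contrast)]]
  fired <- trigger_fires(d, policy)
  preferred <- if (policy$direction == "higher_better") {
    differences$adp_sch > 0
  } else {
    differences$adp_sch < 0
  }
  tibble::tibble(
    patient_id = differences$patient_id,
    fraction_index = differences$fraction_index,
    fired = fired,
    preferred = preferred,
    adapt = fired & preferred
  )
}

#' Proportion of treatments adapted
#'
#' @param decisions Decision table from [adaptation_decision()].
#' @return Fraction of fractions adapted, in \[0, 1\].
#' @export
proportion_adapted <- function(decisions) {
  if (nrow(decisions) == 0L) {
    stop("no decisions: proportion adapted is undefined", call. = FALSE)
  }
  mean(decisions$adapt)
}

#' Counterfactual metric differences under a trigger policy
#'
#' The distribution of metric values that a trigger policy would have
#' realized: the adapted-dose value for fractions where adaptation occurred
#' and the scheduled-dose value elsewhere, both expressed as differences from
#' the reference dose (`adp_ref` / `sch_ref`).
#'
#' @param differences Difference table rows for the policy metric, one per
#'   fraction.
#' @param decisions Matching decision table from [adaptation_decision()].
#' @return Numeric vector, one counterfactual difference per fraction.
#' @export
counterfactual_values <- function(differences, decisions) {
  if (nrow(differences) != nrow(decisions) ||
      !all(differences$patient_id == decisions$patient_id &
           differences$fraction_index == decisions$fraction_index)) {
    stop("decisions do not match the difference rows one-to-one", call. = FALSE)
  }
  ifelse(decisions$adapt, differences$adp_ref, differences$sch_ref)
}

#' Percentile bands of a value distribution
#'
#' Percentiles at the requested levels under linear interpolation between
#' closest ranks (R type 7), the same quantile convention used by
#' [summarize_cohort()].
#'
#' @param values Non-empty numeric vector.
#' @param levels Percentile levels in (0, 100); default the seven band bounds
#'   5, 10, 25, 50, 75, 90, 95.
#' @return Named numeric vector ordered by level (`p5`, `p10`, ...).
#' @export
percentile_bands <- function(values, levels = c(5, 10, 25, 50, 75, 90, 95)) {
  if (length(values) == 0L) stop("no values: bands are undefined", call. = FALSE)
  stopifnot(all(levels > 0 & levels < 100))
  levels <- sort(levels)
  q <- stats::quantile(values, probs = levels / 100, type = 7, names = FALSE)
  stats::setNames(q, paste0("p", levels))
}

#' Default trigger-value grid for a set of observed differences
#'
#' Ascending thresholds spanning `floor(min)` to `ceiling(max)` of the
#' observed differences at a fixed step: 0.25 Gy for dose-unit metrics and
#' 1 percentage point for volume-unit metrics by default. An extreme that
#' falls exactly on a grid point is bracketed by one extra step so that the
#' laxest end of the grid never fires.
#'
#' @param d Observed differences (the contrast to be swept).
#' @param unit `"Gy"` or `"percent"`.
#' @param step Grid step; defaults to 0.25 (Gy) or 1 (percent).
#' @return Ascending numeric vector of trigger values.
#' @export
trigger_grid <- function(d, unit = c("Gy", "percent"), step = NULL) {
  unit <- match.arg(unit)
  if (is.null(step)) step <- if (unit == "Gy") 0.25 else 1
  stopifnot(step > 0, all(is.finite(d)), length(d) > 0L)
  # strictly bracket the observed range: when an extreme lands exactly on a
  # grid point, extend one step so the laxest end fires nothing
  lo <- floor(min(d))
  if (lo >= min(d)) lo <- lo - step
  hi <- ceiling(max(d))
  if (hi <= max(d)) hi <- hi + step
  seq(lo, hi, by = step)
}

#' Sweep a trigger parameter over a grid of action levels
#'
#' For each candidate trigger value: re-derives the fraction-level adaptation
#' decisions, the proportion of treatments adapted, and the percentile bands
#' of the counterfactual difference distribution. Because the preference
#' condition is fixed per fraction, the proportion-adapted curve equals the
#' empirical CDF (taken in the strictness direction) of the trigger contrast
#' restricted to preference-satisfying fractions, scaled by the overall
#' preference-satisfying share — so it is monotone in strictness and need not
#' reach 1.
#'
#' @param differences Difference table rows for a single site and metric.
#' @param contrast `"SCH_REF"` or `"ADP_REF"`.
#' @param direction Metric direction; looked up from the catalog when `NULL`.
#' @param grid Ascending trigger values; defaults to [trigger_grid()] over
#'   the observed contrast at the default step.
#' @param step Grid step passed to [trigger_grid()] when `grid` is `NULL`.
#' @param levels Percentile band levels, passed to [percentile_bands()].
#' @return A tibble of class `trigger_sweep`, one row per grid value:
#'   `value`, `proportion_adapted`, `n_adapted`, and one `p<level>` column
#'   per band level. Attributes `metric_id`, `contrast`, `site`, `unit`,
#'   `direction`, `n_fractions` carry the sweep metadata.
#' @export
sweep_trigger <- function(differences, contrast = c("SCH_REF", "ADP_REF"),
                          direction = NULL, grid = NULL, step = NULL,
                          levels = c(5, 10, 25, 50, 75, 90, 95)) {
  contrast <- match.arg(contrast)
  metric_id <- unique(differences$metric_id)
  site <- unique(differences$site)
  unit <- unique(differences$unit)
  if (length(metric_id) != 1L || length(site) != 1L) {
    stop("sweep expects differences for exactly one site and metric",
         call. = FALSE)
  }
  if (nrow(differences) == 0L) stop("no fractions to sweep", call. = FALSE)
  if (is.null(grid)) {
    grid <- trigger_grid(differences[[tolower(contrast)]], unit = unit,
                         step = step)
  }
  stopifnot(length(grid) > 0L, !is.unsorted(grid, strictly = TRUE))

  rows <- lapply(grid, function(v) {
    policy <- trigger_policy(metric_id, v, direction = direction,
                             contrast = contrast)
    dec <- adaptation_decision(differences, policy)
    cf <- counterfactual_values(differences, dec)
    bands <- percentile_bands(cf, levels)
    c(value = v, proportion_adapted = proportion_adapted(dec),
      n_adapted = sum(dec$adapt), bands)
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  attr(out, "metric_id") <- metric_id
  attr(out, "contrast") <- contrast
  attr(out, "site") <- site
  attr(out, "unit") <- unit
  attr(out, "direction") <- direction %||%
    metric_slots()$direction[metric_slots()$metric_id == metric_id]
  attr(out, "n_fractions") <- nrow(differences)
  class(out) <- c("trigger_sweep", class(out))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
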