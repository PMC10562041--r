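test_that("trigger firing respects metric direction with inclusive boundaries", {
  cov <- trigger_policy("ptv_d95", -0.5, contrast = "SCH_REF")
  expect_equal(cov$direction, "higher_better")
  expect_true(trigger_fires(-0.6, cov))   # worse coverage than the action level
  expect_true(trigger_fires(-0.5, cov))   # boundary fires
  expect_false(trigger_fires(-0.4, cov))

  oar <- trigger_policy("rectum_v40gy", 5, contrast = "SCH_REF")
  expect_equal(oar$direction, "lower_better")
  expect_true(trigger_fires(6.8, oar))
  expect_true(trigger_fires(5, oar))
  expect_false(trigger_fires(4.9, oar))
})

test_that("adaptation requires both firing and dosimetric preference", {
  d <- make_diffs(sch_ref = c(-0.6, -0.6, -0.3, -0.2),
                  adp_ref = c(-0.15, -0.7, 0.0, -0.2))
  pol <- trigger_policy("ptv_d95", -0.5)
  dec <- adaptation_decision(d, pol)
  expect_equal(dec$fired, c(TRUE, TRUE, FALSE, FALSE))
  # adp_sch = 0.45, -0.1, 0.3, 0: ties are not preferred
  expect_equal(dec$preferred, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(dec$adapt, dec$fired & dec$preferred)
  expect_equal(proportion_adapted(dec), 0.25)
  expect_error(proportion_adapted(dec[0, ]), "undefined")
})

test_that("counterfactual values select adp_ref when adapted, sch_ref otherwise", {
  d <- make_diffs(sch_ref = c(-0.30, -0.10), adp_ref = c(0.00, -0.02))
  dec <- tibble::tibble(patient_id = d$patient_id,
                        fraction_index = d$fraction_index,
                        fired = c(TRUE, FALSE), preferred = c(TRUE, TRUE),
                        adapt = c(TRUE, FALSE))
  expect_equal(counterfactual_values(d, dec), c(0.00, -0.10))
  expect_error(counterfactual_values(d, dec[c(2, 1), ]), "one-to-one")

  none <- dplyr::mutate(dec, adapt = FALSE)
  expect_equal(counterfactual_values(d, none), d$sch_ref)
  all_ <- dplyr::mutate(dec, adapt = TRUE)
  expect_equal(counterfactual_values(d, all_), d$adp_ref)
})

test_that("percentile bands follow the stated quantile convention", {
  expect_equal(percentile_bands(0:100)[["p50"]], 50)
  expect_equal(percentile_bands(c(0, 1, 2, 3))[["p25"]], 0.75)
  const <- percentile_bands(rep(1.5, 10))
  expect_true(all(const == 1.5))
  expect_equal(names(const), c("p5", "p10", "p25", "p50", "p75", "p90", "p95"))
  expect_error(percentile_bands(numeric(0)), "undefined")
})

test_that("sweeps match an independent per-value brute-force evaluation", {
  set.seed(21)
  for (direction in c("higher_better", "lower_better")) {
    metric <- if (direction == "higher_better") "ptv_d95" else "rectum_v40gy"
    sgn <- if (direction == "higher_better") -1 else 1
    d <- make_diffs(sch_ref = sgn * abs(rnorm(120, 0.5, 0.4)),
                    adp_ref = rnorm(120, 0, 0.05),
                    metric_id = metric,
                    unit = if (direction == "higher_better") "Gy" else "percent")
    sw <- sweep_trigger(d, contrast = "SCH_REF", step = 0.25)
    for (i in seq_len(nrow(sw))) {
      bf <- bf_sweep_point(d, sw$value[i], direction)
      expect_equal(sw$proportion_adapted[i], bf$proportion)
      expect_equal(unlist(sw[i, c("p5", "p10", "p25", "p50", "p75", "p90", "p95")]),
                   percentile_bands(bf$cf), ignore_attr = TRUE)
    }
    # band rows ordered at every grid value
    bands <- as.matrix(sw[, c("p5", "p10", "p25", "p50", "p75", "p90", "p95")])
    expect_true(all(apply(bands, 1, function(r) all(diff(r) >= 0))))
  }
})

test_that("the proportion-adapted curve is the preference-restricted empirical CDF", {
  set.seed(33)
  d <- make_diffs(sch_ref = -abs(rnorm(200, 0.4, 0.3)) + 0.15,
                  adp_ref = rnorm(200, 0, 0.05))
  sw <- sweep_trigger(d, contrast = "SCH_REF")
  pref <- d$adp_sch > 0
  expected <- vapply(sw$value,
                     function(v) sum(pref & d$sch_ref <= v) / nrow(d),
                     numeric(1))
  expect_equal(sw$proportion_adapted, expected)
  # monotone non-decreasing in strictness (ascending values for coverage)
  expect_true(all(diff(sw$proportion_adapted) >= 0))
  # laxest end fires nothing; strictest end reaches exactly the
  # preference-satisfying share, not 100%
  expect_equal(sw$proportion_adapted[1], 0)
  expect_equal(sw$proportion_adapted[nrow(sw)], mean(pref))
  expect_lt(sw$proportion_adapted[nrow(sw)], 1)
})

test_that("a left-skewed cohort yields steeper proportion gains near zero", {
  # mirrors the non-linearity observation: halving the trigger-step change
  # can more than double the proportion increment
  set.seed(55)
  cal <- calibrate_skewnorm(-0.14, 0.28, -4)
  d <- make_diffs(sch_ref = rskewnorm(5000, cal$xi, cal$omega, cal$alpha),
                  adp_ref = rnorm(5000, 0, 0.02))
  sw <- sweep_trigger(d, contrast = "SCH_REF", grid = c(-1, -0.5, -0.25))
  gain1 <- sw$proportion_adapted[2] - sw$proportion_adapted[1]  # -1 -> -0.5
  gain2 <- sw$proportion_adapted[3] - sw$proportion_adapted[2]  # -0.5 -> -0.25
  expect_gt(gain2, 2 * gain1)  # half the step change, over twice the effect
})

test_that("degenerate all-zero difference metrics sweep to zero adaptation", {
  d <- make_diffs(sch_ref = rep(0, 10), adp_ref = rep(0, 10),
                  metric_id = "bowel_v55gy", unit = "percent",
                  site = "prostate_fossa_boost")
  sw <- sweep_trigger(d, contrast = "SCH_REF")
  expect_true(all(sw$proportion_adapted == 0))
  expect_true(all(as.matrix(sw[, grep("^p[0-9]+$", names(sw))]) == 0))
})
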