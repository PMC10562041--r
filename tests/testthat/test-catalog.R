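test_that("the four shipped regimens are internally consistent", {
  reg <- site_registry()
  expect_equal(nrow(reg), 4)
  expect_equal(reg$total_dose_gy, c(55, 19.8, 70.2, 40))
  expect_equal(reg$n_fractions, c(20L, 11L, 26L, 5L))
  for (site in reg$site) {
    rx <- prescription(site)
    expect_equal(rx$dose_per_fraction_gy * rx$n_fractions, rx$total_dose_gy,
                 tolerance = 1e-9)
  }
  expect_error(prescription("head_and_neck"), "unknown site")
})

test_that("every site has exactly 16 metric slots with consistent kinds", {
  for (site in site_registry()$site) {
    slots <- standard_metric_set(site)
    expect_equal(nrow(slots), 16)
    expect_equal(anyDuplicated(slots$metric_id), 0)
    d_kinds <- slots$kind %in% c("D_relvol", "D_absvol")
    expect_true(all(slots$unit[d_kinds] == "Gy"))
    expect_true(all(slots$unit[!d_kinds] == "percent"))
    # coverage metrics and only coverage metrics are higher-better
    expect_setequal(slots$metric_id[slots$direction == "higher_better"],
                    c("ptv_d99", "ptv_d95", "ctv_d99", "ctv_v100"))
    # per-fraction scaling applies exactly to the absolute-dose volume metrics
    expect_setequal(slots$metric_id[slots$scale_per_fraction],
                    c("bowel_v55gy", "bladder_v65gy", "bladder_v40gy",
                      "rectum_v65gy", "rectum_v40gy"))
  }
})

test_that("site-specific statuses match the clinical applicability rules", {
  bl <- standard_metric_set("bladder_hypofx")
  expect_true(all(bl$status[bl$structure == "bladder"] == "not_appropriate"))
  expect_equal(bl$status[bl$metric_id == "rectum_v65gy"], "inadequate_dose")
  expect_equal(bl$status[bl$metric_id == "bowel_v55gy"], "valid")

  expect_true(all(standard_metric_set("prostate_fossa_boost")$status == "valid"))
  expect_true(all(standard_metric_set("prostate_sv_hypofx")$status == "valid"))

  sb <- standard_metric_set("prostate_sbrt")
  expect_setequal(sb$metric_id[sb$status == "inadequate_dose"],
                  c("bowel_v55gy", "bladder_v65gy", "rectum_v65gy"))
})

test_that("per-fraction scaling divides the limit by the fraction count and inverts", {
  expect_equal(per_fraction_threshold(40, "bladder_hypofx"), 2)
  expect_equal(per_fraction_threshold(65, "prostate_sv_hypofx"), 2.5)
  expect_equal(per_fraction_threshold(55, "prostate_fossa_boost"), 5)
  for (site in site_registry()$site) {
    rx <- prescription(site)
    for (limit in c(40, 55, 65)) {
      expect_equal(per_fraction_threshold(limit, rx) * rx$n_fractions, limit)
    }
  }
  expect_error(per_fraction_threshold(-1, "bladder_hypofx"), "positive")
})

test_that("relative-dose thresholds are fractions of the per-fraction prescription", {
  expect_equal(relative_dose_threshold(100, "prostate_sv_hypofx"), 2.7)
  expect_equal(relative_dose_threshold(100, "prostate_sbrt"), 8)
  expect_equal(relative_dose_threshold(50, "bladder_hypofx"), 1.375)
})

test_that("evaluate_fraction is deterministic, propagates statuses and flags missing masks", {
  spec <- phantom_spec(rx = "prostate_sbrt", seed = 5L)
  fr <- generate_phantom_fraction(spec, displacement = c(2, -3, 1))

  mt <- evaluate_fraction(fr$grids, fr$masks, spec$rx, "p1", 1L)
  mt2 <- evaluate_fraction(fr$grids, fr$masks, spec$rx, "p1", 1L)
  expect_identical(mt, mt2)
  expect_equal(nrow(mt), 16)

  nonvalid <- mt[mt$status != "valid", ]
  expect_gt(nrow(nonvalid), 0)
  expect_true(all(is.na(nonvalid$ref_value)))
  expect_true(all(!is.na(mt$ref_value[mt$status == "valid"])))

  # identical REF/SCH/ADP grids and masks give identical columns
  same <- evaluate_fraction(
    list(REF = fr$grids$REF, SCH = fr$grids$REF, ADP = fr$grids$REF),
    fr$masks$REF, spec$rx
  )
  expect_equal(same$sch_value, same$ref_value)
  expect_equal(same$adp_value, same$ref_value)

  incomplete <- fr$masks
  incomplete$REF$rectum <- NULL
  expect_error(evaluate_fraction(fr$grids, incomplete, spec$rx),
               "missing structure")
})
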