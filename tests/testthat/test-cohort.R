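test_that("skew-normal calibration hits the target median and IQR exactly", {
  for (alpha in c(-4, 0, 2)) {
    cal <- calibrate_skewnorm(-0.14, 0.28, alpha)
    q <- qskewnorm(c(0.25, 0.5, 0.75), cal$xi, cal$omega, cal$alpha)
    expect_equal(q[2], -0.14, tolerance = 1e-7)
    expect_equal(q[3] - q[1], 0.28, tolerance = 1e-7)
  }
  # CDF/quantile are mutual inverses and reduce to the normal at alpha = 0
  expect_equal(pskewnorm(qskewnorm(0.3, alpha = -4), alpha = -4), 0.3,
               tolerance = 1e-7)
  expect_equal(qskewnorm(0.8), qnorm(0.8), tolerance = 1e-7)
})

test_that("the sampler matches the analytic skew-normal quartiles", {
  set.seed(17)
  cal <- calibrate_skewnorm(-0.14, 0.28, -4)
  x <- rskewnorm(2e5, cal$xi, cal$omega, cal$alpha)
  expect_equal(median(x), -0.14, tolerance = 0.005)
  expect_equal(IQR(x), 0.28, tolerance = 0.01)
  expect_lt(mean((x - mean(x))^3) / sd(x)^3, -0.3)  # clearly left-skewed
})

test_that("cohorts are reproducible and patient substreams are stable", {
  spec <- cohort_spec(seed = 4L)
  a <- generate_metric_cohort(spec)
  b <- generate_metric_cohort(spec)
  expect_identical(a, b)

  small <- cohort_spec(n_patients = c(prostate_sv_hypofx = 2L), seed = 4L)
  big <- cohort_spec(n_patients = c(prostate_sv_hypofx = 5L), seed = 4L)
  ta <- generate_metric_cohort(small)
  tb <- generate_metric_cohort(big)
  expect_identical(ta, tb[tb$patient_id %in% unique(ta$patient_id), ])
})

test_that("generated tables have the cohort scale and schema invariants", {
  tbl <- generate_metric_cohort(cohort_spec(seed = 2L))
  # 16 patients, 320 fractions, 16 metric slots each
  expect_equal(length(unique(tbl$patient_id)), 16)
  expect_equal(nrow(dplyr::distinct(tbl, patient_id, fraction_index)), 320)
  expect_equal(nrow(tbl), 320 * 16)
  expect_silent(arttrigger:::validate_metric_table(tbl))

  # fraction counts follow the prescriptions
  counts <- tbl |>
    dplyr::distinct(site, patient_id, fraction_index) |>
    dplyr::count(site, patient_id)
  reg <- site_registry()
  expect_equal(counts$n, reg$n_fractions[match(counts$site, reg$site)])

  # REF constant per patient x metric; values present iff valid
  expect_true(all(is.na(tbl$sch_value[tbl$status != "valid"])))
  expect_true(all(!is.na(tbl$sch_value[tbl$status == "valid"])))
})

test_that("an all-zero-noise spec yields identically zero differences", {
  params <- default_metric_params() |>
    dplyr::mutate(sch_median = 0, sch_iqr = 0, sch_alpha = 0,
                  adp_median = 0, adp_iqr = 0)
  spec <- cohort_spec(n_patients = c(prostate_sv_hypofx = 2L),
                      metric_params = params, seed = 1L)
  d <- compute_differences(generate_metric_cohort(spec))
  expect_true(all(d$sch_ref == 0 & d$adp_ref == 0 & d$adp_sch == 0))
  # no trigger at a negative coverage threshold ever fires
  pol <- trigger_policy("ptv_d95", -0.25)
  dd <- d[d$metric_id == "ptv_d95", ]
  expect_equal(proportion_adapted(adaptation_decision(dd, pol)), 0)
})

test_that("generated difference distributions have the configured shape", {
  spec <- cohort_spec(n_patients = c(prostate_sv_hypofx = 50L), seed = 8L)
  d <- compute_differences(generate_metric_cohort(spec))  # 1300 fractions

  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  cov <- d$sch_ref[d$metric_id == "ptv_d95"]
  expect_lt(skew(cov), 0)  # coverage deficits are left-skewed
  oar <- d$sch_ref[d$metric_id == "bladder_v65gy"]
  expect_gt(skew(oar), 0)  # right-skewed OAR preset

  # adapted doses hug the reference more tightly than scheduled ones
  for (m in c("ptv_d95", "ptv_d99", "ctv_v100")) {
    expect_lt(IQR(d$adp_ref[d$metric_id == m]),
              IQR(d$sch_ref[d$metric_id == m]))
  }
})

test_that("a configurable minority of fractions violates preference", {
  spec <- cohort_spec(n_patients = c(prostate_sv_hypofx = 50L), seed = 13L)
  d <- compute_differences(generate_metric_cohort(spec))
  viol <- mean(d$adp_sch[d$metric_id == "ptv_d95"] <= 0)
  expect_gt(viol, 0.02)  # the adaptation ceiling stays below 100%
  expect_lt(viol, 0.5)   # but adaptation is usually preferred
})

test_that("cohort specs round-trip through YAML and regenerate identically", {
  spec <- cohort_spec(n_patients = c(prostate_sbrt = 2L,
                                     bladder_hypofx = 1L), seed = 6L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_spec(spec, path)
  back <- read_cohort_spec(path)
  expect_equal(back$n_patients, spec$n_patients)
  expect_equal(back$seed, spec$seed)
  expect_identical(generate_metric_cohort(back), generate_metric_cohort(spec))
})

test_that("malformed specs are rejected", {
  expect_error(cohort_spec(n_patients = c(elbow = 2L)), "unknown site")
  expect_error(cohort_spec(n_patients = c(prostate_sbrt = 0L)), ">= 1")
  bad <- dplyr::mutate(default_metric_params(),
                       sch_iqr = dplyr::if_else(dplyr::row_number() == 1,
                                                -1, sch_iqr))
  expect_error(cohort_spec(metric_params = bad), "scales")
})
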