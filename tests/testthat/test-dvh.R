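test_that("DVH metrics reproduce hand-computed values on a 4-voxel structure", {
  g <- dose_grid(array(c(1, 2, 3, 4), dim = c(4, 1, 1)), spacing = c(10, 10, 10))
  m <- structure_mask(array(TRUE, dim = c(4, 1, 1)), "ptv", "target")
  cv <- compute_cumulative_dvh(g, m)

  expect_equal(cv$total_volume_cc, 4)
  expect_equal(volume_at_dose(cv, 2), 75)           # 3 of 4 voxels >= 2 Gy
  expect_equal(volume_at_dose(cv, 0), 100)
  expect_equal(volume_at_dose(cv, 5), 0)
  expect_equal(dose_at_relative_volume(cv, 50), 3)  # hottest 50% = {3,4}
  expect_equal(dose_at_relative_volume(cv, 100), 1) # full-volume minimum
  expect_equal(dose_at_absolute_volume(cv, 2), 3)   # hottest 2 cc = {3,4}
  expect_equal(dose_at_absolute_volume(cv, 0), 4)   # zero-volume limit = max
  expect_equal(dose_at_absolute_volume(cv, 10), 1)  # over-volume limit = min
})

test_that("uniform dose collapses the DVH to a step at the dose level", {
  g <- dose_grid(array(2, dim = c(3, 3, 3)), spacing = c(2, 2, 2))
  m <- structure_mask(array(TRUE, dim = c(3, 3, 3)), "ptv", "target")
  cv <- compute_cumulative_dvh(g, m)

  below <- cv$dose_edges <= 2 + 1e-9
  expect_true(all(cv$cum_volume_fraction[below] == 1))
  expect_true(all(cv$cum_volume_fraction[!below] == 0))
  for (x in c(1, 50, 99, 100)) {
    expect_equal(dose_at_relative_volume(cv, x), 2)
  }
})

test_that("degenerate and invalid inputs are rejected", {
  g <- dose_grid(array(1, dim = c(2, 2, 2)), spacing = c(1, 1, 1))
  empty <- structure_mask(array(FALSE, dim = c(2, 2, 2)), "void", "oar")
  expect_error(compute_cumulative_dvh(g, empty), "empty")

  wrong <- structure_mask(array(TRUE, dim = c(3, 2, 2)), "s", "oar")
  expect_error(compute_cumulative_dvh(g, wrong), "congruent")

  m <- structure_mask(array(TRUE, dim = c(2, 2, 2)), "s", "oar")
  cv <- compute_cumulative_dvh(g, m)
  expect_error(dose_at_relative_volume(cv, 0), "0, 100")
  expect_error(dose_at_relative_volume(cv, 101), "0, 100")
  expect_error(dose_at_absolute_volume(cv, -1), "non-negative")
  expect_error(volume_at_dose(cv, -0.1), "non-negative")

  expect_error(dose_grid(array(-1, dim = c(1, 1, 1)), c(1, 1, 1)), "finite")
  expect_error(dose_grid(array(1, dim = c(1, 1, 1)), c(0, 1, 1)), "positive")
})

test_that("curve invariants hold on random phantoms", {
  set.seed(42)
  for (rep in 1:20) {
    gm <- random_grid_mask()
    cv <- compute_cumulative_dvh(gm$grid, gm$mask)
    expect_true(all(diff(cv$cum_volume_fraction) <= 0))
    expect_equal(cv$cum_volume_fraction[1], 1)
    expect_true(all(diff(cv$dose_edges) > 0))
    expect_equal(cv$total_volume_cc,
                 sum(gm$mask$occupancy) * voxel_volume_cc(gm$grid))
  }
})

test_that("engine metrics match the brute-force voxel-multiset oracle", {
  set.seed(7)
  bw <- 0.01
  for (rep in 1:50) {
    gm <- random_grid_mask()
    doses <- gm$grid$values[gm$mask$occupancy]
    vox <- voxel_volume_cc(gm$grid)
    cv <- compute_cumulative_dvh(gm$grid, gm$mask, bin_width = bw)
    vol_tol <- 100 / length(doses) + 1e-9

    for (x in c(2, 50, 95, 99, 100)) {
      expect_lt(abs(dose_at_relative_volume(cv, x) -
                      bf_dose_at_relative_volume(doses, x)), bw + 1e-9)
    }
    for (x in c(0, 0.03, vox * 1.7, sum(gm$mask$occupancy) * vox * 2)) {
      expect_lt(abs(dose_at_absolute_volume(cv, x) -
                      bf_dose_at_absolute_volume(doses, x, vox)), bw + 1e-9)
    }
    for (t in c(0, 1, 5, 9.99)) {
      expect_lt(abs(volume_at_dose(cv, t) - bf_volume_at_dose(doses, t)),
                vol_tol)
    }
  }
})

test_that("Dx% and VxGy are monotone and consistent under round trip", {
  set.seed(11)
  for (rep in 1:10) {
    gm <- random_grid_mask()
    cv <- compute_cumulative_dvh(gm$grid, gm$mask)
    n <- sum(gm$mask$occupancy)

    xs <- c(1, 5, 25, 50, 75, 95, 100)
    dx <- vapply(xs, function(x) dose_at_relative_volume(cv, x), numeric(1))
    expect_true(all(diff(dx) <= 0))

    ts <- seq(0, max(cv$dose_edges), length.out = 9)
    vs <- vapply(ts, function(t) volume_at_dose(cv, t), numeric(1))
    expect_true(all(diff(vs) <= 1e-12))

    for (x in c(10, 50, 90)) {
      v <- volume_at_dose(cv, dose_at_relative_volume(cv, x))
      expect_gte(v, x - 100 / n - 1e-9)
    }
  }
})
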