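test_that("dose difference is measured minus calculated, with resampling", {
  a <- planar_dose_from_matrix(matrix(100, 40, 40))
  expect_true(all(dose_difference(a, a) == 0))
  b <- planar_dose_from_matrix(matrix(105, 40, 40))
  expect_true(all(dose_difference(a, b) == 5))
  # resampled half-pixel shift of a linear ramp -> difference = slope * shift
  ramp <- planar_dose_from_matrix(outer(seq(0, 78, by = 2), rep(1, 40)),
                                  pixel = 0.1)   # slope 20 %/cm along x
  shifted <- shift_planar(ramp, 0.05, 0)
  dd <- dose_difference(ramp, shifted)
  expect_equal(unname(dd[10:30, 10:30]),
               matrix(-20 * 0.05, 21, 21), tolerance = 1e-6)
})

test_that("DTA recovers known shifts and caps where no agreement exists", {
  ramp <- planar_dose_from_matrix(outer(seq(50, 150, length.out = 101),
                                        rep(1, 101)), pixel = 0.1)
  expect_true(all(dta(ramp, ramp) < 1e-9))
  sh <- shift_planar(ramp, 0.25, 0)
  d <- dta(ramp, sh)
  expect_equal(unname(d[20:80, 20:80]), matrix(0.25, 61, 61),
               tolerance = 0.02)
  # flat field with an offset: no crossing anywhere -> cap
  flat <- planar_dose_from_matrix(matrix(100, 30, 30))
  off <- planar_dose_from_matrix(matrix(105, 30, 30))
  expect_true(all(dta(flat, off, cap = 1) == 1))
})

test_that("composite criterion passes by dose OR distance", {
  pl <- fx_memo("planar2", planar_dose(fx_beam(), fx_aperture(), NULL,
                                       depth = 2))
  expect_equal(composite_pass(pl, pl)$pass_rate, 100)
  flat <- planar_dose_from_matrix(matrix(100, 60, 60))
  r <- composite_pass(flat, planar_dose_from_matrix(matrix(105, 60, 60)))
  expect_equal(r$pass_rate, 0)
  # sub-tolerance spatial shift of a penumbra passes via DTA
  sh <- shift_planar(pl, 0.25, 0)
  expect_equal(composite_pass(pl, sh)$pass_rate, 100)
  # histogram covers every evaluated point
  expect_identical(sum(r$histogram$count), sum(r$mask))
})

test_that("pass rate is monotone in tolerances and threshold", {
  pl <- fx_memo("planar2", planar_dose(fx_beam(), fx_aperture(), NULL,
                                       depth = 2))
  set.seed(7)
  noisy <- pl
  noisy$values <- pl$values + matrix(rnorm(length(pl$values), 0, 3),
                                     nrow(pl$values))
  base <- composite_pass(pl, noisy)$pass_rate
  expect_gte(composite_pass(pl, noisy, dose_tol = 5)$pass_rate, base)
  expect_gte(composite_pass(pl, noisy, dist_tol = 0.6)$pass_rate, base)
  expect_lte(composite_pass(pl, noisy, threshold = 5)$pass_rate,
             composite_pass(pl, noisy, threshold = 50)$pass_rate + 100)
  expect_true(composite_pass(pl, noisy, threshold = 50)$pass_rate >= 0)
})

test_that("DVH metrics match closed forms", {
  arr <- array(100, c(5, 5, 4))
  mask <- array(TRUE, dim(arr))
  expect_equal(metric_d_span(dvh(arr, mask)), 0, tolerance = 0.11)
  # uniform linear distribution 90..110: D10 = 108, D90 = 92, span 16
  lin <- array(seq(90, 110, length.out = 2000), c(10, 10, 20))
  dl <- dvh(lin, array(TRUE, dim(lin)))
  expect_equal(dvh_dose_at(dl, 10), 108, tolerance = 0.05)
  expect_equal(dvh_dose_at(dl, 90), 92, tolerance = 0.05)
  expect_equal(metric_d_span(dl), 16, tolerance = 0.1)
  # V95 of a uniform 96% dose is 100%
  expect_equal(dvh_volume_at(dvh(array(96, c(4, 4, 4)),
                                 array(TRUE, c(4, 4, 4))), 95), 100)
  # DVH is monotone non-increasing and starts at 100
  expect_true(all(diff(dl$volume) <= 0))
  expect_equal(dl$volume[1], 100)
})

test_that("V95 matching finds the expected scale factor", {
  set.seed(3)
  a <- array(rnorm(4000, 100, 4), c(20, 20, 10))
  mask <- array(TRUE, dim(a))
  expect_equal(normalize_match_v95(a, a, mask)$factor, 1, tolerance = 1e-3)
  expect_equal(normalize_match_v95(a, 0.5 * a, mask)$factor, 2,
               tolerance = 1e-3)
  # monotone: a hotter reference never needs a smaller factor
  f1 <- normalize_match_v95(a, 0.8 * a, mask)$factor
  f2 <- normalize_match_v95(1.05 * a, 0.8 * a, mask)$factor
  expect_gte(f2, f1)
})
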