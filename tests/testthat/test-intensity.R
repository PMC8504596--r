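test_that("IRF operator is continuous, non-increasing and clamped", {
  expect_equal(irf_from_dmax(95), 1)
  expect_equal(irf_from_dmax(110), 100 / 110)
  expect_equal(irf_from_dmax(130), 0.8)
  expect_error(irf_from_dmax(0), "positive")
  g <- seq(50, 200, by = 0.05)
  v <- irf_from_dmax(g)
  expect_true(all(diff(v) <= 0))
  expect_true(all(v >= 0.8 & v <= 1))
  # continuity at the two joints: 100% and 100/0.8 = 125%
  expect_lt(abs(irf_from_dmax(100 - 1e-9) - irf_from_dmax(100 + 1e-9)), 1e-6)
  expect_lt(abs(irf_from_dmax(125 - 1e-9) - irf_from_dmax(125 + 1e-9)), 1e-6)
  expect_equal(irf_from_dmax(125), 0.8)
  # user-configurable limits
  expect_equal(irf_from_dmax(200, irf_min = 0.7), 0.7)
})

test_that("ray maximum dose finds hot voxels along eligible rays", {
  ph <- wavy_slab_phantom(amplitude = 0)
  fan <- make_fan_grid(fx_aperture())
  mk <- function(vals) structure(list(values = vals, origin = ph$grid$origin,
                                      spacing = ph$grid$spacing),
                                 class = "dose3d")
  v <- array(100, dim(ph$grid$values))
  rm_ <- ray_max_dose(mk(v), ph$ptv, ph$grid, fan)
  expect_equal(unname(rm_$dmax[rm_$eligible]),
               rep(100, sum(rm_$eligible)))
  # a 110% hot block inside the PTV spanning the axis ray (2 voxels per
  # axis so trilinear interpolation at the ray reaches the full value)
  kc <- which(ph$ptv[30, 30, ])[3]
  v2 <- v; v2[30:31, 30:31, kc + 0:1] <- 110
  rm2 <- ray_max_dose(mk(v2), ph$ptv, ph$grid, fan)
  ic <- which.min(abs(fan$x)); jc <- which.min(abs(fan$y))
  expect_equal(rm2$dmax[ic, jc], 110, tolerance = 0.01)
  # margin wider than the PTV: degenerate, error path
  expect_error(ray_max_dose(mk(v), ph$ptv, ph$grid, fan, margin = 5),
               "eligible")
})

test_that("intensity map composes ray maxima, extension and clamping", {
  ph <- wavy_slab_phantom(amplitude = 0)
  fan <- make_fan_grid(fx_aperture())
  mk <- function(vals) structure(list(values = vals, origin = ph$grid$origin,
                                      spacing = ph$grid$spacing),
                                 class = "dose3d")
  # conformal dose without hot spots -> IRF identically 1
  cool <- mk(array(98, dim(ph$grid$values)))
  im1 <- build_intensity_map(cool, ph$ptv, ph$grid, fan)
  expect_true(all(im1$irf == 1))
  # idempotent on a cool distribution: weights stay all-ones
  im1b <- build_intensity_map(cool, ph$ptv, ph$grid, fan)
  expect_identical(im1$irf, im1b$irf)
  # hot half-field at 110% -> IRF ~ 0.909 there, 1 elsewhere, halo outside
  v <- array(98, dim(ph$grid$values))
  x <- ph$grid$origin[1] + (seq_len(dim(v)[1]) - 0.5) * ph$grid$spacing[1]
  v[x < -1, , ] <- 110
  im2 <- build_intensity_map(mk(v), ph$ptv, ph$grid, fan)
  hotlines <- im2$eligible & outer(fan$x < -1.5, rep(TRUE, length(fan$y)))
  coollines <- im2$eligible & outer(fan$x > 0.5, rep(TRUE, length(fan$y)))
  expect_equal(unname(im2$irf[hotlines]),
               rep(100 / 110, sum(hotlines)), tolerance = 0.005)
  expect_true(all(im2$irf[coollines] == 1))
  # extension halo: ineligible lines adjacent to the hot side carry its value
  halo <- !im2$eligible & outer(fan$x < -3.6, rep(TRUE, length(fan$y))) &
    outer(rep(TRUE, length(fan$x)), abs(fan$y) < 1)
  expect_equal(unname(im2$irf[halo]), rep(100 / 110, sum(halo)),
               tolerance = 0.005)
  expect_true(all(im2$irf >= 0.8 & im2$irf <= 1))
})

test_that("applying the intensity map reduces the PTV maximum dose", {
  ph <- fx_phantom()
  res <- fx_bect_plan()
  imap <- build_intensity_map(res$dose, ph$ptv, ph$grid, res$fan)
  expect_lt(min(imap$irf), 1)           # the fixture does produce hot spots
  fan2 <- res$fan
  fan2$weights <- imap$irf
  d2 <- compute_dose(ph$grid, fx_beam(), fx_aperture(), fan2, res$bolus)
  expect_lt(max(d2$values[ph$ptv]), max(res$dose$values[ph$ptv]))
})
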