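test_that("effective depth integrates density and bolus along the ray", {
  wt <- fx_tank()
  expect_equal(effective_depth(wt, c(0, 0), 105), 5, tolerance = 1e-6)
  # half-density slab 2 cm over water: depth 5 -> 2*0.5 + 3 = 4.0
  hd <- water_tank(c(12, 12, 8), c(0.2, 0.2, 0.2), 100)
  z <- hd$origin[3] + (seq_len(dim(hd$values)[3]) - 0.5) * 0.2
  hd$values[, , z - 100 < 2] <- 0.5
  expect_equal(effective_depth(hd, c(0, 0), 105), 4, tolerance = 0.03)
  # 2 cm wax bolus (rho_e 0.92) over water depth 3 -> 2*0.92 + 3 = 4.84
  fan <- make_fan_grid(fx_aperture())
  bol <- bolus_surface(matrix(2, length(fan$x), length(fan$y)), fan,
                       density = 0.92)
  expect_equal(effective_depth(wt, c(0, 0), 103, bolus = bol), 4.84,
               tolerance = 1e-6)
  # ray missing the grid
  expect_equal(effective_depth(wt, c(0, 0), 99), 0)
})

test_that("open-field water dose matches the PDD on the central axis", {
  d <- fx_memo("wt_dose", compute_dose(fx_tank(), fx_beam(), fx_aperture()))
  ca <- ca_profile(d)
  expect_equal(ca$value[which.min(abs(ca$depth - 5))], 90, tolerance = 0.5 / 90)
  expect_lte(abs(max(ca$value) - 100), 0.5)
  expect_true(all(d$values >= 0) && all(is.finite(d$values)))
})

test_that("dose is linear in the fan-line weights", {
  wt <- water_tank(c(8, 8, 6), c(0.25, 0.25, 0.25), 100)
  ap <- rectangular_aperture(6, 6)
  fan <- make_fan_grid(ap, spacing = 0.25)
  d1 <- compute_dose(wt, fx_beam(), ap, fan)
  fan$weights <- fan$weights * 0.8
  d2 <- compute_dose(wt, fx_beam(), ap, fan)
  expect_equal(d2$values, d1$values * 0.8, tolerance = 1e-9)
})

test_that("a uniform pin array scales dose by its IRF at depth", {
  wt <- fx_tank()
  ap <- fx_aperture()
  pat <- uniform_pin_array(0.315)        # catalog IRF 75.0%
  d_open <- fx_memo("wt_dose", compute_dose(wt, fx_beam(), ap))
  d_mod <- compute_dose(wt, fx_beam(), ap, blocks = pat)
  co <- ca_profile(d_open); cm <- ca_profile(d_mod)
  k <- which.min(abs(co$depth - 2))
  expect_equal(cm$value[k] / co$value[k], 0.75, tolerance = 0.02 / 0.75)
})

test_that("planar dose matches the PDD in-field and decays outside", {
  b <- fx_beam()
  pl <- fx_memo("planar2", planar_dose(b, fx_aperture(), NULL, depth = 2))
  cen <- abs(outer(pl$x, rep(1, length(pl$y)))) <= 2 &
    abs(outer(rep(1, length(pl$x)), pl$y)) <= 2
  expect_equal(mean(pl$values[cen]), pdd(b, 2), tolerance = 0.01)
  expect_lt(max(abs(pl$values[cen] - pdd(b, 2))) / pdd(b, 2), 0.01)
  # >= 2 cm outside the aperture edge: below 5%
  out <- abs(outer(pl$x, rep(1, length(pl$y)))) >= 7
  expect_lt(max(pl$values[out]), 5)
})

test_that("modulated planar dose tracks the local fluence ratio", {
  b <- fx_beam()
  ap <- fx_aperture()
  pat <- uniform_pin_array(0.417)        # catalog IRF 56.2%
  pl_open <- fx_memo("planar2", planar_dose(b, ap, NULL, depth = 2))
  pl_mod <- planar_dose(b, ap, pat, depth = 2)
  cen <- abs(outer(pl_open$x, rep(1, length(pl_open$y)))) <= 2 &
    abs(outer(rep(1, length(pl_open$x)), pl_open$y)) <= 2
  ratio <- mean(pl_mod$values[cen]) / mean(pl_open$values[cen])
  expect_equal(ratio, 0.562, tolerance = 0.02 / 0.562)
})
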