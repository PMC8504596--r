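test_that("create fills the range deficit to the distal PTV", {
  # flat slab, distal water depth 3.0, R90 5.0, density 1.0 -> t = 2.0
  ph <- wavy_slab_phantom(amplitude = 0)
  fan <- make_fan_grid(fx_aperture())
  bol <- op_create(ph$ptv, ph$grid, fx_beam(), fan, density = 1.0)
  el <- attr(bol, "eligible")
  expect_equal(unname(bol$t[el]), rep(2, sum(el)), tolerance = 0.05)
  # extension: ineligible lines copy the (constant) eligible value
  expect_equal(range(bol$t), range(bol$t[el]), tolerance = 1e-9)
  # distal at R90 -> zero thickness
  b3 <- make_beam(3, 16)
  bol0 <- op_create(ph$ptv, ph$grid, b3, fan, density = 1.0)
  expect_lte(max(bol0$t), 0.06)
})

test_that("create thickness is anti-correlated with distal depth", {
  ph <- fx_phantom()
  fan <- make_fan_grid(fx_aperture())
  bol <- op_create(ph$ptv, ph$grid, fx_beam(), fan)
  el <- attr(bol, "eligible")
  ext <- imbect:::ray_ptv_extent(ph$grid, ph$ptv, fan)
  expect_lt(stats::cor(bol$t[el], ext$distal_z[el]), -0.95)
  # peak-to-peak thickness = distal depth range / density (the distal
  # surface seen through the voxelized mask is quantized by one z spacing)
  iy <- which.min(abs(fan$y))
  row <- bol$t[, iy][el[, iy]]
  distal_ptp <- diff(range(ext$distal_z[el[, iy], iy]))
  expect_equal(diff(range(row)), distal_ptp / 0.92, tolerance = 0.02)
  expect_equal(distal_ptp, 2 * 0.5, tolerance = 0.25)
})

test_that("isodose shift applies the per-line crossing correction", {
  ph <- wavy_slab_phantom(amplitude = 0)   # distal depth 3.0 everywhere
  fan <- make_fan_grid(fx_aperture())
  bol <- op_create(ph$ptv, ph$grid, fx_beam(), fan, density = 1.0)
  mk_dose <- function(z90_depth) {
    v <- array(0, dim(ph$grid$values))
    z <- ph$grid$origin[3] +
      (seq_len(dim(v)[3]) - 0.5) * ph$grid$spacing[3] - ph$grid$origin[3]
    for (k in seq_along(z)) v[, , k] <- 90 + 10 * (z90_depth - z[k])
    structure(list(values = v, origin = ph$grid$origin,
                   spacing = ph$grid$spacing), class = "dose3d")
  }
  ext <- imbect:::ray_ptv_extent(ph$grid, ph$ptv, fan)
  # dose already conformal (90% at the distal surface): fixed point up to
  # the voxelized distal-surface quantization
  b1 <- op_isodose_shift(bol, mk_dose(3.0), ph$ptv, ph$grid, fan)
  expect_lt(max(abs(b1$t - bol$t)), 0.06)
  # 90% crossing deep of the distal PTV: per-line rule arithmetic
  # t += (z_90 - z_distal) / density, checked line by line
  b2 <- op_isodose_shift(bol, mk_dose(3.4), ph$ptv, ph$grid, fan)
  el <- attr(b2, "eligible")
  expected <- ((100 + 3.4) - ext$distal_z[el]) / 1.0
  expect_equal(unname(b2$t[el] - bol$t[el]), unname(expected),
               tolerance = 0.01)
})

test_that("smoothing preserves constants and mass, reduces variance", {
  fan <- make_fan_grid(fx_aperture())
  n1 <- length(fan$x); n2 <- length(fan$y)
  uni <- bolus_surface(matrix(1.5, n1, n2), fan)
  expect_equal(op_smooth(uni)$t, uni$t, tolerance = 1e-9)
  # single-line spike: peak reduced, mass preserved away from edges
  sp <- matrix(0.5, n1, n2)
  sp[31, 31] <- 3
  spike <- bolus_surface(sp, fan)
  sm <- op_smooth(spike)
  expect_lt(max(sm$t), max(spike$t))
  expect_equal(sum(sm$t - 0.5), sum(spike$t - 0.5), tolerance = 0.005)
  expect_identical(sm$footprint, spike$footprint)
  # variance decreases monotonically under repeated smoothing
  r <- bolus_surface(matrix(runif(n1 * n2, 0, 2), n1, n2), fan)
  v0 <- stats::var(as.vector(r$t))
  s1 <- op_smooth(r); s2 <- op_smooth(s1)
  expect_lt(stats::var(as.vector(s1$t)), v0)
  expect_lt(stats::var(as.vector(s2$t)), stats::var(as.vector(s1$t)))
})

test_that("specified shift adds uniformly with a floor at zero", {
  fan <- make_fan_grid(fx_aperture())
  n1 <- length(fan$x); n2 <- length(fan$y)
  t0 <- matrix(1, n1, n2); t0[1, 1] <- 0.05
  bol <- bolus_surface(t0, fan)
  shaved <- op_specified_shift(bol, -0.1)
  expect_equal(shaved$t[2, 2], 0.9)
  expect_equal(shaved$t[1, 1], 0)        # floored
  expect_equal(op_specified_shift(bol, 0)$t, bol$t)
})

test_that("truncation drops mass outside the field without changing dose", {
  ph <- fx_phantom()
  ap <- fx_aperture()
  fan <- make_fan_grid(ap)
  bol <- op_create(ph$ptv, ph$grid, fx_beam(), fan)
  tr <- op_truncate(bol, ap)
  expect_lt(bolus_volume(tr), bolus_volume(bol))
  d0 <- compute_dose(ph$grid, fx_beam(), ap, fan, bol)
  d1 <- compute_dose(ph$grid, fx_beam(), ap, fan, tr)
  gx <- ph$grid$origin[1] + (seq_len(dim(d0$values)[1]) - 0.5) * 0.2
  gy <- ph$grid$origin[2] + (seq_len(dim(d0$values)[2]) - 0.5) * 0.2
  infield <- abs(outer(gx, rep(1, length(gy)))) < 5 &
    abs(outer(rep(1, length(gx)), gy)) < 5
  delta <- abs(d1$values - d0$values)[rep(infield, dim(d0$values)[3])]
  expect_lt(max(delta), 0.5)
  # an all-inside footprint is untouched
  small <- bolus_surface(matrix(1, length(fan$x), length(fan$y)), fan)
  small$t[abs(fan$x) > 4, ] <- 0; small$t[, abs(fan$y) > 4] <- 0
  expect_equal(op_truncate(bolus_surface(small$t, fan), ap)$t, small$t)
})

test_that("height extension is nearest-neighbor with deterministic ties", {
  fan <- make_fan_grid(rectangular_aperture(4, 4), spacing = 0.5, margin = 0.5)
  n1 <- length(fan$x); n2 <- length(fan$y)
  t0 <- matrix(0, n1, n2)
  el <- matrix(FALSE, n1, n2)
  # all eligible -> identity
  expect_equal(op_height_extension(bolus_surface(t0 + 2, fan), !el)$t,
               t0 + 2)
  # single eligible line -> constant map
  el1 <- el; el1[3, 4] <- TRUE
  tt <- t0; tt[3, 4] <- 1.7
  expect_true(all(op_height_extension(bolus_surface(tt, fan), el1)$t == 1.7))
  # two eligible points -> Voronoi split, checked against a brute oracle
  el2 <- el; el2[2, 5] <- TRUE; el2[8, 5] <- TRUE
  tv <- t0; tv[2, 5] <- 1; tv[8, 5] <- 2
  out <- op_height_extension(bolus_surface(tv, fan), el2)$t
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    d1 <- (fan$x[i] - fan$x[2])^2 + (fan$y[j] - fan$y[5])^2
    d2 <- (fan$x[i] - fan$x[8])^2 + (fan$y[j] - fan$y[5])^2
    expect_equal(out[i, j], if (d1 <= d2) 1 else 2)  # tie -> lower index
  }
})
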