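test_that("blocked-area relation reproduces the catalog IRF table", {
  d <- c(0.158, 0.223, 0.273, 0.315, 0.352, 0.386, 0.417, 0.473)
  irf_pct <- c(93.7, 87.5, 81.2, 75.0, 68.8, 62.5, 56.2, 43.6)
  expect_equal(100 * irf_for_diameter(d, 0.6), irf_pct, tolerance = 0.0006)
  expect_equal(irf_for_diameter(0, 0.6), 1)
})

test_that("diameter/IRF round trip is exact and matches a sampling oracle", {
  irf <- seq(0.001, 1, length.out = 500)
  expect_equal(irf_for_diameter(diameter_for_irf(irf, 0.6), 0.6), irf,
               tolerance = 1e-12)
  expect_equal(diameter_for_irf(1), 0)
  expect_error(diameter_for_irf(0), "irf")
  expect_error(diameter_for_irf(1.2), "irf")
  # numeric inversion of the blocked-area fraction by 2D cell sampling
  f <- function(d) blocked_fraction_oracle(d, 0.6) - 0.2
  d_oracle <- stats::uniroot(f, c(0.2, 0.35), tol = 1e-5)$root
  expect_equal(diameter_for_irf(0.80, 0.6), d_oracle, tolerance = 0.002)
  expect_equal(diameter_for_irf(0.80, 0.6), 0.2818, tolerance = 0.002)
  # catalog anchor: IRF 0.937 -> d = 0.158
  expect_equal(diameter_for_irf(0.937, 0.6), 0.158, tolerance = 0.007)
})

test_that("catalog snapping is nearest with a no-pin floor and small-tie rule", {
  expect_equal(snap_to_catalog(0.16), 0.158)
  expect_true(is.na(snap_to_catalog(0.05)))          # closer to 0 than 0.158
  expect_true(is.na(snap_to_catalog(0.078)))
  expect_equal(snap_to_catalog(0.08), 0.158)
  expect_equal(snap_to_catalog(0.30), 0.315)         # |0.015| < |0.027|
  expect_equal(snap_to_catalog((0.158 + 0.223) / 2), 0.158)  # tie -> smaller
  expect_equal(snap_to_catalog(1.0), 0.473)
})

test_that("hexagonal lattice has the stated geometry", {
  ap <- fx_aperture()
  sites <- hex_lattice(ap, 0.6, 93.5)
  # exact closed-form count for a centered rectangle
  w <- 10 * 0.935; ry <- 0.6 * sqrt(3) / 2
  nrows <- 0
  for (j in -ceiling(w / 2 / ry):ceiling(w / 2 / ry)) {
    if (abs(j) * ry >= w / 2) next
    off <- if (j %% 2 == 0) 0 else 0.3
    nrows <- nrows + sum(abs(seq(-20, 20) * 0.6 + off) < w / 2)
  }
  expect_identical(nrow(sites), as.integer(nrows))
  # and within 10% of the packing-density estimate area / ((sqrt(3)/2) r^2)
  expect_equal(nrow(sites), w^2 / (sqrt(3) / 2 * 0.36), tolerance = 0.1)
  # interior nearest-neighbor distance = r
  interior <- abs(sites[, 1]) < 3 & abs(sites[, 2]) < 3
  for (k in which(interior)[1:25]) {
    d2 <- (sites[, 1] - sites[k, 1])^2 + (sites[, 2] - sites[k, 2])^2
    expect_equal(sqrt(min(d2[d2 > 0])), 0.6, tolerance = 1e-9)
  }
  # contains the on-axis site
  expect_true(any(sites[, 1] == 0 & sites[, 2] == 0))
})

test_that("segmentation of uniform objectives gives uniform patterns", {
  ap <- fx_aperture()
  cat_ <- pin_catalog()
  expect_length(segment(function(x, y) rep(1, length(x)), cat_, ap)$x, 0L)
  p937 <- segment(function(x, y) rep(0.937, length(x)), cat_, ap)
  expect_true(all(p937$diameter == 0.158))
  expect_identical(length(p937$x), nrow(hex_lattice(ap)))
  p436 <- segment(function(x, y) rep(0.436, length(x)), cat_, ap)
  expect_true(all(p436$diameter == 0.473))
})

test_that("segmentation is monotone in the objective", {
  ap <- fx_aperture()
  cat_ <- pin_catalog()
  getd <- function(irf) {
    p <- segment(function(x, y) rep(irf, length(x)), cat_, ap)
    sites <- attr(p, "sites")
    d <- rep(0, nrow(sites))
    if (length(p$x))
      d[match(paste(p$x, p$y), paste(sites[, 1], sites[, 2]))] <- p$diameter
    d
  }
  for (pair in list(c(0.95, 0.90), c(0.90, 0.80), c(0.85, 0.55)))
    expect_true(all(getd(pair[2]) >= getd(pair[1])))
})

test_that("refinement dithers between catalog steps and respects fixed points", {
  ap <- fx_aperture()
  cat_ <- pin_catalog()
  b <- fx_beam()
  # objective exactly on a catalog value: already within tolerance, 0 sweeps
  p <- segment(function(x, y) rep(0.875, length(x)), cat_, ap)
  r0 <- refine(p, catalog = cat_, aperture = ap, beam = b, tolerance = 0.03)
  expect_identical(attr(r0, "iterations"), 0L)
  expect_identical(r0$diameter, p$diameter)
  # tolerance 1 accepts anything immediately
  p9 <- segment(function(x, y) rep(0.90, length(x)), cat_, ap)
  r1 <- refine(p9, catalog = cat_, aperture = ap, beam = b, tolerance = 1)
  expect_identical(attr(r1, "iterations"), 0L)
  # objective between catalog steps (0.90): converges to a mixed pattern
  r <- refine(p9, catalog = cat_, aperture = ap, beam = b,
              tolerance = 0.02, max_iter = 20)
  expect_lte(attr(r, "iterations"), 20L)
  expect_gt(length(unique(r$diameter)), 1L)
  sites <- attr(r, "sites")
  cen <- abs(sites[, 1]) <= 2.8 & abs(sites[, 2]) <= 2.8
  expect_equal(mean(attr(r, "achieved")[cen]), 0.90, tolerance = 0.02 / 0.90)
})
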