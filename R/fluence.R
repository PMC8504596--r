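#' Fan-line grid for pencil-beam transport
#'
#' Pencil beams are indexed by fan lines: diverging rays from the virtual
#' source (z = 0) through a regular (x_i, y_j) grid in the isocenter plane.
#' The per-line `weights` hold the intensity-modulation factor w_ij applied
#' to the pencil weights (1 everywhere for an unmodulated beam); beam
#' collimation and penumbra are carried by the transported surface fluence,
#' not by the weights.
#'
#' @param aperture An `aperture`; the grid covers its bounding box plus
#'   `margin` on each side.
#' @param spacing Fan-line spacing in the isocenter plane, cm.
#' @param margin Extra lateral coverage beyond the aperture, cm.
#' @return A `fan_grid` with fields `x`, `y` (isocenter-plane positions,
#'   containing the on-axis line), `spacing`, and `weights` (matrix
#'   `length(x)` x `length(y)`).
#' @export
make_fan_grid <- function(aperture, spacing = 0.2, margin = 2) {
  stopifnot(inherits(aperture, "aperture"), spacing > 0, margin >= 0)
  v <- aperture$vertices
  nx <- ceiling((max(abs(v[, 1])) + margin) / spacing)
  ny <- ceiling((max(abs(v[, 2])) + margin) / spacing)
  x <- seq(-nx, nx) * spacing
  y <- seq(-ny, ny) * spacing
  structure(list(x = x, y = y, spacing = spacing,
                 weights = matrix(1, length(x), length(y))),
            class = "fan_grid")
}

#' Unmodulated fan-line collimation weights
#'
#' Indicator weights of the open beam: 1 for fan lines inside the aperture,
#' 0 outside. Penumbra is produced downstream by Gaussian in-air spreading of
#' the collimated fluence, not by fractional weights.
#'
#' @param fan A `fan_grid`.
#' @param aperture An `aperture`.
#' @return A matrix congruent with `fan$weights`.
#' @export
fan_weights_unmodulated <- function(fan, aperture) {
  g <- expand.grid(x = fan$x, y = fan$y)
  m <- point_in_polygon(g$x, g$y, aperture$vertices)
  matrix(as.numeric(m), length(fan$x), length(fan$y))
}

#' Transport electron fluence to a transverse plane
#'
#' Computes the relative electron fluence at `surface_z` (the bolus/patient
#' entrance plane, or any plane downstream of the collimator). The open-field
#' fluence is the aperture indicator, projected by similar triangles and
#' spread by an in-air Gaussian of width `sigma_air = sigma_theta *
#' (surface_z - collimator_z)`. Each island block removes, per the
#' perfect-collimation assumption, all electrons incident on its top face:
#' its contribution is subtracted as the fluence of a square pencil of side
#' `d * sqrt(pi)/2` (equal area to the circular block) centered at the
#' block's projected position and spread by the same Gaussian. Negative
#' results (overlapping shadows) are clamped to zero.
#'
#' When `blocks` is non-NULL and the beam has not yet received the modulator
#' corrections, they are applied internally (angular spread x 1.5, R90
#' - 0.1 cm), so that both the open-field and the block terms use the
#' modulator-corrected angular spread.
#'
#' @param fan A `fan_grid`; fluence is returned at the fan-line positions
#'   projected to `surface_z`.
#' @param aperture An `aperture`.
#' @param blocks An `island_pattern` or NULL.
#' @param beam A [make_beam()] object.
#' @param surface_z Plane distance from the virtual source, cm; must exceed
#'   the collimator plane distance.
#' @return A `surface_fluence`: list with `values` (matrix over fan indices),
#'   `x`, `y` (isocenter-plane fan positions), `z`, `sigma_air`.
#' @export
transport_fluence <- function(fan, aperture, blocks = NULL, beam,
                              surface_z) {
  stopifnot(inherits(fan, "fan_grid"), inherits(aperture, "aperture"),
            inherits(beam, "beam_model"))
  if (surface_z <= aperture$collimator_z)
    stop("'surface_z' must be downstream of the collimator plane",
         call. = FALSE)
  if (!is.null(blocks) && !beam$modulator_corrected)
    beam <- apply_modulator_corrections(beam)
  sigma <- beam$sigma_theta0 * (surface_z - aperture$collimator_z)
  scale <- surface_z / aperture$iso_z
  xs <- fan$x * scale          # fan positions at the target plane
  ys <- fan$y * scale
  vals <- open_field_fluence(xs, ys, aperture_at(aperture, surface_z), sigma)

  if (!is.null(blocks) && length(blocks$x) > 0L) {
    bscale <- surface_z / blocks$plane_z
    inside <- point_in_polygon(blocks$x / blocks$plane_z * aperture$iso_z,
                               blocks$y / blocks$plane_z * aperture$iso_z,
                               aperture$vertices)
    if (any(!inside))
      warning(sum(!inside), " island block(s) outside the aperture; applied anyway")
    for (l in seq_along(blocks$x)) {
      s <- blocks$diameter[l] * sqrt(pi) / 2 * bscale
      xc <- blocks$x[l] * bscale
      yc <- blocks$y[l] * bscale
      fx <- stats::pnorm((xs - xc + s / 2) / sigma) -
        stats::pnorm((xs - xc - s / 2) / sigma)
      fy <- stats::pnorm((ys - yc + s / 2) / sigma) -
        stats::pnorm((ys - yc - s / 2) / sigma)
      vals <- vals - outer(fx, fy)
    }
    vals[vals < 0] <- 0
  }
  structure(list(values = vals, x = fan$x, y = fan$y, z = surface_z,
                 sigma_air = sigma), class = "surface_fluence")
}

# Open-field fluence at points (xs x ys) in the plane: polygon indicator
# rasterized on an internal fine grid, convolved with a separable Gaussian,
# then bilinearly sampled. For sigma below the raster step the indicator is
# sampled directly.
open_field_fluence <- function(xs, ys, poly, sigma, h = 0.05) {
  if (sigma < h) {
    g <- expand.grid(x = xs, y = ys)
    return(matrix(as.numeric(point_in_polygon(g$x, g$y, poly)),
                  length(xs), length(ys)))
  }
  pad <- 4 * sigma + 2 * h
  gx <- seq(min(xs) - pad, max(xs) + pad, by = h)
  gy <- seq(min(ys) - pad, max(ys) + pad, by = h)
  gg <- expand.grid(x = gx, y = gy)
  ind <- matrix(as.numeric(point_in_polygon(gg$x, gg$y, poly)),
                length(gx), length(gy))
  k <- gauss_kernel_1d(sigma, h)
  sm <- conv_separable(ind, k)
  bilinear_sample(gx, gy, sm, xs, ys, outer_grid = TRUE)
}

gauss_kernel_1d <- function(sigma, h) {
  m <- ceiling(4 * sigma / h)
  k <- stats::dnorm(seq(-m, m) * h, sd = sigma)
  k / sum(k)
}

# separable convolution (zero-padded edges) via banded matrix products
conv_separable <- function(mat, k) {
  m <- (length(k) - 1L) / 2L
  n1 <- nrow(mat); n2 <- ncol(mat)
  conv1 <- function(n) {
    K <- matrix(0, n, n)
    for (j in seq(-m, m)) {
      idx <- seq_len(n)
      ok <- idx + j >= 1 & idx + j <= n
      K[cbind(idx[ok], idx[ok] + j)] <- k[j + m + 1L]
    }
    K
  }
  conv1(n1) %*% mat %*% t(conv1(n2))
}

# bilinear sampling of matrix `vals` defined on axes gx, gy at points;
# outer_grid=TRUE returns the full outer grid xs x ys, else paired points.
bilinear_sample <- function(gx, gy, vals, xs, ys, outer_grid = FALSE) {
  ix <- findInterval(xs, gx, rightmost.closed = TRUE)
  iy <- findInterval(ys, gy, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), length(gx) - 1L)
  iy <- pmin(pmax(iy, 1L), length(gy) - 1L)
  tx <- (xs - gx[ix]) / (gx[ix + 1L] - gx[ix])
  ty <- (ys - gy[iy]) / (gy[iy + 1L] - gy[iy])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  if (outer_grid) {
    v00 <- vals[ix, iy, drop = FALSE]; v10 <- vals[ix + 1L, iy, drop = FALSE]
    v01 <- vals[ix, iy + 1L, drop = FALSE]; v11 <- vals[ix + 1L, iy + 1L, drop = FALSE]
    wx0 <- 1 - tx; wy0 <- 1 - ty
    v00 * outer(wx0, wy0) + v10 * outer(tx, wy0) +
      v01 * outer(wx0, ty) + v11 * outer(tx, ty)
  } else {
    v00 <- vals[cbind(ix, iy)]; v10 <- vals[cbind(ix + 1L, iy)]
    v01 <- vals[cbind(ix, iy + 1L)]; v11 <- vals[cbind(ix + 1L, iy + 1L)]
    v00 * (1 - tx) * (1 - ty) + v10 * tx * (1 - ty) +
      v01 * (1 - tx) * ty + v11 * tx * ty
  }
}
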