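#' Synthetic phantoms, PTVs and apertures
#'
#' All geometry lives in the beam-eye coordinate system: the virtual electron
#' source sits at z = 0, z increases away from the source along the beam
#' axis, the isocenter plane is at z = 100 cm and the collimator (modulator)
#' plane at z = 93.5 cm. Voxel (1,1,1) of a density grid is centered at
#' `origin + spacing/2` (half-open voxel extents).
#'
#' @name phantom-fixtures
NULL

new_density_grid <- function(origin, spacing, values) {
  stopifnot(length(origin) == 3L, length(spacing) == 3L, all(spacing > 0),
            length(dim(values)) == 3L, all(values >= 0))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 values = values), class = "density_grid")
}

# voxel-center coordinates along axis k (1=x, 2=y, 3=z)
grid_axis <- function(grid, k) {
  n <- dim(grid$values)[k]
  grid$origin[k] + (seq_len(n) - 0.5) * grid$spacing[k]
}

#' Uniform water tank phantom
#'
#' A uniform relative-electron-density 1.0 grid whose top surface lies at the
#' stated source-to-surface distance (`z = ssd` in beam coordinates), centered
#' laterally on the beam axis.
#'
#' @param extent Lateral and depth extents `c(x, y, z)` in cm.
#' @param spacing Voxel spacing `c(dx, dy, dz)` in cm.
#' @param ssd Source-to-surface distance, cm.
#' @return A `density_grid`.
#' @export
water_tank <- function(extent = c(12, 12, 8), spacing = c(0.2, 0.2, 0.2),
                       ssd = 100) {
  stopifnot(all(extent > 0), all(spacing > 0), ssd > 0)
  dims <- pmax(round(extent / spacing), 1L)
  vals <- array(1, dim = dims)
  new_density_grid(c(-extent[1] / 2, -extent[2] / 2, ssd), spacing, vals)
}

#' Slab phantom with a sinusoidal distal PTV surface
#'
#' A flat-entrance, water-equivalent slab phantom whose PTV has a flat
#' proximal surface and a distal surface that is sinusoidal in x:
#' `z_distal(x) = base_depth + amplitude * sin(2*pi*x / period)`. With
#' `amplitude = 0` the PTV reduces to a flat slab. The undulating distal
#' surface is the stand-in for the irregular chest-wall / temple anatomy that
#' makes a conformal bolus spatially variable and thereby produces hot spots
#' in the PTV (thicker bolus pulls the dose maximum closer to the source,
#' raising it by inverse square).
#'
#' Defaults emulate a gentle chest-wall-like case: a 6 x 6 cm PTV, proximal
#' depth 0.5 cm, distal base depth 3.0 cm with 0.5 cm amplitude undulation of
#' 8 cm period, inside a 12 x 12 x 6 cm water-density phantom at 100 cm SSD.
#'
#' @param amplitude Distal-surface sine amplitude, cm (>= 0).
#' @param period Distal-surface sine period, cm.
#' @param base_depth Mean distal PTV depth, cm.
#' @param proximal_depth Proximal PTV depth, cm.
#' @param ptv_halfwidth Lateral PTV half-width in x and y, cm.
#' @param extent,spacing,ssd As in [water_tank()].
#' @return A list with elements `grid` (a `density_grid`) and `ptv` (a logical
#'   array congruent with the grid).
#' @export
wavy_slab_phantom <- function(amplitude = 0.5, period = 8, base_depth = 3.0,
                              proximal_depth = 0.5, ptv_halfwidth = 3.0,
                              extent = c(12, 12, 6),
                              spacing = c(0.2, 0.2, 0.2), ssd = 100) {
  stopifnot(amplitude >= 0, period > 0,
            base_depth + amplitude < extent[3],
            proximal_depth < base_depth - amplitude)
  grid <- water_tank(extent, spacing, ssd)
  x <- grid_axis(grid, 1); y <- grid_axis(grid, 2); z <- grid_axis(grid, 3)
  depth <- z - ssd
  distal <- base_depth + amplitude * sin(2 * pi * x / period)
  ptv <- array(FALSE, dim = dim(grid$values))
  iny <- abs(y) <= ptv_halfwidth
  for (i in seq_along(x)) {
    if (abs(x[i]) > ptv_halfwidth) next
    inz <- depth >= proximal_depth & depth <= distal[i]
    ptv[i, iny, inz] <- TRUE
  }
  list(grid = grid, ptv = ptv)
}

#' Rectangular beam aperture
#'
#' A centered rectangular aperture specified in the isocenter plane
#' (z = 100 cm); the physical collimating insert sits at the 93.5 cm plane,
#' where the opening scales by similar triangles about the virtual source.
#'
#' @param width,height Side lengths at the isocenter plane, cm.
#' @param collimator_z Source-to-collimator distance, cm.
#' @return An `aperture` object (simple polygon, counter-clockwise vertices).
#' @export
rectangular_aperture <- function(width, height = width, collimator_z = 93.5) {
  if (width <= 0 || height <= 0)
    stop("aperture sides must be positive", call. = FALSE)
  v <- cbind(x = c(-1, 1, 1, -1) * width / 2,
             y = c(-1, -1, 1, 1) * height / 2)
  structure(list(vertices = v, collimator_z = collimator_z,
                 iso_z = 100), class = "aperture")
}

#' Project aperture vertices to another transverse plane
#'
#' Similar-triangle projection about the virtual source at z = 0:
#' `x(z) = x(z0) * z / z0`.
#'
#' @param aperture An `aperture`.
#' @param z Target plane distance from the source, cm.
#' @return A two-column vertex matrix in the target plane.
#' @export
aperture_at <- function(aperture, z) {
  stopifnot(inherits(aperture, "aperture"))
  aperture$vertices * (z / aperture$iso_z)
}

#' Aperture polygon area (isocenter plane)
#' @param aperture An `aperture`.
#' @return Area in cm^2.
#' @export
aperture_area <- function(aperture) {
  v <- aperture$vertices
  abs(polygon_area(v[, 1], v[, 2]))
}

# signed shoelace area
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param px,py Point coordinates (vectors).
#' @param poly Two-column vertex matrix of a simple polygon.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_grid> %d x %d x %d voxels, spacing %.2g x %.2g x %.2g cm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.1f, %.1f, %.1f) cm; surface z = %.1f cm\n",
              x$origin[1], x$origin[2], x$origin[3], x$origin[3]))
  invisible(x)
}
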