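#' Radiological (water-equivalent) depth along a fan line
#'
#' Line integral of relative electron density along the diverging ray from
#' the phantom surface to `point_z`, including the obliquity of the ray, plus
#' the water-equivalent thickness of an optional bolus on that ray
#' (`thickness * bolus density`).
#'
#' @param grid A `density_grid`.
#' @param ray Isocenter-plane coordinates `c(x, y)` of the fan line, cm.
#' @param point_z Beam-axis coordinate of the endpoint, cm.
#' @param bolus Optional `bolus_surface`.
#' @return Water-equivalent depth in cm; 0 if the ray misses the grid.
#' @export
effective_depth <- function(grid, ray, point_z, bolus = NULL) {
  stopifnot(inherits(grid, "density_grid"), length(ray) == 2L)
  z0 <- grid$origin[3]
  if (point_z <= z0) return(0)
  dz <- grid$spacing[3] / 2
  z <- seq(z0 + dz / 2, point_z, by = dz)
  iso <- 100
  xs <- ray[1] * z / iso
  ys <- ray[2] * z / iso
  rho <- sample_grid_trilinear(grid$values, grid$origin, grid$spacing,
                               xs, ys, z)
  obliq <- sqrt(1 + (ray[1]^2 + ray[2]^2) / iso^2)
  wet <- sum(rho) * dz * obliq
  if (!is.null(bolus))
    wet <- wet + bolus_wet_at(bolus, ray[1], ray[2])
  wet
}

# trilinear sampling of a 3D array at physical points (vectors);
# points outside the grid return 0
sample_grid_trilinear <- function(values, origin, spacing, xs, ys, zs) {
  d <- dim(values)
  fi <- (xs - origin[1]) / spacing[1] - 0.5
  fj <- (ys - origin[2]) / spacing[2] - 0.5
  fk <- (zs - origin[3]) / spacing[3] - 0.5
  out <- numeric(length(fi))
  inside <- fi > -0.5 & fi < d[1] - 0.5 & fj > -0.5 & fj < d[2] - 0.5 &
    fk > -0.5 & fk < d[3] - 0.5
  if (!any(inside)) return(out)
  cl <- function(f, n) pmin(pmax(f, 0), n - 1 - 1e-9)
  fi <- cl(fi[inside], d[1]); fj <- cl(fj[inside], d[2]); fk <- cl(fk[inside], d[3])
  i0 <- floor(fi); j0 <- floor(fj); k0 <- floor(fk)
  tx <- fi - i0; ty <- fj - j0; tz <- fk - k0
  i0 <- as.integer(i0) + 1L; j0 <- as.integer(j0) + 1L; k0 <- as.integer(k0) + 1L
  i1 <- pmin(i0 + 1L, d[1]); j1 <- pmin(j0 + 1L, d[2]); k1 <- pmin(k0 + 1L, d[3])
  v <- values[cbind(i0, j0, k0)] * (1 - tx) * (1 - ty) * (1 - tz) +
    values[cbind(i1, j0, k0)] * tx * (1 - ty) * (1 - tz) +
    values[cbind(i0, j1, k0)] * (1 - tx) * ty * (1 - tz) +
    values[cbind(i0, j0, k1)] * (1 - tx) * (1 - ty) * tz +
    values[cbind(i1, j1, k0)] * tx * ty * (1 - tz) +
    values[cbind(i1, j0, k1)] * tx * (1 - ty) * tz +
    values[cbind(i0, j1, k1)] * (1 - tx) * ty * tz +
    values[cbind(i1, j1, k1)] * tx * ty * tz
  out[inside] <- v
  out
}

# row-stochastic Gaussian smoothing matrix on a 1D uniform grid;
# identity when sigma is negligible relative to the grid step
gauss_smooth_matrix <- function(pos, sigma) {
  n <- length(pos)
  if (sigma < 0.1 * (pos[2] - pos[1])) return(diag(n))
  K <- stats::dnorm(outer(pos, pos, "-"), sd = sigma)
  K / rowSums(K)
}

# Raw (unnormalized) central-axis dose in water versus depth for a given
# aperture at a given SSD -- the "given dose" machinery. Uses the identical
# fluence + smoothing path as compute_dose so discretization cancels in the
# normalization.
central_axis_raw <- function(beam, aperture, ssd, depths,
                             fan_spacing = 0.2) {
  fan <- make_fan_grid(aperture, spacing = fan_spacing)
  phi <- transport_fluence(fan, aperture, NULL, beam, ssd)$values
  iso <- 100
  ic <- which.min(abs(fan$x)); jc <- which.min(abs(fan$y))
  vapply(depths, function(d) {
    z <- ssd + d
    xs <- fan$x * z / iso; ys <- fan$y * z / iso
    sk <- sigma_kernel(beam, d, ssd)
    Kx <- gauss_smooth_matrix(xs, sk)
    Ky <- gauss_smooth_matrix(ys, sk)
    A <- phi * pdd(beam, d) * ((iso + d) / z)^2
    as.numeric(Kx[ic, , drop = FALSE] %*% A %*% Ky[jc, ])
  }, numeric(1))
}

.given_cache <- new.env(parent = emptyenv())

#' Given dose (normalization point) for an aperture
#'
#' The given dose is the maximum central-axis dose in water for the effective
#' field -- the minimum-area rectangle circumscribing the patient aperture --
#' at the treatment SSD, without the intensity modulator. All dose outputs of
#' the engine are in percent of this value. Output-factor variation with
#' field size is not modelled.
#'
#' @param beam A [make_beam()] object (the unmodulated beam).
#' @param aperture An `aperture`.
#' @param ssd Source-to-surface distance, cm.
#' @param fan_spacing Fan-line spacing used internally, cm.
#' @return The raw engine value corresponding to 100%.
#' @export
given_dose_raw <- function(beam, aperture, ssd, fan_spacing = 0.2) {
  v <- aperture$vertices
  bbox <- rectangular_aperture(diff(range(v[, 1])), diff(range(v[, 2])),
                               collimator_z = aperture$collimator_z)
  key <- paste(beam$R90, beam$nominal_energy, beam$sigma_theta0,
               beam$xray_tail, beam$surface_dose, beam$modulator_corrected,
               diff(range(v[, 1])), diff(range(v[, 2])), ssd, fan_spacing,
               sep = "|")
  hit <- .given_cache[[key]]
  if (!is.null(hit)) return(hit)
  depths <- seq(max(beam$R100 - 1, 0.2), beam$R100 + 1, by = 0.05)
  val <- max(central_axis_raw(beam, bbox, ssd, depths, fan_spacing))
  assign(key, val, envir = .given_cache)
  val
}

#' Compute a 3D dose distribution
#'
#' Single-pass Fermi-Eyges pencil-beam dose computation of Eq-(3) form:
#' the electron component is the per-slice Gaussian lateral spreading of
#' `w_ij * phi_ij * De(effective depth)` over the diverging fan-line lattice,
#' and the background x-ray component is the spreading of the open-field
#' fluence times a linearly ramped bremsstrahlung tail (island blocks do not
#' perturb the bremsstrahlung; the per-line modulation weights scale both
#' components, keeping dose exactly linear in the weights). Inverse-square
#' divergence is applied about the virtual source. Output is normalized so
#' that the open effective field in water at the same SSD has a central-axis
#' maximum of 100% (the given dose).
#'
#' The per-line modulation weights come from `fan$weights` (all 1 for an
#' unmodulated beam); aperture collimation and island-block shadows enter
#' through the transported surface fluence ([transport_fluence()], the
#' negative-fluence block model applied in the first transport step only).
#' When `blocks` is non-NULL the beam receives the modulator corrections
#' internally; the given-dose normalization always uses the uncorrected beam.
#'
#' @param grid A `density_grid` (dose is returned on the same voxel grid).
#' @param beam A [make_beam()] object (base beam, without modulator
#'   corrections).
#' @param aperture An `aperture`.
#' @param fan A `fan_grid` or NULL (default grid built from the aperture).
#' @param bolus Optional `bolus_surface` (adds water-equivalent depth per fan
#'   line; the bolus is treated as an upstream range shifter).
#' @param blocks Optional `island_pattern`.
#' @return A `dose3d`: list with `values` (3D array, percent of given dose),
#'   `origin`, `spacing`, `ssd`, `given_raw`, and `fan` (the fan grid used).
#' @export
compute_dose <- function(grid, beam, aperture, fan = NULL, bolus = NULL,
                         blocks = NULL) {
  stopifnot(inherits(grid, "density_grid"), inherits(beam, "beam_model"),
            inherits(aperture, "aperture"))
  if (is.null(fan)) fan <- make_fan_grid(aperture)
  ssd <- grid$origin[3]
  given <- given_dose_raw(beam, aperture, ssd, fan$spacing)

  tbeam <- if (!is.null(blocks) && !beam$modulator_corrected)
    apply_modulator_corrections(beam) else beam
  phi <- transport_fluence(fan, aperture, blocks, tbeam, ssd)$values
  phi_open <- if (is.null(blocks)) phi else
    transport_fluence(fan, aperture, NULL, tbeam, ssd)$values
  if (max(phi) < 1e-9) {
    warning("aperture transmits no fluence; returning zero dose")
    return(structure(list(values = array(0, dim(grid$values)),
                          origin = grid$origin, spacing = grid$spacing,
                          ssd = ssd, given_raw = given, fan = fan),
                     class = "dose3d"))
  }
  w <- fan$weights
  iso <- 100
  nx <- length(fan$x); ny <- length(fan$y)
  zc <- grid_axis(grid, 3)
  dzv <- grid$spacing[3]
  obliq <- sqrt(1 + outer(fan$x^2, fan$y^2, "+") / iso^2)
  bwet <- if (is.null(bolus)) matrix(0, nx, ny) else
    outer(seq_len(nx), seq_len(ny),
          function(i, j) bolus_wet_at(bolus, fan$x[i], fan$y[j]))

  gx <- grid_axis(grid, 1); gy <- grid_axis(grid, 2)
  out <- array(0, dim = dim(grid$values))
  deff <- bwet
  rho_prev <- NULL
  for (k in seq_along(zc)) {
    z <- zc[k]
    xs <- fan$x * z / iso; ys <- fan$y * z / iso
    pts <- expand.grid(x = xs, y = ys)
    rho <- matrix(sample_grid_trilinear(grid$values, grid$origin,
                                        grid$spacing, pts$x, pts$y,
                                        rep(z, nrow(pts))), nx, ny)
    if (is.null(rho_prev)) {
      deff <- deff + rho * (dzv / 2) * obliq
    } else {
      deff <- deff + (rho + rho_prev) / 2 * dzv * obliq
    }
    rho_prev <- rho
    depth <- z - ssd
    A <- w * (phi * matrix(de_component(tbeam, deff), nx, ny) +
                phi_open * matrix(dx_component(tbeam, deff), nx, ny))
    A <- A * ((iso + deff) / z)^2
    sk <- sigma_kernel(tbeam, depth, ssd)
    Kx <- gauss_smooth_matrix(xs, sk)
    Ky <- gauss_smooth_matrix(ys, sk)
    dfan <- Kx %*% A %*% t(Ky)
    out[, , k] <- bilinear_sample(xs, ys, dfan, gx, gy, outer_grid = TRUE)
  }
  structure(list(values = out * (100 / given), origin = grid$origin,
                 spacing = grid$spacing, ssd = ssd, given_raw = given,
                 fan = fan), class = "dose3d")
}

#' Planar dose in water at a stated depth
#'
#' Percent-of-given-dose distribution in a transverse plane at `depth` in a
#' water phantom at `ssd`, with an optional island-block intensity modulator
#' -- the calculated side of the clinical QA comparison. 100% equals the
#' given dose of the open effective field without the modulator.
#'
#' @param beam A [make_beam()] object (base beam; modulator corrections are
#'   applied internally when `blocks` is present).
#' @param aperture An `aperture`.
#' @param blocks Optional `island_pattern`.
#' @param depth Measurement depth in water, cm (>= 0).
#' @param ssd Source-to-surface distance, cm.
#' @param pixel Output pixel size, cm (0.1 for clinical QA).
#' @param fan_spacing Internal fan-line spacing, cm.
#' @param margin Lateral margin beyond the aperture, cm.
#' @return A `planar_dose`: list with `values` (matrix), `x`, `y`
#'   (plane coordinates, cm), `pixel`, `depth`, `ssd`.
#' @export
planar_dose <- function(beam, aperture, blocks = NULL, depth, ssd = 100,
                        pixel = 0.1, fan_spacing = 0.1, margin = 3) {
  stopifnot(depth >= 0)
  fan <- make_fan_grid(aperture, spacing = fan_spacing, margin = margin + 1)
  given <- given_dose_raw(beam, aperture, ssd, fan_spacing)
  tbeam <- if (!is.null(blocks) && !beam$modulator_corrected)
    apply_modulator_corrections(beam) else beam
  z <- ssd + depth
  phi <- transport_fluence(fan, aperture, blocks, tbeam, ssd)$values
  phi_open <- if (is.null(blocks)) phi else
    transport_fluence(fan, aperture, NULL, tbeam, ssd)$values
  iso <- 100
  obliq <- sqrt(1 + outer(fan$x^2, fan$y^2, "+") / iso^2)
  deff <- depth * obliq
  A <- fan$weights * (phi * matrix(de_component(tbeam, deff),
                                   length(fan$x), length(fan$y)) +
                      phi_open * matrix(dx_component(tbeam, deff),
                                        length(fan$x), length(fan$y)))
  A <- A * ((iso + deff) / z)^2
  xs <- fan$x * z / iso; ys <- fan$y * z / iso
  sk <- sigma_kernel(tbeam, depth, ssd)
  dfan <- gauss_smooth_matrix(xs, sk) %*% A %*%
    t(gauss_smooth_matrix(ys, sk))
  v <- aperture$vertices * (z / iso)
  px <- seq(min(v[, 1]) - margin, max(v[, 1]) + margin, by = pixel)
  py <- seq(min(v[, 2]) - margin, max(v[, 2]) + margin, by = pixel)
  vals <- bilinear_sample(xs, ys, dfan, px, py, outer_grid = TRUE)
  new_planar_dose(vals * (100 / given), px, py, pixel, depth, ssd)
}

new_planar_dose <- function(values, x, y, pixel, depth, ssd) {
  stopifnot(all(is.finite(values)), pixel > 0)
  values[values < 0] <- 0
  structure(list(values = values, x = x, y = y, pixel = pixel,
                 depth = depth, ssd = ssd), class = "planar_dose")
}

#' @export
print.dose3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose3d> %d x %d x %d voxels; max %.1f%% of given dose\n",
              d[1], d[2], d[3], max(x$values)))
  invisible(x)
}

#' @export
print.planar_dose <- function(x, ...) {
  cat(sprintf(
    "<planar_dose> %d x %d px (%.2g cm), depth %.1f cm, SSD %.0f cm, max %.1f%%\n",
    nrow(x$values), ncol(x$values), x$pixel, x$depth, x$ssd, max(x$values)))
  invisible(x)
}
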