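#' Bolus surface
#'
#' A variable-thickness range-compensating bolus described per fan line:
#' physical thickness `t` (cm) on the fan-line lattice, with a relative
#' electron density (default 0.92, machinable wax) used to convert thickness
#' to water-equivalent depth. The bolus is modelled as an upstream range
#' shifter: it adds `t * density` of water-equivalent depth to every ray, and
#' the dose engine does not displace the phantom surface geometrically.
#'
#' @param t Thickness matrix (cm) over the fan grid.
#' @param fan The `fan_grid` the thickness is defined on.
#' @param density Bolus relative electron density.
#' @param footprint Logical matrix of fan lines carrying bolus (default all).
#' @return A `bolus_surface`.
#' @export
bolus_surface <- function(t, fan, density = 0.92, footprint = NULL) {
  stopifnot(inherits(fan, "fan_grid"),
            nrow(t) == length(fan$x), ncol(t) == length(fan$y),
            all(is.finite(t)), all(t >= 0), density > 0)
  if (is.null(footprint))
    footprint <- matrix(TRUE, nrow(t), ncol(t))
  structure(list(t = t, x = fan$x, y = fan$y, density = density,
                 footprint = footprint), class = "bolus_surface")
}

# water-equivalent bolus thickness at isocenter-plane points (vectorized)
bolus_wet_at <- function(bolus, x, y) {
  n <- max(length(x), length(y))
  bilinear_sample(bolus$x, bolus$y, bolus$t,
                  rep_len(x, n), rep_len(y, n)) * bolus$density
}

#' Bolus mass surrogate
#'
#' Thickness integral `sum(t) * cell area` over the fan grid, cm^3 (times the
#' physical density gives grams).
#' @param bolus A `bolus_surface`.
#' @return Volume in cm^3.
#' @export
bolus_volume <- function(bolus) {
  dx <- bolus$x[2] - bolus$x[1]
  sum(bolus$t) * dx^2
}

# --- ray geometry helpers -------------------------------------------------

# sample a 3D field trilinearly along the fan ray (x_iso, y_iso) at axial
# coordinates z (vector)
ray_sample <- function(values, origin, spacing, x_iso, y_iso, z) {
  sample_grid_trilinear(values, origin, spacing,
                        x_iso * z / 100, y_iso * z / 100, z)
}

# per-fan-line PTV intersection: list of logical `hits`, and matrices of the
# proximal and distal PTV z (beam-axis cm; NA where the ray misses)
ray_ptv_extent <- function(grid, ptv, fan) {
  zf <- seq(grid$origin[3] + grid$spacing[3] / 4,
            grid$origin[3] + dim(grid$values)[3] * grid$spacing[3],
            by = grid$spacing[3] / 2)
  nx <- length(fan$x); ny <- length(fan$y)
  prox <- dist <- matrix(NA_real_, nx, ny)
  pm <- ptv * 1
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      v <- ray_sample(pm, grid$origin, grid$spacing, fan$x[i], fan$y[j], zf)
      k <- which(v > 0.5)
      if (length(k)) { prox[i, j] <- zf[k[1]]; dist[i, j] <- zf[k[length(k)]] }
    }
  }
  list(hits = !is.na(prox), proximal_z = prox, distal_z = dist)
}

# erode a fan-grid mask laterally by `margin` cm (disk structuring element)
erode_mask <- function(mask, spacing, margin) {
  if (margin <= 0) return(mask)
  rad <- floor(margin / spacing)
  offs <- expand.grid(di = -rad:rad, dj = -rad:rad)
  offs <- offs[sqrt(offs$di^2 + offs$dj^2) * spacing <= margin, ]
  n1 <- nrow(mask); n2 <- ncol(mask)
  out <- mask
  comp <- !mask
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    i <- seq_len(n1); j <- seq_len(n2)
    si <- i + di; sj <- j + dj
    oki <- si >= 1 & si <= n1; okj <- sj >= 1 & sj <= n2
    shifted <- matrix(TRUE, n1, n2)  # outside the grid counts as background
    shifted[i[oki], j[okj]] <- comp[si[oki], sj[okj]]
    out <- out & !shifted
  }
  out
}

# deepest downward crossing of `level` (%) along each fan ray of a dose3d;
# returns beam-axis z (NA where the dose never reaches the level)
ray_level_depth <- function(dose, fan, level = 90) {
  zf <- seq(dose$origin[3] + dose$spacing[3] / 4,
            dose$origin[3] + dim(dose$values)[3] * dose$spacing[3] -
              dose$spacing[3] / 4,
            by = dose$spacing[3] / 2)
  nx <- length(fan$x); ny <- length(fan$y)
  out <- matrix(NA_real_, nx, ny)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      v <- ray_sample(dose$values, dose$origin, dose$spacing,
                      fan$x[i], fan$y[j], zf)
      above <- which(v >= level)
      if (!length(above)) next
      k <- above[length(above)]
      if (k == length(zf)) { out[i, j] <- zf[k]; next }
      # linear interpolation of the crossing below the last point >= level
      out[i, j] <- zf[k] + (v[k] - level) / (v[k] - v[k + 1]) *
        (zf[k + 1] - zf[k])
    }
  }
  out
}

# --- operators ------------------------------------------------------------

#' Create a conformal bolus from the distal PTV surface
#'
#' For each fan line passing through the PTV eroded laterally by
#' `inner_margin` (isocenter-plane projection), the thickness is the range
#' deficit converted to bolus material:
#' `t = (R_percent - WET(distal PTV)) / density`, floored at zero, where
#' `R_percent` is the depth of the conformed percent dose in water and
#' `WET(distal PTV)` the water-equivalent depth of the distal PTV surface
#' along the ray. Fan lines outside the eroded PTV receive the nearest
#' eligible value ([op_height_extension()]).
#'
#' @param ptv Logical PTV array congruent with `grid`.
#' @param grid A `density_grid`.
#' @param beam A [make_beam()] object.
#' @param fan A `fan_grid`.
#' @param percent Percent dose conformed to the distal PTV (default 90).
#' @param inner_margin Lateral erosion inside the PTV edge, cm (default 0.7).
#' @param density Bolus relative electron density.
#' @return A `bolus_surface` with attribute `eligible` (the eroded mask).
#' @export
op_create <- function(ptv, grid, beam, fan, percent = 90,
                      inner_margin = 0.7, density = 0.92) {
  if (!any(ptv)) stop("PTV is empty", call. = FALSE)
  ext <- ray_ptv_extent(grid, ptv, fan)
  eligible <- erode_mask(ext$hits, fan$spacing, inner_margin)
  if (!any(eligible))
    stop("no fan lines remain after PTV erosion; margin too large",
         call. = FALSE)
  rdepth <- depth_of_percent(beam, percent)
  t <- matrix(0, length(fan$x), length(fan$y))
  for (idx in which(eligible)) {
    ij <- arrayInd(idx, dim(eligible))
    wet <- effective_depth(grid, c(fan$x[ij[1]], fan$y[ij[2]]),
                           ext$distal_z[idx])
    t[idx] <- max((rdepth - wet) / density, 0)
  }
  b <- bolus_surface(t, fan, density)
  b <- op_height_extension(b, eligible)
  attr(b, "eligible") <- eligible
  b
}

#' Shift bolus thickness so the therapeutic isodose meets the distal PTV
#'
#' One correction pass: for each fan line passing through the PTV eroded by
#' `inner_margin`, the thickness changes by the distance between the deepest
#' `percent`% crossing of the supplied dose (computed with the current bolus)
#' and the distal PTV surface, converted to bolus material:
#' `t += (z_level - z_distalPTV) / density`. Lines on which the dose never
#' reaches the level are left unchanged and counted (attribute
#' `n_no_crossing`). Ineligible lines are re-extended from the nearest
#' eligible line.
#'
#' @param bolus Current `bolus_surface`.
#' @param dose `dose3d` computed with `bolus` in place.
#' @param ptv,grid,fan As in [op_create()].
#' @param inner_margin Lateral erosion, cm (default 0.5).
#' @param percent Conformed percent dose (default 90).
#' @return Updated `bolus_surface`.
#' @export
op_isodose_shift <- function(bolus, dose, ptv, grid, fan,
                             inner_margin = 0.5, percent = 90) {
  ext <- ray_ptv_extent(grid, ptv, fan)
  eligible <- erode_mask(ext$hits, fan$spacing, inner_margin)
  zlev <- ray_level_depth(dose, fan, percent)
  t <- bolus$t
  no_cross <- 0L
  for (idx in which(eligible)) {
    if (is.na(zlev[idx])) { no_cross <- no_cross + 1L; next }
    t[idx] <- max(t[idx] + (zlev[idx] - ext$distal_z[idx]) / bolus$density, 0)
  }
  b <- bolus_surface(t, list_fan(bolus), bolus$density, bolus$footprint)
  b <- op_height_extension(b, eligible)
  attr(b, "eligible") <- eligible
  attr(b, "n_no_crossing") <- no_cross
  b
}

# reconstruct a minimal fan_grid view from a bolus (same lattice)
list_fan <- function(bolus) {
  structure(list(x = bolus$x, y = bolus$y, spacing = bolus$x[2] - bolus$x[1],
                 weights = matrix(1, length(bolus$x), length(bolus$y))),
            class = "fan_grid")
}

#' Smooth the bolus thickness map
#'
#' Convolution with a normalized radial Gaussian kernel
#' `exp(-exp_mult * (rho / R)^2)` truncated at `rho = R`, where
#' `R = radius_mult * 1.5` cm. The kernel is renormalized over the footprint
#' so edges are not drained; the footprint itself never changes.
#'
#' @param bolus A `bolus_surface`.
#' @param exp_mult Multiplier in the Gaussian exponent (default 2).
#' @param radius_mult Multiplier of the 1.5 cm smoothing radius (default 1).
#' @return Smoothed `bolus_surface`.
#' @export
op_smooth <- function(bolus, exp_mult = 2, radius_mult = 1) {
  R <- radius_mult * 1.5
  sp <- bolus$x[2] - bolus$x[1]
  rad <- floor(R / sp)
  offs <- expand.grid(di = -rad:rad, dj = -rad:rad)
  rho <- sqrt(offs$di^2 + offs$dj^2) * sp
  keep <- rho <= R
  offs <- offs[keep, ]; wk <- exp(-exp_mult * (rho[keep] / R)^2)
  n1 <- nrow(bolus$t); n2 <- ncol(bolus$t)
  num <- matrix(0, n1, n2); den <- matrix(0, n1, n2)
  fp <- bolus$footprint * 1
  tf <- bolus$t * fp
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    ti <- max(1, 1 - di):min(n1, n1 - di)
    tj <- max(1, 1 - dj):min(n2, n2 - dj)
    num[ti, tj] <- num[ti, tj] + wk[k] * tf[ti + di, tj + dj]
    den[ti, tj] <- den[ti, tj] + wk[k] * fp[ti + di, tj + dj]
  }
  t <- bolus$t
  ok <- bolus$footprint & den > 0
  t[ok] <- num[ok] / den[ok]
  bolus_surface(t, list_fan(bolus), bolus$density, bolus$footprint)
}

#' Shift the entire proximal bolus surface by a fixed thickness
#'
#' `t = max(t + delta, 0)` on the footprint; negative `delta` shaves the
#' bolus uniformly (e.g. -0.1 cm as a coverage margin).
#'
#' @param bolus A `bolus_surface`.
#' @param delta Thickness change, cm (may be negative).
#' @return Updated `bolus_surface`.
#' @export
op_specified_shift <- function(bolus, delta) {
  t <- bolus$t
  t[bolus$footprint] <- pmax(t[bolus$footprint] + delta, 0)
  bolus_surface(t, list_fan(bolus), bolus$density, bolus$footprint)
}

#' Truncate bolus outside the treatment field
#'
#' Sets the thickness of fan lines outside the projected aperture plus
#' `margin` to zero, reducing bolus mass. Because those rays carry essentially
#' no fluence, the dose inside the field is unchanged (within 0.5%).
#'
#' @param bolus A `bolus_surface`.
#' @param aperture An `aperture`.
#' @param margin Lateral margin kept beyond the aperture edge, cm.
#' @return Updated `bolus_surface`.
#' @export
op_truncate <- function(bolus, aperture, margin = 0.5) {
  g <- expand.grid(x = bolus$x, y = bolus$y)
  inside <- point_in_polygon(g$x, g$y, aperture$vertices) |
    polygon_edge_distance(g$x, g$y, aperture$vertices) <= margin
  t <- bolus$t
  t[!inside] <- 0
  bolus_surface(t, list_fan(bolus), bolus$density, bolus$footprint)
}

# distance from points to the boundary of a polygon
polygon_edge_distance <- function(px, py, poly) {
  n <- nrow(poly)
  dmin <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    tt <- pmin(pmax(((px - ax) * vx + (py - ay) * vy) / (vx^2 + vy^2), 0), 1)
    d <- sqrt((px - (ax + tt * vx))^2 + (py - (ay + tt * vy))^2)
    dmin <- pmin(dmin, d)
    j <- i
  }
  dmin
}

#' Extend bolus height to ineligible fan lines
#'
#' Each fan line outside `eligible` receives the thickness of the nearest
#' eligible fan line (Euclidean distance in the isocenter plane; exact ties
#' broken toward the lower linear index).
#'
#' @param bolus A `bolus_surface`.
#' @param eligible Logical matrix over the fan grid.
#' @return Updated `bolus_surface`.
#' @export
op_height_extension <- function(bolus, eligible) {
  stopifnot(all(dim(eligible) == dim(bolus$t)))
  if (all(eligible)) return(bolus)
  if (!any(eligible)) stop("no eligible fan lines", call. = FALSE)
  t <- bolus$t
  t[!eligible] <- nearest_fill(bolus$t, eligible, bolus$x, bolus$y)
  bolus_surface(t, list_fan(bolus), bolus$density, bolus$footprint)
}

# values of nearest TRUE cell for every FALSE cell (ties -> lower linear index)
nearest_fill <- function(vals, eligible, x, y) {
  src <- which(eligible)            # ascending linear index
  sij <- arrayInd(src, dim(eligible))
  sx <- x[sij[, 1]]; sy <- y[sij[, 2]]
  tgt <- which(!eligible)
  tij <- arrayInd(tgt, dim(eligible))
  tx <- x[tij[, 1]]; ty <- y[tij[, 2]]
  out <- numeric(length(tgt))
  for (m in seq_along(tgt)) {
    d2 <- (sx - tx[m])^2 + (sy - ty[m])^2
    out[m] <- vals[src[which.min(d2)]]  # which.min takes the first minimum
  }
  out
}

#' @export
print.bolus_surface <- function(x, ...) {
  cat(sprintf(
    "<bolus_surface> %d x %d fan lines; t in [%.2f, %.2f] cm; density %.2f\n",
    nrow(x$t), ncol(x$t), min(x$t), max(x$t), x$density))
  invisible(x)
}
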