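#' Tungsten island-block catalog
#'
#' The set of available tungsten pin diameters and the hexagonal lattice
#' spacing they are used with. The default catalog holds the eight
#' commercially available diameters for a 0.6 cm hexagonal spacing specified
#' at the 93.5 cm source-to-collimator plane.
#'
#' @param diameters Strictly increasing pin diameters, cm, all < `r`.
#' @param r Hexagonal lattice spacing (nearest-neighbor distance), cm.
#' @param plane_z Source-to-collimator distance at which the lattice is
#'   specified, cm.
#' @return A `pin_catalog`.
#' @export
pin_catalog <- function(diameters = c(0.158, 0.223, 0.273, 0.315,
                                      0.352, 0.386, 0.417, 0.473),
                        r = 0.6, plane_z = 93.5) {
  stopifnot(all(diff(diameters) > 0), all(diameters > 0),
            all(diameters < r), r > 0, plane_z > 0)
  structure(list(diameters = diameters, r = r, plane_z = plane_z),
            class = "pin_catalog")
}

#' Intensity reduction factor of a pin diameter on a hexagonal lattice
#'
#' The far-field IRF of a uniform array of circular island blocks of diameter
#' `d` on a hexagonal lattice of spacing `r` equals one minus the blocked
#' area fraction: `IRF = 1 - pi * d^2 / (2 * sqrt(3) * r^2)`.
#'
#' @param d Pin diameter(s), cm.
#' @param r Lattice spacing, cm.
#' @return IRF value(s) in (0, 1].
#' @export
irf_for_diameter <- function(d, r = 0.6) {
  stopifnot(all(d >= 0), r > 0)
  1 - pi * d^2 / (2 * sqrt(3) * r^2)
}

#' Pin diameter achieving a target IRF
#'
#' Closed-form inverse of [irf_for_diameter()]:
#' `d = r * sqrt(2 * sqrt(3) / pi * (1 - IRF))`. An IRF of 1 maps to 0 (no
#' pin).
#'
#' @param irf Target intensity reduction factor(s), in (0, 1].
#' @param r Lattice spacing, cm.
#' @return Continuous diameter(s), cm.
#' @export
diameter_for_irf <- function(irf, r = 0.6) {
  if (any(irf <= 0) || any(irf > 1))
    stop("'irf' must lie in (0, 1]", call. = FALSE)
  r * sqrt(2 * sqrt(3) / pi * (1 - irf))
}

#' Snap a continuous diameter to the catalog
#'
#' Returns the nearest available diameter, `NA` (no pin) when the continuous
#' diameter is closer to zero than to the smallest catalog diameter, and
#' breaks exact ties toward the smaller diameter.
#'
#' @param d Continuous diameter(s), cm (>= 0).
#' @param catalog A [pin_catalog()].
#' @return Catalog diameter(s) or `NA` for no pin.
#' @export
snap_to_catalog <- function(d, catalog = pin_catalog()) {
  stopifnot(all(d >= 0))
  cand <- c(0, catalog$diameters)
  idx <- vapply(d, function(di) {
    err <- abs(cand - di)
    which(err <= min(err) + 1e-12)[1]  # ties -> smaller diameter
  }, integer(1))
  out <- cand[idx]
  out[out == 0] <- NA_real_
  out
}

#' Hexagonal lattice sites covering an aperture
#'
#' Pointy-row hexagonal lattice in the collimator plane: rows parallel to x
#' with pitch `r * sqrt(3) / 2`, alternate rows offset by `r / 2`, origin on
#' the beam axis (the lattice contains the on-axis site). Sites are kept if
#' they fall inside the aperture projected to the lattice plane.
#'
#' @param aperture An `aperture`.
#' @param r Lattice spacing, cm.
#' @param plane_z Lattice plane distance from the source, cm.
#' @return A two-column matrix of (x, y) sites in the lattice plane, ordered
#'   row-major (by row, then by x within row).
#' @export
hex_lattice <- function(aperture, r = 0.6, plane_z = 93.5) {
  poly <- aperture_at(aperture, plane_z)
  ry <- r * sqrt(3) / 2
  jmax <- ceiling(max(abs(poly[, 2])) / ry) + 1L
  imax <- ceiling(max(abs(poly[, 1])) / r) + 1L
  sites <- NULL
  for (j in seq(-jmax, jmax)) {
    off <- if (j %% 2 == 0) 0 else r / 2
    x <- seq(-imax, imax) * r + off
    y <- rep(j * ry, length(x))
    keep <- point_in_polygon(x, y, poly)
    if (any(keep)) sites <- rbind(sites, cbind(x = x[keep], y = y[keep]))
  }
  sites
}

#' Island-block pattern
#'
#' @param x,y Pin centers in the lattice plane, cm.
#' @param diameter Pin diameters, cm (each a catalog diameter).
#' @param catalog The [pin_catalog()] the pattern draws from.
#' @return An `island_pattern`.
#' @export
island_pattern <- function(x, y, diameter, catalog = pin_catalog()) {
  stopifnot(length(x) == length(y), length(x) == length(diameter))
  if (length(diameter) &&
      !all(vapply(diameter, function(d)
        any(abs(catalog$diameters - d) < 1e-9), logical(1))))
    stop("all diameters must come from the catalog", call. = FALSE)
  if (anyDuplicated(paste(round(x, 6), round(y, 6))))
    stop("duplicate pin sites", call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 diameter = as.numeric(diameter),
                 plane_z = catalog$plane_z, r = catalog$r,
                 catalog = catalog), class = "island_pattern")
}

#' Segment an intensity map into an island-block pattern
#'
#' Initial segmentation step: the objective IRF is sampled at each hexagonal
#' lattice site (projected to the isocenter plane by similar triangles), the
#' continuous diameter is computed by [diameter_for_irf()], and snapped to
#' the catalog by [snap_to_catalog()]. Sites snapping to "no pin" are
#' omitted.
#'
#' @param intensity An `intensity_map` (see [build_intensity_map()]) or a
#'   function `f(x, y)` returning the objective IRF at isocenter-plane
#'   coordinates.
#' @param catalog A [pin_catalog()].
#' @param aperture An `aperture`.
#' @return An `island_pattern`; the full site list and per-site objective are
#'   attached as attributes `sites` and `objective` for use by [refine()].
#' @export
segment <- function(intensity, catalog = pin_catalog(), aperture) {
  sites <- hex_lattice(aperture, catalog$r, catalog$plane_z)
  iso_scale <- 100 / catalog$plane_z
  xi <- sites[, 1] * iso_scale
  yi <- sites[, 2] * iso_scale
  obj <- sample_intensity(intensity, xi, yi)
  obj <- pmin(pmax(obj, 1e-6), 1)
  d <- snap_to_catalog(diameter_for_irf(obj, catalog$r), catalog)
  keep <- !is.na(d)
  pat <- island_pattern(sites[keep, 1], sites[keep, 2], d[keep], catalog)
  attr(pat, "sites") <- sites
  attr(pat, "objective") <- obj
  pat
}

sample_intensity <- function(intensity, x, y) {
  if (is.function(intensity)) return(intensity(x, y))
  stopifnot(inherits(intensity, "intensity_map"))
  bilinear_sample(intensity$x, intensity$y, intensity$irf, x, y)
}

#' Iteratively refine an island-block pattern against its objective
#'
#' Compares the intensity achieved by the current pattern with the objective
#' at every lattice site and steps failing sites one catalog position in the
#' correcting direction (including adding or removing a pin). The achieved
#' intensity is the relative fluence at the clinical QA reference geometry --
#' the entrance plane of a water phantom at 100 cm SSD, whose 2 cm QA depth
#' the fluence pattern projects onto -- computed with [transport_fluence()]
#' and normalized by the open field. Within a sweep, sites are visited in
#' row-major order and the predicted achieved map is updated incrementally
#' with the analytic single-block kernel after each change, so neighboring
#' sites see the running correction (an error-diffusion style dithering that
#' lets a mixture of adjacent diameters approximate an objective between
#' catalog steps). Iteration stops when no site fails, when a sweep changes
#' nothing, when `max_iter` is reached, or when a pattern state repeats
#' (oscillation), in which case the best state so far (smallest maximum
#' absolute error) is returned.
#'
#' @param pattern An `island_pattern` from [segment()] (site list and
#'   objective attributes required).
#' @param objective Optional override of the per-site objective IRF vector.
#' @param catalog A [pin_catalog()].
#' @param aperture The `aperture` the pattern was segmented for.
#' @param beam A [make_beam()] object.
#' @param tolerance Allowed |achieved - objective| per site (default 0.03).
#' @param max_iter Maximum number of sweeps.
#' @param ssd Reference SSD, cm.
#' @return A refined `island_pattern`; attributes `iterations`, `achieved`
#'   and `sites` report the loop outcome.
#' @export
refine <- function(pattern, objective = NULL, catalog = pin_catalog(),
                   aperture, beam, tolerance = 0.03, max_iter = 20,
                   ssd = 100) {
  sites <- attr(pattern, "sites")
  if (is.null(sites))
    stop("'pattern' must carry the lattice site list from segment()",
         call. = FALSE)
  if (is.null(objective)) objective <- attr(pattern, "objective")
  stopifnot(length(objective) == nrow(sites))
  ord <- order(sites[, 2], sites[, 1])  # row-major, deterministic
  cand <- c(0, catalog$diameters)
  # current diameter index per site (1 = no pin)
  dcur <- rep(1L, nrow(sites))
  if (length(pattern$x)) {
    key <- paste(round(sites[, 1], 6), round(sites[, 2], 6))
    pkey <- paste(round(pattern$x, 6), round(pattern$y, 6))
    dcur[match(pkey, key)] <-
      vapply(pattern$diameter,
             function(d) which.min(abs(cand - d)), integer(1))
  }
  fan <- make_fan_grid(aperture, spacing = 0.1)
  tbeam <- if (beam$modulator_corrected) beam else
    apply_modulator_corrections(beam)
  sigma <- tbeam$sigma_theta0 * (ssd - aperture$collimator_z)
  scale <- ssd / catalog$plane_z
  phi_open <- transport_fluence(fan, aperture, NULL, tbeam, ssd)
  open_at <- bilinear_sample(phi_open$x * ssd / 100, phi_open$y * ssd / 100,
                             phi_open$values,
                             sites[, 1] * scale, sites[, 2] * scale)
  open_at[open_at < 1e-6] <- 1e-6

  achieved_at_sites <- function(didx) {
    pins <- didx > 1L
    pat <- island_pattern(sites[pins, 1], sites[pins, 2],
                          cand[didx[pins]], catalog)
    fl <- transport_fluence(fan, aperture, pat, tbeam, ssd)
    ach <- bilinear_sample(fl$x * ssd / 100, fl$y * ssd / 100, fl$values,
                           sites[, 1] * scale, sites[, 2] * scale)
    pmin(ach / open_at, 1.5)
  }
  # analytic deficit of one block (diameter d at site m) at all sites
  block_kernel <- function(m, d) {
    s <- d * sqrt(pi) / 2 * scale
    dx <- (sites[, 1] - sites[m, 1]) * scale
    dy <- (sites[, 2] - sites[m, 2]) * scale
    (stats::pnorm((dx + s / 2) / sigma) - stats::pnorm((dx - s / 2) / sigma)) *
      (stats::pnorm((dy + s / 2) / sigma) - stats::pnorm((dy - s / 2) / sigma))
  }

  seen <- character(0)
  best <- dcur; best_err <- Inf
  iters <- 0L
  ach <- achieved_at_sites(dcur)
  repeat {
    err <- ach - objective
    maxerr <- max(abs(err))
    if (maxerr < best_err) { best <- dcur; best_err <- maxerr }
    state <- paste(dcur, collapse = ",")
    if (maxerr <= tolerance || iters >= max_iter || state %in% seen) break
    seen <- c(seen, state)
    pred <- ach
    changed <- FALSE
    for (m in ord) {
      e <- pred[m] - objective[m]
      if (abs(e) <= tolerance) next
      step <- if (e > 0) 1L else -1L  # achieved too high -> bigger pin
      newidx <- dcur[m] + step
      if (newidx < 1L || newidx > length(cand)) next
      delta <- numeric(nrow(sites))
      if (dcur[m] > 1L) delta <- delta + block_kernel(m, cand[dcur[m]])
      if (newidx > 1L) delta <- delta - block_kernel(m, cand[newidx])
      pred <- pred + delta / open_at
      dcur[m] <- newidx
      changed <- TRUE
    }
    iters <- iters + 1L
    if (!changed) break
    ach <- achieved_at_sites(dcur)
  }
  err <- ach - objective
  if (max(abs(err)) < best_err) best <- dcur
  pins <- best > 1L
  out <- island_pattern(sites[pins, 1], sites[pins, 2], cand[best[pins]],
                        catalog)
  attr(out, "sites") <- sites
  attr(out, "objective") <- objective
  attr(out, "iterations") <- iters
  attr(out, "achieved") <- achieved_at_sites(best)
  out
}

#' @export
print.island_pattern <- function(x, ...) {
  cat(sprintf("<island_pattern> %d pins on a %.2g cm hex lattice at z = %.1f cm\n",
              length(x$x), x$r, x$plane_z))
  if (length(x$x)) {
    tb <- table(x$diameter)
    cat("  diameters:",
        paste(sprintf("%s cm x %d", names(tb), as.integer(tb)),
              collapse = ", "), "\n")
  }
  invisible(x)
}
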