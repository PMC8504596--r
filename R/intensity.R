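#' Maximum dose along each fan-line ray inside the PTV
#'
#' For each fan line whose ray passes through the PTV eroded laterally by
#' `margin` (isocenter-plane projection), returns the maximum percent dose
#' over trilinearly interpolated samples of the dose along the ray, restricted
#' to the PTV; the sampling step is half the dose-grid z spacing. Lines not
#' meeting the erosion criterion are marked ineligible (NA).
#'
#' @param dose A `dose3d`.
#' @param ptv Logical PTV array congruent with the dose grid.
#' @param grid The `density_grid` of the dose.
#' @param fan A `fan_grid`.
#' @param margin Lateral erosion inside the PTV edge, cm (default 0.5).
#' @return List with `dmax` (matrix, NA where ineligible) and `eligible`
#'   (logical matrix).
#' @export
ray_max_dose <- function(dose, ptv, grid, fan, margin = 0.5) {
  if (!any(ptv)) stop("PTV is empty", call. = FALSE)
  ext <- ray_ptv_extent(grid, ptv, fan)
  eligible <- erode_mask(ext$hits, fan$spacing, margin)
  if (!any(eligible))
    stop("margin larger than the PTV: no eligible fan lines", call. = FALSE)
  zf <- seq(dose$origin[3] + dose$spacing[3] / 4,
            dose$origin[3] + dim(dose$values)[3] * dose$spacing[3],
            by = dose$spacing[3] / 2)
  pm <- ptv * 1
  dmax <- matrix(NA_real_, length(fan$x), length(fan$y))
  for (idx in which(eligible)) {
    ij <- arrayInd(idx, dim(eligible))
    xi <- fan$x[ij[1]]; yj <- fan$y[ij[2]]
    inptv <- ray_sample(pm, grid$origin, grid$spacing, xi, yj, zf) > 0.5
    if (!any(inptv)) { eligible[idx] <- FALSE; next }
    dv <- ray_sample(dose$values, dose$origin, dose$spacing, xi, yj,
                     zf[inptv])
    dmax[idx] <- max(dv)
  }
  list(dmax = dmax, eligible = eligible)
}

#' Intensity reduction factor from a ray-line maximum dose
#'
#' The IRF operator: 1.000 for `dmax` below 100%, `100 / dmax` for `dmax`
#' between 100% and `100 / irf_min` % (125% at the default lower limit 0.8),
#' and `irf_min` beyond -- continuous at both joints and non-increasing.
#'
#' @param dmax Maximum percent dose along the ray (> 0); vectorized.
#' @param irf_min,irf_max User limits on the IRF (defaults 0.8 and 1.0).
#' @return IRF value(s) in `[irf_min, irf_max]`.
#' @export
irf_from_dmax <- function(dmax, irf_min = 0.8, irf_max = 1.0) {
  if (any(!is.finite(dmax)) || any(dmax <= 0))
    stop("'dmax' must be positive", call. = FALSE)
  stopifnot(irf_min > 0, irf_min <= irf_max, irf_max <= 1)
  pmin(pmax(100 / dmax, irf_min), irf_max)
}

#' Build an intensity map from a dose distribution
#'
#' Derives the objective per-fan-line intensity reduction factors from the
#' dose computed with the current bolus: eligible fan lines (rays within
#' `margin` inside the PTV edge) get `irf_from_dmax` of their ray maximum
#' dose; all other lines are filled from the nearest eligible line (the same
#' rule as bolus height extension); the whole map is clamped to
#' `[irf_min, irf_max]`.
#'
#' @inheritParams ray_max_dose
#' @param irf_min,irf_max IRF limits (study defaults 0.8 and 1.0).
#' @return An `intensity_map`: list with `irf` (matrix over the fan grid),
#'   `x`, `y`, `eligible`, `margin`.
#' @export
build_intensity_map <- function(dose, ptv, grid, fan, margin = 0.5,
                                irf_min = 0.8, irf_max = 1.0) {
  rm_ <- ray_max_dose(dose, ptv, grid, fan, margin)
  irf <- matrix(irf_max, length(fan$x), length(fan$y))
  irf[rm_$eligible] <- irf_from_dmax(rm_$dmax[rm_$eligible],
                                     irf_min, irf_max)
  irf[!rm_$eligible] <- nearest_fill(irf, rm_$eligible, fan$x, fan$y)
  irf <- pmin(pmax(irf, irf_min), irf_max)
  structure(list(irf = irf, x = fan$x, y = fan$y,
                 eligible = rm_$eligible, margin = margin,
                 dmax = rm_$dmax),
            class = "intensity_map")
}

#' @export
print.intensity_map <- function(x, ...) {
  cat(sprintf("<intensity_map> %d x %d fan lines; IRF in [%.3f, %.3f]\n",
              nrow(x$irf), ncol(x$irf), min(x$irf), max(x$irf)))
  invisible(x)
}
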