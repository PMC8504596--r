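#' Planar dose container
#'
#' Constructs a `planar_dose` from a plain matrix, for synthetic QA fixtures
#' and for data read from the ASCII planar format.
#'
#' @param values Percent-dose matrix (x along rows, y along columns).
#' @param pixel Pixel size, cm.
#' @param depth Measurement depth, cm.
#' @param ssd Source-to-surface distance, cm.
#' @param origin Coordinates of the first pixel center `c(x0, y0)`, cm; the
#'   default centers the grid on the beam axis.
#' @return A `planar_dose`.
#' @export
planar_dose_from_matrix <- function(values, pixel = 0.1, depth = 2,
                                    ssd = 100, origin = NULL) {
  if (is.null(origin))
    origin <- -c(nrow(values) - 1, ncol(values) - 1) / 2 * pixel
  x <- origin[1] + (seq_len(nrow(values)) - 1) * pixel
  y <- origin[2] + (seq_len(ncol(values)) - 1) * pixel
  new_planar_dose(values, x, y, pixel, depth, ssd)
}

# resample planar dose `p` onto the grid of `ref` (bilinear, clamped edges)
resample_planar <- function(p, ref) {
  if (identical(p$x, ref$x) && identical(p$y, ref$y)) return(p)
  vals <- bilinear_sample(p$x, p$y, p$values, ref$x, ref$y, outer_grid = TRUE)
  new_planar_dose(vals, ref$x, ref$y, ref$pixel, p$depth, p$ssd)
}

#' Shift a planar dose laterally
#'
#' Resamples the distribution at positions displaced by `(dx, dy)` cm
#' (bilinear, clamped at the edges); used to build QA fixtures with a known
#' spatial offset.
#'
#' @param p A `planar_dose`.
#' @param dx,dy Shift in cm.
#' @return A shifted `planar_dose` on the same grid.
#' @export
shift_planar <- function(p, dx = 0, dy = 0) {
  vals <- bilinear_sample(p$x, p$y, p$values, p$x - dx, p$y - dy,
                          outer_grid = TRUE)
  new_planar_dose(vals, p$x, p$y, p$pixel, p$depth, p$ssd)
}

#' Dose-difference map
#'
#' `measured - calculated`, in percent-of-given-dose points; the measured
#' distribution is bilinearly resampled onto the calculated grid if the grids
#' differ.
#'
#' @param calc,meas `planar_dose` objects (calculated is the reference grid).
#' @return Matrix of dose differences on the calculated grid.
#' @export
dose_difference <- function(calc, meas) {
  stopifnot(inherits(calc, "planar_dose"), inherits(meas, "planar_dose"))
  resample_planar(meas, calc)$values - calc$values
}

#' Distance-to-agreement map
#'
#' For each evaluated point, the distance to the closest location where the
#' calculated distribution has the same value as the measured dose at that
#' point. Iso-level locations are found at subpixel accuracy by linear
#' interpolation along grid segments whose endpoint values straddle the
#' level; measured values are grouped into `level_bin` percent bins so the
#' crossing set is shared within a bin. The search is capped at `cap` cm:
#' points with no equal-value location within the cap (e.g. a uniform offset
#' in a flat region) are recorded at `cap`.
#'
#' The comparison is directional -- calculated is the reference surface that
#' is searched, matching the clinical convention of evaluating measurement
#' against calculation; exchanging the arguments is equivalent only up to
#' interpolation.
#'
#' @param calc,meas `planar_dose` objects.
#' @param cap Search cap, cm (default 1).
#' @param mask Optional logical matrix of points to evaluate (default all).
#' @param level_bin Measured-value binning, percent points (default 0.25).
#' @return Matrix of DTA values in cm (NA outside `mask`).
#' @export
dta <- function(calc, meas, cap = 1.0, mask = NULL, level_bin = 0.25) {
  stopifnot(inherits(calc, "planar_dose"))
  mv <- resample_planar(meas, calc)$values
  cv <- calc$values
  if (is.null(mask)) mask <- matrix(TRUE, nrow(cv), ncol(cv))
  out <- matrix(NA_real_, nrow(cv), ncol(cv))
  pts <- which(mask)
  if (!length(pts)) return(out)
  lev <- round(mv[pts] / level_bin) * level_bin
  pij <- arrayInd(pts, dim(cv))
  px <- calc$x[pij[, 1]]; py <- calc$y[pij[, 2]]
  for (v in unique(lev)) {
    sel <- lev == v
    cr <- iso_crossings(cv, calc$x, calc$y, v)
    if (is.null(cr)) { out[pts[sel]] <- cap; next }
    for (m in which(sel)) {
      d2 <- (cr[, 1] - px[m])^2 + (cr[, 2] - py[m])^2
      out[pts[m]] <- min(sqrt(min(d2)), cap)
    }
  }
  out
}

# subpixel points where the field `cv` (on axes x, y) crosses level v:
# linear interpolation along horizontal and vertical grid segments
iso_crossings <- function(cv, x, y, v) {
  e <- cv - v
  out <- NULL
  # vertical segments (along x, within columns)
  s <- e[-nrow(e), ] * e[-1, ]
  hit <- which(s <= 0 & (e[-nrow(e), ] != e[-1, ]))
  if (length(hit)) {
    ij <- arrayInd(hit, dim(s))
    f <- e[cbind(ij[, 1], ij[, 2])] /
      (e[cbind(ij[, 1], ij[, 2])] - e[cbind(ij[, 1] + 1L, ij[, 2])])
    out <- rbind(out, cbind(x[ij[, 1]] + f * (x[ij[, 1] + 1L] - x[ij[, 1]]),
                            y[ij[, 2]]))
  }
  # horizontal segments (along y, within rows)
  s <- e[, -ncol(e)] * e[, -1]
  hit <- which(s <= 0 & (e[, -ncol(e)] != e[, -1]))
  if (length(hit)) {
    ij <- arrayInd(hit, dim(s))
    f <- e[cbind(ij[, 1], ij[, 2])] /
      (e[cbind(ij[, 1], ij[, 2])] - e[cbind(ij[, 1], ij[, 2] + 1L)])
    out <- rbind(out, cbind(x[ij[, 1]],
                            y[ij[, 2]] + f * (y[ij[, 2] + 1L] - y[ij[, 2]])))
  }
  # exact hits (flat region exactly at the level)
  ex <- which(e == 0)
  if (length(ex)) {
    ij <- arrayInd(ex, dim(e))
    out <- rbind(out, cbind(x[ij[, 1]], y[ij[, 2]]))
  }
  out
}

#' Composite dose-difference / DTA quality-assurance comparison
#'
#' Clinical QA criterion: a point passes if the absolute dose difference is
#' within `dose_tol` percent OR the distance to agreement is within
#' `dist_tol` cm. Points are evaluated where the calculated dose is at least
#' `threshold` (by default interpreted as percent of the calculated maximum;
#' set `threshold_mode = "given"` to threshold on percent of given dose
#' directly). The report includes a histogram of dose differences over the
#' evaluated points with the subset below 80% of the given dose flagged
#' separately.
#'
#' @param calc,meas `planar_dose` objects.
#' @param dose_tol Dose tolerance, percent points (default 3).
#' @param dist_tol Distance tolerance, cm (default 0.3).
#' @param threshold Inclusion threshold, percent (default 10).
#' @param threshold_mode `"max"` (percent of calculated maximum, default) or
#'   `"given"` (percent of given dose).
#' @param cap DTA search cap, cm.
#' @param hist_bin Histogram bin width, percent points.
#' @return A `qa_report`: list with `diff`, `dta`, `pass`, `mask`,
#'   `pass_rate` (percent), `histogram` (data.frame with `bin_lo`, `bin_hi`,
#'   `count`, `count_lt80`), and the parameters used.
#' @export
composite_pass <- function(calc, meas, dose_tol = 3, dist_tol = 0.3,
                           threshold = 10, threshold_mode = c("max", "given"),
                           cap = 1.0, hist_bin = 1) {
  threshold_mode <- match.arg(threshold_mode)
  thr <- if (threshold_mode == "max")
    threshold / 100 * max(calc$values) else threshold
  mask <- calc$values >= thr
  dd <- dose_difference(calc, meas)
  pass <- abs(dd) <= dose_tol
  # DTA is only needed where the dose criterion fails
  need <- mask & !pass
  dmap <- matrix(NA_real_, nrow(mask), ncol(mask))
  if (any(need)) dmap[need] <- dta(calc, meas, cap = cap, mask = need)[need]
  dmap[mask & pass] <- 0
  pass <- pass | (!is.na(dmap) & dmap <= dist_tol)
  pr <- 100 * sum(pass & mask) / sum(mask)
  dd_m <- dd[mask]
  lt80 <- calc$values[mask] < 80
  brk <- seq(floor(min(dd_m) / hist_bin) * hist_bin,
             ceiling(max(dd_m) / hist_bin) * hist_bin + hist_bin,
             by = hist_bin)
  nb <- length(brk) - 1L
  bin_of <- function(v) pmin(pmax(findInterval(v, brk,
                                               rightmost.closed = TRUE), 1L), nb)
  histo <- data.frame(bin_lo = brk[-length(brk)], bin_hi = brk[-1],
                      count = tabulate(bin_of(dd_m), nb),
                      count_lt80 = tabulate(bin_of(dd_m[lt80]), nb))
  structure(list(diff = dd, dta = dmap, pass = pass & mask, mask = mask,
                 pass_rate = pr, histogram = histo,
                 params = list(dose_tol = dose_tol, dist_tol = dist_tol,
                               threshold = threshold,
                               threshold_mode = threshold_mode, cap = cap)),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("<qa_report> %.1f%% of %d evaluated points pass %g%% / %g cm\n",
              x$pass_rate, sum(x$mask), x$params$dose_tol,
              x$params$dist_tol))
  invisible(x)
}

#' Cumulative dose-volume histogram
#'
#' Volume fraction (percent) of the masked structure receiving at least each
#' dose level.
#'
#' @param dose A `dose3d` (or a numeric array of percent dose).
#' @param mask Logical array selecting the structure's voxels.
#' @param bins Dose bin width, percent (default 0.1).
#' @return A `dvh`: data.frame with columns `dose` and `volume` (percent),
#'   monotone non-increasing with `volume[dose = 0] = 100`.
#' @export
dvh <- function(dose, mask, bins = 0.1) {
  vals <- if (inherits(dose, "dose3d")) dose$values else dose
  stopifnot(all(dim(vals) == dim(mask)), any(mask))
  d <- vals[mask]
  lev <- seq(0, max(d) + bins, by = bins)
  vol <- 100 * (1 - stats::ecdf(d)(lev - 1e-12))
  structure(data.frame(dose = lev, volume = vol), class = c("dvh", "data.frame"))
}

#' Dose at a cumulative-volume level
#'
#' `D_x`: the dose received by at least `x`% of the structure volume, by
#' linear interpolation of the cumulative DVH.
#'
#' @param dvh A [dvh()].
#' @param volume Volume level, percent.
#' @return Dose in percent.
#' @export
dvh_dose_at <- function(dvh, volume) {
  stopifnot(volume >= 0, volume <= 100)
  v <- dvh$volume; d <- dvh$dose
  if (volume >= v[1]) return(d[1])
  k <- which(v <= volume)[1]  # volume is non-increasing in dose
  if (is.na(k)) return(d[length(d)])
  if (k == 1L || v[k - 1L] == v[k]) return(d[k])
  d[k - 1L] + (v[k - 1L] - volume) / (v[k - 1L] - v[k]) * (d[k] - d[k - 1L])
}

#' Dose-span plan metric
#'
#' `metric_d_span(dvh, 90, 10)` returns `D10 - D90`, the dose span covering
#' the central 80% of the structure volume (smaller is more homogeneous).
#'
#' @param dvh A [dvh()].
#' @param hi,lo Volume levels, percent (defaults 90 and 10).
#' @return Dose span in percent points.
#' @export
metric_d_span <- function(dvh, hi = 90, lo = 10) {
  dvh_dose_at(dvh, lo) - dvh_dose_at(dvh, hi)
}

#' Volume receiving at least a dose level
#' @param dvh A [dvh()].
#' @param dose Dose level, percent (default 95).
#' @return Volume in percent.
#' @export
dvh_volume_at <- function(dvh, dose = 95) {
  stats::approx(dvh$dose, dvh$volume, xout = dose, rule = 2,
                ties = "ordered")$y
}

#' Scale one plan so its PTV V95 matches another
#'
#' Finds, by bisection, the scalar factor `f` such that the V95 of
#' `f * dose_b` over the PTV matches the V95 of `dose_a` within `tol`
#' percentage points, and returns the scaled dose. Used to put two plans on a
#' common coverage normalization before comparing DVH metrics.
#'
#' @param dose_a Reference `dose3d` (or array).
#' @param dose_b `dose3d` (or array) to be scaled.
#' @param ptv Logical structure mask.
#' @param tol V95 matching tolerance, percentage points.
#' @return List with `dose` (scaled values of `dose_b`, same class as input),
#'   `factor`, `v95`.
#' @export
normalize_match_v95 <- function(dose_a, dose_b, ptv, tol = 0.1) {
  va <- if (inherits(dose_a, "dose3d")) dose_a$values else dose_a
  vb <- if (inherits(dose_b, "dose3d")) dose_b$values else dose_b
  target <- 100 * mean(va[ptv] >= 95)
  v95_of <- function(f) 100 * mean(f * vb[ptv] >= 95)
  lo <- 0.25; hi <- 4
  if (v95_of(lo) > target || v95_of(hi) < target)
    stop("V95 matching factor outside [0.25, 4]", call. = FALSE)
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (v95_of(mid) < target) lo <- mid else hi <- mid
    if (abs(v95_of(mid) - target) <= tol && hi - lo < 1e-4) break
  }
  f <- hi  # smallest factor reaching the target coverage
  out <- dose_b
  if (inherits(dose_b, "dose3d")) out$values <- vb * f else out <- vb * f
  list(dose = out, factor = f, v95 = v95_of(f))
}
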