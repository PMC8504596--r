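#' Run a bolus design operator sequence
#'
#' Executes an ordered list of bolus/intensity operators, recomputing dose
#' whenever an operator needs it, and returns the final bolus, the intensity
#' map (if the sequence contains an intensity-modulation step) and the final
#' dose. This is the engine behind both the plain BECT sequence (create,
#' smooth, isodose shift iterations, truncate, specified shift) and the
#' IM-BECT sequence that adds the intensity-modulation step followed by bolus
#' reoptimization (isodose shift, smooth, specified shift with the modulated
#' weights in place).
#'
#' Each element of `sequence` is a list with an `op` name and its parameters:
#' \describe{
#'   \item{create}{`percent` (90), `margin` (0.7 cm)}
#'   \item{smooth}{`exp_mult` (2), `radius_mult` (1)}
#'   \item{isodose_shift}{`margin` (0.5 cm), `percent` (90)}
#'   \item{specified_shift}{`delta` (cm)}
#'   \item{truncate}{`margin` (0.5 cm)}
#'   \item{height_extension}{none (uses the last eligibility mask)}
#'   \item{intensity_modulation}{`margin` (0.5 cm), `irf_min` (0.8),
#'     `irf_max` (1.0)}
#' }
#'
#' @param grid A `density_grid`.
#' @param ptv Logical PTV array congruent with `grid`.
#' @param beam A [make_beam()] object.
#' @param aperture An `aperture`.
#' @param sequence Ordered list of operator specs (see Details); may be empty.
#' @param fan Optional `fan_grid` (default built from the aperture).
#' @param bolus Optional starting `bolus_surface` (for sequences without a
#'   create step).
#' @param density Bolus relative electron density.
#' @return A list with `bolus`, `intensity` (an `intensity_map` or NULL),
#'   `dose` (final `dose3d`), `fan` (with final weights), and `log` (one
#'   entry per executed operator).
#' @export
run_sequence <- function(grid, ptv, beam, aperture, sequence,
                         fan = NULL, bolus = NULL, density = 0.92) {
  if (is.null(fan)) fan <- make_fan_grid(aperture)
  intensity <- NULL
  log <- list()
  eligible_last <- NULL
  dose <- NULL
  need_dose <- function() compute_dose(grid, beam, aperture, fan, bolus)

  for (stepn in seq_along(sequence)) {
    spec <- sequence[[stepn]]
    op <- spec$op
    p <- function(name, default) if (is.null(spec[[name]])) default else spec[[name]]
    if (op == "create") {
      bolus <- op_create(ptv, grid, beam, fan, percent = p("percent", 90),
                         inner_margin = p("margin", 0.7), density = density)
      eligible_last <- attr(bolus, "eligible")
    } else if (op == "smooth") {
      bolus <- op_smooth(bolus, p("exp_mult", 2), p("radius_mult", 1))
    } else if (op == "isodose_shift") {
      dose <- need_dose()
      bolus <- op_isodose_shift(bolus, dose, ptv, grid, fan,
                                inner_margin = p("margin", 0.5),
                                percent = p("percent", 90))
      eligible_last <- attr(bolus, "eligible")
    } else if (op == "specified_shift") {
      bolus <- op_specified_shift(bolus, p("delta", -0.1))
    } else if (op == "truncate") {
      bolus <- op_truncate(bolus, aperture, p("margin", 0.5))
    } else if (op == "height_extension") {
      if (is.null(eligible_last))
        stop("height_extension needs a preceding create/isodose_shift step",
             call. = FALSE)
      bolus <- op_height_extension(bolus, eligible_last)
    } else if (op == "intensity_modulation") {
      dose <- need_dose()
      intensity <- build_intensity_map(dose, ptv, grid, fan,
                                       margin = p("margin", 0.5),
                                       irf_min = p("irf_min", 0.8),
                                       irf_max = p("irf_max", 1.0))
      fan$weights <- intensity$irf
    } else {
      stop("unknown operator: ", op, call. = FALSE)
    }
    log[[stepn]] <- list(step = stepn, op = op,
                         params = spec[setdiff(names(spec), "op")],
                         bolus_range = if (!is.null(bolus)) range(bolus$t))
  }
  dose <- if (is.null(bolus) && !length(sequence)) dose else need_dose()
  list(bolus = bolus, intensity = intensity, dose = dose, fan = fan,
       log = log)
}

#' Conformality of the therapeutic isodose to the distal PTV
#'
#' For every eligible fan line (ray inside the PTV eroded by `margin`),
#' compares the deepest `level`% dose crossing with the distal PTV surface
#' and reports the fraction within `tol` cm.
#'
#' @param dose A `dose3d`.
#' @param ptv,grid,fan As in [op_create()].
#' @param margin Lateral erosion, cm.
#' @param level Percent dose level (default 90).
#' @param tol Agreement tolerance, cm (default 0.2).
#' @return List with `fraction_within` (percent), `errors` (matrix of
#'   `z_level - z_distal` in cm, NA where ineligible), `eligible`.
#' @export
conformality_stats <- function(dose, ptv, grid, fan, margin = 0.5,
                               level = 90, tol = 0.2) {
  ext <- ray_ptv_extent(grid, ptv, fan)
  eligible <- erode_mask(ext$hits, fan$spacing, margin)
  zlev <- ray_level_depth(dose, fan, level)
  err <- matrix(NA_real_, length(fan$x), length(fan$y))
  err[eligible] <- zlev[eligible] - ext$distal_z[eligible]
  ok <- !is.na(err[eligible]) & abs(err[eligible]) <= tol
  nocross <- is.na(zlev[eligible])
  list(fraction_within = 100 * sum(ok) / sum(eligible),
       n_no_crossing = sum(nocross), errors = err, eligible = eligible)
}
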