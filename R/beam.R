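#' Construct an analytic electron beam model
#'
#' Builds a `beam_model` describing a matched clinical electron beam by an
#' analytic central-axis percent depth-dose (PDD) family: a parabolic buildup
#' from the surface dose to 100% at `R100`, a sigmoid (logistic) falloff
#' passing exactly through (`R90`, 90%) down to the practical range `Rp`, and
#' a constant bremsstrahlung (x-ray) tail beyond `Rp`. The family is a
#' self-contained stand-in for commissioned accelerator data; only internal
#' consistency (the stated anchor points and monotonicity) is guaranteed.
#'
#' Fixed construction rules: `R100 = 0.6 * R90` and `Rp = 0.5 * energy` (cm,
#' energy in MeV), standard electron rules of thumb. The in-phantom scattering
#' power constant is calibrated at construction so that the lateral pencil
#' spread at depth `R90 / 2` in water equals `0.17 * R90` cm (0.85 cm for a
#' 16 MeV, R90 = 5 cm beam); see [sigma_kernel()].
#'
#' The default initial angular spread `sigma_theta0 = 0.035` rad is a
#' representative clinical value for a collimated electron beam (it sets the
#' in-air penumbra downstream of the 93.5 cm collimator plane); it is not
#' taken from commissioning data and should be set explicitly in the beam
#' config block when a different machine is being emulated.
#'
#' @param r90 Depth of the 90% dose, cm. Must be > 0.5.
#' @param energy Nominal beam energy, MeV.
#' @param sigma_theta0 Initial angular spread, radians.
#' @param xray_tail X-ray (bremsstrahlung) tail level, percent of given dose.
#'   Must lie in (0, 10).
#' @param surface_dose Surface dose, percent (default 85).
#' @param virtual_source_to_isocenter Distance from the virtual electron
#'   source to isocenter, cm (fixed at 100 in clinical practice).
#' @param collimator_z Source-to-collimator distance, cm (modulator plane).
#' @return An object of class `beam_model`.
#' @examples
#' b <- make_beam(5.0, 16)
#' pdd(b, 5.0)  # 90
#' @export
make_beam <- function(r90, energy, sigma_theta0 = 0.035, xray_tail = 3,
                      surface_dose = 85,
                      virtual_source_to_isocenter = 100,
                      collimator_z = 93.5) {
  if (!is.numeric(r90) || length(r90) != 1L || !is.finite(r90) || r90 <= 0.5)
    stop("'r90' must be a single finite value > 0.5 cm", call. = FALSE)
  if (!is.numeric(energy) || energy <= 0)
    stop("'energy' must be positive (MeV)", call. = FALSE)
  if (xray_tail <= 0 || xray_tail >= 10)
    stop("'xray_tail' must lie in (0, 10) percent", call. = FALSE)
  r100 <- 0.6 * r90
  rp <- 0.5 * energy
  if (rp <= r90)
    stop("practical range 0.5*energy must exceed R90; increase 'energy'",
         call. = FALSE)
  tab <- pdd_table_analytic(r100, r90, rp, xray_tail, surface_dose)
  beam <- structure(list(
    nominal_energy = energy,
    R100 = r100, R90 = r90, Rp = rp,
    pdd_table = tab,
    sigma_theta0 = sigma_theta0,
    xray_tail = xray_tail,
    surface_dose = surface_dose,
    virtual_source_to_isocenter = virtual_source_to_isocenter,
    collimator_z = collimator_z,
    modulator_corrected = FALSE,
    scatter_k = NA_real_
  ), class = "beam_model")
  beam$scatter_k <- calibrate_scatter_k(beam)
  beam
}

# Analytic PDD table: parabolic buildup, logistic falloff anchored exactly at
# (R100, 100) and (R90, 90), constant tail beyond Rp. Returned as a two-column
# data.frame (depth_cm, percent) with R100, R90, Rp as exact nodes.
pdd_table_analytic <- function(r100, r90, rp, tail, surface_dose) {
  w <- (rp - r90) / 4  # falloff steepness scale
  f <- function(z, z50) 1 / (1 + exp((z - z50) / w))
  gtarget <- (90 - tail) / (100 - tail)
  gg <- function(z50) {
    (f(r90, z50) - f(rp, z50)) / (f(r100, z50) - f(rp, z50)) - gtarget
  }
  z50 <- stats::uniroot(gg, c(r100 + 1e-6, rp + 20 * w), tol = 1e-12)$root
  depths <- sort(unique(c(seq(0, rp + 2, by = 0.02), r100, r90, rp)))
  pct <- numeric(length(depths))
  bu <- depths < r100
  u <- depths[bu] / r100
  pct[bu] <- surface_dose + (100 - surface_dose) * (1 - (1 - u)^2)
  fo <- depths >= r100 & depths <= rp
  g <- (f(depths[fo], z50) - f(rp, z50)) / (f(r100, z50) - f(rp, z50))
  pct[fo] <- tail + (100 - tail) * g
  pct[depths > rp] <- tail
  data.frame(depth_cm = depths, percent = pct)
}

#' Evaluate the central-axis percent depth dose
#'
#' Linear interpolation of the beam's tabulated PDD; depths beyond the last
#' table entry return the constant x-ray tail.
#'
#' @param beam A [make_beam()] object.
#' @param depth Depth(s) in cm, all >= 0.
#' @return Percent dose value(s).
#' @export
pdd <- function(beam, depth) {
  stopifnot(inherits(beam, "beam_model"))
  if (any(!is.finite(depth)) || any(depth < 0))
    stop("'depth' must be finite and non-negative", call. = FALSE)
  tab <- beam$pdd_table
  stats::approx(tab$depth_cm, tab$percent, xout = depth,
                rule = 2, ties = "ordered")$y
}

#' Depth of a given percent dose on the distal falloff
#'
#' Finds the (unique) depth beyond `R100` at which the PDD equals `percent`.
#'
#' @param beam A [make_beam()] object.
#' @param percent Percent dose level, must lie in (xray_tail, 100).
#' @return Depth in cm.
#' @export
depth_of_percent <- function(beam, percent) {
  stopifnot(inherits(beam, "beam_model"))
  if (percent <= beam$xray_tail || percent >= 100)
    stop("'percent' must lie strictly between the x-ray tail and 100",
         call. = FALSE)
  tab <- beam$pdd_table
  i <- which(tab$depth_cm >= beam$R100 & tab$depth_cm <= beam$Rp)
  # falloff is strictly decreasing there: invert by interpolation on the
  # reversed (increasing) branch
  stats::approx(rev(tab$percent[i]), rev(tab$depth_cm[i]), xout = percent,
                ties = "ordered")$y
}

#' Apply the modulator-specific beam corrections
#'
#' When an island-block intensity modulator (tungsten pins embedded in
#' machinable foam, rho = 0.096 g/cm^3, 1.27 cm thick) sits in the beam, the
#' beam model is corrected in two ways: the energy loss in the foam is
#' represented by a rigid 0.1 cm upstream shift of the depth-dose curve
#' (R90 decreases by exactly 0.1 cm), and the additional scatter in the foam
#' is represented by multiplying the initial angular spread by exactly 1.5.
#'
#' The operation is deliberately not idempotent: applying it twice shifts R90
#' by 0.2 cm and multiplies the angular spread by 2.25. Callers that may
#' receive an already-corrected beam should test `beam$modulator_corrected`.
#'
#' @param beam A [make_beam()] object.
#' @return A new, corrected `beam_model`; the input is unmodified.
#' @export
apply_modulator_corrections <- function(beam) {
  stopifnot(inherits(beam, "beam_model"))
  shift <- 0.1
  tab <- beam$pdd_table
  d <- tab$depth_cm - shift
  keep <- d >= 0
  newtab <- data.frame(depth_cm = c(0, d[keep]),
                       percent = c(pdd(beam, shift), tab$percent[keep]))
  # drop a possible duplicate depth-0 node
  newtab <- newtab[!duplicated(newtab$depth_cm), ]
  out <- beam
  out$pdd_table <- newtab
  out$R100 <- beam$R100 - shift
  out$R90 <- beam$R90 - shift
  out$Rp <- beam$Rp - shift
  out$sigma_theta0 <- beam$sigma_theta0 * 1.5
  out$modulator_corrected <- TRUE
  out
}

# X-ray background component: linear ramp from 0 at the surface up to the
# tail level at Rp, constant beyond. A declared simple stand-in for an
# empirical bremsstrahlung model.
dx_component <- function(beam, depth) {
  pmin(depth / beam$Rp, 1) * beam$xray_tail
}

# Electron component of the PDD (total minus x-ray background, floored at 0).
de_component <- function(beam, depth) {
  pmax(pdd(beam, depth) - dx_component(beam, depth), 0)
}

# Calibrate the in-water scattering-power constant k so that the total
# lateral pencil sigma at depth R90/2 (SSD 100) is 0.17*R90 cm.
calibrate_scatter_k <- function(beam) {
  target <- 0.17 * beam$R90
  dref <- beam$R90 / 2
  air <- beam$virtual_source_to_isocenter - beam$collimator_z  # cm of air
  s_air2 <- beam$sigma_theta0^2 * ((air + dref)^2 - air^2)
  i_ref <- scatter_integral(dref, beam$Rp)
  k <- max(target^2 - s_air2, 1e-6) / i_ref
  k
}

# I(depth) = int_0^depth (depth - t)^2 / (1 - t/Rp)^2 dt with the relative
# residual energy floored at 0.1 to avoid the practical-range divergence.
scatter_integral <- function(depth, rp) {
  vapply(depth, function(d) {
    if (d <= 0) return(0)
    t <- seq(0, d, length.out = 101L)
    e <- pmax(1 - t / rp, 0.1)
    y <- (d - t)^2 / e^2
    sum((y[-1] + y[-length(y)]) / 2) * (t[2] - t[1])
  }, numeric(1))
}

#' Lateral pencil-beam spread at depth
#'
#' Fermi-Eyges style accumulation of the lateral Gaussian sigma of a pencil
#' beam: the in-air divergence term grows as `sigma_theta0 * (z - z_col)` and
#' in-phantom multiple Coulomb scattering adds
#' `k * int (depth - t)^2 / E_rel(t)^2 dt` with `E_rel(t) = 1 - t/Rp`. Only
#' the growth beyond the phantom surface is returned (the in-air spread up to
#' the surface is carried by the surface fluence map). The constant `k` is
#' calibrated per beam at construction (see [make_beam()]). The result is
#' capped at 2 cm (depths beyond the practical range carry essentially no
#' electron dose).
#'
#' @param beam A [make_beam()] object.
#' @param depth Depth(s) below the phantom surface, cm.
#' @param surface_z Source-to-surface distance of the phantom, cm.
#' @return Sigma in cm (same length as `depth`).
#' @export
sigma_kernel <- function(beam, depth, surface_z) {
  air <- surface_z - beam$collimator_z
  s2 <- beam$sigma_theta0^2 * ((air + depth)^2 - air^2) +
    beam$scatter_k * scatter_integral(depth, beam$Rp)
  pmin(sqrt(pmax(s2, 0)), 2)
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf("<beam_model> %g MeV  R100=%.2f  R90=%.2f  Rp=%.2f cm\n",
              x$nominal_energy, x$R100, x$R90, x$Rp))
  cat(sprintf("  sigma_theta0=%.4f rad  x-ray tail=%.1f%%  corrected=%s\n",
              x$sigma_theta0, x$xray_tail, x$modulator_corrected))
  invisible(x)
}
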