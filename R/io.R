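#' Write a planar map in the ASCII dialect
#'
#' Plain-text format for 2D maps (planar dose, bolus thickness, intensity
#' maps): `#`-prefixed header lines `field`, `depth_cm`, `ssd_cm`,
#' `pixel_cm`, `nx`, `ny`, `origin` followed by `ny` rows of `nx`
#' whitespace-separated values (row-major: each text row is one y index,
#' values along x).
#'
#' @param p A `planar_dose` (or any object with `values`, `x`, `y`, `pixel`,
#'   `depth`, `ssd`).
#' @param path Output file path.
#' @param field Name of the stored quantity (default `"percent_dose"`;
#'   `"thickness_cm"` and `"irf"` are used for bolus and intensity maps).
#' @return `path`, invisibly.
#' @export
write_planar <- function(p, path, field = "percent_dose") {
  hdr <- c(paste("# field", field),
           paste("# depth_cm", format(p$depth, digits = 12)),
           paste("# ssd_cm", format(p$ssd, digits = 12)),
           paste("# pixel_cm", format(p$pixel, digits = 12)),
           paste("# nx", nrow(p$values)),
           paste("# ny", ncol(p$values)),
           paste("# origin", format(p$x[1], digits = 12),
                 format(p$y[1], digits = 12)))
  rows <- apply(p$values, 2, function(r)
    paste(format(r, digits = 9, trim = TRUE, scientific = FALSE),
          collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a planar map written by [write_planar()]
#'
#' @param path File path.
#' @return A `planar_dose` with attribute `field`.
#' @export
read_planar <- function(path) {
  lines <- readLines(path)
  ish <- grepl("^#", lines)
  hdr <- strsplit(sub("^#\\s*", "", lines[ish]), "\\s+")
  kv <- stats::setNames(lapply(hdr, function(h) h[-1]),
                        vapply(hdr, `[`, "", 1))
  nx <- as.integer(kv$nx); ny <- as.integer(kv$ny)
  vals <- matrix(scan(text = paste(lines[!ish], collapse = "\n"),
                      quiet = TRUE), nx, ny)
  org <- as.numeric(kv$origin)
  p <- planar_dose_from_matrix(vals, pixel = as.numeric(kv$pixel_cm),
                               depth = as.numeric(kv$depth_cm),
                               ssd = as.numeric(kv$ssd_cm), origin = org)
  attr(p, "field") <- kv$field
  p
}

# planar view of fan-grid maps (bolus thickness, IRF) for write_planar
fan_map_as_planar <- function(values, x, y, field_depth = 0, ssd = 100) {
  structure(list(values = values, x = x, y = y, pixel = x[2] - x[1],
                 depth = field_depth, ssd = ssd), class = "planar_dose")
}

#' Write an island-block pattern as CSV
#'
#' One row per pin with columns `x_cm`, `y_cm`, `diameter_cm`, coordinates in
#' the lattice (collimator) plane. This file is the fabrication hand-off.
#'
#' @param pattern An `island_pattern`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pin_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "island_pattern"))
  df <- data.frame(x_cm = pattern$x, y_cm = pattern$y,
                   diameter_cm = pattern$diameter)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate an island-block pattern CSV
#'
#' Validates that every diameter belongs to the catalog and that every pin
#' center lies on the hexagonal lattice (pointy-row, on-axis origin) of the
#' catalog's spacing, within `tol` cm.
#'
#' @param path CSV path written by [write_pin_pattern()].
#' @param catalog A [pin_catalog()].
#' @param tol Lattice/catalog matching tolerance, cm.
#' @return An `island_pattern`.
#' @export
read_pin_pattern <- function(path, catalog = pin_catalog(), tol = 1e-6) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x_cm", "y_cm", "diameter_cm") %in% names(df)))
  if (nrow(df)) {
    okd <- vapply(df$diameter_cm, function(d)
      any(abs(catalog$diameters - d) < tol), logical(1))
    if (!all(okd)) stop("pin diameters not in the catalog", call. = FALSE)
    ry <- catalog$r * sqrt(3) / 2
    jrow <- df$y_cm / ry
    if (any(abs(jrow - round(jrow)) > tol / ry))
      stop("pin rows are off the hexagonal lattice", call. = FALSE)
    off <- ifelse(round(jrow) %% 2 == 0, 0, catalog$r / 2)
    icol <- (df$x_cm - off) / catalog$r
    if (any(abs(icol - round(icol)) > tol / catalog$r))
      stop("pin columns are off the hexagonal lattice", call. = FALSE)
  }
  island_pattern(df$x_cm, df$y_cm, df$diameter_cm, catalog)
}

#' Read a run configuration
#'
#' Parses and validates the structured-text (YAML) configuration driving the
#' planning, segmentation and QA stages. Recognized blocks: `beam`
#' (`energy_mev`, `r90_cm`, `sigma_theta0_rad`, `xray_tail_pct`), `phantom`
#' (`type` = `water_tank` | `wavy_slab` and the fixture parameters),
#' `aperture` (`width_cm`, `height_cm`), `sequence` (ordered operator list),
#' `modulation` (`irf_min`, `irf_max`, `margin_cm`), `catalog`
#' (`diameters_cm`, `spacing_cm`), `qa` (`dose_tol_pct`, `dist_tol_cm`,
#' `threshold_pct`), `seed`, `output_dir`.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A raw configuration list (as from [yaml::read_yaml()]).
#' @export
validate_run_config <- function(cfg) {
  defaults <- list(
    beam = list(energy_mev = 16, r90_cm = 5.0, sigma_theta0_rad = 0.035,
                xray_tail_pct = 3.0),
    phantom = list(type = "wavy_slab"),
    aperture = list(width_cm = 8, height_cm = 8),
    sequence = list(),
    modulation = list(irf_min = 0.8, irf_max = 1.0, margin_cm = 0.5),
    catalog = list(),
    qa = list(dose_tol_pct = 3, dist_tol_cm = 0.3, threshold_pct = 10),
    bolus_density = 0.92,
    seed = 1L,
    output_dir = "."
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]) && nm != "sequence")
      cfg[[nm]] <- utils::modifyList(defaults[[nm]], cfg[[nm]])
  }
  known_ops <- c("create", "smooth", "isodose_shift", "specified_shift",
                 "truncate", "height_extension", "intensity_modulation")
  for (s in cfg$sequence) {
    if (is.null(s$op) || !(s$op %in% known_ops))
      stop("unknown operator in sequence: ",
           if (is.null(s$op)) "<missing>" else s$op, call. = FALSE)
  }
  if (!cfg$phantom$type %in% c("water_tank", "wavy_slab"))
    stop("unknown phantom type: ", cfg$phantom$type, call. = FALSE)
  with(cfg$beam, stopifnot(r90_cm > 0.5, energy_mev > 0))
  stopifnot(cfg$modulation$irf_min > 0,
            cfg$modulation$irf_min <= cfg$modulation$irf_max,
            cfg$modulation$irf_max <= 1)
  class(cfg) <- "run_config"
  cfg
}

# materialize beam / phantom / aperture / catalog from a config
config_beam <- function(cfg) {
  b <- cfg$beam
  make_beam(b$r90_cm, b$energy_mev, sigma_theta0 = b$sigma_theta0_rad,
            xray_tail = b$xray_tail_pct)
}

config_phantom <- function(cfg) {
  p <- cfg$phantom
  if (p$type == "water_tank") {
    args <- p[names(p) %in% c("extent", "spacing", "ssd")]
    list(grid = do.call(water_tank, lapply(args, unlist)), ptv = NULL)
  } else {
    args <- p[names(p) %in% c("amplitude", "period", "base_depth",
                              "proximal_depth", "ptv_halfwidth",
                              "extent", "spacing", "ssd")]
    do.call(wavy_slab_phantom, lapply(args, unlist))
  }
}

config_aperture <- function(cfg) {
  rectangular_aperture(cfg$aperture$width_cm, cfg$aperture$height_cm)
}

config_catalog <- function(cfg) {
  ct <- cfg$catalog
  if (!length(ct)) return(pin_catalog())
  args <- list()
  if (!is.null(ct$diameters_cm)) args$diameters <- unlist(ct$diameters_cm)
  if (!is.null(ct$spacing_cm)) args$r <- ct$spacing_cm
  do.call(pin_catalog, args)
}
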