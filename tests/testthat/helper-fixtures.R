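# Shared fixtures, memoised so expensive plans are computed once per run.
.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

fx_beam <- function() fx_memo("beam", make_beam(5, 16))
fx_aperture <- function() rectangular_aperture(10, 10)
fx_phantom <- function() fx_memo("phantom", wavy_slab_phantom())

# Table-1/2 style operator sequences (chest-wall column)
bect_sequence <- function(create_margin = 0.5, shave = -0.1) {
  list(list(op = "create", percent = 90, margin = create_margin),
       list(op = "smooth"),
       list(op = "isodose_shift"),
       list(op = "smooth"),
       list(op = "isodose_shift"),
       list(op = "smooth"),
       list(op = "truncate"),
       list(op = "specified_shift", delta = shave))
}

imbect_sequence <- function() {
  c(bect_sequence(),
    list(list(op = "intensity_modulation"),
         list(op = "isodose_shift"),
         list(op = "smooth"),
         list(op = "specified_shift", delta = -0.1)))
}

fx_bect_plan <- function() fx_memo("bect", {
  ph <- fx_phantom()
  run_sequence(ph$grid, ph$ptv, fx_beam(), fx_aperture(), bect_sequence())
})

fx_imbect_plan <- function() fx_memo("imbect", {
  ph <- fx_phantom()
  run_sequence(ph$grid, ph$ptv, fx_beam(), fx_aperture(), imbect_sequence())
})

# small water tank for engine tests
fx_tank <- function() fx_memo("tank", water_tank(c(12, 12, 8),
                                                 c(0.2, 0.2, 0.2), 100))

# central-axis profile of a dose3d (depth, value)
ca_profile <- function(dose) {
  gx <- dose$origin[1] + (seq_len(dim(dose$values)[1]) - 0.5) * dose$spacing[1]
  gy <- dose$origin[2] + (seq_len(dim(dose$values)[2]) - 0.5) * dose$spacing[2]
  zc <- dose$origin[3] + (seq_len(dim(dose$values)[3]) - 0.5) * dose$spacing[3]
  i <- which.min(abs(gx)); j <- which.min(abs(gy))
  data.frame(depth = zc - dose$origin[3], value = dose$values[i, j, ])
}

# brute-force blocked-area fraction of a hexagonal pin array: dense point
# sampling of one rhombic unit cell with circles at the lattice points
blocked_fraction_oracle <- function(d, r, n = 401) {
  a1 <- c(r, 0); a2 <- c(r / 2, r * sqrt(3) / 2)
  u <- (seq_len(n) - 0.5) / n
  g <- expand.grid(u = u, v = u)
  px <- g$u * a1[1] + g$v * a2[1]
  py <- g$u * a1[2] + g$v * a2[2]
  corners <- rbind(c(0, 0), a1, a2, a1 + a2)
  hit <- rep(FALSE, nrow(g))
  for (k in seq_len(nrow(corners)))
    hit <- hit | ((px - corners[k, 1])^2 + (py - corners[k, 2])^2 <= (d / 2)^2)
  mean(hit)
}

# uniform pin array covering an aperture
uniform_pin_array <- function(d, aperture = fx_aperture(),
                              catalog = pin_catalog()) {
  sites <- hex_lattice(aperture, catalog$r, catalog$plane_z)
  island_pattern(sites[, 1], sites[, 2], rep(d, nrow(sites)), catalog)
}
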