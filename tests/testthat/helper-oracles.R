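# Independent numerical oracles, kept deliberately separate from the
# package's own implementations.

# Klein-Nishina energy-transfer acceptance via midpoint quadrature in the
# electron-energy domain: dsigma/dT = dsigma/dcos * dcos/dT with
# cos(theta) = 1 - T / (k (E - T)) and dcos/dT = -E / (k (E - T)^2).
kn_accept_oracle <- function(threshold_keV, photon_keV = 511, n_grid = 2e5) {
  k <- photon_keV / 511
  t_max <- photon_keV * 2 * k / (1 + 2 * k)
  tt <- seq(0, t_max, length.out = n_grid + 1)
  tm <- (tt[-1] + tt[-length(tt)]) / 2
  cost <- 1 - tm / (k * (photon_keV - tm))
  r <- 1 / (1 + k * (1 - cost))
  dcs <- r^2 * (r + 1 / r - (1 - cost^2))
  jac <- photon_keV / (k * (photon_keV - tm)^2)
  w <- dcs * jac
  sum(w[tm > threshold_keV]) / sum(w)
}

# Chord length of one photon through the scintillator material of a design,
# by fine ray marching (indicator integration); independent of the
# analytical ray-cylinder solution.
ray_march_chord <- function(design, x, y, z, dx, dy, dz, s_max = 300, ds = 2e-4) {
  s <- seq(ds / 2, s_max, by = ds)
  px <- x + s * dx
  py <- y + s * dy
  pz <- z + s * dz
  r <- sqrt(px^2 + py^2)
  spec <- design$spec
  if (design$family == "crystal") {
    units <- unit_table(design)
    in_z <- rep(FALSE, length(s))
    for (u in seq_len(nrow(units))) {
      if (units$fill[u] > 0) {
        in_z <- in_z | (pz >= units$z_start[u] & pz <= units$z_end[u])
      }
    }
    inside <- r >= spec$ring_inner_radius &
      r <= spec$ring_inner_radius + spec$crystal_depth & in_z
  } else {
    inside <- rep(FALSE, length(s))
    for (l in seq_len(spec$n_layers)) {
      inside <- inside |
        (r >= spec$layer_radii[l] & r <= spec$layer_radii[l] + spec$strip_thickness)
    }
    inside <- inside & abs(pz) <= spec$strip_length / 2
  }
  sum(inside) * ds
}

# Small crystal barrel used where the full-size designs would be overkill.
tiny_barrel <- function(n_units = 4, ual = 10, gap = 0, radius = 20, depth = 2,
                        material_name = "BGO", occupancy = "full") {
  build_design(list(
    name = "tiny_barrel", family = "crystal", material = material_name,
    n_units = n_units, unit_axial_length = ual, inter_unit_gap = gap,
    n_blocks_per_ring = 4, n_crystals_axial = 10, n_crystals_transaxial = 10,
    crystal_transaxial = 0.3, crystal_axial = 0.3, crystal_depth = depth,
    ring_inner_radius = radius, packing_fraction = 1, energy_acceptance = 1,
    occupancy = occupancy
  ))
}

# Hand-built event rows for targeted transport checks.
event_row <- function(x = 0, y = 0, z = 0, dx = 1, dy = 0, dz = 0, id = 1L) {
  tibble::tibble(event_id = id, x = x, y = y, z = z, dx = dx, dy = dy, dz = dz)
}

# Hand-built hit rows for coincidence-building checks.
hit_row <- function(id, photon, z_true, x_det, y_det, z_det, unit = 1L,
                    detected = TRUE) {
  tibble::tibble(
    event_id = id, photon = photon, z_true = z_true,
    x_det = x_det, y_det = y_det, z_det = z_det, unit = as.integer(unit),
    path_water = 0, path_detector = 1, p_detect = 1, detected = detected
  )
}

# Periodicity score of a profile: lag-`pitch` autocorrelation of the
# moving-average-detrended sensitivity, high only for wavy profiles.
wavy_score <- function(profile, pitch_slices, z_max = 85) {
  x <- profile$sensitivity[abs(profile$slice_center) < z_max]
  trend <- stats::filter(x, rep(1 / pitch_slices, pitch_slices), sides = 2)
  r <- (x - trend)[!is.na(trend)]
  stats::acf(r, lag.max = pitch_slices + 2, plot = FALSE)$acf[pitch_slices + 1]
}
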