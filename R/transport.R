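# Analytical 511 keV photon transport: exact ray-cylinder chords through the
# phantom and the detector shells, exponential attenuation/interaction laws,
# and a Klein-Nishina energy-deposit acceptance for plastic strips.

# Distance along the ray at which it exits an infinite cylinder of radius R
# centred on the z axis, for start points radially inside R. Inf for rays
# with no transaxial component.
ray_cylinder_exit <- function(x, y, dx, dy, R) {
  a <- dx^2 + dy^2
  b <- 2 * (x * dx + y * dy)
  cc <- x^2 + y^2 - R^2
  disc <- b^2 - 4 * a * cc
  s <- (-b + sqrt(pmax(disc, 0))) / (2 * a)
  s[a < 1e-12] <- Inf
  s
}

#' Path length of a photon through the water phantom
#'
#' Exact ray-cylinder and ray-slab intersection of one annihilation photon
#' with the water cylinder. Emission points may lie inside or axially
#' outside the phantom (the line source is longer than the phantom).
#'
#' @param events Event tibble from [sample_events()].
#' @param phantom A [water_phantom()] spec, or `NULL` for no phantom.
#' @param which_photon `"A"` (the stored direction) or `"B"` (antiparallel).
#' @return Numeric vector of in-water path lengths, cm.
#' @export
water_path <- function(events, phantom, which_photon = c("A", "B")) {
  which_photon <- match.arg(which_photon)
  if (is.null(phantom)) {
    return(rep(0, nrow(events)))
  }
  stopifnot(inherits(phantom, "phantom_spec"))
  sgn <- if (which_photon == "A") 1 else -1
  dx <- sgn * events$dx
  dy <- sgn * events$dy
  dz <- sgn * events$dz
  s_cyl <- ray_cylinder_exit(events$x, events$y, dx, dy, phantom$diameter / 2)
  zlo <- phantom$center - phantom$length / 2
  zhi <- phantom$center + phantom$length / 2
  t1 <- (zlo - events$z) / dz
  t2 <- (zhi - events$z) / dz
  s_slab_lo <- pmin(t1, t2)
  s_slab_hi <- pmax(t1, t2)
  # purely transaxial rays: inside the slab forever or never
  flat <- abs(dz) < 1e-12
  inside <- events$z >= zlo & events$z <= zhi
  s_slab_lo[flat] <- ifelse(inside[flat], -Inf, Inf)
  s_slab_hi[flat] <- ifelse(inside[flat], Inf, Inf)
  lo <- pmax(0, s_slab_lo)
  hi <- pmin(s_cyl, s_slab_hi)
  pmax(0, hi - lo)
}

#' Photon survival through an attenuating path
#'
#' @param path Path length in the medium, cm.
#' @param mu Linear attenuation coefficient, 1/cm.
#' @return `exp(-mu * path)`, in (0, 1].
#' @export
survival_probability <- function(path, mu) {
  if (any(path < 0)) abort("path must be >= 0")
  if (any(mu < 0)) abort("mu must be >= 0")
  exp(-mu * path)
}

#' Photon interaction probability in scintillator
#'
#' @param path_in_detector Chord length through scintillator material, cm.
#' @param material A [material()] (or anything with a `mu_511` field).
#' @return `1 - exp(-mu_511 * path)`.
#' @export
interaction_probability <- function(path_in_detector, material) {
  if (any(path_in_detector < 0)) abort("path must be >= 0")
  p <- -expm1(-material$mu_511 * path_in_detector)
  # perfect absorber (mu = Inf) on a zero-length chord is still a miss
  p[path_in_detector == 0] <- 0
  p
}

#' Intersect annihilation photons with the detector
#'
#' Propagates each event's photon A and B through the detector geometry and
#' accumulates, per photon, the chord length through scintillator material:
#' for crystal-family designs the portion of the barrel-shell chord that
#' overlaps populated detection units, for strip-family designs the sum of
#' chords over the (up to `n_layers`) layer shells within the strip length.
#' A photon whose ray never crosses populated material is a miss.
#'
#' The returned detection probability `p_detect` combines water survival,
#' the interaction probability in scintillator, the surface packing (crystal)
#' or azimuthal fill (strip) factor, and the family's energy acceptance:
#' an energy-window factor for crystals, the Klein-Nishina energy-deposit
#' acceptance above the design's threshold for plastic strips.
#'
#' @param events Event tibble from [sample_events()].
#' @param design A [build_design()] object.
#' @param phantom Optional [water_phantom()]; attenuates but never scatters
#'   (attenuated photons are lost, so only true unscattered coincidences are
#'   scored).
#' @param seed Master seed; the detection stream is derived from it and is
#'   independent of the design, so runs on the same events are coupled.
#' @param draw If `FALSE`, skip the Bernoulli detection draw (the `detected`
#'   column is then `NA`).
#' @return A tibble with two rows per event (`photon` = "A", "B"): entry
#'   point `x_det, y_det, z_det`, detection unit, in-water and in-detector
#'   path lengths, `p_detect`, and the `detected` flag. `z_true` carries the
#'   annihilation axial position. Misses have `p_detect = 0`.
#' @export
trace_photons <- function(events, design, phantom = NULL, seed = 1, draw = TRUE) {
  stopifnot(inherits(design, "pet_design"))
  hits <- dplyr::bind_rows(
    trace_one_side(events, design, phantom, "A"),
    trace_one_side(events, design, phantom, "B")
  )
  hits <- dplyr::arrange(hits, .data$event_id, .data$photon)
  if (draw && nrow(hits) > 0) {
    hits$detected <- draw_detections(hits, seed)$detected
  } else {
    hits$detected <- rep(NA, nrow(hits))
  }
  hits
}

trace_one_side <- function(events, design, phantom, which_photon) {
  sgn <- if (which_photon == "A") 1 else -1
  n <- nrow(events)
  dx <- sgn * events$dx
  dy <- sgn * events$dy
  dz <- sgn * events$dz
  pw <- water_path(events, phantom, which_photon)
  mu_w <- if (is.null(phantom)) 0 else phantom$mu_water
  surv <- exp(-mu_w * pw)

  geo <- if (design$family == "crystal") {
    crystal_geometry(events$x, events$y, events$z, dx, dy, dz, design)
  } else {
    strip_geometry(events$x, events$y, events$z, dx, dy, dz, design)
  }
  acc <- family_acceptance(design)
  p <- surv * interaction_probability(geo$path, design$material) * acc
  tibble::tibble(
    event_id = events$event_id,
    photon = which_photon,
    z_true = events$z,
    x_det = geo$x_det, y_det = geo$y_det, z_det = geo$z_det,
    unit = geo$unit,
    path_water = pw,
    path_detector = geo$path,
    p_detect = p
  )
}

# Geometry-independent acceptance factors per family.
family_acceptance <- function(design) {
  s <- design$spec
  if (design$family == "crystal") {
    s$packing_fraction * s$energy_acceptance
  } else {
    s$azimuthal_fill * compton_accept_fraction(s$energy_threshold_keV)
  }
}

# Chord of each ray through the crystal barrel shell, weighted by the axial
# occupancy of the detection units it sweeps over.
crystal_geometry <- function(x, y, z, dx, dy, dz, design) {
  s <- design$spec
  R <- s$ring_inner_radius
  s_in <- ray_cylinder_exit(x, y, dx, dy, R)
  s_out <- ray_cylinder_exit(x, y, dx, dy, R + s$crystal_depth)
  chord <- s_out - s_in
  z_in <- z + s_in * dz
  z_out <- z + s_out * dz
  zmin <- pmin(z_in, z_out)
  zmax <- pmax(z_in, z_out)
  units <- unit_table(design)
  # weighted overlap of the chord's axial sweep with populated units
  wsum <- numeric(length(x))
  for (u in seq_len(nrow(units))) {
    if (units$fill[u] <= 0) next
    wsum <- wsum + units$fill[u] *
      pmax(0, pmin(zmax, units$z_end[u]) - pmax(zmin, units$z_start[u]))
  }
  span <- zmax - zmin
  frac <- ifelse(span > 1e-9, wsum / span, point_fill(z_in, units))
  frac[!is.finite(s_in)] <- 0
  path <- ifelse(is.finite(chord), chord * frac, 0)
  unit <- unit_of_z(z_in, units)
  # a ray entering over a gap but sweeping into a unit: attribute it to the
  # unit nearest its entry point
  need <- path > 0 & is.na(unit)
  if (any(need)) {
    mid <- (pmax(zmin, min(units$z_start)) + pmin(zmax, max(units$z_end))) / 2
    unit[need] <- nearest_active_unit(mid[need], units)
  }
  ok <- path > 0
  list(
    path = path,
    x_det = ifelse(ok, x + s_in * dx, NA_real_),
    y_det = ifelse(ok, y + s_in * dy, NA_real_),
    z_det = ifelse(ok, z_in, NA_real_),
    unit = ifelse(ok, unit, NA_integer_)
  )
}

point_fill <- function(z, units) {
  u <- unit_of_z(z, units)
  ifelse(is.na(u), 0, units$fill[ifelse(is.na(u), 1L, u)])
}

unit_of_z <- function(z, units) {
  edges <- as.vector(rbind(units$z_start, units$z_end))
  pos <- findInterval(z, edges)
  inside <- pos %% 2 == 1
  out <- rep(NA_integer_, length(z))
  out[inside] <- as.integer((pos[inside] + 1) / 2)
  out
}

nearest_active_unit <- function(z, units) {
  act <- units[units$fill > 0, ]
  centers <- (act$z_start + act$z_end) / 2
  act$unit[pmax(1L, pmin(length(centers), findInterval(z, centers) + 1L))]
}

# Summed chord of each ray through the concentric strip-layer shells,
# truncated to the strip length; entry point taken at the first layer hit.
strip_geometry <- function(x, y, z, dx, dy, dz, design) {
  s <- design$spec
  half <- s$strip_length / 2
  n <- length(x)
  total <- numeric(n)
  x_det <- rep(NA_real_, n)
  y_det <- rep(NA_real_, n)
  z_det <- rep(NA_real_, n)
  for (l in seq_len(s$n_layers)) {
    r <- s$layer_radii[l]
    s_in <- ray_cylinder_exit(x, y, dx, dy, r)
    s_out <- ray_cylinder_exit(x, y, dx, dy, r + s$strip_thickness)
    z_in <- z + s_in * dz
    z_out <- z + s_out * dz
    zmin <- pmin(z_in, z_out)
    zmax <- pmax(z_in, z_out)
    olap <- pmax(0, pmin(zmax, half) - pmax(zmin, -half))
    span <- zmax - zmin
    frac <- ifelse(span > 1e-9, olap / span, as.numeric(abs(z_in) <= half))
    pathl <- ifelse(is.finite(s_out - s_in), (s_out - s_in) * frac, 0)
    first <- pathl > 0 & total == 0
    x_det[first] <- (x + s_in * dx)[first]
    y_det[first] <- (y + s_in * dy)[first]
    z_det[first] <- z_in[first]
    total <- total + pathl
  }
  list(path = total, x_det = x_det, y_det = y_det, z_det = z_det,
       unit = rep(1L, n))
}

#' Bernoulli detection draw
#'
#' Draws the detection flag for each photon from its detection probability
#' under a seeded stream derived from the master seed (one uniform per
#' photon, in event order, independent of the design).
#'
#' @param hits Hit tibble from [trace_photons()] (needs `p_detect`).
#' @param seed Master seed.
#' @return `hits` with the `detected` logical column filled.
#' @export
draw_detections <- function(hits, seed = 1) {
  if (any(hits$p_detect < 0 | hits$p_detect > 1, na.rm = TRUE)) {
    abort("p_detect must lie in [0, 1]")
  }
  withr_seed(stage_seed(seed, "detection"), {
    u <- runif(nrow(hits))
  })
  hits$detected <- u < hits$p_detect
  hits
}
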