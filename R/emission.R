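#' Measurement setups: axial line source and water phantom
#'
#' The two NEMA-style measurement setups the simulator emulates: a thin
#' axial line source centred on the scanner axis (default 1 mm diameter,
#' 250 cm long, 1 MBq), optionally surrounded by a water-filled cylinder
#' (default 20 cm diameter, 183 cm long) that mimics a human body.
#'
#' @param length Source length `L_mean`, cm.
#' @param diameter Source diameter, cm.
#' @param activity Initial activity `A_mean`, kBq.
#' @param center Axial position of the source centre, cm.
#' @return `line_source()` returns a `source_spec` list; `water_phantom()` a
#'   `phantom_spec` list.
#' @export
#' @examples
#' src <- line_source()
#' ph <- water_phantom()
line_source <- function(length = 250, diameter = 0.1, activity = 1000, center = 0) {
  if (length <= 0) abort("source length must be positive")
  if (diameter < 0) abort("source diameter must be >= 0")
  if (activity <= 0) abort("source activity must be positive")
  structure(
    list(length = length, diameter = diameter, activity = activity, center = center),
    class = "source_spec"
  )
}

#' @rdname line_source
#' @param mu_water Linear attenuation coefficient of water at 511 keV, 1/cm.
#' @export
water_phantom <- function(diameter = 20, length = 183, mu_water = 0.096, center = 0) {
  if (diameter <= 0 || length <= 0) abort("phantom dimensions must be positive")
  structure(
    list(diameter = diameter, length = length, mu_water = mu_water, center = center),
    class = "phantom_spec"
  )
}

#' Sample annihilation events
#'
#' Draws `n` positron annihilations uniformly within the line-source
#' cylinder, each with an isotropic back-to-back photon direction pair
#' (photon B is exactly antiparallel to photon A). The stream is fully
#' reproducible: identical `(n, seed)` give identical output.
#'
#' @param source A [line_source()] spec.
#' @param n Number of annihilations to sample.
#' @param seed Master seed; the emission stream is derived from it.
#' @return A tibble with one row per event: `event_id`, position `x, y, z`
#'   (cm) and the unit direction `dx, dy, dz` of photon A.
#' @export
#' @examples
#' sample_events(line_source(), 5, seed = 1)
sample_events <- function(source, n, seed = 1) {
  stopifnot(inherits(source, "source_spec"))
  if (n < 0) abort("n must be >= 0")
  n <- as.integer(n)
  cols <- c("event_id", "x", "y", "z", "dx", "dy", "dz")
  if (n == 0) {
    return(tibble::as_tibble(stats::setNames(
      c(list(integer(0)), rep(list(numeric(0)), 6)), cols
    )))
  }
  withr_seed(stage_seed(seed, "emission"), {
    z <- runif(n, source$center - source$length / 2, source$center + source$length / 2)
    r <- source$diameter / 2 * sqrt(runif(n))
    phi <- runif(n, 0, 2 * pi)
    dz <- runif(n, -1, 1)
    psi <- runif(n, 0, 2 * pi)
  })
  dt <- sqrt(pmax(0, 1 - dz^2))
  tibble::tibble(
    event_id = seq_len(n),
    x = r * cos(phi), y = r * sin(phi), z = z,
    dx = dt * cos(psi), dy = dt * sin(psi), dz = dz
  )
}

#' Simulated acquisition duration for a decay count
#'
#' The time over which a source of activity `A_mean` produces `n` decays;
#' used to convert slice counts into rates.
#'
#' @param n Number of simulated decays.
#' @param source A [line_source()] spec (activity in kBq).
#' @return Duration in seconds.
#' @export
#' @examples
#' duration_for(1e6, line_source(activity = 1000)) # 1 second
duration_for <- function(n, source) {
  stopifnot(inherits(source, "source_spec"))
  if (n <= 0) abort("n must be positive")
  if (source$activity <= 0) abort("source activity must be positive")
  n / (source$activity * 1000)
}

#' Write / read a list-mode event stream
#'
#' @param events Event tibble from [sample_events()].
#' @param path File path for the CSV (columns `x, y, z, dx, dy, dz`).
#' @return `write_events()` returns `path` invisibly; `read_events()` the
#'   event tibble.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
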