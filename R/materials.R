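#' Scintillator and phantom materials
#'
#' Reference table of the materials used by the bundled scanner designs:
#' linear attenuation coefficient at 511 keV and a dimensionless cost weight
#' per unit scintillator volume (LYSO/LSO = 1 by convention; BGO is taken as
#' the midpoint of the commonly quoted 2--3x price advantage, i.e. 0.4;
#' plastic scintillator is far cheaper still). The `ideal` material is a
#' perfect absorber used for geometry-only studies such as solid-angle
#' checks.
#'
#' Attenuation coefficients are standard narrow-beam values at 511 keV:
#' BGO 0.955 /cm, LYSO/LSO 0.87 /cm, polyvinyltoluene-based plastic
#' 0.098 /cm, water 0.096 /cm.
#'
#' @return A tibble with columns `material`, `mu_511` (1/cm) and
#'   `relative_cost_per_volume`.
#' @export
#' @examples
#' pet_materials()
pet_materials <- function() {
  tibble::tibble(
    material = c("LYSO", "LSO", "BGO", "plastic", "water", "ideal"),
    mu_511 = c(0.87, 0.87, 0.955, 0.098, 0.096, Inf),
    relative_cost_per_volume = c(1, 1, 0.4, 0.02, 0, 0)
  )
}

#' Look up one material
#'
#' @param name Material name; one of the rows of [pet_materials()], case
#'   insensitive.
#' @param mu_511 Optional override of the attenuation coefficient (1/cm).
#' @param relative_cost_per_volume Optional override of the cost weight.
#' @return A list with fields `name`, `mu_511`, `relative_cost_per_volume`.
#' @export
#' @examples
#' material("BGO")
material <- function(name, mu_511 = NULL, relative_cost_per_volume = NULL) {
  tab <- pet_materials()
  i <- match(toupper(name), toupper(tab$material))
  if (is.na(i)) {
    abort(paste0("unknown material: '", name, "'"))
  }
  out <- list(
    name = tab$material[i],
    mu_511 = if (is.null(mu_511)) tab$mu_511[i] else mu_511,
    relative_cost_per_volume = if (is.null(relative_cost_per_volume)) {
      tab$relative_cost_per_volume[i]
    } else {
      relative_cost_per_volume
    }
  )
  if (out$mu_511 <= 0) abort("mu_511 must be positive")
  if (out$relative_cost_per_volume < 0) abort("relative_cost_per_volume must be >= 0")
  structure(out, class = "pet_material")
}

#' @export
print.pet_material <- function(x, ...) {
  cat(sprintf(
    "<pet_material> %s  mu_511 = %g /cm  cost/volume = %g\n",
    x$name, x$mu_511, x$relative_cost_per_volume
  ))
  invisible(x)
}
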