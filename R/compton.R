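#' Klein-Nishina energy-deposit acceptance
#'
#' Fraction of single Compton scatters of a photon (default 511 keV) that
#' deposit more than `threshold_keV` on the recoil electron, computed from
#' the Klein-Nishina differential cross-section. Plastic scintillator strips
#' detect annihilation photons via Compton scattering only, so this fraction
#' multiplies the strip-family detection probability; the maximum possible
#' deposit is the Compton edge, `E * 2k / (1 + 2k)` with `k = E / 511`
#' (340.67 keV for 511 keV photons).
#'
#' @param threshold_keV Energy-loss threshold, keV, in `[0, photon_keV]`.
#' @param photon_keV Incident photon energy, keV.
#' @return Acceptance probability in `[0, 1]`.
#' @export
#' @examples
#' compton_accept_fraction(200)
#' compton_accept_fraction(341) # above the Compton edge
compton_accept_fraction <- function(threshold_keV, photon_keV = 511) {
  if (threshold_keV < 0 || threshold_keV > photon_keV) {
    abort("threshold must lie in [0, photon energy]")
  }
  k <- photon_keV / 511
  edge <- photon_keV * 2 * k / (1 + 2 * k)
  if (threshold_keV == 0) {
    return(1)
  }
  if (threshold_keV >= edge) {
    return(0)
  }
  # deposit T > thr corresponds to scattering angles with
  # cos(theta) < 1 - thr / (k * (E - thr))
  cos_max <- 1 - threshold_keV / (k * (photon_keV - threshold_keV))
  num <- integrate(kn_dcs_dcos, -1, cos_max, k = k, rel.tol = 1e-10)$value
  den <- integrate(kn_dcs_dcos, -1, 1, k = k, rel.tol = 1e-10)$value
  num / den
}

# Klein-Nishina dsigma/dcos(theta), up to constants: with the scattered-to-
# incident energy ratio r = 1 / (1 + k (1 - cos)), proportional to
# r^2 (r + 1/r - sin^2 theta).
kn_dcs_dcos <- function(cost, k) {
  r <- 1 / (1 + k * (1 - cost))
  r^2 * (r + 1 / r - (1 - cost^2))
}
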