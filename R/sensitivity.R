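#' Bin coincidences into axial slices and compute rates
#'
#' Counts coincidences per contiguous axial slice of width `d` and divides
#' by the acquisition duration. Slices are assigned by the true annihilation
#' position by default (noiseless in simulation); LOR axial midpoint
#' assignment is available as an option.
#'
#' @param records Coincidence tibble from [build_coincidences()].
#' @param duration Acquisition duration, s.
#' @param slice_width Slice width `d`, cm.
#' @param axial_range Two-element axial range to bin over, cm; defaults to
#'   the 250 cm line-source span.
#' @param assign `"true"` (bin by `z_true`) or `"midpoint"` (bin by
#'   `(z_A + z_B) / 2`).
#' @return A tibble with `slice_center` (cm), `counts` and `rate` (cps), one
#'   row per slice; counts outside the range are dropped.
#' @export
slice_rates <- function(records, duration, slice_width = 1,
                        axial_range = c(-125, 125),
                        assign = c("true", "midpoint")) {
  assign <- match.arg(assign)
  if (slice_width <= 0) abort("slice width must be positive")
  if (duration <= 0) abort("duration must be positive")
  breaks <- seq(axial_range[1], axial_range[2], by = slice_width)
  if (max(breaks) < axial_range[2]) breaks <- c(breaks, max(breaks) + slice_width)
  z <- if (assign == "true") records$z_true else (records$z_A + records$z_B) / 2
  idx <- findInterval(z, breaks, rightmost.closed = TRUE)
  idx <- idx[idx >= 1 & idx <= length(breaks) - 1]
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  tibble::tibble(
    slice_center = (breaks[-length(breaks)] + breaks[-1]) / 2,
    counts = counts,
    rate = counts / duration
  )
}

#' Per-slice sensitivity profile
#'
#' Converts slice rates into sensitivity: each slice of width `d` contains
#' the fraction `d / L_mean` of the source activity, so
#' `S_i = R_i * L_mean / (d * A_mean)` in cps/kBq.
#'
#' @param rates Slice-rate tibble from [slice_rates()].
#' @param source The [line_source()] the rates were measured with.
#' @param slice_width Slice width `d`, cm (must match the binning).
#' @return A `sensitivity_profile` tibble with columns `slice_center`,
#'   `counts`, `rate` and `sensitivity`, and attributes `slice_width`,
#'   `source_length`, `activity`.
#' @export
sensitivity_profile <- function(rates, source, slice_width = 1) {
  stopifnot(inherits(source, "source_spec"))
  if (source$activity <= 0) abort("source activity must be positive")
  out <- dplyr::mutate(
    rates,
    sensitivity = .data$rate * source$length / (slice_width * source$activity)
  )
  structure(
    out,
    slice_width = slice_width,
    source_length = source$length,
    activity = source$activity,
    class = c("sensitivity_profile", class(out))
  )
}

#' Total-body sensitivity
#'
#' Average detected-annihilation rate over the slices spanning a body-length
#' axial range (183 cm by default), divided by the activity within that
#' range. Slices outside a short scanner contribute zero counts but are
#' still averaged over, so scanners shorter than the body are penalised by
#' the empty slices.
#'
#' @param profile A [sensitivity_profile()].
#' @param body_length Body axial extent, cm.
#' @param A_body Activity within the body range, kBq; defaults to the
#'   source-activity fraction inside it,
#'   `A_mean * min(1, body_length / L_mean)`.
#' @return A one-row tibble with `S_TB` (cps/kBq), `A_body` (kBq) and the
#'   number of body-range slices `N`.
#' @export
total_body_sensitivity <- function(profile, body_length = 183, A_body = NULL) {
  d <- attr(profile, "slice_width")
  if (is.null(d)) abort("profile must come from sensitivity_profile()")
  if (is.null(A_body)) {
    A_body <- attr(profile, "activity") *
      min(1, body_length / attr(profile, "source_length"))
  }
  if (A_body <= 0) abort("A_body must be positive")
  N <- ceiling(body_length / d)
  in_body <- abs(profile$slice_center) <= body_length / 2
  tibble::tibble(
    S_TB = sum(profile$rate[in_body]) / (A_body * N),
    A_body = A_body,
    N = as.integer(N)
  )
}

#' Relative system cost
#'
#' Cost model: half of a PET system's price is attributed to the
#' photosensors and electronics (proxied by the photosensor covered area)
#' and half to the scintillators (volume weighted by the material cost),
#' each expressed relative to a reference design:
#' `cost = 0.5 * area / area_ref + 0.5 * (V * w) / (V_ref * w_ref)`.
#'
#' @param design A `pet_design`.
#' @param reference The reference `pet_design` (cost 1 by construction).
#' @return Dimensionless relative cost.
#' @export
#' @examples
#' ref <- build_design("uexplorer_full_lyso_194")
#' relative_cost(build_design("uexplorer_full_bgo_194"), ref) # 30% cheaper
relative_cost <- function(design, reference) {
  a <- pm_covered_area(design)
  a0 <- pm_covered_area(reference)
  v <- scintillator_volume(design) * design$material$relative_cost_per_volume
  v0 <- scintillator_volume(reference) * reference$material$relative_cost_per_volume
  if (a0 <= 0 || v0 <= 0) abort("reference design has zero covered area or scintillator cost")
  0.5 * a / a0 + 0.5 * v / v0
}

#' Cost-normalised total-body figure of merit
#'
#' `TB-FOM = S_TB / cost`, expressed relative to the reference design's own
#' sensitivity-to-cost ratio, so the reference scores exactly 1.
#'
#' @param s_tb Total-body sensitivity of the design, cps/kBq.
#' @param cost Relative cost of the design (see [relative_cost()]).
#' @param s_tb_ref,cost_ref The reference design's values.
#' @return A one-row tibble with `relative_cost` and `tb_fom`.
#' @export
tb_fom <- function(s_tb, cost, s_tb_ref, cost_ref = 1) {
  if (cost <= 0 || cost_ref <= 0) abort("cost must be positive")
  if (s_tb_ref <= 0) abort("reference S_TB must be positive")
  tibble::tibble(
    relative_cost = cost,
    tb_fom = (s_tb / cost) / (s_tb_ref / cost_ref)
  )
}

#' Write a sensitivity profile as TSV
#'
#' @param profile A [sensitivity_profile()].
#' @param path Output TSV path (columns `slice_center_cm`, `R_cps`,
#'   `S_cps_per_kBq`).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  out <- tibble::tibble(
    slice_center_cm = profile$slice_center,
    R_cps = profile$rate,
    S_cps_per_kBq = profile$sensitivity
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
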