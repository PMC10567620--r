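#' Pair detected photons into true coincidences
#'
#' One coincidence per event in which both photons were detected. The
#' line-of-response (LOR) obliqueness angle `theta` is measured from the
#' transaxial plane: 0 degrees for an LOR perpendicular to the scanner axis,
#' 90 degrees for an axial LOR. Pairing uses ground-truth event identity
#' (no timing window; randoms are out of scope).
#'
#' @param hits Hit tibble from [trace_photons()] with the `detected` flag.
#' @return A tibble with one row per true coincidence: detection points of
#'   both photons, `theta` (degrees), unit indices `unit_A`, `unit_B`, and
#'   the true annihilation axial position `z_true`.
#' @export
build_coincidences <- function(hits) {
  det <- dplyr::filter(hits, .data$detected)
  wide <- tidyr::pivot_wider(
    dplyr::select(det, "event_id", "photon", "z_true",
                  "x_det", "y_det", "z_det", "unit"),
    names_from = "photon",
    values_from = c("x_det", "y_det", "z_det", "unit")
  )
  need <- c("x_det_A", "y_det_A", "z_det_A", "unit_A",
            "x_det_B", "y_det_B", "z_det_B", "unit_B")
  missing <- setdiff(need, names(wide))
  for (m in missing) wide[[m]] <- if (grepl("unit", m)) NA_integer_ else NA_real_
  both <- dplyr::filter(
    wide,
    !is.na(.data$z_det_A) & !is.na(.data$z_det_B)
  )
  dtrans <- sqrt((both$x_det_A - both$x_det_B)^2 + (both$y_det_A - both$y_det_B)^2)
  dax <- abs(both$z_det_A - both$z_det_B)
  tibble::tibble(
    event_id = both$event_id,
    z_A = both$z_det_A,
    z_B = both$z_det_B,
    theta = atan2(dax, dtrans) * 180 / pi,
    unit_A = both$unit_A,
    unit_B = both$unit_B,
    z_true = both$z_true
  )
}

#' Oblique-LOR suppression cuts
#'
#' `cut_spec()` bundles the two cut parameters: the acceptance angle
#' `theta_AA` used for axially continuous strip detectors, and the maximum
#' ring (detection-unit) difference used for block-structured crystal
#' scanners.
#'
#' @param theta_AA Acceptance angle in degrees from the transaxial plane
#'   (LORs with `theta <= theta_AA` are kept); `NULL` if unused.
#' @param max_ring_difference Maximum |unit_A - unit_B| kept; `NULL` if
#'   unused.
#' @return A `cut_spec` list.
#' @export
#' @examples
#' cut_spec(theta_AA = 57)
#' cut_spec(max_ring_difference = 5)
cut_spec <- function(theta_AA = NULL, max_ring_difference = NULL) {
  if (!is.null(theta_AA) && (theta_AA <= 0 || theta_AA > 90)) {
    abort("theta_AA must lie in (0, 90]")
  }
  if (!is.null(max_ring_difference) && max_ring_difference < 0) {
    abort("max_ring_difference must be >= 0")
  }
  structure(
    list(theta_AA = theta_AA, max_ring_difference = max_ring_difference),
    class = "cut_spec"
  )
}

#' @rdname cut_spec
#' @description
#' `default_cut()` returns the cut recorded in a bundled design's config:
#' `theta_AA = 57` degrees for strip-family designs and the ring-difference
#' count equivalent to the same angle for crystal-family designs (5 units
#' for the full uEXPLORER-like segmentation).
#' @param design A `pet_design`.
#' @export
default_cut <- function(design) {
  stopifnot(inherits(design, "pet_design"))
  cfg <- design$cut
  if (is.null(cfg)) {
    if (design$family == "strip") {
      return(cut_spec(theta_AA = 57))
    }
    return(cut_spec(max_ring_difference = equivalent_ring_cut(design)))
  }
  if (identical(cfg$type, "acceptance_angle")) {
    cut_spec(theta_AA = cfg$theta_AA)
  } else {
    cut_spec(max_ring_difference = cfg$max_ring_difference)
  }
}

#' Ring-difference count equivalent to an acceptance angle
#'
#' Number of detection-unit pitches spanned axially by an LOR at the given
#' acceptance angle across the detector bore, rounded to the nearest count.
#' Reproduces the 5-unit cut for the 24.35 cm uEXPLORER-like unit pitch at
#' 57 degrees, and large (ineffective) counts for short-AFOV scanners whose
#' LORs all lie inside the cut.
#'
#' @param design A crystal-family `pet_design`.
#' @param theta_AA Acceptance angle in degrees.
#' @return Integer ring-difference count.
#' @export
equivalent_ring_cut <- function(design, theta_AA = 57) {
  stopifnot(design$family == "crystal")
  s <- design$spec
  pitch <- s$unit_axial_length + s$inter_unit_gap
  as.integer(round(tan(theta_AA * pi / 180) * 2 * s$ring_inner_radius / pitch))
}

#' @rdname cut_spec
#' @description
#' `apply_angle_cut()` keeps coincidences with `theta <= theta_AA`
#' (boundary inclusive); `apply_ring_difference_cut()` keeps those with
#' `|unit_A - unit_B| <= max_ring_difference`. Both are idempotent and
#' order-independent.
#' @param records Coincidence tibble from [build_coincidences()].
#' @param cut A `cut_spec`.
#' @param convention Reference plane for `theta_AA`: `"transaxial"`
#'   (default; larger theta = more oblique) or `"axial"` (the complement).
#' @export
apply_angle_cut <- function(records, cut, convention = c("transaxial", "axial")) {
  convention <- match.arg(convention)
  if (is.null(cut$theta_AA)) abort("cut spec has no theta_AA")
  if (convention == "transaxial") {
    dplyr::filter(records, .data$theta <= cut$theta_AA)
  } else {
    dplyr::filter(records, 90 - .data$theta <= cut$theta_AA)
  }
}

#' @rdname cut_spec
#' @export
apply_ring_difference_cut <- function(records, cut) {
  if (is.null(cut$max_ring_difference)) abort("cut spec has no max_ring_difference")
  dplyr::filter(records, abs(.data$unit_A - .data$unit_B) <= cut$max_ring_difference)
}

#' @rdname cut_spec
#' @description
#' `apply_cut()` dispatches on the fields present in the cut spec: the angle
#' cut when `theta_AA` is set, the ring-difference cut when
#' `max_ring_difference` is set.
#' @export
apply_cut <- function(records, cut) {
  if (!is.null(cut$theta_AA)) {
    apply_angle_cut(records, cut)
  } else {
    apply_ring_difference_cut(records, cut)
  }
}

#' Write a coincidence list-mode CSV
#'
#' @param records Coincidence tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coincidences <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}
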