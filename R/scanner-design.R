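#' Build a scanner design
#'
#' Constructs a validated `pet_design` object, either from the bundled design
#' library (by name) or from a complete custom specification. Two detector
#' families are supported:
#'
#' * `"crystal"` — radially arranged scintillation crystals grouped into
#'   axial detection units (rings) of blocks, as in uEXPLORER-like and
#'   Biograph Vision-like tomographs. The axial extent is
#'   `n_units * unit_axial_length + (n_units - 1) * inter_unit_gap`.
#' * `"strip"` — axially arranged plastic scintillator strips in concentric
#'   layers read out at both ends, as in J-PET-like tomographs. The axial
#'   extent equals the strip length.
#'
#' @param config A design name (see [design_names()]) or a named list with at
#'   least `name`, `family`, `material` and the family-specific geometry
#'   fields (see [crystal_spec()] and [strip_spec()]).
#' @param ... Field overrides applied on top of `config` when `config` is a
#'   bundled design name.
#' @return A `pet_design` object.
#' @export
#' @examples
#' d <- build_design("biograph_vision")
#' axial_extent(d)
build_design <- function(config, ...) {
  if (is.character(config) && length(config) == 1) {
    config <- design_config(config)
  }
  if (!is.list(config)) abort("config must be a design name or a named list")
  dots <- list(...)
  config[names(dots)] <- dots
  family <- config$family %||% abort("design config needs a 'family' field")
  if (!family %in% c("crystal", "strip")) {
    abort("family must be 'crystal' or 'strip'")
  }
  mat <- config$material
  if (is.character(mat)) mat <- material(mat)
  spec <- if (family == "crystal") {
    do.call(crystal_spec, config[intersect(names(config), names(formals(crystal_spec)))])
  } else {
    do.call(strip_spec, config[intersect(names(config), names(formals(strip_spec)))])
  }
  d <- new_pet_design(
    name = config$name %||% "custom",
    family = family,
    spec = spec,
    material = mat,
    cut = config$cut %||% NULL
  )
  if (!is.null(config$afov) && abs(d$afov - config$afov) > 0.05) {
    abort(sprintf(
      "derived axial extent %.3f cm disagrees with cataloged AFOV %.3f cm",
      d$afov, config$afov
    ))
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Crystal-family geometry specification
#'
#' Describes a barrel of radially oriented crystals grouped into `n_units`
#' axial detection units, each holding `n_blocks_per_ring` transaxial blocks.
#' Crystal counts enter only the covered-area and volume accounting; photon
#' transport treats the barrel as an attenuating shell of depth
#' `crystal_depth` with an axial occupancy mask and a surface packing
#' fraction.
#'
#' @param n_units Number of axial detection units (rings).
#' @param unit_axial_length Axial length of one unit (cm).
#' @param inter_unit_gap Axial gap between adjacent units (cm).
#' @param n_blocks_per_ring Transaxial blocks per unit.
#' @param n_crystals_axial Crystals along z per unit.
#' @param n_crystals_transaxial Crystals along the circumference per block.
#' @param crystal_transaxial,crystal_axial,crystal_depth Crystal dimensions (cm).
#' @param ring_inner_radius Inner radius of the crystal shell (cm).
#' @param packing_fraction Fraction of the barrel surface that is active
#'   scintillator (absorbs inter-crystal and inter-block gaps).
#' @param energy_acceptance Probability that an interacting photon passes the
#'   energy window (photopeak-type acceptance).
#' @param occupancy Logical matrix `n_units x n_blocks_per_ring` (or a
#'   per-unit logical vector, recycled over blocks), `TRUE` where a block is
#'   populated. Also accepts `"full"` or `"alternating"`.
#' @return A list of class `crystal_spec`.
#' @export
crystal_spec <- function(n_units,
                         unit_axial_length,
                         inter_unit_gap = 0,
                         n_blocks_per_ring = 1,
                         n_crystals_axial = 1,
                         n_crystals_transaxial = 1,
                         crystal_transaxial,
                         crystal_axial,
                         crystal_depth,
                         ring_inner_radius,
                         packing_fraction = 0.85,
                         energy_acceptance = 1,
                         occupancy = "full") {
  stopifnot(length(n_units) == 1)
  if (n_units < 1) abort("n_units must be at least 1")
  dims <- c(
    unit_axial_length = unit_axial_length, crystal_transaxial = crystal_transaxial,
    crystal_axial = crystal_axial, crystal_depth = crystal_depth,
    ring_inner_radius = ring_inner_radius
  )
  if (any(dims <= 0)) {
    abort(paste0("non-positive dimension: ", paste(names(dims)[dims <= 0], collapse = ", ")))
  }
  if (inter_unit_gap < 0) abort("inter_unit_gap must be >= 0")
  if (packing_fraction <= 0 || packing_fraction > 1) abort("packing_fraction must be in (0, 1]")
  if (energy_acceptance < 0 || energy_acceptance > 1) abort("energy_acceptance must be in [0, 1]")
  occ <- normalize_occupancy(occupancy, n_units, n_blocks_per_ring)
  structure(
    list(
      n_units = as.integer(n_units),
      unit_axial_length = unit_axial_length,
      inter_unit_gap = inter_unit_gap,
      n_blocks_per_ring = as.integer(n_blocks_per_ring),
      n_crystals_axial = as.integer(n_crystals_axial),
      n_crystals_transaxial = as.integer(n_crystals_transaxial),
      crystal_transaxial = crystal_transaxial,
      crystal_axial = crystal_axial,
      crystal_depth = crystal_depth,
      ring_inner_radius = ring_inner_radius,
      packing_fraction = packing_fraction,
      energy_acceptance = energy_acceptance,
      occupancy = occ
    ),
    class = "crystal_spec"
  )
}

normalize_occupancy <- function(occupancy, n_units, n_blocks) {
  if (is.character(occupancy)) {
    occupancy <- switch(occupancy,
      full = matrix(TRUE, n_units, n_blocks),
      alternating = matrix(rep(seq_len(n_units) %% 2 == 1, n_blocks), n_units, n_blocks),
      abort(paste0("unknown occupancy keyword: '", occupancy, "'"))
    )
  }
  if (is.vector(occupancy) && !is.matrix(occupancy)) {
    if (length(occupancy) != n_units) {
      abort("per-unit occupancy vector must have one flag per unit")
    }
    occupancy <- matrix(rep(as.logical(occupancy), n_blocks), n_units, n_blocks)
  }
  if (!is.matrix(occupancy) || !identical(dim(occupancy), c(as.integer(n_units), as.integer(n_blocks)))) {
    abort("occupancy mask must be n_units x n_blocks_per_ring")
  }
  storage.mode(occupancy) <- "logical"
  occupancy
}

#' Strip-family geometry specification
#'
#' Describes concentric layers of axial plastic scintillator strips with SiPM
#' readout on both strip ends, plus wavelength-shifting (WLS) readouts that
#' enter only the photosensor covered-area accounting.
#'
#' @param n_layers Number of concentric strip layers (2, 3 or 4 for the
#'   bundled designs).
#' @param strip_length Strip (and scanner axial) length, cm.
#' @param strip_width Transaxial strip width, cm.
#' @param strip_thickness Radial strip thickness, cm.
#' @param layer_radii Inner radius of each layer, cm; strictly increasing.
#' @param n_strips_per_layer Strips per layer; defaults to the densest
#'   azimuthal tiling `floor(2 * pi * r / strip_width)`.
#' @param wls_unit_area Photosensor face area per WLS readout, cm^2
#'   (default the 3 mm x 6 mm face).
#' @param n_wls_readouts Number of WLS readout channels; defaults to one per
#'   scintillator strip.
#' @param azimuthal_fill Fraction of each layer's circumference covered by
#'   active strip material.
#' @param energy_threshold_keV Energy-loss threshold for accepting a Compton
#'   interaction in plastic (keV).
#' @return A list of class `strip_spec`.
#' @export
strip_spec <- function(n_layers,
                       strip_length,
                       strip_width,
                       strip_thickness,
                       layer_radii,
                       n_strips_per_layer = NULL,
                       wls_unit_area = 0.3 * 0.6,
                       n_wls_readouts = NULL,
                       azimuthal_fill = 0.98,
                       energy_threshold_keV = 200) {
  n_layers <- as.integer(n_layers)
  if (n_layers < 1) abort("n_layers must be at least 1")
  if (length(layer_radii) != n_layers) abort("layer_radii must have one radius per layer")
  if (any(diff(layer_radii) <= 0)) abort("layer radii must be strictly increasing")
  if (strip_length <= 0 || strip_width <= 0 || strip_thickness <= 0) {
    abort("non-positive dimension in strip spec")
  }
  if (is.null(n_strips_per_layer)) {
    n_strips_per_layer <- floor(2 * pi * layer_radii / strip_width)
  }
  n_strips_per_layer <- as.integer(n_strips_per_layer)
  if (length(n_strips_per_layer) == 1) n_strips_per_layer <- rep(n_strips_per_layer, n_layers)
  if (is.null(n_wls_readouts)) n_wls_readouts <- sum(n_strips_per_layer)
  if (energy_threshold_keV < 0 || energy_threshold_keV > 511) {
    abort("energy_threshold_keV must lie in [0, 511]")
  }
  structure(
    list(
      n_layers = n_layers,
      strip_length = strip_length,
      strip_width = strip_width,
      strip_thickness = strip_thickness,
      layer_radii = as.numeric(layer_radii),
      n_strips_per_layer = n_strips_per_layer,
      wls_unit_area = wls_unit_area,
      n_wls_readouts = as.integer(n_wls_readouts),
      azimuthal_fill = azimuthal_fill,
      energy_threshold_keV = energy_threshold_keV
    ),
    class = "strip_spec"
  )
}

new_pet_design <- function(name, family, spec, material, cut = NULL) {
  d <- structure(
    list(name = name, family = family, spec = spec, material = material, cut = cut),
    class = "pet_design"
  )
  d$afov <- axial_extent(d)
  if (d$afov <= 0) abort("design has non-positive axial extent")
  d
}

#' @export
print.pet_design <- function(x, ...) {
  cat(sprintf(
    "<pet_design> %s [%s, %s]\n  AFOV %.1f cm | photosensor area %.0f cm^2 | scintillator %.0f cm^3\n",
    x$name, x$family, x$material$name, x$afov, pm_covered_area(x), scintillator_volume(x)
  ))
  invisible(x)
}

#' Axial extent (AFOV) of a design
#'
#' Total axial span of the detector, including inter-unit gaps for
#' crystal-family designs; equals the strip length for strip-family designs.
#'
#' @param design A `pet_design`.
#' @return Axial extent in cm.
#' @export
axial_extent <- function(design) {
  stopifnot(inherits(design, "pet_design"))
  s <- design$spec
  if (design$family == "crystal") {
    s$n_units * s$unit_axial_length + (s$n_units - 1) * s$inter_unit_gap
  } else {
    s$strip_length
  }
}

#' Photosensor (photomultiplier) covered area
#'
#' Total area of photosensor-coupled faces: for crystal-family designs the
#' sum over populated crystals of the crystal end face
#' (`crystal_transaxial * crystal_axial`); for strip-family designs both end
#' faces of every strip (`2 * strip_width * strip_thickness`) plus the WLS
#' readout faces (`n_wls_readouts * wls_unit_area`).
#'
#' @param design A `pet_design`.
#' @return Covered area in cm^2.
#' @export
pm_covered_area <- function(design) {
  stopifnot(inherits(design, "pet_design"))
  s <- design$spec
  if (design$family == "crystal") {
    n_cry <- sum(s$occupancy) * s$n_crystals_axial * s$n_crystals_transaxial
    n_cry * s$crystal_transaxial * s$crystal_axial
  } else {
    sum(s$n_strips_per_layer) * 2 * s$strip_width * s$strip_thickness +
      s$n_wls_readouts * s$wls_unit_area
  }
}

#' Total scintillator volume
#'
#' @param design A `pet_design`.
#' @return Volume of populated scintillator elements in cm^3.
#' @export
scintillator_volume <- function(design) {
  stopifnot(inherits(design, "pet_design"))
  s <- design$spec
  if (design$family == "crystal") {
    n_cry <- sum(s$occupancy) * s$n_crystals_axial * s$n_crystals_transaxial
    n_cry * s$crystal_transaxial * s$crystal_axial * s$crystal_depth
  } else {
    sum(s$n_strips_per_layer) * s$strip_width * s$strip_thickness * s$strip_length
  }
}

#' Remove detector blocks according to an occupancy mask
#'
#' Applies a sparsity pattern to a crystal-family design: masked blocks are
#' removed, so covered area and scintillator volume scale with the mask fill
#' factor, and photon transport sees the corresponding axial gaps.
#'
#' @param design A crystal-family `pet_design`.
#' @param pattern Logical mask, `n_units x n_blocks_per_ring` (or a per-unit
#'   vector recycled over blocks); combined (AND) with the current occupancy.
#' @return The sparsified `pet_design`.
#' @export
#' @examples
#' full <- build_design("uexplorer_full_lyso_194")
#' half <- sparsify(full, rep(c(TRUE, FALSE), length.out = 8))
#' pm_covered_area(half) / pm_covered_area(full)
sparsify <- function(design, pattern) {
  stopifnot(inherits(design, "pet_design"))
  if (design$family != "crystal") abort("sparsify applies to crystal-family designs")
  s <- design$spec
  pattern <- normalize_occupancy(pattern, s$n_units, s$n_blocks_per_ring)
  s$occupancy <- s$occupancy & pattern
  design$spec <- s
  design
}

#' Axial detection-unit table
#'
#' Axial start/end of every detection unit together with its azimuthal block
#' fill factor; the basis of sparse-geometry transport and of the
#' ring-difference coincidence cut.
#'
#' @param design A `pet_design`.
#' @return A tibble with columns `unit`, `z_start`, `z_end`, `fill`. For
#'   strip-family designs a single unit spanning the whole AFOV.
#' @export
unit_table <- function(design) {
  stopifnot(inherits(design, "pet_design"))
  s <- design$spec
  if (design$family == "crystal") {
    pitch <- s$unit_axial_length + s$inter_unit_gap
    z0 <- -design$afov / 2
    # ends computed on the same float grid as the next unit's start, so the
    # interleaved edge vector is exactly non-decreasing
    tibble::tibble(
      unit = seq_len(s$n_units),
      z_start = z0 + (seq_len(s$n_units) - 1) * pitch,
      z_end = z0 + seq_len(s$n_units) * pitch - s$inter_unit_gap,
      fill = rowMeans(s$occupancy)
    )
  } else {
    tibble::tibble(
      unit = 1L, z_start = -design$afov / 2, z_end = design$afov / 2, fill = 1
    )
  }
}

#' Summarize one or more designs
#'
#' @param designs A `pet_design` or a list of them.
#' @return A tibble with one row per design: name, family, material, AFOV,
#'   photosensor covered area, and scintillator volume.
#' @export
design_summary <- function(designs) {
  if (inherits(designs, "pet_design")) designs <- list(designs)
  purrr::map_dfr(designs, function(d) {
    tibble::tibble(
      design = d$name,
      family = d$family,
      material = d$material$name,
      afov_cm = d$afov,
      pm_covered_area_cm2 = pm_covered_area(d),
      scintillator_volume_cm3 = scintillator_volume(d)
    )
  })
}

#' Ideal-barrel design for geometry-only studies
#'
#' A continuous single-unit crystal barrel made of the perfectly absorbing
#' `ideal` material with unit packing and energy acceptance: any photon whose
#' ray crosses the shell is detected. Used for solid-angle cross-checks.
#'
#' @param ring_inner_radius Barrel inner radius, cm.
#' @param afov Barrel axial length, cm.
#' @return A `pet_design`.
#' @export
ideal_barrel_design <- function(ring_inner_radius = 39.3, afov = 194.8) {
  new_pet_design(
    name = "ideal_barrel",
    family = "crystal",
    spec = crystal_spec(
      n_units = 1, unit_axial_length = afov, inter_unit_gap = 0,
      crystal_transaxial = 0.1, crystal_axial = 0.1, crystal_depth = 1,
      ring_inner_radius = ring_inner_radius,
      packing_fraction = 1, energy_acceptance = 1
    ),
    material = material("ideal")
  )
}
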