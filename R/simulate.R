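#' Simulate one scanner design end to end
#'
#' Runs the full pipeline for one design and one measurement setup: sample
#' annihilation events from the line source, propagate both photons through
#' the (optional) water phantom and the detector, draw detections, pair true
#' coincidences, optionally apply the design's oblique-LOR cut, and bin the
#' result into a per-slice sensitivity profile.
#'
#' @param design A `pet_design` or bundled design name.
#' @param n_events Number of annihilations to simulate.
#' @param seed Master seed; every random stage derives its stream from it,
#'   so identical arguments give identical results.
#' @param source A [line_source()].
#' @param phantom `NULL`, `TRUE` (default [water_phantom()]), or a
#'   [water_phantom()] spec.
#' @param cut `NULL` for no cut, `TRUE` for the design's [default_cut()], or
#'   a [cut_spec()].
#' @param slice_width Axial slice width `d`, cm.
#' @param keep_coincidences Keep the coincidence tibble in the result.
#' @return A `pet_sim` object: the design, the [sensitivity_profile()], the
#'   [total_body_sensitivity()] row, counts, duration and run metadata.
#' @export
#' @examples
#' sim <- simulate_design("biograph_vision", n_events = 2e4, seed = 7)
#' glance(sim)
simulate_design <- function(design, n_events, seed = 1,
                            source = line_source(),
                            phantom = NULL,
                            cut = NULL,
                            slice_width = 1,
                            keep_coincidences = FALSE) {
  if (is.character(design)) design <- build_design(design)
  stopifnot(inherits(design, "pet_design"))
  if (n_events <= 0) abort("n_events must be positive")
  if (isTRUE(phantom)) phantom <- water_phantom()
  cut_used <- if (isTRUE(cut)) {
    default_cut(design)
  } else if (isFALSE(cut)) {
    NULL
  } else {
    cut
  }
  t0 <- Sys.time()
  events <- sample_events(source, n_events, seed = seed)
  hits <- trace_photons(events, design, phantom = phantom, seed = seed)
  coins <- build_coincidences(hits)
  n_raw <- nrow(coins)
  if (!is.null(cut_used)) coins <- apply_cut(coins, cut_used)
  duration <- duration_for(n_events, source)
  half_span <- max(source$length, design$afov) / 2
  rates <- slice_rates(coins, duration, slice_width = slice_width,
                       axial_range = c(-half_span, half_span))
  profile <- sensitivity_profile(rates, source, slice_width = slice_width)
  tb <- total_body_sensitivity(profile)
  structure(
    list(
      design = design,
      profile = profile,
      tb = tb,
      n_events = n_events,
      n_coincidences_raw = n_raw,
      n_coincidences = nrow(coins),
      duration = duration,
      seed = seed,
      phantom = phantom,
      cut = cut_used,
      slice_width = slice_width,
      coincidences = if (keep_coincidences) coins else NULL,
      runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "pet_sim"
  )
}

#' @export
print.pet_sim <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<pet_sim> %s | %s events, seed %s\n",
      "  phantom: %s | cut: %s\n",
      "  coincidences: %d (%.2f%% of events) | S_TB = %.2f cps/kBq\n"
    ),
    x$design$name, format(x$n_events, big.mark = ","), x$seed,
    if (is.null(x$phantom)) "none" else "water cylinder",
    cut_label(x$cut),
    x$n_coincidences, 100 * x$n_coincidences / x$n_events, x$tb$S_TB
  ))
  invisible(x)
}

cut_label <- function(cut) {
  if (is.null(cut)) {
    "none"
  } else if (!is.null(cut$theta_AA)) {
    sprintf("theta <= %g deg", cut$theta_AA)
  } else {
    sprintf("|ring diff| <= %d", cut$max_ring_difference)
  }
}

#' @export
tidy.pet_sim <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$profile), design = x$design$name,
                .before = 1)
}

#' @export
glance.pet_sim <- function(x, ...) {
  central <- central_sensitivity(x$profile)
  tibble::tibble(
    design = x$design$name,
    family = x$design$family,
    material = x$design$material$name,
    afov_cm = x$design$afov,
    n_events = x$n_events,
    n_coincidences = x$n_coincidences,
    central_sensitivity = central,
    S_TB = x$tb$S_TB,
    pm_covered_area_cm2 = pm_covered_area(x$design),
    scintillator_volume_cm3 = scintillator_volume(x$design),
    phantom = !is.null(x$phantom),
    cut = cut_label(x$cut),
    seed = x$seed
  )
}

#' Central-slice sensitivity of a profile
#'
#' Mean sensitivity of the slices within `half_width` of the scanner centre;
#' a short central average damps single-slice Monte Carlo noise.
#'
#' @param profile A [sensitivity_profile()].
#' @param half_width Half-width of the central window, cm.
#' @return Central sensitivity, cps/kBq.
#' @export
central_sensitivity <- function(profile, half_width = 2.5) {
  mean(profile$sensitivity[abs(profile$slice_center) <= half_width])
}

#' Simulate a grid of designs
#'
#' @param designs Character vector of design names or list of `pet_design`
#'   objects; defaults to the full bundled library.
#' @param n_events,seed,source,phantom,cut,slice_width Passed to
#'   [simulate_design()] (the same master seed is reused for every design,
#'   which couples the runs through common random numbers).
#' @return A named list of `pet_sim` objects.
#' @export
run_design_grid <- function(designs = design_names(), n_events = 2e6, seed = 1,
                            source = line_source(), phantom = NULL,
                            cut = NULL, slice_width = 1) {
  if (is.character(designs)) designs <- design_library(designs)
  if (inherits(designs, "pet_design")) designs <- list(designs)
  sims <- purrr::map(designs, function(d) {
    simulate_design(d, n_events = n_events, seed = seed, source = source,
                    phantom = phantom, cut = cut, slice_width = slice_width)
  })
  stats::setNames(sims, purrr::map_chr(sims, function(s) s$design$name))
}

#' Rank simulated designs by cost-normalised figure of merit
#'
#' Combines per-design summaries with the cost model: relative cost and
#' TB-FOM against a reference design (the 194.8 cm full LYSO uEXPLORER-like
#' build by default), sorted by TB-FOM. The covered-area column provides the
#' sensitivity-versus-photosensor-area scatter data.
#'
#' @param sims A list of `pet_sim` objects (e.g. from [run_design_grid()]),
#'   or a pre-built [glance()] tibble that includes the reference design.
#' @param reference Name of the reference design.
#' @return A tibble sorted by decreasing `tb_fom`, with `relative_cost` and
#'   `tb_fom` columns added; the reference design has `tb_fom = 1`.
#' @export
compare_designs <- function(sims, reference = "uexplorer_full_lyso_194") {
  if (inherits(sims, "pet_sim")) sims <- list(sims)
  if (is.data.frame(sims)) {
    summaries <- sims
    designs <- design_library(summaries$design)
  } else {
    if (length(sims) == 0) abort("no summaries to compare")
    summaries <- purrr::map_dfr(sims, glance)
    designs <- purrr::map(sims, function(s) s$design)
  }
  ref_design <- build_design(reference)
  ref_row <- dplyr::filter(summaries, .data$design == reference)
  if (nrow(ref_row) == 0) {
    abort(paste0("reference design '", reference, "' is not among the summaries"))
  }
  ref_stb <- ref_row$S_TB[1]
  cost <- unname(purrr::map_dbl(designs, relative_cost, reference = ref_design))
  out <- dplyr::mutate(
    summaries,
    relative_cost = cost,
    tb_fom = (.data$S_TB / cost) / ref_stb
  )
  dplyr::arrange(out, dplyr::desc(.data$tb_fom))
}
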