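#' The bundled scanner design library
#'
#' Seventeen parametric tomograph configurations are shipped as plain-text
#' YAML files under `inst/extdata/designs`: eight uEXPLORER-like crystal
#' scanners (LYSO/BGO x 194.8/97.4 cm AFOV x full/sparse), eight J-PET-like
#' plastic-strip scanners (2/3/4 layers, 4x20 or 6x30 mm strip cross
#' section, 200/250 cm AFOV), and a Biograph Vision-like clinical reference.
#' Each file also carries the cataloged AFOV and the design's default
#' oblique-LOR cut.
#'
#' @return `design_names()` returns the sorted vector of bundled design
#'   names; `design_config(name)` the raw named list read from the YAML
#'   file; `design_library(names)` a named list of built [build_design()]
#'   objects.
#' @export
design_names <- function() {
  files <- list.files(design_dir(), pattern = "\\.yaml$")
  sort(sub("\\.yaml$", "", files))
}

design_dir <- function() {
  system.file("extdata", "designs", package = "tbpetsim", mustWork = TRUE)
}

#' @rdname design_names
#' @param name A bundled design name.
#' @export
design_config <- function(name) {
  path <- file.path(design_dir(), paste0(name, ".yaml"))
  if (!file.exists(path)) {
    abort(paste0(
      "unknown design name: '", name, "'. Available: ",
      paste(design_names(), collapse = ", ")
    ))
  }
  yaml::read_yaml(path)
}

#' @rdname design_names
#' @param names Design names to build; defaults to the full library.
#' @export
design_library <- function(names = design_names()) {
  designs <- lapply(names, build_design)
  stats::setNames(designs, names)
}

#' Cataloged axial field of view of a bundled design
#'
#' @param name A bundled design name.
#' @return The AFOV recorded in the design's config file, cm.
#' @export
cataloged_afov <- function(name) {
  design_config(name)$afov
}
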