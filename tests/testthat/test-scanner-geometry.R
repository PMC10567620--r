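test_that("every bundled design builds and reproduces its cataloged AFOV", {
  nms <- design_names()
  expect_length(nms, 17)
  for (nm in nms) {
    d <- build_design(nm)
    expect_s3_class(d, "pet_design")
    expect_equal(axial_extent(d), cataloged_afov(nm), tolerance = 0.05 / cataloged_afov(nm))
  }
})

test_that("clinical-reference geometry assembles to the printed dimensions", {
  d <- build_design("biograph_vision")
  expect_equal(axial_extent(d), 26.3, tolerance = 1e-9)
  # 8 rings x 38 panels x 20 x 10 crystals with a 3.2 x 3.2 mm face
  expect_equal(pm_covered_area(d), 60800 * 0.32 * 0.32, tolerance = 1e-12)
  u <- build_design("uexplorer_full_bgo_194")
  expect_equal(axial_extent(u), 194.8, tolerance = 1e-9)
})

test_that("axial extent arithmetic covers gaps and single units", {
  two <- tiny_barrel(n_units = 2, ual = 10, gap = 1)
  expect_equal(axial_extent(two), 21)
  one <- tiny_barrel(n_units = 1, ual = 3.2)
  expect_equal(axial_extent(one), 3.2)
})

test_that("covered area and volume follow the element arithmetic", {
  # one plastic strip, 6 x 30 mm cross section, both end faces, no WLS
  strip1 <- build_design(list(
    name = "one_strip", family = "strip", material = "plastic",
    n_layers = 1, strip_length = 200, strip_width = 0.6, strip_thickness = 3,
    layer_radii = 41.5, n_strips_per_layer = 1, n_wls_readouts = 0
  ))
  expect_equal(pm_covered_area(strip1), 3.6)
  expect_equal(scintillator_volume(strip1), 0.6 * 3 * 200)

  cry1 <- build_design(list(
    name = "one_crystal", family = "crystal", material = "LSO",
    n_units = 1, unit_axial_length = 0.32, n_blocks_per_ring = 1,
    n_crystals_axial = 1, n_crystals_transaxial = 1,
    crystal_transaxial = 0.32, crystal_axial = 0.32, crystal_depth = 2,
    ring_inner_radius = 39.3
  ))
  expect_equal(scintillator_volume(cry1), 0.2048)
  expect_equal(pm_covered_area(cry1), 0.1024)
})

test_that("sparsification scales area and volume by the fill factor", {
  full <- tiny_barrel(n_units = 10)
  same <- sparsify(full, matrix(TRUE, 10, 4))
  expect_equal(pm_covered_area(same), pm_covered_area(full))
  expect_identical(same$spec$occupancy, full$spec$occupancy)

  alt <- sparsify(full, rep(c(TRUE, FALSE), 5))
  expect_equal(sum(rowSums(alt$spec$occupancy) > 0), 5)
  expect_equal(pm_covered_area(alt), pm_covered_area(full) / 2)

  set.seed(42)
  mask <- matrix(runif(40) < 0.5, 10, 4)
  rnd <- sparsify(full, mask)
  f <- mean(mask)
  expect_equal(pm_covered_area(rnd), f * pm_covered_area(full))
  expect_equal(scintillator_volume(rnd), f * scintillator_volume(full))

  expect_error(sparsify(full, matrix(TRUE, 3, 4)), "occupancy")
  expect_error(sparsify(build_design("jpet_2l_6x30_200"), mask), "crystal")
})

test_that("bundled sparse variants have close to half the covered area", {
  for (m in c("bgo", "lyso")) {
    for (L in c("194", "97")) {
      full <- build_design(sprintf("uexplorer_full_%s_%s", m, L))
      sparse <- build_design(sprintf("uexplorer_sparse_%s_%s", m, L))
      ratio <- pm_covered_area(sparse) / pm_covered_area(full)
      expect_gt(ratio, 0.45)
      expect_lt(ratio, 0.55)
    }
  }
})

test_that("degenerate or unknown configurations are rejected", {
  expect_error(build_design("no_such_scanner"), "unknown design")
  expect_error(tiny_barrel(n_units = 0), "n_units")
  expect_error(build_design(list(
    name = "bad", family = "crystal", material = "BGO",
    n_units = 2, unit_axial_length = -5, crystal_transaxial = 0.3,
    crystal_axial = 0.3, crystal_depth = 2, ring_inner_radius = 20
  )), "non-positive")
  expect_error(build_design(list(
    name = "bad", family = "strip", material = "plastic",
    n_layers = 2, strip_length = 200, strip_width = 0.6, strip_thickness = 3,
    layer_radii = c(45, 41)
  )), "increasing")
})

test_that("design summaries collect one row per design", {
  lib <- design_library(c("biograph_vision", "jpet_2l_4x20_200"))
  s <- design_summary(lib)
  expect_equal(nrow(s), 2)
  expect_named(s, c("design", "family", "material", "afov_cm",
                    "pm_covered_area_cm2", "scintillator_volume_cm3"))
  expect_equal(s$afov_cm, c(26.3, 200))
})
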