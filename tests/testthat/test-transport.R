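test_that("water path lengths match exact cylinder/slab geometry", {
  ph <- water_phantom() # 20 cm diameter x 183 cm
  # center, purely transaxial: the phantom radius
  expect_equal(water_path(event_row(dx = 1, dy = 0, dz = 0), ph), 10)
  # center, purely axial: half the phantom length
  expect_equal(water_path(event_row(dx = 0, dy = 0, dz = 1), ph), 91.5)
  # no phantom configured
  expect_equal(water_path(event_row(), NULL), 0)
  # emitted beyond the end cap: photon B (antiparallel) re-enters and
  # crosses the whole phantom, photon A never enters
  far <- event_row(z = 100, dx = 0, dy = 0, dz = 1)
  expect_equal(water_path(far, ph, "A"), 0)
  expect_equal(water_path(far, ph, "B"), 183)
  # oblique from center: exits through the barrel side
  ob <- event_row(dx = sqrt(0.5), dy = 0, dz = sqrt(0.5))
  expect_equal(water_path(ob, ph), 10 / sqrt(0.5))
})

test_that("survival and interaction probabilities follow the exponential law", {
  expect_equal(survival_probability(0, 0.096), 1)
  expect_equal(survival_probability(10, 0.096), exp(-0.96))
  expect_equal(survival_probability(10, 0.096), 0.3829, tolerance = 1e-4)
  expect_lt(survival_probability(20, 0.096), survival_probability(10, 0.096))
  expect_error(survival_probability(-1, 0.1), ">= 0")

  bgo <- material("BGO")
  lyso <- material("LYSO")
  expect_equal(interaction_probability(0, bgo), 0)
  expect_equal(interaction_probability(1.81, bgo), 1 - exp(-0.955 * 1.81))
  expect_equal(interaction_probability(1.81, bgo), 0.8222, tolerance = 5e-4)
  expect_gt(interaction_probability(1, bgo), interaction_probability(1, lyso))
})

test_that("detector chords match closed-form and ray-marching oracles", {
  barrel <- tiny_barrel(n_units = 1, ual = 400, radius = 20, depth = 2)
  # normal incidence: chord equals the crystal depth
  h0 <- trace_photons(event_row(dx = 1, dy = 0, dz = 0), barrel, draw = FALSE)
  expect_equal(h0$path_detector, rep(2, 2))
  # oblique from the axis: chord = depth / cos(theta) for a full barrel
  for (theta in c(10, 30, 55, 70) * pi / 180) {
    ev <- event_row(dx = cos(theta), dy = 0, dz = sin(theta))
    h <- trace_photons(ev, barrel, draw = FALSE)
    expect_equal(h$path_detector[1], 2 / cos(theta), tolerance = 1e-6)
  }
  # axial photon from the center of a barrel-only design escapes
  hax <- trace_photons(event_row(dx = 0, dy = 0, dz = 1), barrel, draw = FALSE)
  expect_equal(hax$path_detector, c(0, 0))
  expect_equal(hax$p_detect, c(0, 0))

  # off-axis random rays against numeric ray marching, including a sparse
  # barrel whose gaps truncate the chord
  sparse <- tiny_barrel(n_units = 8, ual = 5, radius = 20, depth = 2,
                        occupancy = "alternating")
  set.seed(99)
  for (i in 1:6) {
    dz <- runif(1, -0.95, 0.95)
    psi <- runif(1, 0, 2 * pi)
    ev <- event_row(
      x = runif(1, -0.05, 0.05), y = runif(1, -0.05, 0.05), z = runif(1, -15, 15),
      dx = sqrt(1 - dz^2) * cos(psi), dy = sqrt(1 - dz^2) * sin(psi), dz = dz
    )
    for (d in list(barrel, sparse)) {
      got <- trace_photons(ev, d, draw = FALSE)$path_detector[1]
      want <- ray_march_chord(d, ev$x, ev$y, ev$z, ev$dx, ev$dy, ev$dz)
      expect_equal(got, want, tolerance = 2e-3)
    }
  }

  # strip family: summed chords over layers
  jp <- build_design("jpet_2l_6x30_200")
  hj <- trace_photons(event_row(dx = 1, dy = 0, dz = 0), jp, draw = FALSE)
  expect_equal(hj$path_detector, rep(6, 2)) # two 3 cm layers at normal incidence
  evo <- event_row(dx = cos(0.5), dy = 0, dz = sin(0.5))
  hjo <- trace_photons(evo, jp, draw = FALSE)
  want <- ray_march_chord(jp, 0, 0, 0, cos(0.5), 0, sin(0.5))
  expect_equal(hjo$path_detector[1], want, tolerance = 2e-3)
})

test_that("Compton energy-deposit acceptance matches an independent quadrature", {
  expect_equal(compton_accept_fraction(0), 1)
  expect_equal(compton_accept_fraction(340.8), 0) # above the Compton edge
  expect_equal(compton_accept_fraction(511 * 2 / 3 + 0.02), 0)
  # monotone non-increasing in the threshold
  grid <- seq(0, 340, by = 20)
  vals <- vapply(grid, compton_accept_fraction, numeric(1))
  expect_true(all(diff(vals) <= 0))
  # independent electron-energy-domain quadrature
  for (thr in c(50, 200, 300)) {
    expect_equal(compton_accept_fraction(thr), kn_accept_oracle(thr),
                 tolerance = 1e-4)
  }
  expect_error(compton_accept_fraction(-1), "threshold")
  expect_error(compton_accept_fraction(600), "threshold")
})

test_that("detection draws are Bernoulli with the computed probability", {
  n <- 1e5
  hits <- tibble::tibble(p_detect = rep(0.5, n))
  det <- draw_detections(hits, seed = 21)$detected
  expect_equal(mean(det), 0.5, tolerance = 3 * sqrt(0.25 / n) / 0.5)
  expect_false(any(draw_detections(tibble::tibble(p_detect = rep(0, 100)), 1)$detected))
  expect_true(all(draw_detections(tibble::tibble(p_detect = rep(1, 100)), 1)$detected))
  expect_error(draw_detections(tibble::tibble(p_detect = 1.5), 1), "0, 1")
  # deterministic under a fixed seed
  expect_identical(det, draw_detections(hits, seed = 21)$detected)
})

test_that("phantom attenuation lowers every slice, all else equal", {
  sim0 <- simulate_design("uexplorer_full_bgo_97", n_events = 2e5, seed = 31)
  simp <- simulate_design("uexplorer_full_bgo_97", n_events = 2e5, seed = 31,
                          phantom = TRUE)
  expect_true(all(simp$profile$counts <= sim0$profile$counts))
  expect_lt(sum(simp$profile$counts), sum(sim0$profile$counts))
})
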