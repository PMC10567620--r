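fake_records <- function(z) {
  tibble::tibble(
    event_id = seq_along(z), z_A = z, z_B = z, theta = 0,
    unit_A = 1L, unit_B = 1L, z_true = z
  )
}

test_that("slice rates bin counts and conserve them", {
  rec <- fake_records(rep(0.2, 100))
  r <- slice_rates(rec, duration = 10, slice_width = 1, axial_range = c(-5, 5))
  expect_equal(sum(r$counts), 100)
  expect_equal(r$rate[r$slice_center == 0.5], 10)
  expect_equal(sum(r$rate) * 10, 100)

  empty <- slice_rates(fake_records(numeric(0)), duration = 1)
  expect_true(all(empty$rate == 0))
  expect_equal(nrow(empty), 250)

  # out-of-range records are dropped, in-range conserved
  rec2 <- fake_records(c(-10, 0, 0, 3, 99))
  r2 <- slice_rates(rec2, duration = 1, axial_range = c(-5, 5))
  expect_equal(sum(r2$counts), 3)
  expect_error(slice_rates(rec, 1, slice_width = 0), "positive")
})

test_that("slice sensitivity applies the per-slice normalisation", {
  src <- line_source(length = 250, activity = 1000)
  rates <- tibble::tibble(slice_center = 0.5, counts = 1000, rate = 100)
  p <- sensitivity_profile(rates, src, slice_width = 1)
  expect_equal(p$sensitivity, 100 * 250 / (1 * 1000)) # 25 cps/kBq
  p0 <- sensitivity_profile(dplyr::mutate(rates, rate = 0), src)
  expect_equal(p0$sensitivity, 0)
  # doubling the activity at fixed rate halves the sensitivity
  p2 <- sensitivity_profile(rates, line_source(length = 250, activity = 2000))
  expect_equal(p2$sensitivity, p$sensitivity / 2)
  expect_error(sensitivity_profile(rates, line_source(activity = -1)), "positive")
})

test_that("total-body sensitivity averages over the body slices, empty included", {
  src <- line_source(length = 2, activity = 1) # A_body = A_mean over a 2 cm body
  rates <- tibble::tibble(slice_center = c(-0.5, 0.5), counts = c(10, 0),
                          rate = c(10, 0))
  p <- sensitivity_profile(rates, src, slice_width = 1)
  tb <- total_body_sensitivity(p, body_length = 2, A_body = 1)
  expect_equal(tb$N, 2L)
  expect_equal(tb$S_TB, (10 + 0) / (1 * 2)) # 5 cps/kBq

  # uniform rate R across all body slices gives S_TB = R / A_body
  rates_u <- tibble::tibble(slice_center = seq(-91, 91) + 0.5 - 0.5,
                            counts = 7, rate = 7)
  pu <- sensitivity_profile(rates_u, line_source(), slice_width = 1)
  tbu <- total_body_sensitivity(pu, body_length = 183, A_body = 2)
  expect_equal(tbu$N, 183L)
  expect_equal(tbu$S_TB, 7 / 2)
  expect_error(total_body_sensitivity(pu, A_body = 0), "positive")
})

test_that("zero-padding penalises scanners much shorter than the body", {
  # a 26.3 cm scanner's rates vanish outside its AFOV; averaging over the
  # 183 cm body bounds S_TB by the AFOV-filled fraction of the peak
  sim <- simulate_design("biograph_vision", n_events = 2e5, seed = 19)
  peak <- max(sim$profile$sensitivity)
  afov <- sim$design$afov
  expect_lt(sim$tb$S_TB, peak * afov / 183 + 0.01)
  # sharper conservation form: the body-range rate sum is at most the peak
  # slice rate times the number of slices the scanner actually covers
  in_body <- abs(sim$profile$slice_center) <= 91.5
  expect_lte(sum(sim$profile$rate[in_body]),
             max(sim$profile$rate) * ceiling(afov) + 1e-9)
  expect_gt(sim$tb$S_TB, 0)
})

test_that("the cost model reproduces the half/half split", {
  ref <- build_design("uexplorer_full_lyso_194")
  expect_equal(relative_cost(ref, ref), 1)
  # same geometry in BGO (cost weight 0.4): photosensor half unchanged,
  # scintillator half scaled, i.e. a 30% total reduction
  bgo <- build_design("uexplorer_full_bgo_194")
  expect_equal(relative_cost(bgo, ref), 0.5 + 0.5 * 0.4)
  # halving covered area at equal scintillator cost
  half_area <- build_design(
    "uexplorer_full_lyso_194",
    n_crystals_transaxial = 35, n_blocks_per_ring = 12,
    material = material("LYSO", relative_cost_per_volume = 2)
  )
  expect_equal(relative_cost(half_area, ref), 0.5 * 0.5 + 0.5 * 1)
})

test_that("the figure of merit is normalised to the reference design", {
  expect_equal(tb_fom(2, 1, s_tb_ref = 2, cost_ref = 1)$tb_fom, 1)
  expect_equal(tb_fom(4, 1, s_tb_ref = 2)$tb_fom, 2)
  expect_equal(tb_fom(2, 0.5, s_tb_ref = 2)$tb_fom, 2)
  expect_error(tb_fom(1, 0, 1), "positive")
})
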