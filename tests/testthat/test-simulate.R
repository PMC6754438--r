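test_that("simulated events hit their configured kinetic targets", {
  wp <- waveform_params()
  k <- ap_kinetics(simulate_event("AP", wp))
  expect_equal(k$AP_t_APD, wp$ap$apd90_ms, tolerance = 3 / 350)
  expect_equal(k$AP_triangulation, wp$ap$apd90_ms - wp$ap$apd30_ms,
               tolerance = 3 / 150)
  kca <- ca_kinetics(simulate_event("Ca", wp))
  expect_equal(kca$Ca_t_decay, wp$ca$tau_ms * log(2), tolerance = 3 / 83)

  flat <- waveform_params(co = list(baseline = 5, amplitude = 0,
                                    delay_ms = 90, rise_ms = 120,
                                    tau_ms = 130))
  ev <- simulate_event("Co", flat)
  expect_equal(ev$value, rep(5, nrow(ev)))

  bad <- waveform_params()
  bad$ap$apd90_ms <- 1000   # exceeds the 833 ms pacing period
  expect_error(simulate_event("AP", bad), class = "ttm_error_shape")
  expect_error(waveform_params(ap = list(baseline = 100, amplitude = 60,
                                         delay_ms = 60, rise_ms = 10,
                                         apd30_ms = 400, apd90_ms = 350)),
               class = "ttm_error_shape")
})

test_that("MOA perturbation factors follow the hypothesis table", {
  # no-effect drug: all factors 1
  f0 <- moa_effect_factors("none", 0.3)
  expect_equal(f0$factor, rep(1, 10))
  f_same <- moa_effect_factors("Co_same", 0.3)
  expect_equal(f_same$factor, rep(1, 10))

  set.seed(12)
  f <- moa_effect_factors("Co_plus_Ca", 0.3)
  get <- function(p) f$factor[f$parameter == p]
  expect_equal(get("Ca_amplitude"), 1.3)
  expect_equal(get("Co_amplitude"), 1.3)
  expect_equal(get("AP_triangulation"), 0.7)
  expect_equal(get("AP_amplitude"), 1)

  # complement cells never take the excluded direction
  for (s in 1:30) {
    set.seed(s)
    fs <- moa_effect_factors("Co_plus_Ca", 0.3)
    not_down <- fs$factor[fs$effect == "not_down"]
    expect_true(all(not_down %in% c(1, 1.3)))
    not_same <- fs$factor[fs$effect == "not_same"]
    expect_true(all(not_same %in% c(0.7, 1.3)))
  }
})

test_that("waveform perturbation shifts measured kinetics as requested", {
  wp <- waveform_params()
  f <- setNames(rep(1, 10), param_ids())
  f["AP_t_APD"] <- 0.8
  f["AP_triangulation"] <- 0.6
  f["Ca_t_decay"] <- 1.25
  wp2 <- apply_factors(wp, f)
  k <- ap_kinetics(simulate_event("AP", wp2))
  expect_equal(k$AP_t_APD, 0.8 * 350, tolerance = 3 / 280)
  expect_equal(k$AP_triangulation, 0.6 * 150, tolerance = 3 / 90)
  kca <- ca_kinetics(simulate_event("Ca", wp2))
  expect_equal(kca$Ca_t_decay, 1.25 * 120 * log(2), tolerance = 3 / 104)
})

test_that("a full noise-free recording survives the cleaning chain intact", {
  rec <- simulate_recording(noise_sd = 0, crosstalk_gain = 0.15)
  k <- quantify_recording(rec$ap, rec$ca, rec$co, rec$ma)
  wp <- waveform_params()
  expect_true(k$usable)
  # dF/F amplitudes: amplitude / baseline of the underlying fluorophore
  expect_equal(k$AP_amplitude, wp$ap$amplitude / wp$ap$baseline,
               tolerance = 0.02)
  expect_equal(k$Ca_amplitude, wp$ca$amplitude / wp$ca$baseline,
               tolerance = 0.02)
  expect_equal(k$Co_amplitude, wp$co$amplitude, tolerance = 0.02)
  expect_equal(k$AP_t_APD, 350, tolerance = 3 / 350)
  expect_equal(k$AP_triangulation, 150, tolerance = 3 / 150)
  expect_equal(k$Ca_t_decay, 120 * log(2), tolerance = 3 / 83)
  expect_equal(k$Co_t_contraction, 0.9 * 120, tolerance = 6 / 108)
})

test_that("fixed seeds reproduce the dataset exactly", {
  d1 <- small_design(seed = 77)
  d2 <- small_design(seed = 77)
  ds1 <- simulate_experiment(d1)
  ds2 <- simulate_experiment(d2)
  expect_equal(ds1$recordings$ap[[1]]$value, ds2$recordings$ap[[1]]$value)
  expect_equal(ds1$recordings$co[[10]]$value, ds2$recordings$co[[10]]$value)
  expect_equal(ds1$ground_truth$directions, ds2$ground_truth$directions)

  ds3 <- simulate_experiment(small_design(seed = 78))
  expect_false(isTRUE(all.equal(ds1$recordings$ap[[1]]$value,
                                ds3$recordings$ap[[1]]$value)))
})

test_that("the simulated plate has the designed replication structure", {
  d <- experiment_design(concentrations_uM = c(0.1, 1), wells = 3,
                         areas = 2, seed = 5)
  ds <- simulate_experiment(d)
  recs <- ds$recordings
  # (2 concentrations + vehicle) x wells x areas x 2 phases
  expect_equal(nrow(recs), 3 * 3 * 2 * 2)
  expect_setequal(unique(recs$concentration_uM), c(0, 0.1, 1))
  counts <- dplyr::count(recs, concentration_uM, phase)
  expect_true(all(counts$n == 6))
  # effect magnitude follows the Hill scaling, saturating at the top dose
  eff <- ds$ground_truth$effect_magnitude
  expect_true(all(diff(eff) >= 0))
  expect_lte(eff[length(eff)], d$magnitude)
})

test_that("an end-to-end drugged dataset recovers its true MOA", {
  d <- experiment_design(moa = "Co_minus_Ca",
                         concentrations_uM = c(0.01, 0.1, 1),
                         wells = 3, areas = 2, seed = 21)
  ds <- simulate_experiment(d)
  wells <- process_recordings(ds)
  sc <- score_conditions(wells)
  top <- dplyr::filter(sc$assignments, concentration_uM == 1,
                       subset == "ALL")
  expect_equal(top$assigned_moa, "Co_minus_Ca")
})
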