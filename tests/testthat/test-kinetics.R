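test_that("APD follows from line geometry on a triangular pulse", {
  # linear rise 0->1 over 10 ms, linear fall over 300 ms, dense sampling;
  # closed form: activation (50% upstroke) at 5 ms after onset, level
  # 1 - f crossed at rise + f * fall on the downstroke
  tr <- pulse_trace(rise_ms = 10, fall_ms = 300)
  apd90_expected <- (10 + 0.9 * 300) - 5   # 275
  apd30_expected <- (10 + 0.3 * 300) - 5   # 95
  expect_equal(apd_at(tr, 0.9), apd90_expected, tolerance = 1e-6)
  expect_equal(apd_at(tr, 0.3), apd30_expected, tolerance = 1e-6)
  k <- ap_kinetics(tr)
  expect_equal(k$AP_triangulation, apd90_expected - apd30_expected,
               tolerance = 1e-6)
  expect_equal(k$AP_amplitude, 1, tolerance = 1e-9)
  expect_equal(k$AP_t_rise, 8, tolerance = 1e-6)   # 10-90% of a 10 ms ramp
})

test_that("a square pulse has (near) zero triangulation", {
  tr <- square_trace(width_ms = 200)
  k <- ap_kinetics(tr)
  # repolarisation happens within one sample: APD30 ~ APD90
  expect_lt(k$AP_triangulation, 1.5)
  expect_gte(k$AP_triangulation, 0)
})

test_that("APD30 <= APD90 for monotone repolarisation", {
  set.seed(8)
  for (i in 1:20) {
    tr <- pulse_trace(rise_ms = runif(1, 2, 20),
                      fall_ms = runif(1, 50, 500))
    expect_lte(apd_at(tr, 0.3), apd_at(tr, 0.9))
  }
})

test_that("incomplete repolarisation or decay raises a typed error", {
  # rises and never comes back down
  t <- seq(0, 500)
  v <- c(rep(0, 50), seq(0, 1, length.out = 20), rep(1, 431))
  tr <- ttm_trace(v, fps = 1000, channel = "AP")
  expect_error(apd_at(tr, 0.9), class = "ttm_error_incomplete")
  ca <- ttm_trace(v, fps = 1000, channel = "Ca")
  expect_error(ca_kinetics(ca), class = "ttm_error_incomplete")
})

test_that("calcium timing follows from line geometry on a triangle", {
  tr <- pulse_trace(rise_ms = 100, fall_ms = 100, channel = "Ca")
  k <- ca_kinetics(tr)
  expect_equal(k$Ca_t_to_peak, 90, tolerance = 1e-5)  # from the 10% crossing
  expect_equal(k$Ca_t_decay, 50, tolerance = 1e-5)    # to the 50% level
  expect_equal(k$Ca_amplitude, 1, tolerance = 1e-9)
})

test_that("contraction kinetics use the same geometry as calcium", {
  tr_ca <- pulse_trace(rise_ms = 100, fall_ms = 100, channel = "Ca")
  tr_co <- pulse_trace(rise_ms = 100, fall_ms = 100, channel = "Co")
  ka <- ca_kinetics(tr_ca)
  kc <- co_kinetics(tr_co)
  expect_equal(kc$Co_t_contraction, ka$Ca_t_to_peak)
  expect_equal(kc$Co_t_relaxation, ka$Ca_t_decay)
  expect_equal(kc$Co_amplitude, ka$Ca_amplitude)
})

test_that("exponential decay gives half-decay time tau * ln(2)", {
  for (tau in c(80, 120, 200)) {
    wp <- waveform_params(ca = list(baseline = 80, amplitude = 40,
                                    delay_ms = 80, rise_ms = 90,
                                    tau_ms = tau))
    ev <- simulate_event("Ca", wp)
    expect_equal(ca_kinetics(ev)$Ca_t_decay, tau * log(2), tolerance = 0.05)
  }
})

test_that("flat traces are flagged unusable, not crashed on", {
  flat <- ttm_trace(rep(3, 300), fps = 1000 / 3, channel = "Ca")
  k <- ca_kinetics(flat)
  expect_equal(k$Ca_amplitude, 0)
  expect_false(k$usable)
  kb <- beat_kinetics(flat, flat, flat)
  expect_false(kb$usable)
})

test_that("a beat record has exactly the ten named parameters", {
  wp <- waveform_params()
  k <- beat_kinetics(simulate_event("AP", wp), simulate_event("Ca", wp),
                     simulate_event("Co", wp))
  expect_true(k$usable)
  expect_identical(setdiff(names(k), "usable"),
                   kinetic_parameters()$parameter)
  pc <- kinetic_parameters()
  expect_equal(sum(startsWith(names(k), "AP_")), 4)
  expect_equal(sum(startsWith(names(k), "Ca_")), 3)
  expect_equal(sum(startsWith(names(k), "Co_")), 3)
  expect_true(all(as.numeric(k[1, pc$parameter]) >= 0))
})

test_that("baseline normalisation is a fieldwise ratio with guards", {
  wp <- waveform_params()
  k <- beat_kinetics(simulate_event("AP", wp), simulate_event("Ca", wp),
                     simulate_event("Co", wp))
  same <- normalize_to_baseline(k, k)
  expect_equal(unname(as.numeric(same[1, kinetic_parameters()$parameter])),
               rep(1, 10))

  doubled <- k
  doubled$Ca_amplitude <- 2 * doubled$Ca_amplitude
  r <- normalize_to_baseline(doubled, k)
  expect_equal(r$Ca_amplitude, 2)
  expect_equal(r$AP_t_APD, 1)

  degenerate <- k
  degenerate$Co_amplitude <- 0
  expect_error(normalize_to_baseline(k, degenerate),
               class = "ttm_error_degenerate_baseline")
})

test_that("aggregation averages fieldwise and skips unusable records", {
  rec <- function(val, usable = TRUE) {
    out <- tibble::as_tibble(setNames(as.list(rep(val, 10)),
                                      kinetic_parameters()$parameter))
    out$usable <- usable
    out
  }
  three <- dplyr::bind_rows(rec(1), rec(2), rec(3))
  agg <- aggregate_kinetics(three)
  expect_equal(agg$AP_amplitude, 2)
  expect_equal(agg$n, 3)

  with_bad <- dplyr::bind_rows(rec(1), rec(3), rec(100, usable = FALSE))
  agg2 <- aggregate_kinetics(with_bad)
  expect_equal(agg2$Ca_t_decay, 2)
  expect_equal(agg2$n, 2)

  all_bad <- dplyr::bind_rows(rec(1, FALSE), rec(2, FALSE))
  expect_error(aggregate_kinetics(all_bad),
               class = "ttm_error_empty_aggregate")
})
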