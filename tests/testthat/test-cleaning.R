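test_that("ratiometric correction removes multiplicative crosstalk", {
  fps <- 1000 / 3
  sig <- ttm_trace(100 + sin(1:300 / 10), fps = fps, channel = "Ca")
  ma_const <- ttm_trace(rep(120, 300), fps = fps, channel = "MA")
  expect_equal(ratiometric_correct(sig, ma_const)$value, sig$value)

  # pure artifact: the signal IS the MA channel -> constant at mean(ma)
  ma <- ttm_trace(120 + 5 * sin(1:300 / 7), fps = fps, channel = "MA")
  as_sig <- ttm_trace(ma$value, fps = fps, channel = "Ca")
  expect_equal(ratiometric_correct(as_sig, ma)$value,
               rep(mean(ma$value), 300))

  expect_error(ratiometric_correct(sig, ttm_trace(rep(1, 10), fps, "MA")),
               class = "ttm_error_input")
  bad_ma <- ttm_trace(c(rep(2, 299), 0), fps = fps, channel = "MA")
  expect_error(ratiometric_correct(sig, bad_ma),
               class = "ttm_error_domain")
})

test_that("ratiometric correction recovers the artifact-free recording", {
  wp <- waveform_params()
  set.seed(7)
  with_ma <- simulate_recording(wp, noise_sd = 0, crosstalk_gain = 0.2)
  set.seed(7)
  without <- simulate_recording(wp, noise_sd = 0, crosstalk_gain = 0)
  corr <- ratiometric_correct(with_ma$ca, with_ma$ma)
  # modulation is removed up to a constant scale; compare mean-normalised
  expect_equal(corr$value / mean(corr$value),
               without$ca$value / mean(without$ca$value),
               tolerance = 1e-10)
})

test_that("mid-range inversion is an involution that preserves range", {
  tr <- ttm_trace(c(5, 3, 5), fps = 10, channel = "AP")
  expect_equal(invert_trace(tr)$value, c(3, 5, 3))
  const <- ttm_trace(rep(4, 5), fps = 10, channel = "AP")
  expect_equal(invert_trace(const)$value, rep(4, 5))
  set.seed(1)
  x <- ttm_trace(runif(50, 10, 20), fps = 10, channel = "AP")
  expect_equal(invert_trace(invert_trace(x))$value, x$value)
  expect_equal(range(invert_trace(x)$value), range(x$value))
})

test_that("pseudo-ratio dF/F_min has zero minimum and is scale invariant", {
  tr <- ttm_trace(c(100, 150, 100), fps = 10, channel = "Ca")
  expect_equal(delta_f_over_f(tr)$value, c(0, 0.5, 0))
  const <- ttm_trace(rep(7, 4), fps = 10, channel = "Ca")
  expect_equal(delta_f_over_f(const)$value, rep(0, 4))
  set.seed(2)
  x <- ttm_trace(runif(100, 50, 90), fps = 10, channel = "Ca")
  expect_equal(min(delta_f_over_f(x)$value), 0)
  scaled <- ttm_trace(3.7 * x$value, fps = 10, channel = "Ca")
  expect_equal(delta_f_over_f(scaled)$value, delta_f_over_f(x)$value)
  neg <- ttm_trace(x$value - 100, fps = 10, channel = "Ca")
  expect_error(delta_f_over_f(neg), class = "ttm_error_domain")
})

test_that("trailing moving average keeps length and never widens the range", {
  tr <- ttm_trace(c(1, 3), fps = 10, channel = "Co")
  expect_equal(moving_average(tr, 2)$value, c(1, 2))
  set.seed(3)
  x <- ttm_trace(rnorm(200), fps = 10, channel = "Co")
  expect_equal(moving_average(x, 1)$value, x$value)
  const <- ttm_trace(rep(2.5, 30), fps = 10, channel = "Co")
  for (w in c(1, 2, 7)) {
    expect_equal(moving_average(const, w)$value, rep(2.5, 30))
  }
  for (w in c(2, 5, 11)) {
    sm <- moving_average(x, w)
    expect_length(sm$value, 200)
    expect_lte(diff(range(sm$value)), diff(range(x$value)))
  }
  expect_error(moving_average(tr, 3), class = "ttm_error_input")
})

test_that("event detection counts paced events and checks their spacing", {
  set.seed(11)
  rec <- simulate_recording(noise_sd = 0.02, crosstalk_gain = 0)
  cfg <- cleaning_config()
  ev <- detect_events(moving_average(rec$co, 2), cfg)
  # 7 s at 1.2 Hz = 8.4 cycles -> 8 complete events
  expect_equal(nrow(ev), 8)
  expect_true(attr(ev, "pass"))
  period <- attr(ev, "period")
  expect_equal(period, (1000 / 3) / 1.2, tolerance = 1e-12)
  expect_true(all(abs(diff(ev$marker) - period) < 0.05 * period))
  expect_true(all(diff(ev$onset) > 0))
  expect_lte(attr(ev, "window"), floor(period))
})

test_that("a displaced event fails the pacing-consistency check", {
  fps <- 1000 / 3
  period_ms <- 1000 / 1.2
  t_ms <- (0:(7 * fps)) / fps * 1000
  onsets <- seq(60, 6900, by = period_ms)
  onsets[4] <- onsets[4] + 0.3 * period_ms   # one beat 30% late
  v <- rep(1, length(t_ms))
  for (o in onsets) {
    in_ev <- t_ms >= o & t_ms < o + 200
    v[in_ev] <- 1 + sin((t_ms[in_ev] - o) / 200 * pi)
  }
  ev <- detect_events(ttm_trace(v, fps = fps, channel = "Ca"),
                      cleaning_config())
  expect_false(attr(ev, "pass"))
  expect_error(average_events(ttm_trace(v, fps, "Ca"), ev),
               class = "ttm_error_interpeak")
})

test_that("flat or too-short traces yield insufficient-events errors", {
  fps <- 1000 / 3
  flat <- ttm_trace(rep(5, 7 * 333), fps = fps, channel = "Co")
  expect_error(detect_events(flat, cleaning_config()),
               class = "ttm_error_insufficient_events")
  short <- ttm_trace(rep(5, 100), fps = fps, channel = "Co")
  expect_error(detect_events(short, cleaning_config()),
               class = "ttm_error_input")
})

test_that("averaging identical events reproduces the single event", {
  # 300 samples/s at 1.2 Hz pacing -> integer 250-sample period, so a
  # noise-free recording has exactly repeating event windows
  set.seed(4)
  rec <- simulate_recording(fps = 300, noise_sd = 0, crosstalk_gain = 0)
  cfg <- cleaning_config()
  ev <- detect_events(rec$ca, cfg)
  avg <- average_events(rec$ca, ev, cfg)
  w <- attr(ev, "window")
  one <- rec$ca$value[ev$start[1]:(ev$start[1] + w - 1)]
  # floating phase arithmetic can flip single samples at segment
  # boundaries between repeats; everything else is bitwise identical
  expect_equal(avg$value, one, tolerance = 1e-3)
  expect_gt(mean(abs(avg$value - one) < 1e-12), 0.98)
  expect_equal(nrow(avg), w)

  few <- ev[1:4, ]
  attr(few, "pass") <- TRUE
  attr(few, "window") <- w
  expect_error(average_events(rec$ca, few, cfg),
               class = "ttm_error_insufficient_events")
})

test_that("event averaging reduces noise close to the 1/sqrt(n) law", {
  # Monte-Carlo: clean template vs noisy copies, residual sd after
  # averaging 5 events should shrink by ~sqrt(5)
  cfg <- cleaning_config(ma_window = 1)
  clean <- simulate_recording(noise_sd = 0, crosstalk_gain = 0)
  ev0 <- detect_events(clean$ca, cfg)
  template <- average_events(clean$ca, ev0, cfg)
  sigma <- 0.8
  ratios <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- retrace_for_test(clean$ca,
                              clean$ca$value + rnorm(nrow(clean$ca), 0, sigma))
    ev <- detect_events(noisy, cfg)
    avg <- average_events(noisy, ev, cfg)
    stats::sd(avg$value - template$value) / sigma
  }, 0)
  expect_equal(mean(ratios), 1 / sqrt(5), tolerance = 0.12)
})

test_that("the full cleaning chain yields a dimensionless averaged beat", {
  set.seed(5)
  rec <- simulate_recording(noise_sd = 0.03, crosstalk_gain = 0.1)
  cfg <- cleaning_config()
  ap <- clean_trace(rec$ap, rec$ma, cfg)
  ca <- clean_trace(rec$ca, rec$ma, cfg)
  co <- clean_trace(rec$co, NULL, cfg)
  expect_equal(trace_fps(ap), 1000 / 3)
  # dF/F floors near zero (event averaging can lift the within-beat
  # minimum slightly off the whole-trace zero) and the AP comes out upright
  expect_lt(min(ap$value), 0.05)
  expect_gt(max(ap$value), 0.3)
  expect_gt(which.max(ap$value), which.min(ap$value[1:which.max(ap$value)]))
  expect_lt(min(ca$value), 0.05)
  # all three averaged beats span one pacing period
  period <- (1000 / 3) / 1.2
  expect_equal(nrow(ap), floor(period))
  expect_equal(nrow(co), floor(period))
})
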