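#' Waveform parameters of the simulated triple transient
#'
#' Phenomenological per-channel templates for one paced beat, chosen to
#' resemble averaged hiPSC-CM optical transients: the action potential is
#' a fast-upstroke pulse with configurable APD30/APD90, calcium and
#' contraction are rise-then-exponential-decay transients. Baselines and
#' amplitudes are arbitrary fluorescence units; all times are
#' milliseconds. The AP template is generated in its physical (inverted)
#' polarity, since the voltage dye dims on depolarisation.
#'
#' @param ap,ca,co Named lists of channel parameters (see defaults).
#' @param ma_baseline Membrane-label (motion-artifact channel) baseline
#'   intensity.
#' @return A `ttm_waveform` list.
#' @export
waveform_params <- function(
    ap = list(baseline = 100, amplitude = 60, delay_ms = 60, rise_ms = 10,
              apd30_ms = 200, apd90_ms = 350),
    ca = list(baseline = 80, amplitude = 40, delay_ms = 80, rise_ms = 90,
              tau_ms = 120),
    co = list(baseline = 5, amplitude = 20, delay_ms = 90, rise_ms = 120,
              tau_ms = 130),
    ma_baseline = 120) {
  wp <- list(ap = ap, ca = ca, co = co, ma_baseline = ma_baseline)
  validate_waveform(wp)
  structure(wp, class = "ttm_waveform")
}

validate_waveform <- function(wp) {
  for (ch in c("ap", "ca", "co")) {
    p <- wp[[ch]]
    if (p$baseline <= 0 || p$amplitude < 0 || p$delay_ms <= 0 ||
        p$rise_ms <= 0) {
      .ttm_stop(paste0("Invalid waveform parameters for channel ", ch, "."),
                "ttm_error_shape")
    }
  }
  if (wp$ap$apd30_ms >= wp$ap$apd90_ms) {
    .ttm_stop("AP shape requires APD30 < APD90.", "ttm_error_shape")
  }
  if (wp$ap$apd30_ms <= 0.6 * wp$ap$rise_ms) {
    .ttm_stop("AP shape infeasible: APD30 must exceed the upstroke time.",
              "ttm_error_shape")
  }
  invisible(wp)
}

# Continuous-time template for one channel over one pacing period.
# Returns function(t_ms in [0, period)) -> intensity. AP is built so that
# APD30/APD90 measured by the kinetics module (50%-upstroke activation,
# linear interpolation) equal the targets exactly; Ca/Co decay
# exponentially so the half-decay time is tau * ln(2).
make_shape <- function(channel, wp, period_ms, tail_ms = 40) {
  if (channel == "AP") {
    p <- wp$ap
    b <- p$baseline; A <- p$amplitude
    if (A == 0) return(function(t) rep(b, length(t)))
    t_on <- p$delay_ms
    t_peak <- t_on + p$rise_ms
    t_act <- t_on + 0.5 * p$rise_ms
    t30 <- t_act + p$apd30_ms     # crossing of 70% amplitude
    t90 <- t_act + p$apd90_ms     # crossing of 10% amplitude
    t_end <- t90 + tail_ms
    if (t_end >= period_ms) {
      .ttm_stop("AP shape infeasible: repolarisation exceeds the pacing period.",
                "ttm_error_shape")
    }
    nodes_t <- c(0, t_on, t_peak, t30, t90, t_end, period_ms)
    nodes_v <- c(b, b, b + A, b + 0.7 * A, b + 0.1 * A, b, b)
    function(t) approx(nodes_t, nodes_v, xout = t, rule = 2)$y
  } else {
    p <- wp[[tolower(channel)]]
    b <- p$baseline; A <- p$amplitude
    if (A == 0) return(function(t) rep(b, length(t)))
    t_on <- p$delay_ms
    t_peak <- t_on + p$rise_ms
    if (t_peak >= period_ms) {
      .ttm_stop("Transient shape infeasible: peak beyond the pacing period.",
                "ttm_error_shape")
    }
    function(t) {
      v <- rep(b, length(t))
      rising <- t >= t_on & t < t_peak
      v[rising] <- b + A * (t[rising] - t_on) / p$rise_ms
      decay <- t >= t_peak
      v[decay] <- b + A * exp(-(t[decay] - t_peak) / p$tau_ms)
      v
    }
  }
}

#' Simulate one noise-free event of one channel
#'
#' Renders one pacing period of the channel template at the per-channel
#' sampling rate. The AP pulse is constructed so that APD30 and APD90
#' measured by [ap_kinetics()] equal the configured targets to within one
#' sample; Ca and Co decay exponentially, so the measured half-decay time
#' is `tau * ln(2)`.
#'
#' @param channel `"AP"`, `"Ca"` or `"Co"`.
#' @param wp A [waveform_params()] object.
#' @param fps Per-channel sampling rate (samples/s).
#' @param pacing_hz Pacing frequency (Hz).
#' @return A single-beat `ttm_trace` (returned in upright polarity; the
#'   emitted AP in a full recording is inverted, see
#'   [simulate_recording()]).
#' @export
simulate_event <- function(channel = c("AP", "Ca", "Co"),
                           wp = waveform_params(), fps = 1000 / 3,
                           pacing_hz = 1.2) {
  channel <- match.arg(channel)
  validate_waveform(wp)
  period_ms <- 1000 / pacing_hz
  shape <- make_shape(channel, wp, period_ms)
  n <- floor(period_ms / 1000 * fps)
  t_ms <- (seq_len(n) - 1) / fps * 1000
  ttm_trace(shape(t_ms), fps = fps, channel = channel)
}

#' Resolve hypothesis-table effects into parameter perturbation factors
#'
#' Maps one MOA column of the hypothesis table onto multiplicative factors
#' for the ten kinetic parameters: `up` becomes `1 + magnitude`, `down`
#' `1 - magnitude`, `same` 1. Complement (NOT) cells cover heterogeneous
#' drug classes, so the simulated drug draws one admissible direction
#' (anything but the negated effect) at random; the draw is made once per
#' drug and exported as ground truth.
#'
#' @param moa An MOA category id, or `NA`/`"none"` for a null drug.
#' @param magnitude Effect magnitude in \[0, 0.5\].
#' @param table A hypothesis table.
#' @return A tibble `parameter`, `effect`, `direction` (the resolved plain
#'   direction) and `factor`.
#' @export
moa_effect_factors <- function(moa, magnitude, table = ttm_hypotheses()) {
  stopifnot(magnitude >= 0, magnitude <= 0.5)
  params <- kinetic_parameters()$parameter
  if (is.null(moa) || is.na(moa) || moa == "none") {
    return(tibble(parameter = params, effect = "same", direction = "same",
                  factor = 1))
  }
  effects <- map_chr(params, function(p) expected_effect(table, moa, p))
  direction <- map_chr(effects, function(e) {
    if (e %in% .effects_plain) return(e)
    admissible <- setdiff(.effects_plain, .effects_not[[e]])
    sample(admissible, 1)
  })
  factor <- c(up = 1 + magnitude, down = 1 - magnitude, same = 1)[direction]
  tibble(parameter = params, effect = effects, direction = direction,
         factor = unname(factor))
}

# Scale the drawn directions to a (possibly smaller) magnitude, keeping
# the direction draw fixed across concentrations.
rescale_factors <- function(factors, magnitude) {
  mutate(factors, factor = unname(
    c(up = 1 + magnitude, down = 1 - magnitude, same = 1)[.data$direction]))
}

#' Apply kinetic-parameter factors to the waveform templates
#'
#' Translates fold changes of the ten kinetic parameters into waveform
#' template parameters: amplitudes scale the template amplitudes, rise
#' and decay times scale the corresponding template times, and the AP
#' duration / triangulation pair is solved jointly (`APD90' = f_APD *
#' APD90`, `triangulation' = f_tri * (APD90 - APD30)`, `APD30' = APD90' -
#' triangulation'`).
#'
#' @param wp A [waveform_params()] object.
#' @param factors A factor tibble from [moa_effect_factors()], or a named
#'   numeric vector of per-parameter fold changes.
#' @return The perturbed `ttm_waveform` (validated; impossible shape
#'   combinations raise a shape error).
#' @export
apply_factors <- function(wp, factors) {
  f <- if (is.data.frame(factors)) {
    setNames(factors$factor, factors$parameter)
  } else {
    factors
  }
  g <- function(p) if (p %in% names(f)) f[[p]] else 1
  wp$ap$amplitude <- wp$ap$amplitude * g("AP_amplitude")
  wp$ap$rise_ms <- wp$ap$rise_ms * g("AP_t_rise")
  tri <- (wp$ap$apd90_ms - wp$ap$apd30_ms) * g("AP_triangulation")
  apd90 <- wp$ap$apd90_ms * g("AP_t_APD")
  wp$ap$apd90_ms <- apd90
  wp$ap$apd30_ms <- apd90 - tri
  wp$ca$amplitude <- wp$ca$amplitude * g("Ca_amplitude")
  wp$ca$rise_ms <- wp$ca$rise_ms * g("Ca_t_to_peak")
  wp$ca$tau_ms <- wp$ca$tau_ms * g("Ca_t_decay")
  wp$co$amplitude <- wp$co$amplitude * g("Co_amplitude")
  wp$co$rise_ms <- wp$co$rise_ms * g("Co_t_contraction")
  wp$co$tau_ms <- wp$co$tau_ms * g("Co_t_relaxation")
  validate_waveform(wp)
  wp
}

#' Perturb a waveform according to one MOA hypothesis
#'
#' Convenience wrapper: resolves the MOA column into factors (drawing NOT
#' cells at random) and applies them to the waveform. The factor table is
#' attached as attribute `"factors"` (simulation ground truth).
#'
#' @inheritParams moa_effect_factors
#' @inheritParams apply_factors
#' @return The perturbed `ttm_waveform`.
#' @export
apply_moa <- function(wp, moa, magnitude, table = ttm_hypotheses()) {
  factors <- moa_effect_factors(moa, magnitude, table)
  out <- apply_factors(wp, factors)
  attr(out, "factors") <- factors
  out
}

#' Simulate one 7-second paced triple-transient recording
#'
#' Evaluates the channel templates along a paced stimulus train, applies
#' the contraction-driven motion artifact multiplicatively to the AP, Ca
#' and membrane-label channels, inverts the emitted AP polarity (the
#' voltage dye dims on depolarisation) and adds Gaussian photometric
#' noise. The result is the set of four raw traces the cleaning chain
#' expects.
#'
#' @param wp A [waveform_params()] object.
#' @param fps Per-channel sampling rate (samples/s).
#' @param duration_s Recording duration (s).
#' @param pacing_hz Pacing frequency (Hz).
#' @param noise_sd Photometric noise standard deviation as a fraction of
#'   each channel's amplitude.
#' @param crosstalk_gain Peak fractional intensity modulation caused by
#'   contraction (0 = no motion artifact).
#' @return A list of `ttm_trace`s: `ap`, `ca`, `co`, `ma`.
#' @export
simulate_recording <- function(wp = waveform_params(), fps = 1000 / 3,
                               duration_s = 7, pacing_hz = 1.2,
                               noise_sd = 0.05, crosstalk_gain = 0.05) {
  validate_waveform(wp)
  period_ms <- 1000 / pacing_hz
  n <- floor(duration_s * fps)
  t_ms <- (seq_len(n) - 1) / fps * 1000
  phase <- t_ms %% period_ms
  ap_shape <- make_shape("AP", wp, period_ms)(phase)
  ca_shape <- make_shape("Ca", wp, period_ms)(phase)
  co_shape <- make_shape("Co", wp, period_ms)(phase)
  co_norm <- if (wp$co$amplitude > 0) {
    (co_shape - wp$co$baseline) / wp$co$amplitude
  } else {
    rep(0, n)
  }
  modulation <- 1 - crosstalk_gain * co_norm
  # emitted AP: reflected about the template mid-range so that mid-range
  # re-inversion downstream recovers the upright pulse
  ap_emit <- (2 * wp$ap$baseline + wp$ap$amplitude - ap_shape) * modulation
  ca_emit <- ca_shape * modulation
  ma <- wp$ma_baseline * modulation
  amp_or_1 <- function(a) if (a > 0) a else 1
  ap_emit <- ap_emit + rnorm(n, 0, noise_sd * amp_or_1(wp$ap$amplitude))
  ca_emit <- ca_emit + rnorm(n, 0, noise_sd * amp_or_1(wp$ca$amplitude))
  co_out <- co_shape + rnorm(n, 0, noise_sd * amp_or_1(wp$co$amplitude))
  # the membrane label is bright and static, so its photometric noise is
  # an order of magnitude below the transient channels
  ma <- pmax(ma + rnorm(n, 0, 0.1 * noise_sd * wp$ma_baseline), 1e-6)
  list(
    ap = ttm_trace(ap_emit, fps = fps, channel = "AP"),
    ca = ttm_trace(ca_emit, fps = fps, channel = "Ca"),
    co = ttm_trace(co_out, fps = fps, channel = "Co"),
    ma = ttm_trace(ma, fps = fps, channel = "MA")
  )
}

#' Design of a simulated concentration-response experiment
#'
#' Mirrors the plate layout of the screening protocol: one drug tested at
#' five concentrations plus vehicle, five wells per condition, three
#' recorded areas per well, each area measured at baseline and after
#' incubation, paced at 1.2 Hz for 7 s per recording at 333.33 samples/s
#' per channel.
#'
#' @param drug Drug label.
#' @param moa True MOA category (`"none"` for a null drug).
#' @param concentrations_uM Tested concentrations (uM); vehicle (0) is
#'   always added.
#' @param magnitude Maximal effect magnitude (fraction, 0--0.5); scaled
#'   along concentration by a Hill curve with EC50 at the middle
#'   concentration.
#' @param hill_n Hill coefficient of the concentration scaling.
#' @param wells Wells per condition.
#' @param areas Areas recorded per well.
#' @param duration_s,pacing_hz,fps Recording parameters.
#' @param noise_sd Photometric noise (fraction of amplitude).
#' @param crosstalk_gain Motion-artifact modulation depth.
#' @param well_cv Lognormal coefficient of variation of well-level
#'   biological variability (applied to each kinetic parameter).
#' @param drift_cv Lognormal CV of the baseline-to-post drift of each
#'   recording pair (the time-dependent effect that motivates vehicle
#'   referencing).
#' @param waveform Base [waveform_params()].
#' @param seed Integer seed; fixed-seed designs reproduce bit-identically.
#' @return A `ttm_design` list.
#' @export
experiment_design <- function(drug = "drug", moa = "none",
                              concentrations_uM = c(0.01, 0.03, 0.1, 0.3, 1),
                              magnitude = 0.3, hill_n = 1.5, wells = 5,
                              areas = 3, duration_s = 7, pacing_hz = 1.2,
                              fps = 1000 / 3, noise_sd = 0.05,
                              crosstalk_gain = 0.05, well_cv = 0.05,
                              drift_cv = 0.03,
                              waveform = waveform_params(), seed = 1L) {
  stopifnot(wells >= 1, areas >= 1, length(concentrations_uM) >= 1,
            all(concentrations_uM > 0), magnitude >= 0, magnitude <= 0.5,
            duration_s * pacing_hz >= 2)
  structure(
    list(drug = drug, moa = moa,
         concentrations_uM = sort(concentrations_uM),
         magnitude = magnitude, hill_n = hill_n, wells = wells,
         areas = areas, duration_s = duration_s, pacing_hz = pacing_hz,
         fps = fps, noise_sd = noise_sd, crosstalk_gain = crosstalk_gain,
         well_cv = well_cv, drift_cv = drift_cv, waveform = waveform,
         seed = as.integer(seed)),
    class = "ttm_design"
  )
}

hill_scale <- function(conc, ec50, n) conc^n / (conc^n + ec50^n)

#' Simulate a complete labelled concentration-response experiment
#'
#' Generates every recording of the plate design in [experiment_design()]:
#' for each condition (vehicle plus each concentration), each well and
#' each area, a baseline and a post-incubation recording. Well-level
#' biological variability and baseline-to-post drift are applied as
#' multiplicative lognormal factors on the kinetic parameters; drug wells
#' are additionally perturbed by the MOA factor set scaled by a Hill
#' function of concentration (EC50 at the middle tested concentration).
#' The MOA's complement (NOT) cells are drawn once per drug. All
#' randomness flows from the design seed.
#'
#' @param design A [experiment_design()].
#' @return A `ttm_dataset`: list with `recordings` (a tibble with columns
#'   `drug`, `concentration_uM`, `well`, `area`, `phase` and list-columns
#'   `ap`, `ca`, `co`, `ma`), the `design`, and `ground_truth` (true MOA,
#'   resolved directions, per-concentration magnitudes, seed).
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "ttm_design"))
  set.seed(design$seed)
  table <- ttm_hypotheses()
  directions <- moa_effect_factors(design$moa, design$magnitude, table)
  concs <- design$concentrations_uM
  ec50 <- median(concs)
  eff <- design$magnitude * hill_scale(concs, ec50, design$hill_n)
  params <- kinetic_parameters()$parameter
  rows <- list()
  for (ci in seq_along(c(0, concs))) {
    conc <- c(0, concs)[ci]
    drug_factors <- if (conc == 0) NULL else
      rescale_factors(directions, eff[ci - 1L])
    for (w in seq_len(design$wells)) {
      well_id <- sprintf("c%02d_w%d", ci - 1L, w)
      f_well <- setNames(rlnorm(length(params), 0, design$well_cv), params)
      wp_well <- apply_factors(design$waveform, f_well)
      for (a in seq_len(design$areas)) {
        f_area <- setNames(rlnorm(length(params), 0, design$well_cv / 2),
                           params)
        wp_base <- apply_factors(wp_well, f_area)
        f_drift <- setNames(rlnorm(length(params), 0, design$drift_cv),
                            params)
        wp_post <- apply_factors(wp_base, f_drift)
        if (!is.null(drug_factors)) {
          wp_post <- apply_factors(wp_post, drug_factors)
        }
        for (ph in c("baseline", "post")) {
          wp_rec <- if (ph == "baseline") wp_base else wp_post
          rec <- simulate_recording(
            wp_rec, fps = design$fps, duration_s = design$duration_s,
            pacing_hz = design$pacing_hz, noise_sd = design$noise_sd,
            crosstalk_gain = design$crosstalk_gain)
          rows[[length(rows) + 1L]] <- tibble(
            drug = design$drug, concentration_uM = conc, well = well_id,
            area = a, phase = ph,
            ap = list(rec$ap), ca = list(rec$ca),
            co = list(rec$co), ma = list(rec$ma))
        }
      }
    }
  }
  structure(
    list(
      recordings = bind_rows(rows),
      design = design,
      ground_truth = list(
        moa = design$moa, directions = directions,
        concentrations_uM = concs, effect_magnitude = eff,
        seed = design$seed)
    ),
    class = "ttm_dataset"
  )
}

#' @export
print.ttm_dataset <- function(x, ...) {
  cat(sprintf("<ttm_dataset> drug=%s true_moa=%s recordings=%d seed=%d\n",
              x$design$drug, x$ground_truth$moa, nrow(x$recordings),
              x$design$seed))
  invisible(x)
}

#' Render traces as an interleaved three-channel frame stack
#'
#' Inverse exercise of the ingest stage: builds small synthetic frames
#' whose ROI mean equals each trace value at the corresponding interleaved
#' frame index. The AP and Ca channels are rendered as uniform frames; the
#' membrane-label channel is a Gaussian blob whose brightness tracks the
#' MA trace and whose centre translates with the contraction trace, so
#' [contraction_trace()] responds to it.
#'
#' @param ap,ca,ma Equal-length `ttm_trace`s driving frame intensity.
#' @param co `ttm_trace` driving the blob displacement.
#' @param dim Frame edge length in pixels.
#' @param max_shift_px Blob displacement at the contraction peak.
#' @return An interleaved `ttm_stack` of `3 * n` frames at three times the
#'   trace sampling rate, channel order AP, Ca, Co.
#' @export
render_interleaved_frames <- function(ap, ca, co, ma, dim = 32,
                                      max_shift_px = 3) {
  n <- nrow(ap)
  if (nrow(ca) != n || nrow(co) != n || nrow(ma) != n) {
    .ttm_stop("All traces must have equal length.", "ttm_error_input")
  }
  xy <- seq_len(dim)
  blob <- function(cx, cy) {
    outer(xy, xy, function(i, j) exp(-((i - cy)^2 + (j - cx)^2) / (2 * 16)))
  }
  rng_co <- range(co$value)
  disp <- if (diff(rng_co) > 0) {
    (co$value - rng_co[1]) / diff(rng_co) * max_shift_px
  } else {
    rep(0, n)
  }
  centre <- (dim + 1) / 2
  frames <- vector("list", 3L * n)
  for (i in seq_len(n)) {
    frames[[3 * i - 2]] <- matrix(ap$value[i], dim, dim)
    frames[[3 * i - 1]] <- matrix(ca$value[i], dim, dim)
    b <- blob(centre + disp[i], centre)
    frames[[3 * i]] <- b * (ma$value[i] * dim^2 / sum(b))
  }
  frame_stack(frames, fps = 3 * trace_fps(ap),
              channels = c("AP", "Ca", "Co"))
}
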