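# Geometry helpers on an averaged beat. All work in milliseconds on the
# (time, value) samples with linear interpolation between samples.

beat_time_ms <- function(trace) (trace$time_s - trace$time_s[1]) * 1000

# Last upward crossing of `level` at or before index `ip`; interpolated
# time in ms, or NA if the trace starts at/above the level.
cross_up_before <- function(t, v, level, ip) {
  idx <- which(v[seq_len(ip - 1)] < level & v[2:ip] >= level)
  if (length(idx) == 0) {
    return(if (v[1] >= level) t[1] else NA_real_)
  }
  i <- idx[length(idx)]
  t[i] + (t[i + 1] - t[i]) * (level - v[i]) / (v[i + 1] - v[i])
}

# First downward crossing of `level` at or after index `ip`; NA if the
# trace never falls to the level.
cross_down_after <- function(t, v, level, ip) {
  n <- length(v)
  if (ip >= n) return(NA_real_)
  seg <- ip:(n - 1)
  idx <- which(v[seg] >= level & v[seg + 1] < level)
  if (length(idx) == 0) return(NA_real_)
  i <- seg[idx[1]]
  t[i] + (t[i + 1] - t[i]) * (v[i] - level) / (v[i] - v[i + 1])
}

# Baseline (pre-upstroke median), amplitude and landmark indices of a
# single averaged beat. The baseline is first bracketed by the pre-peak
# minimum, then refined as the median of all samples before the 10%
# upstroke crossing.
beat_geometry <- function(trace, onset_frac = 0.1) {
  t <- beat_time_ms(trace)
  v <- trace$value
  ip <- which.max(v)
  b0 <- min(v[seq_len(ip)])
  amp0 <- v[ip] - b0
  if (amp0 <= .Machine$double.eps * max(1, abs(b0))) {
    return(list(t = t, v = v, peak_idx = ip, peak_time = t[ip],
                baseline = b0, amplitude = 0, onset_time = NA_real_,
                usable = FALSE))
  }
  lvl <- b0 + onset_frac * amp0
  pre <- which(v[seq_len(ip)] < lvl)
  baseline <- if (length(pre) >= 1) median(v[seq_len(max(pre))]) else b0
  amp <- v[ip] - baseline
  onset <- cross_up_before(t, v, baseline + onset_frac * amp, ip)
  list(t = t, v = v, peak_idx = ip, peak_time = t[ip], baseline = baseline,
       amplitude = amp, onset_time = onset, usable = TRUE)
}

#' Action potential duration at a repolarisation fraction
#'
#' APD is measured from activation (the 50%-amplitude crossing on the
#' upstroke) to the first post-peak crossing of `amplitude * (1 -
#' fraction)` above baseline, with linear interpolation between samples.
#' `apd_at(x, 0.9)` is APD90, `apd_at(x, 0.3)` APD30.
#'
#' @param avg_ap The averaged AP beat (`ttm_trace`).
#' @param fraction Repolarisation fraction in (0, 1).
#' @return APD in milliseconds.
#' @export
apd_at <- function(avg_ap, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  g <- beat_geometry(avg_ap)
  if (!g$usable) {
    .ttm_stop("Flat trace: no action potential to measure.",
              "ttm_error_input")
  }
  t_act <- cross_up_before(g$t, g$v, g$baseline + 0.5 * g$amplitude,
                           g$peak_idx)
  level <- g$baseline + (1 - fraction) * g$amplitude
  t_rep <- cross_down_after(g$t, g$v, level, g$peak_idx)
  if (is.na(t_rep)) {
    .ttm_stop(sprintf(
      "Repolarisation never reaches %d%% within the beat window.",
      round(100 * fraction)), "ttm_error_incomplete")
  }
  t_rep - t_act
}

#' Quantify the four AP kinetic parameters
#'
#' Amplitude is peak minus pre-upstroke baseline; `AP_t_rise` the
#' 10--90% upstroke time; `AP_t_APD` the APD at `apd_level` repolarisation
#' (default APD90); `AP_triangulation` = APD90 - APD30, a non-negative
#' repolarisation-shape measure that rises with proarrhythmic
#' triangulation of the AP.
#'
#' @param avg_ap The averaged AP beat.
#' @param apd_level Repolarisation fraction used for `AP_t_APD`.
#' @return A one-row tibble: `AP_amplitude`, `AP_t_rise`, `AP_t_APD`,
#'   `AP_triangulation`, `usable`.
#' @export
ap_kinetics <- function(avg_ap, apd_level = 0.9) {
  g <- beat_geometry(avg_ap)
  if (!g$usable) {
    return(tibble(AP_amplitude = 0, AP_t_rise = NA_real_,
                  AP_t_APD = NA_real_, AP_triangulation = NA_real_,
                  usable = FALSE))
  }
  t10 <- cross_up_before(g$t, g$v, g$baseline + 0.1 * g$amplitude, g$peak_idx)
  t90 <- cross_up_before(g$t, g$v, g$baseline + 0.9 * g$amplitude, g$peak_idx)
  apd90 <- apd_at(avg_ap, 0.9)
  apd30 <- apd_at(avg_ap, 0.3)
  tibble(
    AP_amplitude = g$amplitude,
    AP_t_rise = t90 - t10,
    AP_t_APD = if (identical(apd_level, 0.9)) apd90 else apd_at(avg_ap, apd_level),
    AP_triangulation = apd90 - apd30,
    usable = TRUE
  )
}

# Shared rise/decay geometry for calcium and contraction transients.
transient_kinetics <- function(avg, decay_level) {
  g <- beat_geometry(avg)
  if (!g$usable) {
    return(list(amplitude = 0, t_to_peak = NA_real_, t_decay = NA_real_,
                usable = FALSE))
  }
  level <- g$baseline + (1 - decay_level) * g$amplitude
  t_dec <- cross_down_after(g$t, g$v, level, g$peak_idx)
  if (is.na(t_dec)) {
    .ttm_stop(sprintf(
      "Transient never decays to %d%% of its amplitude within the beat window.",
      round(100 * (1 - decay_level))), "ttm_error_incomplete")
  }
  list(amplitude = g$amplitude,
       t_to_peak = g$peak_time - g$onset_time,
       t_decay = t_dec - g$peak_time,
       usable = TRUE)
}

#' Quantify the three calcium kinetic parameters
#'
#' Amplitude is peak minus baseline; `Ca_t_to_peak` the time from the 10%
#' onset crossing to the peak; `Ca_t_decay` the time from the peak until
#' the transient has decayed by `decay_level` of its amplitude (default
#' 50%, i.e. half-decay time).
#'
#' @param avg_ca The averaged Ca beat.
#' @param decay_level Fraction of amplitude decayed (default 0.5).
#' @return A one-row tibble: `Ca_amplitude`, `Ca_t_to_peak`, `Ca_t_decay`,
#'   `usable`.
#' @export
ca_kinetics <- function(avg_ca, decay_level = 0.5) {
  k <- transient_kinetics(avg_ca, decay_level)
  tibble(Ca_amplitude = k$amplitude, Ca_t_to_peak = k$t_to_peak,
         Ca_t_decay = k$t_decay, usable = k$usable)
}

#' Quantify the three contraction kinetic parameters
#'
#' Identical geometry to [ca_kinetics()] on the contraction trace:
#' `Co_t_contraction` is onset-to-peak, `Co_t_relaxation` the
#' `decay_level` relaxation time from the peak.
#'
#' @param avg_co The averaged Co beat.
#' @param decay_level Fraction of amplitude relaxed (default 0.5).
#' @return A one-row tibble: `Co_amplitude`, `Co_t_contraction`,
#'   `Co_t_relaxation`, `usable`.
#' @export
co_kinetics <- function(avg_co, decay_level = 0.5) {
  k <- transient_kinetics(avg_co, decay_level)
  tibble(Co_amplitude = k$amplitude, Co_t_contraction = k$t_to_peak,
         Co_t_relaxation = k$t_decay, usable = k$usable)
}

#' Summarise one recording into the ten kinetic parameters
#'
#' Runs [ap_kinetics()], [ca_kinetics()] and [co_kinetics()] on the three
#' averaged beats of one recording and binds them into a single ten-column
#' record. A channel whose measurement fails (flat trace, incomplete
#' repolarisation or decay) flags the whole record unusable instead of
#' raising, so a screening run can drop and log it.
#'
#' @param avg_ap,avg_ca,avg_co Averaged beats of the three channels.
#' @param apd_level,decay_level See [ap_kinetics()], [ca_kinetics()].
#' @return A one-row tibble with the ten kinetic parameter columns and
#'   `usable`.
#' @export
beat_kinetics <- function(avg_ap, avg_ca, avg_co, apd_level = 0.9,
                          decay_level = 0.5) {
  safe <- function(f) {
    tryCatch(f, ttm_error = function(e) NULL)
  }
  ap <- safe(ap_kinetics(avg_ap, apd_level))
  ca <- safe(ca_kinetics(avg_ca, decay_level))
  co <- safe(co_kinetics(avg_co, decay_level))
  na_row <- function(cols) {
    as_tibble(setNames(as.list(rep(NA_real_, length(cols))), cols)) |>
      mutate(usable = FALSE)
  }
  pc <- kinetic_parameters()
  if (is.null(ap)) ap <- na_row(pc$parameter[pc$channel == "AP"])
  if (is.null(ca)) ca <- na_row(pc$parameter[pc$channel == "Ca"])
  if (is.null(co)) co <- na_row(pc$parameter[pc$channel == "Co"])
  out <- bind_cols(ap[setdiff(names(ap), "usable")],
                   ca[setdiff(names(ca), "usable")],
                   co[setdiff(names(co), "usable")])
  out$usable <- ap$usable && ca$usable && co$usable &&
    !anyNA(as.numeric(out[1, pc$parameter]))
  out
}

#' Normalise a post-drug record to its own baseline record
#'
#' Every area is measured before and after compound addition; the
#' post-incubation parameters are divided fieldwise by the paired baseline
#' parameters, giving dimensionless fold changes (1 = no change). This
#' removes the large between-sample variation of absolute hiPSC-CM
#' kinetics.
#'
#' @param post,baseline One-row kinetic parameter tibbles
#'   ([beat_kinetics()] output).
#' @return A one-row tibble of fold changes with `usable`.
#' @export
normalize_to_baseline <- function(post, baseline) {
  cols <- kinetic_parameters()$parameter
  b <- as.numeric(baseline[1, cols])
  p <- as.numeric(post[1, cols])
  if (anyNA(b) || any(b <= 0)) {
    .ttm_stop(
      "Baseline record has a non-positive or missing parameter; cannot normalise.",
      "ttm_error_degenerate_baseline")
  }
  out <- as_tibble(setNames(as.list(p / b), cols))
  out$usable <- isTRUE(post$usable) && isTRUE(baseline$usable) && !anyNA(p)
  out
}

#' Average kinetic records across replicates
#'
#' Fieldwise arithmetic mean of kinetic parameter records, used for both
#' aggregation levels of the plate design: the three areas of a well into
#' a well record, and the wells of a condition into a condition record.
#' Records flagged unusable are excluded; the contributor count is
#' reported.
#'
#' @param records A tibble of kinetic parameter rows (with `usable`).
#' @return A one-row tibble of means with `n` contributors and `usable`.
#' @export
aggregate_kinetics <- function(records) {
  cols <- intersect(kinetic_parameters()$parameter, names(records))
  keep <- if ("usable" %in% names(records)) records$usable else
    rep(TRUE, nrow(records))
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    .ttm_stop("All records are unusable; nothing to aggregate.",
              "ttm_error_empty_aggregate")
  }
  kept <- records[keep, cols]
  out <- as_tibble(as.list(colMeans(kept)))
  out$n <- sum(keep)
  out$usable <- TRUE
  out
}
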