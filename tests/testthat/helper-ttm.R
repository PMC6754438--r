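# Shared fixtures, all built in code.

param_ids <- function() kinetic_parameters()$parameter

# Vehicle Gaussians with given means/sds for all ten parameters.
make_stats <- function(mean = 1, sd = 0.05, n = 5) {
  st <- tibble::tibble(parameter = param_ids(),
                       mean = rep_len(mean, 10), sd = rep_len(sd, 10),
                       n = n)
  class(st) <- c("ttm_vehicle_stats", class(st))
  st
}

# A linear rise/fall pulse trace sampled at `fps`, preceded by a flat
# baseline segment. Times in ms.
pulse_trace <- function(rise_ms, fall_ms, amplitude = 1, baseline = 0,
                        pre_ms = 50, post_ms = 50, fps = 1000,
                        channel = "AP") {
  t_on <- pre_ms
  t_peak <- pre_ms + rise_ms
  t_end <- t_peak + fall_ms
  total <- t_end + post_ms
  t <- seq(0, total, by = 1000 / fps)
  v <- rep(baseline, length(t))
  r <- t >= t_on & t < t_peak
  v[r] <- baseline + amplitude * (t[r] - t_on) / rise_ms
  f <- t >= t_peak & t < t_end
  v[f] <- baseline + amplitude * (1 - (t[f] - t_peak) / fall_ms)
  ttm_trace(v, fps = fps, channel = channel)
}

# A square pulse with near-instant (one sample) edges.
square_trace <- function(width_ms, amplitude = 1, baseline = 0,
                         pre_ms = 50, post_ms = 50, fps = 1000,
                         channel = "AP") {
  t <- seq(0, pre_ms + width_ms + post_ms, by = 1000 / fps)
  v <- rep(baseline, length(t))
  v[t >= pre_ms & t < pre_ms + width_ms] <- baseline + amplitude
  ttm_trace(v, fps = fps, channel = channel)
}

# Small frame stack of constant-valued frames.
const_stack <- function(values, fps = 1000, dim = 4,
                        channels = c("AP", "Ca", "Co")) {
  frame_stack(lapply(values, function(v) matrix(v, dim, dim)),
              fps = fps, channels = channels)
}

# Rebuild a trace with new values, keeping rate/channel.
retrace_for_test <- function(tr, value) {
  ttm_trace(value, fps = trace_fps(tr), channel = trace_channel(tr),
            t0 = tr$time_s[1])
}

# Fast experiment design for tests that only need structure, not power.
small_design <- function(...) {
  experiment_design(concentrations_uM = c(0.1, 1), wells = 2, areas = 1,
                    duration_s = 6, ...)
}
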