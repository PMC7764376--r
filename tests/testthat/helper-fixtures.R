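# shared fixtures: analytic signals, small synthetic serials and a
# finite-difference gradient checker for the network implementations

# sinusoidal "breathing" trace with a trough at t = 0
sine_breathing <- function(rate_bpm, dur_s, fs = 25) {
  tt <- (seq_len(floor(dur_s * fs)) - 1) / fs
  time_series(-cos(2 * pi * tt * rate_bpm / 60), fs)
}

# one noiseless serial with strong baseline wander (easiest regime for
# waveform recovery); returns normalized ppg + volume and the truth events
strong_bw_serial <- function(rate_bpm = 10, dur_s = 150, seed = 11,
                             bw_amp = 0.5, am_depth = 0, fm_depth = 0,
                             noise_sd = 0, hr_bpm = 72) {
  b <- generate_breathing_trace(
    breathing_spec(rate_bpm, dur_s, ibi_jitter_cv = 0.03,
                   amplitude_jitter_cv = 0.05, seed = seed))
  mod <- ppg_modulation_spec(hr_bpm = hr_bpm, am_depth = am_depth,
                             bw_amp = bw_amp, fm_depth = fm_depth,
                             noise_sd = noise_sd, seed = seed + 1L)
  list(ppg = normalize_serial(generate_ppg(b$trace, b$events, mod)),
       volume = normalize_serial(b$trace), events = b$events)
}

# central finite-difference gradient of a scalar loss over flat parameters
numerical_gradient <- function(loss_fn, params, eps = 1e-5) {
  flat <- ppgresp:::.flatten_params(params)
  g <- numeric(length(flat))
  for (i in seq_along(flat)) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    g[i] <- (loss_fn(ppgresp:::.unflatten_params(up, params)) -
               loss_fn(ppgresp:::.unflatten_params(dn, params))) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) max(abs(a - b) / pmax(1e-8, abs(a) + abs(b)))
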