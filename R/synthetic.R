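#' Specification of a coached breathing process
#'
#' Describes one coached breathing serial: the target rate, duration and
#' inspiration:expiration shape, plus breath-to-breath variability. A breath
#' is a raised-cosine rise over the inspiration time followed by a
#' raised-cosine fall over the expiration time; total breath duration is
#' drawn around `60/rate_bpm` with multiplicative log-normal jitter.
#'
#' @param rate_bpm Target breathing rate in breaths per minute.
#' @param duration_s Serial duration in seconds.
#' @param ie_ratio Target inspiration/expiration duration ratio.
#' @param ibi_jitter_cv Coefficient of variation of the breath-to-breath
#'   interval (0 = perfectly paced).
#' @param amplitude_jitter_cv Coefficient of variation of breath depth.
#' @param seed Integer seed; the generated serial is a deterministic
#'   function of the spec including this seed.
#'
#' @return A `breathing_spec` object.
#' @export
breathing_spec <- function(rate_bpm, duration_s, ie_ratio = 1,
                           ibi_jitter_cv = 0, amplitude_jitter_cv = 0,
                           seed = 1L) {
  stopifnot(rate_bpm > 0, duration_s > 0, ie_ratio > 0,
            ibi_jitter_cv >= 0, amplitude_jitter_cv >= 0)
  structure(list(rate_bpm = rate_bpm, duration_s = duration_s,
                 ie_ratio = ie_ratio, ibi_jitter_cv = ibi_jitter_cv,
                 amplitude_jitter_cv = amplitude_jitter_cv,
                 seed = as.integer(seed)),
            class = "breathing_spec")
}

# log-normal multiplier with unit mean and coefficient of variation ~ cv
.lnorm_jitter <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a relative tidal-volume trace with known breath events
#'
#' Produces the ground-truth breathing process of one coached serial:
#' a concatenation of breaths, each a raised-cosine rise over Tinsp and a
#' raised-cosine fall over Texp, together with the exact breath events
#' (trough/peak/trough times in continuous time, not snapped to samples).
#' The trace is in relative (unitless) volume; only shape matters.
#'
#' @param spec A [breathing_spec()].
#' @param rate Sampling rate of the emitted trace, Hz.
#'
#' @return A list with elements `trace` (a [time_series()]) and `events`
#'   (a data frame with one row per complete breath: `trough_time`,
#'   `peak_time`, `next_trough_time`, `next_peak_time`, `tinsp`, `texp`,
#'   `ie_ratio`, `amplitude`).
#' @export
#'
#' @examples
#' b <- generate_breathing_trace(breathing_spec(10, 60))
#' nrow(b$events)  # 10 breaths
generate_breathing_trace <- function(spec, rate = 25) {
  stopifnot(inherits(spec, "breathing_spec"), rate > 0)
  base_t <- 60 / spec$rate_bpm
  if (spec$duration_s < base_t)
    stop(sprintf("duration (%g s) is shorter than one breath (%g s)",
                 spec$duration_s, base_t))
  set.seed(spec$seed)
  # draw generously, then truncate at the serial duration
  n_max <- ceiling(spec$duration_s / base_t * 2) + 4L
  tot <- base_t * .lnorm_jitter(n_max, spec$ibi_jitter_cv)
  amp <- .lnorm_jitter(n_max, spec$amplitude_jitter_cv)
  starts <- c(0, cumsum(tot))[seq_len(n_max)]
  keep <- starts < spec$duration_s
  tot <- tot[keep]; amp <- amp[keep]; starts <- starts[keep]
  tinsp <- tot * spec$ie_ratio / (1 + spec$ie_ratio)
  texp <- tot - tinsp

  n <- floor(spec$duration_s * rate)
  tt <- (seq_len(n) - 1) / rate
  i <- findInterval(tt, starts)
  ph <- tt - starts[i]
  rising <- ph < tinsp[i]
  v <- numeric(n)
  v[rising] <- 0.5 * amp[i[rising]] *
    (1 - cos(pi * ph[rising] / tinsp[i[rising]]))
  v[!rising] <- 0.5 * amp[i[!rising]] *
    (1 + cos(pi * (ph[!rising] - tinsp[i[!rising]]) / texp[i[!rising]]))

  complete <- (starts + tot) <= spec$duration_s + 1e-9
  ev <- data.frame(
    trough_time = starts[complete],
    peak_time = (starts + tinsp)[complete],
    next_trough_time = (starts + tot)[complete],
    tinsp = tinsp[complete],
    texp = texp[complete],
    amplitude = amp[complete]
  )
  ev$next_peak_time <- c(ev$peak_time[-1], NA_real_)
  ev$ie_ratio <- ev$tinsp / ev$texp
  list(trace = time_series(v, rate), events = ev)
}

#' Specification of respiratory modulation of a PPG signal
#'
#' Parameters controlling how breathing modulates the synthetic pulse
#' photoplethysmogram: pulse-amplitude modulation, baseline wander and
#' beat-interval (frequency) modulation, plus additive white noise.
#' All depths are expressed relative to the unit pulse amplitude.
#'
#' @param hr_bpm Mean heart rate, beats per minute. Must exceed the
#'   breathing rate of the paired volume trace.
#' @param am_depth Fractional pulse-amplitude modulation in `[0, 1)`.
#' @param bw_amp Baseline-wander amplitude relative to pulse amplitude.
#' @param fm_depth Fractional beat-interval modulation in `[0, 1)`;
#'   values >= 1 could produce non-positive beat intervals and error.
#' @param noise_sd Additive white-noise SD relative to pulse amplitude.
#' @param seed Integer seed for the noise draw.
#'
#' @return A `ppg_modulation_spec` object.
#' @export
ppg_modulation_spec <- function(hr_bpm = 70, am_depth = 0.3, bw_amp = 0.3,
                                fm_depth = 0.05, noise_sd = 0.05,
                                seed = 1L) {
  stopifnot(hr_bpm > 0, am_depth >= 0, am_depth < 1, bw_amp >= 0,
            noise_sd >= 0)
  if (fm_depth < 0 || fm_depth >= 1)
    stop("fm_depth must lie in [0, 1): beat intervals must stay positive")
  structure(list(hr_bpm = hr_bpm, am_depth = am_depth, bw_amp = bw_amp,
                 fm_depth = fm_depth, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ppg_modulation_spec")
}

# raised-cosine lobe contribution over sample times tt
.rc_lobe <- function(tt, center, width, amp) {
  out <- numeric(length(tt))
  inw <- abs(tt - center) <= width / 2
  out[inw] <- 0.5 * amp * (1 + cos(2 * pi * (tt[inw] - center) / width))
  out
}

#' Synthesize a PPG trace modulated by a breathing volume trace
#'
#' Builds a pulse train as a sum of per-beat waveforms (each beat is a
#' systolic raised-cosine lobe plus a dicrotic lobe at 0.45 relative
#' amplitude, offset by 0.4 of the beat interval). Breathing modulates the
#' train three ways, with `vhat` the volume trace rescaled to `[-1, 1]`:
#' the beat interval is `(60/hr_bpm) * (1 + fm_depth * vhat)`, the pulse
#' amplitude is scaled by `(1 + am_depth * vhat)`, and a baseline term
#' `bw_amp * vhat` plus white noise is added.
#'
#' @param volume Reference volume trace ([time_series()]) paired with the
#'   events; defines the timeline of the PPG.
#' @param events Breath events of the volume trace (used to validate that
#'   the cardiac rate exceeds the breathing rate).
#' @param mod A [ppg_modulation_spec()].
#'
#' @return A [time_series()] PPG at the volume trace's sampling rate.
#' @export
generate_ppg <- function(volume, events, mod) {
  stopifnot(inherits(volume, "time_series"),
            inherits(mod, "ppg_modulation_spec"))
  if (!is.null(events) && nrow(events) > 1) {
    br <- 60 / stats::median(diff(events$peak_time), na.rm = TRUE)
    if (is.finite(br) && mod$hr_bpm <= br)
      stop("hr_bpm must exceed the breathing rate of the paired process")
  }
  v <- volume$samples
  n <- length(v)
  rate <- volume$rate
  dur <- n / rate
  rng <- range(v)
  vhat <- if (diff(rng) > 0) 2 * (v - rng[1]) / diff(rng) - 1 else rep(0, n)
  vhat_at <- function(t) vhat[pmin(n, pmax(1L, floor(t * rate) + 1L))]

  base_bi <- 60 / mod$hr_bpm
  # beat onsets: interval modulated by the volume at the beat onset
  beats <- numeric(ceiling(dur / (base_bi * (1 - mod$fm_depth))) + 2L)
  ivals <- beats
  nb <- 0L
  t <- 0
  while (t < dur) {
    nb <- nb + 1L
    beats[nb] <- t
    ivals[nb] <- base_bi * (1 + mod$fm_depth * vhat_at(t))
    t <- t + ivals[nb]
  }
  beats <- beats[seq_len(nb)]
  ivals <- ivals[seq_len(nb)]

  tt <- (seq_len(n) - 1) / rate
  y <- numeric(n)
  for (b in seq_len(nb)) {
    s <- beats[b]; bi <- ivals[b]
    a <- 1 + mod$am_depth * vhat_at(s)
    i0 <- max(1L, floor(s * rate) + 1L)
    i1 <- min(n, ceiling((s + bi) * rate) + 1L)
    idx <- i0:i1
    y[idx] <- y[idx] +
      .rc_lobe(tt[idx], s + 0.2 * bi, 0.4 * bi, a) +
      .rc_lobe(tt[idx], s + 0.6 * bi, 0.5 * bi, 0.45 * a)
  }
  y <- y + mod$bw_amp * vhat
  if (mod$noise_sd > 0) {
    set.seed(mod$seed)
    y <- y + stats::rnorm(n, sd = mod$noise_sd)
  }
  time_series(y, rate, t0 = volume$t0)
}

#' Specification of a synthetic study cohort
#'
#' Describes the full study design emulated by the simulator: a number of
#' subjects, a set of coached breathing rates, a serial duration, and
#' uniform ranges from which each subject's physiological parameters are
#' drawn once. Defaults mirror a 22-subject study with coached rates of
#' 6, 8, 10, 12 and 14 breaths per minute and five-minute serials.
#'
#' @param n_subjects Number of subjects.
#' @param rates_bpm Coached breathing rates, breaths per minute.
#' @param serial_duration_s Duration of each serial, seconds.
#' @param sample_rate Sampling rate of emitted traces, Hz. With
#'   `raw_rates = TRUE` the PPG is emitted at 75 Hz and the volume at
#'   100 Hz instead, to exercise the resampling stage.
#' @param param_ranges Named list of `c(lo, hi)` uniform ranges for the
#'   per-subject parameters `hr_bpm`, `am_depth`, `bw_amp`, `fm_depth`,
#'   `noise_sd`, `ie_ratio`, `ibi_jitter_cv`, `amplitude_jitter_cv`.
#'   Entries override the defaults documented in
#'   [default_param_ranges()].
#' @param raw_rates Emit native-rate signals (75 Hz PPG, 100 Hz volume)?
#' @param master_seed Master seed; the whole cohort is a deterministic
#'   function of the spec including this seed.
#'
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 22, rates_bpm = c(6, 8, 10, 12, 14),
                        serial_duration_s = 300, sample_rate = 25,
                        param_ranges = list(), raw_rates = FALSE,
                        master_seed = 20201212L) {
  stopifnot(n_subjects >= 1, length(rates_bpm) >= 1, all(rates_bpm > 0),
            serial_duration_s > 0, sample_rate > 0)
  pr <- utils::modifyList(default_param_ranges(), param_ranges)
  structure(list(n_subjects = as.integer(n_subjects),
                 rates_bpm = as.numeric(rates_bpm),
                 serial_duration_s = serial_duration_s,
                 sample_rate = sample_rate,
                 param_ranges = pr, raw_rates = isTRUE(raw_rates),
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Default per-subject parameter ranges for the cohort simulator
#'
#' The study being emulated reports no subject heart rates or modulation
#' strengths, so these ranges are the package's own choice of plausible
#' adult physiology and PPG respiratory-modulation strengths; every range
#' can be overridden through `cohort_spec(param_ranges = ...)`.
#'
#' @return Named list of `c(lo, hi)` ranges.
#' @export
default_param_ranges <- function() {
  list(hr_bpm = c(55, 95),
       am_depth = c(0.1, 0.5),
       bw_amp = c(0.1, 0.6),
       fm_depth = c(0.02, 0.1),
       noise_sd = c(0, 0.1),
       ie_ratio = c(0.8, 1.2),
       ibi_jitter_cv = c(0.02, 0.08),
       amplitude_jitter_cv = c(0.05, 0.15))
}

#' Generate a synthetic cohort of paired PPG / volume serials
#'
#' Draws each subject's physiological parameters once from the ranges in
#' the spec, then generates one serial (paired PPG and reference volume
#' trace plus exact breath events) per subject and coached rate. The
#' result is bit-reproducible given the spec's `master_seed`.
#'
#' @param spec A [cohort_spec()].
#'
#' @return A `ppg_cohort` object: a list with `spec`, `subjects` (data
#'   frame of drawn per-subject parameters) and `serials`, a list of
#'   records each holding `subject_id`, `rate_bpm`, `ppg`, `volume`,
#'   `events` and the generating parameter set.
#' @export
#'
#' @examples
#' co <- generate_cohort(cohort_spec(n_subjects = 1, rates_bpm = 10,
#'                                   serial_duration_s = 60))
#' length(co$serials)  # 1
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$master_seed)
  pr <- spec$param_ranges
  draw <- function(nm) stats::runif(spec$n_subjects, pr[[nm]][1], pr[[nm]][2])
  subjects <- data.frame(subject_id = seq_len(spec$n_subjects))
  for (nm in names(pr)) subjects[[nm]] <- draw(nm)
  n_serial <- spec$n_subjects * length(spec$rates_bpm)
  seeds_breath <- sample.int(.Machine$integer.max - 1L, n_serial)
  seeds_ppg <- sample.int(.Machine$integer.max - 1L, n_serial)

  ppg_rate <- if (spec$raw_rates) 75 else spec$sample_rate
  vol_rate <- if (spec$raw_rates) 100 else spec$sample_rate

  serials <- vector("list", n_serial)
  k <- 0L
  for (s in seq_len(spec$n_subjects)) {
    for (r in spec$rates_bpm) {
      k <- k + 1L
      bs <- breathing_spec(r, spec$serial_duration_s,
                           ie_ratio = subjects$ie_ratio[s],
                           ibi_jitter_cv = subjects$ibi_jitter_cv[s],
                           amplitude_jitter_cv = subjects$amplitude_jitter_cv[s],
                           seed = seeds_breath[k])
      vol <- generate_breathing_trace(bs, rate = vol_rate)
      # modulation source at the PPG's own rate (same breaths: same seed)
      vol_src <- if (ppg_rate == vol_rate) vol
                 else generate_breathing_trace(bs, rate = ppg_rate)
      mod <- ppg_modulation_spec(hr_bpm = subjects$hr_bpm[s],
                                 am_depth = subjects$am_depth[s],
                                 bw_amp = subjects$bw_amp[s],
                                 fm_depth = subjects$fm_depth[s],
                                 noise_sd = subjects$noise_sd[s],
                                 seed = seeds_ppg[k])
      ppg <- generate_ppg(vol_src$trace, vol_src$events, mod)
      serials[[k]] <- list(subject_id = s, rate_bpm = r, ppg = ppg,
                           volume = vol$trace, events = vol$events,
                           breathing_spec = bs, modulation_spec = mod)
    }
  }
  structure(list(spec = spec, subjects = subjects, serials = serials),
            class = "ppg_cohort")
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cat(sprintf("<ppg_cohort> %d subjects x %d rates = %d serials of %g s @ %g Hz\n",
              x$spec$n_subjects, length(x$spec$rates_bpm),
              length(x$serials), x$spec$serial_duration_s,
              x$serials[[1]]$ppg$rate))
  invisible(x)
}
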