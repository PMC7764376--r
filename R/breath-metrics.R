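#' Savitzky-Golay smoothing of a tidal-volume waveform
#'
#' Least-squares polynomial smoothing applied to a predicted (or
#' reference) volume trace before breath segmentation. The default
#' 1-second window at order 3 suppresses residual cardiac ripple
#' (>= 0.9 Hz) while passing breathing content (<= 0.25 Hz at the coached
#' rates) essentially untouched.
#'
#' @param tvw A [time_series()].
#' @param sg_window_s Window length in seconds; the sample count is
#'   rounded to the nearest odd integer.
#' @param sg_order Polynomial order (< window length in samples).
#' @return A smoothed [time_series()] of the same length.
#' @export
smooth_tvw <- function(tvw, sg_window_s = 1.0, sg_order = 3) {
  stopifnot(inherits(tvw, "time_series"))
  n <- round(sg_window_s * tvw$rate)
  if (n %% 2 == 0) n <- n + 1
  if (n < 3) stop("smoothing window too short")
  if (sg_order >= n) stop("sg_order must be smaller than the window length")
  if (length(tvw$samples) <= n) stop("trace shorter than smoothing window")
  time_series(signal::sgolayfilt(tvw$samples, p = sg_order, n = n),
              tvw$rate, tvw$t0)
}

# local maxima / minima of x, admitting the boundary samples; plateaus
# contribute their trailing edge (where the slope turns)
.local_extrema <- function(x) {
  n <- length(x)
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (!length(nz)) return(list(peaks = integer(), troughs = integer()))
  # carry the last non-zero slope through plateaus (leading plateau takes
  # the first real slope)
  s[seq_len(nz[1])] <- s[nz[1]]
  filled <- s != 0
  s <- s[cummax(seq_along(s) * filled)]
  chg <- which(s[-1] != s[-length(s)]) + 1L
  peaks <- chg[s[chg] < 0]
  troughs <- chg[s[chg] > 0]
  # boundaries: sample 1 / n acts as the extremum that opens/closes the
  # alternating sequence
  if (s[1] > 0) troughs <- c(1L, troughs) else peaks <- c(1L, peaks)
  if (s[length(s)] > 0) peaks <- c(peaks, n) else troughs <- c(troughs, n)
  list(peaks = sort(unique(peaks)), troughs = sort(unique(troughs)))
}

# collapse same-type runs in an alternating extrema sequence, keeping the
# most extreme candidate of each run
.enforce_alternation <- function(idx, type, x) {
  keep <- rep(TRUE, length(idx))
  i <- 1L
  while (i < length(idx)) {
    j <- i + 1L
    while (j <= length(idx) && type[j] == type[i]) j <- j + 1L
    if (j - i > 1L) {
      run <- i:(j - 1L)
      best <- if (type[i] == "peak") run[which.max(x[idx[run]])]
              else run[which.min(x[idx[run]])]
      keep[setdiff(run, best)] <- FALSE
      idx <- idx[keep]; type <- type[keep]
      keep <- rep(TRUE, length(idx))
      i <- 1L
    } else i <- j
  }
  list(idx = idx, type = type)
}

#' Segment a tidal-volume waveform into breaths
#'
#' Finds the strictly alternating trough/peak sequence of a (smoothed)
#' volume trace. Candidate extrema are local extrema (boundary samples
#' included); adjacent trough-peak swings smaller than
#' `prominence_frac` times the serial's 5th-95th percentile range are
#' pruned, peaks closer together than `min_ibi_s` are resolved by keeping
#' the higher peak, and incomplete leading/trailing half-breaths are
#' dropped so that every returned event is a complete
#' trough-peak-trough breath.
#'
#' @param tvw A smoothed [time_series()].
#' @param prominence_frac Minimum swing as a fraction of the 5th-95th
#'   percentile amplitude range.
#' @param min_ibi_s Minimum separation between successive peaks, seconds
#'   (2 s caps the detectable rate at 30 breaths/min).
#' @return A data frame of breath events (`trough_time`, `peak_time`,
#'   `next_trough_time`, `next_peak_time`, `tinsp`, `texp`, `ie_ratio`),
#'   empty with attribute `flag = "no_breaths"` when fewer than two
#'   complete breaths are found.
#' @export
detect_breaths <- function(tvw, prominence_frac = 0.2, min_ibi_s = 2.0) {
  stopifnot(inherits(tvw, "time_series"))
  x <- tvw$samples
  empty <- structure(
    data.frame(trough_time = numeric(), peak_time = numeric(),
               next_trough_time = numeric(), next_peak_time = numeric(),
               tinsp = numeric(), texp = numeric(), ie_ratio = numeric()),
    flag = "no_breaths")
  qr <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  span <- qr[2] - qr[1]
  if (!is.finite(span) || span <= 0) {
    warning("constant or degenerate trace: no breaths detected")
    return(empty)
  }
  prom <- prominence_frac * span

  ex <- .local_extrema(x)
  idx <- c(ex$peaks, ex$troughs)
  type <- c(rep("peak", length(ex$peaks)), rep("trough", length(ex$troughs)))
  o <- order(idx)
  idx <- idx[o]; type <- type[o]
  al <- .enforce_alternation(idx, type, x)
  idx <- al$idx; type <- al$type

  # prune sub-threshold swings, smallest first, re-alternating as we go
  repeat {
    if (length(idx) < 2L) break
    swings <- abs(diff(x[idx]))
    w <- which.min(swings)
    if (swings[w] >= prom) break
    idx <- idx[-c(w, w + 1L)]
    type <- type[-c(w, w + 1L)]
    al <- .enforce_alternation(idx, type, x)
    idx <- al$idx; type <- al$type
  }

  # minimum inter-peak separation: drop the lower of two close peaks
  repeat {
    pk <- which(type == "peak")
    if (length(pk) < 2L) break
    gaps <- diff(idx[pk]) / tvw$rate
    v <- which(gaps < min_ibi_s)
    if (!length(v)) break
    a <- pk[v[1]]; b <- pk[v[1] + 1L]
    drop_i <- if (x[idx[a]] >= x[idx[b]]) b else a
    idx <- idx[-drop_i]; type <- type[-drop_i]
    al <- .enforce_alternation(idx, type, x)
    idx <- al$idx; type <- al$type
  }

  # trim to trough ... trough
  while (length(type) && type[1] != "trough") {
    idx <- idx[-1]; type <- type[-1]
  }
  while (length(type) && type[length(type)] != "trough") {
    idx <- idx[-length(idx)]; type <- type[-length(type)]
  }
  n_breaths <- (length(idx) - 1L) %/% 2L
  if (n_breaths < 2L) {
    warning("fewer than two complete breaths detected")
    return(empty)
  }
  tt <- ts_time(tvw)
  tr <- idx[seq(1L, by = 2L, length.out = n_breaths + 1L)]
  pk <- idx[seq(2L, by = 2L, length.out = n_breaths)]
  ev <- data.frame(trough_time = tt[tr[-length(tr)]],
                   peak_time = tt[pk],
                   next_trough_time = tt[tr[-1]])
  ev$next_peak_time <- c(ev$peak_time[-1], NA_real_)
  ev$tinsp <- ev$peak_time - ev$trough_time
  ev$texp <- ev$next_trough_time - ev$peak_time
  ev$ie_ratio <- ev$tinsp / ev$texp
  ev
}

#' Summarize breath events of one evaluation window
#'
#' Per-window means of the five breathing metrics: inspiration time,
#' expiration time, I:E ratio (per breath, then averaged), inter-breath
#' interval (consecutive peak-to-peak), and breathing rate computed by
#' counting complete breaths over the window duration — deliberately
#' independent of the IBI.
#'
#' @param events Breath events from [detect_breaths()] (or ground truth).
#' @param window_duration_s Duration of the evaluation window, seconds.
#' @return A one-row data frame (`n_breaths`, `tinsp_s`, `texp_s`,
#'   `ie_ratio`, `ibi_s`, `br_bpm`, `flag`); metrics are `NA` with
#'   `flag = "undefined"` when fewer than two breaths are available
#'   (the window is retained, not dropped).
#' @export
compute_metrics <- function(events, window_duration_s) {
  stopifnot(window_duration_s > 0)
  if (is.null(events) || nrow(events) < 2L)
    return(data.frame(n_breaths = if (is.null(events)) 0L else nrow(events),
                      tinsp_s = NA_real_, texp_s = NA_real_,
                      ie_ratio = NA_real_, ibi_s = NA_real_,
                      br_bpm = NA_real_, flag = "undefined",
                      stringsAsFactors = FALSE))
  data.frame(n_breaths = nrow(events),
             tinsp_s = mean(events$tinsp),
             texp_s = mean(events$texp),
             ie_ratio = mean(events$ie_ratio),
             ibi_s = mean(diff(events$peak_time)),
             br_bpm = 60 * nrow(events) / window_duration_s,
             flag = "", stringsAsFactors = FALSE)
}

#' Match derived breaths to reference breaths by peak time
#'
#' Greedy nearest-neighbour matching of peak times: the globally closest
#' derived/reference pair is matched first, each breath is used at most
#' once, and pairs further apart than `max_offset_s` are rejected.
#' Unmatched derived breaths are counted as spurious, unmatched reference
#' breaths as missed.
#'
#' @param derived_events,reference_events Time-sorted breath-event data
#'   frames with a `peak_time` column.
#' @param max_offset_s Maximum |peak-time difference| for a valid match;
#'   defaults to half the reference median IBI.
#' @return List with `pairs` (data frame: `derived_peak`,
#'   `reference_peak`, `offset_s`), `n_spurious` and `n_missed`.
#' @export
pair_breaths <- function(derived_events, reference_events,
                         max_offset_s = NULL) {
  dp <- derived_events$peak_time
  rp <- reference_events$peak_time
  if (is.null(max_offset_s)) {
    ibi <- stats::median(diff(rp))
    max_offset_s <- if (is.finite(ibi)) ibi / 2 else Inf
  }
  pairs <- data.frame(derived_peak = numeric(), reference_peak = numeric(),
                      offset_s = numeric())
  if (length(dp) && length(rp)) {
    off <- abs(outer(dp, rp, "-"))
    repeat {
      w <- which.min(off)
      if (!length(w) || off[w] > max_offset_s || !is.finite(off[w])) break
      i <- (w - 1L) %% length(dp) + 1L
      j <- (w - 1L) %/% length(dp) + 1L
      pairs <- rbind(pairs, data.frame(derived_peak = dp[i],
                                       reference_peak = rp[j],
                                       offset_s = abs(dp[i] - rp[j])))
      off[i, ] <- Inf
      off[, j] <- Inf
    }
  }
  pairs <- pairs[order(pairs$reference_peak), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       n_spurious = length(dp) - nrow(pairs),
       n_missed = length(rp) - nrow(pairs))
}
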