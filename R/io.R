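#' Read a two-column (time, value) CSV signal
#'
#' Expects two numeric columns: time in seconds and sample value. The
#' sampling rate is inferred from the median time step; spacing deviating
#' from uniform by more than 1% of that step is an error, as are missing
#' values and duplicated timestamps (reported with their row index).
#'
#' @param path Path to the CSV file.
#' @return A [time_series()].
#' @export
read_signal_csv <- function(path) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("expected two columns (time_s, value) in ", path)
  tt <- as.numeric(d[[1]]); x <- as.numeric(d[[2]])
  bad <- which(!is.finite(tt) | !is.finite(x))
  if (length(bad))
    stop("non-finite or missing value at row ", bad[1], " of ", path)
  if (length(tt) < 2) stop("need at least two samples")
  dt <- diff(tt)
  dup <- which(dt <= 0)
  if (length(dup))
    stop("non-increasing or duplicated timestamp at row ", dup[1] + 1L,
         " of ", path)
  step <- stats::median(dt)
  if (any(abs(dt - step) > 0.01 * step))
    stop("non-uniform sampling (beyond 1% of the median step) in ", path)
  time_series(x, rate = 1 / step, t0 = tt[1])
}

#' Write a time series as a two-column CSV
#'
#' @param ts A [time_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(ts, path) {
  stopifnot(inherits(ts, "time_series"))
  d <- data.frame(time_s = ts_time(ts), value = ts$samples)
  utils::write.csv(format(d, digits = 12, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- minimal EDF (European Data Format) writer / reader -------------------
# 16-bit EDF with one-second data records; enough for round-tripping the
# simulator's output and for reading single channels out of multi-channel
# files. Physical dimension is "a.u." throughout (relative signals).

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write channels to an EDF file
#'
#' Writes one or more equally long channels sharing a common integer
#' sampling rate to a minimal EDF file with one-second data records and
#' 16-bit samples. The trailing partial second, if any, is dropped.
#'
#' @param channels Named list of [time_series()] objects; names become the
#'   EDF channel labels. All channels must have integer sampling rates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(channels, path) {
  stopifnot(is.list(channels), length(channels) > 0,
            !is.null(names(channels)))
  ns <- length(channels)
  rates <- vapply(channels, function(x) x$rate, numeric(1))
  if (any(rates != round(rates)))
    stop("EDF writer requires integer sampling rates")
  n_rec <- min(vapply(channels, function(x)
    floor(length(x$samples) / x$rate), numeric(1)))
  if (n_rec < 1) stop("channels shorter than one 1-second record")

  phys_min <- phys_max <- dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- channels[[i]]$samples[seq_len(n_rec * rates[i])]
    lo <- min(x); hi <- max(x)
    if (hi <= lo) hi <- lo + 1
    pm <- pretty(c(lo, hi), n = 2)
    phys_min[[i]] <- pm[1]; phys_max[[i]] <- pm[length(pm)]
    dig[[i]] <- as.integer(round((x - phys_min[[i]]) /
      (phys_max[[i]] - phys_min[[i]]) * 65534 - 32767))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X", 80), .edf_pad("X", 80),
    .edf_pad("01.01.20", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (ns + 1), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad("1", 8), .edf_pad(ns, 4))
  fields <- list(
    c(vapply(names(channels), .edf_pad, "", width = 16)),
    rep(.edf_pad("", 80), ns),
    rep(.edf_pad("a.u.", 8), ns),
    vapply(phys_min, .edf_pad, "", width = 8),
    vapply(phys_max, .edf_pad, "", width = 8),
    rep(.edf_pad("-32767", 8), ns),
    rep(.edf_pad("32767", 8), ns),
    rep(.edf_pad("", 80), ns),
    vapply(rates, .edf_pad, "", width = 8),
    rep(.edf_pad("", 32), ns))
  writeChar(paste0(hdr, paste0(unlist(fields), collapse = "")), con,
            eos = NULL)
  for (r in seq_len(n_rec))
    for (i in seq_len(ns))
      writeBin(dig[[i]][((r - 1) * rates[i] + 1):(r * rates[i])], con,
               size = 2, endian = "little")
  invisible(path)
}

#' Read one channel from an EDF file
#'
#' @param path Path to an EDF file.
#' @param channel_label Label of the channel to extract. A missing label
#'   is an error that lists the labels present in the file.
#' @return A [time_series()].
#' @export
read_edf <- function(path, channel_label) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin_ <- as.numeric(rdv(8)); dmax_ <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  ch <- match(channel_label, labels)
  if (is.na(ch))
    stop("channel '", channel_label, "' not found; available: ",
         paste(labels, collapse = ", "))
  out <- numeric(n_rec * spr[ch])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, integer(), n = spr[i], size = 2,
                      endian = "little")
      if (i == ch)
        out[((r - 1) * spr[ch] + 1):(r * spr[ch])] <- vals
    }
  }
  scale <- (pmax_[ch] - pmin_[ch]) / (dmax_[ch] - dmin_[ch])
  time_series(pmin_[ch] + (out - dmin_[ch]) * scale,
              rate = spr[ch] / rec_dur)
}

#' Resample a time series to a target rate
#'
#' Fourier-domain resampling: the spectrum is truncated (downsampling) or
#' zero-padded (upsampling) and inverted at the new rate, which is exact
#' for band-limited content and introduces no group delay. The covered
#' duration is preserved to within one output sample. A series already at
#' the target rate is returned unchanged.
#'
#' @param ts A [time_series()].
#' @param target_rate Target sampling rate, Hz.
#' @return A [time_series()] at `target_rate`.
#' @export
resample_to <- function(ts, target_rate = 25) {
  stopifnot(inherits(ts, "time_series"))
  if (!is.numeric(target_rate) || target_rate <= 0)
    stop("target_rate must be positive")
  if (isTRUE(all.equal(ts$rate, target_rate))) return(ts)
  n <- length(ts$samples)
  n2 <- floor(n * target_rate / ts$rate)
  if (n2 < 2) stop("resampled signal would be shorter than two samples")
  X <- stats::fft(ts$samples)
  Y <- complex(length.out = n2)
  m <- min(n, n2)
  h <- if (m %% 2 == 0) m %/% 2 - 1L else (m - 1L) %/% 2L
  Y[1] <- X[1]
  if (h > 0) {
    Y[1 + seq_len(h)] <- X[1 + seq_len(h)]
    Y[n2 + 1 - seq_len(h)] <- X[n + 1 - seq_len(h)]
  }
  if (m %% 2 == 0) Y[m %/% 2 + 1] <- X[m %/% 2 + 1]
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  time_series(y, target_rate, t0 = ts$t0)
}

#' Z-score normalize a serial
#'
#' Centers and scales one serial to zero mean and unit variance; this is
#' the scaling applied to both PPG inputs and volume regression targets.
#' Constant signals are an error.
#'
#' @param ts A [time_series()].
#' @return A normalized [time_series()].
#' @export
normalize_serial <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  s <- stats::sd(ts$samples)
  if (!is.finite(s) || s == 0) stop("cannot normalize a constant signal")
  time_series((ts$samples - mean(ts$samples)) / s, ts$rate, ts$t0)
}

#' Write a cohort to disk as CSV signals plus ground-truth JSON
#'
#' Each serial becomes `subject<S>_rate<R>_ppg.csv`,
#' `subject<S>_rate<R>_vol.csv` and `subject<S>_rate<R>_truth.json`
#' (breath events plus generator parameters). Optionally an EDF file with
#' both channels is written alongside.
#'
#' @param cohort A `ppg_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param edf Also write a two-channel EDF per serial?
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir, edf = FALSE) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$serials) {
    stem <- file.path(dir, sprintf("subject%02d_rate%02d",
                                   rec$subject_id, rec$rate_bpm))
    write_signal_csv(rec$ppg, paste0(stem, "_ppg.csv"))
    write_signal_csv(rec$volume, paste0(stem, "_vol.csv"))
    truth <- list(subject_id = rec$subject_id, rate_bpm = rec$rate_bpm,
                  events = rec$events,
                  breathing_spec = unclass(rec$breathing_spec),
                  modulation_spec = unclass(rec$modulation_spec))
    jsonlite::write_json(truth, paste0(stem, "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    if (edf)
      write_edf(list(PPG = rec$ppg, Volume = rec$volume),
                paste0(stem, ".edf"))
  }
  invisible(dir)
}
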