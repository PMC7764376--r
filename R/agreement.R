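#' Pearson correlation between predicted and reference waveform segments
#'
#' Computed on the overlapping region of the two segments (the predicted
#' trace starts after the warm-up region under causal alignment, so the
#' overlap is resolved by time, not by index).
#'
#' @param predicted,reference [time_series()] segments at the same rate.
#' @return List with `r`, `p` and `n` (overlap length); `r` is `NA` when
#'   either segment has zero variance.
#' @export
window_correlation <- function(predicted, reference) {
  stopifnot(inherits(predicted, "time_series"),
            inherits(reference, "time_series"))
  if (abs(predicted$rate - reference$rate) > 1e-9)
    stop("segments must share a sampling rate")
  t_lo <- max(predicted$t0, reference$t0)
  ip <- round((t_lo - predicted$t0) * predicted$rate)
  ir <- round((t_lo - reference$t0) * reference$rate)
  n <- min(length(predicted$samples) - ip, length(reference$samples) - ir)
  if (n < 3) stop("segments do not overlap")
  a <- predicted$samples[ip + seq_len(n)]
  b <- reference$samples[ir + seq_len(n)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Fraction of windows exceeding each correlation threshold
#'
#' @param r_values Per-window Pearson correlations (`NA`s are dropped).
#' @param thresholds Ascending correlation thresholds.
#' @return Data frame with `threshold` and `fraction` (non-increasing,
#'   in `[0, 1]`).
#' @export
exceedance_curve <- function(r_values, thresholds = seq(0, 1, by = 0.05)) {
  r_values <- r_values[!is.na(r_values)]
  if (!length(r_values)) stop("no correlation values supplied")
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  data.frame(threshold = thresholds,
             fraction = vapply(thresholds,
                               function(th) mean(r_values >= th),
                               numeric(1)))
}

#' Paired t-test between derived and reference metric values
#'
#' Two-sided paired t-test plus the per-arm mean (SD) summaries. Pairs
#' with a missing value in either arm are dropped pairwise.
#'
#' @param derived,reference Equal-length numeric vectors.
#' @return List with `t`, `p`, `df`, `n`, `mean_derived`, `sd_derived`,
#'   `mean_reference`, `sd_reference`, `mean_diff`.
#' @export
paired_ttest <- function(derived, reference) {
  if (length(derived) != length(reference))
    stop("derived and reference must have equal length")
  ok <- is.finite(derived) & is.finite(reference)
  d <- derived[ok]; r <- reference[ok]
  if (length(d) < 2) stop("need at least two complete pairs")
  if (stats::sd(d - r) == 0) {
    # constant differences: t.test refuses; the limit is exact
    md <- mean(d - r)
    tt <- list(statistic = if (md == 0) 0 else sign(md) * Inf,
               p.value = if (md == 0) 1 else 0,
               parameter = length(d) - 1)
  } else {
    tt <- stats::t.test(d, r, paired = TRUE)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n = length(d),
       mean_derived = mean(d), sd_derived = stats::sd(d),
       mean_reference = mean(r), sd_reference = stats::sd(r),
       mean_diff = mean(d - r))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `derived - reference` in absolute mode, or percent
#' differences `100 * (derived - reference) / pair mean` in relative
#' mode. Bias is the mean difference and the 95% limits of agreement are
#' `bias +/- 1.96 * SD(differences)`.
#'
#' @param derived,reference Equal-length numeric vectors; pairs with a
#'   missing value are dropped pairwise.
#' @param relative Use percent-of-pair-mean differences?
#' @return An `agreement_result` list: `n`, `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `relative`, plus the per-pair `means` and `diffs` used
#'   (for Bland-Altman plots).
#' @export
bland_altman <- function(derived, reference, relative = FALSE) {
  if (length(derived) != length(reference))
    stop("derived and reference must have equal length")
  ok <- is.finite(derived) & is.finite(reference)
  d <- derived[ok]; r <- reference[ok]
  if (length(d) < 2) stop("need at least two complete pairs")
  m <- (d + r) / 2
  if (relative && any(m == 0))
    stop("relative mode undefined: a pair mean equals zero")
  diffs <- if (relative) 100 * (d - r) / m else d - r
  bias <- mean(diffs)
  sdd <- stats::sd(diffs)
  structure(list(n = length(d), bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 relative = relative, means = m, diffs = diffs),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s): n = %d, bias = %.4g, 95%% LoA %.4g to %.4g\n",
              if (x$relative) "percent differences" else "absolute",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

.metric_cols <- c(tinsp_s = "Tinsp (s)", texp_s = "Texp (s)",
                  ie_ratio = "I:E ratio", ibi_s = "IBI (s)",
                  br_bpm = "BR (BPM)")

#' Build the agreement report from per-window metric rows
#'
#' Takes the per-window metric table produced by the pipeline (one row
#' per window and method, reference included) and assembles, for every
#' metric and derived method: per-arm mean (SD) with the paired t-test
#' p-value (a Table-2-style layout); Pearson r between derived and
#' reference metric values, absolute and percent Bland-Altman bias with
#' 95% limits of agreement (a Table-3-style layout); and tidy
#' Bland-Altman plot points. Windows with undefined metrics are dropped
#' pairwise per metric, with the drop counts reported.
#'
#' @param windows Data frame with columns `subject_id`, `rate_bpm`,
#'   `fold`, `method`, the five metric columns (`tinsp_s`, `texp_s`,
#'   `ie_ratio`, `ibi_s`, `br_bpm`) and `r_window`; the reference rows
#'   have `method == "reference"`.
#' @return A `ppg_report` list: `summary` (per-arm means and t-tests),
#'   `agreement` (r, absolute and percent bias/LoA per metric x method),
#'   `plot_data` (tidy per-pair points) and `exceedance` (per-method
#'   waveform-correlation exceedance curve).
#' @export
build_report <- function(windows) {
  if (is.null(windows) || !nrow(windows)) stop("empty metric table")
  if (!"method" %in% names(windows)) stop("missing 'method' column")
  methods <- setdiff(unique(windows$method), "reference")
  if (!length(methods)) stop("no derived methods in the metric table")
  ref <- windows[windows$method == "reference", ]
  if (!nrow(ref)) stop("no reference rows in the metric table")
  key <- function(d) paste(d$subject_id, d$rate_bpm, d$fold)

  summary_rows <- list(); agree_rows <- list(); plot_rows <- list()
  for (met in names(.metric_cols)) {
    for (m in methods) {
      der <- windows[windows$method == m, ]
      i <- match(key(ref), key(der))
      x <- der[[met]][i]; y <- ref[[met]]
      ok <- is.finite(x) & is.finite(y)
      n_drop <- sum(!ok)
      if (sum(ok) < 3) {
        warning(sprintf("metric %s / method %s: too few defined pairs",
                        met, m))
        next
      }
      tt <- paired_ttest(x[ok], y[ok])
      ct <- if (stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
        stats::cor.test(x[ok], y[ok])
      else list(estimate = NA_real_, p.value = NA_real_)
      ba <- bland_altman(x[ok], y[ok])
      bp <- bland_altman(x[ok], y[ok], relative = TRUE)
      summary_rows[[paste(met, m)]] <- data.frame(
        metric = .metric_cols[[met]], method = m, n = tt$n,
        mean_reference = tt$mean_reference,
        sd_reference = tt$sd_reference,
        mean_derived = tt$mean_derived, sd_derived = tt$sd_derived,
        t = tt$t, p_value = tt$p, n_dropped = n_drop)
      agree_rows[[paste(met, m)]] <- data.frame(
        metric = .metric_cols[[met]], method = m, n = ba$n,
        pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
        bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
        relative_bias_pct = bp$bias, relative_loa_low = bp$loa_low,
        relative_loa_high = bp$loa_high)
      plot_rows[[paste(met, m)]] <- data.frame(
        metric = .metric_cols[[met]], method = m,
        pair_mean = ba$means, pair_diff = ba$diffs, pair_diff_pct = bp$diffs)
    }
  }
  exceed <- list()
  for (m in methods) {
    rv <- windows$r_window[windows$method == m]
    rv <- rv[!is.na(rv)]
    if (length(rv))
      exceed[[m]] <- cbind(method = m, exceedance_curve(rv))
  }
  structure(list(summary = do.call(rbind, c(summary_rows,
                                            make.row.names = FALSE)),
                 agreement = do.call(rbind, c(agree_rows,
                                              make.row.names = FALSE)),
                 plot_data = do.call(rbind, c(plot_rows,
                                              make.row.names = FALSE)),
                 exceedance = do.call(rbind, c(exceed,
                                               make.row.names = FALSE))),
            class = "ppg_report")
}

#' @export
print.ppg_report <- function(x, ...) {
  cat("<ppg_report>\n\nAgreement (bias and 95% LoA):\n")
  print(x$agreement[, c("metric", "method", "n", "pearson_r", "bias",
                        "loa_low", "loa_high", "relative_bias_pct")],
        digits = 3, row.names = FALSE)
  invisible(x)
}
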