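#' Build sliding-window training pairs from aligned PPG and volume traces
#'
#' Slides a `input_len`-sample window over the PPG at stride 1; each window
#' is paired with a single volume sample. Under the default causal
#' alignment the target is the volume sample aligned with the *last*
#' sample of the input window, so the mapping could run in real time;
#' `"center"` aligns the target with the window midpoint instead.
#'
#' @param ppg,volume Aligned [time_series()] at the same rate.
#' @param input_len Window length in samples.
#' @param alignment `"causal"` (default) or `"center"`.
#'
#' @return A list with `X` (matrix, one window per row), `y` (targets),
#'   `start` (window start indices), `target_index` (index of each
#'   target sample in the serial), `input_len` and `alignment`.
#' @export
#'
#' @examples
#' b <- generate_breathing_trace(breathing_spec(10, 300))
#' p <- make_training_pairs(b$trace, b$trace)
#' nrow(p$X)  # 7500 - 320 + 1 = 7181
make_training_pairs <- function(ppg, volume, input_len = 320,
                                alignment = c("causal", "center")) {
  alignment <- match.arg(alignment)
  stopifnot(inherits(ppg, "time_series"), inherits(volume, "time_series"))
  if (abs(ppg$rate - volume$rate) > 1e-9)
    stop("ppg and volume must share a sampling rate")
  n <- min(length(ppg$samples), length(volume$samples))
  if (n < input_len)
    stop("serial shorter (", n, ") than one input window (", input_len, ")")
  starts <- seq_len(n - input_len + 1L)
  offset <- if (alignment == "causal") input_len - 1L
            else as.integer(floor(input_len / 2))
  X <- matrix(0, nrow = length(starts), ncol = input_len)
  for (j in seq_len(input_len)) X[, j] <- ppg$samples[starts + j - 1L]
  list(X = X, y = volume$samples[starts + offset], start = starts,
       target_index = starts + offset, input_len = as.integer(input_len),
       alignment = alignment)
}

#' Split a serial's timeline into contiguous cross-validation folds
#'
#' Divides `n_samples` into `k` contiguous, disjoint test blocks covering
#' the serial (60-second blocks for a 300-second serial with `k = 5`).
#' Each block is one evaluation window; training material for a fold is
#' the complement, with any training pair whose input window overlaps the
#' test block excluded (see [fold_training_starts()]).
#'
#' @param n_samples Number of samples in the serial.
#' @param k Number of folds (>= 2).
#' @return A `fold_split` object with a `blocks` data frame of test block
#'   boundaries (`fold`, `start`, `end`, sample indices, inclusive).
#' @export
split_serial_folds <- function(n_samples, k = 5) {
  if (k < 2) stop("k must be at least 2")
  if (n_samples < k) stop("serial shorter than k samples")
  bounds <- round(seq(0, n_samples, length.out = k + 1))
  blocks <- data.frame(fold = seq_len(k) - 1L,
                       start = bounds[-(k + 1)] + 1L,
                       end = bounds[-1])
  structure(list(n_samples = as.integer(n_samples), k = as.integer(k),
                 blocks = blocks), class = "fold_split")
}

#' Training-pair start indices for one fold
#'
#' Returns the start indices of all stride-1 training pairs whose input
#' window `[i, i + input_len - 1]` does not intersect the fold's held-out
#' test block, enforcing the no-leakage contract.
#'
#' @param split A [split_serial_folds()] result.
#' @param fold Fold index, `0 .. k-1`.
#' @param input_len Input window length in samples.
#' @return Integer vector of admissible window start indices.
#' @export
fold_training_starts <- function(split, fold, input_len = 320) {
  stopifnot(inherits(split, "fold_split"))
  b <- split$blocks[split$blocks$fold == fold, ]
  if (nrow(b) != 1) stop("unknown fold ", fold)
  starts <- seq_len(split$n_samples - input_len + 1L)
  ends <- starts + input_len - 1L
  starts[ends < b$start | starts > b$end]
}

#' Audit a fold split for train/test leakage
#'
#' Counts training input windows that intersect their own fold's held-out
#' block. Any correct split yields zero.
#'
#' @param split A [split_serial_folds()] result.
#' @param input_len Input window length in samples.
#' @return Total number of violating (fold, window) combinations.
#' @export
audit_leakage <- function(split, input_len = 320) {
  stopifnot(inherits(split, "fold_split"))
  total <- 0L
  for (f in split$blocks$fold) {
    b <- split$blocks[split$blocks$fold == f, ]
    s <- fold_training_starts(split, f, input_len)
    e <- s + input_len - 1L
    total <- total + sum(e >= b$start & s <= b$end)
  }
  total
}

#' Enumerate the evaluation windows of a cohort
#'
#' One evaluation window per serial per fold: the plan behind the
#' "subjects x rates x folds" window count of the default design
#' (22 x 5 x 5 = 550).
#'
#' @param cohort A `ppg_cohort`.
#' @param k Number of folds.
#' @return Data frame with one row per evaluation window: `subject_id`,
#'   `rate_bpm`, `fold`, `serial_index`, and the test block boundaries
#'   `start`/`end` in samples.
#' @export
window_plan <- function(cohort, k = 5) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  out <- vector("list", length(cohort$serials))
  for (i in seq_along(cohort$serials)) {
    rec <- cohort$serials[[i]]
    sp <- split_serial_folds(length(rec$ppg$samples), k)
    out[[i]] <- data.frame(subject_id = rec$subject_id,
                           rate_bpm = rec$rate_bpm, fold = sp$blocks$fold,
                           serial_index = i, start = sp$blocks$start,
                           end = sp$blocks$end)
  }
  do.call(rbind, out)
}
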