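#' Configuration of a full simulate-train-evaluate experiment
#'
#' Bundles every tunable of the end-to-end pipeline: the synthetic cohort,
#' the windowing and cross-validation design, the extractors to run, the
#' breath-detection parameters and the master seed. The defaults encode
#' the emulated study design: 22 subjects x 5 coached rates x 5 folds =
#' 550 evaluation windows of 60 s each.
#'
#' @param cohort A [cohort_spec()].
#' @param k Number of contiguous cross-validation folds per serial.
#' @param input_len Extractor input window, samples (320 at 25 Hz is
#'   12.8 s).
#' @param alignment Target alignment of the sliding window
#'   (`"causal"` or `"center"`).
#' @param methods Extractors to evaluate; any of `"oracle"` (model-free
#'   band-pass baseline), `"lstm"`, `"unet"`.
#' @param lstm,unet [extractor_config()]s for the two networks.
#' @param train_stride Subsampling stride applied to the stride-1
#'   training pairs before fitting (1 = use every pair).
#' @param pooled Train one model per architecture per fold on pairs
#'   pooled across all serials, instead of the default per-serial models.
#' @param sg_window_s,sg_order Savitzky-Golay smoothing applied to each
#'   derived volume waveform before breath detection.
#' @param smooth_reference Also smooth the reference trace before
#'   detecting reference breaths?
#' @param prominence_frac,min_ibi_s Breath-detector parameters, see
#'   [detect_breaths()].
#' @param oracle_band Pass band of the band-pass baseline, Hz.
#' @param seed Master seed for the run (training initialization and batch
#'   order; the cohort has its own `master_seed`).
#' @param out_dir Directory for result files, or `NULL` to skip writing.
#'
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(cohort = cohort_spec(), k = 5,
                              input_len = 320,
                              alignment = c("causal", "center"),
                              methods = c("oracle", "lstm", "unet"),
                              lstm = extractor_config("lstm"),
                              unet = extractor_config("unet"),
                              train_stride = 1, pooled = FALSE,
                              sg_window_s = 1.0, sg_order = 3,
                              smooth_reference = FALSE,
                              prominence_frac = 0.2, min_ibi_s = 2.0,
                              oracle_band = c(0.05, 0.5), seed = 1L,
                              out_dir = NULL) {
  alignment <- match.arg(alignment)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(inherits(cohort, "cohort_spec"), k >= 2, input_len >= 8,
            train_stride >= 1)
  lstm$input_len <- as.integer(input_len)
  unet$input_len <- as.integer(input_len)
  structure(list(cohort = cohort, k = as.integer(k),
                 input_len = as.integer(input_len), alignment = alignment,
                 methods = methods, lstm = lstm, unet = unet,
                 train_stride = as.integer(train_stride),
                 pooled = isTRUE(pooled),
                 sg_window_s = sg_window_s, sg_order = sg_order,
                 smooth_reference = isTRUE(smooth_reference),
                 prominence_frac = prominence_frac, min_ibi_s = min_ibi_s,
                 oracle_band = oracle_band, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

# deterministic sub-seed for serial i, fold f, method m
.derive_seed <- function(master, i, f, m) {
  as.integer((as.numeric(master) * 7919 + i * 1009 + f * 101 +
                match(m, c("lstm", "unet", "oracle")) * 7) %%
               (.Machine$integer.max - 1)) + 1L
}

# normalized serial record: z-scored ppg and volume at the working rate
.prepare_serial <- function(rec, target_rate = 25) {
  ppg <- rec$ppg; vol <- rec$volume
  if (abs(ppg$rate - target_rate) > 1e-9) ppg <- resample_to(ppg, target_rate)
  if (abs(vol$rate - target_rate) > 1e-9) vol <- resample_to(vol, target_rate)
  n <- min(length(ppg$samples), length(vol$samples))
  ppg$samples <- ppg$samples[seq_len(n)]
  vol$samples <- vol$samples[seq_len(n)]
  rec$ppg <- normalize_serial(ppg)
  rec$volume <- normalize_serial(vol)
  rec
}

# slice by sample indices, preserving the serial time base
.block_ts <- function(ts, start, end) {
  time_series(ts$samples[start:end], ts$rate,
              t0 = ts$t0 + (start - 1) / ts$rate)
}

# training pairs for one serial and fold, subsampled by stride
.fold_pairs <- function(pairs, split, fold, input_len, stride) {
  ok <- fold_training_starts(split, fold, input_len)
  ok <- ok[seq(1L, length(ok), by = stride)]
  idx <- match(ok, pairs$start)
  list(X = pairs$X[idx, , drop = FALSE], y = pairs$y[idx])
}

# train one network on given pairs and predict the block of one serial
.predict_block_nn <- function(kind, config, X, y, ppg, block, seed) {
  cfg <- config[[kind]]
  cfg$seed <- seed
  ex <- train_extractor(build_extractor(cfg), X, y)
  L <- config$input_len
  i0 <- max(1L, block$start - (L - 1L))
  list(tvw = predict_tvw(ex, .block_ts(ppg, i0, block$end),
                         alignment = config$alignment),
       extractor = ex)
}

#' Run the full simulate-train-evaluate-report experiment
#'
#' Generates (or accepts) a synthetic cohort, then for every serial and
#' fold: trains the configured extractors on the fold's training pairs
#' (input windows overlapping the held-out block are excluded), predicts
#' the held-out block, smooths it, segments breaths and computes the five
#' breathing metrics for the reference and every method, plus the
#' waveform Pearson correlation. Finally assembles the agreement report.
#' A failure in any window is logged and flagged; the run continues
#' (all-windows policy, no window is excluded).
#'
#' @param config An [experiment_config()].
#' @param cohort Optional pre-generated `ppg_cohort` (otherwise generated
#'   from `config$cohort`).
#' @return A `ppg_experiment` list: `windows` (per-window metric rows),
#'   `report` (a `ppg_report`), `failures` (character log) and `config`.
#'   Written to `config$out_dir` when set.
#' @export
run_experiment <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  t_start <- Sys.time()
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  serials <- lapply(cohort$serials, .prepare_serial)
  nn_methods <- intersect(config$methods, c("lstm", "unet"))
  failures <- character()
  rows <- list()

  pooled_models <- NULL
  if (config$pooled && length(nn_methods)) {
    pooled_models <- .train_pooled(config, serials, nn_methods)
  }

  for (i in seq_along(serials)) {
    rec <- serials[[i]]
    n <- length(rec$ppg$samples)
    split <- split_serial_folds(n, config$k)
    pairs <- if (length(nn_methods) && !config$pooled)
      make_training_pairs(rec$ppg, rec$volume, config$input_len,
                          config$alignment)
    oracle_tvw <- if ("oracle" %in% config$methods)
      bandpass_oracle_extract(rec$ppg, config$oracle_band)

    for (f in split$blocks$fold) {
      b <- split$blocks[split$blocks$fold == f, ]
      dur_block <- (b$end - b$start + 1) / rec$ppg$rate
      ref_block <- .block_ts(rec$volume, b$start, b$end)
      ref_for_events <- if (config$smooth_reference)
        smooth_tvw(ref_block, config$sg_window_s, config$sg_order)
      else ref_block
      ref_ev <- suppressWarnings(
        detect_breaths(ref_for_events, config$prominence_frac,
                       config$min_ibi_s))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject_id = rec$subject_id, rate_bpm = rec$rate_bpm,
                   fold = f, method = "reference", r_window = NA_real_),
        compute_metrics(ref_ev, dur_block))

      for (m in config$methods) {
        row <- tryCatch({
          tvw <- if (m == "oracle") {
            .block_ts(oracle_tvw, b$start, b$end)
          } else if (config$pooled) {
            .predict_pooled(pooled_models[[paste(m, f)]], config, rec, b)
          } else {
            fp <- .fold_pairs(pairs, split, f, config$input_len,
                              config$train_stride)
            .predict_block_nn(m, config, fp$X, fp$y, rec$ppg, b,
                              .derive_seed(config$seed, i, f, m))$tvw
          }
          sm <- smooth_tvw(tvw, config$sg_window_s, config$sg_order)
          ev <- suppressWarnings(
            detect_breaths(sm, config$prominence_frac, config$min_ibi_s))
          wc <- window_correlation(tvw, ref_block)
          cbind(data.frame(subject_id = rec$subject_id,
                           rate_bpm = rec$rate_bpm, fold = f, method = m,
                           r_window = wc$r),
                compute_metrics(ev, ts_duration(tvw)))
        }, error = function(e) {
          failures <<- c(failures, sprintf(
            "serial %d fold %d method %s: %s", i, f, m, conditionMessage(e)))
          cbind(data.frame(subject_id = rec$subject_id,
                           rate_bpm = rec$rate_bpm, fold = f, method = m,
                           r_window = NA_real_),
                compute_metrics(NULL, dur_block))
        })
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  windows <- do.call(rbind, c(rows, make.row.names = FALSE))
  report <- build_report(windows)
  result <- structure(list(windows = windows, report = report,
                           failures = failures, config = config,
                           elapsed_s = as.numeric(difftime(Sys.time(),
                                                           t_start,
                                                           units = "secs"))),
                      class = "ppg_experiment")
  if (!is.null(config$out_dir)) write_experiment(result, config$out_dir)
  result
}

# pooled mode: one model per architecture per fold, trained on pairs
# pooled across all serials
.train_pooled <- function(config, serials, nn_methods) {
  models <- list()
  k <- config$k
  pairs_all <- lapply(serials, function(rec)
    make_training_pairs(rec$ppg, rec$volume, config$input_len,
                        config$alignment))
  for (f in seq_len(k) - 1L) {
    Xs <- list(); ys <- list()
    for (i in seq_along(serials)) {
      split <- split_serial_folds(length(serials[[i]]$ppg$samples), k)
      fp <- .fold_pairs(pairs_all[[i]], split, f, config$input_len,
                        config$train_stride)
      Xs[[i]] <- fp$X; ys[[i]] <- fp$y
    }
    X <- do.call(rbind, Xs); y <- unlist(ys)
    for (m in nn_methods) {
      cfg <- config[[m]]
      cfg$seed <- .derive_seed(config$seed, 0L, f, m)
      models[[paste(m, f)]] <- train_extractor(build_extractor(cfg), X, y)
    }
  }
  models
}

.predict_pooled <- function(model, config, rec, block) {
  L <- config$input_len
  i0 <- max(1L, block$start - (L - 1L))
  predict_tvw(model, .block_ts(rec$ppg, i0, block$end),
              alignment = config$alignment)
}

#' @export
print.ppg_experiment <- function(x, ...) {
  cat(sprintf("<ppg_experiment> %d windows (%d failures), %.1f s\n",
              sum(x$windows$method != "reference"), length(x$failures),
              x$elapsed_s))
  print(x$report)
  invisible(x)
}

#' Write experiment results to a directory
#'
#' Emits `windows.csv` (per-window metrics), `summary.csv` (per-arm means
#' and paired t-tests), `agreement.csv` (Pearson r and Bland-Altman
#' absolute/percent bias with limits of agreement), `exceedance.csv`,
#' `plot_data.csv` (Bland-Altman points), `config.yaml` and `run.log`.
#'
#' @param result A `ppg_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(result, dir) {
  stopifnot(inherits(result, "ppg_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$windows, file.path(dir, "windows.csv"),
                   row.names = FALSE)
  utils::write.csv(result$report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(result$report$agreement, file.path(dir, "agreement.csv"),
                   row.names = FALSE)
  utils::write.csv(result$report$exceedance, file.path(dir, "exceedance.csv"),
                   row.names = FALSE)
  utils::write.csv(result$report$plot_data, file.path(dir, "plot_data.csv"),
                   row.names = FALSE)
  yaml::write_yaml(config_to_list(result$config),
                   file.path(dir, "config.yaml"))
  writeLines(c(sprintf("elapsed_s: %.1f", result$elapsed_s),
               sprintf("failures: %d", length(result$failures)),
               result$failures), file.path(dir, "run.log"))
  invisible(dir)
}

#' Convert an experiment config to a plain list (YAML-ready)
#' @param config An [experiment_config()].
#' @return A nested plain list.
#' @export
config_to_list <- function(config) {
  out <- unclass(config)
  out$cohort <- unclass(out$cohort)
  out$lstm <- unclass(out$lstm)
  out$unet <- unclass(out$unet)
  out
}

#' Read an experiment config from a YAML file
#'
#' The YAML mirrors the [experiment_config()] arguments; the `cohort`
#' entry mirrors [cohort_spec()] and `lstm`/`unet` mirror
#' [extractor_config()].
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) {
    if (!is.null(y$cohort$param_ranges))
      y$cohort$param_ranges <- lapply(y$cohort$param_ranges, unlist)
    y$cohort <- do.call(cohort_spec, y$cohort)
  }
  for (m in c("lstm", "unet"))
    if (!is.null(y[[m]]))
      y[[m]] <- do.call(extractor_config,
                        c(list(kind = m),
                          y[[m]][setdiff(names(y[[m]]), "kind")]))
  do.call(experiment_config, y)
}

#' Total train/test leakage across a cohort's fold splits
#'
#' @param cohort A `ppg_cohort`.
#' @param k Folds per serial.
#' @param input_len Input window length, samples.
#' @return Total count of training input windows intersecting their own
#'   fold's held-out block (zero for a correct split).
#' @export
cohort_leakage <- function(cohort, k = 5, input_len = 320) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  sum(vapply(cohort$serials, function(rec)
    audit_leakage(split_serial_folds(length(rec$ppg$samples), k),
                  input_len), numeric(1)))
}
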