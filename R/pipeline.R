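#' Resolved configuration of a pipeline run
#'
#' Bundles every stage's settings into one JSON-serializable object. Each
#' run writes its resolved configuration next to its outputs so results
#' are reproducible from the files alone.
#'
#' @param seed Master seed; per-subject and per-stage seeds derive from it.
#' @param n_subjects Number of synthetic subjects.
#' @param n_trials,beats_per_trial Acquisition protocol shape.
#' @param fs Sampling rate, Hz.
#' @param target_len Samples per normalized beat.
#' @param filter Bandpass settings: list(low, high, order).
#' @param cwt CWT settings: list(n_scales, fmin, fmax, wavelet).
#' @param image_shape Scalogram image size `c(H, W)`.
#' @param n_train,n_test Split sizes.
#' @param alpha Penalty-loss weight (scalar, or vector for a grid study).
#' @param epochs Training epochs.
#' @param subject_cfg A [subject_config()].
#' @param net_cfg An [ssrnet_config()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 0, n_subjects = 6, n_trials = 30,
                       beats_per_trial = 5, fs = 500, target_len = 128,
                       filter = list(low = 0.3, high = 5, order = 4),
                       cwt = list(n_scales = 64, fmin = 0.5, fmax = 20,
                                  wavelet = "db8"),
                       image_shape = c(32, 32), n_train = 120, n_test = 30,
                       alpha = 3, epochs = 100,
                       subject_cfg = subject_config(),
                       net_cfg = ssrnet_config(input_shape = image_shape)) {
  structure(list(seed = seed, n_subjects = n_subjects, n_trials = n_trials,
                 beats_per_trial = beats_per_trial, fs = fs,
                 target_len = target_len, filter = filter, cwt = cwt,
                 image_shape = image_shape, n_train = n_train,
                 n_test = n_test, alpha = alpha, epochs = epochs,
                 subject_cfg = subject_cfg, net_cfg = net_cfg),
            class = "run_config")
}

#' Write a run configuration as JSON
#' @param config A [run_config()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate and write the per-subject datasets
#'
#' Generates `n_subjects` synthetic subjects under the configured protocol
#' and writes each as CSV/JSON files ([write_subject_dataset()]), plus a
#' manifest (`manifest.csv`) with an MD5 checksum per file and the
#' resolved run configuration.
#'
#' @param config A [run_config()].
#' @param outdir Output directory.
#' @return Invisibly, the manifest data frame.
#' @export
run_simulate <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    stop("I/O error: cannot create ", outdir, call. = FALSE)
  }
  files <- character(0)
  for (i in seq_len(config$n_subjects)) {
    prof <- generate_subject(seed = derive_seed(config$seed, i),
                             config = config$subject_cfg,
                             subject_id = sprintf("S%02d", i))
    dat <- emulate_protocol(prof, n_trials = config$n_trials,
                            beats_per_trial = config$beats_per_trial,
                            fs = config$fs)
    files <- c(files, write_subject_dataset(dat, outdir))
    message(sprintf("subject %s: %d trials written", prof$subject_id,
                    length(dat$trials)))
  }
  cfg_path <- file.path(outdir, "run_config.json")
  write_run_config(config, cfg_path)
  files <- c(files, cfg_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# Process one subject end to end, returning evaluation reports and
# training reports for each penalty weight in the alpha grid.
run_subject <- function(config, subject_index, profile = NULL,
                        verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(profile)) {
    profile <- generate_subject(seed = derive_seed(config$seed, subject_index),
                                config = config$subject_cfg,
                                subject_id = sprintf("S%02d", subject_index))
  }
  dat <- emulate_protocol(profile, n_trials = config$n_trials,
                          beats_per_trial = config$beats_per_trial,
                          fs = config$fs)
  say("[simulate] %s: %d trials", profile$subject_id, length(dat$trials))

  beats <- extract_beats(dat, target_len = config$target_len,
                         low = config$filter$low, high = config$filter$high,
                         order = config$filter$order)
  say("[preprocess] %d beats segmented and normalized", nrow(beats$beats))

  scales <- default_scales(config$target_len, fmin = config$cwt$fmin,
                           fmax = config$cwt$fmax,
                           n_scales = config$cwt$n_scales)
  images <- beats_to_images(beats, scales = scales,
                            wavelet = config$cwt$wavelet,
                            out_shape = config$image_shape)
  say("[features] %d scalogram images of %dx%d", dim(images)[3],
      dim(images)[1], dim(images)[2])

  sp <- split_dataset(beats$meta$trial_index, n_train = config$n_train,
                      n_test = config$n_test,
                      seed = derive_seed(config$seed, 100 + subject_index))
  say("[split] %d training / %d test pairs", length(sp$train),
      length(sp$test))

  out <- list(profile = profile, meta = beats$meta, split = sp,
              alpha_runs = list())
  for (a in config$alpha) {
    fits <- train_subject_models(
      images[, , sp$train, drop = FALSE],
      sbp_refs = beats$meta$cuff_SBP[sp$train],
      dbp_refs = beats$meta$cuff_DBP[sp$train],
      config = config$net_cfg, alpha = a, epochs = config$epochs,
      seed = derive_seed(config$seed, 200 + subject_index))
    reports <- list()
    for (target in c("SBP", "DBP")) {
      refs <- if (target == "SBP") beats$meta$cuff_SBP else beats$meta$cuff_DBP
      preds <- predict_bp(fits[[target]]$model, images[, , sp$test, drop = FALSE])
      reports[[target]] <- evaluate_predictions(preds, refs[sp$test],
                                                target = target)
      say("[evaluate] alpha=%g %s: ME %+.2f +/- %.2f, MAE %.2f, AAMI %s", a,
          target, reports[[target]]$ME, reports[[target]]$ME_SD,
          reports[[target]]$MAE,
          ifelse(reports[[target]]$aami_pass, "pass", "fail"))
    }
    out$alpha_runs[[as.character(a)]] <- list(alpha = a, fits = fits,
                                              reports = reports)
  }
  out
}

#' Run the full pipeline: simulate, preprocess, extract features, train
#' and evaluate
#'
#' Executes every stage for each synthetic subject and each penalty weight
#' in the alpha grid, and assembles the per-(subject, target) accuracy
#' summary. When `outdir` is given, writes the summary CSV, the per-model
#' loss histories, the Bland-Altman tables and the resolved configuration.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory.
#' @param verbose Log record counts at stage boundaries.
#' @return List of class `pipeline_result`: `subjects` (per-subject
#'   results) and `summary` (data frame with one row per subject, target
#'   and alpha).
#' @export
run_full <- function(config = run_config(), outdir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    run_subject(config, i, verbose = verbose)
  })
  rows <- list()
  for (s in subjects) {
    for (ar in s$alpha_runs) {
      for (target in names(ar$reports)) {
        r <- ar$reports[[target]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s$profile$subject_id, target = target,
          alpha = ar$alpha, n_test = r$n, ME = r$ME, ME_SD = r$ME_SD,
          MAE = r$MAE, MAE_SD = r$MAE_SD, ba_bias = r$bland_altman$bias,
          ba_low = r$bland_altman$loa_low, ba_high = r$bland_altman$loa_high,
          aami_pass = r$aami_pass)
      }
    }
  }
  res <- structure(list(subjects = subjects, summary = do.call(rbind, rows),
                        config = config),
                   class = "pipeline_result")
  if (!is.null(outdir)) {
    if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
      stop("I/O error: cannot create ", outdir, call. = FALSE)
    }
    utils::write.csv(res$summary, file.path(outdir, "summary.csv"),
                     row.names = FALSE)
    write_run_config(config, file.path(outdir, "run_config.json"))
    for (s in subjects) {
      for (ar in s$alpha_runs) {
        for (target in names(ar$fits)) {
          rep <- ar$fits[[target]]$report
          utils::write.csv(
            data.frame(epoch = seq_along(rep$loss_history),
                       loss = rep$loss_history),
            file.path(outdir, sprintf("%s_%s_alpha%g_loss.csv",
                                      s$profile$subject_id, target, ar$alpha)),
            row.names = FALSE)
          ba <- ar$reports[[target]]$bland_altman$table
          utils::write.csv(
            ba, file.path(outdir, sprintf("%s_%s_alpha%g_bland_altman.csv",
                                          s$profile$subject_id, target,
                                          ar$alpha)),
            row.names = FALSE)
        }
      }
    }
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", length(x$subjects), "subject(s)\n\n")
  print(x$summary, digits = 3)
  invisible(x)
}
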