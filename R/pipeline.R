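#' Configuration for a full synthetic-to-metrics pipeline run
#'
#' Bundles the per-stage settings of [run_pipeline()]: synthesis (beats per
#' class, heart rate, sampling rate, noise), conditioning ([filter_spec()]
#' parameters), rendering (image size/format) and training
#' ([train_config()] parameters), plus one global seed from which every
#' stage seed is derived.
#'
#' @param seed global integer seed.
#' @param beats_per_class beats synthesised per morphology class.
#' @param heart_rate_bpm mean synthetic heart rate.
#' @param fs sampling rate (Hz).
#' @param rr_jitter_frac RR jitter fraction (see [generate_recording()]).
#' @param noise list of [noise_spec()] arguments (empty = clean signal).
#' @param preprocess conditioning applied before peak detection:
#'   `"bandlimit"` (default; 0.5--40 Hz band limiting), `"denoise"` (band
#'   limiting plus magnitude-threshold denoising; note that on long
#'   recordings the relative threshold also suppresses QRS harmonics), or
#'   `"none"`.
#' @param filter list of [filter_spec()] arguments.
#' @param use_true_peaks logical; segment on the synthetic ground-truth
#'   peaks instead of the detector.
#' @param image list: `size` (pixels), `format` ("png"/"jpg"), `v_range`.
#' @param train list of [train_config()] arguments (architecture, epochs,
#'   batch_size, learning_rate, optimizer).
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, beats_per_class = 50L,
                       heart_rate_bpm = 70, fs = 360,
                       rr_jitter_frac = 0.03,
                       noise = list(),
                       preprocess = c("bandlimit", "denoise", "none"),
                       filter = list(low_hz = 0.5, high_hz = 40,
                                     rel_threshold = 0.2),
                       use_true_peaks = FALSE,
                       image = list(size = 64L, format = "png",
                                    v_range = c(-1.5, 2.0)),
                       train = list(architecture = "small_cnn", epochs = 5L,
                                    batch_size = 16L, learning_rate = 3e-3,
                                    optimizer = "adam"),
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  preprocess <- match.arg(preprocess)
  # validate stage configs by constructing them
  do.call(noise_spec, noise)
  do.call(filter_spec, filter)
  do.call(train_config, c(train, list(seed = as.integer(seed),
                                      image_size = as.integer(image$size))))
  structure(list(seed = as.integer(seed),
                 beats_per_class = as.integer(beats_per_class),
                 heart_rate_bpm = as.numeric(heart_rate_bpm),
                 fs = as.numeric(fs),
                 rr_jitter_frac = as.numeric(rr_jitter_frac),
                 noise = noise, preprocess = preprocess,
                 filter = filter, use_true_peaks = isTRUE(use_true_peaks),
                 image = list(size = as.integer(image$size),
                              format = as.character(image$format %||% "png"),
                              v_range = as.numeric(image$v_range %||% c(-1.5, 2.0))),
                 train = train, log_level = log_level),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$log_level <- lst$log_level %||% "info"
  do.call(run_config, lst)
}

#' Run the full pipeline: simulate, condition, segment, render, train, score
#'
#' Generates one synthetic recording per morphology class, optionally adds
#' noise and applies the frequency-domain conditioning, finds R peaks
#' (detector or ground truth), cuts half-RR beat segments labeled by their
#' recording's class, renders them to images, balances and half-splits the
#' dataset, trains the configured network on the training half and evaluates
#' it on the test half. All artifacts (config, image dataset, manifests,
#' confusion table, metrics, log) are written under one timestamped run
#' directory. A rerun with the same configuration reproduces the same
#' confusion table.
#'
#' @param config a [run_config()].
#' @param base_dir directory under which the run directory is created.
#' @return An object of class `pipeline_run`: list with `run_dir`,
#'   `confusion` ([confusion_table()]), `report` ([metrics_report()]),
#'   `model` and the train/test manifests.
#' @export
run_pipeline <- function(config = run_config(), base_dir = tempdir()) {
  stopifnot(inherits(config, "run_config"))
  run_dir <- file.path(base_dir,
                       sprintf("run_%s_seed%d",
                               format(Sys.time(), "%Y%m%d_%H%M%S"),
                               config$seed))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(run_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (config$log_level == "info") message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  save_run_config(config, file.path(run_dir, "config.yaml"))
  rr <- 60 / config$heart_rate_bpm
  dur <- (config$beats_per_class + 2.5) * rr
  nz <- do.call(noise_spec, config$noise)
  fspec <- do.call(filter_spec, config$filter)

  beats <- list()
  for (cls in beat_classes()) {
    code <- beat_class_code(cls)
    rec <- stage("simulate", generate_recording(
      cls, duration_s = dur, fs = config$fs,
      heart_rate_bpm = config$heart_rate_bpm, noise = nz,
      rr_jitter_frac = config$rr_jitter_frac,
      seed = config$seed * 10L + code))
    sig <- rec$signal
    if (config$preprocess == "bandlimit") {
      sig <- stage("preprocess", bandlimit(sig, fspec))
    } else if (config$preprocess == "denoise") {
      sig <- stage("preprocess", fft_threshold_denoise(sig, fspec))
    }
    pk <- if (config$use_true_peaks) {
      rpeak_list(rec$true_r_peaks, config$fs)
    } else {
      stage("segment", detect_r_peaks(sig))
    }
    segs <- stage("segment", segment_beats(sig, pk,
                                           labels = rep(cls, length(pk$indices))))
    logf("simulated %s: %d beats -> %d segments", cls,
         length(rec$true_r_peaks), length(segs))
    beats <- c(beats, segs)
  }

  manifest <- stage("render", build_image_dataset(
    beats, file.path(run_dir, "images"), format = config$image$format,
    size = config$image$size, v_range = config$image$v_range,
    source = sprintf("synthetic seed %d", config$seed)))
  logf("rendered %d images (%s)", nrow(manifest),
       paste(attr(manifest, "class_counts"), collapse = "/"))

  manifest <- stage("balance", balance_classes(manifest, "min_class",
                                               seed = config$seed))
  halves <- stage("split", split_half(manifest, seed = config$seed))
  utils::write.csv(halves$train, file.path(run_dir, "train_manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(halves$test, file.path(run_dir, "test_manifest.csv"),
                   row.names = FALSE)
  logf("balanced to %d per class; split %d train / %d test",
       min(table(manifest$label)), nrow(halves$train), nrow(halves$test))

  tcfg <- do.call(train_config,
                  c(config$train, list(seed = config$seed,
                                       image_size = config$image$size)))
  model <- stage("train", train_beat_classifier(halves$train, tcfg))
  save_model(model, file.path(run_dir, "model.rds"))
  ct <- stage("evaluate", evaluate_classifier(model, halves$test))
  report <- stage("metrics", metrics_report(ct, partial = TRUE))
  write_confusion_csv(ct, file.path(run_dir, "confusion.csv"))
  jsonlite::write_json(
    list(accuracy = report$accuracy, macro_recall = report$macro_recall,
         macro_precision = report$macro_precision, macro_f1 = report$macro_f1,
         kappa = report$kappa, n = report$n,
         per_class = report$per_class),
    file.path(run_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  logf("test accuracy %.3f, kappa %.3f", report$accuracy, report$kappa)

  structure(list(run_dir = run_dir, confusion = ct, report = report,
                 model = model, train_manifest = halves$train,
                 test_manifest = halves$test),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>", x$run_dir, "\n")
  print(x$report)
  invisible(x)
}
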