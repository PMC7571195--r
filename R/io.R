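# Delimited-text formats for trials, rasters and reports, plus the run
# configuration shared by the command-line interface.

#' Write and read labelled-trial feature tables
#'
#' Long CSV format with header `subject, trial, label, feature, t0..t63`:
#' one row per trial feature series. `read_feature_table()` validates that
#' every trial supplies exactly the 16 canonical features with 64 samples
#' each and a `low`/`high` label, and normalises the row order.
#'
#' @param trials List of [labeled_trial()]s.
#' @param path File path.
#' @return `write_feature_table()` the path, invisibly;
#'   `read_feature_table()` a list of [labeled_trial()]s.
#' @export
write_feature_table <- function(trials, path) {
  rows <- lapply(trials, function(tr) {
    data.frame(subject = tr$subject_id, trial = tr$trial_id,
               label = tr$label, feature = rownames(tr$features),
               tr$features, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df)[-(1:4)] <- paste0("t", 0:63)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "trial", "label", "feature", paste0("t", 0:63))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_invalid("feature table lacks column(s): %s",
                 paste(missing_cols, collapse = ", "))
  bad_label <- setdiff(unique(df$label), c("low", "high"))
  if (length(bad_label))
    stop_invalid("unknown label(s): %s", paste(bad_label, collapse = ", "))
  key <- paste(df$subject, df$trial, sep = "\r")
  lapply(split(seq_len(nrow(df)), factor(key, unique(key))), function(idx) {
    sub <- df[idx, ]
    missing_f <- setdiff(valence_features(), sub$feature)
    if (length(missing_f))
      stop_invalid("trial %s/%s is missing feature row(s): %s",
                   sub$subject[1], sub$trial[1],
                   paste(missing_f, collapse = ", "))
    if (anyDuplicated(sub$feature))
      stop_invalid("trial %s/%s has duplicated feature rows",
                   sub$subject[1], sub$trial[1])
    m <- as.matrix(sub[, paste0("t", 0:63)])
    if (anyNA(m) || ncol(m) != 64L)
      stop_invalid("trial %s/%s has an invalid sample count",
                   sub$subject[1], sub$trial[1])
    rownames(m) <- sub$feature
    colnames(m) <- NULL
    if (length(unique(sub$label)) != 1L)
      stop_invalid("trial %s/%s has inconsistent labels",
                   sub$subject[1], sub$trial[1])
    labeled_trial(sub$subject[1], sub$trial[1], sub$label[1],
                  m[valence_features(), ])
  })
}

#' Serialise a spike raster as a sparse event list
#'
#' CSV with a shape header comment line (`# rows=<n> steps=<n>`), then
#' `neuron_index, time_step` pairs (both 1-based row / 0-based step).
#'
#' @param raster A `spike_raster`.
#' @param path File path.
#' @export
write_spike_raster <- function(raster, path) {
  ev <- which(raster > 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rows=%d steps=%d", nrow(raster), ncol(raster)), con)
  utils::write.csv(data.frame(neuron_index = ev[, 1],
                              time_step = ev[, 2] - 1L),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_raster
#' @export
read_spike_raster <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("# rows=(\\d+) steps=(\\d+)", hdr))[[1]]
  if (length(m) != 3L) stop_invalid("missing raster shape header in %s", path)
  ev <- utils::read.csv(path, skip = 1L)
  raster <- matrix(0L, as.integer(m[2]), as.integer(m[3]))
  raster[cbind(ev$neuron_index, ev$time_step + 1L)] <- 1L
  raster
}

#' Write and read an evaluation report CSV
#'
#' Columns `Subject, Facial, Peripheral, FusionDecision, FusionFeatures`
#' (accuracy percentages, two decimals) with a final `Total` row, one data
#' row per subject. Modes not supplied are written as `NA`.
#'
#' @param reports Named list of [loso_evaluate()] reports; recognised names
#'   are `facial_only`, `peripheral_only`, `decision`, `feature`.
#' @param path File path.
#' @return `write_report()` the path, invisibly; `read_report()` a data
#'   frame.
#' @export
write_report <- function(reports, path) {
  if (inherits(reports, "eval_report"))
    reports <- stats::setNames(list(reports), reports$fusion_mode)
  stopifnot(length(reports) > 0L)
  cols <- c(facial_only = "Facial", peripheral_only = "Peripheral",
            decision = "FusionDecision", feature = "FusionFeatures")
  unknown <- setdiff(names(reports), names(cols))
  if (length(unknown))
    stop_invalid("unknown report mode(s): %s", paste(unknown, collapse = ", "))
  subjects <- unique(unlist(lapply(reports, function(r) r$per_subject$subject)))
  out <- data.frame(Subject = c(subjects, "Total"), stringsAsFactors = FALSE)
  for (mode in names(cols)) {
    v <- rep(NA_real_, length(subjects) + 1L)
    if (mode %in% names(reports)) {
      r <- reports[[mode]]
      v[match(r$per_subject$subject, subjects)] <- r$per_subject$accuracy
      v[length(v)] <- r$total$accuracy
    }
    out[[cols[[mode]]]] <- round(v, 2)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write and read a raw multimodal recording
#'
#' Plain-text directory layout: `meta.csv` (sampling rates, duration,
#' label), `physio.csv` (ECG, respiration, temperature, GSR), `gaze.csv`
#' (left/right pupil, empty fields marking eye closure), `landmarks.csv`
#' (long format `frame, point, x, y`) and `ground_truth.csv` (R-peak times
#' and respiration cycles).
#'
#' @param raw A `raw_recording`.
#' @param dir Directory to create/fill.
#' @return `write_raw_recording()` the directory, invisibly;
#'   `read_raw_recording()` a `raw_recording`.
#' @export
write_raw_recording <- function(raw, dir) {
  stopifnot(inherits(raw, "raw_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(
    fs_physio = raw$fs_physio, fs_video = raw$fs_video,
    fs_gaze = raw$fs_gaze, trial_duration = raw$trial_duration,
    label = raw$label), file.path(dir, "meta.csv"), row.names = FALSE)
  utils::write.csv(data.frame(ecg = raw$ecg, respiration = raw$respiration,
                              temperature = raw$temperature, gsr = raw$gsr),
                   file.path(dir, "physio.csv"), row.names = FALSE)
  utils::write.csv(data.frame(pupil_left = raw$pupil_left,
                              pupil_right = raw$pupil_right),
                   file.path(dir, "gaze.csv"), row.names = FALSE)
  lm <- raw$landmarks
  utils::write.csv(data.frame(
    frame = rep(seq_len(dim(lm)[1]), times = 68L),
    point = rep(seq_len(68L), each = dim(lm)[1]),
    x = as.vector(lm[, , 1]), y = as.vector(lm[, , 2])),
    file.path(dir, "landmarks.csv"), row.names = FALSE)
  gt <- data.frame(
    kind = c(rep("r_peak", length(raw$true_r_times)),
             rep("resp_cycle", nrow(raw$true_resp_cycles))),
    time = c(raw$true_r_times, raw$true_resp_cycles$time),
    amplitude = c(rep(NA_real_, length(raw$true_r_times)),
                  raw$true_resp_cycles$amplitude))
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_raw_recording
#' @export
read_raw_recording <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "meta.csv"))
  physio <- utils::read.csv(file.path(dir, "physio.csv"))
  gaze <- utils::read.csv(file.path(dir, "gaze.csv"))
  lm <- utils::read.csv(file.path(dir, "landmarks.csv"))
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  n_frames <- max(lm$frame)
  landmarks <- array(NA_real_, c(n_frames, 68L, 2L))
  landmarks[cbind(lm$frame, lm$point, 1L)] <- lm$x
  landmarks[cbind(lm$frame, lm$point, 2L)] <- lm$y
  structure(list(
    ecg = physio$ecg, respiration = physio$respiration,
    temperature = physio$temperature, gsr = physio$gsr,
    pupil_left = gaze$pupil_left, pupil_right = gaze$pupil_right,
    landmarks = landmarks,
    true_r_times = gt$time[gt$kind == "r_peak"],
    true_resp_cycles = data.frame(time = gt$time[gt$kind == "resp_cycle"],
                                  amplitude = gt$amplitude[gt$kind == "resp_cycle"]),
    fs_physio = meta$fs_physio, fs_video = meta$fs_video,
    fs_gaze = meta$fs_gaze, trial_duration = meta$trial_duration,
    label = meta$label), class = "raw_recording")
}

#' Load a run configuration
#'
#' Reads a YAML config with blocks `synth`, `reservoir`, `readout`, `eval`
#' and a top-level `seed`, applies CLI-style overrides, rejects unknown
#' keys, and resolves every block through its parameter constructor so the
#' fully resolved configuration is validated and loggable.
#'
#' @param path Path to a YAML file, or `NULL` for defaults.
#' @param overrides Named list overriding `seed` or `block.field` entries
#'   (e.g. `list("eval.fusion_mode" = "decision")`).
#' @return List with elements `synth`, `reservoir`, `readout`, `eval`,
#'   `seed`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_invalid("reading config files requires the `yaml` package")
    yaml::read_yaml(path)
  }
  known <- c("synth", "reservoir", "readout", "eval", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop_invalid("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) cfg[[parts]] <- overrides[[nm]]
    else cfg[[parts[1]]][[parts[2]]] <- overrides[[nm]]
  }
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  build <- function(block, ctor, default_seed) {
    args <- as.list(cfg[[block]])
    ctor_args <- names(formals(ctor))
    unknown <- setdiff(names(args), ctor_args)
    if (length(unknown))
      stop_invalid("unknown key(s) in `%s` block: %s", block,
                   paste(unknown, collapse = ", "))
    if ("seed" %in% ctor_args && is.null(args$seed)) args$seed <- default_seed
    do.call(ctor, args)
  }
  list(synth = build("synth", synth_config, derive_seed(seed, 1L)),
       reservoir = build("reservoir", reservoir_params, derive_seed(seed, 2L)),
       readout = build("readout", readout_params, NULL),
       eval = build("eval", eval_params, derive_seed(seed, 3L)),
       seed = seed)
}
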