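# Synthetic multimodal data generator.
#
# Emulates the statistical structure of a stimulus-response affect study:
# a cohort of subjects each contributing a set of labelled trials, where the
# discriminative signal for high valence is concentrated in the mouth-related
# facial distances and in pupil diameter, riding on slow subject- and
# trial-level drift plus measurement noise.

#' Configuration for the synthetic multimodal generator
#'
#' @param n_subjects Number of subjects (>= 2). Default 27, the cohort size
#'   the pipeline was designed around.
#' @param trials_per_subject Trials per subject (>= 2). May be a vector, one
#'   entry per subject (recycled), since real cohorts have uneven trial
#'   counts. Default 14.
#' @param class_balance Expected fraction of low-valence trials, in (0, 1).
#'   Default 0.5307.
#' @param effect_size Additive class separation (feature units) applied to
#'   the mouth-opening (f9), mouth-width (f10) and pupil rows of
#'   high-valence trials, scaled along time by a half-sine template.
#' @param noise_sd Standard deviation of i.i.d. measurement noise added to
#'   every feature sample (feature units).
#' @param fs_physio Physiological sampling rate in Hz (default 256).
#' @param fs_video Video frame rate in frames/s (default 60).
#' @param fs_gaze Gaze-tracker sampling rate in Hz (default 60).
#' @param trial_duration Trial length in seconds; must be at least 32 s so a
#'   trial contains the 2-s neutral baseline plus the 30-s analysis window.
#' @param seed Integer seed; the generator is fully deterministic given it.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 27, trials_per_subject = 14,
                         class_balance = 0.5307, effect_size = 1,
                         noise_sd = 0.2, fs_physio = 256, fs_video = 60,
                         fs_gaze = 60, trial_duration = 40, seed = 1L) {
  check_number(n_subjects, "n_subjects", lower = 2)
  if (!is.numeric(trials_per_subject) || length(trials_per_subject) < 1L ||
      any(trials_per_subject < 2))
    stop_invalid("`trials_per_subject` must be numeric with all entries >= 2")
  check_number(class_balance, "class_balance", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(effect_size, "effect_size", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(fs_physio, "fs_physio", lower = 1)
  check_number(fs_video, "fs_video", lower = 1)
  check_number(fs_gaze, "fs_gaze", lower = 1)
  check_number(trial_duration, "trial_duration", lower = 32)
  check_number(seed, "seed")
  structure(list(
    n_subjects = as.integer(n_subjects),
    trials_per_subject = as.integer(trials_per_subject),
    class_balance = class_balance, effect_size = effect_size,
    noise_sd = noise_sd, fs_physio = fs_physio, fs_video = fs_video,
    fs_gaze = fs_gaze, trial_duration = trial_duration,
    seed = as.integer(seed)), class = "synth_config")
}

#' Temporal template of the class effect
#'
#' Half-sine over the 64-sample analysis window: the emotional response is
#' modelled as rising smoothly from the start of the window, peaking at its
#' middle, and decaying by the end. High-valence trials receive
#' `effect_size * valence_effect_template()` added to the f9, f10 and pupil
#' rows.
#'
#' @param n_samples Number of samples in the window (default 64).
#' @return Numeric vector in `[0, 1]`.
#' @export
valence_effect_template <- function(n_samples = 64L) {
  sin(pi * (seq_len(n_samples) - 1L) / (n_samples - 1L))
}

# Rows of the feature matrix carrying the class effect.
effect_rows <- function() c("f9", "f10", "pupil")

#' Construct a labelled trial
#'
#' @param subject_id,trial_id Identifiers.
#' @param label `"low"` or `"high"` valence.
#' @param features 16 x 64 numeric matrix, rows in [valence_features()] order.
#' @return An object of class `labeled_trial`.
#' @export
labeled_trial <- function(subject_id, trial_id, label, features) {
  label <- match.arg(label, c("low", "high"))
  if (!is.matrix(features) || nrow(features) != 16L || ncol(features) != 64L)
    stop_invalid("`features` must be a 16 x 64 matrix (got %s x %s)",
                 nrow(features), ncol(features))
  if (is.null(rownames(features))) rownames(features) <- valence_features()
  if (!identical(rownames(features), valence_features()))
    features <- features[valence_features(), , drop = FALSE]
  structure(list(subject_id = as.character(subject_id),
                 trial_id = as.character(trial_id),
                 label = label, features = features),
            class = "labeled_trial")
}

#' @export
print.labeled_trial <- function(x, ...) {
  cat(sprintf("<labeled_trial> subject %s, trial %s, label %s, 16 x 64 features\n",
              x$subject_id, x$trial_id, x$label))
  invisible(x)
}

# One smooth slow-drift series: Gaussian random walk low-pass filtered by a
# short moving average, so the within-window fluctuation is slower than ~1 Hz
# at the 64-sample / 30-s resolution of the analysis window.
smooth_process <- function(n, step_sd = 0.1, ma = 5L) {
  rw <- cumsum(stats::rnorm(n + 2L * ma, sd = step_sd))
  sm <- stats::filter(rw, rep(1 / ma, ma), sides = 2L)
  as.numeric(sm[(ma + 1L):(ma + n)])
}

#' Generate a labelled synthetic dataset of feature matrices
#'
#' Draws `n_subjects x trials_per_subject` trials. Each feature series is the
#' sum of a subject-level offset, a slow trial-specific drift, the class
#' effect (high-valence trials only, on the f9, f10 and pupil rows, shaped by
#' [valence_effect_template()]), and i.i.d. Gaussian noise.
#'
#' @param config A [synth_config()].
#' @return List of [labeled_trial()] objects.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synth_config"))
    stop_invalid("`config` must be a synth_config")
  feats <- valence_features()
  template <- valence_effect_template()
  n_trials <- rep_len(config$trials_per_subject, config$n_subjects)
  with_seed(derive_seed(config$seed, 101L), {
    trials <- vector("list", sum(n_trials))
    k <- 0L
    for (s in seq_len(config$n_subjects)) {
      subj_offset <- stats::rnorm(length(feats), sd = 0.3)
      names(subj_offset) <- feats
      for (tr in seq_len(n_trials[s])) {
        label <- if (stats::runif(1) < config$class_balance) "low" else "high"
        m <- matrix(0, length(feats), 64L, dimnames = list(feats, NULL))
        for (f in feats)
          m[f, ] <- subj_offset[f] + smooth_process(64L) +
            stats::rnorm(64L, sd = config$noise_sd)
        if (label == "high")
          m[effect_rows(), ] <- m[effect_rows(), ] +
            rep(config$effect_size * template, each = length(effect_rows()))
        k <- k + 1L
        trials[[k]] <- labeled_trial(sprintf("S%02d", s),
                                     sprintf("T%02d", tr), label, m)
      }
    }
    trials
  })
}

#' Generate one raw multimodal recording
#'
#' Produces raw signals with known ground truth so the feature extractors can
#' be validated: an ECG built from QRS-like templates at a stated heart rate
#' with baseline wander, a sinusoidal respiration trace, slowly drifting skin
#' temperature and GSR, pupil diameter with blink gaps (`NA`), and a 68-point
#' facial landmark sequence whose mouth geometry carries the class effect.
#' The class effect (pupil dilation, mouth widening/opening) is shaped by the
#' half-sine template over the last 30 s, leaving the first 2 s neutral.
#'
#' @param label `"low"` or `"high"` valence.
#' @param config A [synth_config()].
#' @param seed Integer seed for this trial.
#' @param heart_rate_bpm Mean heart rate in beats/min (default 60).
#' @param resp_rate_hz Respiration rate in Hz (default 0.25).
#' @param resp_amplitude Respiration amplitude in arbitrary units (default 1).
#' @param blink_rate_hz Expected blink rate in blinks/s (default 0.2); set to
#'   0 for a gap-free pupil series.
#'
#' @return An object of class `raw_recording` with elements `ecg`,
#'   `respiration`, `temperature`, `gsr` (each at `fs_physio`), `pupil_left`,
#'   `pupil_right` (at `fs_gaze`, `NA` marks eye closure), `landmarks`
#'   (`n_frames x 68 x 2` array at `fs_video`), ground truth `true_r_times`
#'   (s) and `true_resp_cycles` (data frame of peak `time` and cycle
#'   `amplitude`), the sampling rates, `trial_duration` and `label`.
#' @export
generate_raw_trial <- function(label, config, seed = config$seed,
                               heart_rate_bpm = 60, resp_rate_hz = 0.25,
                               resp_amplitude = 1, blink_rate_hz = 0.2) {
  if (!inherits(config, "synth_config"))
    stop_invalid("`config` must be a synth_config")
  label <- match.arg(label, c("low", "high"))
  check_number(heart_rate_bpm, "heart_rate_bpm", lower = 20, upper = 240)
  check_number(resp_rate_hz, "resp_rate_hz", lower = 0.05, upper = 1)
  dur <- config$trial_duration
  with_seed(derive_seed(seed, 211L), {
    fs <- config$fs_physio
    t_phys <- seq(0, dur, by = 1 / fs)

    ## ECG: R times from jittered RR intervals, QRS + T templates,
    ## respiration-locked baseline wander.
    mean_rr <- 60 / heart_rate_bpm
    n_beats <- ceiling(dur / mean_rr) + 2L
    rr <- stats::rnorm(n_beats, mean = mean_rr, sd = 0.02 * mean_rr)
    r_times <- cumsum(rr)
    r_times <- r_times[r_times > 0.2 & r_times < dur - 0.1]
    ecg <- numeric(length(t_phys))
    for (rt in r_times) {
      ecg <- ecg + 1.0 * exp(-((t_phys - rt) / 0.012)^2)            # R wave
      ecg <- ecg - 0.15 * exp(-((t_phys - rt + 0.04) / 0.02)^2)     # Q/S dip
      ecg <- ecg + 0.20 * exp(-((t_phys - rt - 0.30) / 0.06)^2)     # T wave
    }
    ecg <- ecg + 0.15 * sin(2 * pi * resp_rate_hz * t_phys) +
      stats::rnorm(length(t_phys), sd = 0.01)

    ## Respiration: pure sinusoid; ground-truth peaks at phase pi/2.
    resp <- resp_amplitude * sin(2 * pi * resp_rate_hz * t_phys)
    peak_times <- (0.25 + seq(0, floor(dur * resp_rate_hz))) / resp_rate_hz
    peak_times <- peak_times[peak_times < dur]
    true_resp <- data.frame(time = peak_times,
                            amplitude = 2 * resp_amplitude)

    temperature <- 33.5 + 0.3 * smooth_process(length(t_phys), step_sd = 0.002,
                                               ma = as.integer(fs))
    gsr <- 2 + 0.5 * smooth_process(length(t_phys), step_sd = 0.002,
                                    ma = as.integer(fs)) +
      abs(stats::rnorm(length(t_phys), sd = 0.01))

    ## Pupil at fs_gaze with class-dependent dilation over the last 30 s.
    t_gaze <- seq(0, dur, by = 1 / config$fs_gaze)
    win_start <- dur - 30
    tpl_gaze <- ifelse(t_gaze >= win_start,
                       sin(pi * (t_gaze - win_start) / 30), 0)
    dilation <- if (label == "high") 0.6 else 0
    pupil_base <- 4 + 0.2 * smooth_process(length(t_gaze), step_sd = 0.01,
                                           ma = as.integer(config$fs_gaze)) +
      dilation * tpl_gaze
    pupil_left <- pupil_base + stats::rnorm(length(t_gaze), sd = 0.02)
    pupil_right <- pupil_base + 0.1 + stats::rnorm(length(t_gaze), sd = 0.02)
    if (blink_rate_hz > 0) {
      n_blinks <- stats::rpois(1, blink_rate_hz * dur)
      if (n_blinks > 0) {
        starts <- stats::runif(n_blinks, 0, dur - 0.3)
        for (b in starts) {
          idx <- which(t_gaze >= b & t_gaze <= b + stats::runif(1, 0.1, 0.3))
          pupil_left[idx] <- NA_real_
          pupil_right[idx] <- NA_real_
        }
        # never blank the whole series ends
        pupil_left[1] <- pupil_base[1]; pupil_right[1] <- pupil_base[1] + 0.1
      }
    }

    ## Landmarks: neutral template with class-modulated mouth geometry.
    t_vid <- seq(0, dur, by = 1 / config$fs_video)
    tpl_vid <- ifelse(t_vid >= win_start, sin(pi * (t_vid - win_start) / 30), 0)
    widen <- if (label == "high") 12 else 0    # mouth width increase, px
    open_ <- if (label == "high") 6 else 0     # lip separation increase, px
    base_face <- neutral_face_template()
    n_frames <- length(t_vid)
    landmarks <- array(NA_real_, c(n_frames, 68L, 2L))
    jitter_x <- smooth_process(n_frames, step_sd = 0.05,
                               ma = as.integer(config$fs_video))
    jitter_y <- smooth_process(n_frames, step_sd = 0.05,
                               ma = as.integer(config$fs_video))
    for (i in seq_len(n_frames)) {
      f <- base_face
      w <- widen * tpl_vid[i] / 2
      o <- open_ * tpl_vid[i] / 2
      f[49, 1] <- f[49, 1] - w; f[55, 1] <- f[55, 1] + w  # mouth corners
      f[50:53, 2] <- f[50:53, 2] - o                       # upper lip up
      f[57:59, 2] <- f[57:59, 2] + o                       # lower lip down
      f[, 1] <- f[, 1] + jitter_x[i]
      f[, 2] <- f[, 2] + jitter_y[i]
      landmarks[i, , ] <- f + stats::rnorm(136, sd = 0.15)
    }

    structure(list(ecg = ecg, respiration = resp, temperature = temperature,
                   gsr = gsr, pupil_left = pupil_left,
                   pupil_right = pupil_right, landmarks = landmarks,
                   true_r_times = r_times, true_resp_cycles = true_resp,
                   fs_physio = fs, fs_video = config$fs_video,
                   fs_gaze = config$fs_gaze, trial_duration = dur,
                   label = label), class = "raw_recording")
  })
}

# A plausible frontal 68-point landmark layout (pixel coordinates, y grows
# downward). Only relative geometry matters: the mapped points used by the
# facial-distance features are placed bilaterally symmetric about x = 300.
neutral_face_template <- function() {
  pts <- matrix(NA_real_, 68L, 2L)
  cx <- 300
  # jaw line 1..17: ellipse arc
  th <- seq(pi, 2 * pi, length.out = 17L)
  pts[1:17, 1] <- cx + 110 * cos(th + pi / 2)
  pts[1:17, 2] <- 260 + 130 * abs(sin(th + pi / 2))
  # right eyebrow 18..22 (subject's right, image left), left eyebrow 23..27
  pts[18:22, 1] <- seq(cx - 90, cx - 30, length.out = 5L)
  pts[18:22, 2] <- 170 - c(0, 6, 9, 8, 5)
  pts[23:27, 1] <- seq(cx + 30, cx + 90, length.out = 5L)
  pts[23:27, 2] <- 170 - c(5, 8, 9, 6, 0)
  # nose bridge 28..31, nostrils 32..36
  pts[28:31, 1] <- cx
  pts[28:31, 2] <- seq(195, 245, length.out = 4L)
  pts[32:36, 1] <- seq(cx - 20, cx + 20, length.out = 5L)
  pts[32:36, 2] <- 258
  # right eye 37..42: 37 outer, 38/39 upper, 40 inner, 41/42 lower
  pts[37:42, 1] <- cx + c(-85, -73, -61, -50, -61, -73)
  pts[37:42, 2] <- c(200, 193, 193, 200, 206, 206)
  # left eye 43..48: 43 inner, 44/45 upper, 46 outer, 47/48 lower
  pts[43:48, 1] <- cx + c(50, 61, 73, 85, 73, 61)
  pts[43:48, 2] <- c(200, 193, 193, 200, 206, 206)
  # outer mouth 49..60
  pts[49:60, 1] <- cx + c(-45, -28, -12, 0, 12, 28, 45, 28, 12, 0, -12, -28)
  pts[49:60, 2] <- c(300, 292, 288, 290, 288, 292, 300, 308, 312, 313, 312, 308)
  # inner mouth 61..68
  pts[61:68, 1] <- cx + c(-35, -12, 0, 12, 35, 12, 0, -12)
  pts[61:68, 2] <- c(300, 296, 297, 296, 300, 304, 305, 304)
  pts
}
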