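# Feature extraction: facial landmark distances and peripheral physiological
# channels, windowed to the last 30 s and resampled to a 16 x 64 matrix.

#' Landmark-index mapping for the facial distance features
#'
#' Indices into the standard 68-point facial landmark layout (1-based).
#' `f1`/`f2` are the perpendicular distances from the outer eyebrow points to
#' the line through the inner eye corners; `f3`/`f4` the eyelid openings;
#' `f5`/`f6` (`f7`/`f8`) the distances from the upper (lower) lip midpoint to
#' the mouth corners; `f9` the lip-to-lip distance and `f10` the
#' mouth-corner-to-mouth-corner distance.
#'
#' @return Named list of landmark indices; pass a modified copy to
#'   [extract_facial_features()] to use a different annotation convention.
#' @export
facial_landmark_map <- function() {
  list(inner_eye_right = 40L, inner_eye_left = 43L,
       brow_right = 19L, brow_left = 26L,
       upper_lid_right = 38L, lower_lid_right = 42L,
       upper_lid_left = 44L, lower_lid_left = 48L,
       mouth_right = 49L, mouth_left = 55L,
       upper_lip = 52L, lower_lip = 58L)
}

point_line_distance <- function(p, a, b) {
  d <- b - a
  abs(d[1] * (a[2] - p[2]) - (a[1] - p[1]) * d[2]) / sqrt(sum(d^2))
}

euclid <- function(p, q) sqrt(sum((p - q)^2))

#' Extract the ten facial distance features from landmark sequences
#'
#' @param landmarks `n_frames x 68 x 2` array of landmark coordinates, or a
#'   list of `68 x 2` matrices (one per frame).
#' @param map Landmark-index mapping, see [facial_landmark_map()].
#' @return A `10 x n_frames` matrix with rows `f1..f10`. Frames with missing
#'   (`NA`) landmarks yield `NA` features which are linearly interpolated
#'   across frames.
#' @export
extract_facial_features <- function(landmarks, map = facial_landmark_map()) {
  if (is.list(landmarks)) {
    n_frames <- length(landmarks)
    frame <- function(i) landmarks[[i]]
  } else {
    stopifnot(length(dim(landmarks)) == 3L, dim(landmarks)[2] == 68L,
              dim(landmarks)[3] == 2L)
    n_frames <- dim(landmarks)[1]
    frame <- function(i) landmarks[i, , ]
  }
  out <- matrix(NA_real_, 10L, n_frames,
                dimnames = list(paste0("f", 1:10), NULL))
  for (i in seq_len(n_frames)) {
    f <- frame(i)
    if (!is.matrix(f) || nrow(f) != 68L) stop_invalid(
      "frame %d does not supply 68 landmark points", i)
    ier <- f[map$inner_eye_right, ]; iel <- f[map$inner_eye_left, ]
    if (anyNA(c(ier, iel))) next
    out["f1", i] <- point_line_distance(f[map$brow_right, ], ier, iel)
    out["f2", i] <- point_line_distance(f[map$brow_left, ], ier, iel)
    out["f3", i] <- euclid(f[map$upper_lid_right, ], f[map$lower_lid_right, ])
    out["f4", i] <- euclid(f[map$upper_lid_left, ], f[map$lower_lid_left, ])
    out["f5", i] <- euclid(f[map$upper_lip, ], f[map$mouth_right, ])
    out["f6", i] <- euclid(f[map$upper_lip, ], f[map$mouth_left, ])
    out["f7", i] <- euclid(f[map$lower_lip, ], f[map$mouth_right, ])
    out["f8", i] <- euclid(f[map$lower_lip, ], f[map$mouth_left, ])
    out["f9", i] <- euclid(f[map$upper_lip, ], f[map$lower_lip, ])
    out["f10", i] <- euclid(f[map$mouth_right, ], f[map$mouth_left, ])
  }
  if (anyNA(out)) {
    for (r in seq_len(nrow(out))) {
      v <- out[r, ]
      if (all(is.na(v))) stop_invalid("feature %s missing in every frame",
                                      rownames(out)[r])
      if (anyNA(v))
        out[r, ] <- stats::approx(which(!is.na(v)), v[!is.na(v)],
                                  xout = seq_along(v), rule = 2)$y
    }
  }
  out
}

#' Subtract the neutral-baseline mean of the first seconds
#'
#' Assumes the face is neutral for the first `baseline_secs` seconds of the
#' trial; the per-feature mean over that span is subtracted so the series
#' express change from neutral.
#'
#' @param features `n_features x n_frames` matrix.
#' @param fs_video Frame rate (frames/s).
#' @param baseline_secs Baseline length in seconds (default 2).
#' @return Matrix of the same shape.
#' @export
subtract_neutral_baseline <- function(features, fs_video, baseline_secs = 2) {
  stopifnot(is.matrix(features))
  n_base <- round(baseline_secs * fs_video)
  if (ncol(features) < n_base)
    stop_invalid("series length %d shorter than the %g-s baseline (%d frames)",
                 ncol(features), baseline_secs, n_base)
  features - rowMeans(features[, seq_len(n_base), drop = FALSE])
}

# Linear-phase type-I FIR by weighted least squares: minimises the squared
# deviation of the zero-phase amplitude A(w) = a0 + sum a_k cos(kw) from the
# desired piecewise-constant response over a dense grid restricted to the
# stated bands (the transition band is unconstrained).
fir_ls <- function(order, bands, desired, weights, fs) {
  stopifnot(order %% 2 == 0, nrow(bands) == length(desired))
  m <- order / 2
  grid <- list(); dvec <- list(); wvec <- list()
  for (b in seq_len(nrow(bands))) {
    w <- seq(bands[b, 1], bands[b, 2], length.out = 16L * (m + 1) %/%
               nrow(bands) + 16L) * 2 * pi / fs
    grid[[b]] <- w
    dvec[[b]] <- rep(desired[b], length(w))
    wvec[[b]] <- rep(weights[b], length(w))
  }
  w <- unlist(grid); d <- unlist(dvec); wt <- sqrt(unlist(wvec))
  G <- cbind(1, cos(outer(w, seq_len(m))))
  a <- qr.solve(G * wt, d * wt)
  # impulse response h[n], n = -m..m: h[0] = a0, h[|k|] = a_k / 2
  h <- c(rev(a[-1] / 2), a[1], a[-1] / 2)
  h
}

# Zero-phase FIR filtering: symmetric odd-length kernel centred on each
# sample; edges handled by reflecting the signal.
filter_zero_phase <- function(x, h) {
  m <- (length(h) - 1L) %/% 2L
  n <- length(x)
  pad_l <- x[pmin(n, m + 1L):2L]
  pad_r <- x[(n - 1L):pmax(1L, n - m)]
  if (m >= n) { # reflect repeatedly for very long kernels
    ref <- c(rev(x), x[-1], rev(x)[-1])
    pad_l <- rep(ref, length.out = m)
    xp <- c(rev(x)[seq_len(m) %% (n - 1L) + 1L], x,
            x[(n - 1L):1L][seq_len(m) %% (n - 1L) + 1L])
  } else {
    xp <- c(pad_l, x, pad_r)
  }
  as.numeric(stats::filter(xp, h, method = "convolution",
                           sides = 2L))[(m + 1L):(m + n)]
}

#' Band-pass preprocess an ECG signal
#'
#' Mean subtraction followed by two cascaded linear-phase FIR stages: a
#' least-squares low-pass (passband up to 40 Hz, ~70 dB stopband from 45 Hz)
#' removing muscular/mains noise, and a high-pass near 0.05 Hz removing
#' respiration-locked baseline wander, realised as subtraction of a
#' 10-s centred moving-average baseline (itself a linear-phase low-pass).
#' Both stages are applied zero-phase so R-peak times are not shifted.
#'
#' @param ecg Numeric ECG series (mV).
#' @param fs Sampling rate in Hz; must be at least 128 so the 40-Hz passband
#'   sits well below Nyquist.
#' @return Filtered series of the same length.
#' @export
preprocess_ecg <- function(ecg, fs) {
  if (fs < 128) stop_invalid(
    "fs = %g Hz is too low for the 0.05-40 Hz band (need fs >= 128)", fs)
  x <- ecg - mean(ecg)
  h <- ecg_lowpass_kernel(fs)
  x <- filter_zero_phase(x, h)
  # high-pass: remove slow baseline (moving average ~0.04 Hz cutoff)
  win <- round(10 * fs)
  if (win %% 2 == 0) win <- win + 1L
  if (win < length(x)) {
    baseline <- filter_zero_phase(x, rep(1 / win, win))
    x <- x - baseline
  } else {
    x <- x - mean(x)
  }
  x
}

# cached per sampling rate; order scales with fs to keep the 5-Hz transition
ecg_lowpass_kernel <- local({
  cache <- list()
  function(fs) {
    key <- as.character(fs)
    if (is.null(cache[[key]])) {
      ord <- 2L * round(0.5 * fs)          # ~1 s long kernel
      cache[[key]] <<- fir_ls(ord, rbind(c(0, 40), c(45, fs / 2)),
                              desired = c(1, 0), weights = c(1, 60), fs = fs)
    }
    cache[[key]]
  }
})

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic QRS detection chain: 5-15 Hz band-pass, five-point derivative,
#' squaring, 150-ms moving-window integration, then adaptive dual thresholds
#' on the integrated signal with 200-ms refractoriness and a search-back pass
#' at half threshold when an expected beat is missed. Fiducial marks are
#' refined to the local ECG maximum within +/-50 ms.
#'
#' @param ecg Preprocessed ECG series (see [preprocess_ecg()]).
#' @param fs Sampling rate in Hz.
#' @return Ascending numeric vector of R-peak times in seconds (empty, with a
#'   warning, when no QRS complexes are found).
#' @export
detect_r_peaks <- function(ecg, fs) {
  n <- length(ecg)
  if (n < fs) { warning("ECG too short for R detection"); return(numeric(0)) }
  if (stats::sd(ecg) < 1e-9) {
    warning("no R peaks found (flat ECG)")
    return(numeric(0))
  }
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, ecg)
  # five-point derivative (Pan-Tompkins kernel), zero-phase
  dk <- c(1, 2, 0, -2, -1) * fs / 8
  dx <- filter_zero_phase(xf, dk)  # orientation immaterial: squared next
  sq <- dx^2
  wi <- max(3L, round(0.150 * fs)); if (wi %% 2 == 0) wi <- wi + 1L
  mwi <- filter_zero_phase(sq, rep(1 / wi, wi))

  refr <- round(0.2 * fs)
  # candidate fiducials: local maxima of the integrated signal
  pk <- pracma::findpeaks(mwi, minpeakdistance = refr, zero = "+")
  if (is.null(pk)) { warning("no R peaks found"); return(numeric(0)) }
  cand <- pk[order(pk[, 2]), , drop = FALSE]
  amps <- cand[, 1]; locs <- cand[, 2]

  spki <- max(amps[seq_len(min(8L, length(amps)))]) / 2
  npki <- mean(amps) / 4
  accepted <- integer(0)
  rr_hist <- numeric(0)
  i <- 1L
  while (i <= length(locs)) {
    thr <- npki + 0.25 * (spki - npki)
    if (amps[i] >= thr) {
      accepted <- c(accepted, locs[i])
      spki <- 0.125 * amps[i] + 0.875 * spki
      if (length(accepted) > 1L)
        rr_hist <- utils::tail(c(rr_hist, diff(utils::tail(accepted, 2L))), 8L)
    } else {
      npki <- 0.125 * amps[i] + 0.875 * npki
      # search-back: if far beyond the expected RR, accept at half threshold
      if (length(rr_hist) >= 2L && length(accepted) > 0L &&
          (locs[i] - accepted[length(accepted)]) > 1.66 * mean(rr_hist) &&
          amps[i] >= thr / 2) {
        accepted <- c(accepted, locs[i])
        spki <- 0.25 * amps[i] + 0.75 * spki
      }
    }
    i <- i + 1L
  }
  if (length(accepted) == 0L) { warning("no R peaks found"); return(numeric(0)) }
  # refine to the ECG maximum within +/-50 ms of the integrated fiducial
  half <- round(0.05 * fs)
  r_idx <- vapply(accepted, function(l) {
    lo <- max(1, l - half); hi <- min(n, l + half)
    as.integer(lo + which.max(ecg[lo:hi]) - 1)
  }, integer(1))
  sort(unique(r_idx - 1L)) / fs
}

#' Heart-rate variability series from R-peak times
#'
#' RR intervals attached to the time of the later R peak of each pair,
#' forming a sparse event series on the trial time axis.
#'
#' @param r_times Ascending R-peak times (s).
#' @return An event series (`time`, `value` = RR interval in s).
#' @export
rr_intervals <- function(r_times) {
  if (length(r_times) < 2L) {
    warning("fewer than 2 R peaks; empty RR series")
    return(event_series(numeric(0), numeric(0)))
  }
  event_series(r_times[-1L], diff(r_times))
}

#' Respiration variability and depth per breathing cycle
#'
#' Peaks and valleys are located (after light smoothing) and each cycle
#' yields its duration (time from the previous peak, "respiration
#' variability") and its depth (peak amplitude minus the preceding valley),
#' both attached to the cycle's peak time.
#'
#' @param resp Respiration series (a.u.).
#' @param fs Sampling rate in Hz.
#' @return List with event series `variability` (s) and `depth` (a.u.).
#' @export
extract_respiration_features <- function(resp, fs) {
  n <- length(resp)
  if (stats::sd(resp) < 1e-9) {
    warning("no respiration cycles detected (flat signal)")
    empty <- event_series(numeric(0), numeric(0))
    return(list(variability = empty, depth = empty))
  }
  win <- max(3L, round(0.5 * fs)); if (win %% 2 == 0) win <- win + 1L
  sm <- filter_zero_phase(resp, rep(1 / win, win))
  mind <- max(1L, round(fs))  # breaths are slower than 1 Hz
  pk <- pracma::findpeaks(sm, minpeakdistance = mind)
  vl <- pracma::findpeaks(-sm, minpeakdistance = mind)
  if (is.null(pk) || nrow(pk) < 2L) {
    warning("fewer than 2 respiration peaks; empty cycle series")
    empty <- event_series(numeric(0), numeric(0))
    return(list(variability = empty, depth = empty))
  }
  peaks <- sort(pk[, 2]); valleys <- if (is.null(vl)) integer(0) else sort(vl[, 2])
  peak_t <- (peaks - 1L) / fs
  variability <- event_series(peak_t[-1L], diff(peak_t))
  dep_t <- c(); dep_v <- c()
  for (p in peaks) {
    prev_v <- valleys[valleys < p]
    if (length(prev_v)) {
      v <- max(prev_v)
      dep_t <- c(dep_t, (p - 1L) / fs)
      dep_v <- c(dep_v, resp[p] - resp[v])
    }
  }
  list(variability = variability, depth = event_series(dep_t, dep_v))
}

#' Mean pupil diameter from both eyes
#'
#' Samplewise mean of the available eyes (`NA` marks eye closure); spans
#' where both eyes are closed are filled by linear interpolation.
#'
#' @param pupil_left,pupil_right Pupil diameter series (mm), `NA` = closed.
#' @return Numeric series of the same length, gap-free.
#' @export
extract_pupil <- function(pupil_left, pupil_right) {
  stopifnot(length(pupil_left) == length(pupil_right))
  m <- rowMeans(cbind(pupil_left, pupil_right), na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  if (all(is.na(m))) stop_invalid("pupil series entirely missing")
  if (anyNA(m)) {
    ok <- which(!is.na(m))
    m <- stats::approx(ok, m[ok], xout = seq_along(m), rule = 2)$y
  }
  m
}

# Resample one series onto the 64-point uniform grid over [t_end-30, t_end].
# Dense series are linearly interpolated; sparse event series are
# step-interpolated (last value carried forward) so no intermediate dynamics
# are invented between events.
window_resample <- function(x, name, t_grid) {
  if (is_event_series(x)) {
    if (nrow(x) == 0L)
      return(rep(0, length(t_grid)))
    if (nrow(x) == 1L)
      return(rep(x$value, length(t_grid)))
    return(stats::approx(x$time, x$value, xout = t_grid, method = "constant",
                         f = 0, rule = 2)$y)
  }
  fs <- attr(x, "fs")
  if (is.null(fs)) stop_invalid("dense series `%s` lacks an `fs` attribute", name)
  t_x <- (seq_along(x) - 1L) / fs
  if (t_x[length(t_x)] < t_grid[1] ||
      t_x[length(t_x)] < t_grid[length(t_grid)] - 1.5 / fs)
    stop_invalid("series `%s` (%.2f s) does not cover the analysis window ending at %.2f s",
                 name, t_x[length(t_x)], t_grid[length(t_grid)])
  stats::approx(t_x, x, xout = t_grid, rule = 2)$y
}

dense_series <- function(x, fs) { attr(x, "fs") <- fs; x }

#' Assemble the 16 x 64 trial feature matrix
#'
#' Restricts every feature series to the last 30 s of the trial, resamples it
#' to 64 uniformly spaced samples, and subtracts the first sample of each row
#' so features express change from the window start. Row order is fixed:
#' `f1..f10`, `hrv`, `resp_variability`, `resp_depth`, `temperature`, `gsr`,
#' `pupil`.
#'
#' @param facial `10 x n_frames` matrix from [extract_facial_features()]
#'   (after [subtract_neutral_baseline()]), frames at `fs_video`.
#' @param physio Named list with event series `hrv`, `resp_variability`,
#'   `resp_depth` and dense series `temperature`, `gsr` (at `fs_physio`) and
#'   `pupil` (at `fs_gaze`).
#' @param trial_duration Trial length in seconds (the window is its last 30 s).
#' @param fs_video,fs_physio,fs_gaze Sampling rates of the dense series.
#' @param window_secs Analysis window length (default 30 s).
#' @param n_samples Samples per row after resampling (default 64).
#' @return `16 x 64` matrix whose first column is all zeros.
#' @export
assemble_feature_matrix <- function(facial, physio, trial_duration,
                                    fs_video, fs_physio, fs_gaze,
                                    window_secs = 30, n_samples = 64L) {
  stopifnot(is.matrix(facial), nrow(facial) == 10L)
  if (trial_duration < window_secs)
    stop_invalid("trial_duration %.1f s shorter than the %g-s analysis window",
                 trial_duration, window_secs)
  t_grid <- trial_duration - window_secs +
    (seq_len(n_samples) - 1L) * window_secs / (n_samples - 1L)
  out <- matrix(NA_real_, 16L, n_samples,
                dimnames = list(valence_features(), NULL))
  for (r in paste0("f", 1:10))
    out[r, ] <- window_resample(dense_series(facial[r, ], fs_video), r, t_grid)
  out["hrv", ] <- window_resample(physio$hrv, "hrv", t_grid)
  out["resp_variability", ] <- window_resample(physio$resp_variability,
                                               "resp_variability", t_grid)
  out["resp_depth", ] <- window_resample(physio$resp_depth, "resp_depth", t_grid)
  out["temperature", ] <- window_resample(dense_series(physio$temperature, fs_physio),
                                          "temperature", t_grid)
  out["gsr", ] <- window_resample(dense_series(physio$gsr, fs_physio), "gsr", t_grid)
  out["pupil", ] <- window_resample(dense_series(physio$pupil, fs_gaze),
                                    "pupil", t_grid)
  out - out[, 1L]
}

#' Full feature extraction for one raw recording
#'
#' Runs every extractor on a [generate_raw_trial()]-shaped recording and
#' assembles the 16 x 64 feature matrix.
#'
#' @param raw A `raw_recording`.
#' @param subject_id,trial_id Identifiers for the resulting trial.
#' @return A [labeled_trial()].
#' @export
extract_trial_features <- function(raw, subject_id = "S01", trial_id = "T01") {
  stopifnot(inherits(raw, "raw_recording"))
  facial <- extract_facial_features(raw$landmarks)
  facial <- subtract_neutral_baseline(facial, raw$fs_video)
  ecg_f <- preprocess_ecg(raw$ecg, raw$fs_physio)
  r_times <- detect_r_peaks(ecg_f, raw$fs_physio)
  resp <- extract_respiration_features(raw$respiration, raw$fs_physio)
  physio <- list(hrv = rr_intervals(r_times),
                 resp_variability = resp$variability,
                 resp_depth = resp$depth,
                 temperature = raw$temperature,
                 gsr = raw$gsr,
                 pupil = extract_pupil(raw$pupil_left, raw$pupil_right))
  m <- assemble_feature_matrix(facial, physio, raw$trial_duration,
                               raw$fs_video, raw$fs_physio, raw$fs_gaze)
  labeled_trial(subject_id, trial_id, raw$label, m)
}
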