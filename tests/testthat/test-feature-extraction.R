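# A simple symmetric synthetic face used by several facial-feature tests:
# only the landmark indices consumed by the distance features are placed
# meaningfully; everything else sits at the origin.
symmetric_face <- function(mouth_half_width = 20, lip_gap = 12) {
  f <- matrix(0, 68, 2)
  map <- facial_landmark_map()
  f[map$inner_eye_right, ] <- c(-25, 0); f[map$inner_eye_left, ] <- c(25, 0)
  f[map$brow_right, ] <- c(-45, -30);    f[map$brow_left, ] <- c(45, -30)
  f[map$upper_lid_right, ] <- c(-35, -5); f[map$lower_lid_right, ] <- c(-35, 5)
  f[map$upper_lid_left, ] <- c(35, -5);   f[map$lower_lid_left, ] <- c(35, 5)
  f[map$mouth_right, ] <- c(-mouth_half_width, 60)
  f[map$mouth_left, ] <- c(mouth_half_width, 60)
  f[map$upper_lip, ] <- c(0, 60 - lip_gap / 2)
  f[map$lower_lip, ] <- c(0, 60 + lip_gap / 2)
  f
}

frames_array <- function(frames) {
  a <- array(NA_real_, c(length(frames), 68, 2))
  for (i in seq_along(frames)) a[i, , ] <- frames[[i]]
  a
}

test_that("facial distances match hand-computed geometry", {
  map <- facial_landmark_map()
  f <- symmetric_face()
  f[map$mouth_right, ] <- c(100, 200); f[map$mouth_left, ] <- c(140, 200)
  feats <- extract_facial_features(frames_array(list(f)))
  expect_equal(unname(feats["f10", 1]), 40)        # Euclidean mouth width
  g <- symmetric_face(mouth_half_width = 20, lip_gap = 12)
  feats <- extract_facial_features(frames_array(list(g)))
  expect_equal(unname(feats["f9", 1]), 12)
  expect_equal(unname(feats["f1", 1]), 30)         # brow to inter-eye line
  expect_equal(unname(feats["f3", 1]), 10)         # eyelid opening
})

test_that("a bilaterally symmetric face yields pairwise equal features", {
  feats <- extract_facial_features(frames_array(list(symmetric_face())))
  expect_equal(unname(feats["f1", ]), unname(feats["f2", ]))
  expect_equal(unname(feats["f3", ]), unname(feats["f4", ]))
  expect_equal(unname(feats["f5", ]), unname(feats["f6", ]))
  expect_equal(unname(feats["f7", ]), unname(feats["f8", ]))
})

test_that("identical frames give constant series and NA frames interpolate", {
  f <- symmetric_face()
  feats <- extract_facial_features(frames_array(list(f, f, f)))
  expect_true(all(apply(feats, 1, function(r) diff(range(r)) == 0)))
  f2 <- f; f2[] <- NA_real_
  f3 <- symmetric_face(mouth_half_width = 30)
  feats <- extract_facial_features(frames_array(list(f, f2, f3)))
  expect_equal(unname(feats["f10", 2]), 50)  # linear midpoint of 40 and 60
})

test_that("facial distances are invariant under rigid transforms", {
  f <- symmetric_face()
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  f_rot <- sweep(f %*% rot, 2, c(17, -31), "+")
  a <- extract_facial_features(frames_array(list(f)))
  b <- extract_facial_features(frames_array(list(f_rot)))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("neutral-baseline subtraction removes the 2-s mean", {
  m <- matrix(5, 2, 300)
  out <- subtract_neutral_baseline(m, fs_video = 60)
  expect_true(all(out == 0))
  m[1, 200] <- 8
  out <- subtract_neutral_baseline(m, fs_video = 60)
  expect_equal(out[1, 200], 3)
  # idempotent once the baseline window is zero
  expect_equal(subtract_neutral_baseline(out, 60), out)
  expect_error(subtract_neutral_baseline(m[, 1:50, drop = FALSE], 60),
               "shorter")
})

test_that("ECG preprocessing passes the band and rejects 50 Hz and DC", {
  fs <- 256
  t <- seq(0, 10, by = 1 / fs)
  core <- 500:2000  # avoid edge transients
  out50 <- preprocess_ecg(sin(2 * pi * 50 * t), fs)
  atten_db <- 20 * log10(stats::sd(out50[core]) /
                           stats::sd(sin(2 * pi * 50 * t)[core]))
  expect_lt(atten_db, -40)
  out10 <- preprocess_ecg(sin(2 * pi * 10 * t), fs)
  gain <- stats::sd(out10[core]) / stats::sd(sin(2 * pi * 10 * t)[core])
  expect_gt(gain, 10^(-1 / 20))  # within the 1 dB passband ripple
  expect_lt(gain, 10^(1 / 20))
  out_dc <- preprocess_ecg(rep(3.3, length(t)), fs)
  expect_lt(abs(mean(out_dc)), 1e-6)
  expect_error(preprocess_ecg(sin(t), fs = 64), "fs")
})

test_that("R peaks are recovered from synthetic ECG at 60 and 75 bpm", {
  cfg <- synth_config(n_subjects = 2, trials_per_subject = 2,
                      trial_duration = 60, seed = 3)
  for (bpm in c(60, 75)) {
    raw <- generate_raw_trial("low", cfg, seed = 40 + bpm,
                              heart_rate_bpm = bpm)
    rt <- detect_r_peaks(preprocess_ecg(raw$ecg, raw$fs_physio),
                         raw$fs_physio)
    expect_lt(abs(length(rt) - length(raw$true_r_times)), 1.5)
    expect_lt(abs(stats::median(diff(rt)) - 60 / bpm), 0.02)
    n <- min(length(rt), length(raw$true_r_times))
    expect_lt(mean(abs(diff(rt[1:n]) - diff(raw$true_r_times[1:n]))), 0.025)
  }
})

test_that("flatline ECG yields an empty peak list with a warning", {
  expect_warning(rt <- detect_r_peaks(rep(0, 2560), 256), "no R peaks")
  expect_length(rt, 0)
})

test_that("respiration cycles of a sinusoid have period 1/f and depth 2A", {
  fs <- 256
  t <- seq(0, 60, by = 1 / fs)
  resp <- 1.7 * sin(2 * pi * 0.25 * t)
  cyc <- extract_respiration_features(resp, fs)
  expect_gt(nrow(cyc$variability), 10)
  expect_true(all(abs(cyc$variability$value - 4) / 4 < 0.02))
  expect_true(all(abs(cyc$depth$value - 2 * 1.7) / (2 * 1.7) < 0.02))
  expect_warning(empty <- extract_respiration_features(rep(1, 1000), fs),
                 "flat")
  expect_identical(nrow(empty$variability), 0L)
})

test_that("a rising-frequency chirp yields decreasing cycle durations", {
  fs <- 64
  t <- seq(0, 60, by = 1 / fs)
  # instantaneous frequency rising 0.15 -> 0.45 Hz
  phase <- 2 * pi * (0.15 * t + 0.0025 * t^2)
  cyc <- extract_respiration_features(sin(phase), fs)
  expect_gt(nrow(cyc$variability), 5)
  expect_true(all(diff(cyc$variability$value) < 0))
})

test_that("pupil averaging uses available eyes and interpolates gaps", {
  expect_equal(extract_pupil(rep(4, 10), rep(6, 10)), rep(5, 10))
  l <- c(4, NA, 4); r <- c(6, 6, 6)
  expect_equal(extract_pupil(l, r), c(5, 6, 5))
  l <- c(4, NA, NA, NA, 5); r <- c(4, NA, NA, NA, 5)
  expect_equal(extract_pupil(l, r), c(4, 4.25, 4.5, 4.75, 5))
  expect_error(extract_pupil(rep(NA_real_, 5), rep(NA_real_, 5)), "missing")
})

test_that("the assembled matrix is 16 x 64 with a zero first column", {
  cfg <- synth_config(n_subjects = 2, trials_per_subject = 2, seed = 3)
  raw <- generate_raw_trial("high", cfg, seed = 17)
  lt <- extract_trial_features(raw, "S01", "T01")
  expect_identical(dim(lt$features), c(16L, 64L))
  expect_true(all(lt$features[, 1] == 0))
  expect_identical(rownames(lt$features), valence_features())
  expect_identical(lt$label, "high")
})

test_that("series on the 64-point window grid are preserved by assembly", {
  dur <- 40; fs <- 63 / 30  # sample times land exactly on the window grid
  grid <- dur - 30 + (0:63) * (30 / 63)
  vals <- sin(grid)
  facial <- matrix(rep(0, 10 * 85), 10,
                   dimnames = list(paste0("f", 1:10), NULL))
  x <- c(rep(0, round((dur - 30) * fs)), vals)
  physio <- list(hrv = event_series(c(0, dur), c(1, 1)),
                 resp_variability = event_series(c(0, dur), c(4, 4)),
                 resp_depth = event_series(c(0, dur), c(2, 2)),
                 temperature = rep(33, 200), gsr = rep(2, 200),
                 pupil = approx(seq(0, dur, length.out = length(x)), x,
                                xout = seq(0, dur, by = 1 / 60))$y)
  m <- assemble_feature_matrix(facial, physio, dur, fs_video = fs / 85 * 85,
                               fs_physio = 200 / dur, fs_gaze = 60)
  expect_equal(unname(m["temperature", ]), rep(0, 64))  # constant -> zeros
  expect_equal(unname(m["hrv", ]), rep(0, 64))
})

test_that("assembly rejects series that do not cover the window", {
  facial <- matrix(0, 10, 2400, dimnames = list(paste0("f", 1:10), NULL))
  physio <- list(hrv = event_series(1, 1), resp_variability = event_series(1, 4),
                 resp_depth = event_series(1, 2),
                 temperature = rep(33, 100), gsr = rep(2, 10240),
                 pupil = rep(4, 2400))
  expect_error(assemble_feature_matrix(facial, physio, 40, 60, 256, 60),
               "temperature")
})

test_that("end-to-end extraction recovers RR and respiration ground truth", {
  cfg <- synth_config(n_subjects = 2, trials_per_subject = 2,
                      trial_duration = 45, seed = 13)
  raw <- generate_raw_trial("low", cfg, seed = 99, heart_rate_bpm = 66,
                            resp_rate_hz = 0.3)
  rt <- detect_r_peaks(preprocess_ecg(raw$ecg, raw$fs_physio), raw$fs_physio)
  n <- min(length(rt), length(raw$true_r_times))
  expect_lt(mean(abs(diff(rt[1:n]) - diff(raw$true_r_times[1:n]))), 0.025)
  cyc <- extract_respiration_features(raw$respiration, raw$fs_physio)
  expect_lt(mean(abs(cyc$variability$value - 1 / 0.3)) / (1 / 0.3), 0.05)
})
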