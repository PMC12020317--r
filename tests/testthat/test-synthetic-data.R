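# Synthetic EMG, artifact injection, percept drift, and the detection
# observer: the stated statistical structure must be recoverable from the
# generated data itself.

test_that("zero activation and zero noise give an identically zero recording", {
  cfg <- sim_config(n_channels = 3,
                    posture_sequence = data.frame(posture_id = 1:2,
                                                  duration_s = 1),
                    activation_matrix = matrix(0, 3, 2),
                    baseline_noise = 0, seed = 1)
  sim <- generate_emg(cfg)
  expect_true(all(sim$recording$samples == 0))
  expect_equal(unname(sim$ground_truth$channel_roles),
               rep("noise_only", 3))
})

test_that("identical seeds give bitwise-identical recordings", {
  cfg <- sim_config(n_channels = 2,
                    posture_sequence = data.frame(posture_id = 1,
                                                  duration_s = 2),
                    activation_matrix = matrix(10, 2, 1), seed = 7)
  a <- generate_emg(cfg)
  b <- generate_emg(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$recording$posture_labels, b$recording$posture_labels)
})

test_that("posture-segment RMS approaches sqrt(activation^2 + noise^2)", {
  cfg <- sim_config(n_channels = 1,
                    posture_sequence = data.frame(posture_id = 3,
                                                  duration_s = 12),
                    activation_matrix = matrix(50, 1, 1),
                    baseline_noise = 2, seed = 11)
  rec <- generate_emg(cfg)$recording
  idx <- which(rec$posture_labels == 3)
  core <- idx[300:(length(idx) - 300)]  # drop ramps
  expect_lt(abs(rms(rec$samples[1, core]) - sqrt(50^2 + 2^2)),
            0.1 * sqrt(50^2 + 2^2))
  expect_lt(abs(rms(rec$samples[1, rec$posture_labels < 0]) - 2), 0.2)
})

test_that("configuration validation rejects impossible bands and durations", {
  expect_error(sim_config(sampling_rate = 500, band = c(15, 350)),
               "sampling_rate")
  expect_error(sim_config(posture_sequence = data.frame(posture_id = 1,
                                                        duration_s = 0)),
               "duration")
  expect_error(sim_config(activation_matrix = matrix(-1, 16, 18)),
               "nonnegative")
})

test_that("artifact injection with zero amplitudes and unit gain is the identity", {
  rec <- noise_recording(2, sd = 5, seed = 2)
  out <- inject_artifact(rec, artifact_spec(70, c(0, 0), broadband_gain = 1), 1)
  expect_identical(out$samples, rec$samples)
  expect_true(all(out$stim_flag))
})

test_that("a consistent 70 Hz artifact dominates the periodogram at 70 Hz", {
  rec <- noise_recording(10, sd = 5, seed = 3)
  out <- inject_artifact(rec, artifact_spec(70, 20, "consistent"), 1)
  # independent oracle: direct periodogram of the injected signal
  pg <- stats::spec.pgram(stats::ts(out$samples[1, ], frequency = 1000),
                          taper = 0, plot = FALSE, detrend = FALSE)
  at70 <- pg$spec[which.min(abs(pg$freq - 70))]
  neighbors <- pg$spec[(pg$freq >= 60 & pg$freq <= 65) |
                         (pg$freq >= 75 & pg$freq <= 80)]
  expect_gt(at70, 10 * median(neighbors))
})

test_that("overall_power mode scales out-of-band median power by the gain", {
  rec <- noise_recording(10, sd = 5, seed = 4)
  out <- inject_artifact(rec,
                         artifact_spec(70, 0, "overall_power",
                                       broadband_gain = 4), 1)
  pg_in <- stats::spec.pgram(stats::ts(rec$samples[1, ], frequency = 1000),
                             taper = 0, plot = FALSE, detrend = FALSE)
  pg_out <- stats::spec.pgram(stats::ts(out$samples[1, ], frequency = 1000),
                              taper = 0, plot = FALSE, detrend = FALSE)
  keep <- pg_in$freq > 10 & pg_in$freq < 500
  for (h in stim_harmonics(70)) keep <- keep & abs(pg_in$freq - h) > 5
  ratio <- median(pg_out$spec[keep]) / median(pg_in$spec[keep])
  expect_lt(abs(ratio - 4), 0.8)
})

test_that("harmonics above the Nyquist frequency are rejected", {
  rec <- noise_recording(1, sd = 1, seed = 5)
  # the 8th harmonic of 70 Hz (560 Hz) exceeds the 500 Hz Nyquist limit
  expect_error(inject_artifact(rec, artifact_spec(70, c(rep(0, 7), 20)), 1),
               "Nyquist")
  # the 7th harmonic (490 Hz) is still legal
  expect_silent(inject_artifact(rec, artifact_spec(70, c(rep(0, 6), 5)), 1))
})

test_that("percept rasters reproduce exact Jaccard geometry under drift", {
  tpl <- limb_template(256, 256, 128)
  # no drift: all pairwise similarities 1
  reports <- generate_percept_series(5, list(translation = c(0, 0),
                                             area_jitter = 0),
                                     tpl, seed = 1, side = 40)
  for (i in 1:4) {
    expect_equal(jaccard(reports[[i]]$location_mask,
                         reports[[i + 1]]$location_mask), 1)
  }
  # one full mask width per session: consecutive sessions disjoint
  reports <- generate_percept_series(3, list(translation = c(0, 40),
                                             area_jitter = 0),
                                     tpl, seed = 1, side = 40)
  expect_equal(jaccard(reports[[1]]$location_mask,
                       reports[[2]]$location_mask), 0)
  # half the mask width: consecutive-session Jaccard = 1/3 (pixel counting)
  reports <- generate_percept_series(3, list(translation = c(0, 20),
                                             area_jitter = 0),
                                     tpl, seed = 1, side = 40)
  expect_equal(jaccard(reports[[1]]$location_mask,
                       reports[[2]]$location_mask), 1 / 3)
})

test_that("percept centroid displacement is linear in session index", {
  tpl <- limb_template(512, 512, 256)
  drift <- c(3, 5)
  reports <- generate_percept_series(6, list(translation = drift,
                                             area_jitter = 0),
                                     tpl, seed = 2, side = 50)
  centroid <- function(m) {
    w <- which(m, arr.ind = TRUE)
    colMeans(w)
  }
  c0 <- centroid(reports[[1]]$location_mask)
  for (s in 2:6) {
    disp <- centroid(reports[[s]]$location_mask) - c0
    expect_true(all(abs(disp - drift * (s - 1)) <= 1))
  }
})

test_that("drift that pushes the mask off the template errors", {
  tpl <- limb_template(64, 64, 32)
  expect_error(generate_percept_series(10, list(translation = c(0, 100),
                                                area_jitter = 0),
                                       tpl, seed = 1, side = 10),
               "off the template")
})

test_that("the step observer implements a deterministic threshold", {
  obs <- make_observer(100, slope = Inf)
  expect_false(obs(99))
  expect_true(obs(100))
  expect_true(obs(250))
  # detection is nondecreasing over a charge sweep
  sweep <- vapply(seq(0, 250, by = 5), obs, logical(1))
  expect_true(all(diff(sweep) >= 0))
})

test_that("a finite-slope observer detects at 50% exactly at its threshold", {
  obs <- make_observer(100, slope = 0.2)
  set.seed(99)
  hits <- mean(replicate(10000, obs(100)))
  expect_lt(abs(hits - 0.5), 0.02)
  # empirical detection rate increases with charge
  rate <- function(q) mean(replicate(2000, obs(q)))
  expect_true(rate(80) < rate(100) && rate(100) < rate(120))
})

test_that("resistance series reproduce their stated drift exactly when noiseless", {
  weeks <- seq(0, 20, by = 2)
  series <- generate_resistance_series(weeks, r0 = 5,
                                       drift_kohm_per_week = -0.078,
                                       trial_sd_kohm = 0, seed = 1)
  r <- vapply(series, function(s)
    estimate_resistance(s$voltages)$resistance, numeric(1))
  fit <- linear_trend_test(weeks, r)
  expect_equal(fit$slope, -0.078, tolerance = 1e-10)
})
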