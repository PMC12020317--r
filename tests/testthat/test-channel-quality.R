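# Responsive vs noise-only classification and crosstalk estimation.

test_that("an all-zero channel is classified noise-only", {
  rec <- emg_recording(matrix(0, 1, 5000))
  cl <- classify_noise_only(extract_features(rec, 100, 100))
  expect_equal(cl$status, "noise_only")
  expect_equal(cl$wfl_variance, 0)
  expect_equal(cl$n_wfl_peaks, 0)
  expect_equal(cl$mav_below_frac, 1)
})

test_that("synthetic responsive and quiet channels recover their ground-truth roles", {
  # well-separated regime: activation 50 uV vs 17 uV MAV criterion, noise
  # 1 uV vs the 0.02 WFL variance criterion
  cfg <- sim_config(n_channels = 2,
                    posture_sequence = data.frame(posture_id = 1:6,
                                                  duration_s = 2),
                    activation_matrix = rbind(rep(50, 6), rep(0, 6)),
                    baseline_noise = 1, seed = 21)
  sim <- generate_emg(cfg)
  cl <- classify_noise_only(extract_features(sim$recording, 100, 100))
  expect_equal(cl$status, unname(sim$ground_truth$channel_roles))
})

test_that("four isolated WFL peaks defeat the noise-only peak criterion", {
  # constructed feature series: flat WFL of 1 uV with 4 peaks at 10x baseline
  nw <- 120
  wfl <- rep(1, nw)
  peaks_at <- c(20, 45, 70, 95)
  wfl[peaks_at] <- 10
  fs <- feature_series(wfl = matrix(wfl, 1), mav = matrix(1, 1, nw),
                       window_ms = 100, step_ms = 100,
                       window_start_s = (0:(nw - 1)) * 0.1,
                       posture = rep(c(-1L, 1L), length.out = nw),
                       stim_flag = rep(FALSE, nw))
  cl <- classify_noise_only(fs, baseline_noise = 1)
  expect_equal(cl$n_wfl_peaks, 4)
  expect_equal(cl$status, "responsive")
  # merging: a single 4-window burst counts once
  wfl2 <- rep(1, nw); wfl2[30:33] <- 10
  fs2 <- feature_series(wfl = matrix(wfl2, 1), mav = matrix(1, 1, nw),
                        window_ms = 100, step_ms = 100,
                        window_start_s = (0:(nw - 1)) * 0.1,
                        posture = rep(-1L, nw), stim_flag = rep(FALSE, nw))
  expect_equal(classify_noise_only(fs2, baseline_noise = 1)$n_wfl_peaks, 1)
})

test_that("classification errors without rest windows and is order-invariant", {
  rec <- emg_recording(matrix(rnorm(2000), 2), posture_labels = rep(1L, 1000))
  expect_error(classify_noise_only(extract_features(rec, 100, 100)),
               "rest")
  # channel order invariance
  cfg <- sim_config(n_channels = 3,
                    posture_sequence = data.frame(posture_id = 1:3,
                                                  duration_s = 2),
                    activation_matrix = rbind(rep(40, 3), rep(0, 3),
                                              rep(60, 3)),
                    baseline_noise = 1, seed = 4)
  rec <- generate_emg(cfg)$recording
  cl <- classify_noise_only(extract_features(rec, 100, 100))
  rec_perm <- rec
  rec_perm$samples <- rec$samples[c(3, 1, 2), ]
  cl_perm <- classify_noise_only(extract_features(rec_perm, 100, 100))
  expect_equal(cl_perm$status, cl$status[c(3, 1, 2)])
})

test_that("crosstalk is Pearson correlation of WFL series with unit diagonal", {
  set.seed(31)
  x <- abs(rnorm(400, sd = 10))
  fs <- feature_series(wfl = rbind(x, x, abs(rnorm(400, sd = 10))),
                       mav = NULL, window_ms = 100, step_ms = 100,
                       window_start_s = (0:399) * 0.1,
                       posture = rep(-1L, 400), stim_flag = rep(FALSE, 400))
  ct <- crosstalk_matrix(fs)
  expect_equal(diag(ct$values), rep(1, 3))
  expect_equal(ct$values, t(ct$values))
  expect_equal(ct$values[1, 2], 1)  # exact copy
  # brute-force oracle for an arbitrary pair
  expect_equal(ct$values[1, 3], cor(x, fs$wfl[3, ]))
})

test_that("independent channels show near-zero crosstalk and mirrors match brute force", {
  set.seed(32)
  nw <- 10000
  a <- abs(rnorm(nw)); b <- abs(rnorm(nw))
  fs <- feature_series(wfl = rbind(a, b), mav = NULL, window_ms = 100,
                       step_ms = 100, window_start_s = (0:(nw - 1)) * 0.1,
                       posture = rep(-1L, nw), stim_flag = rep(FALSE, nw))
  expect_lt(abs(crosstalk_matrix(fs)$values[1, 2]), 0.05)
  # mirror-activation pair equals the independent correlation oracle
  m <- max(a) - a
  fs2 <- feature_series(wfl = rbind(a, m), mav = NULL, window_ms = 100,
                        step_ms = 100, window_start_s = (0:(nw - 1)) * 0.1,
                        posture = rep(-1L, nw), stim_flag = rep(FALSE, nw))
  expect_equal(crosstalk_matrix(fs2)$values[1, 2], cor(a, m))
})

test_that("zero-variance channels get zero crosstalk with a warning", {
  fs <- feature_series(wfl = rbind(abs(rnorm(100)), rep(2, 100)),
                       mav = NULL, window_ms = 100, step_ms = 100,
                       window_start_s = (0:99) * 0.1,
                       posture = rep(-1L, 100), stim_flag = rep(FALSE, 100))
  expect_warning(ct <- crosstalk_matrix(fs), "zero-variance")
  expect_equal(ct$values[1, 2], 0)
  expect_equal(diag(ct$values), c(1, 1))
})

test_that("crosstalk matrices are permutation-equivariant", {
  set.seed(33)
  w <- matrix(abs(rnorm(4 * 300)), 4)
  mk <- function(w) feature_series(
    wfl = w, mav = NULL, window_ms = 100, step_ms = 100,
    window_start_s = (0:299) * 0.1, posture = rep(-1L, 300),
    stim_flag = rep(FALSE, 300))
  perm <- c(3, 1, 4, 2)
  v1 <- crosstalk_matrix(mk(w))$values[perm, perm]
  v2 <- crosstalk_matrix(mk(w[perm, ]))$values
  expect_equal(v1, v2)
})

test_that("crosstalk trends recover noiseless slopes and flag constants", {
  mk_mat <- function(mean_val, week) {
    v <- matrix(mean_val, 3, 3); diag(v) <- 1
    structure(list(values = v, zero_variance = rep(FALSE, 3),
                   session_time = week),
              class = "crosstalk_matrix")
  }
  weeks <- seq(2, 20, by = 2)
  # identical matrices: zero slope, F = 0, p = 1
  const <- lapply(weeks, function(w) mk_mat(0.3, w))
  res <- crosstalk_trend(const)
  expect_equal(res$slope, 0)
  expect_equal(res$p_value, 1)
  # exact linear decline recovered to machine precision
  lin <- lapply(weeks, function(w) mk_mat(0.3 - 0.01 * w, w))
  res <- crosstalk_trend(lin)
  expect_equal(res$slope, -0.01, tolerance = 1e-12)
  expect_error(crosstalk_trend(const[1:2]), "3 sessions")
})
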