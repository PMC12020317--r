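# Shared fixtures, all generated in code.

rms <- function(x) sqrt(mean(x^2))

# band-limited noise recording via the package generator (one channel)
noise_recording <- function(duration_s, sd = 5, act = 0, seed = 1) {
  cfg <- sim_config(
    n_channels = 1,
    posture_sequence = data.frame(posture_id = 1, duration_s = duration_s),
    activation_matrix = matrix(act, 1, 1),
    baseline_noise = sd, seed = seed)
  generate_emg(cfg)$recording
}

# one synthetic channel with a known artifact category; returns the assigned
# category from the full classification + categorization path
categorize_synthetic_channel <- function(category, seed,
                                         trial_s = 2, n_trials = 3) {
  act <- if (category == "unresponsive") 0 else 50
  noise <- if (category == "unresponsive") 1 else 5
  movement <- {
    cfg <- sim_config(
      n_channels = 1,
      posture_sequence = data.frame(posture_id = 1:2, duration_s = 2),
      activation_matrix = matrix(act, 1, 2),
      baseline_noise = noise, seed = seed)
    generate_emg(cfg)$recording
  }
  status <- classify_noise_only(extract_features(movement, 100, 100))$status
  one_rec <- function(s) {
    cfg <- sim_config(
      n_channels = 1,
      posture_sequence = data.frame(posture_id = 1, duration_s = trial_s),
      activation_matrix = matrix(act, 1, 1),
      baseline_noise = noise, seed = s)
    generate_emg(cfg)$recording
  }
  trials <- lapply(seq_len(n_trials), function(i) {
    stim <- one_rec(seed * 100 + i)
    stim <- switch(category,
      consistent_artifact = inject_artifact(
        stim, artifact_spec(70, c(40, 20, 10)), 1),
      intermittent_artifact = if (i == 2) inject_artifact(
        stim, artifact_spec(70, c(40, 20, 10), "intermittent"), 1,
        active = TRUE) else stim,
      increased_overall_power = inject_artifact(
        stim, artifact_spec(70, 0, "overall_power", broadband_gain = 25), 1),
      stim)
    list(stim = stim, nostim = one_rec(seed * 100 + 50 + i))
  })
  categorize_channel(trials, status)$category
}

# posture_trial stand-in for condition comparisons
fake_trial <- function(target, time_to_target, path_eff, success = TRUE) {
  structure(list(target = target, trajectory = NULL, success = success,
                 time_to_target = time_to_target,
                 path_efficiency = path_eff,
                 stim_frequency_log = NULL),
            class = "posture_trial")
}

# full controller-recovery experiment; returns sign accuracy on the held-out
# (excluded) repetitions and the trained controller
controller_recovery <- function(snr = 25, seed = 3, n_time = 40) {
  map <- disjoint_channel_map(3)
  ds <- simulate_controller_dataset(map, n_reps = 10, n_time = n_time,
                                    snr = snr, seed = seed)
  train <- list(); valid <- list(); held <- list()
  for (p in seq_along(ds)) {
    sel <- select_repetitions(ds[[p]])
    train <- c(train, ds[[p]][sel$train])
    valid <- c(valid, ds[[p]][sel$validation])
    held <- c(held, ds[[p]][sel$excluded])
  }
  ctrl <- train_ann(train, valid, hidden_nodes = 14, seed = seed)
  hold <- seq(round(n_time / 4) + 1, round(3 * n_time / 4))
  num <- 0; den <- 0
  for (tr in held) {
    r <- decode(ctrl, tr$features, raw = TRUE)
    rm_ <- rowMeans(r[, hold])
    for (d in 1:3) {
      if (tr$direction[d] == 0) next
      den <- den + 1
      if (sign(rm_[d]) == tr$direction[d] && abs(rm_[d]) > 0.05)
        num <- num + 1
    }
  }
  list(controller = ctrl, map = map, sign_accuracy = num / den,
       validation_rmse = ctrl$validation_rmse)
}
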