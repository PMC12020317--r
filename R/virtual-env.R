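# Virtual posture-matching environment: velocity integration under the
# study's success rule (all DOFs within 15% of target for 1 consecutive
# second inside a 30 s limit), graded stimulation feedback, and the
# time-to-target / path-efficiency outcome metrics.

#' Stimulation feedback frequency for a posture error
#'
#' Three-level mapping from joint-angle error to sensory-feedback pulse
#' frequency: 0 Hz while any DOF error exceeds 22.5% of range, 50 Hz once
#' all errors are within 22.5%, and 100 Hz once all are within 15%. Pulse
#' width and amplitude stay constant (250 us, 0.3 mA) so frequency alone
#' codes proximity.
#'
#' @param state,target length-3 joint-angle vectors in normalized range
#'   units (`[-1, 1]` per DOF).
#' @param band_outer,band_inner the 22.5% and 15% bands in range units.
#' @return Pulse frequency in Hz: 0, 50, or 100.
#' @export
#' @examples
#' stim_feedback(c(0, 0, 0), c(0.2, 0.2, 0.2))  # 50
stim_feedback <- function(state, target, band_outer = 0.225,
                          band_inner = 0.15) {
  err <- abs(state - target)
  if (all(err <= band_inner)) 100
  else if (all(err <= band_outer)) 50
  else 0
}

#' Run one virtual posture-matching trial
#'
#' Integrates decoded 3-DOF velocities in 50 ms steps with joint angles
#' clipped to `[-1, 1]`. The trial succeeds when all three joint-angle errors
#' stay within `band` of the target continuously for `dwell_s` seconds
#' before the `limit_s` trial limit; time-to-target is the time at the end
#' of that dwell. The stimulation feedback frequency is logged at every
#' step.
#'
#' @param controller an `ann_controller` from [train_ann()], or any function
#'   mapping a feature vector to a length-3 velocity (range/s).
#' @param feature_stream either a channels x steps matrix of WFL vectors
#'   (open loop) or a function `(state, target, t)` returning the feature
#'   vector (closed loop, standing in for the user reacting to what they
#'   see).
#' @param target length-3 target posture in normalized range units.
#' @param start starting posture (default the origin).
#' @param dt integration step in seconds (the 50 ms feature update rate).
#' @param limit_s trial limit in seconds.
#' @param band success band as a fraction of full range per DOF.
#' @param dwell_s required continuous in-band dwell in seconds.
#' @return A `posture_trial` list: `target`, `trajectory` (3 x samples,
#'   including the start), `success`, `time_to_target` (s, `NA` on failure),
#'   `path_efficiency`, `stim_frequency_log`.
#' @export
run_trial <- function(controller, feature_stream, target,
                      start = c(0, 0, 0), dt = 0.05, limit_s = 30,
                      band = 0.15, dwell_s = 1) {
  closed_loop <- is.function(feature_stream)
  if (!closed_loop) {
    feature_stream <- as.matrix(feature_stream)
    if (ncol(feature_stream) == 0) stop("empty feature stream")
  }
  vel_fun <- if (inherits(controller, "ann_controller")) {
    function(f) decode(controller, f)
  } else controller

  n_steps <- round(limit_s / dt)
  if (!closed_loop) n_steps <- min(n_steps, ncol(feature_stream))
  traj <- matrix(NA_real_, 3, n_steps + 1)
  stim_log <- numeric(n_steps + 1)
  state <- as.numeric(start)
  counter <- 0L
  success <- FALSE
  tt <- NA_real_
  k_end <- n_steps
  for (k in 0:n_steps) {
    traj[, k + 1] <- state
    stim_log[k + 1] <- stim_feedback(state, target, band_inner = band)
    counter <- if (all(abs(state - target) <= band)) counter + 1L else 0L
    if ((counter - 1L) * dt >= dwell_s) {
      success <- TRUE
      tt <- k * dt
      k_end <- k
      break
    }
    if (k == n_steps) break
    f <- if (closed_loop) feature_stream(state, target, k * dt)
         else feature_stream[, k + 1]
    v <- vel_fun(f)
    state <- pmin(pmax(state + v * dt, -1), 1)
  }
  traj <- traj[, seq_len(k_end + 1), drop = FALSE]
  # a motionless timed-out trial legitimately has zero traveled distance
  pe <- if (ncol(traj) < 2) NA_real_
        else suppressWarnings(path_efficiency(traj))
  structure(list(target = target, trajectory = traj, success = success,
                 time_to_target = tt,
                 path_efficiency = pe,
                 stim_frequency_log = stim_log[seq_len(k_end + 1)]),
            class = "posture_trial")
}

#' Path efficiency of a joint-angle trajectory
#'
#' Euclidean distance between the starting and final positions divided by
#' the total distance traveled in joint-angle space. By the triangle
#' inequality the value is at most 1, with equality only for monotone
#' straight-line motion; a trajectory that never moves has zero traveled
#' distance and reports 0 with a warning.
#'
#' @param trajectory 3 x samples matrix of joint angles (>= 2 samples).
#' @return Proportion in `[0, 1]`.
#' @export
#' @examples
#' path_efficiency(cbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))  # 0.707
path_efficiency <- function(trajectory) {
  trajectory <- as.matrix(trajectory)
  if (ncol(trajectory) < 2) stop("need at least 2 trajectory samples")
  steps <- diff(t(trajectory))
  traveled <- sum(sqrt(rowSums(steps^2)))
  if (traveled == 0) {
    warning("zero traveled distance; path efficiency undefined, returning 0")
    return(0)
  }
  disp <- sqrt(sum((trajectory[, ncol(trajectory)] - trajectory[, 1])^2))
  disp / traveled
}

#' Generate random reachable target postures
#'
#' Uniform in `[-range, range]` per DOF so every target leaves margin for
#' the 15% success band inside the clipped joint range.
#'
#' @param n number of targets.
#' @param range per-DOF half-range.
#' @param seed integer seed.
#' @return A list of length-3 target vectors.
#' @export
random_targets <- function(n, range = 0.8, seed = 1) {
  with_seed(seed, lapply(seq_len(n), function(i)
    stats::runif(3, -range, range)))
}

#' Compare posture-matching performance between stimulation conditions
#'
#' Per-condition medians of time-to-target and path efficiency plus paired
#' Wilcoxon signed-rank p-values across matched targets, and per-condition
#' success rates. Failed trials contribute the trial limit as their
#' time-to-target (conservative censoring at 30 s).
#'
#' @param trials_stim,trials_nostim lists of `posture_trial`s with matched
#'   targets in matching order.
#' @param limit_s trial limit used for censoring failed trials.
#' @return A list with `median_time_to_target`, `median_path_efficiency`,
#'   `success_rate` (each per condition), and `p_time`, `p_path`.
#' @export
evaluate_conditions <- function(trials_stim, trials_nostim, limit_s = 30) {
  if (length(trials_stim) != length(trials_nostim))
    stop("conditions must have the same number of matched trials")
  tgt_s <- t(sapply(trials_stim, `[[`, "target"))
  tgt_n <- t(sapply(trials_nostim, `[[`, "target"))
  if (max(abs(tgt_s - tgt_n)) > 1e-9)
    stop("targets are not matched across conditions")
  tts <- function(trials) vapply(trials, function(tr)
    if (tr$success) tr$time_to_target else limit_s, numeric(1))
  pe <- function(trials) vapply(trials, `[[`, numeric(1), "path_efficiency")
  sr <- function(trials) mean(vapply(trials, `[[`, logical(1), "success"))
  t_s <- tts(trials_stim); t_n <- tts(trials_nostim)
  p_s <- pe(trials_stim); p_n <- pe(trials_nostim)
  list(median_time_to_target = c(stim = stats::median(t_s),
                                 nostim = stats::median(t_n)),
       median_path_efficiency = c(stim = stats::median(p_s),
                                  nostim = stats::median(p_n)),
       success_rate = c(stim = sr(trials_stim), nostim = sr(trials_nostim)),
       p_time = group_compare(list(t_s, t_n), paired = TRUE)$p_value,
       p_path = group_compare(list(p_s, p_n), paired = TRUE)$p_value)
}
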