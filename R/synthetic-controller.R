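# Synthetic, ground-truthed controller training data: channel-disjoint WFL
# activation per DOF direction, used for controller recovery experiments and
# as the scripted "ideal user" in closed-loop evaluation.

#' Channel map with disjoint channels per DOF direction
#'
#' Assigns `per_direction` dedicated channels to each of the six DOF
#' directions (dof1+, dof1-, dof2+, dof2-, dof3+, dof3-), the separable
#' regime in which a proportional controller is identifiable by
#' construction.
#'
#' @param per_direction channels dedicated to each direction.
#' @return A list with `n_channels` and `channels`, a list of 6 index
#'   vectors in direction order.
#' @export
disjoint_channel_map <- function(per_direction = 3) {
  idx <- split(seq_len(6 * per_direction),
               rep(1:6, each = per_direction))
  list(n_channels = 6 * per_direction, channels = unname(idx))
}

# direction vector -> active direction slots (dof, sign) as indices 1..6
direction_slots <- function(direction) {
  slots <- integer(0)
  for (d in 1:3) {
    if (direction[d] > 0) slots <- c(slots, 2 * d - 1)
    if (direction[d] < 0) slots <- c(slots, 2 * d)
  }
  slots
}

#' Encode a movement intent as a channel WFL vector
#'
#' The generative model of the synthetic user: channels dedicated to each
#' active DOF direction carry WFL amplitude proportional to that DOF's
#' intent magnitude; all other channels stay at baseline. Additive Gaussian
#' noise with SD `amplitude / snr` is applied and the result clipped at zero
#' (WFL is nonnegative).
#'
#' @param intent length-3 vector; sign selects the direction, magnitude in
#'   `[0, 1]` scales the activation.
#' @param map a [disjoint_channel_map()].
#' @param amplitude full-intent WFL amplitude in uV.
#' @param snr amplitude signal-to-noise ratio (Inf for noiseless).
#' @return A length-`map$n_channels` WFL vector.
#' @export
encode_effort <- function(intent, map, amplitude = 30, snr = Inf) {
  x <- numeric(map$n_channels)
  for (d in 1:3) {
    if (intent[d] == 0) next
    slot <- if (intent[d] > 0) 2 * d - 1 else 2 * d
    x[map$channels[[slot]]] <- amplitude * abs(intent[d])
  }
  if (is.finite(snr)) {
    x <- x + stats::rnorm(length(x), sd = amplitude / snr)
  }
  pmax(x, 0)
}

#' Simulate a channel-disjoint controller training dataset
#'
#' Generates `n_reps` repetitions of every posture in [enumerate_postures()]:
#' each repetition is a [training_trial()] whose WFL features follow
#' [encode_effort()] under a trapezoidal effort envelope (ramp up over the
#' first quarter, hold, ramp down over the last quarter).
#'
#' @param map a [disjoint_channel_map()].
#' @param n_reps repetitions per posture (the study collected 10).
#' @param n_time time points per repetition (50 ms steps).
#' @param amplitude full-effort WFL amplitude in uV.
#' @param snr amplitude signal-to-noise ratio.
#' @param seed integer seed.
#' @return A list of 18 elements (one per posture), each a list of `n_reps`
#'   [training_trial()]s.
#' @export
simulate_controller_dataset <- function(map = disjoint_channel_map(),
                                        n_reps = 10, n_time = 40,
                                        amplitude = 30, snr = 25, seed = 1) {
  postures <- enumerate_postures()
  ramp <- max(1L, round(n_time / 4))
  env <- c(seq(0, 1, length.out = ramp),
           rep(1, n_time - 2 * ramp),
           seq(1, 0, length.out = ramp))
  with_seed(seed, {
    lapply(seq_len(nrow(postures)), function(p) {
      dir <- postures[p, ]
      lapply(seq_len(n_reps), function(r) {
        feats <- sapply(env, function(e)
          encode_effort(dir * e, map, amplitude, snr))
        training_trial(posture_id = p, direction = dir, features = feats)
      })
    })
  })
}

#' Scripted ideal user for closed-loop evaluation
#'
#' Returns a feature-stream function for [run_trial()]: at every step the
#' "user" encodes an intent proportional to the remaining error (saturating
#' at full effort for errors beyond `saturation` range units), through the
#' same generative channel map the controller was trained on.
#'
#' @param map a [disjoint_channel_map()].
#' @param amplitude full-effort WFL amplitude in uV.
#' @param snr amplitude signal-to-noise ratio of the encoding.
#' @param saturation error (range units) at which intent saturates at 1.
#' @return A function `(state, target, t)` returning a WFL feature vector.
#' @export
scripted_user <- function(map = disjoint_channel_map(), amplitude = 30,
                          snr = Inf, saturation = 0.3) {
  function(state, target, t) {
    err <- target - state
    intent <- sign(err) * pmin(abs(err) / saturation, 1)
    encode_effort(intent, map, amplitude, snr)
  }
}
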