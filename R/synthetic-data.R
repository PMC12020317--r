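# Ground-truthed synthetic inputs: surrogate intramuscular EMG, stimulation
# artifact injection, percept drawings with session drift, a detection
# observer for threshold psychophysics, and tissue-resistance series.
#
# The EMG model is interference EMG at the "filtered stochastic" level: band-
# limited Gaussian noise, amplitude-modulated by a posture envelope with
# 200 ms raised-cosine ramps. Motor units and volume conduction are out of
# scope; the point is to give every downstream stage a signal with the right
# first- and second-order statistics and a known ground truth.

# run code with a temporary RNG state so generators are pure in (config, seed)
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic EMG generator
#'
#' @param n_channels number of EMG channels (16 in the implanted system).
#' @param sampling_rate Hz; must exceed twice the upper band edge.
#' @param posture_sequence data frame with columns `posture_id` and
#'   `duration_s`, in presentation order. Rest blocks of `rest_s` seconds are
#'   interleaved automatically (before, between, and after postures).
#' @param activation_matrix channels x postures nonnegative matrix of target
#'   RMS amplitudes in uV; column `p` is the activation of each channel while
#'   posture `posture_sequence$posture_id[p]` is held.
#' @param baseline_noise baseline noise RMS in uV, common to all channels.
#' @param band two-element numeric, passband of the EMG content in Hz.
#' @param rest_s duration of each interleaved rest block in seconds.
#' @param ramp_s rise/fall time of the activation envelope in seconds.
#' @param seed integer seed; identical seeds give bitwise-identical recordings.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_channels = 16, sampling_rate = 1000,
                       posture_sequence = data.frame(
                         posture_id = 1:18, duration_s = 3),
                       activation_matrix = matrix(
                         50, n_channels, nrow(posture_sequence)),
                       baseline_noise = 2, band = c(15, 350),
                       rest_s = 2, ramp_s = 0.2, seed = 1) {
  posture_sequence <- as.data.frame(posture_sequence)
  stopifnot(all(c("posture_id", "duration_s") %in% names(posture_sequence)))
  activation_matrix <- as.matrix(activation_matrix)
  if (sampling_rate <= 2 * band[2])
    stop("sampling_rate must exceed twice the upper band edge")
  if (band[1] <= 0 || band[1] >= band[2])
    stop("band must satisfy 0 < low < high")
  if (any(posture_sequence$duration_s <= 0)) stop("all durations must be > 0")
  if (any(activation_matrix < 0))
    stop("activation_matrix entries must be nonnegative")
  if (nrow(activation_matrix) != n_channels ||
      ncol(activation_matrix) != nrow(posture_sequence))
    stop("activation_matrix must be n_channels x n_postures")
  if (baseline_noise < 0) stop("baseline_noise must be nonnegative")
  structure(
    list(n_channels = n_channels, sampling_rate = sampling_rate,
         posture_sequence = posture_sequence,
         activation_matrix = activation_matrix,
         baseline_noise = baseline_noise, band = band,
         rest_s = rest_s, ramp_s = ramp_s, seed = as.integer(seed)),
    class = "sim_config")
}

# unit-RMS band-limited Gaussian noise; zero-variance input returns zeros
bandlimited_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  hp <- butter_design(4, band[1], fs, "high")
  lp <- butter_design(4, band[2], fs, "low")
  pad <- min(n - 1L, as.integer(round(3 * fs / band[1])))
  x <- filtfilt_zp(filtfilt_zp(x, hp$b, hp$a, pad), lp$b, lp$a, pad)
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

# raised-cosine on/off envelope for one segment within a signal of length n
segment_envelope <- function(n, from, to, ramp) {
  env <- numeric(n)
  len <- to - from + 1
  ramp <- min(ramp, floor(len / 2))
  core <- rep(1, len)
  if (ramp > 0) {
    up <- (1 - cos(pi * seq_len(ramp) / ramp)) / 2
    core[seq_len(ramp)] <- up
    core[seq(len, len - ramp + 1)] <- up
  }
  env[from:to] <- core
  env
}

#' Generate a labeled synthetic EMG recording with ground truth
#'
#' Produces band-limited Gaussian interference EMG in which each channel's RMS
#' during posture `p` approaches `sqrt(activation[ch, p]^2 + baseline^2)`:
#' an activation component (raised-cosine ramped envelope times unit-RMS
#' band-limited noise) summed with an independent baseline noise floor. Rest
#' blocks separate postures and carry label `-1`.
#'
#' @param config a [sim_config()].
#' @return A list with elements `recording` (an [emg_recording()]) and
#'   `ground_truth` (list with `channel_roles`, `"responsive"` for channels
#'   with any nonzero activation, else `"noise_only"`).
#' @export
#' @examples
#' cfg <- sim_config(n_channels = 2,
#'                   posture_sequence = data.frame(posture_id = 1, duration_s = 3),
#'                   activation_matrix = matrix(c(50, 0), 2, 1), seed = 7)
#' sim <- generate_emg(cfg)
#' sim$ground_truth$channel_roles
generate_emg <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  ps <- config$posture_sequence
  k <- nrow(ps)
  rest_n <- round(config$rest_s * fs)
  post_n <- round(ps$duration_s * fs)
  ramp_n <- round(config$ramp_s * fs)

  # timeline: rest, posture 1, rest, posture 2, ..., rest
  blocks <- integer(0)
  labels <- integer(0)
  starts <- integer(k); ends <- integer(k)
  pos <- 0L
  add_block <- function(n, lab) {
    labels <<- c(labels, rep(lab, n))
    pos <<- pos + n
  }
  add_block(rest_n, -1L)
  for (i in seq_len(k)) {
    starts[i] <- pos + 1L
    add_block(post_n[i], as.integer(ps$posture_id[i]))
    ends[i] <- pos
    add_block(rest_n, -1L)
  }
  n <- pos

  samples <- with_seed(config$seed, {
    out <- matrix(0, config$n_channels, n)
    envs <- lapply(seq_len(k), function(i)
      segment_envelope(n, starts[i], ends[i], ramp_n))
    for (ch in seq_len(config$n_channels)) {
      act <- config$activation_matrix[ch, ]
      x <- numeric(n)
      if (any(act > 0)) {
        env <- numeric(n)
        for (i in seq_len(k)) env <- env + act[i] * envs[[i]]
        x <- env * bandlimited_noise(n, fs, config$band)
      }
      if (config$baseline_noise > 0) {
        x <- x + config$baseline_noise * bandlimited_noise(n, fs, config$band)
      }
      out[ch, ] <- x
    }
    out
  })

  roles <- ifelse(rowSums(config$activation_matrix) > 0,
                  "responsive", "noise_only")
  list(recording = emg_recording(samples, fs, posture_labels = labels),
       ground_truth = list(channel_roles = roles,
                           activation_matrix = config$activation_matrix))
}

#' Stimulation artifact specification
#'
#' @param f_stim stimulation frequency in Hz (the study used 70 Hz).
#' @param harmonic_amplitudes numeric vector of sinusoid amplitudes in uV;
#'   element `h` is the amplitude at `h * f_stim`.
#' @param mode `"consistent"` (artifact in every trial), `"intermittent"`
#'   (artifact in a random fraction of trials), or `"overall_power"`
#'   (broadband multiplicative power increase).
#' @param intermittent_fraction proportion of trials affected in intermittent
#'   mode.
#' @param broadband_gain power multiplier for `"overall_power"` mode; >= 1.
#' @return An `artifact_spec` list.
#' @export
artifact_spec <- function(f_stim = 70, harmonic_amplitudes = c(20, 10, 5),
                          mode = c("consistent", "intermittent", "overall_power"),
                          intermittent_fraction = 1 / 3, broadband_gain = 1) {
  mode <- match.arg(mode)
  if (f_stim <= 0) stop("f_stim must be positive")
  if (broadband_gain < 1) stop("broadband_gain must be >= 1")
  if (intermittent_fraction < 0 || intermittent_fraction > 1)
    stop("intermittent_fraction must be in [0, 1]")
  structure(list(f_stim = f_stim, harmonic_amplitudes = harmonic_amplitudes,
                 mode = mode, intermittent_fraction = intermittent_fraction,
                 broadband_gain = broadband_gain),
            class = "artifact_spec")
}

#' Inject a stimulation artifact into an EMG recording
#'
#' Adds additive sinusoids at the stimulation frequency and its harmonics
#' (modes `"consistent"` and `"intermittent"`) or applies a multiplicative
#' broadband power increase (mode `"overall_power"`) to the affected channels,
#' and raises the stimulation-on flag for the whole recording.
#'
#' @param recording an [emg_recording()]; one recording is one trial.
#' @param spec an [artifact_spec()].
#' @param affected_channels integer vector of channel indices to contaminate.
#' @param active for intermittent mode, whether the artifact is present in
#'   this trial; `NULL` (default) draws `runif(1) < intermittent_fraction`
#'   from the current RNG stream.
#' @return The contaminated [emg_recording()] with `stim_flag` all `TRUE`.
#' @export
inject_artifact <- function(recording, spec, affected_channels, active = NULL) {
  stopifnot(inherits(recording, "emg_recording"),
            inherits(spec, "artifact_spec"))
  fs <- recording$sampling_rate
  if (spec$f_stim >= fs / 2) stop("f_stim must be below the Nyquist frequency")
  harmonics <- spec$f_stim * seq_along(spec$harmonic_amplitudes)
  if (any(harmonics >= fs / 2 & spec$harmonic_amplitudes > 0))
    stop("harmonic above the Nyquist frequency")
  out <- recording
  out$stim_flag <- rep(TRUE, n_samples(recording))

  present <- switch(spec$mode,
    consistent = TRUE,
    overall_power = TRUE,
    intermittent = if (is.null(active)) {
      stats::runif(1) < spec$intermittent_fraction
    } else isTRUE(active))
  if (!present) return(out)

  if (spec$mode == "overall_power") {
    out$samples[affected_channels, ] <-
      out$samples[affected_channels, , drop = FALSE] * sqrt(spec$broadband_gain)
    return(out)
  }
  tt <- (seq_len(n_samples(recording)) - 1) / fs
  wave <- numeric(length(tt))
  for (h in seq_along(spec$harmonic_amplitudes)) {
    a <- spec$harmonic_amplitudes[h]
    if (a > 0) wave <- wave + a * sin(2 * pi * harmonics[h] * tt)
  }
  for (ch in affected_channels) out$samples[ch, ] <- out$samples[ch, ] + wave
  out
}

#' Upper-limb drawing template
#'
#' The template on which percept locations are drawn: a `height` x `width`
#' binary raster with a horizontal wrist line. Pixels in rows strictly above
#' (smaller row index than) `wrist_row` are distal to the wrist, i.e. on the
#' hand.
#'
#' @param width,height raster dimensions in pixels.
#' @param wrist_row row index of the wrist line.
#' @return A `limb_template` list.
#' @export
limb_template <- function(width = 512, height = 512, wrist_row = 256) {
  stopifnot(wrist_row >= 1, wrist_row <= height)
  structure(list(width = width, height = height, wrist_row = wrist_row),
            class = "limb_template")
}

# square percept mask; errors if entirely off-template
square_mask <- function(template, center_rc, side) {
  half <- side / 2
  rows <- seq(ceiling(center_rc[1] - half), floor(center_rc[1] + half - 1e-9))
  cols <- seq(ceiling(center_rc[2] - half), floor(center_rc[2] + half - 1e-9))
  rows <- rows[rows >= 1 & rows <= template$height]
  cols <- cols[cols >= 1 & cols <= template$width]
  if (length(rows) == 0 || length(cols) == 0)
    stop("percept mask has drifted entirely off the template")
  m <- matrix(FALSE, template$height, template$width)
  m[rows, cols] <- TRUE
  m
}

# default descriptor lexicon: per-descriptor report probabilities
default_descriptor_probs <- c(
  vibration = 0.67, pressure = 0.31, tingle = 0.20, electrical = 0.20,
  tickling = 0.10, pulsing = 0.10, buzzing = 0.10, tap = 0.05,
  contraction = 0.15, movement = 0.10, tight = 0.10,
  sharp = 0.03, ache = 0.02, shock = 0.02)

#' Generate a drifting series of percept reports for one contact
#'
#' Simulates session-to-session percept drawings: a square mask whose center
#' translates by `drift$translation` pixels per session and whose side length
#' jitters by a fraction `drift$area_jitter`, plus quality descriptors drawn
#' independently per session from a categorical lexicon.
#'
#' @param n_sessions number of sessions.
#' @param drift list with `translation` (length-2 numeric, (row, col) pixels
#'   per session) and `area_jitter` (fractional side-length jitter SD).
#' @param template a [limb_template()].
#' @param seed integer seed.
#' @param center starting mask center, (row, col); defaults to mid-hand.
#' @param side mask side length in pixels.
#' @param descriptor_probs named per-descriptor report probabilities.
#' @return A list of `percept_report` objects (see [percept_report()]),
#'   sessions numbered 1..n.
#' @export
generate_percept_series <- function(n_sessions,
                                    drift = list(translation = c(0, 0),
                                                 area_jitter = 0),
                                    template = limb_template(), seed = 1,
                                    center = NULL, side = 60,
                                    descriptor_probs = default_descriptor_probs) {
  if (is.null(center)) center <- c(template$wrist_row / 2, template$width / 2)
  with_seed(seed, {
    lapply(seq_len(n_sessions), function(s) {
      ctr <- center + drift$translation * (s - 1)
      sd_side <- side * (1 + drift$area_jitter * stats::rnorm(1))
      mask <- square_mask(template, round(ctr), max(2, round(sd_side)))
      reported <- names(descriptor_probs)[
        stats::runif(length(descriptor_probs)) < descriptor_probs]
      percept_report(contact = 1L, session_time = s, location_mask = mask,
                     descriptors = reported)
    })
  })
}

#' Construct a psychophysical detection observer
#'
#' Stands in for the participant during threshold measurement: a callable
#' that reports detection of a stimulus of a given charge per phase with
#' probability given by a logistic function of charge. `slope = Inf` gives a
#' deterministic step observer (detected iff charge >= latent threshold);
#' finite slopes give a 50% detection rate exactly at the latent threshold.
#'
#' @param latent_threshold latent threshold charge in nC; must be positive.
#' @param slope logistic steepness in 1/nC; `Inf` for a deterministic step.
#' @return A function of one argument `charge_nC` returning `TRUE`/`FALSE`,
#'   with class `detection_observer` and the parameters as attributes.
#' @export
#' @examples
#' obs <- make_observer(100, slope = Inf)
#' obs(99); obs(100)
make_observer <- function(latent_threshold, slope = Inf) {
  if (latent_threshold <= 0) stop("latent_threshold must be positive")
  f <- if (is.infinite(slope)) {
    function(charge_nC) charge_nC >= latent_threshold
  } else {
    function(charge_nC) {
      p <- stats::plogis(slope * (charge_nC - latent_threshold))
      stats::runif(1) < p
    }
  }
  structure(f, class = c("detection_observer", "function"),
            latent_threshold = latent_threshold, slope = slope)
}

#' Generate a tissue-resistance session series with drift and trial noise
#'
#' Simulates the per-session resistance probe: at each session the true
#' resistance is `r0 + drift_kohm_per_week * week`, and each of `n_trials`
#' probe pulses yields a voltage `R * I` plus Gaussian noise.
#'
#' @param weeks numeric vector of session times in weeks post-implant.
#' @param r0 true resistance at week 0, kOhm.
#' @param drift_kohm_per_week linear drift of the true resistance.
#' @param trial_sd_kohm per-trial measurement noise SD, in kOhm equivalents.
#' @param n_trials probe repetitions per session (the protocol uses 8).
#' @param probe the probe pulse, a [stim_pulse()]; default 0.2 mA / 70 us.
#' @param seed integer seed.
#' @return A list with one element per session: `week`, `true_resistance`,
#'   and `voltages` (volts, length `n_trials`).
#' @export
generate_resistance_series <- function(weeks, r0 = 4.1,
                                       drift_kohm_per_week = 0,
                                       trial_sd_kohm = 0, n_trials = 8,
                                       probe = stim_pulse(0.2, 70, frequency = 1000),
                                       seed = 1) {
  i_ma <- probe$amplitude
  with_seed(seed, {
    lapply(weeks, function(w) {
      r_true <- r0 + drift_kohm_per_week * w
      r_trials <- r_true + trial_sd_kohm * stats::rnorm(n_trials)
      list(week = w, true_resistance = r_true,
           voltages = r_trials * i_ma)  # kOhm * mA = V
    })
  })
}
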