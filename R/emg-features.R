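# Windowed EMG feature extraction: waveform length (WFL) and mean absolute
# value (MAV), the two features the implant computes, plus the quantization
# models of its raw-EMG and feature streaming paths.

#' Per-window EMG feature series
#'
#' Holds WFL and/or MAV values per channel and window, together with the
#' windowing metadata and per-window posture/stimulation labels. Windows are
#' half-open intervals `[t, t + window_ms)`; trailing samples that do not fill
#' a whole window are dropped (streaming semantics, no padding).
#'
#' @param wfl,mav channels x windows numeric matrices in uV (either may be
#'   `NULL` when only one feature was computed).
#' @param window_ms,step_ms window duration and hop in milliseconds.
#' @param window_start_s numeric vector of window start times in seconds.
#' @param posture integer vector, majority posture label per window (-1 rest).
#' @param stim_flag logical vector, `TRUE` if any sample in the window had
#'   stimulation active.
#' @return A `feature_series` object.
#' @export
feature_series <- function(wfl = NULL, mav = NULL, window_ms, step_ms,
                           window_start_s, posture, stim_flag) {
  if (!is.null(wfl) && any(wfl < 0)) stop("WFL values must be nonnegative")
  if (!is.null(mav) && any(mav < 0)) stop("MAV values must be nonnegative")
  if (step_ms > window_ms) stop("step_ms must be <= window_ms")
  structure(list(wfl = wfl, mav = mav, window_ms = window_ms,
                 step_ms = step_ms, window_start_s = window_start_s,
                 posture = as.integer(posture),
                 stim_flag = as.logical(stim_flag)),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  m <- if (!is.null(x$wfl)) x$wfl else x$mav
  cat(sprintf("<feature_series> %d channel(s), %d windows (%g ms / %g ms step)\n",
              nrow(m), ncol(m), x$window_ms, x$step_ms))
  invisible(x)
}

# most frequent label in a window (ties resolved to the smaller label)
majority_label <- function(labels) {
  tab <- table(labels)
  as.integer(names(tab)[which.max(tab)])
}

window_index <- function(n, win, step) {
  if (n < win) stop("recording shorter than one window")
  starts <- seq(1L, n - win + 1L, by = step)
  starts
}

#' Extract windowed WFL and MAV features from an EMG recording
#'
#' WFL of a window is the sum of absolute sample-to-sample changes within the
#' window divided by the number of samples in the window; MAV is the mean of
#' the rectified signal. Both are in uV and homogeneous of degree 1 in signal
#' amplitude.
#'
#' @param recording an [emg_recording()].
#' @param window_ms,step_ms window length and hop in milliseconds; the
#'   window must contain at least 2 samples for WFL.
#' @return A [feature_series()] with both `wfl` and `mav` filled.
#' @export
#' @examples
#' rec <- emg_recording(matrix(c(0, 1, 3, 2), 1), sampling_rate = 40)
#' extract_features(rec, window_ms = 100, step_ms = 100)$wfl  # (1+2+1)/4 = 1
extract_features <- function(recording, window_ms = 100, step_ms = window_ms) {
  stopifnot(inherits(recording, "emg_recording"))
  fs <- recording$sampling_rate
  win <- round(window_ms / 1000 * fs)
  step <- max(1L, round(step_ms / 1000 * fs))
  if (win < 2) stop("window must contain at least 2 samples")
  n <- n_samples(recording)
  starts <- window_index(n, win, step)
  nw <- length(starts)
  nc <- n_channels(recording)

  wfl <- matrix(0, nc, nw)
  mav <- matrix(0, nc, nw)
  for (ch in seq_len(nc)) {
    x <- recording$samples[ch, ]
    ad <- abs(diff(x))
    cad <- c(0, cumsum(ad))       # cad[i+1] = sum(ad[1:i])
    cab <- c(0, cumsum(abs(x)))
    # window at s covers samples s..s+win-1, diffs s..s+win-2
    wfl[ch, ] <- (cad[starts + win - 1L] - cad[starts]) / win
    mav[ch, ] <- (cab[starts + win] - cab[starts]) / win
  }
  posture <- vapply(starts, function(s)
    majority_label(recording$posture_labels[s:(s + win - 1L)]), integer(1))
  stim <- vapply(starts, function(s)
    any(recording$stim_flag[s:(s + win - 1L)]), logical(1))
  feature_series(wfl = wfl, mav = mav, window_ms = window_ms,
                 step_ms = step_ms, window_start_s = (starts - 1) / fs,
                 posture = posture, stim_flag = stim)
}

#' @rdname extract_features
#' @export
compute_wfl <- function(recording, window_ms = 100, step_ms = window_ms) {
  extract_features(recording, window_ms, step_ms)
}

#' @rdname extract_features
#' @export
compute_mav <- function(recording, window_ms = 100, step_ms = window_ms) {
  extract_features(recording, window_ms, step_ms)
}

#' Raw-EMG quantization model
#'
#' The implant records raw EMG at 8-bit resolution (eight channels at a time)
#' or 16-bit resolution (four channels), with an input-referred resolution
#' that depends on the configured gain: 10-100 uV/LSB at 8 bits and
#' 0.04-0.4 uV/LSB at 16 bits.
#'
#' @param bit_depth 8 or 16.
#' @param input_referred_resolution uV per least significant bit; must fall
#'   in the legal range for the chosen bit depth.
#' @return A `quantization_model` list.
#' @export
quantization_model <- function(bit_depth = 8, input_referred_resolution = 10) {
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  rng <- if (bit_depth == 8) c(10, 100) else c(0.04, 0.4)
  if (input_referred_resolution < rng[1] || input_referred_resolution > rng[2])
    stop(sprintf("resolution for %d-bit must lie in [%g, %g] uV/LSB",
                 bit_depth, rng[1], rng[2]))
  structure(list(bit_depth = bit_depth,
                 resolution = input_referred_resolution),
            class = "quantization_model")
}

#' Quantize a recording to the implant's ADC grid
#'
#' Rounds every sample to the nearest least-significant-bit step and clips to
#' the signed representable range of the bit depth (e.g. -128..127 LSB at
#' 8 bits). Quantization error before clipping is at most half a step.
#'
#' @param recording an [emg_recording()].
#' @param model a [quantization_model()].
#' @return The quantized [emg_recording()].
#' @export
#' @examples
#' m <- quantization_model(8, 10)
#' rec <- emg_recording(matrix(c(14, 2000), 1))
#' quantize(rec, m)$samples  # 10, 1270
quantize <- function(recording, model) {
  stopifnot(inherits(recording, "emg_recording"),
            inherits(model, "quantization_model"))
  half <- 2^(model$bit_depth - 1)
  q <- round(recording$samples / model$resolution)
  q <- pmin(pmax(q, -half), half - 1)
  out <- recording
  out$samples <- q * model$resolution
  out
}

#' Stream controller features the way the implant does
#'
#' Computes WFL with 100 ms windows at a 50 ms update rate from a 1 kHz
#' recording, then quantizes the feature values to a 10-bit dynamic range
#' over a configurable full scale (default 0-200 uV).
#'
#' @param recording an [emg_recording()] sampled at 1 kHz.
#' @param full_scale_uv full scale of the 10-bit feature quantizer in uV.
#' @return A [feature_series()] whose `wfl` is 10-bit quantized; `mav` is
#'   `NULL` (the streaming path carries WFL only).
#' @export
stream_features <- function(recording, full_scale_uv = 200) {
  stopifnot(inherits(recording, "emg_recording"))
  if (recording$sampling_rate != 1000)
    stop("feature streaming is defined for 1 kHz recordings")
  fst <- extract_features(recording, window_ms = 100, step_ms = 50)
  res <- full_scale_uv / 1023
  q <- pmin(pmax(round(fst$wfl / res), 0), 1023) * res
  feature_series(wfl = q, mav = NULL, window_ms = 100, step_ms = 50,
                 window_start_s = fst$window_start_s,
                 posture = fst$posture, stim_flag = fst$stim_flag)
}

#' Write a feature series as long-format TSV
#'
#' Columns: `channel`, `window_start_s`, `wfl_uv`, `mav_uv`, `posture_id`,
#' `stim_flag`.
#'
#' @param features a [feature_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(features, path) {
  m <- if (!is.null(features$wfl)) features$wfl else features$mav
  nc <- nrow(m); nw <- ncol(m)
  df <- data.frame(
    channel = rep(seq_len(nc), times = nw),
    window_start_s = rep(features$window_start_s, each = nc),
    wfl_uv = if (!is.null(features$wfl)) as.vector(features$wfl) else NA,
    mav_uv = if (!is.null(features$mav)) as.vector(features$mav) else NA,
    posture_id = rep(features$posture, each = nc),
    stim_flag = rep(as.integer(features$stim_flag), each = nc))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
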