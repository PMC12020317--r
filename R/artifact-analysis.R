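# Spectral statistics for stimulation-artifact detection: short-time Fourier
# spectrograms, the ratio-of-frequency-power-increased (phi_f) at the
# stimulation frequency and harmonics, the ratio-of-overall-power-increased
# (phi_overall), and the five-way channel categorization.

#' Harmonics of the stimulation frequency inside the analysis band
#'
#' @param f_stim stimulation frequency in Hz.
#' @param fmin,fmax analysis band limits in Hz (the study analyzed 10-500 Hz,
#'   giving harmonics 70, 140, ..., 490 for 70 Hz stimulation).
#' @return Numeric vector of integer multiples of `f_stim` in `(fmin, fmax]`.
#' @export
#' @examples
#' stim_harmonics(70)  # 70 140 210 280 350 420 490
stim_harmonics <- function(f_stim = 70, fmin = 10, fmax = 500) {
  h <- f_stim * seq_len(floor(fmax / f_stim))
  h[h > fmin]
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' Short-time Fourier spectrogram of one EMG channel
#'
#' Power spectral density per (frequency bin, time frame), computed with
#' Hann-tapered windows of `window_s` seconds at 50% overlap. The frequency
#' resolution is `1/window_s` (2 Hz for the study's 500 ms windows), so a
#' 70 Hz stimulation tone falls exactly on a bin. The PSD is one-sided and
#' scaled so that summing over bins times the bin width recovers the signal
#' power (Parseval).
#'
#' @param recording an [emg_recording()].
#' @param window_s STFT window duration in seconds.
#' @param channel channel index to analyze.
#' @param overlap fractional window overlap.
#' @param window taper: `"hann"` or `"rect"`.
#' @return A list with `power` (bins x frames, uV^2/Hz), `freq` (Hz), and
#'   `time` (frame centers, s).
#' @export
emg_spectrogram <- function(recording, window_s = 0.5, channel = 1,
                            overlap = 0.5, window = c("hann", "rect")) {
  stopifnot(inherits(recording, "emg_recording"))
  window <- match.arg(window)
  fs <- recording$sampling_rate
  x <- recording$samples[channel, ]
  nwin <- round(window_s * fs)
  if (length(x) < nwin) stop("recording shorter than one STFT window")
  hop <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  w <- if (window == "hann") hann_window(nwin) else rep(1, nwin)
  wnorm <- sum(w^2)
  nf <- nwin %/% 2 + 1
  pow <- matrix(0, nf, length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + nwin - 1L)] * w
    X <- stats::fft(seg)[seq_len(nf)]
    p <- (Mod(X)^2) / (fs * wnorm)
    # one-sided: double everything except DC and (for even nwin) Nyquist
    dbl <- seq(2, nf - if (nwin %% 2 == 0) 1 else 0)
    p[dbl] <- 2 * p[dbl]
    pow[, j] <- p
  }
  list(power = pow, freq = (seq_len(nf) - 1) * fs / nwin,
       time = (starts - 1 + nwin / 2) / fs, window_s = window_s)
}

# pooled (frames and bins) power in a set of frequency bands
pooled_band_power <- function(spec, bands) {
  sel <- rep(FALSE, length(spec$freq))
  for (b in bands) sel <- sel | (spec$freq >= b[1] & spec$freq <= b[2])
  spec$power[sel, , drop = FALSE]
}

# excess narrowband power at f: median-over-frames power at the bin nearest f
# minus the pooled median power in the neighbor bands [f-10,f-5] and [f+5,f+10]
narrowband_excess <- function(spec, f) {
  bin <- which.min(abs(spec$freq - f))
  at_f <- stats::median(spec$power[bin, ])
  nb <- pooled_band_power(spec, list(c(f - 10, f - 5), c(f + 5, f + 10)))
  floor_level <- stats::median(nb)
  c(excess = at_f - floor_level, floor = floor_level)
}

#' Ratio of frequency power increased at the stimulation frequency
#'
#' For recordings of the same channel with and without stimulation, computes
#' the excess narrowband power at `f` (median power at the `f` bin across
#' frames minus the median power at neighboring frequencies, 5-10 Hz to
#' either side) in each condition, and returns their ratio
#' `phi_f = excess_stim / excess_nostim`. The denominator is floored at the
#' no-stimulation neighbor-band noise level so the ratio stays finite and
#' conservative; a nonpositive stimulation excess reports 0 (the "<= 1"
#' sentinel for no artifact).
#'
#' @param stim_rec,nostim_rec [emg_recording()]s of the same channel with and
#'   without stimulation.
#' @param f analyzed frequency in Hz; it and its neighbor bands must lie
#'   within 10-500 Hz.
#' @param window_s STFT window in seconds.
#' @param channel channel index.
#' @return The dimensionless ratio `phi_f`.
#' @export
phi_at_frequency <- function(stim_rec, nostim_rec, f, window_s = 0.5,
                             channel = 1) {
  if (f - 10 < 10 || f + 10 > 500)
    stop("f and its neighbor bands must lie inside 10-500 Hz")
  es <- narrowband_excess(
    emg_spectrogram(stim_rec, window_s, channel), f)
  en <- narrowband_excess(
    emg_spectrogram(nostim_rec, window_s, channel), f)
  if (es["excess"] <= 0) return(0)
  denom <- max(en["excess"], en["floor"])
  if (denom <= 0) denom <- .Machine$double.eps
  unname(es["excess"] / denom)
}

#' Ratio of overall power increased under stimulation
#'
#' Median spectrogram power across all frames and all frequency bins in
#' 10-500 Hz -- excluding bins within +/- 5 Hz of the stimulation frequency
#' and each of its harmonics -- with stimulation, divided by the same
#' quantity without stimulation. A value near 1 means stimulation added no
#' broadband power; large values flag either true broadband contamination or
#' a voluntary change in muscle tension.
#'
#' @inheritParams phi_at_frequency
#' @param f_stim stimulation frequency whose harmonics are excluded.
#' @return The dimensionless ratio `phi_overall`.
#' @export
phi_overall <- function(stim_rec, nostim_rec, f_stim = 70, window_s = 0.5,
                        channel = 1) {
  spec_s <- emg_spectrogram(stim_rec, window_s, channel)
  spec_n <- emg_spectrogram(nostim_rec, window_s, channel)
  keep <- spec_s$freq >= 10 & spec_s$freq <= 500
  for (h in stim_harmonics(f_stim)) {
    keep <- keep & !(spec_s$freq >= h - 5 & spec_s$freq <= h + 5)
  }
  num <- stats::median(spec_s$power[keep, ])
  den <- stats::median(spec_n$power[keep, ])
  if (den <= 0) stop("no-stimulation power is zero; ratio undefined")
  num / den
}

#' Categorize a channel's response to stimulation
#'
#' Assigns each channel one of five categories from its per-trial phi
#' statistics and its responsiveness classification, with the precedence:
#' unresponsive (noise-only channels), increased overall power
#' (`phi_overall >= threshold` in any trial), consistent artifact (maximum
#' `phi_f` over harmonics `>= threshold` in every trial), intermittent
#' artifact (in at least one but not all trials), else unaffected.
#'
#' @param trials a list of trials, each a list with elements `stim` and
#'   `nostim` ([emg_recording()]s of the same channel).
#' @param status the channel's responsiveness: `"responsive"` or
#'   `"noise_only"` (e.g. from [classify_noise_only()]).
#' @param f_stim stimulation frequency in Hz.
#' @param threshold the phi decision threshold (the study used 15).
#' @param window_s STFT window in seconds.
#' @param channel channel index within the recordings.
#' @return A list with `category` (one of `"unaffected"`,
#'   `"increased_overall_power"`, `"intermittent_artifact"`,
#'   `"consistent_artifact"`, `"unresponsive"`), `phi_f` (trials x harmonics
#'   matrix), and `phi_overall` (per trial).
#' @export
categorize_channel <- function(trials, status, f_stim = 70, threshold = 15,
                               window_s = 0.5, channel = 1) {
  if (length(trials) == 0) stop("need at least one trial")
  harmonics <- stim_harmonics(f_stim)
  harmonics <- harmonics[harmonics - 10 >= 10 & harmonics + 10 <= 500]
  phi_f <- t(vapply(trials, function(tr) {
    vapply(harmonics, function(h)
      phi_at_frequency(tr$stim, tr$nostim, h, window_s, channel), numeric(1))
  }, numeric(length(harmonics))))
  phi_ov <- vapply(trials, function(tr)
    phi_overall(tr$stim, tr$nostim, f_stim, window_s, channel), numeric(1))

  max_f <- apply(phi_f, 1, max)
  category <-
    if (identical(status, "noise_only")) "unresponsive"
    else if (any(phi_ov >= threshold)) "increased_overall_power"
    else if (all(max_f >= threshold)) "consistent_artifact"
    else if (any(max_f >= threshold)) "intermittent_artifact"
    else "unaffected"
  list(category = category,
       phi_f = matrix(phi_f, nrow = length(trials),
                      dimnames = list(NULL, paste0(harmonics, "Hz"))),
       phi_overall = phi_ov)
}
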