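# IIR filter design and zero-phase filtering.
#
# No DSP package ships with this toolchain, so Butterworth design is done the
# classical way: analog prototype poles, frequency prewarping, bilinear
# transform. Only lowpass/highpass sections are needed; the EMG bandpass is a
# cascade of the two (band edges 15 and 350 Hz are far apart, so the cascade
# is indistinguishable from a direct bandpass design at the stated tolerances).

# polynomial coefficients (descending powers) from roots, real part
poly_from_roots <- function(r) {
  p <- 1
  for (rk in r) p <- c(p, 0) - c(0, p * rk)
  Re(p)
}

# prototype Butterworth poles on the unit circle, left half-plane
butter_prototype <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# digital Butterworth via bilinear transform; type "low" or "high"
butter_design <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (fc <= 0 || fc >= fs / 2) stop("cutoff must lie in (0, Nyquist)")
  wc <- 2 * fs * tan(pi * fc / fs)  # prewarped analog cutoff, rad/s
  pk <- butter_prototype(n)
  if (type == "low") {
    p_analog <- wc * pk
    z_digital <- rep(-1, n)  # zeros at Nyquist
    ref <- 1                 # normalize |H| at z = 1 (DC)
  } else {
    p_analog <- wc / pk
    z_digital <- rep(1, n)   # zeros at DC
    ref <- -1                # normalize |H| at z = -1 (Nyquist)
  }
  fs2 <- 2 * fs
  p_digital <- (fs2 + p_analog) / (fs2 - p_analog)
  a <- poly_from_roots(p_digital)
  b <- poly_from_roots(z_digital)
  h <- sum(b * ref^-(seq_along(b) - 1)) / sum(a * ref^-(seq_along(a) - 1))
  list(b = b / h, a = a)
}

# causal IIR filter, zero initial state (difference equation with b, a)
apply_iir <- function(x, b, a) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution", sides = 1)
  v <- as.numeric(v)[-seq_len(nb - 1)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# forward-backward (zero-phase) filtering with odd-reflection edge padding
filtfilt_zp <- function(x, b, a, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 3L * 100L)
  if (pad > 0) {
    left <- 2 * x[1] - x[seq(pad + 1, 2)]
    right <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  y <- apply_iir(xp, b, a)
  y <- rev(apply_iir(rev(y), b, a))
  if (pad > 0) y <- y[seq(pad + 1, pad + n)]
  y
}

#' Zero-phase Butterworth bandpass filter for EMG recordings
#'
#' Applies the implant's 15-350 Hz style bandpass to every channel of a
#' recording: a 4th-order Butterworth highpass at `low` cascaded with a
#' 4th-order Butterworth lowpass at `high`, each run forward and backward so
#' the filter is zero-phase and posture labels stay aligned with the signal.
#'
#' @param recording an [emg_recording()].
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order filter order for each of the highpass and lowpass sections.
#' @return A filtered [emg_recording()] with unchanged labels and flags.
#' @export
#' @examples
#' rec <- emg_recording(matrix(sin(2 * pi * 100 * (0:999) / 1000), 1))
#' out <- bandpass(rec, 15, 350)
bandpass <- function(recording, low = 15, high = 350, order = 4) {
  stopifnot(inherits(recording, "emg_recording"))
  fs <- recording$sampling_rate
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= fs / 2) stop("high band edge must be below the Nyquist frequency")
  hp <- butter_design(order, low, fs, "high")
  lp <- butter_design(order, high, fs, "low")
  pad <- min(n_samples(recording) - 1L, as.integer(round(3 * fs / low)))
  out <- recording
  out$samples <- t(apply(recording$samples, 1, function(x) {
    filtfilt_zp(filtfilt_zp(x, hp$b, hp$a, pad), lp$b, lp$a, pad)
  }))
  out
}
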