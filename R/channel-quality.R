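# Channel-quality classification (responsive vs noise-only) and inter-channel
# crosstalk, both computed on the WFL feature series.

#' Classify EMG channels as responsive or noise-only
#'
#' A channel is noise-only when all three criteria hold: the variance of its
#' WFL series is below 0.02, it has at most three WFL peaks exceeding three
#' times the baseline noise level, and at least 90% of its MAV windows fall
#' below 17 uV. The baseline noise level per channel is the median WFL over
#' rest-labeled windows. A WFL "peak" is a local maximum above the 3x-baseline
#' line; threshold crossings closer than `merge_gap` windows apart are merged
#' and counted once, so one burst is one peak.
#'
#' @param features a [feature_series()] with both `wfl` and `mav`, covering at
#'   least one posture cycle and containing rest-labeled windows.
#' @param baseline_noise optional numeric vector of per-channel baseline noise
#'   levels in uV; when `NULL` (default) it is estimated as the median WFL of
#'   rest windows.
#' @param wfl_var_threshold,max_peaks,mav_threshold_uv,mav_frac the published
#'   criteria: 0.02, 3 peaks, 17 uV, 90%.
#' @param merge_gap peaks separated by fewer than this many windows count as
#'   one.
#' @return A data frame with one row per channel: `channel`, `status`
#'   (`"responsive"`/`"noise_only"`), `wfl_variance`, `n_wfl_peaks`,
#'   `mav_below_frac`, `baseline_noise`.
#' @export
classify_noise_only <- function(features, baseline_noise = NULL,
                                wfl_var_threshold = 0.02, max_peaks = 3,
                                mav_threshold_uv = 17, mav_frac = 0.90,
                                merge_gap = 3) {
  stopifnot(inherits(features, "feature_series"))
  if (is.null(features$wfl) || is.null(features$mav))
    stop("classification needs both WFL and MAV features")
  rest <- features$posture < 0
  if (is.null(baseline_noise)) {
    if (!any(rest)) stop("no rest-labeled windows: baseline noise undefined")
    baseline_noise <- apply(features$wfl[, rest, drop = FALSE], 1, stats::median)
  }
  nc <- nrow(features$wfl)
  out <- lapply(seq_len(nc), function(ch) {
    w <- features$wfl[ch, ]
    m <- features$mav[ch, ]
    v <- stats::var(w)
    np <- count_wfl_peaks(w, 3 * baseline_noise[ch], merge_gap)
    frac <- mean(m < mav_threshold_uv)
    noise <- (v < wfl_var_threshold) && (np <= max_peaks) && (frac >= mav_frac)
    data.frame(channel = ch,
               status = if (noise) "noise_only" else "responsive",
               wfl_variance = v, n_wfl_peaks = np, mav_below_frac = frac,
               baseline_noise = baseline_noise[ch])
  })
  do.call(rbind, out)
}

# count merged excursions of a WFL series above a threshold
count_wfl_peaks <- function(wfl, threshold, merge_gap = 3) {
  above <- which(wfl > threshold)
  if (length(above) == 0) return(0L)
  # cluster indices whose gaps are < merge_gap windows
  breaks <- c(TRUE, diff(above) >= merge_gap)
  sum(breaks)
}

#' Crosstalk matrix of an EMG feature series
#'
#' Crosstalk between channels is estimated as the zero-lag normalized cross-
#' correlation (Pearson correlation) of the two channels' WFL series across
#' the entirety of the signal. Lower values mean more independent control
#' sources.
#'
#' @param features a [feature_series()] with at least 2 channels.
#' @param session_time optional session time in weeks post-implant, carried
#'   for trend analysis.
#' @return A `crosstalk_matrix` object: list with `values` (symmetric
#'   channels x channels matrix, unit diagonal), `zero_variance` (logical
#'   per channel; such channels get correlation 0 with a warning), and
#'   `session_time`.
#' @export
crosstalk_matrix <- function(features, session_time = NA_real_) {
  stopifnot(inherits(features, "feature_series"))
  w <- features$wfl
  if (is.null(w)) stop("crosstalk is computed on the WFL series")
  if (nrow(w) < 2) stop("need at least 2 channels")
  sds <- apply(w, 1, stats::sd)
  zv <- sds == 0
  vals <- diag(nrow(w))
  ok <- which(!zv)
  if (length(ok) >= 2) {
    vals[ok, ok] <- stats::cor(t(w[ok, , drop = FALSE]))
  }
  if (any(zv)) {
    warning("zero-variance channel(s): ", paste(which(zv), collapse = ", "),
            "; crosstalk entries set to 0")
  }
  diag(vals) <- 1
  structure(list(values = vals, zero_variance = zv,
                 session_time = session_time),
            class = "crosstalk_matrix")
}

#' Trend of mean channel crosstalk across sessions
#'
#' Regresses the mean off-diagonal cross-correlation per session on session
#' time and tests the linear model against a constant (intercept-only) model
#' with an F-test, as used to assess the chronic stability of the sensing
#' modules.
#'
#' @param matrices a list of [crosstalk_matrix()] objects (>= 3 sessions),
#'   each with a `session_time` in weeks.
#' @return A [linear_trend_test()] result, plus element `mean_crosstalk`
#'   (per-session means, named by week).
#' @export
crosstalk_trend <- function(matrices) {
  if (length(matrices) < 3) stop("need at least 3 sessions for a trend")
  means <- vapply(matrices, function(m) {
    v <- m$values
    mean(v[upper.tri(v)])
  }, numeric(1))
  weeks <- vapply(matrices, function(m) m$session_time, numeric(1))
  if (anyNA(weeks)) stop("all matrices need a session_time")
  res <- linear_trend_test(weeks, means)
  res$mean_crosstalk <- stats::setNames(means, weeks)
  res
}
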