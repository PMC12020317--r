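#' Multichannel intramuscular EMG recording
#'
#' Container for a multichannel EMG time series in microvolts with per-sample
#' posture labels and a stimulation on/off flag, the unit of data every other
#' analysis in the package consumes. Channels are rows of `samples`.
#'
#' @param samples numeric matrix, channels x samples, in uV.
#' @param sampling_rate sampling rate in Hz (default 1000, the implant's rate).
#' @param posture_labels integer vector, one label per sample; `-1` marks rest.
#'   Defaults to all rest.
#' @param stim_flag logical vector, one per sample, `TRUE` while nerve
#'   stimulation is active. Defaults to all `FALSE`.
#'
#' @return An object of class `emg_recording`: a list with elements `samples`,
#'   `sampling_rate`, `posture_labels`, `stim_flag`.
#' @export
#' @examples
#' rec <- emg_recording(matrix(rnorm(2000), nrow = 2), sampling_rate = 1000)
#' rec
emg_recording <- function(samples, sampling_rate = 1000,
                          posture_labels = NULL, stim_flag = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  n <- ncol(samples)
  if (is.null(posture_labels)) posture_labels <- rep(-1L, n)
  if (is.null(stim_flag)) stim_flag <- rep(FALSE, n)
  if (length(posture_labels) != n)
    stop("posture_labels must have one entry per sample")
  if (length(stim_flag) != n)
    stop("stim_flag must have one entry per sample")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0)
    stop("sampling_rate must be a positive scalar (Hz)")
  structure(
    list(samples = samples,
         sampling_rate = as.numeric(sampling_rate),
         posture_labels = as.integer(posture_labels),
         stim_flag = as.logical(stim_flag)),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  dur <- ncol(x$samples) / x$sampling_rate
  cat(sprintf("<emg_recording> %d channel(s), %.2f s at %g Hz\n",
              nrow(x$samples), dur, x$sampling_rate))
  postures <- unique(x$posture_labels[x$posture_labels >= 0])
  cat(sprintf("  postures: %d distinct, stim on for %.1f%% of samples\n",
              length(postures), 100 * mean(x$stim_flag)))
  invisible(x)
}

#' @export
`[.emg_recording` <- function(x, channels, ...) {
  emg_recording(x$samples[channels, , drop = FALSE], x$sampling_rate,
                x$posture_labels, x$stim_flag)
}

n_channels <- function(rec) nrow(rec$samples)
n_samples <- function(rec) ncol(rec$samples)

#' Write / read an EMG recording as TSV with a JSON header line
#'
#' Plain-text serialization of an [emg_recording()]: the first line is a `#`
#' comment holding a JSON object with `sampling_rate_hz`; subsequent lines are
#' tab-separated columns `posture_id`, `stim_flag`, then one column per
#' channel in uV.
#'
#' @param rec an `emg_recording`.
#' @param path file path.
#' @return `write_recording_tsv` returns `path` invisibly;
#'   `read_recording_tsv` returns an `emg_recording`.
#' @export
write_recording_tsv <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  hdr <- sprintf("#%s", jsonlite::toJSON(
    list(sampling_rate_hz = rec$sampling_rate), auto_unbox = TRUE))
  df <- data.frame(posture_id = rec$posture_labels,
                   stim_flag = as.integer(rec$stim_flag),
                   t(rec$samples))
  names(df) <- c("posture_id", "stim_flag",
                 paste0("ch", seq_len(n_channels(rec))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- jsonlite::fromJSON(sub("^#", "", hdr))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1)
  emg_recording(t(as.matrix(df[, -(1:2), drop = FALSE])),
                sampling_rate = meta$sampling_rate_hz,
                posture_labels = df$posture_id,
                stim_flag = as.logical(df$stim_flag))
}
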