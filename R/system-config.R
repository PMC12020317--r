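#' Implanted system architecture and its derived channel counts
#'
#' Data model of the implanted device layout: stimulation modules each
#' driving 16-channel nerve-cuff electrodes, and sensing modules whose 16
#' channels are configured as bipolar intramuscular recording pairs. The
#' constructor derives the counts the rest of the package assumes.
#'
#' @param n_stim_modules number of stimulation modules.
#' @param cuffs_per_stim_module nerve cuffs connected to each.
#' @param channels_per_cuff stimulating contacts per cuff.
#' @param n_sense_modules number of sensing modules.
#' @param channels_per_sense_module electrode channels per sensing module;
#'   configured as bipolar pairs, so must be even.
#' @param tims_per_sense_module intramuscular electrode arrays per sensing
#'   module.
#' @param f_stim stimulation frequency used for artifact analysis, Hz.
#' @return A `system_config` list with derived fields
#'   `bipolar_pairs_per_sense_module`, `total_stim_channels`, `n_tims`,
#'   `total_bipolar_channels`, and `highest_harmonic_hz` (largest analyzed
#'   harmonic of `f_stim` within 10-500 Hz).
#' @export
#' @examples
#' cfg <- system_config()
#' cfg$total_stim_channels    # 64
#' cfg$highest_harmonic_hz    # 490
system_config <- function(n_stim_modules = 2, cuffs_per_stim_module = 2,
                          channels_per_cuff = 16, n_sense_modules = 2,
                          channels_per_sense_module = 16,
                          tims_per_sense_module = 2, f_stim = 70) {
  if (channels_per_sense_module %% 2 != 0)
    stop("sense channels are configured as bipolar pairs; count must be even")
  structure(list(
    n_stim_modules = n_stim_modules,
    cuffs_per_stim_module = cuffs_per_stim_module,
    channels_per_cuff = channels_per_cuff,
    n_sense_modules = n_sense_modules,
    channels_per_sense_module = channels_per_sense_module,
    tims_per_sense_module = tims_per_sense_module,
    f_stim = f_stim,
    bipolar_pairs_per_sense_module = channels_per_sense_module / 2,
    total_stim_channels =
      n_stim_modules * cuffs_per_stim_module * channels_per_cuff,
    n_tims = n_sense_modules * tims_per_sense_module,
    total_bipolar_channels = n_sense_modules * channels_per_sense_module / 2,
    highest_harmonic_hz = max(stim_harmonics(f_stim))),
    class = "system_config")
}
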