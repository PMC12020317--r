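# Psychophysics and electrode-health analytics: charge arithmetic, the
# Shannon charge-safety limit, the two-phase threshold search, tissue
# resistance estimation, and percept location/quality stability metrics.

#' Biphasic stimulation pulse
#'
#' Charge-balanced, cathode-first biphasic rectangular pulse with an anodic
#' phase twice the width (and half the amplitude) of the cathodic phase.
#' Charge per phase is `amplitude * cathodic_width`.
#'
#' @param amplitude cathodic amplitude in mA.
#' @param cathodic_width cathodic phase width in us.
#' @param frequency pulse train frequency in Hz.
#' @return A `stim_pulse` list with the derived `anodic_width` (us),
#'   `anodic_amplitude` (mA), and `charge_per_phase` (nC).
#' @export
#' @examples
#' stim_pulse(0.3, 250)$charge_per_phase  # 75 nC
stim_pulse <- function(amplitude, cathodic_width, frequency = 100) {
  stopifnot(amplitude >= 0, cathodic_width >= 0, frequency > 0)
  structure(list(amplitude = amplitude, cathodic_width = cathodic_width,
                 anodic_width = 2 * cathodic_width,
                 anodic_amplitude = amplitude / 2,
                 frequency = frequency,
                 charge_per_phase = charge_per_phase(amplitude, cathodic_width)),
            class = "stim_pulse")
}

#' Charge per phase of a stimulation pulse
#'
#' Q = I * t: 1 mA times 1 us is 1 nC.
#'
#' @param amplitude_ma cathodic current in mA.
#' @param width_us cathodic phase width in us.
#' @return Charge per phase in nC.
#' @export
#' @examples
#' charge_per_phase(0.3, 250)  # 75
charge_per_phase <- function(amplitude_ma, width_us) {
  stopifnot(all(amplitude_ma >= 0), all(width_us >= 0))
  amplitude_ma * width_us
}

#' Shannon charge-safety limit
#'
#' Solves the Shannon criterion `log10(Q/A) = k - log10(Q)` (Q in uC, A in
#' cm^2) for the maximum safe charge per phase: `Q = 10^((k + log10(A)) / 2)`.
#' For the study's 0.5 mm^2 nerve-cuff contacts and k = 1.1 this gives the
#' 250 nC safety limit used throughout.
#'
#' @param k Shannon coefficient (dimensionless).
#' @param contact_area_cm2 geometric contact area in cm^2.
#' @return The charge limit in nC.
#' @export
#' @examples
#' shannon_limit(1.1, 0.005)  # ~250 nC
shannon_limit <- function(k = 1.1, contact_area_cm2 = 0.005) {
  if (contact_area_cm2 <= 0) stop("contact area must be positive")
  q_uc <- 10^((k + log10(contact_area_cm2)) / 2)
  1000 * q_uc
}

#' Measure a perceptual detection threshold
#'
#' The study's two-phase protocol. Phase 1: stimulate at 100 Hz with a fixed
#' 250 us cathodic width, ramping amplitude from zero in 0.01 mA steps until
#' the observer reports a sensation or the next step would exceed the charge
#' safety limit (in which case the measurement is censored). Phase 2: hold
#' that amplitude and binary-search the cathodic width on 10-250 us until
#' the bracket is within 10 us, returning the smallest detected width.
#'
#' @param observer a detection observer, e.g. from [make_observer()]: a
#'   function of charge in nC returning `TRUE`/`FALSE`.
#' @param safety_limit_nc charge safety limit in nC; the study set 250 nC
#'   from the Shannon limit of its 0.5 mm^2 contacts (see [shannon_limit()]).
#' @param amplitude_step phase-1 amplitude increment in mA.
#' @param start_width_us phase-1 (and binary-search upper) width in us.
#' @param min_width_us binary-search lower width bound in us.
#' @param width_resolution_us binary-search stopping bracket in us.
#' @return A `threshold_measurement` list: `amplitude` (mA), `pulse_width`
#'   (us), `threshold_charge` (nC), `censored`. When censored, amplitude and
#'   width are `NA`.
#' @export
#' @examples
#' obs <- make_observer(100, slope = Inf)
#' measure_threshold(obs)$threshold_charge
measure_threshold <- function(observer, safety_limit_nc = 250,
                              amplitude_step = 0.01, start_width_us = 250,
                              min_width_us = 10, width_resolution_us = 10) {
  # phase 1: amplitude ramp at fixed width
  amp <- 0
  detected <- FALSE
  repeat {
    amp_next <- amp + amplitude_step
    if (charge_per_phase(amp_next, start_width_us) > safety_limit_nc) break
    amp <- amp_next
    if (observer(charge_per_phase(amp, start_width_us))) {
      detected <- TRUE
      break
    }
  }
  if (!detected) {
    return(structure(list(amplitude = NA_real_, pulse_width = NA_real_,
                          threshold_charge = NA_real_, censored = TRUE),
                     class = "threshold_measurement"))
  }
  # phase 2: binary search on cathodic width at the detected amplitude
  lo <- min_width_us
  hi <- start_width_us
  while (hi - lo > width_resolution_us) {
    mid <- (lo + hi) / 2
    if (observer(charge_per_phase(amp, mid))) hi <- mid else lo <- mid
  }
  width <- if (observer(charge_per_phase(amp, lo))) lo else hi
  structure(list(amplitude = amp, pulse_width = width,
                 threshold_charge = charge_per_phase(amp, width),
                 censored = FALSE),
            class = "threshold_measurement")
}

#' Estimate tissue resistance from probe-pulse voltages
#'
#' Ohm's law per trial (`R = V / I`) with the study's sub-threshold probe
#' (1000 Hz, 70 us, 0.2 mA), averaged across eight trials. A contact with any
#' single trial exceeding 15 kOhm is flagged for exclusion, since such values
#' indicate a loose connector rather than a true tissue change.
#'
#' @param trial_voltages measured voltages in V, one per trial.
#' @param probe the probe pulse, a [stim_pulse()].
#' @param exclusion_kohm single-trial exclusion threshold in kOhm.
#' @return A `resistance_measurement` list: `resistance` (kOhm, mean over
#'   trials), `trial_resistances`, `n_trials`, `excluded`.
#' @export
#' @examples
#' estimate_resistance(rep(0.8, 8))$resistance  # 4 kOhm
estimate_resistance <- function(trial_voltages,
                                probe = stim_pulse(0.2, 70, frequency = 1000),
                                exclusion_kohm = 15) {
  if (probe$amplitude <= 0) stop("probe current must be positive")
  r <- trial_voltages / probe$amplitude  # V / mA = kOhm
  structure(list(resistance = mean(r), trial_resistances = r,
                 n_trials = length(r),
                 excluded = any(r > exclusion_kohm)),
            class = "resistance_measurement")
}

#' Jaccard similarity of two binary masks
#'
#' Intersection over union of the selected pixels. Two empty masks have no
#' defined overlap; the coefficient is reported as 0 with a warning.
#'
#' @param mask_a,mask_b logical matrices of identical dimensions.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
#' jaccard(a, a)  # 1
jaccard <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b)))
    stop("masks must have identical dimensions")
  u <- sum(mask_a | mask_b)
  if (u == 0) {
    warning("both masks are empty; Jaccard similarity undefined, returning 0")
    return(0)
  }
  sum(mask_a & mask_b) / u
}

#' One percept report: location, quality, and derived categories
#'
#' @param contact contact identifier.
#' @param session_time session time in weeks post-implant (or session index).
#' @param location_mask logical matrix of drawn pixels on the limb template.
#' @param descriptors character vector of self-chosen quality descriptors.
#' @param category_map descriptor-to-category table (see
#'   [default_descriptor_map()]).
#' @return A `percept_report` list with derived `categories` and
#'   `proprioception_only`.
#' @export
percept_report <- function(contact, session_time, location_mask,
                           descriptors = character(),
                           category_map = default_descriptor_map()) {
  categories <- categorize_descriptors(descriptors, category_map)
  structure(list(contact = contact, session_time = session_time,
                 location_mask = location_mask, descriptors = descriptors,
                 categories = categories,
                 proprioception_only = identical(categories, "proprioceptive")),
            class = "percept_report")
}

#' Default descriptor-to-category map
#'
#' The editable lexicon shipped with the package (a TSV under `extdata`),
#' mapping each quality descriptor to tactile, proprioceptive, or pain.
#'
#' @return A data frame with columns `descriptor` and `category`.
#' @export
default_descriptor_map <- function() {
  path <- system.file("extdata", "descriptor_categories.tsv",
                      package = "prosthesim")
  if (path == "") path <- file.path("inst", "extdata",
                                    "descriptor_categories.tsv")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Categorize quality descriptors
#'
#' Maps each reported descriptor to its category (tactile, proprioceptive,
#' pain) and returns the union; reports may carry several categories. Unknown
#' descriptors default to tactile with a warning.
#'
#' @param descriptors character vector of reported descriptors.
#' @param category_map data frame with columns `descriptor`, `category`.
#' @return Character vector of categories (sorted, unique); empty input gives
#'   an empty set.
#' @export
#' @examples
#' categorize_descriptors(c("vibration", "pressure"))  # "tactile"
categorize_descriptors <- function(descriptors,
                                   category_map = default_descriptor_map()) {
  if (length(descriptors) == 0) return(character())
  idx <- match(tolower(descriptors), category_map$descriptor)
  if (anyNA(idx)) {
    warning("unknown descriptor(s) defaulted to tactile: ",
            paste(descriptors[is.na(idx)], collapse = ", "))
  }
  cats <- ifelse(is.na(idx), "tactile", category_map$category[idx])
  sort(unique(cats))
}

#' Percept location stability for one contact
#'
#' Mean Jaccard similarity over all unordered pairs of sessions' location
#' drawings, excluding proprioception-only reports (whose locations the study
#' did not analyze).
#'
#' @param reports list of [percept_report()]s for one contact.
#' @return Mean pairwise Jaccard similarity, or `NA` if fewer than two usable
#'   sessions remain.
#' @export
location_stability <- function(reports) {
  usable <- Filter(function(r) !r$proprioception_only, reports)
  n <- length(usable)
  if (n < 2) return(NA_real_)
  sims <- utils::combn(n, 2, function(ij)
    jaccard(usable[[ij[1]]]$location_mask, usable[[ij[2]]]$location_mask))
  mean(sims)
}

#' Fraction of contacts evoking percepts on the hand
#'
#' A contact counts as "on the hand" when its mask has at least one pixel
#' distal to the template's wrist line. Proprioception-only contacts are
#' excluded from the denominator.
#'
#' @param reports list of [percept_report()]s, one per contact.
#' @param template a [limb_template()].
#' @return Proportion in `[0, 1]` (`NaN` when no usable contacts).
#' @export
hand_fraction <- function(reports, template) {
  usable <- Filter(function(r) !r$proprioception_only, reports)
  if (length(usable) == 0) return(NaN)
  distal_rows <- seq_len(template$wrist_row - 1)
  on_hand <- vapply(usable, function(r)
    any(r$location_mask[distal_rows, , drop = FALSE]), logical(1))
  mean(on_hand)
}

#' Write / read a binary percept mask as plain-text PBM (P1)
#'
#' @param mask logical matrix.
#' @param path file path.
#' @return `write_mask_pbm` returns `path` invisibly; `read_mask_pbm` returns
#'   a logical matrix.
#' @export
write_mask_pbm <- function(mask, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P1", paste(ncol(mask), nrow(mask))), con)
  apply(mask, 1, function(row)
    writeLines(paste(as.integer(row), collapse = " "), con))
  invisible(path)
}

#' @rdname write_mask_pbm
#' @export
read_mask_pbm <- function(path) {
  lines <- readLines(path)
  stopifnot(lines[1] == "P1")
  dims <- as.integer(strsplit(lines[2], " ")[[1]])
  vals <- as.integer(unlist(strsplit(paste(lines[-(1:2)], collapse = " "),
                                     "\\s+")))
  vals <- vals[!is.na(vals)]
  matrix(as.logical(vals), nrow = dims[2], ncol = dims[1], byrow = TRUE)
}
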