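# Charge arithmetic, Shannon limit, threshold search, resistance, Jaccard
# stability, and descriptor categorization.

test_that("charge per phase is amplitude times cathodic width", {
  expect_equal(charge_per_phase(0.3, 250), 75)
  expect_equal(charge_per_phase(0, 1000), 0)
  expect_equal(charge_per_phase(1.0, 250), 250)
  p <- stim_pulse(0.3, 250)
  expect_equal(p$charge_per_phase, 75)
  expect_equal(p$anodic_width, 500)        # anodic phase twice the width
  expect_equal(p$anodic_amplitude, 0.15)   # and half the amplitude
})

test_that("the Shannon limit reproduces its closed form and the 250 nC bound", {
  expect_equal(signif(shannon_limit(1.1, 0.005), 2), 250)
  expect_equal(shannon_limit(0, 1), 1000)  # Q = 1 uC
  expect_equal(shannon_limit(1.1, 0.02),
               1000 * 10^((1.1 + log10(0.02)) / 2), tolerance = 1e-12)
  # strictly increasing in k and in area
  ks <- seq(0, 2, by = 0.25)
  expect_true(all(diff(vapply(ks, shannon_limit, numeric(1),
                              contact_area_cm2 = 0.005)) > 0))
  as_ <- seq(0.001, 0.05, by = 0.005)
  expect_true(all(diff(vapply(as_, function(a)
    shannon_limit(1.1, a), numeric(1))) > 0))
  expect_error(shannon_limit(1.1, 0), "positive")
})

test_that("threshold search recovers a deterministic latent threshold within the grid", {
  obs <- make_observer(50, slope = Inf)
  m <- measure_threshold(obs)
  expect_false(m$censored)
  expect_gte(m$threshold_charge, 50)
  expect_lte(m$threshold_charge, 50 + 0.01 * 250 + m$amplitude * 10)
  # hyper-sensitive observer bottoms out at the search grid floor
  all_yes <- make_observer(1e-9, slope = Inf)
  m2 <- measure_threshold(all_yes)
  expect_equal(m2$amplitude, 0.01)
  expect_equal(m2$pulse_width, 10)
  expect_equal(m2$threshold_charge, 0.1)
  # observer that never detects below the limit is censored
  m3 <- measure_threshold(make_observer(1e6, slope = Inf))
  expect_true(m3$censored)
  expect_true(is.na(m3$threshold_charge))
})

test_that("non-censored thresholds never exceed the safety limit (property)", {
  set.seed(55)
  for (i in 1:200) {
    latent <- runif(1, 20, 240)
    m <- measure_threshold(make_observer(latent, slope = Inf))
    expect_false(m$censored)
    expect_gte(m$threshold_charge, latent)
    expect_lte(m$threshold_charge, 250)
    expect_lte(m$threshold_charge, latent + 0.01 * 250 + m$amplitude * 10)
  }
})

test_that("resistance estimation follows Ohm's law with the 15 kOhm exclusion", {
  r <- estimate_resistance(rep(0.8, 8))
  expect_equal(r$resistance, 4.0)
  expect_equal(r$n_trials, 8)
  expect_false(r$excluded)
  # one loose-connector trial triggers exclusion
  r2 <- estimate_resistance(c(16 * 0.2, rep(4 * 0.2, 7)))
  expect_true(r2$excluded)
  expect_error(estimate_resistance(rep(0.8, 8),
                                   probe = stim_pulse(0, 70)), "positive")
})

test_that("Jaccard similarity matches pixel counting", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  expect_equal(jaccard(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[11:20, 11:20] <- TRUE
  expect_equal(jaccard(a, b), 0)
  # |A| = |B| = 100, overlap 50 -> 50/150
  c_ <- matrix(FALSE, 20, 20); c_[6:15, 1:10] <- TRUE
  expect_equal(jaccard(a, c_), 50 / 150)
  expect_equal(jaccard(a, c_), jaccard(c_, a))
  expect_error(jaccard(a, matrix(FALSE, 10, 10)), "dimensions")
  expect_warning(j0 <- jaccard(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5)),
                 "empty")
  expect_equal(j0, 0)
})

test_that("location stability is the mean pairwise Jaccard over usable sessions", {
  tpl <- limb_template(64, 64, 32)
  mk <- function(rows) {
    m <- matrix(FALSE, 64, 64); m[rows, 1:10] <- TRUE
    percept_report(1, 1, m, "vibration")
  }
  # three identical masks
  expect_equal(location_stability(list(mk(1:6), mk(1:6), mk(1:6))), 1)
  # pairwise disjoint
  expect_equal(location_stability(list(mk(1:6), mk(11:16), mk(21:26))), 0)
  # pairwise J = {1, 0.5, 0.5} -> mean 2/3
  reports <- list(mk(1:6), mk(1:6), mk(3:8))
  expect_equal(location_stability(reports), 2 / 3, tolerance = 1e-12)
  # invariance to session ordering
  expect_equal(location_stability(reports[c(3, 1, 2)]),
               location_stability(reports))
  # proprioception-only reports are excluded
  prop <- percept_report(1, 4, mk(1:6)$location_mask, "contraction")
  expect_equal(location_stability(c(reports, list(prop))),
               location_stability(reports))
  expect_true(is.na(location_stability(list(mk(1:6)))))
})

test_that("hand fraction counts contacts with any pixel distal to the wrist", {
  tpl <- limb_template(64, 64, 32)
  mk <- function(rows, desc = "pressure") {
    m <- matrix(FALSE, 64, 64); m[rows, 5:10] <- TRUE
    percept_report(1, 1, m, desc)
  }
  distal <- mk(10:15)    # above the wrist line
  proximal <- mk(40:45)  # below
  straddle <- mk(30:35)  # one pixel distal is enough
  expect_equal(hand_fraction(list(distal, distal), tpl), 1)
  expect_equal(hand_fraction(list(proximal, proximal), tpl), 0)
  reports <- c(list(distal, straddle, distal),
               replicate(12, proximal, simplify = FALSE))
  expect_equal(hand_fraction(reports, tpl), 3 / 15)
  # proprioception-only contacts leave the denominator
  reports2 <- c(reports, list(mk(10:15, "contraction")))
  expect_equal(hand_fraction(reports2, tpl), 3 / 15)
})

test_that("descriptor categorization maps the lexicon and defaults unknowns", {
  expect_equal(categorize_descriptors(c("vibration", "pressure")), "tactile")
  expect_equal(categorize_descriptors("contraction"), "proprioceptive")
  expect_equal(categorize_descriptors(character()), character())
  expect_equal(categorize_descriptors(c("sharp", "vibration")),
               c("pain", "tactile"))
  expect_warning(cats <- categorize_descriptors("weird_term"), "unknown")
  expect_equal(cats, "tactile")
  # the proprioception-only flag needs every category to be proprioceptive
  m <- matrix(TRUE, 4, 4)
  expect_true(percept_report(1, 1, m, c("contraction", "movement"))$proprioception_only)
  expect_false(percept_report(1, 1, m, c("contraction", "vibration"))$proprioception_only)
})

test_that("percept masks round-trip through plain-text PBM", {
  m <- matrix(FALSE, 12, 9); m[3:7, 2:5] <- TRUE
  p <- withr::local_tempfile(fileext = ".pbm")
  write_mask_pbm(m, p)
  expect_identical(read_mask_pbm(p), m)
})
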