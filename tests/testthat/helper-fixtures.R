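# Shared fixtures: analytic lane signals and cheap classified cohorts.

# A lane made of explicit Gaussian components on a uniform grid; no baseline
# unless requested. Used to compare the detector against closed forms.
gaussian_lane <- function(centers, amps, sigma = 0.01, n = 2001,
                          baseline = 0, lane_id = "fixture") {
  x <- seq(0, 1, length.out = n)
  y <- rep(baseline, n)
  for (i in seq_along(centers)) {
    y <- y + amps[i] * exp(-(x - centers[i])^2 / (2 * sigma^2))
  }
  data.frame(lane_id = lane_id, lane_kind = "sample", position = x,
             intensity = pmax(y, 0), stringsAsFactors = FALSE)
}

# Brute-force peak oracle: every strict local maximum of the raw signal whose
# height clears the prominence fraction of the signal maximum.
brute_force_peaks <- function(lane, min_height_frac = 0.05) {
  y <- lane$intensity
  n <- length(y)
  i <- which(y[-c(1, n)] > y[-c(n - 1, n)] & y[-c(1, n)] > y[-c(1, 2)]) + 1L
  i <- i[y[i] >= min_height_frac * max(y)]
  lane$position[i]
}

# Classified cohort without gel rendering: template-rule classes.
classified_cohort <- function(params) {
  rec <- simulate_cohort(params, render = FALSE)$records
  rec$profile_class <- template_profile_class(rec$hepatic_weight)
  rec
}

# Region map matching the canonical reference geometry (a = 0.20, b = 0.64).
fixture_regions <- function() {
  refs <- simulate_reference_lanes(cohort_sim_params(), noise = FALSE)
  calibrate_regions(detect_bands(refs$acidic), detect_bands(refs$basic))
}

# Manufactured band set with given basic indices / regions, for classifier
# rule tests (intensity descending in the order given).
band_fixture <- function(basic_index, region = rep("basic", length(basic_index)),
                         intensity = rev(seq_along(basic_index))) {
  pos <- ifelse(region == "basic", 0.64 + 0.05 * ifelse(is.na(basic_index), 7, basic_index),
                ifelse(region == "neutral", 0.4, 0.1))
  data.frame(lane_id = "fx", position = pos, left = pos - 0.02,
             right = pos + 0.02, intensity = intensity, height = intensity,
             region = region, basic_index = as.integer(basic_index),
             stringsAsFactors = FALSE)
}
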