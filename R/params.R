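#' Simulation parameters for a synthetic neonatal cohort
#'
#' Bundles the generative settings for [simulate_cohort()]: stratum sizes, the
#' logistic maturation curve linking developmental age to the hepatic share of
#' circulating EPO, age-sampling ranges, and gel-rendering noise settings.
#'
#' The hepatic fraction follows `h(x) = 1 / (1 + exp(k * (x - m)))`, a strictly
#' decreasing logistic in developmental age `x` (weeks), with midpoint
#' `logistic_midpoint` and slope `logistic_slope`. Each simulated subject gets
#' an independent maturation-tempo jitter (s.d. `maturation_jitter_sd`, weeks)
#' added to its developmental age *inside* `h()` only, so that profile classes
#' vary smoothly around the midpoint while remaining independent of
#' chronological age given developmental age.
#'
#' @param n_per_group integer vector of length 4: subjects per developmental-age
#'   stratum (at or below 37, 37-41, 41-49, over 49 weeks). Default
#'   `c(34, 27, 16, 12)`, the stratum sizes of the study cohort.
#' @param logistic_midpoint midpoint `m` of the maturation logistic, weeks.
#' @param logistic_slope slope `k` of the maturation logistic, per week; > 0.
#' @param maturation_jitter_sd s.d. (weeks) of the subject-level maturation
#'   jitter; 0 gives a fully deterministic hepatic fraction.
#' @param ca_range_days closed interval of admissible chronological ages, days.
#' @param ga_range_weeks closed interval of admissible gestational ages, weeks.
#' @param da_range_weeks closed interval of developmental ages covered by the
#'   cohort, weeks.
#' @param lane_noise_sd s.d. of additive Gaussian intensity noise on rendered
#'   lanes, in units of the lane maximum (lanes are rescaled to max 1).
#' @param band_sigma Gaussian band width (s.d.) in normalised lane coordinates.
#' @param lane_points number of sampling points per rendered lane.
#' @param oxygen_driven logical; if `TRUE` the generator switches to the
#'   alternative model in which the hepatic fraction is a logistic of
#'   *chronological* age (midpoint `oxygen_midpoint_weeks`), used to study the
#'   power of [test_oxygen_decoupling()].
#' @param oxygen_midpoint_weeks postnatal midpoint (weeks) of the
#'   oxygen-driven alternative; the default 3 weeks, with slope
#'   `oxygen_slope`, makes the postnatal shutdown essentially complete by the
#'   sixth week after birth.
#' @param oxygen_slope slope (per week) of the oxygen-driven alternative.
#' @param seed master seed; every draw in [simulate_cohort()] is a pure
#'   function of the parameters including this seed.
#'
#' @return an object of class `cohort_sim_params` (a validated list).
#' @seealso [simulate_cohort()], [hepatic_fraction()], [render_lane()]
#' @export
#' @examples
#' p <- cohort_sim_params(n_per_group = c(5, 5, 5, 5), seed = 7)
#' hepatic_fraction(43, p)  # 0.5 at the midpoint
cohort_sim_params <- function(n_per_group = c(34L, 27L, 16L, 12L),
                              logistic_midpoint = 43,
                              logistic_slope = 0.5,
                              maturation_jitter_sd = 2,
                              ca_range_days = c(1, 335),
                              ga_range_weeks = c(24, 42),
                              da_range_weeks = c(29, 56),
                              lane_noise_sd = 0.015,
                              band_sigma = 0.012,
                              lane_points = 600L,
                              oxygen_driven = FALSE,
                              oxygen_midpoint_weeks = 3,
                              oxygen_slope = 1.5,
                              seed = 1L) {
  if (length(n_per_group) != 4L || any(!is.finite(n_per_group)) ||
      any(n_per_group < 0) || any(n_per_group != round(n_per_group))) {
    stop("n_per_group must be 4 non-negative integers", call. = FALSE)
  }
  if (!is.finite(logistic_slope) || logistic_slope <= 0) {
    stop("logistic_slope must be > 0", call. = FALSE)
  }
  if (!is.finite(band_sigma) || band_sigma <= 0) {
    stop("band_sigma must be > 0", call. = FALSE)
  }
  if (maturation_jitter_sd < 0) stop("maturation_jitter_sd must be >= 0", call. = FALSE)
  if (lane_noise_sd < 0) stop("lane_noise_sd must be >= 0", call. = FALSE)
  check_range <- function(r, what) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      stop(sprintf("%s must be a non-empty interval", what), call. = FALSE)
    }
  }
  check_range(ca_range_days, "ca_range_days")
  check_range(ga_range_weeks, "ga_range_weeks")
  check_range(da_range_weeks, "da_range_weeks")
  structure(list(
    n_per_group = as.integer(n_per_group),
    logistic_midpoint = logistic_midpoint,
    logistic_slope = logistic_slope,
    maturation_jitter_sd = maturation_jitter_sd,
    ca_range_days = as.numeric(ca_range_days),
    ga_range_weeks = as.numeric(ga_range_weeks),
    da_range_weeks = as.numeric(da_range_weeks),
    lane_noise_sd = lane_noise_sd,
    band_sigma = band_sigma,
    lane_points = as.integer(lane_points),
    oxygen_driven = isTRUE(oxygen_driven),
    oxygen_midpoint_weeks = oxygen_midpoint_weeks,
    oxygen_slope = oxygen_slope,
    seed = as.integer(seed)
  ), class = "cohort_sim_params")
}

#' Simulation parameters for a synthetic liver-organoid time course
#'
#' Settings for [simulate_organoid_counts()]: the day grid and oxygen
#' conditions of the differentiation protocol, the EPO competence window, the
#' hypoxia-target induction gain, and the negative-binomial noise model.
#'
#' Per gene `g` and sample `s`, counts are drawn as
#' `NB(mean = L_s * mu_g(day, condition), size = 1/dispersion)` where `L_s` is
#' a per-sample library-size factor drawn uniformly from
#' `library_size_range`. The EPO mean under hypoxia is
#' `base * (1 + (gain - 1) * c(day))` with competence window
#' `c(day) = max(0, (w(day) - w(19)) / (1 - w(19)))`,
#' `w(day) = exp(-(day - p)^2 / (2 wdt^2))`; the rescaling pins `c(19)` to 0 so
#' the window is closed at the end of differentiation. Under normoxia the EPO
#' mean stays at `base` at every day. Hypoxia-target genes are multiplied by
#' `hif_target_gain` under hypoxia at every day; maturation and population
#' markers rise along a monotone logistic in day; background genes are flat.
#'
#' @param timepoints strictly increasing day grid, within `[0, 21]`.
#' @param conditions character vector of oxygen conditions.
#' @param n_replicates biological replicates per (day, condition); >= 2.
#' @param epo_peak_day day `p` at which the EPO competence window peaks.
#' @param epo_window_width Gaussian width `wdt` (days) of the window.
#' @param epo_hypoxia_gain peak fold induction `gain` of EPO under hypoxia
#'   (> 1).
#' @param hif_target_gain fold induction of hypoxia-target genes under
#'   hypoxia, applied at every day.
#' @param dispersion negative-binomial dispersion (1/size); > 0.
#' @param library_size_range interval of per-sample library-size factors.
#' @param gene_catalog data frame describing the gene roles and mean
#'   parameters; see [default_marker_catalog()].
#' @param seed master seed.
#'
#' @return an object of class `organoid_sim_params`.
#' @seealso [simulate_organoid_counts()], [default_marker_catalog()]
#' @export
organoid_sim_params <- function(timepoints = c(0, 2, 4, 7, 9, 11, 13, 15, 17, 19),
                                conditions = c("normoxia", "hypoxia"),
                                n_replicates = 3L,
                                epo_peak_day = 12,
                                epo_window_width = 3,
                                epo_hypoxia_gain = 20,
                                hif_target_gain = 4,
                                dispersion = 0.01,
                                library_size_range = c(0.8, 1.2),
                                gene_catalog = default_marker_catalog(),
                                seed = 1L) {
  if (any(diff(timepoints) <= 0) || any(timepoints < 0) || any(timepoints > 21)) {
    stop("timepoints must be strictly increasing and within [0, 21]", call. = FALSE)
  }
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  if (epo_hypoxia_gain <= 1) stop("epo_hypoxia_gain must be > 1", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (length(library_size_range) != 2L || library_size_range[1] <= 0 ||
      library_size_range[1] > library_size_range[2]) {
    stop("library_size_range must be a positive non-empty interval", call. = FALSE)
  }
  validate_gene_catalog(gene_catalog)
  structure(list(
    timepoints = as.numeric(timepoints),
    conditions = as.character(conditions),
    n_replicates = as.integer(n_replicates),
    epo_peak_day = epo_peak_day,
    epo_window_width = epo_window_width,
    epo_hypoxia_gain = epo_hypoxia_gain,
    hif_target_gain = hif_target_gain,
    dispersion = dispersion,
    library_size_range = as.numeric(library_size_range),
    gene_catalog = gene_catalog,
    seed = as.integer(seed)
  ), class = "organoid_sim_params")
}

gene_roles <- c("epo", "hif_target", "maturation_marker", "population_marker",
                "transcription_factor", "background")

validate_gene_catalog <- function(catalog) {
  need <- c("gene", "role", "population", "mean_lo", "mean_hi",
            "midpoint_day", "rise_scale")
  if (!is.data.frame(catalog) || !all(need %in% names(catalog))) {
    stop("gene_catalog must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(catalog$role), gene_roles)
  if (length(bad)) {
    stop("unknown gene role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(catalog$gene)) stop("duplicate gene ids in catalog", call. = FALSE)
  invisible(catalog)
}
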