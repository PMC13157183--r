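#' Hepatic fraction of circulating EPO as a function of developmental age
#'
#' The generative maturation curve: the share of circulating EPO of hepatic
#' (foetal-liver) origin, `h(da) = 1 / (1 + exp(k * (da - m)))`. It is strictly
#' decreasing in developmental age and, by construction, depends on
#' developmental age only -- never on chronological age -- encoding the claim
#' that the hepatic-to-renal switch tracks maturation rather than time spent
#' breathing atmospheric oxygen.
#'
#' @param da developmental age(s), weeks; finite and positive.
#' @param params a [cohort_sim_params()] object.
#' @return hepatic fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' p <- cohort_sim_params()
#' hepatic_fraction(43, p)          # 0.5 at the midpoint
#' hepatic_fraction(47, p)          # 1 / (1 + e^2)
hepatic_fraction <- function(da, params = cohort_sim_params()) {
  if (any(!is.finite(da)) || any(da <= 0)) {
    stop("developmental age must be finite and > 0", call. = FALSE)
  }
  1 / (1 + exp(params$logistic_slope * (da - params$logistic_midpoint)))
}

# Canonical band-slot geometry on the normalised lane coordinate
# (x = 0 most acidic / pH 2 end, x = 1 most basic / pH 6 end) and the fixed
# hepatic / renal intensity templates. Positions and weights are package
# conventions: the source gels describe band positions categorically, so the
# grids below are free parameters chosen once. Basic slots are listed in
# increasing x; slot j corresponds to basic index j (index 1 adjacent to the
# neutral boundary).
gel_slots <- function() {
  list(
    acidic  = c(0.06, 0.12, 0.18),
    neutral = c(0.26, 0.32, 0.38, 0.44, 0.50, 0.56),
    basic   = c(0.66, 0.72, 0.78, 0.84, 0.90, 0.96)
  )
}

# Intensity weights per slot for the two pure components. The hepatic (foetal
# liver) component concentrates its three heaviest bands at basic indices
# 3-5; the renal component puts its dominant mass in the neutral region with
# minor basic/acidic flanking bands. The weights place the foetal<->mixed
# classification boundary of the mixed lane exactly at hepatic weight 0.5 and
# the mixed<->adult boundary near 0.31.
gel_templates <- function() {
  list(
    hepatic = list(
      acidic  = c(0.08, 0.08, 0.08),
      neutral = c(0.08, 0.09, 0.10, 0.10, 0.09, 0.08),
      basic   = c(0.25, 0.55, 1.00, 0.90, 0.70, 0.30)
    ),
    renal = list(
      acidic  = c(0.08, 0.08, 0.08),
      neutral = c(0.22, 0.32, 0.40, 0.36, 0.30, 0.22),
      basic   = c(0.25, 0.20, 0.35, 0.10, 0.05, 0.05)
    )
  )
}

# Combined band amplitudes for a lane with a given hepatic weight, rescaled to
# unit maximum (each lane is "auto-exposed"; the classifier is scale
# invariant). Returns data frame: position, amplitude, slot region, slot index.
lane_band_weights <- function(hepatic_weight) {
  stopifnot(is.finite(hepatic_weight), hepatic_weight >= 0, hepatic_weight <= 1)
  slots <- gel_slots()
  tpl <- gel_templates()
  reg <- rep(names(slots), lengths(slots))
  pos <- unlist(slots, use.names = FALSE)
  amp <- hepatic_weight * unlist(tpl$hepatic, use.names = FALSE) +
    (1 - hepatic_weight) * unlist(tpl$renal, use.names = FALSE)
  amp <- amp / max(amp)
  idx <- unlist(lapply(slots, seq_along), use.names = FALSE)
  data.frame(position = pos, amplitude = amp, slot_region = reg,
             slot_index = idx, stringsAsFactors = FALSE)
}

#' Render a densitometric gel lane for a given hepatic weight
#'
#' Produces one IEF-PAGE lane as a sampled signal over the normalised
#' acidic-to-basic coordinate: a slowly varying polynomial baseline plus
#' Gaussian bands (the hepatic/renal template mixture) plus additive Gaussian
#' noise truncated at zero. At the default settings a lane carries 15 bands,
#' within the 11-16 range typical of human EPO profiles.
#'
#' @param hepatic_weight mixing fraction of the hepatic component, in
#'   `[0, 1]`.
#' @param params a [cohort_sim_params()] object (noise and width settings).
#' @param lane_id lane identifier stored in the output.
#' @param lane_kind one of `"sample"`, `"acidic_reference"`,
#'   `"basic_reference"`.
#' @param noise logical; `FALSE` renders the noise-free signal
#'   (baseline still included).
#' @return a `LaneProfile` data frame: `lane_id`, `lane_kind`, `position`
#'   (strictly increasing in `[0, 1]`), `intensity` (non-negative).
#' @export
render_lane <- function(hepatic_weight, params = cohort_sim_params(),
                        lane_id = "lane", lane_kind = "sample", noise = TRUE) {
  bands <- lane_band_weights(hepatic_weight)
  render_band_lane(bands$position, bands$amplitude, params, lane_id, lane_kind,
                   noise = noise)
}

render_band_lane <- function(positions, amplitudes, params, lane_id,
                             lane_kind, noise = TRUE) {
  x <- seq(0, 1, length.out = params$lane_points)
  sig <- lane_baseline(x)
  for (i in seq_along(positions)) {
    sig <- sig + amplitudes[i] *
      exp(-(x - positions[i])^2 / (2 * params$band_sigma^2))
  }
  if (noise && params$lane_noise_sd > 0) {
    sig <- sig + stats::rnorm(length(x), sd = params$lane_noise_sd)
  }
  data.frame(lane_id = lane_id, lane_kind = lane_kind, position = x,
             intensity = pmax(sig, 0), stringsAsFactors = FALSE)
}

# Slowly varying optical background of the membrane scan.
lane_baseline <- function(x) 0.06 + 0.04 * x - 0.05 * x^2

#' Render the recombinant-drug calibration lanes
#'
#' Two reference lanes bracketing the neutral region: an acidic reference
#' (darbepoetin alfa-like, bands confined to low coordinates) and a basic
#' reference (epoetin alfa/beta-like, bands confined to high coordinates).
#' Their supports are disjoint with a gap, which [calibrate_regions()] turns
#' into the neutral interval.
#'
#' @inheritParams render_lane
#' @param noise logical, as in [render_lane()].
#' @return list with `LaneProfile` data frames `acidic` and `basic`.
#' @export
simulate_reference_lanes <- function(params = cohort_sim_params(), noise = TRUE) {
  slots <- gel_slots()
  draw <- function() list(
    acidic = render_band_lane(slots$acidic, rep(0.8, length(slots$acidic)),
                              params, "acidic_ref", "acidic_reference", noise),
    basic = render_band_lane(slots$basic, rep(0.8, length(slots$basic)),
                             params, "basic_ref", "basic_reference", noise)
  )
  if (noise) withr::with_seed(derive_seed(params$seed, 10000L), draw()) else draw()
}

# Deterministic 32-bit substream seed from a master seed and stream index.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i)) %% 2147483629)
}

# Stratum bounds in developmental age (weeks); G1..G4.
age_group_bounds <- function(da_range = c(29, 56)) {
  lo <- c(da_range[1], 37, 41, 49)
  hi <- c(37, 41, 49, da_range[2])
  data.frame(group = paste0("G", 1:4), lo = lo, hi = hi)
}

#' Simulate a neonatal cohort with gel lanes
#'
#' Draws, per developmental-age stratum, subjects with developmental age
#' uniform on the stratum and chronological age uniform on an interval that is
#' feasible for the *whole* stratum (so developmental and chronological age
#' are exactly independent within stratum); gestational age is the difference.
#' Each subject's hepatic weight is the maturation logistic evaluated at its
#' developmental age plus an independent maturation-tempo jitter, and its gel
#' lane is rendered from the hepatic/renal template mixture.
#'
#' Under `params$oxygen_driven = TRUE` the hepatic weight instead follows a
#' logistic of chronological age (midpoint `oxygen_midpoint_weeks`); this
#' alternative generator exists only to measure the power of
#' [test_oxygen_decoupling()].
#'
#' @param params a [cohort_sim_params()] object.
#' @param render logical; if `FALSE`, skip lane rendering (the records still
#'   carry the latent hepatic weight, and [template_profile_class()] can
#'   classify them cheaply).
#' @return list with elements
#'   * `records`: one row per subject -- `subject_id`, `lane_id`, `group`,
#'     `gestational_age_weeks`, `chronological_age_days`,
#'     `developmental_age_weeks`, `hepatic_weight`;
#'   * `lanes`: long `LaneProfile` table of all sample lanes (or `NULL`);
#'   * `reference`: long table of the two calibration lanes (or `NULL`).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_sim_params(n_per_group = c(3, 3, 3, 3)),
#'                           render = FALSE)
#' nrow(cohort$records)
simulate_cohort <- function(params = cohort_sim_params(), render = TRUE) {
  stopifnot(inherits(params, "cohort_sim_params"))
  bounds <- age_group_bounds(params$da_range_weeks)
  ga <- params$ga_range_weeks
  ca <- params$ca_range_days
  # chronological-age interval feasible for every developmental age in the
  # stratum: ga = da - ca/7 must stay inside ga_range for all da in [lo, hi]
  feas <- lapply(seq_len(4), function(g) {
    lo_ca <- max(ca[1], 7 * (bounds$hi[g] - ga[2]))
    hi_ca <- min(ca[2], 7 * (bounds$lo[g] - ga[1]))
    if (params$n_per_group[g] > 0 && lo_ca > hi_ca) {
      stop(sprintf(
        "stratum %s (%g-%g weeks) infeasible given ga range [%g, %g] and ca range [%g, %g]",
        bounds$group[g], bounds$lo[g], bounds$hi[g], ga[1], ga[2], ca[1], ca[2]),
        call. = FALSE)
    }
    c(lo_ca, hi_ca)
  })
  n_total <- sum(params$n_per_group)
  if (n_total == 0L) {
    empty <- data.frame(subject_id = character(), lane_id = character(),
                        group = character(), gestational_age_weeks = numeric(),
                        chronological_age_days = numeric(),
                        developmental_age_weeks = numeric(),
                        hepatic_weight = numeric(), stringsAsFactors = FALSE)
    return(list(records = empty, lanes = NULL, reference = NULL))
  }
  records <- withr::with_seed(params$seed, {
    rows <- lapply(seq_len(4), function(g) {
      n <- params$n_per_group[g]
      if (n == 0L) return(NULL)
      da <- stats::runif(n, bounds$lo[g], bounds$hi[g])
      cad <- stats::runif(n, feas[[g]][1], feas[[g]][2])
      jit <- stats::rnorm(n, sd = params$maturation_jitter_sd)
      h <- if (params$oxygen_driven) {
        1 / (1 + exp(params$oxygen_slope *
                       (cad / 7 + jit - params$oxygen_midpoint_weeks)))
      } else {
        1 / (1 + exp(params$logistic_slope *
                       (da + jit - params$logistic_midpoint)))
      }
      data.frame(group = bounds$group[g], gestational_age_weeks = da - cad / 7,
                 chronological_age_days = cad, developmental_age_weeks = da,
                 hepatic_weight = h, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  records$subject_id <- sprintf("S%03d", seq_len(nrow(records)))
  records$lane_id <- records$subject_id
  records <- records[, c("subject_id", "lane_id", "group",
                         "gestational_age_weeks", "chronological_age_days",
                         "developmental_age_weeks", "hepatic_weight")]
  lanes <- NULL
  reference <- NULL
  if (render) {
    lanes <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
      # deterministic per-lane substream derived from the master seed
      withr::with_seed(derive_seed(params$seed, i),
        render_lane(records$hepatic_weight[i], params,
                    lane_id = records$lane_id[i]))
    }))
    refs <- simulate_reference_lanes(params)
    reference <- rbind(refs$acidic, refs$basic)
  }
  list(records = records, lanes = lanes, reference = reference)
}

#' Noise-free template classification of a hepatic weight
#'
#' Classifies the exact (noise-free) band set implied by a hepatic weight,
#' bypassing lane rendering and band detection: the combined template
#' amplitudes are fed directly to the region/indexing and top-3 classification
#' rules used for detected lanes. Useful for large Monte-Carlo studies of the
#' cohort statistics where gel rendering is irrelevant.
#'
#' @param hepatic_weight numeric vector of hepatic weights in `[0, 1]`.
#' @return character vector: `"foetal"`, `"mixed"` or `"adult"`.
#' @export
template_profile_class <- function(hepatic_weight) {
  regions <- template_region_map()
  vapply(hepatic_weight, function(h) {
    w <- lane_band_weights(h)
    bands <- data.frame(lane_id = "template", position = w$position,
                        left = w$position - 0.02, right = w$position + 0.02,
                        intensity = w$amplitude, region = NA_character_,
                        basic_index = NA_integer_, stringsAsFactors = FALSE)
    bands <- assign_regions_and_index(bands, regions)
    classify_profile(select_top3(bands), regions)$profile_class
  }, character(1))
}

# Region map implied by the canonical reference-slot geometry and the default
# margin; equals calibrate_regions() run on noise-free reference lanes.
template_region_map <- function(margin = 0.02) {
  slots <- gel_slots()
  region_map(max(slots$acidic) + margin, min(slots$basic) - margin, margin)
}
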