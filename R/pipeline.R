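#' Run the full gel-profile cohort pipeline on one synthetic cohort
#'
#' Simulate the cohort, render lanes and calibration references, detect
#' bands, calibrate the gel regions, classify every lane, build the
#' age-group by profile contingency table and test independence. This is the
#' end-to-end path from generative parameters to the headline association
#' p-value.
#'
#' @param params a [cohort_sim_params()] object.
#' @param B permutation resamples for the independence-test fallback.
#' @return list: `records` (with `profile_class`), `regions`, `calls`,
#'   `table`, `association`.
#' @export
#' @examples
#' \donttest{
#' out <- cohort_pipeline(cohort_sim_params(n_per_group = c(8, 8, 8, 8)))
#' out$association$p_value
#' }
cohort_pipeline <- function(params = cohort_sim_params(), B = 10000L) {
  cohort <- simulate_cohort(params, render = TRUE)
  acid <- cohort$reference[cohort$reference$lane_kind == "acidic_reference", ]
  basi <- cohort$reference[cohort$reference$lane_kind == "basic_reference", ]
  regions <- calibrate_regions(detect_bands(acid), detect_bands(basi))
  calls <- call_profiles(cohort$lanes, regions)
  rec <- cohort$records
  rec$profile_class <- calls$profile_class[match(rec$lane_id, calls$lane_id)]
  tab <- build_contingency(rec)
  assoc <- test_independence(tab, B = B, seed = derive_seed(params$seed, 20000L))
  list(records = rec, regions = regions, calls = calls, table = tab,
       association = assoc)
}
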