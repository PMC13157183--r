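#' @title Band detection and profile classification for IEF-PAGE lanes
#' @description Operations turning a 1-D lane densitometry signal into a
#'   foetal / mixed / adult EPO profile call: baseline-corrected peak
#'   detection, region calibration from the recombinant reference drugs,
#'   basic-band indexing, and the top-3 classification rules.
#' @name gel_isoform
NULL

validate_lane <- function(lane) {
  if (!is.data.frame(lane) || !all(c("position", "intensity") %in% names(lane))) {
    stop("a lane must be a data frame with columns position and intensity",
         call. = FALSE)
  }
  if (nrow(lane) < 50L) stop("a lane needs >= 50 sample points", call. = FALSE)
  if (any(diff(lane$position) <= 0)) {
    stop("lane positions must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(lane$intensity)) || any(lane$intensity < 0)) {
    stop("lane intensities must be finite and non-negative", call. = FALSE)
  }
  invisible(lane)
}

roll_min <- function(x, w) {
  n <- length(x)
  h <- w %/% 2L
  vapply(seq_len(n), function(i) min(x[max(1L, i - h):min(n, i + h)]),
         numeric(1))
}

roll_mean <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  h <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)  # partial windows at the edges
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# Topographic prominence of each local maximum: height above the higher of
# the two saddle minima separating the peak from higher ground (or from the
# signal edge when no higher ground exists on that side).
peak_prominence <- function(sig, peaks) {
  n <- length(sig)
  vapply(peaks, function(p) {
    h <- sig[p]
    lmin <- h
    i <- p
    while (i > 1L) {
      i <- i - 1L
      if (sig[i] > h) break
      if (sig[i] < lmin) lmin <- sig[i]
    }
    rmin <- h
    j <- p
    while (j < n) {
      j <- j + 1L
      if (sig[j] > h) break
      if (sig[j] < rmin) rmin <- sig[j]
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect bands in a lane densitometry signal
#'
#' Light moving-average smoothing, baseline estimation by a rolling minimum
#' (window ten times `min_separation`) followed by a smoothing pass, then peak
#' calling on the baseline-subtracted signal: local maxima with topographic
#' prominence at least `min_prominence` times the corrected-signal maximum and
#' pairwise separation at least `min_separation` become bands. Band intensity
#' is the trapezoidal area of the corrected signal between the flanking minima
#' bounding the peak -- an area measure is robust to band-width variation.
#'
#' @param lane a `LaneProfile` data frame (`position`, `intensity`, optionally
#'   `lane_id`).
#' @param min_prominence prominence threshold as a fraction of the corrected
#'   signal maximum.
#' @param min_separation minimum apex separation in normalised coordinates;
#'   also sets the smoothing and baseline windows.
#' @return a `BandSet` data frame sorted by position: `lane_id`, `position`
#'   (apex), `left`, `right` (bounds), `intensity` (area), `height`, `region`
#'   (`NA` until [assign_regions_and_index()]), `basic_index` (`NA`).
#' @export
#' @examples
#' x <- seq(0, 1, length.out = 1001)
#' lane <- data.frame(position = x,
#'                    intensity = exp(-(x - 0.5)^2 / (2 * 0.01^2)))
#' detect_bands(lane)
detect_bands <- function(lane, min_prominence = 0.05, min_separation = 0.015) {
  validate_lane(lane)
  id <- if ("lane_id" %in% names(lane)) lane$lane_id[1] else "lane"
  pos <- lane$position
  int <- lane$intensity
  dx <- mean(diff(pos))
  w_smooth <- max(1L, round(min_separation / dx))
  if (w_smooth %% 2L == 0L) w_smooth <- w_smooth + 1L
  sm <- roll_mean(int, w_smooth)
  w_base <- max(3L, round(10 * min_separation / dx))
  baseline <- roll_mean(roll_min(sm, w_base), w_base)
  sig <- pmax(sm - baseline, 0)
  n <- length(sig)
  cand <- which(sig[-c(1L, n)] > sig[-c(n - 1L, n)] &
                  sig[-c(1L, n)] >= sig[-c(1L, 2L)]) + 1L
  cand <- cand[sig[cand] > 0]
  if (length(cand)) {
    prom <- peak_prominence(sig, cand)
    cand <- cand[prom >= min_prominence * max(sig)]
  }
  if (!length(cand)) {
    stop(sprintf("no bands detected in lane %s", id), call. = FALSE)
  }
  # enforce min_separation, keeping taller peaks first
  cand <- cand[order(sig[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (p in cand) {
    if (!length(keep) || all(abs(pos[p] - pos[keep]) >= min_separation)) {
      keep <- c(keep, p)
    }
  }
  peaks <- sort(keep)
  k <- length(peaks)
  lb <- integer(k)
  rb <- integer(k)
  for (i in seq_len(k)) {
    lo <- if (i == 1L) 1L else peaks[i - 1L]
    hi <- if (i == k) n else peaks[i + 1L]
    lb[i] <- if (peaks[i] > lo) lo - 1L + which.min(sig[lo:(peaks[i] - 1L)]) else lo
    rb[i] <- if (hi > peaks[i]) peaks[i] + which.min(sig[(peaks[i] + 1L):hi]) else hi
  }
  area <- vapply(seq_len(k), function(i) {
    r <- lb[i]:rb[i]
    max(trapz(pos[r], sig[r]), 0)
  }, numeric(1))
  data.frame(lane_id = id, position = pos[peaks], left = pos[lb],
             right = pos[rb], intensity = area, height = sig[peaks],
             region = NA_character_, basic_index = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Region map of an IEF gel
#'
#' The acidic / neutral / basic partition of the normalised lane coordinate:
#' acidic `[0, a]`, neutral `(a, b)`, basic `[b, 1]`.
#'
#' @param a upper bound of the acidic region.
#' @param b lower bound of the basic region.
#' @param margin the margin used to derive `a` and `b` (bookkeeping).
#' @return an object of class `region_map`.
#' @export
region_map <- function(a, b, margin = NA_real_) {
  if (!(0 < a && a < b && b < 1)) {
    stop(sprintf("invalid region boundaries: a = %.4f, b = %.4f", a, b),
         call. = FALSE)
  }
  structure(list(a = a, b = b, margin = margin), class = "region_map")
}

#' Calibrate gel regions from the reference-drug band sets
#'
#' The neutral region is defined by exclusion of the acidic and basic regions,
#' which are anchored by the recombinant reference drugs: the acidic boundary
#' sits `margin` above the most basic acidic-reference band and the basic
#' boundary `margin` below the most acidic basic-reference band.
#'
#' @param acidic_ref,basic_ref `BandSet` data frames from [detect_bands()] run
#'   on the two reference lanes.
#' @param margin region margin in normalised coordinates.
#' @return a [region_map()].
#' @export
calibrate_regions <- function(acidic_ref, basic_ref, margin = 0.02) {
  if (!nrow(acidic_ref) || !nrow(basic_ref)) {
    stop("both reference band sets must be non-empty", call. = FALSE)
  }
  a <- max(acidic_ref$position) + margin
  b <- min(basic_ref$position) - margin
  if (a >= b) {
    stop(sprintf(
      "reference lanes overlap or are inverted: acidic boundary %.4f >= basic boundary %.4f",
      a, b), call. = FALSE)
  }
  region_map(a, b, margin)
}

#' Label band regions and index the basic-area bands 1-6
#'
#' Each band is labelled by the region containing its apex. Basic-region bands
#' are sorted by position and indexed 1 to 6 starting at the band nearest the
#' neutral boundary and increasing toward the basic extreme; bands beyond the
#' sixth stay unindexed. (The numbering direction is a package convention: it
#' places mixed profiles `{1,2,3}` adjacent to the neutral zone, consistent
#' with a partial renal contribution.)
#'
#' @param bands a `BandSet` data frame.
#' @param regions a [region_map()].
#' @return the `BandSet` with `region` and `basic_index` filled in.
#' @export
assign_regions_and_index <- function(bands, regions) {
  stopifnot(inherits(regions, "region_map"))
  bands$region <- ifelse(bands$position <= regions$a, "acidic",
                         ifelse(bands$position < regions$b, "neutral", "basic"))
  bands$basic_index <- NA_integer_
  bi <- which(bands$region == "basic")
  if (length(bi)) {
    ord <- bi[order(bands$position[bi])]
    ranks <- seq_along(ord)
    ranks[ranks > 6L] <- NA_integer_
    bands$basic_index[ord] <- as.integer(ranks)
  }
  bands
}

#' Select the three most intense bands of a lane
#'
#' Ties are broken toward the more basic (higher-coordinate) position; this
#' stable rule is a documented package convention.
#'
#' @param bands a `BandSet` data frame with >= 3 bands.
#' @return the three top bands, intensity-sorted descending.
#' @export
select_top3 <- function(bands) {
  if (nrow(bands) < 3L) {
    stop(sprintf("insufficient bands for classification (%d < 3)", nrow(bands)),
         call. = FALSE)
  }
  bands[order(-bands$intensity, -bands$position), ][1:3, ]
}

#' Classify a lane as foetal, mixed or adult from its top-3 bands
#'
#' Decision rules, in order: (1) if any of the three most intense bands lies
#' in the neutral (or acidic) region, the profile is adult -- the hallmark of
#' renal EPO; (2) otherwise all three are basic: index set `{3,4,5}` is
#' foetal, `{2,3,4}` or `{1,2,3}` is mixed; (3) any other all-basic index set
#' falls back to the median rule (median index >= 4 foetal, else mixed).
#' The branch taken is recorded in `rule_fired`.
#'
#' @param top3 the output of [select_top3()]; every band must carry a region
#'   label.
#' @param regions the [region_map()] used for labelling (kept for provenance).
#' @return an object of class `profile_call`: list with `lane_id`,
#'   `profile_class`, `rule_fired`, `top3`.
#' @export
classify_profile <- function(top3, regions) {
  stopifnot(nrow(top3) == 3L, !any(is.na(top3$region)))
  mk <- function(class, rule) {
    structure(list(lane_id = top3$lane_id[1], profile_class = class,
                   rule_fired = rule, top3 = top3), class = "profile_call")
  }
  if (any(top3$region != "basic")) {
    return(mk("adult", "adult_top3_outside_basic"))
  }
  if (any(is.na(top3$basic_index))) {
    stop(sprintf("unindexed dominant band in lane %s (basic rank > 6)",
                 top3$lane_id[1]), call. = FALSE)
  }
  s <- sort(top3$basic_index)
  if (identical(s, c(3L, 4L, 5L))) return(mk("foetal", "foetal_345"))
  if (identical(s, c(2L, 3L, 4L))) return(mk("mixed", "mixed_234"))
  if (identical(s, c(1L, 2L, 3L))) return(mk("mixed", "mixed_123"))
  if (stats::median(s) >= 4) mk("foetal", "foetal_fallback_median")
  else mk("mixed", "mixed_fallback_median")
}

#' @export
print.profile_call <- function(x, ...) {
  cat(sprintf("<profile_call> lane %s: %s (%s); top-3 indices: %s\n",
              x$lane_id, x$profile_class, x$rule_fired,
              paste(ifelse(is.na(x$top3$basic_index), x$top3$region,
                           x$top3$basic_index), collapse = ", ")))
  invisible(x)
}

#' End-to-end profile call for one lane
#'
#' Convenience wrapper: [detect_bands()], [assign_regions_and_index()],
#' [select_top3()], [classify_profile()].
#'
#' @inheritParams detect_bands
#' @param regions a [region_map()].
#' @return a `profile_call`.
#' @export
call_profile <- function(lane, regions, min_prominence = 0.05,
                         min_separation = 0.015) {
  bands <- detect_bands(lane, min_prominence, min_separation)
  bands <- assign_regions_and_index(bands, regions)
  classify_profile(select_top3(bands), regions)
}

#' Profile calls for a long lane table
#'
#' @param lanes long `LaneProfile` table (multiple `lane_id`s) of sample
#'   lanes.
#' @param regions a [region_map()], e.g. from [calibrate_regions()].
#' @param ... passed to [detect_bands()].
#' @return data frame: `lane_id`, `profile_class`, `rule_fired`,
#'   `top3_indices` (comma-separated, neutral/acidic bands shown by region).
#' @export
call_profiles <- function(lanes, regions, ...) {
  ids <- unique(lanes$lane_id)
  rows <- lapply(ids, function(id) {
    pc <- call_profile(lanes[lanes$lane_id == id, , drop = FALSE], regions, ...)
    data.frame(lane_id = id, profile_class = pc$profile_class,
               rule_fired = pc$rule_fired,
               top3_indices = paste(ifelse(is.na(pc$top3$basic_index),
                                           pc$top3$region, pc$top3$basic_index),
                                    collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
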