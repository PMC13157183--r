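#' Default marker-gene catalog for the organoid simulation
#'
#' A compact catalog mixing the genes named in the main analyses (EPO; the
#' hypoxia targets VEGFA, EGLN3, NDRG1, PDK1, HK2; the maturation markers
#' ALB, CYP3A4, CYP3A7; the transcription factors GATA4, GATA2, HNF4A, FOXA2;
#' the qPCR reference genes RPLP0, ACTB, RPL13A) with synthetic placeholder
#' markers for the major hepatic cell populations (hepatocytes, immature
#' hepatocytes, cholangiocytes, Kupffer cells, liver sinusoidal endothelial
#' cells, hepatic stellate cells; gene ids prefixed `SYN_`) and `n_background`
#' flat background genes (ids `BG001`...). The background filler is not
#' cosmetic: median-of-ratios size factors computed on a handful of genes are
#' biased by the hypoxia-induced targets (a composition effect that makes
#' null genes look regulated), and it sets a realistic multiple-testing
#' burden and variance-moderation pool for the induction test. The catalog is
#' an ordinary data frame and is user-replaceable.
#'
#' Columns: `gene`, `role` (one of epo, hif_target, maturation_marker,
#' population_marker, transcription_factor, background), `population` (for
#' population markers), `mean_lo` / `mean_hi` (early / late expected
#' normalised expression), `midpoint_day` and `rise_scale` (logistic rise in
#' day for genes whose mean changes with differentiation; constant genes have
#' `mean_hi = mean_lo`).
#'
#' @param n_background number of additional flat background genes.
#' @return the catalog data frame.
#' @export
default_marker_catalog <- function(n_background = 50L) {
  row <- function(gene, role, population = NA_character_, lo, hi = lo,
                  mid = 12, scale = 2) {
    data.frame(gene = gene, role = role, population = population,
               mean_lo = lo, mean_hi = hi, midpoint_day = mid,
               rise_scale = scale, stringsAsFactors = FALSE)
  }
  pops <- data.frame(
    population = c("hepatocytes", "immature_hepatocytes", "cholangiocytes",
                   "kupffer_cells", "liver_sinusoidal_endothelial_cells",
                   "hepatic_stellate_cells"),
    code = c("HEP", "IMH", "CHO", "KUP", "LSEC", "HSC"),
    mid = c(13, 8, 11, 12, 10, 12),
    hi = c(300, 150, 120, 80, 100, 90),
    stringsAsFactors = FALSE
  )
  pop_rows <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    rbind(
      row(sprintf("SYN_%s_1", pops$code[i]),
          "population_marker", pops$population[i], lo = 5, hi = pops$hi[i],
          mid = pops$mid[i]),
      row(sprintf("SYN_%s_2", pops$code[i]),
          "population_marker", pops$population[i], lo = 8,
          hi = pops$hi[i] * 0.6, mid = pops$mid[i] + 1)
    )
  }))
  bg_rows <- NULL
  if (n_background > 0L) {
    bg_means <- round(exp(seq(log(5), log(500), length.out = n_background)))
    bg_rows <- do.call(rbind, lapply(seq_len(n_background), function(i) {
      row(sprintf("BG%03d", i), "background", lo = bg_means[i])
    }))
  }
  rbind(
    row("EPO", "epo", lo = 30),
    row("VEGFA", "hif_target", lo = 200),
    row("EGLN3", "hif_target", lo = 150),
    row("NDRG1", "hif_target", lo = 120),
    row("PDK1", "hif_target", lo = 180),
    row("HK2", "hif_target", lo = 250),
    row("ALB", "maturation_marker", lo = 2, hi = 400, mid = 12),
    row("CYP3A4", "maturation_marker", lo = 1, hi = 150, mid = 14),
    row("CYP3A7", "maturation_marker", lo = 3, hi = 250, mid = 11),
    row("GATA4", "transcription_factor", lo = 90),
    row("GATA2", "transcription_factor", lo = 60),
    row("HNF4A", "transcription_factor", lo = 140),
    row("FOXA2", "transcription_factor", lo = 110),
    row("RPLP0", "background", lo = 2000),
    row("ACTB", "background", lo = 2500),
    row("RPL13A", "background", lo = 1800),
    pop_rows,
    bg_rows
  )
}

#' EPO competence window
#'
#' Gaussian window in day, rescaled so that it is exactly closed on day 19:
#' `c(day) = max(0, (w(day) - w(19)) / (1 - w(19)))` with
#' `w(day) = exp(-(day - p)^2 / (2 width^2))`.
#'
#' @param day day(s) of differentiation.
#' @param peak_day window peak `p`.
#' @param width Gaussian width, days.
#' @param close_day day at which the window is pinned to zero.
#' @return window value(s) in `[0, 1]`.
#' @export
epo_competence_window <- function(day, peak_day = 12, width = 3,
                                  close_day = 19) {
  w <- exp(-(day - peak_day)^2 / (2 * width^2))
  w19 <- exp(-(close_day - peak_day)^2 / (2 * width^2))
  pmax(0, (w - w19) / (1 - w19))
}

#' Expected normalised expression of a catalog gene
#'
#' The noise-free mean surface of the organoid generator, exposed so that the
#' downstream summaries can be checked against closed forms.
#'
#' @param gene gene id present in `params$gene_catalog`.
#' @param day day(s) of differentiation.
#' @param condition `"normoxia"` or `"hypoxia"`.
#' @param params an [organoid_sim_params()] object.
#' @return expected expression value(s) before library-size scaling.
#' @export
organoid_gene_mean <- function(gene, day, condition,
                               params = organoid_sim_params()) {
  cat_ <- params$gene_catalog
  i <- match(gene, cat_$gene)
  if (is.na(i)) stop(sprintf("gene %s not in catalog", gene), call. = FALSE)
  role <- cat_$role[i]
  base <- cat_$mean_lo[i] +
    (cat_$mean_hi[i] - cat_$mean_lo[i]) *
    stats::plogis((day - cat_$midpoint_day[i]) / cat_$rise_scale[i])
  hyp <- condition == "hypoxia"
  if (role == "epo") {
    win <- epo_competence_window(day, params$epo_peak_day,
                                 params$epo_window_width,
                                 close_day = max(params$timepoints))
    cat_$mean_lo[i] * ifelse(hyp, 1 + (params$epo_hypoxia_gain - 1) * win, 1)
  } else if (role == "hif_target") {
    base * ifelse(hyp, params$hif_target_gain, 1)
  } else {
    base + 0 * hyp
  }
}

#' Simulate an organoid differentiation count matrix
#'
#' Negative-binomial counts for every catalog gene across the
#' (day, condition, replicate) grid: `NB(mean = L_s * mu_g(day, condition),
#' size = 1/dispersion)` with per-sample library factors `L_s` drawn from
#' `library_size_range`. See [organoid_sim_params()] for the mean model.
#'
#' @param params an [organoid_sim_params()] object.
#' @return list with `counts` (integer gene x sample matrix) and `meta`
#'   (data frame `sample_id`, `day`, `condition`, `replicate`,
#'   `library_factor`).
#' @export
#' @examples
#' sim <- simulate_organoid_counts(organoid_sim_params(seed = 3))
#' dim(sim$counts)
simulate_organoid_counts <- function(params = organoid_sim_params()) {
  stopifnot(inherits(params, "organoid_sim_params"))
  grid <- expand.grid(replicate = seq_len(params$n_replicates),
                      condition = params$conditions,
                      day = params$timepoints,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("day", "condition", "replicate")]
  grid$sample_id <- sprintf("d%02d_%s_r%d", grid$day,
                            substr(grid$condition, 1, 4), grid$replicate)
  genes <- params$gene_catalog$gene
  withr::with_seed(params$seed, {
    grid$library_factor <- stats::runif(nrow(grid),
                                        params$library_size_range[1],
                                        params$library_size_range[2])
    counts <- matrix(0L, nrow = length(genes), ncol = nrow(grid),
                     dimnames = list(genes, grid$sample_id))
    for (g in seq_along(genes)) {
      mu <- organoid_gene_mean(genes[g], grid$day, grid$condition, params) *
        grid$library_factor
      counts[g, ] <- stats::rnbinom(nrow(grid), mu = mu,
                                    size = 1 / params$dispersion)
    }
    list(counts = counts, meta = grid[, c("sample_id", "day", "condition",
                                          "replicate", "library_factor")])
  })
}

#' Simulate a qPCR Ct table from known relative expressions
#'
#' Emits, per sample, the three reference-gene Cts (RPLP0, ACTB, RPL13A at
#' fixed offsets around `ref_ct_base`) and one target Ct per requested
#' relative expression: `Ct_target = mean(reference Cts) - log2(rel_expr)`,
#' each with optional Gaussian noise. [delta_ct()] inverts this mapping
#' exactly when the noise is zero.
#'
#' @param rel_expr data frame `sample_id`, `gene`, `rel_expr` (> 0).
#' @param ref_ct_base centre of the reference-gene Cts.
#' @param noise_sd Gaussian noise s.d. on every emitted Ct.
#' @param seed seed for the noise draw.
#' @param reference_genes the three reference-gene ids.
#' @return long `CtTable` data frame: `sample_id`, `gene`, `ct`.
#' @export
simulate_ct_table <- function(rel_expr, ref_ct_base = 20, noise_sd = 0,
                              seed = 1L,
                              reference_genes = c("RPLP0", "ACTB", "RPL13A")) {
  stopifnot(all(c("sample_id", "gene", "rel_expr") %in% names(rel_expr)))
  if (any(!is.finite(rel_expr$rel_expr)) || any(rel_expr$rel_expr <= 0)) {
    stop("relative expressions must be positive", call. = FALSE)
  }
  samples <- unique(rel_expr$sample_id)
  offsets <- c(-0.5, 0, 0.5)
  withr::with_seed(seed, {
    refs <- do.call(rbind, lapply(samples, function(s) {
      data.frame(sample_id = s, gene = reference_genes,
                 ct = ref_ct_base + offsets +
                   stats::rnorm(3, sd = noise_sd), stringsAsFactors = FALSE)
    }))
    ref_mean <- tapply(refs$ct, refs$sample_id, mean)
    targets <- data.frame(
      sample_id = rel_expr$sample_id, gene = rel_expr$gene,
      ct = as.numeric(ref_mean[rel_expr$sample_id]) -
        log2(rel_expr$rel_expr) + stats::rnorm(nrow(rel_expr), sd = noise_sd),
      stringsAsFactors = FALSE)
    rbind(refs, targets)
  })
}
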