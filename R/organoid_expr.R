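#' @title Organoid expression time-course analysis
#' @description Median-of-ratios size factors, count normalisation and
#'   stabilisation, marker-set trajectories, EPO competence-window summaries,
#'   day-19 hypoxia induction testing, 2^-DeltaCt quantification and PCA
#'   diagnostics.
#' @name organoid_expr
NULL

validate_counts <- function(counts) {
  if (!is.matrix(counts) || any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be a non-negative numeric matrix", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("duplicate gene or sample ids in count matrix", call. = FALSE)
  }
  invisible(counts)
}

#' Median-of-ratios size factors
#'
#' The per-sample scaling constants of the standard RNA-seq normalisation: a
#' pseudo-reference is the per-gene geometric mean over samples, computed on
#' the genes with no zero count anywhere, and each sample's factor is the
#' median over those genes of its count-to-reference ratio.
#'
#' @param counts gene x sample count matrix with >= 2 samples.
#' @return positive numeric vector of per-sample factors.
#' @export
#' @examples
#' m <- matrix(c(2, 4, 10, 4, 8, 20), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' size_factors(m)  # c(1/sqrt(2), sqrt(2))
size_factors <- function(counts) {
  validate_counts(counts)
  if (ncol(counts) < 2L) stop("need >= 2 samples", call. = FALSE)
  keep <- rowSums(counts == 0) == 0
  if (!any(keep)) {
    stop(paste("no gene has all-positive counts across samples;",
               "consider restricting to a high-expression gene subset",
               "before estimating factors"), call. = FALSE)
  }
  ref <- exp(rowMeans(log(counts[keep, , drop = FALSE])))
  f <- apply(counts[keep, , drop = FALSE] / ref, 2, stats::median)
  if (any(f <= 0)) stop("non-positive size factor estimated", call. = FALSE)
  f
}

#' Divide counts by their size factors
#'
#' @param counts gene x sample count matrix.
#' @param factors per-sample positive factors, e.g. from [size_factors()].
#' @return normalised matrix.
#' @export
normalize_counts <- function(counts, factors) {
  validate_counts(counts)
  if (length(factors) != ncol(counts) || any(factors <= 0)) {
    stop("factors must be positive, one per sample", call. = FALSE)
  }
  sweep(counts, 2, factors, "/")
}

#' Variance-stabilising transform used for exploratory analyses
#'
#' `log2(x + 1)` on normalised counts: monotone, maps 0 to 0, preserves
#' per-gene ordering, and flattens the mean-variance trend enough for
#' trajectory and PCA summaries.
#'
#' @param x non-negative matrix (normalised counts).
#' @return transformed matrix.
#' @export
stabilize <- function(x) {
  if (any(x < 0)) stop("stabilize() needs non-negative input", call. = FALSE)
  log2(x + 1)
}

#' Mean stabilised trajectories of marker gene sets
#'
#' For each marker set: the stabilised expression is averaged over the
#' member genes present in the matrix (per sample), then summarised over
#' replicates per (day, condition). Catalog genes absent from the matrix are
#' excluded with a warning; sets with no present gene are reported in the
#' `absent_sets` attribute rather than silently dropped.
#'
#' @param stabilized stabilised gene x sample matrix.
#' @param meta sample metadata (`sample_id`, `day`, `condition`).
#' @param marker_sets named list: population / set name -> character vector
#'   of gene ids. See [marker_sets_from_catalog()].
#' @return `TrajectoryTable` data frame: `set`, `day`, `condition`, `mean`,
#'   `sd`, `n`; attribute `absent_sets`.
#' @export
markerset_trajectory <- function(stabilized, meta, marker_sets) {
  stopifnot(is.list(marker_sets), length(marker_sets) > 0)
  present <- lapply(marker_sets, function(g) intersect(g, rownames(stabilized)))
  absent <- names(marker_sets)[lengths(present) == 0]
  missing_genes <- unlist(lapply(names(marker_sets), function(s) {
    setdiff(marker_sets[[s]], rownames(stabilized))
  }))
  if (length(absent) == length(marker_sets)) {
    stop("no catalog gene present in the matrix for any set", call. = FALSE)
  }
  if (length(missing_genes)) {
    warning("catalog gene(s) absent from matrix: ",
            paste(unique(missing_genes), collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(colnames(stabilized), meta$sample_id), ]
  rows <- lapply(setdiff(names(marker_sets), absent), function(s) {
    per_sample <- colMeans(stabilized[present[[s]], , drop = FALSE])
    agg <- stats::aggregate(per_sample,
                            by = list(day = meta$day, condition = meta$condition),
                            FUN = function(v) c(mean = mean(v),
                                                sd = stats::sd(v),
                                                n = length(v)))
    data.frame(set = s, day = agg$day, condition = agg$condition,
               mean = agg$x[, "mean"],
               sd = ifelse(is.na(agg$x[, "sd"]), 0, agg$x[, "sd"]),
               n = as.integer(agg$x[, "n"]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$set, out$condition, out$day), ]
  rownames(out) <- NULL
  attr(out, "absent_sets") <- absent
  out
}

#' Marker sets from a gene catalog
#'
#' Groups a catalog data frame (see [default_marker_catalog()]) into the
#' named gene lists consumed by [markerset_trajectory()]: one set per
#' population plus `maturation_markers`, `hypoxia_targets` and
#' `transcription_factors`.
#'
#' @param catalog a gene catalog data frame.
#' @return named list of character vectors.
#' @export
marker_sets_from_catalog <- function(catalog) {
  validate_gene_catalog(catalog)
  sets <- list(
    maturation_markers = catalog$gene[catalog$role == "maturation_marker"],
    hypoxia_targets = catalog$gene[catalog$role == "hif_target"],
    transcription_factors = catalog$gene[catalog$role == "transcription_factor"]
  )
  pops <- unique(stats::na.omit(catalog$population))
  for (p in pops) {
    sets[[p]] <- catalog$gene[!is.na(catalog$population) &
                                catalog$population == p]
  }
  sets[lengths(sets) > 0]
}

#' Summarise the EPO expression trajectory
#'
#' Per condition: the peak day (argmax of the replicate-mean normalised
#' expression over the day grid; ties resolve to the earliest day) and the
#' decline ratio (terminal-day mean over peak mean). The late-induction flag
#' reports whether the gene still responds to hypoxia at the terminal day
#' according to [hypoxia_induction_test()] (BH-adjusted p < 0.05 with a
#' positive log2 fold change).
#'
#' @param counts gene x sample count matrix.
#' @param meta sample metadata.
#' @param gene gene id, default `"EPO"`.
#' @return list: `per_condition` data frame (`condition`, `peak_day`,
#'   `peak_mean`, `terminal_mean`, `decline_ratio`), `terminal_day`,
#'   `late_induction` (logical), `induction_log2fc`, `induction_padj`.
#' @export
epo_trajectory_summary <- function(counts, meta, gene = "EPO") {
  validate_counts(counts)
  if (!gene %in% rownames(counts)) {
    stop(sprintf("gene %s absent from count matrix", gene), call. = FALSE)
  }
  norm <- normalize_counts(counts, size_factors(counts))
  expr <- norm[gene, ]
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  terminal_day <- max(meta$day)
  per_cond <- lapply(unique(meta$condition), function(cond) {
    sel <- meta$condition == cond
    if (length(unique(meta$day[sel])) < 2L) {
      stop("need >= 2 timepoints per condition", call. = FALSE)
    }
    day_means <- tapply(expr[sel], meta$day[sel], mean)
    days <- as.numeric(names(day_means))
    ord <- order(days)
    days <- days[ord]
    day_means <- day_means[ord]
    peak_i <- which.max(day_means)  # first maximum = earliest day on ties
    data.frame(condition = cond, peak_day = days[peak_i],
               peak_mean = unname(day_means[peak_i]),
               terminal_mean = unname(day_means[days == terminal_day]),
               decline_ratio = unname(day_means[days == terminal_day] /
                                        day_means[peak_i]),
               stringsAsFactors = FALSE)
  })
  per_cond <- do.call(rbind, per_cond)
  ind <- NULL
  late <- NA
  lfc <- NA_real_
  padj <- NA_real_
  if (length(unique(meta$condition)) >= 2L) {
    ind <- hypoxia_induction_test(counts, meta, day = terminal_day)
    row <- ind[ind$gene == gene, ]
    lfc <- row$log2fc
    padj <- row$padj
    late <- isTRUE(row$tested) && !is.na(padj) && padj < 0.05 && lfc > 0
  }
  list(per_condition = per_cond, terminal_day = terminal_day,
       late_induction = late, induction_log2fc = lfc, induction_padj = padj)
}

#' Hypoxia induction test at a fixed day
#'
#' Per gene: log2 fold change of the condition means of normalised counts
#' (pseudocount 0.5), a moderated t-test on stabilised values (limma with an
#' intensity-trended variance prior -- with three replicates per condition a
#' plain two-sample test has two to four residual degrees of freedom and no
#' power against a genome-wide adjustment), and Benjamini-Hochberg adjustment
#' across the tested genes. Genes with all-zero counts in both groups are
#' reported as untested (keeping the BH denominator explicit) rather than
#' silently dropped.
#'
#' @param counts gene x sample count matrix.
#' @param meta sample metadata (`sample_id`, `day`, `condition`).
#' @param day the day at which to contrast hypoxia vs normoxia.
#' @param pseudocount added to the group means before the log2 ratio.
#' @return `InductionResult` data frame: `gene`, `mean_normoxia`,
#'   `mean_hypoxia`, `log2fc`, `p_value`, `padj`, `tested`.
#' @export
hypoxia_induction_test <- function(counts, meta, day, pseudocount = 0.5) {
  validate_counts(counts)
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  if (!day %in% meta$day) {
    stop(sprintf("day %s absent from sample metadata", format(day)),
         call. = FALSE)
  }
  sel <- meta$day == day
  cond <- meta$condition[sel]
  if (min(table(cond)) < 2L || length(unique(cond)) != 2L) {
    stop("need >= 2 replicates per condition at the chosen day", call. = FALSE)
  }
  norm <- normalize_counts(counts, size_factors(counts))[, sel, drop = FALSE]
  stab <- stabilize(norm)
  hyp <- cond == "hypoxia"
  tested <- rowSums(norm) > 0
  mean_h <- rowMeans(norm[, hyp, drop = FALSE])
  mean_n <- rowMeans(norm[, !hyp, drop = FALSE])
  lfc <- log2((mean_h + pseudocount) / (mean_n + pseudocount))
  p <- rep(NA_real_, nrow(counts))
  constant <- apply(stab, 1, function(v) stats::sd(v) == 0)
  p[tested & constant] <- 1  # identical values in both conditions
  pool <- tested & !constant
  if (sum(pool) >= 2L) {
    design <- stats::model.matrix(~hyp)
    fit <- limma::eBayes(limma::lmFit(stab[pool, , drop = FALSE], design),
                         trend = sum(pool) >= 10)
    p[pool] <- fit$p.value[, 2]
  } else if (sum(pool) == 1L) {
    g <- which(pool)
    p[g] <- stats::t.test(stab[g, hyp], stab[g, !hyp],
                          var.equal = TRUE)$p.value
  }
  res <- data.frame(gene = rownames(counts), mean_normoxia = mean_n,
                    mean_hypoxia = mean_h,
                    log2fc = ifelse(tested, lfc, NA_real_),
                    p_value = p, tested = tested,
                    row.names = NULL, stringsAsFactors = FALSE)
  res$padj <- NA_real_
  res$padj[res$tested] <- stats::p.adjust(res$p_value[res$tested], "BH")
  res
}

#' Relative expression by the 2^-DeltaCt method
#'
#' `DeltaCt = Ct_target - mean(Ct of the three reference genes)` per sample;
#' relative expression is `2^-DeltaCt`.
#'
#' @param ct long `CtTable` data frame: `sample_id`, `gene`, `ct`.
#' @param targets target gene ids; default: every non-reference gene present.
#' @param reference_genes the three reference-gene ids.
#' @return data frame `sample_id`, `gene`, `delta_ct`, `rel_expr`.
#' @export
#' @examples
#' ct <- data.frame(sample_id = "s1",
#'                  gene = c("RPLP0", "ACTB", "RPL13A", "EPO"),
#'                  ct = c(20, 21, 22, 20))
#' delta_ct(ct)  # DeltaCt = -1, rel_expr = 2
delta_ct <- function(ct, targets = NULL,
                     reference_genes = c("RPLP0", "ACTB", "RPL13A")) {
  stopifnot(all(c("sample_id", "gene", "ct") %in% names(ct)))
  if (length(reference_genes) != 3L) {
    stop("exactly three reference genes are required", call. = FALSE)
  }
  if (is.null(targets)) targets <- setdiff(unique(ct$gene), reference_genes)
  rows <- lapply(unique(ct$sample_id), function(s) {
    sub <- ct[ct$sample_id == s, ]
    ref <- sub$ct[match(reference_genes, sub$gene)]
    if (anyNA(ref)) {
      stop(sprintf("missing reference Ct for sample %s, gene %s", s,
                   paste(reference_genes[is.na(ref)], collapse = ", ")),
           call. = FALSE)
    }
    tg <- sub[sub$gene %in% targets, , drop = FALSE]
    if (!nrow(tg)) return(NULL)
    d <- tg$ct - mean(ref)
    data.frame(sample_id = s, gene = tg$gene, delta_ct = d,
               rel_expr = 2^(-d), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' PCA summary of the stabilised expression matrix
#'
#' Principal components of the samples on gene-centred stabilised values
#' (no unit-variance scaling: the dominant developmental trajectory is the
#' signal of interest). Diagnostics report the Spearman correlation of the
#' PC1 score with day, and the mean within-(day, condition) replicate
#' distance relative to the mean between-group distance.
#'
#' @param stabilized stabilised gene x sample matrix with >= 3 samples.
#' @param meta sample metadata.
#' @param n_pcs number of components to report.
#' @return list: `var_frac`, `scores` (data frame with meta columns),
#'   `pc1_day_cor`, `within_between_ratio`.
#' @export
pca_summary <- function(stabilized, meta, n_pcs = 5L) {
  if (ncol(stabilized) < 3L) stop("need >= 3 samples for PCA", call. = FALSE)
  meta <- meta[match(colnames(stabilized), meta$sample_id), ]
  centred <- stabilized - rowMeans(stabilized)
  pc <- stats::prcomp(t(centred), center = FALSE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- data.frame(sample_id = colnames(stabilized),
                       day = meta$day, condition = meta$condition,
                       pc$x[, seq_len(n_pcs), drop = FALSE],
                       row.names = NULL, stringsAsFactors = FALSE)
  grp <- interaction(meta$day, meta$condition, drop = TRUE)
  d <- as.matrix(stats::dist(pc$x))
  same <- outer(grp, grp, "==")
  diag(same) <- NA
  within <- mean(d[which(same)], na.rm = TRUE)
  between <- mean(d[which(!same)], na.rm = TRUE)
  list(var_frac = var_frac[seq_len(n_pcs)],
       scores = scores,
       pc1_day_cor = stats::cor(scores$PC1, meta$day, method = "spearman"),
       within_between_ratio = within / between)
}
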