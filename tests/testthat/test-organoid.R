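test_that("gene catalog and parameter validation catch bad configurations", {
  cat_ <- default_marker_catalog()
  expect_false(anyDuplicated(cat_$gene) > 0)
  bad <- cat_
  bad$role[1] <- "mystery"
  expect_error(organoid_sim_params(gene_catalog = bad), "unknown gene role")
  expect_error(organoid_sim_params(timepoints = c(0, 5, 3)), "increasing")
  expect_error(organoid_sim_params(n_replicates = 1), ">= 2")
  expect_error(organoid_sim_params(epo_hypoxia_gain = 1), "> 1")
  expect_error(organoid_sim_params(dispersion = 0), "> 0")
})

test_that("the mean model encodes the competence window and constant induction", {
  op <- organoid_sim_params()
  # window closed at day 19: peak-to-terminal ratio under hypoxia exceeds 10
  peak <- organoid_gene_mean("EPO", 12, "hypoxia", op)
  term <- organoid_gene_mean("EPO", 19, "hypoxia", op)
  expect_gt(peak / term, 10)
  expect_equal(term, organoid_gene_mean("EPO", 19, "normoxia", op))
  # normoxia EPO mean is flat across the grid
  expect_true(all(organoid_gene_mean("EPO", op$timepoints, "normoxia", op) ==
                    organoid_gene_mean("EPO", 0, "normoxia", op)))
  # hypoxia targets are induced by the same factor at every day
  ratio <- organoid_gene_mean("VEGFA", op$timepoints, "hypoxia", op) /
    organoid_gene_mean("VEGFA", op$timepoints, "normoxia", op)
  expect_equal(ratio, rep(op$hif_target_gain, length(op$timepoints)))
  expect_error(organoid_gene_mean("NOPE", 0, "normoxia", op), "not in catalog")
  # the rescaled window is exactly zero at the terminal day and one at the peak
  expect_equal(epo_competence_window(19), 0)
  expect_equal(epo_competence_window(12), 1)
})

test_that("count simulation is reproducible with negative-binomial moments", {
  op <- organoid_sim_params(seed = 5)
  sim <- simulate_organoid_counts(op)
  expect_equal(dim(sim$counts), c(nrow(op$gene_catalog), 60L))
  expect_true(all(sim$counts >= 0))
  expect_identical(sim$counts, simulate_organoid_counts(op)$counts)
  # moments: mean ~ mu and var ~ mu + phi mu^2 at many replicates
  op2 <- organoid_sim_params(n_replicates = 200L, timepoints = c(0, 19),
                             library_size_range = c(1, 1), dispersion = 0.05,
                             seed = 6)
  sim2 <- simulate_organoid_counts(op2)
  sel <- sim2$meta$day == 0 & sim2$meta$condition == "normoxia"
  x <- sim2$counts["VEGFA", sel]
  mu <- organoid_gene_mean("VEGFA", 0, "normoxia", op2)
  expect_equal(mean(x), mu, tolerance = 0.05)
  expect_equal(var(x), mu + 0.05 * mu^2, tolerance = 0.25)
})

test_that("size factors follow the median-of-ratios closed forms", {
  m <- matrix(c(2, 4, 10, 4, 8, 20), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(size_factors(m), c(s1 = 1 / sqrt(2), s2 = sqrt(2)))
  same <- cbind(s1 = c(5, 7, 9), s2 = c(5, 7, 9))
  rownames(same) <- letters[1:3]
  expect_equal(unname(size_factors(same)), c(1, 1))
  # genes with any zero are excluded from the reference set
  withzero <- rbind(m, d = c(0, 1000))
  expect_equal(size_factors(withzero), size_factors(m))
  allzero <- matrix(c(0, 1, 1, 0), 2, 2,
                    dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(allzero), "no gene has all-positive counts")
})

test_that("size factors are scale equivariant, idempotent and match DESeq2", {
  withr::with_seed(42, {
    m <- matrix(rpois(310, lambda = 80) + 1L, nrow = 31)  # odd gene count
    dimnames(m) <- list(paste0("g", 1:31), paste0("s", 1:10))
  })
  f <- size_factors(m)
  # scaling one sample by c scales its factor by c relative to the others
  # (the geometric-mean reference absorbs a common c^(1/n))
  m2 <- m
  m2[, 3] <- m2[, 3] * 4
  f2 <- size_factors(m2)
  rel <- f2 / f
  expect_equal(unname(rel[3] / rel[1]), 4, tolerance = 1e-9)
  expect_lt(max(abs(rel[-3] / rel[1] - 1)), 1e-9)
  # re-estimating on normalised counts gives a constant factor (the
  # geometric mean of the originals); rescaled, it is exactly one
  renorm <- size_factors(normalize_counts(m, f))
  expect_lt(diff(range(renorm)), 1e-9)
  expect_equal(unname(renorm / exp(mean(log(f)))), rep(1, 10),
               tolerance = 1e-9)
  skip_if_not_installed("DESeq2")
  expect_equal(unname(f),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("normalisation and stabilisation obey their unit identities", {
  m <- matrix(c(2, 4, 10, 4, 8, 20), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(normalize_counts(m, c(1, 1)), m)
  expect_equal(normalize_counts(m, c(2, 2)), m / 2)
  norm <- normalize_counts(m, size_factors(m))
  expect_equal(norm[, 1], norm[, 2])  # the 2x sample is equalised exactly
  expect_error(normalize_counts(m, c(1, 0)), "positive")
  expect_equal(stabilize(matrix(c(0, 1, 7), 1)), matrix(c(0, 1, 3), 1))
  expect_error(stabilize(matrix(-1)), "non-negative")
})

test_that("marker trajectories average genes then replicates and flag gaps", {
  op <- organoid_sim_params(seed = 9)
  sim <- simulate_organoid_counts(op)
  stab <- stabilize(normalize_counts(sim$counts, size_factors(sim$counts)))
  sets <- marker_sets_from_catalog(op$gene_catalog)
  tr <- markerset_trajectory(stab, sim$meta, sets)
  expect_true(all(tr$n == 3))
  expect_true(all(tr$sd >= 0))
  # on the noise-free mean surface the maturation set rises strictly from
  # day 7 to day 19
  exact <- stabilize(t(vapply(rownames(sim$counts), function(g) {
    organoid_gene_mean(g, sim$meta$day, sim$meta$condition, op)
  }, numeric(nrow(sim$meta)))))
  colnames(exact) <- sim$meta$sample_id
  trx <- markerset_trajectory(exact, sim$meta, sets)
  mmx <- trx[trx$set == "maturation_markers" & trx$condition == "normoxia", ]
  expect_true(all(diff(mmx$mean[mmx$day >= 7]) > 0))
  # constant genes give a flat trajectory at the stabilise-scale value
  const <- matrix(7, nrow = 2, ncol = ncol(stab),
                  dimnames = list(c("K1", "K2"), colnames(stab)))
  trc <- markerset_trajectory(rbind(stab, const), sim$meta, list(k = c("K1", "K2")))
  expect_true(all(trc$mean == 7))
  # absent genes are dropped with a warning; fully absent sets are reported
  expect_warning(
    tr2 <- markerset_trajectory(stab, sim$meta,
                                list(maturation_markers = c("ALB", "GHOST"),
                                     phantom = "NOT_THERE")),
    "GHOST")
  expect_equal(attr(tr2, "absent_sets"), "phantom")
  expect_error(markerset_trajectory(stab, sim$meta, list(a = "NOT_THERE")),
               "no catalog gene")
})

test_that("EPO trajectory summary recovers the window and its closure", {
  sim <- simulate_organoid_counts(organoid_sim_params(seed = 2))
  es <- epo_trajectory_summary(sim$counts, sim$meta)
  hyp <- es$per_condition[es$per_condition$condition == "hypoxia", ]
  expect_true(hyp$peak_day %in% c(11, 13))
  expect_lt(hyp$decline_ratio, 0.1)
  expect_false(es$late_induction)
  expect_error(epo_trajectory_summary(sim$counts, sim$meta, gene = "GHOST"),
               "GHOST")
  # constant gene: peak at the earliest day by the tie rule, ratio one
  cm <- matrix(50L, nrow = 2, ncol = 12,
               dimnames = list(c("EPO", "X"), paste0("s", 1:12)))
  meta <- data.frame(sample_id = paste0("s", 1:12),
                     day = rep(c(0, 7, 19), each = 4),
                     condition = rep(c("normoxia", "hypoxia"), 6),
                     replicate = rep(1:2, 6))
  esc <- epo_trajectory_summary(cm, meta)
  expect_true(all(esc$per_condition$peak_day == 0))
  expect_true(all(esc$per_condition$decline_ratio == 1))
})

test_that("induction testing handles degenerate genes and keeps BH honest", {
  sim <- simulate_organoid_counts(organoid_sim_params(seed = 4))
  counts <- rbind(sim$counts, ZERO = 0L)
  ind <- hypoxia_induction_test(counts, sim$meta, day = 19)
  z <- ind[ind$gene == "ZERO", ]
  expect_false(z$tested)
  expect_true(is.na(z$padj))
  # adjusted p >= raw p, bounded by one, BH reproducible by p.adjust
  ok <- ind$tested
  expect_true(all(ind$padj[ok] >= ind$p_value[ok]))
  expect_true(all(ind$padj[ok] <= 1))
  expect_equal(ind$padj[ok], p.adjust(ind$p_value[ok], "BH"))
  expect_error(hypoxia_induction_test(sim$counts, sim$meta, day = 5),
               "day 5 absent")
  # identical samples: every gene has log2FC 0 and p 1
  cm <- matrix(rep(c(5L, 40L, 0L, 200L), 6), ncol = 6,
               dimnames = list(c("A", "B", "Z", "C"), paste0("s", 1:6)))
  meta6 <- data.frame(sample_id = paste0("s", 1:6), day = 19,
                      condition = rep(c("normoxia", "hypoxia"), each = 3),
                      replicate = rep(1:3, 2))
  flat <- hypoxia_induction_test(cm, meta6, day = 19)
  expect_equal(flat$log2fc[flat$tested], rep(0, 3))
  expect_equal(flat$p_value[flat$tested], rep(1, 3))
  expect_false(flat$tested[flat$gene == "Z"])
})

test_that("the 2^-DeltaCt method reproduces its closed-form examples", {
  ct <- data.frame(sample_id = "s1",
                   gene = c("RPLP0", "ACTB", "RPL13A", "EPO", "ALB", "CYP3A4"),
                   ct = c(20, 21, 22, 20, 21, 22))
  out <- delta_ct(ct)
  expect_equal(out$rel_expr[out$gene == "EPO"], 2)     # DeltaCt = -1
  expect_equal(out$rel_expr[out$gene == "ALB"], 1)     # at the reference mean
  expect_equal(out$rel_expr[out$gene == "CYP3A4"], 0.5)
  missing_ref <- ct[ct$gene != "ACTB", ]
  expect_error(delta_ct(missing_ref), "s1.*ACTB")
})

test_that("PCA summary reflects the developmental gradient and duplicates", {
  # rank-1 gradient dominates PC1
  withr::with_seed(10, {
    grad <- seq(0, 5, length.out = 12)
    m <- outer(runif(40, 0.5, 2), grad) + matrix(rnorm(480, sd = 0.01), 40)
  })
  dimnames(m) <- list(paste0("g", 1:40), paste0("s", 1:12))
  meta <- data.frame(sample_id = paste0("s", 1:12), day = rep(1:6, each = 2),
                     condition = "normoxia", replicate = rep(1:2, 6))
  pc <- pca_summary(m, meta)
  expect_gt(pc$var_frac[1], 0.9)
  expect_gt(abs(pc$pc1_day_cor), 0.8)
  dup <- m
  dup[, 2] <- dup[, 1]
  sc <- pca_summary(dup, meta)$scores
  expect_equal(unname(unlist(sc[1, -(1:3)])), unname(unlist(sc[2, -(1:3)])))
  expect_error(pca_summary(m[, 1:2], meta[1:2, ]), ">= 3 samples")
  # on simulated organoids PC1 tracks the day
  sim <- simulate_organoid_counts(organoid_sim_params(seed = 12))
  stab <- stabilize(normalize_counts(sim$counts, size_factors(sim$counts)))
  pco <- pca_summary(stab, sim$meta)
  expect_gt(abs(pco$pc1_day_cor), 0.8)
  expect_lt(pco$within_between_ratio, 1)
})

test_that("plain-text round trips preserve lanes, cohorts and counts", {
  dir <- withr::local_tempdir()
  p <- cohort_sim_params(n_per_group = c(2L, 0L, 0L, 1L), seed = 2)
  cohort <- simulate_cohort(p)
  lp <- file.path(dir, "lanes.tsv")
  write_lanes(cohort$lanes, lp)
  expect_equal(read_lanes(lp), cohort$lanes, tolerance = 1e-9)
  cp <- file.path(dir, "cohort.csv")
  write_cohort(cohort$records[, -3], cp)  # group is re-derivable
  back <- read_cohort(cp)
  expect_equal(back$gestational_age_weeks, cohort$records$gestational_age_weeks,
               tolerance = 1e-9)
  sim <- simulate_organoid_counts(organoid_sim_params(seed = 2))
  np <- file.path(dir, "counts.tsv")
  write_counts(sim$counts, np)
  expect_equal(read_counts(np), sim$counts)
})
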