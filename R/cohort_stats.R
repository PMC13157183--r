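#' @title Cohort statistics for the hepatic-to-renal EPO switch
#' @description Age-group assignment, the 4 x 3 developmental-age x profile
#'   contingency table, the independence test with its exact/permutation
#'   fallback, proportion summaries, the oxygen-decoupling test and logistic
#'   maturation-parameter recovery.
#' @name cohort_stats
NULL

age_group_levels <- c("G1", "G2", "G3", "G4")
age_group_labels <- c("<=37", "(37,41]", "(41,49]", ">49")
profile_levels <- c("foetal", "mixed", "adult")

#' Assign developmental-age groups
#'
#' Half-open binning of developmental age (weeks): `da <= 37` is G1,
#' `37 < da <= 41` G2, `41 < da <= 49` G3, `da > 49` G4. Developmental age is
#' the sum of gestational age (weeks) and chronological age divided by 7
#' (exact days, no rounding to completed weeks).
#'
#' @param da developmental age(s) in weeks.
#' @return ordered factor with levels `G1 < G2 < G3 < G4`.
#' @export
#' @examples
#' assign_age_group(c(37, 41, 41.1, 56))
assign_age_group <- function(da) {
  if (any(!is.finite(da)) || any(da < 0)) {
    stop("developmental age must be finite and non-negative", call. = FALSE)
  }
  cut(da, breaks = c(-Inf, 37, 41, 49, Inf), labels = age_group_levels,
      right = TRUE, ordered_result = TRUE)
}

#' Developmental age of neonate records
#'
#' @param records data frame with `gestational_age_weeks` and
#'   `chronological_age_days`.
#' @return the records with `developmental_age_weeks` and `group` columns
#'   (re)derived.
#' @export
derive_developmental_age <- function(records) {
  need <- c("gestational_age_weeks", "chronological_age_days")
  if (!all(need %in% names(records))) {
    stop("records need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- !is.finite(records$gestational_age_weeks) |
    !is.finite(records$chronological_age_days) |
    records$chronological_age_days < 0
  if (any(bad)) {
    stop("invalid ages for subject(s): ",
         paste(records$subject_id[bad], collapse = ", "), call. = FALSE)
  }
  records$developmental_age_weeks <-
    records$gestational_age_weeks + records$chronological_age_days / 7
  records$group <- assign_age_group(records$developmental_age_weeks)
  records
}

#' Build the 4 x 3 age-group by profile contingency table
#'
#' @param records data frame with a `profile_class` column (values foetal /
#'   mixed / adult) and either a `group` column or the age columns needed by
#'   [derive_developmental_age()].
#' @return integer matrix, rows G1..G4, columns foetal / mixed / adult.
#' @export
build_contingency <- function(records) {
  if (nrow(records) == 0L) {
    tab <- matrix(0L, 4, 3, dimnames = list(age_group_levels, profile_levels))
    return(tab)
  }
  if (!"group" %in% names(records)) records <- derive_developmental_age(records)
  if (!"profile_class" %in% names(records) || anyNA(records$profile_class)) {
    miss <- if ("profile_class" %in% names(records)) {
      records$subject_id[is.na(records$profile_class)]
    } else records$subject_id
    stop("unclassified record(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  g <- factor(as.character(records$group), levels = age_group_levels)
  p <- factor(as.character(records$profile_class), levels = profile_levels)
  if (anyNA(p)) stop("unknown profile class in records", call. = FALSE)
  tab <- table(g, p)
  matrix(as.integer(tab), 4, 3, dimnames = list(age_group_levels, profile_levels))
}

#' Test independence of profile class and developmental-age group
#'
#' Pearson chi-square test of independence without continuity correction on
#' the rows (and columns) with non-zero totals. When the smallest expected
#' count falls below 5 the method switches, as is conventional, to an exact
#' or permutation test: Fisher's exact test for a 2 x 2 table, otherwise a
#' Monte-Carlo permutation null of the chi-square statistic with `B`
#' resamples (fixed row and column margins).
#'
#' @param tab contingency matrix, e.g. from [build_contingency()].
#' @param B permutation resamples for the r x c fallback.
#' @param seed optional seed for the permutation draw; `NULL` uses the
#'   session RNG stream.
#' @return list of class `association_result`: `method`, `statistic`, `df`,
#'   `p_value`, `expected`, `min_expected`.
#' @export
#' @examples
#' test_independence(matrix(c(10, 0, 0, 10), 2, 2))$statistic  # 20
test_independence <- function(tab, B = 10000L, seed = NULL) {
  tab <- as.matrix(tab)
  if (sum(tab) < 1) stop("contingency table has zero grand total", call. = FALSE)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  tab2 <- tab[keep_r, keep_c, drop = FALSE]
  if (nrow(tab2) < 2L || ncol(tab2) < 2L) {
    stop("need at least two non-empty rows and columns", call. = FALSE)
  }
  expected <- outer(rowSums(tab2), colSums(tab2)) / sum(tab2)
  min_expected <- min(expected)
  if (min_expected >= 5) {
    ct <- stats::chisq.test(tab2, correct = FALSE)
    res <- list(method = "chi_square",
                statistic = unname(ct$statistic),
                df = unname(ct$parameter),
                p_value = unname(ct$p.value))
  } else if (nrow(tab2) == 2L && ncol(tab2) == 2L) {
    ft <- stats::fisher.test(tab2)
    res <- list(method = "fisher_exact_or_permutation",
                statistic = NA_real_, df = NA_real_,
                p_value = unname(ft$p.value))
  } else {
    run <- function() stats::chisq.test(tab2, correct = FALSE,
                                        simulate.p.value = TRUE, B = B)
    ct <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    res <- list(method = "fisher_exact_or_permutation",
                statistic = unname(ct$statistic), df = NA_real_,
                p_value = unname(ct$p.value))
  }
  res$expected <- expected
  res$min_expected <- min_expected
  class(res) <- "association_result"
  res
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> %s: statistic = %s, df = %s, p = %.4g (min expected %.2f)\n",
              x$method, format(x$statistic, digits = 4),
              format(x$df), x$p_value, x$min_expected))
  invisible(x)
}

#' Per-group profile percentages
#'
#' Row-wise percentages of the contingency table, the data behind a
#' proportional (percentage-based) plot. Rows with zero total are excluded
#' and flagged.
#'
#' @param tab contingency matrix.
#' @return data frame `group`, `n`, one percentage column per profile class;
#'   attribute `excluded` lists zero-total groups.
#' @export
proportions_by_group <- function(tab) {
  tab <- as.matrix(tab)
  totals <- rowSums(tab)
  keep <- totals > 0
  pct <- sweep(tab[keep, , drop = FALSE], 1, totals[keep], "/") * 100
  out <- data.frame(group = rownames(tab)[keep], n = as.integer(totals[keep]),
                    pct, stringsAsFactors = FALSE, row.names = NULL)
  names(out)[-(1:2)] <- paste0(colnames(tab), "_pct")
  attr(out, "excluded") <- rownames(tab)[!keep]
  out
}

#' Oxygen-decoupling test: does profile class track chronological age within
#' developmental-age strata?
#'
#' Within each developmental-age stratum, chronological age is compared
#' across the observed profile classes by a rank test (Wilcoxon for two
#' classes, Kruskal-Wallis for three). Under the maturation hypothesis the
#' class carries no information about chronological age once developmental
#' age is fixed, so these tests should reject at the nominal rate only.
#' Classes with fewer than two records in a stratum are excluded from that
#' stratum's test (rank tests have no resolution at n = 1); strata left with
#' a single class are skipped with a notice. p-values are reported per
#' stratum without multiplicity correction (a Benjamini-Hochberg column is
#' exposed but secondary), mirroring the qualitative character of the claim.
#'
#' @param records classified records with `group` (or age columns),
#'   `chronological_age_days` and `profile_class`.
#' @param alpha rejection level used for the pooled summary.
#' @return list of class `decoupling_result`: `per_stratum` data frame
#'   (`group`, `n`, `n_classes_tested`, `p_value`, `p_bh`, `skipped`,
#'   `note`), `frac_rejected` (fraction of tested strata with
#'   `p < alpha`), `n_tested`.
#' @export
test_oxygen_decoupling <- function(records, alpha = 0.05) {
  if (!"group" %in% names(records)) records <- derive_developmental_age(records)
  if (!"profile_class" %in% names(records)) {
    stop("records must carry profile_class", call. = FALSE)
  }
  sizes <- table(factor(records$group, levels = age_group_levels))
  if (sum(sizes >= 4) < 2) {
    stop("need >= 2 strata with >= 4 records each", call. = FALSE)
  }
  rows <- lapply(age_group_levels, function(g) {
    sub <- records[records$group == g, , drop = FALSE]
    out <- data.frame(group = g, n = nrow(sub), n_classes_tested = 0L,
                      p_value = NA_real_, skipped = TRUE, note = "",
                      stringsAsFactors = FALSE)
    if (nrow(sub) < 4L) {
      out$note <- "fewer than 4 records"
      return(out)
    }
    cls <- table(sub$profile_class)
    keep_cls <- names(cls)[cls >= 2L]
    sub <- sub[sub$profile_class %in% keep_cls, , drop = FALSE]
    if (length(keep_cls) < 2L) {
      out$note <- "single profile class observed"
      return(out)
    }
    cls_f <- factor(sub$profile_class)
    p <- if (nlevels(cls_f) == 2L) {
      stats::wilcox.test(chronological_age_days ~ cls_f, data = sub,
                         exact = TRUE)$p.value
    } else {
      stats::kruskal.test(sub$chronological_age_days, cls_f)$p.value
    }
    out$n_classes_tested <- nlevels(cls_f)
    out$p_value <- p
    out$skipped <- FALSE
    out
  })
  per_stratum <- do.call(rbind, rows)
  tested <- !per_stratum$skipped
  per_stratum$p_bh <- NA_real_
  per_stratum$p_bh[tested] <- stats::p.adjust(per_stratum$p_value[tested], "BH")
  structure(list(
    per_stratum = per_stratum,
    frac_rejected = if (any(tested)) {
      mean(per_stratum$p_value[tested] < alpha)
    } else NA_real_,
    n_tested = sum(tested)
  ), class = "decoupling_result")
}

#' @export
print.decoupling_result <- function(x, ...) {
  cat("<decoupling_result> per-stratum rank tests of chronological age by profile class\n")
  print(x$per_stratum, row.names = FALSE)
  cat(sprintf("tested strata: %d; fraction with p < 0.05: %s\n",
              x$n_tested, format(x$frac_rejected, digits = 3)))
  invisible(x)
}

#' Recover the maturation logistic from a classified cohort
#'
#' Maximum-likelihood logistic regression of the binary response "foetal vs
#' not" on developmental age. The estimated midpoint is
#' `m_hat = -intercept / slope` (the developmental age at which the foetal
#' probability crosses one half) and the slope is reported as
#' `k_hat = -slope` so that a positive value means the foetal probability
#' falls with age. Wald confidence intervals come from the delta method;
#' under perfect separation (or a single observed class) the fit is flagged
#' and intervals are suppressed.
#'
#' @param records classified records with `developmental_age_weeks` and
#'   `profile_class`; needs >= 30 records spanning >= 10 weeks.
#' @param conf_level confidence level for the Wald intervals.
#' @return list of class `maturation_fit`: `m_hat`, `k_hat`, `m_ci`, `k_ci`,
#'   `converged`, `separation`, `n`.
#' @export
fit_maturation_logistic <- function(records, conf_level = 0.95) {
  if (!"developmental_age_weeks" %in% names(records)) {
    records <- derive_developmental_age(records)
  }
  da <- records$developmental_age_weeks
  if (nrow(records) < 30L || diff(range(da)) < 10) {
    stop("need >= 30 classified records spanning >= 10 weeks", call. = FALSE)
  }
  y <- as.integer(records$profile_class == "foetal")
  out <- list(m_hat = NA_real_, k_hat = NA_real_, m_ci = c(NA_real_, NA_real_),
              k_ci = c(NA_real_, NA_real_), converged = FALSE,
              separation = FALSE, n = length(y))
  class(out) <- "maturation_fit"
  if (length(unique(y)) == 1L) {
    out$separation <- TRUE
    return(out)
  }
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ da, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warned <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  b <- stats::coef(fit)
  out$m_hat <- unname(-b[1] / b[2])
  out$k_hat <- unname(-b[2])
  out$converged <- isTRUE(fit$converged)
  out$separation <- sep_warned
  if (!sep_warned && out$converged) {
    v <- stats::vcov(fit)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    # delta method for m = -b0/b1
    grad <- c(-1 / b[2], b[1] / b[2]^2)
    se_m <- sqrt(drop(t(grad) %*% v %*% grad))
    se_k <- sqrt(v[2, 2])
    out$m_ci <- out$m_hat + c(-1, 1) * z * se_m
    out$k_ci <- out$k_hat + c(-1, 1) * z * se_k
  }
  out
}

#' @export
print.maturation_fit <- function(x, ...) {
  cat(sprintf(
    "<maturation_fit> n = %d: midpoint %.2f wk [%.2f, %.2f], slope %.3f/wk [%.3f, %.3f]%s%s\n",
    x$n, x$m_hat, x$m_ci[1], x$m_ci[2], x$k_hat, x$k_ci[1], x$k_ci[2],
    if (x$separation) " (separation flagged)" else "",
    if (!x$converged && !x$separation) " (did not converge)" else ""))
  invisible(x)
}
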