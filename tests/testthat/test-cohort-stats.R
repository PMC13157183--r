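test_that("age groups use the documented half-open bins", {
  expect_equal(as.character(assign_age_group(c(37, 41, 41.1, 49, 49.01, 56))),
               c("G1", "G2", "G3", "G3", "G4", "G4"))
  expect_equal(as.character(assign_age_group(30 + 14 / 7)), "G1")
  expect_true(is.ordered(assign_age_group(40)))
  expect_error(assign_age_group(-1), "non-negative")
  rec <- data.frame(subject_id = "s1", gestational_age_weeks = 30,
                    chronological_age_days = 14)
  expect_equal(derive_developmental_age(rec)$developmental_age_weeks, 32)
  bad <- data.frame(subject_id = "s9", gestational_age_weeks = 30,
                    chronological_age_days = NA_real_)
  expect_error(derive_developmental_age(bad), "s9")
})

test_that("contingency tables count classified records exactly", {
  expect_equal(sum(build_contingency(data.frame())), 0L)
  one <- data.frame(subject_id = "a", group = factor("G1"),
                    profile_class = "foetal")
  tab <- build_contingency(one)
  expect_equal(tab["G1", "foetal"], 1L)
  expect_equal(sum(tab), 1L)
  un <- data.frame(subject_id = c("a", "b"), group = factor(c("G1", "G2")),
                   profile_class = c("foetal", NA))
  expect_error(build_contingency(un), "unclassified record.*b")
})

test_that("independence test reproduces closed forms and switches methods", {
  # identical row proportions: statistic 0, p 1
  same <- matrix(c(10, 10, 10, 20, 20, 20), nrow = 2, byrow = TRUE)
  r <- test_independence(same)
  expect_equal(r$method, "chi_square")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # 2x2 diagonal: N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)) = 20, df 1
  diag2 <- matrix(c(10, 0, 0, 10), 2, 2)
  r2 <- test_independence(diag2)
  expect_equal(r2$statistic, 20)
  expect_equal(r2$df, 1)
  expect_equal(r2$method, "chi_square")  # min expected exactly 5
  # min expected below 5: 2x2 goes to Fisher
  r3 <- test_independence(matrix(c(3, 1, 1, 3), 2, 2))
  expect_equal(r3$method, "fisher_exact_or_permutation")
  expect_true(r3$p_value >= 0 && r3$p_value <= 1)
  # r x c with small expected counts goes to the seeded permutation null
  small <- matrix(c(6, 1, 0, 5, 2, 1, 2, 4, 2, 0, 2, 7), nrow = 4, byrow = TRUE)
  r4 <- test_independence(small, seed = 5)
  expect_equal(r4$method, "fisher_exact_or_permutation")
  expect_lt(r4$min_expected, 5)
  expect_identical(r4$p_value, test_independence(small, seed = 5)$p_value)
  expect_error(test_independence(matrix(0, 2, 2)), "zero grand total")
})

test_that("chi-square statistic equals the brute-force sum over cells", {
  withr::with_seed(12, {
    for (i in 1:5) {
      tab <- matrix(rpois(12, lambda = 40), nrow = 4)
      r <- test_independence(tab)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      expect_equal(r$statistic, sum((tab - expected)^2 / expected),
                   tolerance = 1e-12)
      expect_equal(r$df, 6)
    }
  })
})

test_that("permutation p agrees with the chi-square p near the method boundary", {
  tab <- matrix(c(9, 5, 2, 5, 9, 2, 4, 5, 3, 6, 5, 2), nrow = 4, byrow = TRUE)
  expect_lt(min(outer(rowSums(tab), colSums(tab)) / sum(tab)), 5)
  perm <- test_independence(tab, B = 10000L, seed = 3)
  asym <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  expect_equal(perm$method, "fisher_exact_or_permutation")
  expect_lt(abs(perm$p_value - asym), 0.05)
})

test_that("group proportions sum to 100 and zero rows are flagged", {
  tab <- matrix(c(10, 10, 0, 0, 0, 0, 2, 1, 1, 0, 0, 4), nrow = 4,
                byrow = TRUE, dimnames = list(paste0("G", 1:4),
                                              c("foetal", "mixed", "adult")))
  pr <- proportions_by_group(tab)
  expect_equal(pr$group, c("G1", "G3", "G4"))
  expect_equal(unname(unlist(pr[1, 3:5])), c(50, 50, 0))
  expect_true(all(abs(rowSums(pr[, 3:5]) - 100) < 1e-9))
  expect_equal(attr(pr, "excluded"), "G2")
})

test_that("foetal proportion is non-increasing across age groups in most cohorts", {
  ok <- vapply(1:20, function(s) {
    rec <- classified_cohort(cohort_sim_params(seed = 400 + s))
    fp <- proportions_by_group(build_contingency(rec))$foetal_pct
    all(diff(fp) <= 0)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("oxygen-decoupling test skips degenerate strata and needs enough data", {
  rec <- classified_cohort(cohort_sim_params(seed = 7))
  rec$profile_class[rec$group == "G1"] <- "foetal"  # force a one-class stratum
  d <- test_oxygen_decoupling(rec)
  g1 <- d$per_stratum[d$per_stratum$group == "G1", ]
  expect_true(g1$skipped)
  expect_match(g1$note, "single profile class")
  expect_true(all(d$per_stratum$p_value[!d$per_stratum$skipped] >= 0))
  few <- rec[rec$group %in% c("G1", "G2"), ][1:5, ]
  expect_error(test_oxygen_decoupling(few), ">= 2 strata")
})

test_that("logistic recovery flags separation and finds a sharp midpoint", {
  rec <- classified_cohort(cohort_sim_params(seed = 3))
  rec$profile_class <- "foetal"
  fit <- fit_maturation_logistic(rec)
  expect_true(fit$separation)
  expect_true(all(is.na(fit$m_ci)))
  expect_error(fit_maturation_logistic(rec[1:10, ]), ">= 30")
  # near-step maturation: the midpoint lands within one inter-record gap of m
  p <- cohort_sim_params(n_per_group = c(125L, 125L, 125L, 125L),
                         logistic_slope = 50, maturation_jitter_sd = 0.25,
                         seed = 17)
  rec2 <- classified_cohort(p)
  fit2 <- suppressWarnings(fit_maturation_logistic(rec2))
  expect_lt(abs(fit2$m_hat - 43), 0.5)
  # a default-slope cohort recovers the midpoint with a sane CI
  rec3 <- classified_cohort(cohort_sim_params(
    n_per_group = c(125L, 125L, 125L, 125L), seed = 18))
  fit3 <- fit_maturation_logistic(rec3)
  expect_true(fit3$converged && !fit3$separation)
  expect_gt(fit3$k_hat, 0)
  expect_lt(fit3$m_ci[1], fit3$m_hat)
  expect_gt(fit3$m_ci[2], fit3$m_hat)
})
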