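# eposwitch

Simulation and analysis of the developmental switch of erythropoietin (EPO)
production from the foetal liver to the kidney.

At birth, EPO production moves from the liver to the kidney. Because
liver-derived and kidney-derived EPO carry different glycoforms, a plasma
sample separated by isoelectric focusing (IEF-PAGE, pH 2–6) reveals the
organ of origin: hepatic EPO concentrates in the basic gel region,
renal EPO in the neutral region. The question the analysis answers is
whether that switch tracks **developmental age** (gestational age +
chronological age/7, in weeks) or **oxygen exposure** (chronological age —
time since birth). The package is aimed at biostatisticians and
computational biologists who want the full chain — generative model, gel
signal processing, cohort statistics, organoid expression time course — as
tested, reproducible code operating on synthetic data with the structure
the analysis assumes.

## The model in brief

* **Maturation model.** The hepatic share of circulating EPO is a logistic
  in developmental age *a*:
  *h(a) = 1 / (1 + exp(k (a − m)))*, with midpoint *m* = 43 wk and slope
  *k* = 0.5 /wk, plus an independent subject-level maturation jitter
  (σ = 2 wk). Within each age stratum, developmental and chronological age
  are sampled independently, so the profile class is independent of oxygen
  exposure given developmental age — exactly the null the decoupling test
  probes.
* **Gel model.** A lane is a baseline + Gaussian-band + noise signal on a
  normalised acidic→basic coordinate; hepatic and renal band templates mix
  linearly with weight *h*. Bands are detected by prominence-thresholded
  peak calling on a baseline-corrected signal, regions are calibrated from
  reference-drug lanes, basic bands are indexed 1–6 from the neutral
  boundary, and each lane is classified **foetal** (top-3 bands at basic
  indices {3,4,5}), **mixed** ({2,3,4} or {1,2,3}) or **adult** (any top-3
  band in the neutral region).
* **Cohort statistics.** 4 age groups × 3 classes contingency table;
  Pearson chi-square without continuity correction, switching to Fisher's
  exact test (2×2) or a seeded permutation null when an expected count
  drops below 5; within-stratum rank tests of chronological age across
  classes; logistic recovery of the maturation midpoint.
* **Organoid model.** Negative-binomial counts over days 0–19 × two oxygen
  conditions × 3 replicates. EPO is hypoxia-inducible (gain 20) only inside
  a Gaussian competence window peaking at day 12 and pinned to zero at day
  19; HIF targets (VEGFA, EGLN3, NDRG1, PDK1, HK2) stay 4-fold inducible at
  every day. Analysis: median-of-ratios size factors, log2(x+1)
  stabilisation, marker-set trajectories, a moderated-t induction test at
  day 19 (limma), 2^−ΔCt quantification and PCA diagnostics.

## Worked example

The numbered scripts under `analysis/` run the whole study; the same can be
done in a few lines:

```r
library(eposwitch)

out <- cohort_pipeline(cohort_sim_params(seed = 20260927))
out$table
#>    foetal mixed adult
#> G1     34     0     0
#> G2     26     0     1
#> G3      3     6     7
#> G4      0     0    12
out$association
#> <association_result> fisher_exact_or_permutation: statistic = 95.76,
#>   df = NA, p = 9.999e-05 (min expected 0.81)
fit_maturation_logistic(out$records)
#> <maturation_fit> n = 89: midpoint 42.51 wk [41.13, 43.90],
#>   slope 0.814/wk [0.372, 1.255]
```

The table shows the foetal profile collapsing and the adult profile taking
over across the four developmental-age groups; the association p-value sits
at the permutation floor (10,000 resamples), far below 0.0001; and the
logistic fit recovers the generative midpoint of 43 weeks from the
classified lanes alone. The within-stratum decoupling test
(`test_oxygen_decoupling(out$records)`) finds no association between class
and chronological age once developmental age is fixed — the central claim.

For the organoid arm:

```r
sim <- simulate_organoid_counts(organoid_sim_params(seed = 20260927))
epo_trajectory_summary(sim$counts, sim$meta)$per_condition
#>  condition peak_day peak_mean terminal_mean decline_ratio
#>   normoxia       15     35.7          27.1         0.759
#>    hypoxia       11    526.1          29.6         0.056
```

Under hypoxia EPO peaks near day 11–13 at ~20-fold induction and collapses
to ~6% of peak by day 19, while `hypoxia_induction_test(sim$counts,
sim$meta, day = 19)` still calls all five HIF targets strongly induced
(log2FC ≈ 2, BH p < 1e-20) with EPO null — the selective, maturation-driven
loss of EPO competence.

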