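---
title: "Methods: simulating and analysing the hepatic-to-renal EPO switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing the hepatic-to-renal EPO switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eposwitch)
```

## The scientific question

Erythropoietin (EPO) is produced by the foetal liver and, after birth, by the
kidney. The two sources leave different fingerprints on the circulating
protein: liver-derived EPO carries glycoforms that focus in the *basic* part
of an IEF-PAGE gel (isoelectric focusing over a pH 2–6 gradient), whereas
renal EPO dominates the *neutral* zone. A lane's profile therefore reports
the organ of origin, and a cohort of neonates of varying gestational and
chronological ages can distinguish two hypotheses for the postnatal switch:

* **maturation**: the hepatic share is a function of *developmental age*
  (gestational age in weeks plus chronological age in days divided by 7);
* **oxygen exposure**: the hepatic share is a function of *chronological
  age*, i.e. of time spent breathing atmospheric oxygen.

This package rebuilds that analysis as a fully synthetic, testable pipeline,
plus the companion *in cellulo* arm: a liver-organoid differentiation time
course in which EPO is hypoxia-inducible only during a transient competence
window while canonical HIF targets stay inducible throughout.

## Cohort generator

### Maturation model

The hepatic fraction of circulating EPO follows a logistic in developmental
age $a$ (weeks):

$$h(a) = \frac{1}{1 + e^{k (a - m)}}, \qquad m = 43 \text{ wk}, \; k = 0.5
\text{ wk}^{-1}.$$

The midpoint and slope are free generative parameters; 43 weeks places the
transition shortly after term, consistent with foetal profiles dominating
below 37 weeks and adult profiles above 49 weeks. Each subject additionally
receives an independent maturation-tempo jitter
$\varepsilon_i \sim N(0, 2^2)$ weeks applied inside the logistic,
$h_i = h(a_i + \varepsilon_i)$. The jitter represents inter-individual
variation in developmental tempo (of the same order as the 37–42-week spread
of normal term birth) and is what makes the class composition change
*gradually* across age strata rather than switching at a hard threshold; it
is drawn independently of chronological age, so the defining property of the
maturation model — the profile carries no information about chronological
age once developmental age is fixed — holds exactly.

### Age sampling and the built-in decoupling

Subjects are drawn per stratum (at or below 37 weeks; 37–41; 41–49; over 49;
default sizes 34/27/16/12). Developmental age is uniform on the stratum, and
chronological age is uniform on the interval that keeps gestational age
$g = a - c/7$ inside its admissible range *for every developmental age in
the stratum*. Sampling the pair this way makes developmental and
chronological age exactly independent within each stratum — the
oxygen-decoupling test's null is true by construction, not merely
approximately. Chronological age runs up to 335 days (about 11 months), the
span needed for the oldest stratum to be reachable with gestational ages up
to 42 weeks.

An alternative generator (`oxygen_driven = TRUE`) replaces the maturation
logistic by a logistic of chronological age with midpoint 3 postnatal weeks
and slope 1.5/wk, i.e. a hepatic shutdown essentially complete by the sixth
postnatal week — the classical oxygen-exposure account. It exists to measure
the power of the decoupling test, not to model the study system.

### Lane rendering

A lane is a sampled signal over a normalised coordinate $x \in [0, 1]$
($x = 0$ most acidic). Band positions live on a fixed canonical grid — 3
acidic, 6 neutral and 6 basic slots — and the hepatic and renal components
contribute fixed intensity weights per slot: the hepatic template puts its
three heaviest bands at basic indices 3–5; the renal template puts its
dominant mass in the neutral slots with minor flanking bands. A lane with
hepatic weight $h$ mixes the two weight vectors linearly, rescales to unit
maximum (auto-exposure; the classifier is scale-invariant), renders each
band as a Gaussian of width $\sigma = 0.012$, and adds a slowly varying
polynomial baseline plus additive Gaussian noise (s.d. 0.015 of the lane
maximum) truncated at zero. Default lanes carry 15 bands, inside the 11–16
range typical of human EPO IEF profiles.

The template weights are free parameters (the source material describes band
positions categorically, not numerically). They were chosen once so that the
classification of the *mixed lane* changes foetal→mixed exactly at
$h = 0.5$ — i.e. at developmental age $m$, which ties the midpoint recovered
by the logistic fit to the generative midpoint — and mixed→adult near
$h \approx 0.31$. Two reference lanes (darbepoetin-like acidic anchor,
epoetin-like basic anchor) are rendered from the acidic and basic slots
only, with disjoint supports.

## Gel-lane analysis

`detect_bands()` works on one lane: (1) a light moving-average smoothing
over a window equal to `min_separation` (0.015 coordinate units by default —
the minimum resolvable band spacing; without it, point noise seeds spurious
local maxima); (2) baseline estimation as a rolling minimum over a window of
ten times `min_separation`, followed by a mean-smoothing pass of the same
width (a simple, monotone-safe estimator for a slowly varying optical
background); (3) peak calling: local maxima of the baseline-subtracted
signal whose topographic prominence reaches `min_prominence` (default 5%) of
the corrected maximum, thinned to a minimum apex separation, with band
bounds at the flanking minima; (4) band intensity as the trapezoidal area
between the bounds — an area measure is robust to band-width variation,
whereas apex height is not.

Regions come from the reference lanes: the acidic boundary is the most basic
acidic-reference band plus a margin $\delta = 0.02$; the basic boundary the
most acidic basic-reference band minus $\delta$; neutral is the exclusion of
both. Basic-region bands are indexed 1–6 *starting at the neutral boundary*
and increasing toward the basic extreme. The direction is a package
convention (the source describes numbering but not its direction): it puts
the mixed-profile sets {1,2,3} and {2,3,4} adjacent to the neutral zone,
where a partial renal contribution should sit.

Classification looks at the three most intense bands (ties broken toward the
more basic position): any top-3 band in the neutral — or acidic — region
means *adult*; all-basic sets {3,4,5} mean *foetal* and {2,3,4} or {1,2,3}
*mixed*; other all-basic sets (never produced by the templates, but possible
on unusual input) fall back to a median-index rule (median ≥ 4 foetal, else
mixed). Each call records which rule fired. A top-3 basic band without an
index (rank > 6) is an error, not a silent guess.

## Cohort statistics

* **Age groups** use half-open bins (≤ 37; (37, 41]; (41, 49]; > 49 weeks);
  the endpoint conventions are ours, documented rather than asserted.
  Developmental age uses exact days/7, never completed weeks.
* **Independence test**: Pearson chi-square without continuity correction on
  the non-empty rows/columns of the 4×3 table. When the smallest expected
  count is below 5 — the conventional operationalisation of "exact test
  where appropriate" — the method switches to Fisher's exact test (2×2) or a
  seeded Monte-Carlo permutation null of the chi-square statistic (10,000
  resamples, fixed margins) for larger tables. The permutation p-value is
  floored at $1/(B+1) \approx 10^{-4}$; at the default cohort size the
  observed statistic exceeds every permuted one, so the reported p sits at
  that floor.
* **Oxygen-decoupling test**: within each stratum, a rank test (Wilcoxon for
  two classes, Kruskal–Wallis for three) of chronological age across
  profile classes. Classes with fewer than two records in a stratum are
  excluded (a rank test has no resolution at $n = 1$), and strata left with
  one class are skipped with a notice. The per-stratum p-values are reported
  without multiplicity correction (a BH column is exposed but secondary),
  mirroring the qualitative nature of the claim; small-class strata make the
  test mildly conservative, which the calibration study in the test suite
  quantifies (rejection ≈ 0.04 at $\alpha = 0.05$).
* **Maturation recovery**: maximum-likelihood logistic regression of
  "foetal vs not" on developmental age; midpoint $\hat m = -\beta_0/\beta_1$
  with delta-method Wald intervals; perfect separation (including a
  single observed class) is flagged and intervals suppressed. Because the
  class boundary sits at $h = 0.5$ and the jitter is symmetric, $\hat m$
  estimates the generative midpoint consistently even though the link is
  probit-like rather than logistic.

## Organoid generator

Counts are negative-binomial, $\mathrm{NB}(L_s \mu_g(d, c),\ 1/\phi)$, on
the protocol grid (days 0, 2, 4, 7, 9, 11, 13, 15, 17, 19; normoxia and
hypoxia at 1% O$_2$; 3 replicates), with per-sample library factors
$L_s \sim U(0.8, 1.2)$ and dispersion $\phi = 0.01$ (tightly controlled
parallel differentiations; larger values are realistic for independent
batches and can be set per run). The mean model:

* **EPO**: base 30 under normoxia at every day; under hypoxia
  $30\,(1 + (G - 1)\,c(d))$ with gain $G = 20$ and competence window
  $c(d) = \max\{0, (w(d) - w(19))/(1 - w(19))\}$,
  $w(d) = e^{-(d - p)^2 / 2\sigma_w^2}$, peak $p = 12$, width
  $\sigma_w = 3$ days. The rescaling pins $c(19) = 0$: the window is closed,
  not merely small, at the end of differentiation.
* **HIF targets** (VEGFA, EGLN3, NDRG1, PDK1, HK2): induced 4-fold under
  hypoxia at *every* day — oxygen sensing never breaks.
* **Maturation markers** (ALB, CYP3A4, CYP3A7) and the synthetic
  population markers (two genes per hepatic population): monotone logistic
  rise in day with population-specific midpoints and amplitudes.
* **Transcription factors** (GATA4, GATA2, HNF4A, FOXA2): flat — none of
  them mirrors the EPO window, encoding the observation that no single
  factor explains the silencing.
* **Background**: 50 flat genes spanning 5–500 expected counts, plus the
  three qPCR reference genes (RPLP0, ACTB, RPL13A) at high expression. The
  filler is not cosmetic: median-of-ratios factors estimated from a
  marker-only catalog are measurably biased by the five induced genes (a
  composition effect that makes null genes look regulated at day 19), and
  the background keeps the multiple-testing burden and the variance-
  moderation pool honest.

`simulate_ct_table()` closes the qPCR loop: reference Cts at fixed offsets
around a base cycle, target Ct = reference mean − log2(relative
expression) + noise, so `delta_ct()` inverts it exactly at zero noise.

## Organoid analysis

Size factors are the classical median-of-ratios (geometric-mean
pseudo-reference over zero-free genes); a matrix with no zero-free gene is
an explicit error, not a silent fallback. The variance-stabilising transform
is $\log_2(x + 1)$ on normalised counts — a deliberate simplification of
model-based VSTs that keeps the monotonicity, 0 ↦ 0, and
trajectory/PCA behaviour the downstream summaries need.

The day-19 induction contrast reports the log2 fold change of condition
means of normalised counts with a 0.5 pseudocount, and p-values from a
moderated t-test (limma with an intensity-trended variance prior) on the
stabilised values, BH-adjusted across tested genes. A plain two-sample test
was evaluated first and rejected: with three replicates per condition the
Welch statistic has only 2–4 residual degrees of freedom, and the weakest of
the five HIF targets then fails a genome-wide BH threshold in roughly half
of the simulated experiments even at low dispersion — variance moderation
across genes is the standard remedy and restores full sensitivity without
touching specificity (EPO stays null). Genes with all-zero counts at the
tested day are reported as untested so the BH denominator is explicit;
genes constant across all samples get p = 1 by definition.

The EPO summary takes the per-condition replicate-mean trajectory of
normalised counts: peak day by argmax (ties to the earliest day), decline
ratio as terminal over peak mean, and a late-induction flag from the
induction test at the terminal day. PCA runs on gene-centred stabilised
values without unit-variance scaling (the dominant developmental trajectory
*is* the signal); diagnostics report the Spearman correlation of PC1 with
day and the within- versus between-group replicate distance.

## Problem sizes and what the tests show

The test suite and acceptance script run entirely on synthetic data at desk
scale: 20 cohorts of 89 lanes for the headline association; 200 lanes per
arm for classification fidelity; 200 null and 100 alternative cohorts
(classified by the noise-free template rule, which agrees with the rendered
pipeline away from class boundaries) for the decoupling calibration and
power; 100 cohorts of 500 for midpoint recovery; 100 organoid simulations
for the selective-decoupling property. These sizes give Monte-Carlo error
comfortably below the asserted margins while keeping the whole suite within
a few minutes on one core.

Passing tests show that the *pipeline* does what it claims on data with the
assumed structure. The generator deliberately omits much of what real data
contain: band positions never shift between gels (no warping or
lane-registration error), noise is homoscedastic and Gaussian, glycoform
chemistry is not modelled, organoid counts have no batch structure, no
sample swaps, and no read- or UMI-level artefacts. Results on real lanes or
real count matrices therefore depend on upstream quality control that this
package does not provide.

## Known limitations

* The basic-band numbering direction and the integrated-area intensity
  measure are conventions; lanes indexed under the opposite convention would swap
  the mixed-profile index sets.
* The permutation fallback bounds p from below at $1/(B+1)$; raise `B` if
  smaller p-values matter.
* The decoupling test is conservative in strata dominated by one class;
  its pooled "fraction of strata rejected" is a summary, not a formal
  combined test.
* `fit_maturation_logistic()` fits a logistic to what is generatively a
  probit-contaminated threshold; the midpoint is consistent, the slope
  estimate is attenuated relative to the template-free $k$.
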