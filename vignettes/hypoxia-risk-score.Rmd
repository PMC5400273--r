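---
title: "Methods: qPCR relative quantification and the hypoxia relapse risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qPCR relative quantification and the hypoxia relapse risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoxiscore)
```

This vignette documents the statistical model behind `hypoxiscore`, the
parameters that matter, the design choices made where the procedure was
genuinely open, what the synthetic-cohort generator does and does not
emulate, and the package's known limitations.

## The measurement model

Quantitative PCR reports, per gene $g$ and sample $s$, the threshold cycle
$Ct_{gs}$: the amplification cycle at which fluorescence crosses a fixed
threshold. One cycle is one doubling, so $Ct$ is (minus) log2 transcript
abundance plus a per-sample loading constant. Wells that never amplify are
*undetermined* and are kept as an explicit mask; wells with $Ct \ge 35$
cycles are treated as non-expressed and masked by
`apply_detection_cutoff()`. The boundary is inclusive — a well at exactly
35.0 is masked — because the cutoff is conventionally quoted as the value
*at* which a gene is called non-expressed; `inclusive = FALSE` flips this.
Masked raw cells and cutoff-masked cells are kept distinct up to that point
so the raw data stay lossless.

Normalization removes the loading constant. For reference set $R$,

$$\Delta Ct_{gs} = Ct_{gs} - \tfrac{1}{|R|}\sum_{r \in R} Ct_{rs},$$

the arithmetic mean of reference $Ct$s being the log2 geometric mean of the
linear reference quantities (standard ΔΔCt practice). Any additive
per-sample offset cancels exactly; this shift invariance is tested. Three
reference strategies are provided:

* **housekeeping** — the card's endogenous controls *RPL32* and *18S*;
* **stability_top_k** — the $k$ most stable genes of `stability_ranking()`,
  a model-based NormFinder-style score. Expression is first centered per
  sample; per gene and patient group the between-group bias $d_{gj}$
  (deviation of the group mean from the gene's overall mean) is shrunk
  toward zero by an empirical-Bayes factor
  $\tau^2/(\tau^2 + s^2_{gj}/n_j)$, where $\tau^2$ is the excess of the
  mean squared bias over its sampling variance (truncated at zero); the
  stability value averages $|\tilde d_{gj}| + s_{gj}/\sqrt{n_j}$ over
  groups, lower being more stable. With no groups it reduces to the
  per-gene standard deviation of sample-centered values. Ties are broken
  alphabetically so the ranking is total;
* **global_mean** — the per-sample mean $Ct$ of all measured genes plays
  the role of the reference, which equals the housekeeping strategy when
  the reference set is the whole panel (tested).

Relative quantification then centers each gene on a calibrator:
$\Delta\Delta Ct_{gs} = \Delta Ct_{gs} - C_g$ and
$RQ_{gs} = 2^{-\Delta\Delta Ct_{gs}}$. No calibrator sample is canonical
for this panel, so the default is the *cohort mean*: $C_g$ is gene $g$'s
mean ΔCt over samples, making each RQ a fold change versus the cohort
average and forcing the per-gene geometric mean of RQ to 1 (verified to
1e-10). A named calibrator sample is supported; which convention produced
any given published RQ table is generally unknowable, so both are
first-class. Masked cells propagate and are excluded pairwise downstream
rather than imputed — the smallest-assumption treatment for a 32-patient
cohort, at the cost of slightly varying per-gene n.

## Group comparisons and the fold convention

For a clinical dichotomy the per-gene effect is the ratio
$r = \bar{RQ}_{case}/\bar{RQ}_{control}$ of arithmetic mean RQs, reported
on the signed fold scale $f(r) = r - 1$ for $r \ge 1$, else $-(1/r - 1)$;
$f$ is antisymmetric under reciprocals, and $r = 2 \mapsto +1$,
$r = 0.5 \mapsto -1$. The "average overexpression" of a group is
$100 \times \operatorname{mean}_g(r_g - 1)$ percent (the mean of $f$ is
also reported, since the summary statistic behind such percentages is
ambiguous in the field).

Significance uses Welch's *t*-test on ΔCt — the log scale, where the noise
model is Gaussian — when Shapiro–Wilk at 0.05 does not reject normality in
either group, otherwise Kruskal–Wallis on RQ (rank-invariant, hence
monotone-transform invariant; tested). Both p-values are always retained in
the output so either column can be inspected; no rule for choosing between
the two tests is standard, so the gate is explicit and documented rather
than implicit. Raw p-values are the primary output (matching common
practice for small panels); a Benjamini–Hochberg column is emitted as a
clearly supplementary extra.

## Clustering

Patients are clustered on raw ΔCt profiles with Euclidean distance and
Ward's minimum-variance criterion in the classical barycenter formulation
(`hclust` method `ward.D2` on Euclidean distances, i.e. Ward on squared
distances; merge heights are checked against a naive
minimum-ΔSS agglomeration oracle in the tests). Whether genes should be
z-scored before the distance computation is an open choice; the default is
raw ΔCt (each cycle is a doubling, so genes are already on a common log
scale), with `standardize = TRUE` available. Masked cells are mean-imputed
per gene, with a warning, only inside the clustering step. Heatmap display
uses `median_center()` — per-gene median subtracted, sign flipped so
above-median expression is positive — which changes only the display, never
the labels. Cluster–relapse association is Pearson's χ² without continuity
correction; with expected counts below 5 a warning is raised and a Fisher
exact p is reported alongside as a supplementary column. Default cuts are
k = 2 on the full panel and k = 3 on the signature genes.

## Survival machinery

Relapse-free survival runs from diagnosis to local or distant recurrence,
in months; everything else is censoring (death without recurrence included
— a documented simplification). Curves are Kaplan–Meier product-limit
estimates via `survival::survfit`, with the standard tie convention
(events precede censorings). `survival_at()` is a right-continuous step
lookup returning both $S(t)$ and the cumulative incidence $1 - S(t)$,
flagged when extrapolating beyond follow-up. The two-group Mantel–Haenszel
(log-rank) test is implemented natively — it is the inner objective of the
cut-point search and is evaluated thousands of times per analysis — by
accumulating, over distinct event times, observed events against their
hypergeometric expectation and variance; p-values come from χ² on 1 df
without continuity correction, plus an O/E hazard-ratio summary. The native
statistic is verified in the tests against both explicit risk-table
enumeration and `survival::survdiff` to 1e-10, and its null rejection rate
is calibrated by simulation.

## The risk score

The score construction is deliberately elementary:

1. **Signature selection** — genes with p < 0.05 and positive fold in the
   recurrent-vs-non-recurrent comparison.
2. **Per-gene optimum threshold** — `optimal_cutpoint()` enumerates every
   midpoint between consecutive sorted distinct RQ values (an exhaustive,
   scale-free grid; "iterative approach" is not otherwise specified
   anywhere), keeps splits leaving at least `ceil(min_frac * n)` patients
   per side (default 10%, guarding against degenerate cuts), and returns
   the τ maximizing the log-rank statistic of the `RQ > τ` split. Ties go
   to the more balanced split, then to the smaller τ. The search is proven
   equal to independent exhaustive enumeration on 200 random instances in
   the acceptance tests.
3. **Scoring** — $S_p = \sum_g 1[RQ_{pg} > \tau_g]$, strictly greater
   (boundary equality scores 0), an integer in $0..k$; patients with masked
   signature genes are flagged incomplete. Raising an RQ can never lower a
   score (tested monotonicity).
4. **Score threshold** — every $s$ with both sides non-empty is profiled by
   the log-rank statistic of $S \le s$ vs $S \ge s+1$; the smallest
   maximizing $s$ is chosen (most inclusive high-risk group under ties),
   and the whole profile is returned.
5. **Evaluation** — per-group KM curves, log-rank p, O/E hazard ratio,
   cumulative incidence at 60 and 120 months, and Cronbach's
   $\alpha = \frac{k}{k-1}(1 - \sum_i \sigma^2_i / \sigma^2_{total})$ of
   the signature items, computed by default on standardized log2(RQ) so it
   reflects only the inter-gene correlation structure (raw-scale option
   available).

The published six-gene optima are packaged as
`published_threshold_table()` for scoring new cohorts without searching.

**Selection optimism.** Steps 2 and 4 are maximally selected statistics.
The in-sample log-rank p of the final split is therefore strongly
anti-conservative: the test suite's null-cohort property run (planted
effect zero, the full search pipeline applied) rejects at 0.05 far above
the nominal rate. No correction is applied, matching the original
procedure; every output that carries such a p labels it in-sample, and it
should be treated as descriptive. A reported hazard-type summary is the
O/E ratio, which is undefined or infinite when one group has no events —
as happens in exactly the situation the score is designed to produce
(a zero-event low-risk group) — so incidence ratios at fixed horizons are
reported alongside and no single "risk multiplier" is endorsed.

## The synthetic cohort generator

`simulate_cohort()` draws cohorts with the structure the analysis assumes,
plus ground truth, so every downstream stage is testable without patient
data. It emulates:

* log-normal expression: $Ct_{gs} = \mu_g + o_s - e_{gs}$ with per-sample
  loading offsets $o_s \sim N(0, 0.5^2)$ cycles (cancelled by
  normalization) and log2 expression $e_{gs} \sim N(\text{shift}_{gs},
  \sigma_g^2)$; targets get $\sigma = 1.5$ cycles, references 0.2 and no
  shifts;
* baseline abundances spanning cycles 22–31 (18S at 12, RPL32 at 20), with
  LEP at cycle 34 so a realistic fraction of its wells crosses the
  detection cutoff;
* covariate margins matching the 32-patient reference cohort (8/24 age,
  1/31 ER, 8/24 PR, 20/12 nodes, 7/24/1 stage, 25/7 grade dichotomy, 27/5
  HER2), drawn as exact counts, rescaled by largest remainder for other n;
* group shifts: +0.5 cycles on all targets in high-grade tumors and +3.7
  cycles on *HER2* in HER2+ tumors (coordinated overexpression in
  aggressive tumors, a strong single-gene HER2 effect);
* relapse: exponential proportional hazards
  $\lambda_s = \lambda_0 \exp(lp_s)$ with, in *linear* mode,
  $lp_s = \sum_g \beta_g z_{gs}$ on cohort-centered log2 expression of the
  signature genes ($\beta = 0.35$ by default), or in *threshold* mode
  $lp_s = \sum_g \beta_g 1[z_{gs} > c]$, a planted step at a known cut
  ($c = 1$, i.e. RQ = 2 versus the cohort mean) for direct recovery tests
  of the cut-point machinery — both plausible readings of how expression
  could drive relapse;
* censoring: administrative horizon 150 months plus independent
  exponential censoring at 0.002/month. The default baseline hazard
  $\lambda_0 = 0.0037$/month was chosen so the mean simulated event count
  matches the reference cohort's 14/32 recurrences under these settings.

Identical seed and configuration give a bit-identical cohort (tested).

It does **not** emulate: amplification-efficiency differences between
assays (the pure $2^{-\Delta\Delta Ct}$ model is assumed throughout, as in
the original analysis), correlated gene-gene expression beyond the planted
group shifts, covariate-covariate dependence (age, ER, PR, nodes, stage,
grade and HER2 are drawn independently), informative censoring, or
measurement artifacts such as plate effects beyond a global per-sample
offset. Passing recovery tests on these cohorts therefore shows the
*machinery* is correct and well calibrated, not that the biological signal
in any real cohort is as clean.

### Validation problem sizes

The test suite validates the machinery at sizes chosen to make the checks
sharp while staying quick: oracle equivalence of the cut-point search on
200 random instances (n ≤ 50); log-rank exactness on 100 random instances
and null calibration over 2 000 replicates (n = 100), plus 2 000
zero-effect generator cohorts for the end-to-end dichotomy calibration;
signature recovery over 50 planted-effect cohorts of n = 300 in threshold
mode with hazard ratio 6 per planted indicator and the cut at RQ = 2 —
a regime designed by an explicit power analysis to be unambiguously
"strong" (the study-sized default baseline hazard leaves unexposed
patients a ~40% relapse probability, which masks per-gene contrasts and is
deliberately *not* used for recovery testing); and cut-point recovery over
50 cohorts of n = 300 with a single planted gene.

## Known limitations

* With 32 patients the score threshold search can return extreme splits
  (e.g. a one-patient high-risk group); the per-candidate profile is
  returned so users can see how flat the objective is.
* The O/E hazard ratio degenerates when a group has zero events; use the
  reported fixed-horizon incidences in that case.
* Cronbach's α on standardized log2(RQ) measures correlation-based
  internal consistency; on six moderately correlated genes it is typically
  far below 1 and is sensitive to the normalization route.
* The NormFinder-style stability ranking is a faithful model-based
  reimplementation, not the original program; shrinkage details differ in
  inessential ways (documented above).
* No amplification-efficiency correction, no Cox regression, no competing
  risks, no treatment-interaction analysis.
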