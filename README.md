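# hypoxiscore

Hypoxia gene-expression relapse risk scoring from qPCR panels.

Solid breast tumors frequently contain poorly oxygenated regions, and the
transcriptional program driven by hypoxia-inducible factors (glycolytic
shift, angiogenesis, invasion, drug resistance) marks aggressive disease.
`hypoxiscore` implements, as a tested and reusable R pipeline, a prognostic
analysis of a 45-gene hypoxia panel measured by RT-qPCR (TaqMan low-density
arrays) in early-stage invasive breast cancer: relative quantification,
group-wise differential expression, unsupervised clustering, and the
construction and evaluation of a 6-gene relapse risk score. It is aimed at
biostatisticians and translational researchers who work with small qPCR
cohorts and relapse-free survival endpoints.

## What it computes

1. **Relative quantification (ΔΔCt).** Raw threshold cycles are masked at a
   detection cutoff (Ct ≥ 35), normalized against a reference level per
   sample — the housekeeping assays *RPL32* and *18S*, the most stable genes
   of a NormFinder-style model-based ranking, or the per-sample global mean —
   and converted to relative quantities
   RQ = 2<sup>−ΔΔCt</sup>, with the cohort-mean ΔCt per gene as the default
   calibrator.
2. **Fold-induction profiles.** For each clinical dichotomy (tumor stage 1
   vs 2–3, mSBR grade 1–3 vs 4–5, HER2−/+, non-recurrent vs recurrent), the
   per-gene ratio r of mean RQs is reported on the signed fold scale
   f(r) = r − 1 for r ≥ 1 and −(1/r − 1) otherwise (so +1 means 2-fold up,
   −1 means 2-fold down), with Welch *t* (on ΔCt) or Kruskal–Wallis (on RQ)
   p-values gated by a per-group Shapiro–Wilk test.
3. **Hierarchical clustering.** Patients are clustered on ΔCt profiles
   (Euclidean distance, Ward's barycenter criterion); cluster–relapse
   association is tested by Pearson's χ²; a median-centered matrix is
   provided for heatmap display.
4. **Relapse risk score.** Genes significantly overexpressed in recurrent
   patients form the signature (on the reference cohort: *EPO*, *ETS1*,
   *ENO1*, *PGK1*, *LDHA*, *TPI*). For each signature gene an optimum RQ
   threshold τ<sub>g</sub> is found by exhaustive search over midpoints of
   consecutive observed values, maximizing the two-group log-rank
   (Mantel–Haenszel) statistic of the resulting survival split. The patient
   score is the indicator sum S = Σ<sub>g</sub> 1[RQ<sub>g</sub> >
   τ<sub>g</sub>], and a score threshold s\* (the published analysis found
   s\* = 2) splits patients into low (S ≤ s\*) and high (S ≥ s\*+1) risk
   groups, summarized by Kaplan–Meier curves, the log-rank test, 5-/10-year
   cumulative relapse incidence, and Cronbach's α of the signature items.
   The published per-gene optima (EPO 7.10, ETS1 1.81, ENO1 1.00, PGK1 1.37,
   LDHA 1.20, TPI 1.14) ship as `published_threshold_table()` so new cohorts
   can be scored without re-searching.

A synthetic-cohort generator (`sim_config()` / `simulate_cohort()`)
reproduces the statistical structure this analysis assumes — log-normal RQ,
covariate margins of the 32-patient reference cohort, planted group shifts,
a proportional-hazards relapse model on the signature genes with censoring,
and full ground truth — so every stage is exercised and validated without
patient data.

**Caveat on in-sample p-values.** Per-gene thresholds and the score
threshold are maximally selected statistics. When they are optimized and
evaluated on the same cohort, the resulting log-rank p-values are strongly
anti-conservative (the test suite demonstrates this on null cohorts); treat
them as descriptive, not confirmatory.

## Worked example

```r
library(hypoxiscore)

cfg <- pipeline_config(simulate = sim_config(), seed = 11,
                       thresholds = "search")
res <- run_pipeline(cfg)
print(res)
print(res$risk)
```

```
pipeline_result: 32 patients, 47 genes, 14 events
signature: FOXO3A, PGK1, TPI
score threshold 2; low/high = 26/6; log-rank p = 1.342e-05; alpha = 0.597
risk groups at score threshold 2: low n = 26 (8 events), high n = 6 (6 events)
log-rank p = 1.342e-05 (in-sample, optimistic if thresholds were searched on this cohort)
  low-risk relapse rate by 60 months: 15.4%
  low-risk relapse rate by 120 months: 27.3%
  high-risk relapse rate by 60 months: 83.3%
  high-risk relapse rate by 120 months: 100.0% (extrapolated)
```

Reading this: the simulated 32-patient cohort had 14 relapses; three genes
passed the p < 0.05 + positive-fold selection against relapse on this
particular draw; the searched score threshold 2 puts 6 patients in the
high-risk group, whose 5-year cumulative relapse incidence (83.3%) vastly
exceeds the low-risk group's (15.4%). The log-rank p is in-sample and
therefore optimistic (see the caveat above). Scoring a cohort against the
published thresholds instead uses `thresholds = "published"` or
`compute_scores(rq, published_threshold_table())`.

To score a real cohort, supply a Ct table (wide `gene,S1,S2,...` or long
`gene,sample,ct`, `Undetermined` allowed) and a clinical CSV with columns
`sample_id,age_group,er,pr,nodes,stage,grade_msbr,her2,relapse,rfs_months`
via `pipeline_config(ct_path = ..., clinical_path = ...)`. A thin
command-line wrapper with `simulate` and `run` subcommands is installed at
`inst/cli/hypoxiscore.R`.

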