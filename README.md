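# dnbscore

Dynamic network biomarkers (DNBs) and a Cox-weighted risk score from
longitudinal plasma proteomics.

## The problem

When a tumor responds — or stops responding — to systemic therapy, the
patient's plasma proteome passes through something like a critical
transition. DNB theory predicts that near such a transition a small group
of molecules starts to behave distinctively: their cross-patient variance
rises sharply, their mutual correlation tightens, and their correlation
with the rest of the network weakens. `dnbscore` implements this analysis
for serial Olink-style NPX measurements collected at baseline (`D0`),
early on treatment (`D5`), during treatment (`DT`) and at progression
(`PD`, mapped to a last-time `LT` role), and carries the resulting
protein panel forward into a prognostic score for expression cohorts with
survival follow-up.

The package is aimed at translational statisticians analysing small
longitudinal trial cohorts: every stage is a plain R function returning a
classed object, the whole chain is reproducible from a single seed, and a
synthetic-cohort generator with planted structure stands in for
non-deposited patient data.

## Methods at a glance

**DNB detection** (`dnb_detect()`), using `D0` as the reference:

1. *Variance burst*: keep proteins whose cross-patient SD at **every**
   post-baseline time point is at least 2x the baseline SD.
2. *Profile standardization*: z-score each survivor's 4-point mean
   trajectory.
3. *Fuzzy c-means clustering* of the standardized profiles, with the
   cluster count chosen by silhouette and a merge fallback when the
   candidates form a single coherent cloud.
4. *Index-based selection*: per cluster, compute SDavg (mean member SD,
   post-baseline), PPCi (mean |Pearson r| within the cluster), PPCo
   (mean |Pearson r| between members and all other proteins), and the
   criticality index

   CI = SDavg x PPCi / PPCo.

   Clusters must fluctuate widely, change PPCi significantly and decrease
   PPCo (permutation-tested against `D0`); among those, the highest CI
   wins.

**Supervised selection** (`plsda()`, VIP >= 1): two-class PLS-DA
(NIPALS, autoscaled) of good vs poor responders on `D0` samples and on
all samples, with variable importance in projection

VIP_j = sqrt(p * sum_a SS_a w_aj^2 / sum_a SS_a),  so sum_j VIP_j^2 = p.

The **DNB panel** is the overlap of the winning cluster and the VIP
selection (`build_panel()`).

**DNBscore** (`build_score_model()`): panel genes are filtered by
tumor-vs-normal Wilcoxon differential expression (BH-adjusted) and by
univariate Cox regression (Breslow ties); each retained gene keeps its
log-hazard coefficient and subjects are scored as

score_i = sum_g beta_g * x_gi.

Scores are median-split (`median_stratify()`; "high" is strictly above
the median), compared by Kaplan–Meier/log-rank (`km_logrank()`), adjusted
for age and stage (`cox_multivariate()`), carried to external cohorts via
a reference-anchored location-scale batch adjustment (`adjust_batches()`),
cut at Youden's J for response classification (`response_cutoff()`), and
correlated with tumor-microenvironment cell fractions
(`fraction_correlation()`).

**Clinical summaries** (`call_responses()`, `efficacy_table()`,
`teae_summary()`, `escalation_state()`): RECIST 1.1 best-overall-response
calling from target-lesion sums (PR = >= 30% shrinkage from baseline,
PD = >= 20% growth over the nadir or new lesions), ORR/DCR tabulation,
worst-grade TEAE tables and modified 3+3 dose-escalation bookkeeping.

## Worked example

Simulate a 40-patient, 120-protein longitudinal cohort with a planted
12-protein DNB (3x variance amplification, intra-cluster correlation 0.7)
and detect it:

```r
library(dnbscore)
sim <- sim_longitudinal_npx(seed = 1)
det <- dnb_detect(sim$npx, seed = 1)
det
#> DNB detection: 12 of 120 proteins pass the 2 x SD filter
#>   clusters: 1 (merged: no separable profile structure)
#>   winning cluster:
#> DNB cluster C1 ( 12 proteins )
#>   SDavg = 3.493  PPCi = 0.738  PPCo = 0.124  CI = 20.805
#>   D0 reference: PPCi = 0.222  PPCo = 0.129
#>   criteria: fluctuation=pass  ppci_change=pass  ppco_decrease=fail
```

All 12 planted proteins are recovered: SDavg ~ 3.5 reflects the planted
variance burst, PPCi rises from 0.22 at baseline to 0.74 on treatment,
and CI ~ 21 dwarfs any background grouping. Intersect with the
responder-discriminant PLS-DA selection and build the score on a
synthetic tumor/normal survival cohort (true log-hazard 0.7 on three
panel genes):

```r
ctr <- run_group_contrasts(sim$npx)
panel <- build_panel(det$members, ctr$d0$selection)

sur <- sim_survival_cohort(seed = 2)
model <- build_score_model(sur$cohort, sprintf("G%03d", 1:12))
model
#> score_model: 3 gene(s) of 12 candidates retained (DE padj < 0.05, Cox p < 0.05)
#>  gene      beta
#>  G001 0.6146471
#>  G002 0.4067652
#>  G003 0.4766119

sc <- score_subjects(model, sur$cohort$expression[, sur$cohort$subject_id])
grp <- median_stratify(sc)
km <- km_logrank(sur$cohort$time, sur$cohort$event, grp)
sprintf("log-rank chi-square = %.1f, p = %.3g", km$chisq, km$p)
#> "log-rank chi-square = 215.4, p = 9.09e-49"

cox_multivariate(sur$cohort, grp)
#>              term        hr    ci_low  ci_high            p
#> 1 score_grouphigh 5.6719899 4.4113477 7.292889 1.001656e-41
#> 2             age 0.9969536 0.9874368 1.006562 5.329859e-01
#> 3           stage 0.9849155 0.9027748 1.074530 7.322816e-01
```

Only the DE-and-prognostic genes survive the two filters, the
median-split groups separate sharply, and the score is an independent
prognostic factor while the inert covariates sit at HR ~ 1.

The trial-style summaries run off plain CSV tables; the package ships
patient-level reconstructions of a published 11-patient dose-escalation
cohort under `inst/extdata/`:

```r
les <- read.csv(system.file("extdata", "lesions_reconstructed.csv",
                            package = "dnbscore"))
efficacy_table(call_responses(les))[c("orr_pct", "dcr_pct")]
#> $orr_pct 36.4
#> $dcr_pct 72.7
```

A one-command pipeline (`run_pipeline("all", config)`) chains every stage
from simulation to the clinical tables, writes CSV outputs plus a JSON
manifest of settings, checksums and filter counts, and is byte-for-byte
reproducible given a seed. `inst/cli/dnb_pipeline.R` wraps it for shell
use.

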