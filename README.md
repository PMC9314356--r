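# polyresilience

Polygenic **resilience** scores for late-onset Alzheimer's disease (LOAD):
a tested R pipeline for finding and evaluating common variants that buffer
high polygenic risk.

## The problem

Genome-wide association studies describe who is at *risk* of LOAD. But some
people sit in the top tier of polygenic risk — often carrying *APOE*-e4 —
and still reach old age unaffected. This package implements the
complementary question as a reusable analysis: do risk-independent common
variants, aggregated into a polygenic resilience score, distinguish
unaffected high-risk individuals ("resilient") from affected individuals
with the same measured risk ("risk-matched cases")?

It is aimed at statistical geneticists who want the whole workflow —
simulation, scoring, stratification, association, meta-analysis, LD
filtering, evaluation — as composable, unit-tested R functions rather than
a chain of shell scripts.

## The method in brief

For person $i$ with effect-allele dosages $g_{ij}$ and external risk-GWAS
weights $\hat\beta_j$ (included at $P < 0.5$):

$$\mathrm{PRS}_i = \sum_j \hat\beta_j\, g_{ij}$$

- **Design 1:** controls at or above the 90th within-study PRS percentile
  of controls are *resilient*; cases with PRS in
  $[\text{cutoff}, \max(\text{control PRS})]$ are *risk-matched*.
- **Design 2:** same idea among *APOE*-e4-like carriers at the 80th
  percentile of a PRS with chr19:44.4–46.5 Mb excised.
- A per-study logistic **resilience GWAS** (resilient vs risk-matched, with
  age, sex and PC covariates) is meta-analyzed with DerSimonian–Laird
  random effects and per-study genomic control.
- Variants with risk $P < 0.5$, and anything in LD with them
  ($r^2 \ge 0.2$ within 1 Mb), are excluded; survivors are LD-clumped. A
  hard *risk-orthogonality certificate* re-checks this after every run.
- **Resilience scores** at ten nested P-value thresholds are standardized
  within study and evaluated in held-out replication studies: pooled OR per
  score SD, 95% CI, P, and Nagelkerke pseudo-$R^2$ converted to the
  liability scale.

Because the real cohorts are access-restricted, the package includes a
liability-threshold simulator (multi-study case-control cohorts, an
*APOE*-like major locus, resilience variants active only above a genetic
risk quantile) and a machine-readable copy of the published per-study
accounting table for exact bookkeeping checks. See the vignette
(`vignettes/polygenic-resilience.Rmd`) for models, assumptions and
parameter rationale.

## Worked example

```r
library(polyresilience)
cfg <- sim_config(n_studies = 7, n_variants = 1500, seed = 1)
report <- run_pipeline(cfg, design = 1, n_replication = 3)
report
```

Output (abridged; ~15 s):

```
<resilience_report design 1: 4 discovery + 3 replication studies>

Sample accounting:
   study n_highrisk n_controls n_riskmatched n_cases pct_controls_retained pct_cases_retained
1 STUDY1        100       1000           502    1000                    10               50.2
...
8  Total        700       7000          3616    7000                    10               51.7

1500 meta-analyzed variants -> 723 marginal after risk exclusion + clumping

Per-threshold evaluation (replication meta-analysis):
   threshold n_snps n_studies  lnor     se   or ci_lower ci_upper        p   r2_liab_pooled
5      1e-02     10         3 0.312 0.0760 1.37     1.18     1.59 4.07e-05           0.0555
7      1e-01     62         3 0.216 0.0643 1.24     1.09     1.41 7.71e-04           0.0241
10     5e-01    333         3 0.178 0.0646 1.19     1.05     1.36 5.97e-03           0.0165
```

Reading it: each study keeps its top 10% of controls as resilient (100 of
1000) and about half its cases as risk-matched. After risk-orthogonal
filtering, 723 marginal variants remain. In the three held-out studies the
resilience score at the 0.1 threshold has pooled OR 1.24 per SD
(95% CI 1.09–1.41): higher resilience scores raise the odds of being a
resilient high-risk control rather than a risk-matched case, explaining
about 2.4% of liability-scale variance in this simulated world. With
`resilience_gamma = 0` the same pipeline returns ORs scattered around 1 —
the null behaviour the test suite checks over 20 seeds.

A command-line interface covers the same stages
(`inst/cli/polyresilience simulate|prs|stratify|gwas|meta|prune|score|pipeline ...`).

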