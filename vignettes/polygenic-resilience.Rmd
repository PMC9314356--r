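---
title: "Polygenic resilience scores for late-onset Alzheimer's disease: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic resilience scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyresilience)
```

## The problem

Some people carry a heavy burden of common risk alleles for late-onset
Alzheimer's disease (LOAD) and nevertheless reach old age cognitively
unaffected. The working hypothesis behind this package is that part of that
protection is itself polygenic: common variants, *statistically independent
of known risk variants*, that reduce the penetrance of a high polygenic risk
load. A polygenic **resilience score** aggregates such risk-orthogonal
variants the same way a polygenic risk score (PRS) aggregates risk alleles.

The package implements the whole analysis as a tested pipeline:

1. **Risk scoring.** A PRS per person from external risk-GWAS weights,
   $PRS_i = \sum_j \hat\beta_j g_{ij}$, at the deliberately permissive
   inclusion threshold $P < 0.5$ (the threshold at which LOAD PRS
   performance is reported to peak, and which later guarantees that any SNP
   *not* used for risk scoring has shown essentially no risk association).
2. **Stratification.** Within each study, unaffected controls in the top
   PRS tier are labelled *resilient*; affected cases whose PRS falls inside
   the resilient controls' score range are *risk-matched cases*. Design 1
   uses the 90th percentile of controls on the genome-wide PRS; design 2
   restricts to APOE-e4-like carriers and uses the 80th percentile of an
   APOE-excised PRS (chr19:44.4-46.5 Mb removed).
3. **Resilience GWAS.** Per study, logistic regression of group membership
   (resilient = 1 vs risk-matched case = 0) on allele dosage with age, sex
   and principal-component covariates, then DerSimonian-Laird random-effects
   inverse-variance meta-analysis with per-study genomic control.
4. **Risk orthogonalization.** Every variant with risk $P < 0.5$, and every
   variant in LD ($r^2 \ge 0.2$ within 1 Mb) with such a variant, is
   excluded; the survivors are greedily LD-clumped. This is deliberately
   conservative: resilience SNPs must not be sub-threshold risk SNPs in
   disguise, at the price of discarding most of the genome.
5. **Scoring and evaluation.** Resilience scores at ten nested P-value
   thresholds ($5\times10^{-8}$ to $0.5$), standardized within study, are
   evaluated in held-out replication studies by logistic regression; lnORs
   are meta-analyzed (random effects), and Nagelkerke pseudo-$R^2$ values
   are converted to the liability scale and pooled with the meta weights.
6. **Risk-resilience interplay.** Pearson correlation between PRS and
   resilience score in controls vs cases, compared with a one-tailed
   Fisher-z test after excluding ultra-high-risk cases (PRS above every
   control) and ultra-low-risk controls (PRS below every case).

Real LOAD cohorts are access-restricted, so the package ships a simulator
whose outputs exercise every stage, plus a machine-readable copy of the
published per-study accounting table for exact bookkeeping checks.

## The generative model

`sim_config()` states the simulated world. Liability of individual $i$ is

$$L_i = G_i + \varepsilon_i, \qquad
  G_i = \sum_j \beta_j g_{ij} + \beta_M g_{iM}, \qquad
  \varepsilon_i \sim N(0,1),$$

with $\beta_j \sim N(0, \texttt{risk\_beta\_sd}^2)$ over
`n_risk_snps` variants and a major-effect locus (frequency 0.2, effect
$\beta_M = 1.0$) standing in for APOE-e4, placed at chr19:45,400,000 so the
design-2 region excision removes it. Disease occurs iff $L'_i > T$, where

$$L'_i = L_i - \mathbb{1}\!\left[G_i > q_{0.8}(G)\right]
         \sum_k \gamma \,(g_{ik} - 2p_k)$$

and $T$ is calibrated by Monte Carlo (50,000 reference draws) so the
*pre-resilience* affection rate equals the prevalence $K = 0.15$.

Design choices that deserve comment:

* **Resilience is conditional.** The protective term only applies above the
  0.8 quantile of genetic risk. This is the minimal generative model making
  resilience statistically independent of risk: resilience variants carry no
  marginal risk effect, and their protective effect exists only where there
  is risk to buffer.
* **The load is centered.** We subtract $\gamma(g - 2p)$, not $\gamma g$.
  Subtracting the raw load would shift the whole high-risk stratum down by
  its mean ($\approx 1.4$ liability units at defaults), making high-risk
  individuals *less* likely to be affected than average — an incoherent
  world that also breaks the prevalence calibration. Centering preserves the
  per-allele effect $\gamma$ and the stratum's mean liability.
* **Calibrated effect sizes.** $\gamma = 0.21$ was calibrated once by
  simulation so that the per-allele odds ratio contrasting unaffected vs
  affected individuals *within the high-risk stratum* is 1.30, the effect
  size the package's signal-recovery suite states. Likewise
  `risk_beta_sd = 0.15` and $\beta_M = 1.0$ were chosen so the design-1
  stratification behaves like the published accounting: 10% of controls are
  resilient by construction, and roughly 30% of cases are risk-matched.
  The published figure is 69.3%; that value reflects APOE dominating the
  real PRS and is not reachable by a well-behaved additive architecture, a
  gap we document rather than chase.
* **LD is block-structured.** Variants come in blocks of `ld_block_size = 4`
  with a shared Gaussian-copula factor (`ld_block_r = 0.4`), giving typical
  within-block dosage $r^2$ around 0.05-0.1 with a tail above 0.2. The LD
  exclusion and clumping rules are therefore exercised but not dominant in
  pipeline runs; crafted high-LD fixtures in the unit tests probe the rules
  sharply. Realistic LD maps from reference haplotypes are out of scope.
* **Covariates are noise.** Principal components are standard-normal noise
  (no population structure is simulated); ages are uniform on 60-90 for
  both AAO (cases) and AAE (controls), matching the report of no group age
  differences and exercising the AAO/AAE >= 60 filter. Sex is Bernoulli(0.5).
* **The prior risk GWAS is emulated**, not re-estimated: reported betas are
  the true liability-scale effects plus noise with SD equal to the standard
  error implied by `n_effective` (default 50,000) and the panel allele
  frequency, $SE = 1/\sqrt{2p(1-p)n}$. Null variants get pure noise, so
  roughly half of all null variants show risk $P < 0.5$ and are excluded
  from resilience scoring — the same behaviour the real filter exhibits.
* **Alleles are never strand-ambiguous** in simulated maps, so the
  harmonization rule that drops palindromic (A/T, C/G) variants — the
  conservative standard when strand provenance is unknown — never bites on
  simulated data; it is tested on explicit fixtures.

What a green simulation-based test does **not** establish: performance on
imputed genotypes with realistic LD and allele-frequency spectra, behaviour
under population stratification, or the published effect sizes themselves
(the real cohorts are restricted-access; the published headline statistics
are directional references only, and the package's exact reproduction
claims are limited to the printed accounting totals).

## Statistical components and conventions

* **Percentiles** use the strict-below rule,
  $100 \cdot \#\{\text{population} < s\}/N$, computed against a stated
  ranking population (controls). Ties share a percentile, and ">= cutoff" is
  inclusive, so selection under ties is deterministic. Case matching uses
  the control-derived score interval $[\text{cutoff}, \max(\text{control
  PRS})]$, not case percentiles.
* **Degenerate studies are dropped, not fatal**: a study with fewer than two
  resilient controls or two matchable cases is excluded with a logged
  reason (the published analysis drops one such study in design 2).
* **Per-variant logistic GWAS** is IRLS in compiled code (RcppArmadillo),
  max 100 iterations, coefficient-change tolerance $10^{-8}$; monomorphic
  variants are skipped; quasi-separation is flagged by a coefficient
  diverging past $|\beta| > 20$ and the variant skipped, never errored.
  The evaluation regressions (one score per study) use `stats::glm`.
* **Genomic control**: $\lambda = \text{median}(z^2)/0.4549$; SEs are
  inflated by $\sqrt\lambda$ only when $\lambda > 1$, applied per study
  before meta-analysis (the convention of per-study correction was chosen
  where the source is ambiguous).
* **Random effects**: DerSimonian-Laird,
  $\tau^2 = \max\!\big(0, (Q - (k-1))/(\sum w - \sum w^2/\sum w)\big)$,
  CI multiplier 1.96, two-sided normal P-values throughout. The reference
  implementation the published analysis used (`metafor`) is not available
  in this environment; the DL arithmetic is implemented directly and
  verified against an independently coded oracle. Wald P-values are clamped
  at $10^{-300}$ to respect the $p > 0$ validity invariant.
* **Meta-GWAS policy**: union of variants across studies (configurable
  minimum), orientation harmonized to the first study carrying each
  variant, irreconcilable allele pairs dropped with a logged count.
* **Nagelkerke $R^2$** uses the covariate-only model as its null, so it
  measures the score's increment, and is converted to the liability scale
  with the standard threshold-model factor
  $K(1-K)/z^2 \cdot K(1-K)/(P(1-P))$; the ascertainment term is applied by
  default and can be disabled. The "prevalence of resilience" $K$ is not
  defined by the source; the default is the pooled proportion of resilient
  individuals among all high-risk samples, overridable.
* **Clumping** reuses the exclusion thresholds ($r^2 \ge 0.2$, 1 Mb,
  inclusive window on $|{\Delta}pos|$) since the published clumping
  parameters are unavailable; ties on P break by (chromosome, position).
  The LD reference for simulated runs is the union of the discovery-study
  genotypes.
* **Ten thresholds** ($5\times10^{-8}$, $10^{-5}$, $10^{-4}$, $10^{-3}$,
  0.01, 0.05, 0.1, 0.2, 0.3, 0.5): the source names only 0.1 and 0.2; the
  series includes both and is overridable. Threshold sets are nested, so
  per-threshold P-values are strongly correlated; no multiplicity
  correction is applied by default, and none of the package's conclusions
  rest on treating the thresholds as independent.
* **Risk-orthogonality certificate**: after every pipeline run the package
  asserts that no scored variant has risk $P < 0.5$ nor $r^2 \ge 0.2$
  within 1 Mb of any such variant. A violation is a hard error, not a
  warning.
* **Evaluation covariates** default to the same set as the discovery GWAS
  (age, sex, all simulated PCs); whether the published evaluation used the
  identical "selected" PCs is unknown, so the set is a single configurable
  knob used consistently in both places.

## Worked example

```{r example, eval = FALSE}
library(polyresilience)
cfg <- sim_config(n_studies = 4, n_cases_per_study = 500,
                  n_controls_per_study = 500, n_variants = 1000, seed = 42)
report <- run_pipeline(cfg, design = 1, n_replication = 2)
report            # accounting, per-threshold OR/R2 table, correlation
```

The per-threshold table mirrors the published evaluation figure: one row
per threshold with the number of SNPs, the pooled OR per score SD with its
95% CI and P, and the pooled observed- and liability-scale $R^2$. OR > 1
means higher resilience scores increase the odds of being a resilient
high-risk control rather than a risk-matched case.

## Validation strategy

The test suite distinguishes three kinds of evidence:

* **Exact bookkeeping**: the bundled per-study accounting fixture must
  reproduce all eight printed grand-total percentages to the printed
  decimal.
* **Oracle equivalence**: the logistic GWAS against the closed-form Woolf
  2x2 estimator and an independent Newton-Raphson fit; DL meta against its
  formulas; $r^2$, percentile ranking and clumping against brute-force
  re-implementations.
* **Statistical behaviour over 20 fixed seeds**: with $\gamma = 0$ the
  pooled evaluation P rejects at the nominal 5% rate (within the binomial
  95% band); with the calibrated $\gamma$ the pooled OR at the
  signal-bearing threshold (the smallest threshold containing at least half
  of the surviving injected SNPs) exceeds 1 at $P < 0.05$ in the majority
  of seeds. The null suite runs at the stated 4x2000x5000 scale; the
  signal suite uses 7 studies of 2000 at 1,500 variants, sized a priori by
  a power analysis, not tuned post hoc.

## Known limitations

* The simulator's LD is piecewise-block and its allele-frequency spectrum
  uniform; neither resembles real imputed data in detail.
* Risk-matched case fractions plateau near 30% at defaults, well below the
  published 69.3% (see above); accounting *totals* are checked against the
  bundled printed table instead.
* DerSimonian-Laird with two or three replication studies is known to be
  slightly anticonservative; the null-calibration suite bounds the damage
  empirically but small-$k$ refinements (Hartung-Knapp) are out of scope.
* Design-2 percentiles are computed within carrier controls (the figure
  caption's reading); the alternative reading (percentiles among all
  controls) is not implemented.
* No clumping is applied to the *risk* PRS (the published supplement that
  would settle this is unavailable); the risk PRS is a plain threshold
  score, and this is configurable nowhere because nothing downstream
  depends on it.
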