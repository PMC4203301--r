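---
title: "Methods: heterozygosity-fitness correlations with capture-mark-recapture survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterozygosity-fitness correlations with capture-mark-recapture survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Heterozygosity-fitness correlations (HFCs) ask whether an individual's
multilocus marker heterozygosity predicts a fitness component — here,
first-year survival in a long-term annually trapped wild mammal population.
Three mechanisms are usually distinguished: *general* effects (variance in
genome-wide inbreeding makes marker heterozygosity a proxy for the
inbreeding coefficient *f*), *local* effects (linkage of particular markers
to fitness loci), and *direct* effects of the scored loci. `hfcsurv`
implements the full analytical chain needed to separate these on annual
capture-mark-recapture data: heterozygosity estimators, pedigree
inbreeding, identity-disequilibrium statistics, Cormack-Jolly-Seber (CJS)
survival models with quasi-likelihood multimodel inference, and a synthetic
population generator that provides ground truth for every step.

# Heterozygosity measures

All three standard microsatellite measures are computed over an
individual's *typed* loci only; missing calls are first-class and never
zero-filled.

* **SH** (standardized heterozygosity): proportion of typed loci
  heterozygous, divided by the mean population observed heterozygosity of
  those same loci. Individuals typed at every locus have mean SH 1 by
  construction.
* **HL** (homozygosity by locus): expected-heterozygosity-weighted
  homozygosity, `sum(E_hom) / (sum(E_hom) + sum(E_het))`, where a locus's
  weight is its expected heterozygosity `1 - sum(p^2)`. Ranges 0 (fully
  heterozygous) to 1.
* **IR** (internal relatedness): `(2H - sum f) / (2N - sum f)` with `H`
  homozygous typed loci, `N` typed loci and `sum f` the summed population
  frequencies of the individual's 2N allele copies; rare-allele
  homozygotes are up-weighted. Ranges -1 to +1 in the canonical two-allele
  case.

The population frequencies behind SH/HL/IR always come from the full
genotype table, reflecting standardization against the study population.
Expected heterozygosity in the per-locus marker summary uses the unbiased
small-sample correction `2n/(2n - 1)`; the HL/IR weights use the plain
`1 - sum(p^2)` (the convention of the measures' original definitions). An
IR denominator of zero is reported as `NA` with a warning, never as a
silent `NaN`.

The **rare-allele score** of a (typically paternal) individual is the
number of its allele copies rarer than 5% in the population, divided by
`2 x` typed loci, making it a per-copy proportion in [0, 1]. The
denominator choice (allele copies rather than loci) keeps a homozygous
rare genotype counting twice.

# Pedigree inbreeding

`f` of an individual is the kinship of its parents, computed by memoized
recursion with founders assumed unrelated and non-inbred; `f = 0` whenever
a parent is unknown. Because unknown ancestry hides inbreeding, analyses
can be restricted to individuals with (i) both parents, (ii) at least one
grandparent, or (iii) all four grandparents known — trading sample size
against bias. Individuals with `f >= 0.125` (matings of first-order or
equivalent relatives) are classified inbred. The recursive engine is
checked in the tests against an independently coded tabular
additive-relationship method and against gene-dropping Monte Carlo.

# Identity disequilibrium

Variance in inbreeding correlates heterozygosity across unlinked loci.
Three diagnostics quantify this:

* **g2** follows the David et al. (2007) multilocus estimator for data
  with missing genotypes, implemented as a ratio of unbiased moment
  estimators: the within-individual cross-locus heterozygosity moment over
  the between-individual product moment, each locus pair normalized by its
  typed count. The exact weighting used by the original RMES program is
  not published in a recoverable form, so this construction (which reduces
  to the standard estimator under complete data and is unbiased under
  missing-at-random typing) is the package's documented choice. The SE is
  an individual-level bootstrap; the p-value permutes each locus's
  heterozygosity column independently — the standard
  identity-disequilibrium null, which preserves locus-wise heterozygosity
  and missingness while destroying cross-locus correlation. Both default
  to 1000 iterations, and every resample is seeded and the seed recorded.
* **HHC** splits the panel at random into two halves (17/18 for 35 loci),
  correlates per-individual proportion-heterozygosity between halves
  (Spearman), and repeats (default 100 splits). Plain proportions, not
  SH-standardized values, are used within halves; this follows the
  procedure as originally described, and the choice is visible in the code
  should users want to change it.
* **Expected r(SH, f)**: under the classical model the expected
  heterozygosity of an individual is proportional to `1 - f`, giving
  `r = -sd(f) / ((1 - E(f)) sd(SH))` for standardized heterozygosity. The
  SD of SH is taken empirically from the data rather than from a
  model-based expression, since the latter's exact transcription is not
  recoverable; the formula is validated against a simulation oracle in the
  tests. The observed counterpart is a Spearman correlation with mid-ranks
  and a two-sided p-value.

# CJS survival models

The likelihood is the standard open-population CJS likelihood conditioned
on first release: known-alive intervals contribute survival and Bernoulli
detection terms, and the tail after the last detection contributes
`chi_j = (1 - phi_j) + phi_j (1 - p_{j+1}) chi_{j+1}`. Models are written
in MARK-style notation, e.g. `Phi(a2-t/sex) p(t)`: two age classes with
year-dependent first-year (cub) survival, a sex effect on adult survival,
year-dependent recapture. Occasions are annual; an individual first caught
as a cub spends exactly its first interval in the cub class. Year-level
covariates (summer rainfall, summer and winter temperature, population
size) attach to the interval starting in that year.

Numerical choices:

* logit link throughout; optimization by BFGS with 5 multi-starts by
  default (first start at zero), objective tolerance `1e-10`; conditional
  SEs from the numerically differentiated Hessian.
* continuous predictors are standardized to mean 0, SD 2 before fitting
  (the Gelman convention), making them comparable with binary predictors
  coded -0.5/+0.5 (sex); parasite loads are `log(x+1)`-transformed and
  scaled within sampling month before pooling.
* missing individual covariates (e.g. single-locus indicators of partially
  typed individuals) are column-mean imputed with the mask retained.
* the reported `deviance` is `-2 log L` minus the saturated value of the
  release-cohort history multinomial (the convention under which the
  bootstrap variance-inflation ratio is centred at 1); QAICc uses the raw
  `-2 log L`. Only within-data differences matter for selection, and both
  conventions give identical differences.
* parameter counting: `k` is the number of design columns, minus one when
  recapture *and* every survival class are year-dependent (the terminal
  `phi x p` product is then confounded and `p_T` is not separately
  estimable). Estimates pinned beyond logit +/-15 are flagged as boundary
  (separation) but still counted in `k`: a separated coefficient consumes
  a degree of freedom, and excluding such coefficients systematically
  rewards overfitted many-parameter models in the single-locus/multilocus
  comparison.
* effective sample size for QAICc is the total number of release events.

**Goodness of fit.** `bootstrap_chat()` simulates replicate datasets from
the fitted model (same releases), refits, and divides the observed deviance
by the mean bootstrap deviance; values below 1 are truncated to 1 for
QAICc use, treating mild underdispersion as noise. The bootstrap simulates
from the model being assessed, including any individual covariates it
carries.

# Multimodel inference

Weights are `exp(-0.5 Delta)` renormalized over *all* considered models
(so printed-style weight tables are reproducible); models with `Delta < 7`
form the plausible set. Averaging is restricted to the plausible set with
weights renormalized inside it — the natural method averages only models
containing the term, the zero method substitutes zero estimates (and SEs)
elsewhere — which preserves the exact identity
`beta_zero = beta_natural x relative_importance` (importance computed
within the plausible set). Reported relative importance follows the
all-considered-weights definition. Unconditional SEs follow
`sum_i w_i sqrt(var_i + (beta_i - beta_bar)^2)`. Evidence ratios are
computed through the Delta identity to survive weight underflow.

The local-vs-general comparison fits, with the same engine, a model with
every retained single-locus heterozygosity indicator (plus its
rainfall interaction) against the multilocus SH model, after two screens:
loci with fewer than 7 heterozygotes in the role group are dropped (the
smallest count at which a single-locus logit coefficient is even roughly
estimable, consistent with the kind of exclusion applied in practice), and
collinear loci are removed by iterative VIF screening at threshold 5.

# The synthetic world

`simulate_population()` states a world rather than tuning one: ~19 social
groups, 35 loci averaging 4.5 alleles (Dirichlet frequencies), 97% typing
completeness, allelic-dropout and false-allele rates of 0.005 each, 5%
incestuous matings among first-order relatives, ~50% extra-group
paternity, 24 annual occasions, mean cub survival ~0.68 with N(0, 0.5)
year effects, adult survival ~0.82 with a small male deficit, and
recapture probabilities around 0.75 varying by year. Climate is Gaussian
by year (summer rainfall mean 400 mm SD 60, summer temperature 14 C SD
0.8, winter temperature 4.5 C SD 1.2 — a stand-in chosen once, since no
parametric climate model is implied by the data the generator emulates;
the parameters are config-exposed). Scenario presets encode the testable
hypotheses: `null`, `general_effect` (survival declining in true f),
`local_effect` (one causal locus), and `paternal_x_rain` (a
paternal-heterozygosity x summer-rainfall interaction of +1.0 on the logit
scale with no individual/maternal effect).

Two honest wrinkles, both recorded in the truth block: (i) the configured
incest rate applies where a first-order relative is actually alive and of
breeding age, so the realized fraction over all matings runs below nominal
in early years — the generator's self-check therefore conditions on
availability; (ii) the generator standardizes its survival covariates
against the *generating* moments (SH against 1 +/- 0.15, climate against
its configured means), whereas the analysis pipeline standardizes
empirically; coefficients recovered by the pipeline are therefore
comparable to, but not numerically identical with, the generating values.

What a green test does and does not establish: the generator reproduces
the statistical *structure* the analysis assumes (Mendelian genotypes,
pedigree-driven identity disequilibrium, covariate-dependent CJS
observation process) but not the ecology of a real population — no
spatial territory geometry, density dependence, disease, age-dependent
fecundity, or trap response. Recovery under this world demonstrates the
estimators are consistent and calibrated, not that any real-data estimate
is correct.

# Known limitations

* The CJS engine covers single-state, live-recapture models only (no
  dead recoveries, multistate, or robust design), matching its scope.
* The g2 weighting is the documented unbiased construction, not a
  byte-level reimplementation of RMES; point estimates on complete data
  coincide with the standard estimator.
* With dozens of single-locus terms on a few hundred Bernoulli survival
  outcomes, separation is common; boundary flags should be inspected
  before interpreting single-locus coefficients.
* p-values for g2 are permutation-based; the bootstrap CI route is also
  available from the stored resamples, and the two can disagree at small
  n.
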