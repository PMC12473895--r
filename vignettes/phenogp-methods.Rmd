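---
title: "Models and methods behind phenogp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenogp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenogp)
```

## The problem

Hybrid breeding programs based on factorial (NC-II) mating designs cross
every female parent to every male parent and evaluate the resulting hybrids
in replicated multi-environment trials. Two prediction strategies compete
for the task of ranking untested hybrids: *genomic prediction* (GP), which
models hybrid performance through marker-based relationship kernels of the
parents, and *phenomic prediction* (PP), which replaces markers with
high-dimensional near-infrared (NIR) reflectance spectra of harvested grain.
`phenogp` implements both, their combination, the variance-component and
heritability analysis that motivates them, and the cross-validation schemes
used to compare them — together with a synthetic-trial generator so that
every stage can be exercised and verified at desk scale without external
data.

## Mixed models for the factorial trial

All phenotypes are modelled additively on the plot level. Within one
environment the full decomposition is

y = mu + f + m + fm + r + e,

with independent zero-mean Gaussian effects: female GCA `f`, male GCA `m`,
their interaction (SCA) `fm`, replicate `r`, and residual `e`. Across `t`
environments the model adds environment `s`, the three genotype-by-
environment interactions `fs`, `ms`, `fms`, and replicate nested in
environment. `reml_single_env()` / `reml_combined()` estimate all variance
components by REML through `lme4::lmer` (bounded at zero, so boundary
estimates are reported as exact zeros), and each term can be tested by a
likelihood-ratio test against the model without it. The LRT statistic is
referred to a plain chi-square with 1 df, mirroring common practice in
trial analysis; because the null value lies on the boundary of the
parameter space this reference is conservative, and the 50:50 mixture
reference is available via `lrt_term(..., boundary = TRUE)`.

Entry-mean heritabilities use the standard combined-trial forms with
`sigma2_g* = sigma2_f + sigma2_m + sigma2_fm` and
`sigma2_gxe* = sigma2_fs + sigma2_ms + sigma2_fms`:

H2 = sigma2_g* / (sigma2_g* + sigma2_gxe*/t + sigma2_e/(t r)),

with the additive numerator `sigma2_f + sigma2_m` for h2 and the single
parental components for h2_f and h2_m. These statistics are scale-free, so
they can be computed from percent-of-total columns of a published table as
well as from raw estimates. The replicate number is exposed as a parameter;
`r = 2` is the default used throughout, which reproduces the published
heritability grid of the motivating trial even though its replicate counts
varied between 2 and 3 across years. `cve()` reports the residual
coefficient of variation 100 * sqrt(sigma2_e) / mean.

Per-environment hybrid BLUEs (`fit_blues()`) come from the same machinery
with hybrids fixed and replicates random; they are the responses for all
prediction models. `spectra_band_decomposition()` applies the combined
model independently to every spectral band and stacks percent-of-variance
and heritability profiles across wavelengths.

## Kernels

* **Genomic.** `vanraden_relationship()` centres marker dosages and forms
  `G = Xc Xc' / n` with `n` the marker count — the formula as used for the
  motivating trial. The classical `2 * sum(p(1-p))` denominator differs
  only by a scalar and is available by argument; a scalar rescaling of a
  kernel is absorbed by its variance component, so predictions are
  unaffected.
* **SCA.** `sca_kronecker()` builds the hybrid-level SCA kernel as the
  Kronecker product of the parental kernels restricted to realized hybrids:
  `H[(f1,m1),(f2,m2)] = G_f[f1,f2] * G_m[m1,m2]`.
* **Phenomic.** Spectra are pretreated by an 11-point, order-2
  Savitzky-Golay first derivative (`savitzky_golay_first_derivative()`),
  which drops the `window - 1` edge bands (4200 bands become 4190), then
  band-scaled to zero mean and unit SD. "Scaled around zero" could mean
  centring only; centring plus unit SD was chosen (and is what `scale_bands()`
  does) so every band enters the kernel with equal weight. The kernel is
  `P = D D' / q` over the `q` retained derivative bands.
* **Record expansion and interactions.** `expand_to_records()` maps any
  entity kernel to record level as `Z K Z'` through an explicit incidence
  map (no positional indexing), and `interaction_hadamard()` forms
  genotype-by-environment covariances as the element-wise product with the
  environment-sharing indicator `Z_E Z_E'`, which is PSD by the Schur
  product theorem. Environment main effects use an identity kernel over
  environment levels — exactly a Gaussian ridge on environment indicators.

## Bayesian multi-kernel prediction

`gibbs_fit()` samples the RKHS mixed model
`y = mu + sum_k u_k + e`, `u_k ~ N(0, sigma2_k K_k)`, `e ~ N(0, sigma2_e I)`.
Each kernel is eigen-decomposed once (`build_model()`), eigenvalues below
`1e-8 * max` being dropped — this also clips the small negative eigenvalues
that floating-point noise produces in assembled kernels. In the eigenbasis
the columns of the effective design are orthonormal, so the full
conditional of a kernel's coefficient vector factorizes into independent
Gaussians and each sweep costs two matrix-vector products per kernel.

Variances get scaled-inverse-chi-square conditionals. The hyperpriors use
`df0 = 5` degrees of freedom with scales set so that the prior mode splits
`R2 = 0.5` of the response variance equally among the kernels and leaves the
rest to the residual — the conventional default of this sampler family; both
are arguments. The source of the motivating analysis did not state its
hyperprior settings, so these defaults are documented as this package's
choice, not as a reproduction. Missing responses are imputed by data
augmentation each sweep, which yields predictions for masked records at no
extra cost and is how the cross-validation engine obtains test-set
predictions. Chains default to 5000 iterations, 1000 burn-in, thinning 10.
A split-chain potential-scale-reduction diagnostic on the variance samples
warns above 1.1; fixing variance components (`fix_varcomp`) turns the
sampler into a conditional model whose posterior-mean fitted values converge
to the closed-form GLS/BLUP solution, which is how the sampler is verified
in the test suite.

## Cross-validation

`make_partitions()` draws seeded 70:30 hybrid splits. CV1 masks all records
of the test hybrids (untested hybrids, characterized environments); CV2 and
CV3 additionally mask one whole environment. The published description
gives only combined record counts, so the scoring split is a design choice
here: CV2 scores the *training* hybrids in the held-out environment
(tested hybrids, uncharacterized environment) and CV3 the *test* hybrids
there (untested in uncharacterized). Accuracy is the Pearson correlation
between predictions and observed BLUEs, computed per test environment, then
averaged (unweighted) within repeat and summarized over repeats.
`tukey_compare()` applies one-way ANOVA with Tukey's HSD at 5% to
repeat-level mean accuracies and emits a compact letter display built from
maximal cliques of the non-significance graph.

## The synthetic-trial generator

`simulate_trial()` emulates the structure the analysis assumes, not the
biology underneath it:

* **Genotypes** are independent biallelic markers with allele frequencies
  drawn from a configurable range; inbred parents are fully homozygous.
  Hybrid dosages are the parental means — the deterministic F1 of inbred
  line crosses. There is no linkage, LD, or selection.
* **Traits** follow the plot-level decomposition above, with every term
  drawn at its configured variance. The default parameterization is the
  grain-yield variance-component profile of the motivating trial
  (`trait_architecture()`), at the trial's scale: 10 x 10 factorial, 8
  environments, 2 replicates. In the default genomic mode the two GCA
  terms are marker-effect sums, scaled so the expected sample variance
  across parents equals the configured component; SCA and all
  environment-related terms are i.i.d. draws, so the genomic kernels carry
  additive signal while SCA signal stays unstructured.
* **Spectra** are sums of smooth per-level curves on a row-normalized cubic
  B-spline basis (about 40 functions over the grid), one curve per level of
  female, male, hybrid, environment, the three interactions (the single
  G x E share is split equally among them), replicate, and a per-record
  residual curve. Band variances follow configured shares that default to
  the decomposition observed for real grain spectra (female 17.6%, male
  26.3%, hybrid 5.1%, environment 37.1%, G x E 10%, replicate 1%, residual
  2.9%), which puts band-wise H2 near 0.97 — inside the 0.91-0.99 range
  reported for real spectra. The wavelength grid is half-open
  (400-2500 nm at 0.5 nm gives exactly 4200 bands, matching the
  instrument's advertised band count rather than the 4201 a closed grid
  would produce). No chemistry is modelled: real NIR spectra owe their
  shape to absorption bands of grain constituents, so passing tests show
  that the *statistical* pipeline is correct, not that NIR predicts any
  particular trait.

## Numerical and test-design choices

* Kernel PSD tolerance: eigenvalues ≥ `-1e-8 * max` accepted, negatives
  clipped at decomposition; symmetry enforced within 1e-10.
* REML fits run with `lme4` defaults except singular-fit checks silenced
  (boundary estimates are expected) and derivative checks off for speed; a
  convergence flag is carried on every `variance_decomposition`.
* All simulation-based tests fix their seeds and run at desk scale: ~150-800
  simulated trials for recovery/null checks, 2000-marker panels, 20-repeat
  cross-validation comparisons with 1000-1500-iteration chains, chosen to
  keep the full suite in the minutes range while leaving Monte-Carlo error
  well below the effects being tested. Statistical assertions use
  Monte-Carlo SE bounds wide enough (typically 3.3 SE) that an
  exactly-correct implementation fails with probability well below 1%.
* Genotype ingestion removes markers with more than 5% missing calls and
  imputes the remainder to the marker mean — the simplest imputation
  consistent with a mean-centred relationship matrix; the threshold is an
  argument.
* `round_half_up()` performs presentation rounding (half away from zero) to
  match how trial reports are conventionally printed; all internal
  computation is full precision.

## Known limitations

* REML variance components rely on `lme4`'s profiled optimizer; the
  monotone-likelihood guarantee is the optimizer's, not re-verified per
  iteration.
* The sampler stores posterior means and variance samples, not full effect
  chains; credible intervals for individual predictions are out of scope.
* Single-trait only; no spatial field-trend correction, no outlier
  screening, and no scatter-correction pretreatments (SNV/MSC) — band
  selection is deliberately absent since fitting all bands is the
  reference behaviour.
* The phenomic kernel requires spectra for every record entering a model,
  including records being predicted; this mirrors the intended use case
  (spectra are cheap once grain exists) but means PP cannot rank crosses
  that were never made.
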