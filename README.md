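# phenogp

Genomic and phenomic prediction for factorial hybrid trials.

`phenogp` is for quantitative geneticists and breeders analysing hybrids
from factorial (NC-II) mating designs — every female parent crossed to every
male parent — evaluated in replicated multi-environment trials. It answers
two linked questions: *how is trait variance partitioned* among female GCA,
male GCA, SCA, environment, and their interactions, and *how well can
untested hybrids or unseen environments be predicted* from parent SNP
genotypes (genomic prediction, GP), from near-infrared grain reflectance
spectra (phenomic prediction, PP), or from both (GP+PP).

## The models

Plot-level phenotypes follow the combined factorial mixed model

```
y = 1μ + Z₁f + Z₂m + Z₃fm + Z₄s + Z₅fs + Z₆ms + Z₇fms + Z₈r(s) + e
```

with all effects independent Gaussian. Variance components are estimated by
REML (lme4), each term tested by likelihood-ratio, and entry-mean
heritabilities computed as

```
H² = σ²g* / (σ²g* + σ²g×e*/t + σ²e/(t·r)),   σ²g* = σ²f + σ²m + σ²fm
```

with the additive numerator σ²f + σ²m for h² and the parental components
for h²f, h²m.

Prediction uses a multi-kernel Bayesian RKHS model fitted by a Gibbs
sampler written for this package: `y = μ + Σₖ uₖ + e` with
`uₖ ~ N(0, σ²ₖ Kₖ)`, effects sampled in each kernel's eigenbasis and missing
records imputed by data augmentation. The kernel stack is assembled from

* `G = XcXc′/n` — VanRaden-style parental relationship from centred dosages,
* `H` — the SCA kernel, a Kronecker product of `G_f` and `G_m` restricted to
  realized hybrids,
* `P = DD′/q` — the phenomic kernel from Savitzky–Golay first-derivative
  (11-point window: 4200 bands → 4190), band-scaled spectra,
* environment ridge blocks and Hadamard G×E / NIR×E interaction kernels
  (`Z K Z′ ⊙ Z_E Z_E′`).

Model comparison runs the three cross-validation scenarios of hybrid
breeding — CV1 (untested hybrids, characterized environments), CV2 (tested
hybrids, uncharacterized environment), CV3 (untested hybrids,
uncharacterized environment) — on seeded 70:30 hybrid splits, scoring
Pearson accuracy per test environment and comparing models by Tukey's HSD
with compact letters.

A first-class synthetic-trial generator (`simulate_trial()`) draws parent
genotypes, plot-level traits with configurable variance components
(defaulting to the grain-yield profile of a real 10 × 10 sorghum hybrid
trial), and smooth NIR spectra with configurable per-band variance shares,
so the whole pipeline is testable without external data.

## Worked example

```r
library(phenogp)

ds <- design_spec(n_female = 10, n_male = 10,
                  environments = paste0("E", 1:4), replicates = 2)
trial <- simulate_trial(ds, trait_architecture(),
                        spectra_gen_spec(stop = 700), seed = 42)

rep <- varcomp_report(trial$phenotypes, "GY")
rep$components
#> # A tibble: 9 × 4
#>   term       estimate percent stars
#> 1 female        0.077     1.3 NS
#> 2 male          0.29      5.1 ***
#> 3 sca           0.042     0.7 *
#> 4 env           4.25     74.2 ***
#> 5 female_env    0.237     4.1 ***
#> 6 male_env      0.1       1.7 ***
#> 7 sca_env       0.018     0.3 NS
#> 8 rep_env       0.017     0.3 *
#> 9 residual      0.7      12.2 <NA>
rep$heritability
#> H2 = 0.698  h2 = 0.627  h2_f = 0.131  h2_m = 0.495  (t = 4, r = 2)
```

The report mirrors a standard trial table: REML estimates, percent of total
variance, LRT stars, and entry-mean heritabilities (here moderate H² with a
male-leaning additive split, as planted by the simulation seed).

```r
inputs <- prediction_inputs(trial)   # BLUEs, G_f, G_m, H, P
acc <- run_scheme(inputs$records, "GY", models = c("GP", "PP", "GP+PP"),
                  scheme = "CV1", n_repeats = 10,
                  G_f = inputs$G_f, G_m = inputs$G_m, H = inputs$H,
                  P = inputs$P, scope = "combined",
                  iters = 2000, burnin = 500, thin = 5, seed = 7)
tukey_compare(acc)$summary
#> # A tibble: 3 × 4
#>   model  mean     se letters
#> 1 GP    0.701 0.0166 a
#> 2 GP+PP 0.702 0.0161 a
#> 3 PP    0.588 0.0148 b
```

On this genomically simulated trait GP and GP+PP share the top letter while
PP trails — the spectra carry hybrid structure but not this trait's marker
signal, so phenomic accuracy reflects line repeatability only.

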