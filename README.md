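# mrfactors

Two-sample Mendelian randomisation (MR) for the causal interplay between
correlated, temporally ordered traits — built around the eight female
reproductive factors (age at menarche, age at first sexual intercourse,
age at first/last birth, number of births, ever-parous status, lifetime
number of sexual partners, age at menopause).

Reproductive factors predict chronic-disease risk, but they also cause one
another: a later menarche delays first intercourse, which delays first
birth, and so on. `mrfactors` is for epidemiologists and statistical
geneticists who want to estimate that interplay from GWAS summary
statistics, with the full sensitivity apparatus such a study needs, and to
validate every estimator against a synthetic cohort with known causal
structure.

## What it implements

**The core estimator.** For instrument SNP *i*, the Wald ratio is
β̂ᵢ = β̂_yi / β̂_xi. The primary estimate pools ratios by inverse variance —
equivalently a weighted regression of β̂_y on β̂_x through the origin with
weights 1/se_y² — under a multiplicative random-effects model whose SE is
inflated by max(1, √(Q/(k−1))), with Q Cochran's heterogeneity statistic.

**The sensitivity suite.** MR-Egger (intercept = directional pleiotropy)
with the I²_GX NOME diagnostic and SIMEX extrapolation when I²_GX < 0.9;
weighted median and weighted mode; MR-PRESSO outlier detection and
correction; the Steiger directionality test and filter; multivariable IVW
for confounder adjustment; mean F = (r²/(1−r²))·((n−k−1)/k) for instrument
strength.

**LD score regression.** LD scores from a reference panel (adjusted-r²
window sums), summary-statistic munging (reference intersection, ambiguous
A/T and G/C SNPs dropped, chr6:26–34 Mb excluded), heritability and
cross-trait genetic correlation with block-jackknife SEs.

**Study orchestration.** Temporal pair plans (primary / bidirectional /
reverse-menopause / five negative controls), per-pair method minima,
split-sample GWAS with fixed-effects meta-analysis, and an end-to-end
`run_full_study()` emitting a tidy report bundle.

**A first-class synthetic world.** Genotype panels with tunable block LD,
eight causally linked trait analogues over a configurable DAG (defaults
reproduce the headline SD-unit effects as a self-consistent set of direct
edges), a shared childhood-body-size confounder, liability-threshold binary
traits (18.69% never parous), pleiotropy injection and controllable sample
overlap.

## Worked example

A 20,000-person cohort with a single true effect — menarche → AFS of
0.09 SD — analysed exactly as a real pair would be:

```r
library(mrfactors)
library(dplyr)

reg <- tibble::tibble(trait = c("menarche", "afs"), type = "continuous")
cfg <- causal_config(traits = reg, n_snps_per_trait = 25,
                     h2 = c(menarche = 0.25, afs = 0.15),
                     theta = tibble::tibble(from = "menarche", to = "afs",
                                            theta = 0.09),
                     confounder_gamma = c(menarche = 0, afs = 0),
                     prevalence = numeric(0), seed = 2)
panel  <- simulate_genotypes(20000, genotype_blocks(10, 10, rho = 0.4),
                             seed = 102)
cohort <- simulate_traits(panel, cfg)

exposure <- standardise_sumstats(run_gwas(panel, cohort, "menarche"))
outcome  <- standardise_sumstats(run_gwas(panel, cohort, "afs"))
instruments <- select_instruments(exposure, panel)   # p < 5e-8, r2 < 0.001
res <- run_pair(exposure, outcome, instruments, seed = 3)
res$results |> select(method, nsnp, b, se, lo_ci, up_ci, p)
```

```
                method nsnp      b     se   lo_ci up_ci        p
1                  ivw   13 0.1124 0.0235  0.0664 0.158 1.71e-06
2                egger   13 0.0121 0.0708 -0.1266 0.151 8.64e-01
3      weighted_median   13 0.1050 0.0209  0.0640 0.146 5.26e-07
4        weighted_mode   13 0.0995 0.0231  0.0544 0.145 1.57e-05
5 ivw_presso_corrected   12 0.0987 0.0152  0.0689 0.129 8.83e-11
```

The IVW estimate (0.112, 95% CI 0.066–0.158) and every robust estimator
cover the configured truth of 0.09 SD; MR-PRESSO trims one outlier and
tightens the estimate to 0.099. The selected instrument set explains
r² = 0.224 of the exposure (mean F = 444), Cochran's Q = 29.7 on 12 df
flags mild heterogeneity, and the Steiger test confirms the instruments
explain far more exposure than outcome variance (direction correct,
p ≈ 1e-308). The Egger slope is imprecise at 13 SNPs — exactly why it is a
sensitivity analysis, not the primary estimator.

The instrument-strength worked example from the published UK Biobank
reproductive-factor instrument table is one call:

```r
mean_f_statistic(r2_total = 0.064, n = 243898, k = 223)
#> 74.72   # printed value 74.95; agreement is bounded by the 2-digit r2
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the package's main computation end to end — simulates the default
eight-trait cohort, runs the per-trait GWAS, the LD-score genetic
correlation matrix, the full temporal pair plan with every sensitivity
analysis, and the split-sample meta-analysis — then writes the acceptance
JSON to `--out`. The seed drives every random draw, so a rerun with the
same seed reproduces the study byte for byte.

## Documentation

The methods vignette (`vignettes/mrfactors-methods.Rmd`) documents the
model, every numerical convention (weighting, jackknife, palindrome window,
empirical-p conventions), what the synthetic generator does and does not
emulate, and the package's known limitations.
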