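---
title: "Methods: causal interplay between reproductive factors by Mendelian randomisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal interplay between reproductive factors by Mendelian randomisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A woman's reproductive life course — age at menarche, age at first sexual
intercourse (AFS), age at first and last live birth (AFB, ALB), number of
births, ever-parous status, lifetime number of sexual partners, age at
menopause — is a set of temporally ordered, genetically correlated traits.
Individual factors predict chronic-disease risk, but treating them one at a
time ignores that earlier factors may *cause* later ones. `mrfactors`
implements the statistical machinery for studying that interplay with
two-sample Mendelian randomisation (MR): genetic variants robustly associated
with an earlier trait serve as instrumental variables, so the estimated
effect on a later trait is protected (under the instrumental assumptions)
from classical confounding and reverse causation.

Because the real biobank-scale data cannot ship with a package, the package
carries a first-class synthetic-cohort generator that emulates the causal
structure such a study infers, and every estimator is exercised against that
generator. A green test therefore establishes that the estimators recover a
*known* synthetic truth at stated sample sizes — not that any particular
epidemiological claim is true.

## The estimator suite

For a harmonised SNP `i` with exposure association `b_xi` (SE `s_xi`) and
outcome association `b_yi` (SE `s_yi`):

* **Wald ratio**: `r_i = b_yi / b_xi`, `se(r_i) = s_yi / |b_xi|`
  (first-order delta method).
* **IVW** (the primary estimator): weighted regression of `b_y` on `b_x`
  through the origin with weights `1/s_y^2` — algebraically the
  inverse-variance weighted mean of the Wald ratios. The SE is multiplied by
  `max(1, sqrt(Q/(k-1)))`: a *multiplicative random-effects* model, floored
  at the fixed-effect SE so under-dispersion never shrinks it.
* **Cochran's Q**: `sum w_i (r_i - b_ivw)^2` with `w_i = se(r_i)^-2`;
  `Q > k-1` flags heterogeneity, a symptom of invalid instruments.
* **MR-Egger**: the same regression *with* an intercept, after re-orienting
  every SNP so `b_x > 0` (without a fixed orientation the intercept is not
  identified). The intercept estimates average directional pleiotropy; the
  slope is the bias-adjusted effect under the InSIDE assumption. `I2_GX =
  max(0, (Q_GX - (k-1))/Q_GX)` with `Q_GX` the exposure-precision-weighted
  dispersion of `b_x` quantifies the no-measurement-error (NOME) assumption;
  below 0.9 the pipeline adds a **SIMEX** correction: exposure betas are
  perturbed with `N(0, lambda * s_x^2)` noise for `lambda` in {0, 0.5, 1,
  1.5, 2}, the mean refitted slope is modelled as a quadratic in `lambda`
  and extrapolated to `lambda = -1`.
* **Weighted median**: the ordered Wald ratios interpolated at cumulative
  standardised weight 0.5 using the midpoint convention
  `s_i = (sum_{j<=i} w_j) - w_i/2`; consistent when valid instruments carry
  at least half the weight.
* **Weighted mode**: argmax of the weight-scaled Gaussian kernel density of
  the ratios; bandwidth is the modified Silverman rule
  `0.9 * min(sd, mad) * k^(-1/5)` times a user factor (default 1).
* **Mean F statistic**: `F = (r2/(1-r2)) * ((n-k-1)/k)` from the aggregate
  instrument `r2 = sum 2*eaf*(1-eaf)*beta_std^2`; above 10 is the
  conventional strong-instrument bar.
* **MR-PRESSO**: observed residual sum of squares around leave-one-out IVW
  slopes, compared against parametric simulations from the betas' sampling
  normals; per-SNP outlier p-values are Bonferroni-corrected; the corrected
  estimate is IVW on the non-flagged SNPs; a distortion p compares the
  resulting shift with shifts from removing random same-size subsets.
* **Steiger**: per-SNP variance explained via the t-statistic transform
  `r2 = t^2/(t^2 + n - 2)`, aggregated by summation; a z-test on the
  difference of Fisher-transformed correlations orients the causal
  direction, and Steiger filtering drops SNPs whose outcome `r2` exceeds
  their exposure `r2`.
* **Multivariable IVW**: weighted regression of `b_y` on the matrix of
  exposure betas (no intercept) over the union of instruments, harmonised
  jointly to the first exposure's orientation — used to adjust for the
  childhood-body-size confounding pathway.
* **Fixed-effects meta-analysis**: inverse-variance pooling of the two
  split-sample estimates with a between-half Q on 1 df.

Bootstrap SEs (median, mode) are parametric: betas resampled from their
sampling normals, default 1000 draws. Binary outcomes are analysed by
logistic regression, carried as log odds throughout, and exponentiated only
in reporting (`or` column).

## LD score regression

Genetic correlation between trait pairs is estimated by LD score regression
re-implemented from first principles:

* LD scores from the synthetic reference panel:
  `l_j = sum_k r2_adj(j,k)` over a 1 Mb window, with the finite-sample
  adjustment `r2_adj = r2 - (1 - r2)/(n_ref - 2)` (self term exactly 1).
* Munging: intersect with the reference SNP list (a stand-in for a
  well-imputed list such as HapMap3 — any `snp/ea/oa` table can be
  substituted), drop strand-ambiguous A/T and G/C SNPs, align z signs to the
  reference effect allele through strand complements, and exclude the
  extended MHC (chr6:26–34 Mb, 1-based inclusive) where exceptional LD
  breaks the regression's assumptions.
* Heritability: `E[chi2_j] = intercept + N*h2*l_j/M`, fitted in two passes —
  an unweighted pass initialises `h2`, then heteroskedasticity weights
  `1/(2*mu_j^2 * l_j)`. This is a documented simplification of the original
  fully iterated scheme; the recovery tests bound its cost. `M` defaults to
  the merged SNP count; when the trait's polygenic background extends over
  SNPs dropped in munging, pass the full panel size (the estimated `h2`
  scales linearly in `M`, and the genetic correlation is invariant to it).
* Genetic correlation: `E[z1*z2] = intercept + sqrt(N1*N2)*rho_g*l/M`, with
  `rg = rho_g / sqrt(h2_1 * h2_2)`; the free intercept absorbs sample
  overlap (`n_overlap * pheno_corr / sqrt(N1 N2)` in expectation). The
  computation is exactly symmetric in the two traits. `rg` is reported
  unclipped; results with a non-positive `h2` are flagged undefined rather
  than guessed.
* All SEs are delete-a-block jackknives over position-contiguous blocks
  (default 200 blocks, at least 10 SNPs each) — an exact arithmetic identity
  with refitting without each block, which the tests verify directly.
* Chi-squared winsorisation (`max(80, 0.001*N)` in common practice) is
  available but off by default: the synthetic world has no confounding
  inflation to trim.

A caveat observed at desk scale: with `M ~ 2000` SNPs and `N ~ 20000`, the
slope term `N*h2/M` is of order 1 per unit of LD score, so extrapolating the
intercept to `l = 0` is noisy (single-run intercept SE around 0.6). The
acceptance suite therefore checks the overlap-scaling behaviour of the
bivariate intercept on replicated draws from the generative model, where the
expectation is exact, while `h2` and `rg` recovery run through the full
individual-level pipeline.

## The synthetic world

`simulate_genotypes()` builds dosages from two latent Gaussian haplotypes
per individual; within a block the latents follow an AR(1) process with
correlation `rho`, and each haplotype carries the alternate allele when its
latent falls below `qnorm(maf)`. Every SNP is in Hardy–Weinberg equilibrium
at its MAF, and block `rho` tunes LD for the clumping and LDSC machinery.
This deliberately ignores real-genome features — no allele-frequency
spectrum, no recombination hotspots, no relatedness or stratification —
which is also why the association scan is plain OLS/logistic with
covariates (a genotyping-batch and an age analogue) rather than a mixed
model: there is no structure for a mixed model to absorb.

`simulate_traits()` generates the eight trait analogues in topological order
of a configurable causal DAG: polygenic component (scaled so realised
genetic variance equals the configured `h2`), direct causal contributions
`theta * upstream trait`, a loading on a shared standard-normal confounder
(the childhood-body-size analogue), optional injected pleiotropy, and
Gaussian noise sized so each trait has unit variance and mean zero. Binary
traits threshold the latent liability at the configured prevalence
(ever-parous default 0.8131, i.e. 18.69% never parous). Missingness is an
optional missing-at-random mask; informative censoring (e.g. menopause
unobserved in younger women) is out of scope.

Defaults are chosen once and stated here:

* **Causal edges.** The study-level estimates the package is designed around
  are *total* (marginal) effects — e.g. a 1 SD later menarche leading to a
  0.09 SD later AFS. The generator needs *direct* edges, so
  `default_theta()` solves `Theta = I - T^{-1}` with `T` the matrix of those
  headline total effects; the implied totals then reproduce the headline
  numbers exactly (e.g. the AFS→ALB direct effect is nearly zero because the
  0.42 SD total flows almost entirely through AFB). Effects into the binary
  parous trait are taken on the liability scale as log odds ratios.
* **Heritabilities** default to SNP-heritability-scale values (0.05–0.20)
  typical for reproductive traits; confounder loadings are modest
  (menarche −0.15, AFS and AFB −0.05) reflecting the adiposity pathway.
* **Scale.** The default study runs at n = 20,000 with 30 direct-effect SNPs
  per trait. Biobank scale (~244k women, 4–223 clumped
  genome-wide-significant SNPs per trait) is not reproducible on a desktop;
  20,000 matches the package's own recovery criteria, and 30 SNPs at the
  default `h2` keeps per-SNP effects discoverable at `p < 5e-8` in
  split-sample halves. Instrument-selection thresholds keep the standard
  values: `p < 5e-8`, clump `r2 < 0.001`, 10,000 kb window.
* `emit_sumstats(mode = "analytic")` is the fast path for estimator tests:
  `beta_hat ~ N(beta_true, 1/sqrt(2*eaf*(1-eaf)*n_eff))` with `beta_true`
  the SNP's total effect through the DAG. It treats SNPs as unlinked and
  uses the liability scale for binary traits; the individual-level route
  (`run_gwas`) is the reference behaviour.
* `simulate_trait_pair()` is the infinitesimal-model companion for LDSC
  studies: every SNP causal, effects correlated at `rg` across two traits,
  environments correlated at `env_corr` (0.3 in the acceptance world, a
  shared-environment stand-in that gives the full-overlap intercept a
  visible target).

Sample overlap is controlled by how cohorts are sliced: the same cohort for
exposure and outcome statistics (full overlap, the primary design),
`split_cohort()` halves (disjoint), or independent panels (none).

## Study orchestration

`build_pair_plan()` turns a temporal partial order (default: menarche ≺ AFS
≺ {AFB, partners}; AFB ≺ ALB ≺ menopause) into the exposure→outcome plan:
every (earlier, later) pair under the transitive closure is primary; number
of births, parous status and partners — whose ordering against several
traits is genuinely unclear — run bidirectionally against every trait they
are not ordered with; menopause runs in reverse against menarche and AFB as
an ovarian-reserve probe; and five fixed negative-control pairs run the
clock backwards (AFB→menarche, AFS→menarche, AFB→AFS, menopause→AFS,
ALB→menarche), where any signal indicates a shared heritable pathway rather
than causation. One pair (menopause→AFS) belongs to both the reverse and the
negative-control sets; the plan keeps a single row per ordered pair with
category priority negative-control > primary > reverse > bidirectional, so
the negative-control list always has exactly five entries. The whole plan
remains overridable — it is configuration, not code.

`run_pair()` applies method minima that mirror how sparse instruments limit
sensitivity analysis: IVW needs 2 SNPs, Egger/median/mode 3, PRESSO 4;
Steiger always runs; SIMEX triggers automatically when `I2_GX < 0.9`.
`run_split_sample_study()` re-runs the GWAS per random half, selects
instruments per half against the *shared* full reference panel (re-deriving
LD from a half-panel would only add noise), runs each pair in both
directions and pools by fixed effects; a pair whose exposure half yields no
instruments runs once, mirroring how sparse traits behave at half power.
`run_full_study()` wires everything together and emits a report bundle of
tibbles (rg matrix, MR results, sensitivity tables, split-sample
meta-analysis, instrument summary, manifest); per-pair failures become
status rows, never a crashed bundle.

## Numerical choices

* p-values come from the normal (Wald) approximation everywhere, so `p` and
  `beta/se` are mutually consistent to machine precision; p is floored at
  the smallest normal double rather than underflowing to 0.
* Confidence intervals are `estimate ± 1.96 * se` (the reporting convention
  of the field's result tables).
* OLS SEs are floored at the smallest normal double so an exactly collinear
  trait/dosage pair is reported (with p at the floor) instead of dropped.
* Harmonisation drops palindromic SNPs whose allele frequency falls within
  0.08 of 0.5 on either side (a common default; frequencies further out
  align the strands).
* Empirical p-values use the `(1 + x)/(n + 1)` convention, so a resampling
  test can never report exactly zero. With MR-PRESSO's default 1000
  simulations and ~50 instruments, the Bonferroni-adjusted per-SNP floor is
  just under 0.05: outlier calls at those settings require an observed
  residual exceeding every simulation, which is by design conservative.
* The MR-PRESSO distortion null uses 1000 random same-size subset removals.
* Egger re-orientation treats an exactly zero exposure beta as positive;
  Wald ratios exclude such SNPs with a warning.
* Clumping ties on p are broken by (chromosome, position) so instrument
  selection is invariant to input row order.
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; study-level functions derive per-stage child seeds
  (kept below 2^31) so one seed reproduces every output byte-for-byte.

## Known limitations

* The SIMEX SE is the naive Egger SE, not an asymptotic SIMEX variance; the
  point estimate is the quantity under test.
* Analytic-mode summary statistics for binary traits live on the liability
  scale, whereas individual-mode logistic GWAS returns log odds; mixing the
  two for a binary trait is not meaningful.
* MR-PRESSO's normal-theory simulation is approximate for binary outcomes
  (log-odds scale); behaviour is documented, not asserted.
* MVMR reports adjusted estimates only — no conditional F statistics or
  covariance-aware weighting.
* The LDSC implementation is unpartitioned, two-pass weighted, and its
  intercept is noisy at desk scale (see above).
* The generator is a test harness for the estimators, not a mechanistic
  claim about how reproductive traits actually arise; in particular the
  default DAG simply restates the headline estimates as a self-consistent
  set of direct effects.
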