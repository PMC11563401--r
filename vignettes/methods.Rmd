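---
title: "Models and methods behind mtgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtgp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mtgp` implements a complete genomic-prediction analysis for inbred crop
panels evaluated in multi-year, multi-condition field trials. This
vignette explains the models, the choices that were genuinely open, the
numerical machinery, and what the synthetic data generator can and
cannot demonstrate.

## The two-stage analysis

Plot records from a randomized complete block trial repeated over years
are first reduced, per trait and condition, with the mixed model

y_ijk = mu + g_i + e_j + r_k(j) + ge_ij + eps_ijk,

where g_i is the genotype effect, e_j the year, r_k(j) the replicate
within year, ge_ij the genotype-by-year interaction and eps the plot
residual. With the genotype fixed, the estimated marginal genotype means
are the adjusted means ("E-BLUEs") that all downstream prediction uses;
with the genotype random, the variance components give the entry-mean
broad-sense heritability

H^2 = sigma_g^2 / (sigma_g^2 + sigma_ge^2 / y + sigma_e^2 / (y r)),

with y years and r replicates. We fit this stage with `lme4::lmer`
(REML), the standard engine for such designs; design terms that a layout
cannot identify (year effects in a single-year subset, and so on) are
dropped and reported as zero variance, and negative-variance boundary
estimates are returned as zero, which is how REML behaves at the
boundary. Conditions are analysed separately in stage one because
summaries, heritabilities and adjusted means are reported per condition;
the cross-condition structure is handled later by the multivariate
models.

Two derived indices are computed from the adjusted means within each
condition: the protein deviation (residuals of protein content regressed
on grain yield) and the yield deviation (the mirror regression). The
regression is computed over per-genotype adjusted means within the
condition; an alternative reading — regressing on raw environment means —
is possible, and the functions accept any pair of named vectors, so that
variant is a one-line change for the user. The coefficient of variation
in the trait summaries divides by the absolute mean so that
negative-mean index traits keep a meaningful CV, and SE is the standard
deviation of the genotype means over the square root of their count;
model-based standard errors would be an alternative, but the descriptive
convention matches how such summary tables are usually built.

The raw-data ANOVA across conditions is a fixed-effects sequential
(type I) decomposition with terms genotype, year, condition, block
(replicate within year-by-condition), and the genotype interactions with
year, condition and year-by-condition, with conventional significance
stars.

## Kinships

The genomic relationship matrix is the VanRaden construction
G = W W' / c with W the column-centered −1/0/+1 dosage matrix and
c = sum_j 2 p_j (1 − p_j), using observed post-filter allele
frequencies (the construction is standard; the frequency choice is ours
and is the usual one). Column centering makes the all-ones vector an
exact null vector of G — G is always singular — and the package treats
that exactly rather than by ridging: all multivariate REML computations
parameterize the genetic effects on the spectral square root of G
(g = L a with G = L L' over the positive eigenvalues), so no inverse of
G is ever formed. For near-fully-inbred panels the mean diagonal of G is
close to 2 (1 + f with inbreeding f near 1); genetic variances are
therefore expressed per unit of genomic relationship, and simulated
heritabilities account for the realized mean diagonal.

The Gaussian kernels for RKHS regression are K_h = exp(−h D / d_med)
with D the mean squared dosage difference and d_med the median
off-diagonal distance, so bandwidths are unitless. The defaults
h ∈ {0.2, 1, 5} give a flat, an intermediate and a local kernel — the
usual kernel-averaging triple; the bandwidths are configurable and
logged because the original multi-kernel recipe leaves them to software
defaults.

## Prediction models

**Univariate GBLUP.** y = mu + g + eps with g ~ N(0, G sigma_G^2). The
REML likelihood is profiled over lambda = sigma_E^2/sigma_G^2 on the
eigendecomposition of the observed submatrix of G; the intercept is
profiled by GLS. Unphenotyped individuals receive kinship-regression
predictions, which coincide with the joint BLUP under the same
covariance.

**Multivariate GBLUP.** Stacked traits with genetic covariance H ⊗ G (H
unstructured) and diagonal residual covariance R ⊗ I. Missing phenotype
cells are simply excluded from the likelihood — exact under a diagonal R
— which is what makes the CV2 masking schemes well defined for this
model. Estimation is EM-REML on the mixed-model equations with three
numerical refinements:

- *PX acceleration*: each M-step additionally regresses the data on the
  conditional means of the genetic effects (with the exact
  second-moment correction), and the resulting trait-space rescaling is
  folded into H. A safeguard monitors the REML log-likelihood and
  replaces any expanded step that decreases it by the plain EM update,
  so the reported likelihood trace is non-decreasing either way.
- *Spectral parameterization*: as above, g = (I ⊗ L) a with
  a ~ N(0, H ⊗ I), which handles the singular G exactly and keeps the
  equations well conditioned.
- *Stationary-point polish*: when the equations are small enough for
  dense evaluations (a few hundred unknowns), a Nelder–Mead pass
  followed by a quasi-Newton finish on the log-Cholesky parameters pins
  the variance estimates to the stationary point. This matters because
  the REML surface can be extremely flat in the signal-to-noise ratio —
  two different optimizers can otherwise agree in likelihood to ten
  digits yet differ visibly in the ratio. Cross-validation loops
  disable the polish and run at a relaxed tolerance (1e-6 relative
  likelihood change) because fold-level accuracies are insensitive to
  the last digits of the variance parameters; direct fits default to
  1e-8 and polish automatically.

An unstructured residual covariance is also available (complete data
only) and is what the genetic-parameter module uses: adjusted means of
two traits measured on the same plots share non-genetic variation, so
forcing a diagonal residual there would push covariance into the genetic
term.

**Bayesian multitrait regressions.** The ridge (BRR) and spike-and-slab
models share the data equation Y = 1 mu' + X B + E with rows of E
multivariate normal N(0, R0), R0 unstructured — note the deliberate
asymmetry with the diagonal-R multivariate GBLUP: each follows its own
model equation. The Gibbs cycle samples trait intercepts, marker-effect
rows (multivariate-normal full conditionals under a common effect
covariance for BRR; per-cell Bernoulli inclusion indicators with
trait-specific Beta-prior inclusion probabilities and exact zeros for
the spike-and-slab), the effect covariance and R0 from inverse-Wishart
full conditionals, and finally imputes every masked phenotype cell from
its conditional normal given the current parameters — the augmentation
that lets these models run under CV2. The RKHS model replaces X B by a
sum of individual-level effect matrices, one per kernel, each with
covariance Sigma_k ⊗ K_h; sampling works in each kernel's eigenbasis
where the full conditional factorizes over eigencomponents. Inner loops
are compiled (RcppArmadillo) and all draws use R's RNG, so chains are
bit-reproducible from `set.seed`.

Sampler defaults are 12000 iterations, 2000 burn-in, thinning 5 — a
desk-scale choice; the tests and the acceptance script use shorter,
explicitly configured chains because the quantities they check (ridge
limits, inclusion probabilities, posterior-mean rankings) stabilize
quickly. Hyperpriors are weakly informative and scale-aware:
inverse-Wishart degrees of freedom t + 3, scales split the empirical
phenotypic variance half genetic / half residual, with the genetic share
divided by the summed marker variance (marker models) or the kernel
count (RKHS). The spike-and-slab inclusion prior is Beta(1, 4) (prior
mean 0.2) with a scaled-inverse-chi-squared slab variance per trait.

**Multivariate random forest.** Trees grow on bootstrap samples; at each
node `mtry` candidate markers are scored by the sum over traits of the
within-node sum-of-squares reduction, each trait normalized by its node
sum of squares, so traits on different scales contribute comparably
(the normalized-composite rule of multivariate forest software).
Splitting respects the minimum terminal-node size; tie-breaks are fully
deterministic (lowest marker index, then lowest threshold, strict
improvement required). Hyperparameters — trees {100, 200, 300}, mtry
{80, 100, 120}, node size {3, 6, 9} — are tuned per training set by
inner 5-fold cross-validation on variance-normalized mean squared error
(a standard loss; the tuning loss is not otherwise pinned down), and
tuning happens inside each training fold rather than once globally. The
forest requires complete training responses and therefore runs only
under CV1-style schemes, where the training set is fully phenotyped.

## Cross-validation schemes

Five folds, ten repeats by default; fold sizes differ by at most one and
plans are shared across models so comparisons are paired. Two analyses
are supported: the same trait under both conditions (the secondary trait
is the target trait's expression under the other management), and a
target trait with its most genetically correlated secondaries (selected
by absolute genomic correlation, derivative indices excluded, ties
broken alphabetically). The masks are: UV-CV1 — target hidden on the
validation fold; MV-CV1 — all modeled traits hidden on the validation
fold; MV-CV2 — target hidden on the validation fold, secondaries visible
everywhere. Models read phenotypes only through an accessor that blanks
masked cells, which is verified by sentinel-poisoning tests: overwriting
every hidden cell with 9999 leaves every model's fit bit-identical.

Accuracy is the Pearson correlation between predictions and the
held-out adjusted means over the validation genotypes; cells with zero
variance are reported as undefined and excluded from aggregation with a
count. The cell summary is mean ± SE with SE = sd over the fold-repeat
accuracies divided by the square root of their number. Duncan's multiple
range test runs per comparison row on the raw accuracies (no Fisher-z
pre-transform, matching the common implementation), using studentized
range quantiles at the protection levels (1 − alpha)^(p − 1); letters
come from maximal non-significant ranges with the containment rule. The
Fisher z comparison of two accuracies uses atanh with the panel size as
the effective n — the effective sample size for correlations estimated
by cross-validation is genuinely ambiguous (fold size, panel size, or
cell count), so the choice is configurable through the function's
arguments.

## The synthetic study

The generator emulates the structure the analysis assumes: ~250 inbred
genotypes; biallelic markers simulated independently (no linkage
disequilibrium) under Hardy–Weinberg proportions deflated to a residual
heterozygosity of 2 %, with minor allele frequencies uniform on
(0.05, 0.5) and 2 % missing calls; true breeding values drawn from
N(0, H ⊗ G) with the realized G, so GBLUP is exactly correctly
specified (an explicit marker-effect mode with the same covariance
exists for the SNP-BLUP equivalence checks); and plot values composed of
a grand mean (10 trait units), the breeding value, year
(variance 0.25), replicate-within-year (0.05), genotype-by-year, and
residual effects over 2 years × 2 replicates × 2 conditions. A trait's
genetic values under the two conditions are drawn jointly with
cross-condition correlation 0.6 — a moderate value chosen once as
realistic for the same trait under contrasting managements, consistent
with multivariate models helping under CV2 but not trivially so. The
default seven-trait architecture spans entry-mean heritabilities from
0.15 to 0.9 and genetic correlations with the yield trait from −0.43 to
+0.34, mirroring the spread seen in multi-trait wheat panels. The
default marker count (5000) is a desk-scale stand-in for array-scale
data: all constructions are per-marker sums, so marker count affects no
code path. One statistical consequence of simulating markers without
linkage disequilibrium deserves note: as the marker count grows far
beyond the panel size, the realized G approaches a sphere (all
eigenvalues similar), which makes the genetic/residual variance split
only weakly identified and caps what any kinship-based predictor can
achieve — real arrays escape this through linkage disequilibrium, which
concentrates G's spectrum. The worked examples and the statistical
checks therefore use moderate marker-to-individual ratios (roughly 1 to
4), where the spectrum of G is informative.

What passing tests on these data do **not** show: behaviour under
linkage disequilibrium and population structure (the panel is one
unstructured population), genotype-by-environment patterns richer than
the year interaction, non-Gaussian residuals, or the actual accuracy
levels of any real trial — the original field data are not public, so
all checks are structural (equivalences, reductions, recoveries,
orderings) rather than numeric reproductions.

## Degenerate inputs and edge policies

- Markers with no observed calls are removed at filtering; filtering
  keeps boundary values (MAF exactly 0.05, missingness exactly 0.20).
- Major-allele ties in HapMap parsing break alphabetically.
- Recoding an already recoded matrix is an error, preventing silent
  double recoding.
- A design with one year and one replicate is rejected as
  non-identifiable.
- Zero-variance prediction or reference vectors yield an undefined
  accuracy (NA) with a warning, never a crash.
- Boundary REML solutions (zero genetic variance, or zero noise with a
  reduced-rank G) are legitimate outcomes; the univariate/multivariate
  reduction is checked on fixtures with interior optima, because at a
  boundary two different optimizers may clamp differently at numerically
  irrelevant magnitudes.
- Covariance updates that lose positive semidefiniteness are projected
  back (eigenvalue flooring), with relative floors so trait scales do
  not matter.

## Problem sizes used by the test suite

The suite runs everything on simulated data sized for interactive use:
panels of 40–250 genotypes and 80–600 markers, 10–20 seeds for
recovery-style checks, two-repeat/five-fold plans for the
cross-validation mechanism checks, and short, explicitly configured
Gibbs chains. These sizes were chosen so that each statistical check has
comfortable Monte-Carlo margins for its stated tolerance.
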