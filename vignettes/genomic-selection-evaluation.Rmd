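---
title: "Evaluating genomic selection in multi-family shrimp populations"
author: "famGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating genomic selection in multi-family shrimp populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

famGS evaluates genomic selection (GS) for growth traits in a
multi-family aquaculture population of the kind used in shrimp
(*Litopenaeus vannamei*) breeding programs: a single cohort of full-sib
families genotyped at genome-wide SNPs and phenotyped for body weight (g)
and body length (mm). Everything runs off a synthetic-data generator, so
the complete analysis — marker-based heritability, three genomic-prediction
models, population stratification, and cross-validation designs probing
marker density and reference/validation relatedness — is reproducible
without any external data.

The statistical backbone is the additive marker model

$$ y = 1\mu + Xg + e, $$

where $X$ is the $n \times m$ dosage matrix ($X_{ij} \in \{0, 1, 2\}$
copies of the alternate allele), $g$ the vector of additive marker
effects, and genomic estimated breeding values are $\mathrm{GEBV} = Xg$.
All models fit markers as random effects with no fixed effects beyond the
intercept. Equivalently, breeding values $u = Xg$ follow the animal model
$u \sim N(0, G\,V_A)$ with the VanRaden genomic relationship matrix

$$ G = \frac{Z Z^\top}{2 \sum_j p_j (1 - p_j)}, \qquad
   Z = X - 2p, $$

with allele frequencies $p_j$ estimated from the sample. Narrow-sense
heritability is $h^2 = V_A / (V_A + V_E)$.

# The synthetic population

The generator emulates the study population the package is calibrated to:

* **Founders.** 13 sires and 13 dams carry phased haplotypes simulated as
  a first-order Markov chain along each chromosome: the latent uniform at
  marker $j$ is copied from marker $j-1$ with probability
  $\exp(-d_{cM}/\ell)$ and redrawn otherwise. The correlation length
  $\ell$ (`ldDecay`, default 5 cM) tunes linkage disequilibrium while
  preserving the per-marker allele frequency exactly; $\ell = 0$ gives
  independent markers, and co-located markers are perfectly correlated
  for any $\ell > 0$. MAFs are drawn uniformly on (0.05, 0.5], mimicking
  a post-QC panel.
* **Map.** 44 chromosomes of 1 Morgan each (a shrimp-like karyotype),
  markers evenly spaced; 23,049 SNPs by default, matching the size of a
  post-QC 2b-RAD panel. No real map exists for this design, so the layout
  is deliberately simple.
* **Families.** Each of 13 full-sib families is produced by one sire and
  one dam (no founder sharing). Meiosis uses Poisson crossover counts at
  the Morgan scale with uniform crossover positions. Conceptually 50
  offspring exist per family and 200 are sampled uniformly without
  replacement; only sampled genomes are instantiated. Family
  representation is therefore multinomial — the real per-family counts are
  unknown, and uniform sampling is the neutral choice.
* **Traits.** 500 small-effect QTL per trait are drawn uniformly among
  the markers with Gaussian effects. Body weight and body length share
  70% of their QTL (with identical effects at shared loci), inducing a
  positive genetic correlation; the fraction is an arbitrary but fixed
  default, as no genetic correlation is reported for the calibration
  population. Environmental noise is drawn, projected orthogonal to the
  genetic values in-sample, and scaled so that the *realized* sample
  satisfies $\mathrm{var}(u)/(\mathrm{var}(u) + V_E) = h^2$ exactly; the
  phenotype is then affinely standardized to the target mean/SD (weight
  5.56 +/- 2.16 g at $h^2 = 0.321$; length 76.99 +/- 9.95 mm at
  $h^2 = 0.452$). The same affine map is applied to the true genetic
  values, so $h^2$ is untouched. This makes the generator's calibration
  exact by construction rather than approximate in expectation.
* **Missingness** is off by default (the panel emulates post-QC markers)
  and injected explicitly to exercise the QC stage; entries are masked
  independently per (individual, marker).

What the generator does *not* emulate: genotyping error, allele dropout
or other sequencing artefacts, selection, multiple generations,
non-additive variance, or a realistic LD landscape beyond first-order
decay. Passing tests therefore demonstrate internal consistency of the
methods under idealized additive full-sib data, not performance on real
genotypes.

# Quality control and imputation

Markers with missing rate above 5% **or** MAF below 0.05 are removed in a
single pass (boundary values are kept; both statistics are computed on the
same input, and a marker failing both filters is counted once).
Individuals are never filtered. Missing calls in retained markers are
imputed by the marker's mean dosage (default) or by the within-family
mean when at least two family members are called. Haplotype-phasing
imputation is deliberately out of scope: at <= 5% missingness per retained
marker, G-matrix and prediction results are insensitive to the imputation
method, and mean imputation keeps the stage dependency-free. Imputed
dosages are fractional; IBS, which needs integral dosages, is computed on
the raw pre-imputation calls with pairwise-complete marker sets.

# REML heritability

`remlH2()` fits $y = 1\mu + u + e$, $u \sim N(0, G V_A)$,
$e \sim N(0, I V_E)$ by restricted maximum likelihood: one
eigendecomposition of $G$ reduces the restricted likelihood to a
one-dimensional profile in $\log \delta$, $\delta = V_E/V_A$, maximised by
Brent search on $[-10, 10]$ (tolerance 1e-8). The bounds constrain $h^2 =
1/(1+\delta)$ to essentially $(0, 1)$; solutions pinned at either end are
flagged as boundary estimates, and negative variance components cannot
occur. The optimizer is verified in the test suite against a 101-point
grid search of an independently coded restricted likelihood (direct
solve/determinant route).

Two estimator behaviours are worth knowing about:

* With a **near-identity** $G$ (unrelated individuals), $\delta$ is barely
  identified and the $[0,1]$-constrained estimator has a large positive
  mean under a pure-noise phenotype (~0.3-0.4 at the sizes we examined).
  This is intrinsic to constrained REML, not an implementation artefact;
  the null-behaviour test therefore uses family-structured genotypes,
  where $h^2$ is identified and null estimates concentrate near zero.
* With 13 full-sib families, single-replicate estimates at $n = 200$ are
  noisy (SD ~ 0.13 at full density) because the between-family contrasts
  carry few degrees of freedom; calibration statements are therefore made
  about means over 20 replicates.

`h2DensityCurve()` subsamples the panel at a ladder of marker densities
(default 0.05 K ... 20 K), rebuilding $G$ and re-running REML for each of
50 uniform subsets per density, and reports per-density means — the
classic attenuation-then-plateau curve: sparse panels estimate
relationships noisily, which dilutes $h^2$ towards zero.

# Prediction models

* **RR-BLUP** (`fitRRBLUP()`): the ridge closed form
  $\hat g = (Z^\top Z + \lambda I)^{-1} Z^\top (y - \bar y)$ on the
  training-centered design, evaluated through the equivalent $n \times n$
  dual system. $\lambda$ equals the REML variance ratio times the
  VanRaden denominator, which splits $V_A$ evenly across markers and
  makes $X\hat g$ reproduce the $G$-matrix BLUP exactly — the package's
  central correctness oracle (checked to 1e-6 relative tolerance).
* **BayesA** (`fitBayesA()`): single-site Gibbs sampler with
  marker-specific variances under a scaled-inverse-$\chi^2(\nu, S)$ prior
  ($\nu = 5$; $S$ chosen so the markers jointly explain $R^2 = 0.5$ of
  the phenotypic variance a priori).
* **Bayesian LASSO** (`fitBayesLasso()`): double-exponential prior via
  the normal scale mixture, inverse-Gaussian full conditionals for the
  per-marker $\tau_j^2$, and a Gamma(1.1, rate) hyperprior on
  $\lambda^2$ whose mode sits at the value implied by the same $R^2$
  heuristic.

Both samplers run 40,000 iterations with 10,000 burn-in by default,
sample full conditionals in a fixed order (intercept, effects in index
order, variances, residual), and are implemented in C++ using R's RNG, so
`seed` makes chains bit-reproducible. Test hooks freeze the variances
(or $\tau^2$) so the conditional posterior mean can be checked against
the implied (weighted-)ridge closed form within Monte-Carlo error;
Monte-Carlo standard errors are estimated by batch means over stored
thinned samples. Cross-validation drivers default to a reduced desk-scale
profile (4,000/1,000), which the pipeline log flags; the full-length
chains are a config switch away.

GEBVs are reported on the deviation scale,
$(X - \text{training centers})\,\hat g$: the intercept shifts every
candidate equally and cancels from every correlation-based accuracy, so
raw-$X$ and centered predictions are equivalent where it matters.

# Stratification

The IBS kinship (proportion of alleles shared identical by state) is
transformed to distances $D = 1 - \mathrm{IBS}$ — the standard choice for
a similarity in $[0,1]$ — and embedded by classical (Gower) scaling:
eigendecomposition of $-\tfrac12 J D^{\circ 2} J$, coordinates scaled by
the square roots of the leading eigenvalues; requested axes with
non-positive eigenvalues are zeroed and flagged. Clustering runs k-means
(Lloyd, k-means++ seeding, best of 50 restarts) on the first three axes.
Because no selection rule for the number of subpopulations is prescribed,
`chooseK()` defaults to maximising the mean silhouette width over a
candidate range; callers can always fix `k` explicitly.

One caveat recorded here because it shaped a test: G and IBS are almost
perfectly *linearly* concordant on family data (Pearson ~ 0.97), but
global rank correlation of off-diagonal entries is much weaker, because
the two statistics order the large near-zero cloud of unrelated pairs
differently (centered cross-products versus raw allele sharing). The
concordance test asserts the linear agreement and the full-sib/unrelated
separation, not a global rank correlation.

# Cross-validation designs

Prediction accuracy is
$r(\mathrm{GEBV}, y) / \sqrt{h^2_{\text{full}}}$, with the full-panel
REML estimate of the trait in the denominator (recomputed per dataset)
and the sign preserved — distant-validation designs can and do produce
negative accuracies.

* **Five-fold CV**: a random partition into five folds whose sizes differ
  by at most one; each individual receives exactly one out-of-fold GEBV
  and the accuracy is the single correlation over the pooled out-of-fold
  predictions (per-fold correlations are kept as diagnostics).
* **Density CV**: for each density in the ladder, 50 uniform marker
  subsets; each subset and fold partition is shared across models, so
  model comparisons are paired. The full panel runs once as a reference.
* **DIST/RAND**: DIST holds out each subpopulation larger than 30 as the
  validation set (reference = all others); RAND draws three stratified
  80/20 splits within every subpopulation. RAND replicates use
  independent seeded draws, so their validation sets may overlap.

# Problem sizes used by the shipped checks

The test suite exercises the qualitative claims at reduced sizes chosen
as a package design point: heritability recovery runs 20 replicates at
the full 200 x 23,049 scale; the density-response check uses a 6,000-marker
dataset (densities 50 and 3,200 against the full panel, two subsets per
density, 4,000/1,000 chains); the relatedness check uses twenty
1,200-marker datasets with 2,000/500 chains, where the DIST < RAND
ordering is insensitive to chain length; k is chosen over 2..6 there,
which pigeonholes at least one subpopulation above the DIST size
threshold. `scripts/acceptance.R` recomputes the calibration quantities
at the full stated scale (20 replicates of 200 x 23,049; 50 phenotype
replicates).

# Numerical choices and degenerate inputs

* GRM eigenvalues are clipped at zero before REML; the GRM validity check
  tolerates eigenvalues down to $-10^{-8}$ times the largest.
* QC threshold comparisons carry a $10^{-9}$ float guard so exact-boundary
  markers (missing rate exactly 5%, MAF exactly 0.05) are kept.
* Constant phenotypes give zero marker effects and the constant as
  intercept in RR-BLUP, and a hard error in the samplers (a zero-variance
  phenotype makes the scale heuristics meaningless).
* A monomorphic-only panel (zero VanRaden denominator) is a hard error.
* Candidate/training marker mismatches in `predictGebv()` are hard
  errors; markers are never silently reordered.
* k-means restarts that converge with an empty cluster are retried
  (bounded); `k = n` returns the trivial singleton clustering directly.
* Gibbs chains abort with a diagnostic if the state goes non-finite;
  non-convergence is otherwise not auto-detected.

# Limitations

* Calibration anchors (heritabilities, phenotype scales, the plateau at
  ~3.2 K markers, DIST < RAND) are properties of the emulated design; the
  package cannot reproduce the original study's exact real-data numbers,
  since those genotypes were never deposited.
* The REML sampling noise at 13 families means single-dataset
  heritability estimates should be read with wide error bars; the package
  reports replicate means for that reason.
* Mean-dosage imputation is a simplification relative to
  haplotype-phasing methods; at the default missingness it is
  inconsequential downstream, but at high missingness it would attenuate
  relationships.
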