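---
title: "Partitioning genetic variance to the subgenomes of an allopolyploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning genetic variance to the subgenomes of an allopolyploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgblup)
```

## The model

An allopolyploid such as bread wheat carries several ancestral subgenomes (A,
B and D) that undergo disomic inheritance. Treating the crop as a diploid
hides the contribution of each subgenome to the genetic variance. With markers
assigned to subgenomes by chromosome, the usual genomic-prediction mixed model

$$y = 1\mu + X\beta + Z g_G + \varepsilon, \qquad
  g_G \sim N(0, \sigma^2_G K_G), \quad \varepsilon \sim N(0, \sigma^2 I)$$

(environments/trials as fixed effects $\beta$, lines as random effects) can be
refined by splitting the total genetic effect $G_j = A_j + B_j + D_j$:

$$y = 1\mu + X\beta + Z g_A + Z g_B + Z g_D + \varepsilon,$$

with $g_s \sim N(0, \sigma^2_s K_s)$ and each $K_s$ built from only that
subgenome's markers. Because no markers are shared across subgenomes, the
covariance of additive-by-additive interactions *between* subgenomes is the
Hadamard product of the component kernels, giving the full subgenome
interaction model with terms $g_{AB}, g_{AD}, g_{BD}$ (and optionally the
three-way $g_{ABD}$) whose covariances are $K_A \odot K_B$ etc. The line-level
sums of the fitted BLUPs are whole-genome (GEBV) and subgenome (SGEBV)
breeding values.

### Kernels

Additive kernels follow the cross-product construction
$K = c^{-1}(M - P)(M - P)^T + 0.01\,I$ with $P$ the matrix of twice the
allele frequencies and $c = 2 p^T(1 - p)$. For boolean-coded inbred scores
(\{0,1\}), which is what both real wheat datasets and the synthetic generator
produce, the package centers by column means and uses
$c = \sum \bar p (1 - \bar p)$ — the inbred analogue; a `double_inbred` flag
doubles the scores to \{0,2\} for the literal diploid formula instead. The
0.01 ridge ("nugget") restores full rank after centering.

The exact whole-genome epistatic kernel is
$H = K \odot K - c^{-2} (W \odot W)(W \odot W)^T$ with $W = M - P$; the
correction removes squared self-pairs, so $H$ equals the kernel of all
distinct marker-pair products. $K \odot K$ is its large-$m$ approximation
(`exact = FALSE`).

**Nugget placement.** Products of kernels must be formed from nugget-free
components — otherwise the exact pairwise identity
$H = 2 c^{-2} E E^T$ breaks — so `build_kernels()` constructs all components
without a ridge, forms the Hadamard products, and only then adds each model
kernel's own 0.01 ridge. `interaction_kernel()` refuses ridged inputs rather
than silently absorbing the error.

### Population structure

Subgenomes segregate independently under Hardy–Weinberg equilibrium, but
breeding programs are structured, which makes the three subgenome kernels
collinear and the variance partition unstable. The remedy implemented here
operates on the whole marker matrix at once: take the SVD of the
column-centered $M$, keep the first $k$ principal-component scores as a fixed
covariate matrix $Q$ (added to the model as $ZQ\gamma$), and rebuild the
marker matrix with those $k$ singular values zeroed. Kernels built from the
deflated matrix $\tilde M$ are free of the removed structure in every
subgenome simultaneously. GEBVs are then reported as the sum of the centered
structure contribution $Q\gamma$ and the genetic effects.

Choices the decomposition has to make, and what this package does:

* **Centering.** The SVD is applied to the column-centered matrix; the column
  means are restored to $\tilde M$ afterwards so that downstream kernel
  construction can re-center with its own frequency estimates (which are
  recomputed from $\tilde M$).
* **Scaling of Q.** $Q$ holds PC scores (left singular vectors times singular
  values); each column is divided by its standard deviation before entering
  the fixed design. The fit is invariant to this scaling; it only conditions
  the solve.
* **Sign convention.** Each score vector's sign is fixed so its
  largest-magnitude element is positive, making results reproducible across
  BLAS implementations.
* **Choosing k.** `collinearity_profile()` re-derives the subgenome kernels
  for a range of `k` and reports the pairwise correlation of their entries;
  the usual choice is the elbow where the curves level off (`k = 5` is the
  shipped default in the examples). `k` is always an explicit user parameter.

### REML

Variance components are estimated by average-information (AI) REML, written
for dense multi-kernel models at desk scale ($n \lesssim 2000$ records, no
approximation switches):

* the phenotype covariance $V = \sum_l \sigma^2_l Z K_l Z^T + \sigma^2 I$ is
  Cholesky-factorized each iteration; the restricted likelihood uses the
  projection-matrix formulation;
* updates are AI steps with step halving against the exact likelihood; a step
  that cannot improve the likelihood falls back to a scaled-gradient (EM-type)
  move. Accepted iterations therefore never decrease the likelihood;
* components are bounded below at $10^{-8} \times$ the phenotypic variance;
  a component finishing on the bound is reported as exactly 0 and flagged
  `boundary`, and its BLUP vector is exactly zero;
* convergence is an absolute log-likelihood change below `1e-6` (default);
  non-convergence is an error carrying the likelihood trajectory;
* starting values split the phenotypic variance equally across all
  components;
* trial fixed effects use the reference-level convention (first level
  dropped); a singular fixed design is an error naming the aliased columns.

Standard errors and sampling correlations of the estimates come from the
inverse AI matrix. AIC is $-2\ell_R + 2t$ with $t$ counting all variance
parameters, boundary-clamped ones included — a deliberate, recorded
convention, comparable only across fits sharing a fixed design. The
likelihood-ratio test for added variance components uses the boundary-mixture
null $0.5\chi^2_0 + 0.5\chi^2_d$ by default (a plain $\chi^2_d$ is available
by flag), since the null value of a variance lies on the edge of its
parameter space.

### Cross-validation

`cross_validate()` reproduces the replicated masking scheme: per replicate
the lines are split into `folds` groups — group sizes are
$\lfloor n/\text{folds}\rfloor$ with the remainder pooled into the final
group, so 1,447 lines give $4 \times 289 + 291$ — all records of a fold's
lines are masked, the model refit, and masked lines predicted through the
kernel rows connecting them to the training lines (kernels and allele
frequencies are computed once from all genotypes; the genotyping of all lines
precedes any phenotyping decision). Pooled predictions are correlated once
per replicate against "true" values from an identity-covariance fit of the
same trial-adjusted model, so models are compared on identical line samples.
The structure contribution $Q\gamma$ is included in the predicted
whole-genome value by default (`include_structure = FALSE` excludes it).
If every genetic component collapses to the boundary the predictions are
constant and that replicate's accuracy is reported as 0.

## Quality control and data conventions

Markers are filtered for minor-allele frequency $\ge 0.01$, missingness
$\le 30\%$ and heterozygosity $\le 10\%$ (defaults; all rules evaluated on
the input matrix so the surviving set is order-independent, and filtering
precedes imputation). Remaining missing scores and heterozygous calls are
replaced by the per-marker population mode — the homozygous major allele —
with ties broken deterministically toward the lower score and logged. Mode
imputation is a deliberate simplification: it is deterministic, testable, and
not part of the statistical framework being studied; an `imputer` hook
accepts any user-supplied routine for users who prefer model-based
imputation. Phenotypes are standardized to zero mean and unit variance
globally (never within environment, to preserve cross-environment
relationships), and the scale is retained for back-transformation.

## The synthetic generator

`simulate_genotypes()` / `simulate_phenotypes()` emulate the features of an
allohexaploid breeding population that the methods actually exercise:

* three subgenomes with unequal marker counts (600/600/300 by default) and
  unequal diversity (the D genome's allele-frequency spread is halved,
  mirroring its bottlenecked history);
* subpopulation structure: Balding–Nichols-style drift of subpopulation
  allele frequencies around ancestral values (`divergence`, default 0.1,
  three subpopulations) — enough that the leading PCs separate subpopulations;
* inbred \{0,1\} genotypes, realized MAF floor enforced by redrawing;
* per-subgenome additive effects (centered scores × normal effect sizes) and
  sampled cross-subgenome epistatic pairs (default 200 per term; sampling
  keeps the generator $O(n \cdot \text{pairs})$ while the kernels model all
  pairs implicitly), every term rescaled so its realized variance equals the
  configured component exactly — defaults
  $\sigma^2_A{:}\sigma^2_B{:}\sigma^2_D = 0.3{:}0.4{:}0.1$,
  $\sigma^2_{AB} = 0.2$, $\sigma^2_e = 1$;
* an unbalanced multi-trial layout: a few check lines replicated in every
  trial, other lines observed in a random subset of trials, optional missing
  records.

What it does **not** emulate: linkage disequilibrium along chromosomes,
realistic site-frequency spectra from coalescent history, selection or
pedigree dynamics, and genotype-by-environment interaction. Passing tests
therefore demonstrate the statistical machinery under known architecture —
not that any particular real population has these properties.

## Worked example

```{r example, eval = FALSE}
cf <- sim_config(n_lines = 300, m = c(A = 120, B = 120, D = 60), seed = 42)
pop <- simulate_population(cf)
ph  <- standardize_phenotypes(pop$pheno, "y")

# choose k from the collinearity diagnostic
prof <- collinearity_profile(pop$markers, ks = 0:5)
plot_collinearity(prof)

basis <- decompose_structure(pop$markers, k = 5)
ks    <- build_kernels(deflate_markers(basis), "ABDxABD")
fit   <- fit_reml(model_spec(ph, "y", ks, structure = basis))
tidy(fit)          # variance components with SEs and boundary flags
autoplot(fit)      # the same, graphically

eff <- assemble_effects(fit)
autoplot(eff)      # GEBV vs SGEBV with 95%-quantile guides
quantile_report(eff)

cv <- cross_validate(ph, pop$markers, "y", model = "ABDxABD", k = 5,
                     folds = 5, reps = 10, seed = 1)
glance(cv)
```

## Problem sizes and numerical notes

The examples, tests and the acceptance script run at desk scale — a few
hundred lines, one to two thousand markers, replicate counts of 5–50 — sizes
chosen so a full pipeline run completes in minutes on a laptop while leaving
every estimator in its well-behaved regime. The dense REML solver costs one
Cholesky factorization of the record-level covariance per iteration
($O(n^3)$), which is the right trade-off below a few thousand records.

Known limitations:

* boundary variance estimates are biased upward by construction (they cannot
  be negative), so averages of clamped estimates over replicates exceed a
  true value of zero; tests and diagnostics treat exact zeros, not small
  means, as the boundary signature;
* the three-way interaction kernel is implemented but excluded from
  `build_kernels(..., "ABDxABD")` by default, because its component is
  routinely estimated on the zero boundary and only adds iterations —
  `three_way = TRUE` restores it;
* with unrelated lines and unreplicated records the epistatic kernel is
  nearly the identity and its variance is confounded with the residual; no
  fitting procedure can rescue that design, and the package's tests use
  related populations with replicated records where the term is identified;
* AIC follows the variance-parameter-only convention; other software may
  count parameters differently, so cross-software AIC equality should not be
  expected.
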