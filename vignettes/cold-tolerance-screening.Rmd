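---
title: "Screening germplasm for cold tolerance with a Smith-Hazel index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening germplasm for cold tolerance with a Smith-Hazel index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldscreen)
```

## The screening problem

Cold stress at the seedling stage is a major constraint on soybean and
other chilling-sensitive crops. A practical, non-destructive screen
measures chlorophyll-fluorescence and leaf traits on a diverse panel of
genotypes grown under control (22 degC) and cold (4 degC) conditions in a
replicated complete-randomization design, and then ranks genotypes with a
single linear *cold tolerance index* (CTI) built from the traits that are
both highly heritable and tightly associated with cold damage: the visual
leaf injury index (LI), the fraction of open PSII centres (qL) and the
maximum PSII quantum efficiency (Fv/Fm).

`coldscreen` implements that workflow end to end: a calibrated simulator
of replicated multi-trait trials, variance-component estimation by
expected mean squares, assembly of the phenotypic (P) and genotypic (G)
covariance matrices, the Smith-Hazel index, tolerance categorization, and
the supporting trait analytics (stress ratios, annotated correlations,
PCA).

## The model behind the simulator

For genotype $i$, trait $t$, treatment $\tau$, trial $k$ and replicate
$j$, the generator draws

$$
y_{itkj\tau} \;=\; \mu_t + \delta_t\,[\tau=\text{cold}]
  + u_{kt} + s_{t\tau}\,( g_{it} + e_{itkj\tau} ),
$$

where $\mu_t$ is the control mean, $\delta_t$ the additive cold shift,
$u_{kt} \sim N(0, \sigma_u^2)$ an additive trial effect shared across
genotypes, $g_i \sim N_p(0, G)$ one genotypic effect vector per genotype,
and $e \sim N_p(0, E)$ an independent residual per replicate. The scale
factor $s_{t\tau}$ is 1 under cold and `control_attenuation` (default
0.2) under control: cold stress is what reveals varietal differences,
while under control conditions all genotypes sit in a narrow band (control
qL spans a few hundredths of a unit, against a cold-stress spread of more
than 0.6). Values are finally clipped to trait bounds (qL, Fv/Fm and
PhiNO in $[0,1]$; LI in $[1,8]$; non-negative NPQt, SPAD, LT, leaf area).

Three modelling choices deserve comment:

* **Attenuation applies to residuals as well as genotype effects.** $G$
  and $E$ are calibrated on the cold-response scale, where trait
  dispersion is an order of magnitude larger than under control (NPQt
  spans roughly 7-43 under control but 370-1750 under cold). Applying the
  cold-scale residual to control observations would produce physically
  impossible control values (NPQt control draws clipping at zero for a
  third of the panel) and destroy cold/control ratios. Compressing the
  whole deviation term under control reproduces the narrow control bands
  a real screen shows. For the same reason the preset uses a per-trait
  attenuation, 0.025 for NPQt and 0.2 elsewhere.
* **Trial effects are additive and shared across genotypes.** There is no
  genotype-by-trial interaction term; two seasonal runs of the same
  screen are treated as exchangeable replications of the same genetic
  signal. This is the simplest structure consistent with pooling trial
  runs, and it is what the default `trials = "average"` analysis assumes.
* **Leaf injury is simulated continuously.** The ordinal 1-8 field scale
  is averaged over plants per replicate in practice, which yields
  fractional values (minimum observed scores like 1.67); the index treats
  LI numerically either way. `ordinal_li = TRUE` rounds onto the integer
  scale for users who want strictly ordinal scores.

### The calibrated preset

`cold_preset()` fixes the study conditions the package's tests and
examples use: 100 genotypes, 2 treatments, 3 replications, 8 traits.
Control means and cold shifts were chosen so that simulated trait ranges
match a diverse seedling-stage soybean screen (cold qL roughly 0.18-0.81,
Fv/Fm 0.10-0.80, NPQt centred near 1000, LI spanning most of 1-8, SPAD
21-39, leaf thickness 0.10-0.37 mm). Genotypic standard deviations are
set per trait on the cold-response scale, and the residual covariance is
$E = G/5$, so with $r = 3$ replicates every trait has an entry-mean
broad-sense heritability of exactly

$$
H^2 \;=\; \frac{\sigma_g^2}{\sigma_g^2 + \sigma_e^2 / r}
      \;=\; \frac{5}{5 + 1/3} \;=\; 93.75\% ,
$$

consistent with the ">90%" heritability regime in which a selection index
over raw trait values is sensible. The genotypic correlation structure
places $\rho(\text{LI}, \text{qL}) = -0.22$ and
$\rho(\text{LI}, \text{Fv/Fm}) = -0.30$ (injury is genetically opposed to
photochemical performance), $\rho(\text{qL}, \text{Fv/Fm}) = +0.5$,
moderate negative correlations of NPQt with both photochemical traits,
and leaves SPAD and leaf area uncorrelated with the rest. Because $E$
shares the correlation structure of $G$, the correlation among cold
*entry means* equals the genotypic correlation exactly -- these are the
values the generator "encodes" and that recovery tests estimate.

What the generator does **not** emulate: genotype-by-trial interaction,
spatial field trends, measurement-device drift, non-Gaussian residuals,
and any mean-variance coupling beyond the two-point control/cold
attenuation. Passing recovery tests on these panels therefore shows the
estimators are correct under the stated model, not that real trials are
free of those complications.

## Variance components and heritability

All estimation is per treatment. Within a treatment the design is a
balanced one-way random-effects layout, so expected mean squares give

$$
\hat\sigma_g^2 = \frac{MSG - MSE}{r}, \qquad
\hat\sigma_e^2 = MSE, \qquad
F = MSG/MSE \sim F_{g-1,\; g(r-1)} .
$$

Negative $\hat\sigma_g^2$ is floored at zero with a warning, keeping
$H^2 \in [0, 100]$. Heritability is reported on the **entry-mean basis**
by default because every downstream quantity (the phenotypic covariance
matrix, the CTI) operates on genotype means; the plot basis
$\sigma_g^2/(\sigma_g^2+\sigma_e^2)$ is available via `basis = "plot"`.
Genetic advance uses $GA = k\,(H^2/100)\,\sigma_p$ with
$\sigma_p = \sqrt{\hat\sigma_g^2 + MSE/r}$ and selection intensity
$k = 2.06$ (top 5%) by default. Both the genotypic coefficient of
variation ($100\,\sigma_g/\bar{x}$) and its phenotypic analogue are
emitted, since screening reports differ in which they tabulate.

With multiple trials the default collapses replicates within trial and
treats trial means as the replication units (`trials = "average"`);
`trials = "pool"` uses every observation. On a single-trial panel the two
coincide.

Genotypic **covariances** come from the analysis of cross-products, the
exact bilinear mirror of the ANOVA: genotype and error mean
cross-products MPG and MPE give $\widehat{\text{cov}}_g = (MPG - MPE)/r$.
The phenotypic matrix is taken on entry means, $P = MPG/r = G + E/r$,
which is the covariance the index actually faces when scoring genotype
means. Symmetry is exact by construction; $P$'s condition number is
checked (threshold $10^8$) and a singular $P$ blocks index estimation
with the most collinear trait pair named.

## The Smith-Hazel index

Given economic weights $a$ (all ones by default, since the index is used
as an unweighted tolerance score), the coefficients solve

$$ P\, b = G\, a $$

as a linear system (no explicit inverse), and each genotype is scored by
the exact dot product $\text{CTI} = b' X$ on its cold entry means. No
standardization or sign-flipping is applied: the index is used on raw
trait values, where high LI dominates the score and low CTI therefore
means tolerant. A `--orient`-style option (`orient` argument) can negate
beneficial traits for users who prefer strictly monotone-bad indices, and
published coefficient vectors can be supplied directly via
`index_coefficients()`, bypassing estimation entirely.

Ranking is ascending in CTI with ties broken by genotype id. The five
tolerance categories (T, MT, MS, S, SS) are assigned, by default, by
cutting the observed CTI range into five equal-width bins -- a
deterministic, scale-free rule chosen because published categorizations
rarely state their breakpoints; quantile bins and user-supplied
breakpoints are provided as alternatives. If every score is identical the
whole panel lands in the middle class with a warning.

Smith-Hazel theory says $b = P^{-1} G a$ maximizes the correlation
between the index and the aggregate genotypic worth $a'g$ among all
linear phenotype indices. The test suite verifies this property against
the simulator's ground truth: the estimated index's correlation with
worth is beaten by at most ~1% of 1,000 random unit weight vectors,
the violations being the sampling accidents expected when $b$ itself is
estimated from 100 genotypes.

## Trait analytics

* **Stress ratios**: per genotype and trait, cold entry mean over control
  entry mean. Control means within `epsilon` (default $10^{-8}$) of zero
  flag the ratio as missing rather than emitting infinities.
* **Correlations**: pairwise-complete Pearson $r$ over the ratio table
  (or cold entry means via `ratio_based = FALSE`), two-sided p from
  $t = r\sqrt{(n-2)/(1-r^2)}$, stars at 0.05/0.01/0.001 per pair --
  mirroring conventional screening figures -- with Holm-adjusted
  p-values emitted alongside for family-wise rigor. $r$ and $r^2$ are
  reported as separate columns; a signed "$r^2$" is never printed.
* **PCA**: singular value decomposition of the centred, unit-scaled
  table (correlation-matrix PCA) because the traits span wildly different
  scales; covariance-matrix PCA via `standardize = FALSE`. Component
  signs are fixed so each component's largest-magnitude loading is
  positive, making loadings reproducible across platforms. Variance
  percentages always sum to 100.

## Numerical choices and degenerate inputs

* Covariance inputs are validated as symmetric PSD (eigenvalue tolerance
  $-10^{-8}$ relative to the largest eigenvalue).
* The index solve records its achieved residual
  $\max_i |(Pb - Ga)_i|$ and warns above $10^{-8}$.
* Constant trait columns: ANOVA reports $F = \text{NaN}$ with a warning,
  correlations report missing entries, PCA refuses standardization.
* All-equal CTI scores collapse to the middle category with a warning;
  ranks remain a permutation.
* Simulation and all stochastic tests are seeded; identical
  configurations yield byte-identical panels and reports.

## Problem sizes used in the test suite

The recovery studies run at sizes where Monte-Carlo error is comfortably
inside the asserted tolerances: heritability recovery uses 200 panels of
100 genotypes x 3 replicates (median $\hat H^2$ within 2 points of the
closed form); genotypic covariance recovery uses 100 panels of 500
genotypes (median entrywise error under 15%, measured ~2%); ratio
correlation recovery uses 50 panels of 100 genotypes (mean within 0.03 of
the encoded correlations); the optimality check pools 10 panels x 1,000
random weight vectors. These sizes were chosen so that each study's
sampling error is a fraction of its tolerance.

## Known limitations

* Estimation is method-of-moments ANOVA on balanced data; there is no
  REML/mixed-model path, no genotype-by-environment modelling and no
  spatial correction. Unbalanced panels are rejected rather than
  approximated.
* The entry-mean phenotypic matrix assumes the index will score genotype
  means computed from the same number of replicates used in estimation.
* Equal-width categorization depends on the observed CTI range, so a
  single extreme genotype can shift every bin; use quantile bins when
  outliers are a concern.
* With $H^2 \approx 94\%$ and 100 genotypes, the single most tolerant
  genotype by CTI coincides with the best truth-worth genotype in only
  about two-thirds of simulated panels (it is within the top three in
  ~96%): even a near-optimal index cannot reliably resolve order
  statistics separated by less than the entry-mean noise. Screens should
  carry a shortlist forward, not a single winner.

## A complete run

```{r, eval = FALSE}
library(coldscreen)

report <- run_screening(config = panel_config(seed = 42))
report
write_screening(report, "results/")
```

The written directory contains the per-trait statistics (`stats.csv`),
the P/G matrices and index coefficients (`matrices.json`,
`coefficients.json`), the full CTI table (`cti.csv`), stress ratios,
correlation matrices and PCA tables, plus a human-readable `report.md`.
Machine-readable files carry full precision; only the report rounds.
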