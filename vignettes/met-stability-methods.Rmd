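---
title: "Methods: mixed-model stability selection for multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model stability selection for multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

## The model

`metstab` analyses multi-environment trials laid out as randomized complete
block designs repeated across environments (location–year combinations):

$$y_{ijk} = \mu + E_j + B_{k(j)} + G_i + GE_{ij} + \varepsilon_{ijk},$$

with environment $E_j$, block-within-environment $B_{k(j)}$, genotype
$G_i$, interaction $GE_{ij}$ and residual all mean-zero Gaussian.
Estimation is REML. Two parameterizations coexist deliberately, mirroring
how these trials are reported:

* **genotype random** — the basis of every index. BLUPs $g_i$ and
  $ge_{ij}$ and environment means $u_j = \hat\mu + \hat E_j$ yield the
  genotypic values $GV_{ij} = u_j + g_i + ge_{ij}$, and $\sigma^2_g$
  enters the phenotypic variance and heritability.
* **genotype fixed** — the basis of the significance report. The genotype
  effect is tested by a Wald-type $F$ at the REML estimates with
  denominator degrees of freedom from the containment method,
  $(g-1)(e-1)$: the genotype effect is contained in the
  genotype-by-environment stratum, and on balanced data with interior
  estimates the statistic reduces exactly to the classical
  $MS_G / MS_{GE}$ ratio. Satterthwaite approximations are intentionally
  out of scope in this version.

Every downstream output records which parameterization produced it
(`genotype_role` on the fit; the pipeline manifest repeats it).

Random terms are tested by REML likelihood-ratio tests with the same fixed
structure in both fits. The default reference is $\chi^2_1$, the
convention most MET reports follow; because the null value of a variance
component lies on the boundary of its parameter space, the calibrated
reference is the 50:50 mixture of a point mass at zero and $\chi^2_1$,
available as `boundary_correct = TRUE` (it halves the p-value of a
positive statistic). In our null simulations at the default layout the
plain reference rejects at about half the nominal level and the mixture
restores nominal size; users comparing power across terms should prefer
the mixture.

Phenotypic-variance shares are reported per parameterization: the
genotype-fixed fit's $\sigma^2_p$ omits $\sigma^2_g$ (there is none), the
genotype-random fit includes it. Both are emitted because published
variance-share tables are ambiguous on this point.

### Numerical details

Fitting goes through `lme4::lmer`. Two optimizer settings are run and the
higher restricted likelihood kept: tight `nloptwrap` tolerances
(`xtol_rel = 1e-12`, `ftol_rel = 1e-14`) polish interior optima to
~1e-6 relative accuracy in the variance components, while the default
tolerances are more robust in near-degenerate profiles (residual variance
orders of magnitude below the other components), where the tight settings
can stall in a local basin. Negative components are handled by lme4's
boundary constraint — estimates are clipped at zero with the profile
re-optimized — and the `boundary` flag on the fit records that state.
Non-convergence is surfaced honestly: the fit is returned with
`converged = FALSE` and a warning, never silently.

The reported interaction matrix `ge` is double-centered, with its margins
folded into $g_i$ and $u_j$ (the fitted surface $u_j + g_i + ge_{ij}$ is
unchanged). Raw interaction BLUPs carry small margin components whenever
the generating interaction has random margins, because the mixed-model
equations split marginal signal between main effects and interaction by
variance ratios; the IPCA machinery below assumes a pure-interaction,
doubly-centered table.

## WAASB and WAASBY

The BLUP interaction matrix is decomposed by SVD into interaction
principal component axes. Scores use the symmetric scaling
$\text{score} = \text{singular vector} \times \sqrt\lambda$ for both
margins — standard biplot practice — so the scored margins reconstruct
the matrix. WAASB is scaling-covariant, and ranking is unaffected by this
choice; it is therefore fixed, not configurable. Axis signs follow a
deterministic convention (the largest-magnitude genotype score on each
axis is positive), which affects only plotted scores, never WAASB, since
the index uses absolute values:

$$\mathrm{WAASB}_i = \frac{\sum_k |IPCA_{ik}|\, EP_k}{\sum_k EP_k},
\qquad EP_k = \lambda_k^2 / \textstyle\sum_m \lambda_m^2 .$$

All $\min(g-1, e-1)$ axes are used by default — the full interaction, not
an arbitrary truncation; `n_axes` restricts to the leading axes (weights
renormalize) when a scree-based cut is wanted.

Mean performance and WAASB are rescaled linearly to 0–100, the desirable
end at 100: `rG` follows the trait's declared direction (plant height or
unfilled grains are lower-better in a rice ideotype; yield higher-better),
`rW` is always lower-better in WAASB. A constant vector has no usable
range and is mapped to 50 with a warning. The superiority index blends the
two at user weights, default $\theta_Y = \theta_S = 50$ (equal emphasis):

$$\mathrm{WAASBY}_i = \frac{rG_i\,\theta_Y + rW_i\,\theta_S}
{\theta_Y + \theta_S}.$$

Quadrant labels split the performance × WAASB plane at the unweighted
means of each coordinate; values exactly on a divider count as the
desirable side (above-mean performance, below-mean WAASB), so quadrant IV
is closed under ties. The weight-grid ranking re-ranks genotypes by
WAASBY as $\theta_S$ sweeps 0–100 in steps of `grid_step`; ties break by
genotype label order so the output is deterministic.

## MTSI

The genotype × trait matrix of WAASBY values (each column
direction-adjusted so 100 is always best) is validated (aligned genotype
sets, no constant columns) and factor-analysed: principal-component
extraction from the trait correlation matrix, Kaiser retention
($\lambda \ge 1$, ties kept, minimum one factor), varimax rotation with
Kaiser normalization to tolerance 1e-6, communality as the row sum of
squared rotated loadings. Factor scores use the regression method
$Z R^{-1} L$; the estimator choice is isolated in one function so a
Bartlett variant could be swapped in. Standardization uses the population
($n$) standard deviation: the choice scales all scores by a common factor,
which cancels in ranking and selection but not in the raw MTSI value, so
it is fixed and documented rather than configurable. A singular
correlation matrix (e.g. duplicated traits) falls back to a
ridge-regularized inverse (1e-8) with a warning.

The ideotype — 100 on every trait — is standardized with the same column
means and SDs and pushed through the same score equation. Then

$$\mathrm{MTSI}_i = \Big[\sum_j (F_{ij} - F_j)^2\Big]^{1/2},$$

ranked ascending. The selection count is round-half-up of
$\text{intensity} \times n_{gen}$ with a floor of one — 18 genotypes at
15 % select exactly 3. Factor contributions
$(F_{ij}-F_j)^2 / \mathrm{MTSI}_i^2$ sum to one per genotype and expose
which trait group keeps each genotype from the ideotype; a genotype
exactly at the ideotype (distance 0) is assigned equal shares.

Note one property that does *not* hold, although intuition suggests it:
improving a single trait index toward 100 can *increase* the ideotype
distance, because the regression score map makes the distance a quadratic
form with cross-terms between traits. Pulling the whole profile toward the
ideotype does shrink the distance proportionally (the map is affine), and
that is the property the test suite asserts.

Selection differentials and gains follow
$SD = X_s - X_0$, $\%SD = 100\,SD/X_0$, $SG = SD \cdot h^2$, reported on
both the BLUP mean-performance scale and the WAASBY scale. The
heritability entering $SG$ is the genotype-mean basis
$h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{gei}/e +
\sigma^2_\varepsilon/(er))$ from that trait's genotype-random fit — the
basis appropriate for means predicted across $e$ environments and $r$
blocks; the plot basis $\sigma^2_g/\sigma^2_p$ is available as an option.

## Genotypic-value indices

With $E$ environments and environment means $u_j$:

$$\mathrm{HMGV}_i = \frac{E}{\sum_j 1/GV_{ij}}, \quad
\mathrm{RPGV}_i = \frac{1}{E}\sum_j \frac{GV_{ij}}{u_j}, \quad
\mathrm{HMRPGV}_i = \frac{E}{\sum_j u_j/GV_{ij}}.$$

$u_j$ comes from the fitted model, not raw cell means, for consistency
with $GV_{ij} = u_j + g_i + ge_{ij}$ (the difference vanishes under
balance). Harmonic means require positive arguments: non-positive
genotypic values raise an error naming the offending cells rather than
silently shifting — traits with legitimate near-zero values (unfilled
grain counts) must be shifted explicitly by the caller, a deliberate
design so the shift is visible in the analysis script. The dimensionless
indices rescale to trait units by the overall mean of the genotypic
values, and `percent_gain()` converts either form to a percent advantage.

## The synthetic generator

The generator emulates the study conditions: 18 genotypes × 6 environments
(two years × three locations) × 3 blocks, one value per plot, grand mean
4360 kg/ha for grain yield. Default variance components were chosen once
as realistic for irrigated rice yield trials — environment SD 500,
block-within-environment SD 100, genotype SD 300, residual SD 400 kg/ha,
and an interaction whose IPCA spectrum is dominated by its first axis
(roughly 70/15/10 shares) — and are not tuned thereafter.

Two interaction structures are available:

* `gei_mode = "lowrank"` (default): an exact bilinear sum
  $\sum_k s_k u_k v_k^\top$ with centered orthonormal axis vectors. The
  singular values equal `gei_axis_scales` exactly, giving a controlled
  ground truth for IPCA-spectrum behaviour; row and column margins are
  exactly zero.
* `gei_mode = "iid"`: unstructured $N(0, \sigma^2_{gei})$ cells — the
  structure the REML variance-component model itself assumes. This is the
  mode for parameter-recovery studies: the exact-zero margins of the
  low-rank construction attenuate the expected genotype-variance estimate
  by $\sigma^2_{gei}/e$ (the model expects interaction noise in the
  genotype margins and finds none), so nominal-value recovery is only
  well-posed under i.i.d. cells. `gei_scales_for_variance()` converts a
  nominal interaction variance into equivalent low-rank scales when the
  spectrum-controlled mode is wanted at a given magnitude.

Multi-trait generation draws genotype effect vectors jointly with
covariance $\mathrm{diag}(\sigma_g)\,C\,\mathrm{diag}(\sigma_g)$ for a
given trait correlation matrix $C$ (PSD-validated); all other effects are
independent per trait. Randomness is organised as one root seed with a
deterministic sub-stream per (effect family, trait), implemented by
reading a fixed position of the root-seeded Mersenne–Twister output
stream; positions depend only on the family and trait index, so adding
traits never perturbs earlier draws, and nearby root seeds yield
decorrelated streams (a linear hash of the root seed does not — in our
diagnostics it measurably correlated interaction draws across consecutive
seeds, biasing replicate studies).

What the generator does *not* emulate — and what passing tests therefore
do not establish about field data: spatial trends within trials,
environmental covariates (year/location structure beyond an exchangeable
environment effect), heavy-tailed or heteroscedastic errors, missing-plot
mechanisms, and measurement artefacts. Results on synthetic data validate
the algebra and the statistical calibration of the pipeline, not the
agronomy.

## Validation problem sizes

The test suite runs every stage at the study layout (18 × 6 × 3):
REML-vs-ANOVA equivalence on 50 balanced datasets (interior estimates,
agreement within 1e-4 relative), variance-component recovery over 200
replicates (means within 2 Monte-Carlo SEs), null calibration of the
interaction LRT over 500 replicates, closed-form WAASB agreement on 100
random 5 × 4 matrices (1e-10), and the genotypic-value inequalities on
1000 random instances. These sizes keep the full suite around four
minutes on one core while leaving Monte-Carlo error well below the
assertion tolerances; `scripts/acceptance.R` repeats the same studies from
a user-supplied seed.

## Known limitations

* Heterogeneous residual variances per environment and factor-analytic
  covariance structures for the interaction term are not modelled.
* Classic AMMI on cell means (and derived statistics such as ASV) is out
  of scope; only the BLUP-based WAASB variant is provided.
* The fixed-genotype F test uses containment degrees of freedom;
  Satterthwaite/Kenward–Roger are not offered.
* Confirmatory factor analysis and oblique rotations are not offered; the
  MTSI stage assumes the correlation-based exploratory model described
  above.
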