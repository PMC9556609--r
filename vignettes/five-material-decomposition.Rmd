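---
title: "Multimodal five-material decomposition for dual-energy CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal five-material decomposition for dual-energy CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dectmix)
```

## The model

Dual-energy CT yields, for a segmented region of interest, the mean linear
attenuation coefficient at two virtual monoenergetic energies, by default
labelled (50, 200) keV. Under the linear mixing assumption, a mixture of
materials with volume fractions $f_i$ attenuates as

$$\mu_E = \sum_i f_i\,\mu_{i,E},$$

and volume conservation adds $\sum_i f_i = 1$. Two energies plus the
conservation row give a $3\times3$ linear system: three materials is the
classical ceiling for this measurement. Clinically measured values arrive in
Hounsfield units and are converted to attenuation at the input boundary via
$\mu(E) = HU(E)\,\mu_{water}(E)/1000 + \mu_{water}(E)$; everything downstream
is expressed in 1/cm, because the mixing model is linear in $\mu$, not in HU.

The package's central subject is what to do when a specimen holds more than
three materials. The motivating case is retrieved stroke thrombi: histology
quantifies the area fractions of red blood cells (RBC), white blood cells
(WBC) and the fibrin/platelets conglomerate, but is blind to two materials
that attenuate X-rays appreciably — the iodinated contrast agent (iomeprol)
enriched in the clot before retrieval, and the formalin the specimen is fixed
in. The three histology fractions $f_j^{Histo}$ (summing to 1) imply an
attenuation point

$$\vec\mu^{Histo} = \sum_{j=1}^3 f_j^{Histo}\vec\mu_j$$

in the $(\mu_{low}, \mu_{high})$ plane. The measured point $\vec\mu^{CT}$
differs from it, and the discrepancy is explained by the hidden materials:
each extra material $k$ with fraction $\tilde f_k$ pulls the point along its
characteristic direction $\vec\mu_k - \vec\mu^{Histo}$. The fractions are
recovered by minimizing

$$\mathcal L = \Big\|\big(\vec\mu^{Histo}-\vec\mu^{CT}\big) -
  \sum_k \tilde f_k\big[\vec\mu^{Histo} - \vec\mu_k\big]\Big\|_2^2,
\qquad \tilde f_k \ge 0,\; \sum_k \tilde f_k \le 1-\varepsilon .$$

The full composition then rescales the histology fractions by
$c_a = 1 - \sum_k \tilde f_k$ and appends the extras, so all $3+n$ fractions
again sum to 1; $c_s = 1/c_a$ is the inverse normalizer used on the
calibration side. With two extras whose directions are linearly independent,
an interior optimum reproduces the measured point exactly (two vectors span
the plane), so the per-energy relative *matching error*
$100\,|\mu^{opt}_E - \mu^{CT}_E| / \mu^{CT}_E$ is only informative for
specimens that end up on the constraint boundary — typically those explained
by formalin alone.

### Basis-material calibration

Attenuation coefficients of biological basis materials are not directly
measurable. Two calibration routes are implemented.

*Aqueous dilution series.* For water-based solutions, attenuation is affine
in concentration, so `fit_series()` performs two independent ordinary
least-squares fits of $\mu$ against concentration and evaluates them at the
stock concentration. This is deliberately a regression in concentration
space, not in the attenuation plane: it is the formulation that yields an
endpoint with per-parameter standard errors, reported as percent relative
errors. Water is never fitted; `water_intersection_check()` uses it purely as
the theoretical zero-concentration point all regressions should pass
through — a systematic-error diagnostic, never an error.

*Specimen groups.* For clot constituents, assumed attenuations (seeded from
tabulated mass attenuation data) are refined by multiplying each
material-energy entry by a correction factor $c_m$, $m \in [1;6]$, and
minimizing over specimens $j$

$$\mathcal L = \sum_j \Big\| \begin{pmatrix}\vec\mu_j' \\ 1\end{pmatrix} -
  M(c)\, \vec f_j^{Histo} \Big\|_2^2,$$

where $\vec\mu_j' = (\vec\mu_j^{CT} - \tilde f_{4,j}\vec\mu_4)/(1-\tilde
f_{4,j})$ removes each specimen's (unknown) formalin fraction and $M(c)$ is
the factor-scaled system matrix over the conservation row. Calibration
specimens are ones without contrast-agent exposure, so formalin is the only
hidden material. The WBC factors are conventionally frozen at 1: WBC
contributes little attenuation, and freezing it keeps the per-group problem
at 4 free factors + 4 formalin fractions. Groups are calibrated separately
and combined by a mean weighted with the inverse of each group's final cost
value — the group that fits the linear model best counts most. Weights are
normalized, so the (arbitrary) scale of the cost cancels; reports also print
the cost per mille for compactness, an interpretation choice since the
aggregation itself is scale-invariant.

## Numerical choices

- **Extra-fraction fit.** The constrained problem has 1 or 2 variables, so it
  is solved *exactly* by active-set enumeration (interior solution, the two
  single-material edges, the $\sum \tilde f = 1-\varepsilon$ edge) rather than
  iteratively. When the unconstrained two-extra solution has a negative
  component, the fit lands on a boundary — this is the mechanism that
  produces formalin-only corrections with nonzero matching error. Collinear
  characteristic directions (degenerate geometry) trigger a warning and a
  reduced single-vector fit. $\varepsilon = 10^{-6}$ keeps $c_s = 1/c_a$
  finite.
- **Group calibration.** The joint cost in $(c, \tilde f_4)$ is neither
  linear nor convex, so a global-then-local scheme is used: each specimen's
  formalin fraction is profiled out in closed form (writing
  $u = 1/(1-\tilde f_4)$ makes the adjusted point linear in $u$ along the ray
  from formalin through the measurement, so the profile is a clipped
  projection), and the remaining bounded 4-factor problem is solved by
  Levenberg–Marquardt from 12 starts (the all-ones start plus 11 uniform
  draws over the factor box $[0.25, 5]$), keeping the best minimum and
  stopping early once a start reaches numerical zero. Runs are reproducible
  bit-for-bit for a fixed seed and configuration; the optimizer contract
  (bounded global search + local refinement), not a specific algorithm, is
  the interface.
- **Three-material solve.** Direct linear solve; condition numbers above
  $10^8$ raise an error, distinguishing genuinely dependent bases (an
  infinite solution set) from merely similar materials. Out-of-gamut
  solutions (negative fractions) are returned as computed with a flag, never
  clamped: the out-of-triangle geometry is exactly what the extra-material
  correction consumes.
- **Tolerances.** Fraction sums are enforced to $10^{-6}$ in the forward
  model; histology tables printed at 3 decimals are renormalized when within
  $5\times10^{-3}$ of 1 and rejected otherwise.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `energies` | (50, 200) | keV | labels of the two monoE channels; the math never uses the literal values |
| `mu_water` | (0.2269, 0.1370) | 1/cm | HU conversion reference; a configuration constant to be set per scanner calibration, not a measured result of this package |
| `bounds_c` | [0.25, 5] | — | correction-factor search box |
| `f4_max` | 0.999 | — | formalin-fraction cap, keeps $c_s$ finite |
| `n_starts` | 12 | — | multistart budget per group |
| `noise_sigma` | 0 (generator), 0.002 in noise studies | 1/cm | additive Gaussian measurement noise per energy |
| `max_condition` | $10^8$ | — | basis conditioning ceiling |

## What the synthetic generator emulates — and what it does not

`make_aqueous_cohort()` reproduces the bench-style protocol: specimens
pipetted from stock solutions (20 mg/ml iomeprol, 40 mg/ml eosin Y
disodiumsalt, 200 mg/ml NaCl, pure water), true fractions given by volume
ratios, noiseless attenuation given exactly by the mixing model.
`make_clot_cohort()` draws histology triples from a two-mode Dirichlet
mixture (a fibrin/platelets-dominant and an RBC-dominant mode, with WBC
capped at 0.15 by rejection — compositions cluster in real clots and WBC
rarely exceeds ~15%), hides uniform formalin (0.05–0.4) and iomeprol
(0–0.065, i.e. up to ~1.3 mg/ml at the 20 mg/ml stock) fractions, and builds
measurements from the *corrected* basis attenuations so that one bundle
exercises both the correction and the calibration modules.

Noise is additive independent Gaussian per energy in $\mu$-space, applied to
measurements only. No noise model for the scanner is available to this
package, so the default study sigma of 0.002 1/cm is an illustrative choice
that reproduces the qualitative behaviour of interest — recovery accuracy
degrading steeply below roughly 0.7 mg/ml of contrast agent — not a
characterization of any device. The generator also does not emulate: image
formation (voxels, PSF, beam hardening — inputs are ROI means of virtual
monoE images), histology image processing (fractions are ingested as
numbers), the treatment of area fractions as volume fractions (taken over
unchanged, as the upstream analysis does), partial-volume contamination from
background voxels, or formalin wash-out over storage time. Passing tests on
synthetic cohorts therefore demonstrate the correctness and conditioning of
the *inference*, not the fidelity of any physical forward model.

## Worked example

```{r}
basis <- read_materials(system.file("extdata", "clot_basis_illustrative.yaml",
                                    package = "dectmix"))
visible <- basis[1:3, ]
extras <- basis[4:5, ]

cohort <- make_clot_cohort(4, visible,
                           mu_formalin = c(0.229, 0.138),
                           mu_iomeprol = c(0.433, 0.152),
                           seed = 11)
h <- cohort$histology[2, ]
fit <- fit_extra_fractions(c(cohort$measurements$mu_low[2],
                             cohort$measurements$mu_high[2]),
                           h, basis, extras)
fit
c(truth_formalin = unname(cohort$formalin[2]),
  truth_iomeprol = unname(cohort$iomeprol[2]))
```

## Design decisions on genuinely open points

- Printed report tables round fractions to 3 decimals and concentrations to
  mg/ml; a rounded fraction times the stock is therefore not always equal to
  the rounded concentration printed next to it. The package computes
  concentrations from full-precision fractions and rounds once at output.
- The endpoint determination from dilution series is implemented as two
  per-energy regressions against concentration (see above); a plane-fit
  alternative would not produce per-parameter errors of the reported form.
- Group membership for calibration is user-specified; no automatic grouping
  heuristic is provided.
- Cost values are stored raw (units $(1/cm)^2$); only displays scale them.

## Problem sizes used by the test suite

The shipped tests run, as the package's own verification scale: 200-draw
round-trip suites for the three-material and extra-material solvers; 20
single-group and 4 three-group noiseless calibration recoveries (4 specimens
per group, factors drawn from $[0.8,1.2]\cup[3.5,4.0]$); a 1000-replicate
Monte-Carlo check that dilution-series endpoints are unbiased at noise
$\sigma = 0.001$ 1/cm; and 300-replicate noise studies per concentration
level for the detection-limit behaviour.

## Known limitations

- With two independent extra materials the fit is exact by construction, so
  residual-based diagnostics carry no information there; trust assessments
  must come from the concentration-dependence of accuracy under noise.
- Histology area fractions are used as volume fractions without correction.
- The linearity of attenuation mixing is assumed, not tested, at the single
  specimen level; the group-calibration cost magnitude is the only indirect
  linearity check available.
- Basis attenuation inputs shipped with the package are illustrative
  defaults; quantitative use requires site-specific calibration via the
  dilution-series or group-calibration routes.
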