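---
title: "Methods: depth-resolved SERS imaging analysis of pesticide penetration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-resolved SERS imaging analysis of pesticide penetration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serspen)
```

This vignette documents the models behind `serspen`, the choices made where
the design was genuinely open, and what the synthetic test-bed does and does
not establish about real imaging data.

## The data model

A hyperspectral SERS cube (`hypermap`) is an `n_depth x n_lateral` grid of
Raman spectra on a shared wavenumber axis, with depth row 1 at the pericarp
surface (0 µm) increasing inward, a per-cube acquisition time in hours, and
micrometre pixel spacing. The analysis assumes the linear mixing model

$$x_{px} = g_{px}\Big(\sum_k c_{k,px}\, s_k(\nu) + b(\nu)\Big) + \varepsilon,$$

where $s_k$ are component signature spectra, $c_{k,px}$ per-pixel
concentrations, $b$ a broad fluorescence baseline, $g_{px}$ a positive
multiplicative gain expressing enhancing-substrate heterogeneity, and
$\varepsilon$ additive Gaussian noise. Every stage of the pipeline either
estimates a factor of this model or consumes one.

## Preprocessing

**Baseline.** The commercial acquisition software used for the original
data applies an unspecified baseline correction; we implement the standard
chemometric choice for fluorescence backgrounds, asymmetric least squares
(a Whittaker smoother with asymmetric weights). Defaults: smoothness
$\lambda = 10^5$ (second-difference penalty; larger is stiffer), asymmetry
$p = 0.01$ (points above the baseline get weight $p$, below $1-p$), 10
reweighting iterations. The corrected signal retains negative residuals —
clipping would bias the similarity metrics — and is clipped to zero only at
the entrance to MCR-ALS, whose model is non-negative. Correction is
translation-equivariant (a constant offset moves the baseline, not the
corrected spectrum).

**Normalization.** Similarity metrics operate on l2-normalized,
baseline-corrected spectra. Whether the original study normalized before
similarity mapping is not stated; l2 after correction is the configurable
default because it makes both Pearson similarity and the
Euclidean-distance similarity scale-free.

## Unmixing and quantification

**VCA.** `run_vca()` follows the canonical algorithm: an SNR estimate from
the rank-$p$ principal subspace decides between projective projection (high
SNR, threshold $15 + 10\log_{10} p$ dB) and mean-removed rank-$(p-1)$
projection; then $p$ iterations each draw a random direction, orthogonalize
it against the endmembers found so far, and select the pixel with the
largest absolute projection. Returned endmembers are actual pixel spectra
(pure-pixel assumption). Determinism: selection ties break to the lowest
pixel index, already-chosen pixels are excluded, and the random directions
come from the supplied seed. The endmember count $p$ defaults to the number
of expected pesticides plus one background/fluorescence component. VCA runs
per cube; pooling cubes across time is possible by row-binding but is not
the default.

**Matching.** Endmembers are assigned to library references one-to-one by
minimizing total spectral angle, solved exactly by bitmask dynamic
programming (equivalent to the Hungarian algorithm at these sizes, which
never exceed a dozen components). Assignments worse than `max_angle`
(default 0.5 rad) become "background".

**MCR-ALS.** `run_mcr_als()` alternates exact non-negative least-squares
solves of $C$ given $S$ (per pixel) and $S$ given $C$ (per channel). The
NNLS sub-solves enumerate candidate active supports — exact for the small
component counts used here and fully vectorized across pixels. After every
$S$-step each row is rescaled to unit maximum with the scale absorbed into
$C$, fixing the bilinear scale ambiguity without changing the
reconstruction. Because both sub-solves are exact minimizers, the
lack-of-fit trace $\mathrm{LOF} = 100\sqrt{\sum r^2 / \sum X^2}$ is
non-increasing; iteration stops when its relative change drops below
`tol = 1e-6` or after `max_iter = 200`. Constraints are non-negativity
only: depth profiles are legitimately non-monotone, so no unimodality or
closure is imposed. Initialization is the matched VCA endmember set; on
heavily mixed cubes with no pure pixels the pipeline falls back to library
reference spectra plus a flat background component.

## Similarity, label and overlap maps

Similarity of a pixel to a reference is Pearson correlation by default
(bounded, offset- and scale-free); the Euclidean-distance similarity
$1/(1+d)$ on l2-normalized spectra is used for the mixed-pesticide overlap
maps. The label rule is: similarity strictly greater than 0.8 → pesticide;
between 0.5 and 0.8 inclusive → suspected (interpreted as partially
metabolized pesticide); otherwise background. The boundary convention
(exactly 0.8 is "suspected") follows the strict reading of "greater than".
The reference may be the matched VCA endmember (default — it is free of
residual cube-specific interference) or the library spectrum.

Overlap maps classify each pixel independently against two references at
the pesticide threshold and encode presence additively: none 0, A only 10,
B only 20, both 30 (codes configurable, kept distinct). With the default
0.8 threshold and distinct references, "both" requires the pixel to sit
within distance 0.25 of two different normalized signatures, which is
geometrically possible only for quite similar references; in practice
overlap codes appear at relaxed thresholds or with strongly overlapping
band sets.

## Penetration profiling

Per-pixel content (an MCR abundance column by default, a characteristic
band's peak intensity — e.g. thiram's 1380 cm⁻¹ — when unmixing is
skipped) is averaged over lateral pixels within contiguous depth bins
(default one pixel row). The total-content curve takes, per time point, the
mean over bins (with uniform bins this equals the pixel mean; a
pixel-weighted option exists). Trends are cubic regression B-splines with
`df = 6` basis functions for the 10-point time course — smooth, but able to
express the mid-course dip; `df = n` interpolates.

## Spectral machine learning

Curation transfers labels from matched endmembers to unlabeled spectra:
K-means (k-means++ seeding, best of 5 Lloyd restarts; default
$k = 2\times$ the number of expected classes) clusters the spectra; each
cluster centroid is baseline-corrected and correlated with every
pesticide-labeled endmember; clusters above the pesticide threshold inherit
that label, below the suspected threshold become background, and the
ambiguous band in between is discarded — training on ambiguous spectra is
deliberately avoided. Splitting is stratified per class,
`round(0.7 · n)` (half-up) to training, seeded. The four families — LDA,
ridge-regularized multinomial logistic (fixed $\lambda = 0.01$), linear
SVM with Platt probability scores, random forest (100 trees) — all expose
per-class continuous scores, so one-vs-rest ROC curves are computed by a
tie-grouped threshold sweep whose trapezoidal AUC equals the pairwise
statistic $P(s^+ > s^-) + \frac12 P(\text{tie})$ exactly. Evaluation
reports per-class AUC on the held-out 30% (training-set ROC can be
obtained by evaluating on the training split), the argmax confusion
matrix, and per-group proportional scores (the fraction of a sample's
spectra predicted as each class).

## The synthetic scene generator

The generator emulates the statistical structure the analysis assumes, at
desk scale (41 × 20 pixels, 281 channels, 400–1800 cm⁻¹ at 5 cm⁻¹ by
default):

- **Signatures**: Lorentzian band superpositions (the Raman convention;
  Gaussian available) with plausible band sets for chlorpyrifos,
  thiabendazole, thiram (1380 cm⁻¹) and acetamiprid.
- **Concentration fields**: the 1-D reaction–diffusion model
  $\partial c/\partial t = D\,\partial^2 c/\partial z^2 - k_0 E(t)\,c$ with
  a Dirichlet surface dose decaying exponentially (drying/washoff of a
  residue that mainly sits at the surface), zero flux at the inner
  boundary, and a consumable, resupplied enzyme pool
  $dE/dt = -\gamma E \langle c\rangle + s(E_0 - E)$. Defaults
  $D = 50\ \mu m^2 h^{-1}$, $k_0 = 2\,h^{-1}$, $E_0 = 1$, $\gamma = 5$,
  $s = 0.05\,h^{-1}$; surface decay 0.05 h⁻¹ and doses 1.0/0.8 chosen once
  for a clear qualitative weakening. Per-component overrides make
  chlorpyrifos behave as a contact pesticide (shallower, faster washoff)
  and acetamiprid as systemic (deeper, persistent) — without them the two
  fields are exactly proportional and unmixing is degenerate by
  construction.
- **Numerics**: explicit finite differences with sub-stepping enforcing
  $D\,\Delta t/\Delta z^2 \le 0.5$ (default ceiling 0.01 h), the
  degradation term applied as an exact exponential per sub-step, the
  enzyme ODE advanced by a midpoint step. Mass is conserved to 0.1% for
  sealed-boundary diffusion, and the $D = 0$ limit matches a high-accuracy
  ODE integration of the enzyme system to 1%.
- **Gain field**: lognormal marginals (log-sd 0.2), Gaussian-smoothed to a
  10 µm correlation length, standardized so the sample log-sd is exact and
  the mean is 1 in expectation.
- **Noise**: additive Gaussian, with the sd derived from a target cube SNR
  (default 25 dB) against the clean signal power.
- **Labeled spectra**: per-class `dose · signature + baseline + noise`,
  dose log-uniform in [0.3, 3] (an order of magnitude around the unit
  surface dose), background as baseline + noise; deterministic shuffling;
  optional synthetic sample groups for proportional scores.

Determinism: one seed per scene; cubes at different time points and every
noise draw use fixed sub-seed offsets, so any cube is reproducible in
isolation.

**Model behavior and a known limitation.** Under this model the enzyme
pool is monotone down-then-up (it relaxes toward a single-dip
quasi-equilibrium set by the single-peaked mean concentration), so the
penetration front — the deepest depth above 5% of the concurrent surface
value — is single-humped: it advances while the pool is being consumed and
retreats as the pool recovers and the surface dose decays. The systemic
component therefore shows a clear advance (through roughly 24 h) followed
by retreat. Field observations additionally describe a *renewed* advance
after an intermediate retreat; reproducing that three-phase pattern would
require an enzymatic defense that is first induced above its initial level
and only then consumed — a different enzyme model than the consumable-pool
form used here. We verified over a broad parameter sweep (including the
enzyme constants) that the present form cannot produce the three-phase
front trajectory at the sampled time points; the package keeps the simpler
model and documents this as its main dynamical limitation.

**What passing tests do not show.** The generator's spectra are idealized:
band positions do not shift with the chemical microenvironment, the
baseline has a fixed shape, the gain is spatially smooth, noise is
homoscedastic Gaussian, and mixture composition varies only with depth (no
lateral patchiness). Results on real cubes — where fluorescence varies per
pixel, cosmic rays occur, and pesticide distribution is laterally patchy —
will be less clean than the synthetic recoveries (e.g. the r > 0.95
abundance recovery at 25 dB).

## Problem sizes and runtime choices

Tests run the full pipeline on reduced grids (20–25 depth rows, 8–12
lateral pixels, 161 channels, 4–10 time points) and the classification
stage on 5000 spectra per class; those sizes exercise every code path while
keeping the whole suite in the minutes range on one core. The brute-force
unmixing oracle enumerates hull-vertex triples of the rank-2 projection,
which is exact for constant-total abundances.

## Degenerate inputs and tie-breaks

- All-identical pixels: VCA refuses (no simplex).
- All-zero spectral matrix: MCR-ALS and lack-of-fit refuse.
- Zero-norm pixels in ED maps are assigned similarity 0.
- K-means duplicate seeds are perturbed by ~1e-9 jitter; restarts keep the
  minimum-inertia solution.
- Stratified splits guarantee at least one spectrum per class on each side.
- Exact-threshold similarities (0.8, 0.5) fall in the "suspected" band.
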