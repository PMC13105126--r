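---
title: "Methods: kernel-based neural mass modeling of CA3"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernel-based neural mass modeling of CA3}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cnmm)
```

## The model and its assumptions

A neural mass is the population of CA3 pyramidal cells inside one
0.2 mm × 0.5 mm bin of the flattened hippocampal map (proximodistal ×
septotemporal axes). Its activity is summarized by a spike density: a
2-ms peristimulus histogram, z-scored, then convolved with a Gaussian
kernel. The model maps the afferent spike densities — entorhinal cortex
(perforant path), dentate gyrus (mossy fibers), and neighboring CA3 masses
(associational connections) — to the target mass's density through four
convolution kernels, summed linearly:

* **EC and DG kernels** — first-order Volterra kernels expanded as
  weighted sums of discrete orthonormal Laguerre functions and their
  elementwise powers, `K(τ) = Σ_{n,p} w_{n,p} L_{n,α}(τ)^p`.
* **Coupling kernel** — a three-dimensional kernel over two spatial lags
  and time, built from outer products of scaled Chebyshev polynomials
  (space) and powered Laguerre functions (time).
* **Feedback kernel** — a plain learned coefficient vector applied to the
  output's own past, with `N_delays` leading zero taps; it absorbs
  intra-mass recurrence (including the pyramidal–basket loop), so the
  coupling convolution excludes the (0, 0) self lag by default
  (`include_self` restores it).

The architecture is linear in its weights by construction; all
nonlinearity enters through the basis powers. No output nonlinearity is
applied. Inputs before `t = 0` are zero, so the first `M/Δt` samples of
any prediction are burn-in and excluded from losses and correlation
scores.

Two prediction modes exist. *Teacher-forced* feeds the recorded reference
output into the feedback kernel (the estimation setting: it keeps weight
fitting a linear problem). *Free-running* iterates the model on its own
lagged output (the deployment setting, and the harder test of a fit).

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `M` | 1000 | ms | kernel memory window; `taps = M/Δt` |
| `Δt` | 2 | ms | sampling period (Nyquist 250 Hz) |
| `nt, pt` (EC, DG) | 8, 5 | – | Laguerre orders × powers → 40 terms each |
| `nt, pt, nx, px, ny, py` (coupling) | 3, 3, 4, 3, 4, 3 | – | 1296 coupling terms |
| `α_EC, α_DG, α_C` | searched | – | Laguerre decay per kernel, in (0, 1) |
| `r_x, r_y` | searched | mm | coupling spatial extents |
| `N_delays` | searched | taps | feedback zero-padding |
| `λ_ridge` | 10 | – | ridge strength |
| smoothing `w` | 100 (EC), 10 (DG/CA3) | ms | Gaussian density bandwidths |
| velocities | 0.27 (EC), 0.32 (DG) | mm/ms | conduction delays |
| PSO | 200 particles, 140 generations; 0.25/2.0/1.0 | – | inertia/cognitive/social |

Search bounds are a package choice (no reference values exist for them): α ∈ [0.05, 0.95],
r_x ∈ [0.2, 1.0] mm, r_y ∈ [0.5, 2.5] mm (spanning one to a few neighbor
bins on each axis), N_delays ∈ [0, 50] taps (0–100 ms, covering plausible
synaptic loop delays). `N_delays` is treated as a continuous swarm
dimension rounded at evaluation, the usual mixed-integer PSO practice.

## Design choices where the design was open

* **Basis indexing.** The expansion sums are read as running over the
  first `N` basis functions *including order 0*: dropping the order-0
  Laguerre function would discard the dominant low-frequency component,
  and the order-0 Chebyshev term carries the spatially uniform part of
  the coupling. Rows are always ordered order-0 first.
* **Laguerre evaluation.** The closed-form expression overflows its
  binomial coefficients near 500 taps and high order; the package uses
  the stable two-term recurrence seeded by
  `L_0(τ) = √(1−α)·α^{τ/2}`, and the test suite checks it against the
  explicit log-domain formula and against orthonormality
  (`|Gram − I| < 1e−6` over ≥ 2000 taps).
* **Spatial lags are physical.** Chebyshev bases are evaluated at
  center-to-center offsets in mm (not bin indices), since the two axes
  have different bin sizes; lags beyond `r_x`/`r_y` are masked, and
  masses missing from the grid contribute zero slices.
* **Feedback length.** The reference description fixes the zero-padding
  metaparameter but not the free length; here the feedback kernel always
  spans the full memory window, with `taps − N_delays` free,
  ridge-regularized coefficients.
* **Estimation loss.** The swarm minimizes *training* MSE; the held-out
  chronological tail (last 20%) is used purely for reporting, both
  teacher-forced and free-running. Validation segments reuse
  training-segment standardization statistics to avoid leakage.
* **Ridge solver.** SVD-based (`d/(d² + λ)` filter factors), robust to
  the exactly collinear or all-zero columns that arise when a candidate
  `r_x` excludes every neighbor lag; the normal-equation solve serves as
  an independent oracle in the tests only.

## Numerical choices

Half-open time bins `[b·Δt, (b+1)·Δt)` with origin 0; conduction delays
rounded to the nearest bin (ties toward +∞) since sub-bin timing is
unobservable at 2 ms. Gaussian smoothing kernels are truncated at ±4
bandwidths, renormalized to unit sum, and applied with zero-padded edges
(output length preserved). Convolutions run through FFTs padded to
5-smooth lengths (mixed-radix FFTs degrade sharply on lengths with large
prime factors); the direct summation agrees to 1e−10 and is kept as a
test oracle. Swarm velocities are clamped to half the bound width per
dimension and positions to the bounds. Degenerate inputs fail loudly:
zero-variance signals cannot be standardized or scored, and a teacher
whose free-running output diverges raises a stability error rather than
returning garbage.

## What the synthetic data emulates — and what it does not

The generator reproduces the *statistical structure* of the original
training data: exploration trajectories with uniformly resampled speed
(0–30 cm/s), heading, and segment duration (0–500 ms) reflected at the
walls of an 80-cm square; hexagonal grid-cell rate maps (three cosine
gratings 60° apart, exponential link with offset `b = −3/2` zeroing the
minimum, dense-grid normalization to a 50-Hz peak); inhomogeneous Poisson
spiking by thinning; and 5.50-Hz homogeneous Poisson noise for the lateral
entorhinal population. Teacher datasets drive a known ground-truth model
with standardized smoothed noise whose bandwidths match the density
pipeline (100 ms EC, 10 ms DG/CA3), so the spectral content resembles
real pipeline output.

What it does **not** emulate: conductance-based synaptic dynamics, cell
morphologies, anatomically constrained connectivity, dorsoventral
gradients of grid properties, or the true CA3 flattened-map geometry.
Passing recovery tests therefore demonstrates that the estimation
machinery identifies models *within the model class* under realistic
signal statistics — not that the class captures every nonlinearity of
biological CA3. Headline accuracies against the original mechanistic
simulation are not reproducible here and are not claimed.

## Problem sizes used in testing

Recovery experiments run a reduced configuration chosen to keep the full
nested estimation exercised while staying desk-scale: memory window
100 ms (50 taps), 3 + 3 Laguerre orders at power 2 for EC/DG, a 2×2×2
coupling basis over a 3×3 neighbor grid, 8,000 ms of teacher data with a
chronological 80/20 split, and a 30-particle × 40-generation swarm. At
these sizes the fixed-metaparameter fit recovers teacher-forced
validation R > 0.999 and the full swarm search recovers free-running
R > 0.99; recovery degrades monotonically as output noise is added, as it
should. The full reference configuration (40 + 40 + 1296 + 491 design
columns at 500 taps) is exercised structurally (column counts, prediction
equivalence) rather than fitted end-to-end.

## Units of the forward model

Layer currents are carried in nA, electrode–layer distances in μm and
conductivity in S/m; with these units `I/(4πσr)` is already in mV, which
is the unit of all LFP outputs. Layer radial centers default to a
plausible CA3 laminar profile (−400 … +175 μm around stratum pyramidale)
and are documented as configuration fixtures, not anatomy. The reference
electrode sits at the radial level of the stratum pyramidale center, 500
μm lateral at 45° between the septal and distal axes. Currents are fitted
on standardized traces and de-standardized with stored (mean, sd) before
the point-source sum, which needs physical amplitudes.

## Known limitations

Kernel strengths are RMS values of expansion coefficients; comparisons
across kernels with different basis sizes are qualitative. The
generation-budget termination is a surrogate for the original wall-clock
budget. Per-mass fitting is open-loop with recorded neighbor inputs; a
coupled closed-loop rollout across masses is not part of the validated
surface. Welch spectra use fixed defaults (2048-sample Hann segments, 50%
overlap) rather than adaptive bandwidth selection, and the spike-density
bandwidths are configuration, not data-driven.
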