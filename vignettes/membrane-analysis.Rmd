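---
title: "Quantifying bilayer curvature, thickness and lipid diffusion with membranekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bilayer curvature, thickness and lipid diffusion with membranekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membranekit)
```

## The problem

Peripheral proteins such as annexins bend the membranes they bind, and
membrane-intercalating small molecules (the phenothiazine trifluoperazine,
TFP, is the motivating example) change the bilayer's thickness, packing and
lipid mobility. Quantifying these effects from molecular-dynamics
trajectories requires a small set of standard estimators: per-leaflet
surface fits and their curvature, phosphate-to-phosphate thickness, lateral
density maps of selected species, area per lipid, and lateral diffusion
constants from mean-squared displacements. `membranekit` implements that
tool chain for orthorhombic bilayer patches, plus the matching AFM
step-height measurement used to determine supported-bilayer thickness
experimentally, and synthetic generators with retained ground truth so every
estimator can be validated without running MD.

All internal units are nm and ns. Conversions happen only at I/O boundaries
(PDB/DCD Angstroms on read; cm^2/s for reported diffusion constants,
1 nm^2/ns = 1e-5 cm^2/s exactly). A single unit system avoids the classic
silent cm^2/s-versus-nm^2/ns errors.

## Leaflet surfaces in the Monge gauge

A nearly flat leaflet is represented by its height function $z(x, y)$ over
the periodic box $(L_x, L_y)$, expanded in a truncated real Fourier basis

$$z(x,y) = a_0 + \sum_{(m,n)} a^c_{mn} \cos\theta_{mn} + a^s_{mn}
\sin\theta_{mn}, \qquad \theta_{mn} = 2\pi\left(\frac{m x}{L_x} +
\frac{n y}{L_y}\right),$$

with $|m|, |n| \le M$ and one member of each conjugate pair kept, so the
surface is real and periodic by construction. The coefficients are the
linear least-squares solution over the leaflet's phosphorus-atom
coordinates; `fit_fourier_surface()` reports the RMS residual and fails on
rank-deficient point sets.

**Mode cutoff.** The default $M = 2$ gives 25 real basis functions,
comfortably determined by the ~260 phosphorus atoms of one leaflet of a
13 nm patch. Protein-scale deformations are long-wavelength, and higher $M$
mostly fits thermal noise: for a Gaussian indentation of width 2 nm the
truncation error of the curvature field is ~2.7% at $M=2$ and ~0.6% at
$M=3$, while the noise variance of the fit grows with the number of modes
(and with $q^4$ in the curvature). $M$ is a parameter everywhere; $M=3$ is
a good choice when sharp protein footprints must be resolved and enough
frames are averaged.

**Curvature.** The mean curvature is evaluated analytically from the
coefficients. The default is the small-slope (linearised) form
$H = \tfrac12 (z_{xx} + z_{yy})$; the full Monge-gauge expression

$$H = \frac{(1+z_y^2) z_{xx} - 2 z_x z_y z_{xy} + (1+z_x^2) z_{yy}}
{2\,(1+z_x^2+z_y^2)^{3/2}}$$

is available as a cross-check (`mode = "full"`). For bilayer slopes
($|\nabla z| < 0.05$) the two agree within 1%. Sign convention: $z$
increases toward the upper leaflet, so an upward bulge has $H < 0$ at its
apex and an indentation has $H > 0$. Published footprint values are often
quoted as magnitudes while the deformation itself is described as "negative
curvature", so `curvature_footprint()` returns the signed region average,
its magnitude, and the extremum of the time-averaged field, and records the
convention in its output.

**Noise and time averaging.** A single-frame fit with 0.1 nm height noise
on 260 points leaves ~30% RMS noise (relative to a typical protein-induced
peak) in the curvature field — curvature amplifies every coefficient error
by $q^2$. Precision therefore comes from time averaging: fields are fitted
per frame and averaged over the terminal analysis window (default the last
40% of frames, the usual "last 200 ns of a 500 ns run" convention, and
configurable). Averaging ~400 statistically independent frames brings the
field error to ~1% of peak.

**Why a disk region for the protein-free baseline.** The box average of the
linearised curvature of any periodic surface is identically zero (every
Fourier mode integrates to zero over its period) — the package asserts this
to 1e-10 as an invariant. A whole-box average is therefore not a meaningful
baseline statistic. The protein-free baseline reported by
`scripts/acceptance.R` instead averages the time-averaged field over a
protein-footprint-sized disk (radius 2.5 nm at the patch center), which is
the quantity comparable to a protein's curvature footprint; when a protein
is present, `footprint_region()` uses the protein particles' lateral
centroid and radius of gyration instead.

## Thickness and area per lipid

Thickness is the vertical phosphate-to-phosphate distance
$z_\mathrm{up}(x,y) - z_\mathrm{lo}(x,y)$ between the two fitted leaflet
surfaces; parallel undulations of the two leaflets cancel exactly. The mean
thickness is the area average of this field over the analysis window. Area
per lipid is $L_x L_y / N_\mathrm{leaflet}$, a function of the box and the
composition only. `dose_trend_report()` turns per-condition summaries into
strict-ordering verdicts (thinning with increasing intercalant dose,
increasing area per lipid), with an optional tolerance that defaults to 0
because the dose-effect orderings of interest are strict.

## Density maps

`density_map()` histograms the wrapped lateral positions of a tag selection
(optionally restricted to one leaflet) into half-open bins matched to the
$[0, L)$ coordinate convention, averages over the window, and normalises to
count nm^-2. The binning makes the conservation identity
$\sum \mathrm{values} \times \mathrm{cell\ area} = $ mean selected count
per frame hold to floating-point exactness; the default 26 x 26 grid
(~0.5 nm bins on a 13 nm box) resolves protein-scale enrichment without
single-occupancy noise.

## Lateral diffusion

`compute_msd()` evaluates $\mathrm{MSD}(t) = \langle (\mathbf r(t_0+t) -
\mathbf r(t_0))^2\rangle$ over x-y displacements of laterally unwrapped
coordinates, averaged over the selected lipids and over time origins placed
every 0.1 ns (100 ps) by default. Lags are binned on the frame grid with no
interpolation and run to half the trajectory length by default
(`max_lag_ns` overrides this when a full-length fit window is wanted).
`fit_diffusion()` fits a straight line with free intercept through
MSD(t) over $(0, t_\mathrm{max}]$ ns (default 50), takes
$D = \mathrm{slope}/4$, and estimates the uncertainty as the absolute
difference between the fits over the two halves of the window.

Two choices here are genuinely open and are exposed as arguments:

* **Free intercept (default).** The Einstein relation is asymptotic; a free
  intercept absorbs short-time non-diffusive motion and leaves the slope as
  the physical quantity. `zero_intercept = TRUE` forces the line through
  the origin.
* **Center-of-mass removal (default on).** Collective leaflet drift
  inflates apparent single-particle diffusion, so the lateral COM of the
  selection (per leaflet when an assignment is supplied) is removed first;
  `remove_com = FALSE` disables it. For $n$ independent walkers the removal
  biases the MSD by a factor $(1 - 1/n)$, negligible at the ensemble sizes
  used here.

## AFM step heights

`bilayer_height()` reproduces the standard supported-lipid-bilayer
measurement: level the image by subtracting a least-squares plane fitted
through the substrate pixels (identified by a two-level threshold), detect
holes down to the substrate, and draw cross-sections across the hole edges
— ten lines per image, each five pixels thick, the band average suppressing
single-pixel noise at least five-fold. For each profile the edge is the
maximum-gradient sample and the two plateau levels are per-side medians
(robust to edge rounding and debris); the step is their difference.
Auto-placement of lines is deterministic given the image, so repeated runs
agree bit-for-bit, and user-supplied lines reproduce the auto-placed result
exactly. Estimates are invariant to global height offsets and to 90-degree
rotations of a symmetric image.

## Synthetic data and what passing tests mean

The generators emulate the study conditions: a 520-lipid 80:20 POPC:POPS
patch (52 POPS per leaflet) in a 13 x 13 nm periodic box with 0, 24 or 48
TFP molecules (4.6% / 9.2% TFP/lipid), headgroups at $\pm d_0/2$
(default $d_0 = 4$ nm) around a midplane carrying thermal undulations —
per-mode Gaussian amplitudes $\propto 1/q^2$ scaled to an RMS roughness of
0.2 nm and redrawn each frame — plus lateral Brownian motion with
per-species D (POPS default 9.9e-3 nm^2/ns = 9.9e-8 cm^2/s, the untreated
bilayer value). A bound protein is represented only by a static Gaussian
dimple on the upper leaflet plus ring-placed marker particles; there is no
particle-level protein model, no force field and no leaflet coupling
dynamics. Consequently the tests demonstrate estimator correctness —
generative parameters are recovered within stated tolerances (thickness
within 1%, species D within 5%, curvature fields within 2% RMS of peak
after averaging, AFM heights within 3 SEM) — but say nothing about
force-field accuracy or sampling of real membranes.

Every generator takes a seed and is bit-reproducible; `synthetic_spec`
records the full parameterisation alongside the data, and generated
trajectories carry their ground truth with them.

## Numerical choices and degenerate inputs

* Leaflet assignment splits headgroups at the median z of one reference
  frame and keeps the assignment fixed (no flip-flop at sub-microsecond
  scales); a configurable minimum z gap (0.5 nm) guards against collapsed
  or single-leaflet inputs, which raise an `ambiguous-leaflet` error.
* Unwrapping uses the minimum-image convention per frame pair and warns
  (not errors) when any single step exceeds a quarter box, a symptom of
  too-sparse sampling.
* Boxes must be orthorhombic; triclinic inputs are rejected outright.
* Fits fail loudly: rank-deficient Fourier designs, fewer points than
  coefficients, fewer than 3 lags in a diffusion fit window, profiles
  without a detectable step (step below 5x the plateau noise), and negative
  thickness (swapped leaflets) all raise typed errors rather than returning
  numbers.
* Ties in density binning cannot occur (half-open bins); particles exactly
  at $L$ are wrapped to 0 before binning.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run entirely on synthetic data at
desk scale, chosen to keep the whole suite under a few minutes: curvature
recovery averages 400 noisy samplings of a static surface; diffusion
recovery uses 1000 walkers for 50 ns at 0.1 ns; the protein-free baseline
uses 2000-4000 frames of the fluctuating 520-lipid patch; AFM recovery uses
three 200 x 200 px images with 10 lines each. The cluster-scale quantities
of the motivating study (protein-induced curvature footprints of order
0.01 nm^-1 from five 500 ns all-atom replicas) require the original MD
trajectories and are out of scope here; the machinery that measures them is
what this package provides and validates.

## Known limitations

* No Helfrich spectrum or bending-modulus estimation, no Gaussian
  curvature, no per-lipid curvature decomposition.
* No XTC/TRR readers (no R implementation exists in this toolchain);
  convert to DCD or the CSV dialect.
* The selection language is deliberately tiny: tag equality and unions.
* AFM module assumes a two-level topograph (substrate + one bilayer); it
  does not handle multilamellar stacks or tip deconvolution.
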