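---
title: "Beam-model commissioning and fluence-map-biased VMAT sampling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam-model commissioning and fluence-map-biased VMAT sampling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(psrdose)
```

## The beam model

A clinical linac photon beam is represented as a *field-independent*
analytical source defined on a phase-space plane just above the secondary
collimator (default 26 cm from the target). The plane is partitioned into
concentric phase-space rings (PSRs); each ring is further split by energy
bin and by particle class — primary photon, scattered photon, contaminant
electron — so a partition of $R$ rings and $E$ energy bins yields
$3RE$ sub-sources. Each sub-source carries two parameters: a relative
intensity (particles per history) and an angular width (the local polar
spread of directions about the focal ray). With 40 rings and 20 energy
bins, the clinical-scale partition, this gives 2400 sub-sources:

```{r}
m <- build_toy_beam_model(40, 20)
m
```

The analytical intensity and direction distributions that a vendor
phase-space file would be fitted with are not available here, so
`toy_beam_spec()` provides a documented toy parameterization that keeps
the *structure* every downstream algorithm relies on: per-ring energy
spectra are gamma-shaped histograms whose mean softens off axis; ring
intensities follow annulus area times an exponential radial decay
(slower for primaries than for head scatter); angular width is constant
for primaries and grows linearly with radius for scattered photons.
Energy within a bin is sampled uniformly — the bins are narrow by
construction, so the within-bin law is immaterial. None of these
functional forms is used by the commissioning or sampling algorithms;
they only have to produce beams with realistic build-up, penumbra and
field-size behavior.

### Jaw-restricted sampling

Source particles are only sampled from sub-sources whose ring overlaps
the jaw opening projected onto the phase-space plane, expanded by a
0.5 cm margin ("nearby" the open area). Because all sampled particles
then come from a restricted intensity mass $m \le 1$, each particle
carries the acceptance weight $m$ (mass over total intensity): a
restricted history represents only that fraction of a full-model
history, which keeps every tally unbiased per history. The polar tilt
about the focal ray is Rayleigh with scale equal to the angular width —
equivalent to independent Gaussian tilts in the two transverse
directions — so a zero width reproduces the focal ray exactly.

## Transport and the concurrent sub-source tally

The full condensed-history Monte Carlo physics is out of scope; the
transport stand-in is a *deterministic per-particle kernel*: all
statistical noise enters through source sampling, and transporting a
fixed particle list is bit-reproducible. Photons deposit along their ray
with $k(d) = A\,(e^{-\mu d} - e^{-\beta d})$, with toy
$\mu(E) = 0.065\,E^{-0.18}$ cm$^{-1}$ and
$\beta(E) = 3.2\,E^{-0.35}$ cm$^{-1}$, giving a build-up region and a
dmax near 1.4–1.5 cm for a 2 MeV mean energy. Electrons deposit a linear
ramp within a finite range $R(E) = 0.2E + 0.05$ cm. The range
coefficients deliberately confine contaminant-electron dose to the
build-up region: the two-stage commissioning model *assumes* voxels
beyond the build-up region are beyond the electron penetration depth,
and the transport honors that assumption so the stage separation is
exact rather than approximate. Deposits are spread laterally over a
Gaussian-weighted 5×5 stencil perpendicular to the ray, with width
$\sigma(d) = \sigma_0 + \sigma_1 d$, larger for scattered photons — this
produces smooth penumbras and field-size dependence. 85% of the particle
energy is deposited over the full kernel, keeping deposition strictly
below the incident energy.

Commissioning needs the dose of *every* sub-source at the commissioning
voxels (matrix $A$: voxels × sub-sources). Rather than transporting each
sub-source separately, the tally is concurrent: a per-voxel row-index
look-up table marks the commissioning voxels (central-axis depth curve
plus inline/cross-line profile rows at the requested depths; negative
entries mean "not used"), and every deposition into a marked voxel is
also accumulated into the $A$ entry whose column is the sub-source index
carried by the particle. One mixed-stream pass therefore produces the
full matrix, bit-identical to the sum of per-sub-source passes over the
same stream. Batch statistics (ten contiguous stream splits by default)
give per-entry standard errors; they are recorded but do not weight the
fit by default, since the weighting scheme of the original procedure is
unstated.

## Two-stage non-negative least-squares commissioning

Commissioning multiplies each sub-source intensity by a non-negative
correction factor so the summed dose matches water-phantom measurements.
Because dose is linear in the intensities, this is a constrained linear
problem solved in two stages:

1. **Photons.** On rows beyond the electron penetration depth (after
   build-up) and outside the penumbra,
   $\hat{x}_p = \arg\min_{x\ge 0} \lVert A_{1p}x - b_1\rVert^2$.
2. **Electrons.** Electron PSRs within one energy bin are grouped into an
   *effective PSR* with a single factor (their individual tallies are too
   noisy — electrons are ~1% of the beam). On build-up rows, with the
   photon dose held fixed,
   $\hat{x}_e = \arg\min_{x\ge 0}
   \lVert A_{2e}x + A_{2p}\hat{x}_p - b_2\rVert^2$.

Stage 2 cannot disturb stage 1: the stage-1 rows receive no electron
dose. No regularization term is used.

Design choices where the procedure was open:

* **Region labels.** The build-up/after split is at the per-field dmax of
  the measured depth curve (parabolic refinement through the three
  samples around the discrete maximum); a fixed depth can be configured.
  Penumbra points are those with dose strictly between 20% and 80% of
  the same-depth central-axis dose, dilated by one measurement point on
  each side (the TG-53-style convention); penumbra rows are excluded
  from both stages. An infinitely sharp edge yields no penumbra points.
* **Global scale.** Water-tank measurements are relative. A closed-form
  scalar $s = \arg\min_s \lVert s\,A_{1p}\mathbf{1} - b_1\rVert$
  pre-scales the data so factors near one mean "no change"; $s$ is kept
  in the result (`global_scale`) so commissioned doses can be reported in
  measurement units. Whether the original procedure normalizes per field
  or globally is unstated; the global choice preserves inter-field
  ratios, which carry output-factor information.
* **Joint fit.** Build-up rows of all commissioning fields enter stage 2
  jointly (the per-field alternative is unstated in the source
  procedure).

### The solver

Both stages use projected gradient descent with Barzilai–Borwein steps, a
halving line search that keeps the objective non-increasing, and
$x_0 = \mathbf{1}$. The iteration works on the normal equations
($p\times p$ Gram matrix, so each step is $O(p^2)$), with columns
equilibrated to unit norm first — a positive diagonal rescale that leaves
the constraint set invariant while conditioning the steps, since
sub-source column norms span orders of magnitude. The rescale is floored
at $10^{-3}$ of the largest column norm so numerically dead columns
(sub-sources with essentially no dose at the fitted voxels) are not
amplified; their gradients stay negligible and they simply remain at the
starting point, an implicit regularization of unidentifiable directions.
Stopping: ten consecutive iterations of relative objective progress below
`tol` (default $10^{-10}$), a vanishing projected gradient, or an
objective below $10^{-20}$ of the data scale; the 20 000-iteration cap
returns the best iterate with a warning. An independent active-set solver
(`pracma::lsqnonneg`) serves as the oracle in the test suite, never as
the implementation.

## Fluence-map-biased control-point sampling

For a VMAT arc of $K$ control points, a fluence-map (FM) stack is built
on a plane at the MLC upper surface (50 cm from the target, 2.5 mm
pixels snapped so the grid edges align with the jaw edges):
$\mathrm{FM}(x,y,k) = \mathrm{MU}_k$ inside the aperture of control
point $k$, $\mathrm{MU}_k\,T$ under a closed leaf inside the jaw
($T = 0.015$ transmission by default), and 0 outside the jaw. For a
particle crossing pixel $(x, y)$, the cumulative distribution over
control points is
$\mathrm{CPDF}_m = \sum_{k \le m} \mathrm{FM}(x,y,k) / \sum_k
\mathrm{FM}(x,y,k)$.

**Biased sampling** draws one uniform $\gamma$ per particle and assigns
the control point $k$ with
$\mathrm{CPDF}_{k-1} \le \gamma < \mathrm{CPDF}_k$ — i.e. exactly the
categorical distribution $\mathrm{FM}(\cdot,k)/\sum\mathrm{FM}$ (the
stated search rule is off-by-one-ambiguous against the CPDF definition;
this reading preserves the intended distribution). The particle weight
is multiplied by $\sum_k \mathrm{FM}(x,y,\cdot)$, which is *constant per
pixel*. The sequential search is replaced by a pre-computed numerical
inverse table (default $16K$ probability bins, nearest-bin lookup); a
draw routed through the table can differ from the exact search only
within half a bin of a CPDF jump, a disagreement rate of about
$K/(4\,n_\mathrm{bins})$ that vanishes as the table refines.

**FM weighting**, the baseline, draws $k$ uniformly over the $K$ control
points and multiplies the weight by $K\cdot\mathrm{FM}(x,y,k)$. The
uniform draw is a design choice (the baseline's multi-control-point draw
is unstated in the source); it makes both estimators unbiased for the
identical per-(pixel, $k$) fluence, so their efficiency comparison is
between estimators of the same quantity. Per pixel, the biased weight is
constant while the weighting estimator's weight fluctuates with $k$, so
the biased variance is never larger, with the gap growing as the FM gets
sparser — exactly the sweeping-aperture situation of VMAT. Particles
landing outside the FM grid or on zero-mass pixels are discarded with
zero weight and counted separately; particles inside the jaw but under a
closed leaf at their assigned control point are counted as "less
useful", the bookkeeping behind the efficiency comparison.

Assigned particles are rotated to their control point's gantry angle
about the y axis through the isocenter (IEC 61217 sense; gantry 0 points
along +z, 180° negates x and z) and transported into the phantom by the
same kernel transport as static fields — a single-control-point open
arc at gantry 0 reproduces the static-field dose bit-for-bit.

Uncertainty-targeted runs accumulate chunks of particles and stop when
the average statistical uncertainty — per-voxel SEM of the chunk means,
relative to the maximum dose, averaged over voxels above 50% of it —
reaches the target. At least ten chunks are required before the estimate
is trusted: the SEM of $B$ batches has relative error
$\approx 1/\sqrt{2(B-1)}$, and stopping on two or three chunks is
little better than a coin flip.

## Evaluation metrics

RMS and maximum differences are percentages of the measured dmax dose.
DTA at a measured point is the smallest distance at which the linearly
interpolated calculated curve attains the measured value; points whose
value is never attained are capped at 1 cm and flagged rather than
silently averaged. Output factors are central-axis doses at each field's
own dmax relative to the 10×10 cm² field. The 3D gamma index uses global
normalization to the reference grid's maximum, a 10% low-dose threshold,
a search radius of three distance criteria and 10× sub-voxel refinement
with trilinear interpolation of the evaluated dose; offsets are visited
in order of increasing distance so the search can stop early. Gamma is
not symmetric in its arguments, and passing rates are monotone in the
criteria (2%/2 mm can never pass less than 1%/1 mm on the same pair).

## What the synthetic data emulate — and what they do not

The generators produce everything the pipeline needs with a known ground
truth: measurements are $b = A x_\mathrm{true} + \varepsilon$ with
homoscedastic absolute Gaussian noise per field (SD expressed as a
percent of the per-field dmax dose; default 0.2%, the tally-noise scale
of the matrix-$A$ computation), reshaped into depth-dose and profile
curves and normalized so the reference field's dmax reads 100. Toy VMAT
arcs offer a sweeping-slit schedule (sparse FMs, the regime where biased
sampling pays off), an oscillating schedule and an open-field control;
MU weights are uniform or peaked and always normalized to one.

The default study uses an 8 rings × 6 energy bins model (432
sub-sources), the 40×40 / 10×10 / 2×2 cm² commissioning field trio with
profiles at 5, 10 and 20 cm depth, 1.5×10⁵ histories per field on a
50×50×30 cm³ water phantom (1 cm lateral, 5 mm depth voxels), and a
K = 36 sweeping-slit arc on a 15 cm cube centered at the isocenter
(5 mm voxels). A clinical-scale preset (40×20, K = 178) exists but the
desk-scale sizes are what the test suite exercises. Because measurements
are generated from the *same* matrix $A$ that commissioning consumes,
noiseless recovery tests isolate the solver; they do not probe transport
model error against real water data, detector volume effects,
heteroscedastic detector noise, beam spot ellipticity (the model is
rotationally symmetric by construction) or CT heterogeneities — none of
which the passing tests speak to.

## Known limitations

* The kernel transport is a stand-in: no condensed-history physics, no
  heterogeneity handling, no absolute calibration to monitor units.
* Angular-width parameters are held fixed during commissioning (they
  enter the dose nonlinearly); only intensities are reweighted.
* Electron effective-PSR factors are only identifiable to the extent the
  build-up rows distinguish the energy bins; with shallow electron
  ranges and few build-up voxels several bins can be degenerate, in
  which case the fitted dose is still exact but individual electron
  factors are not unique.
* Gamma-index comparisons between two noisy doses saturate when the dose
  criterion is within ~2 standard deviations of the combined noise;
  estimator-equivalence checks are therefore run at uncertainties where
  the criterion sits near 3σ.
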