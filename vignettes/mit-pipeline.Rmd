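---
title: "Magnetic induction tomography: forward simulation and learned reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetic induction tomography: forward simulation and learned reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mitnet)
```

## The problem

Magnetic induction tomography (MIT) images the electrical conductivity of a
body without contact: an AC excitation coil drives eddy currents in the
tissue, and receiver coils pick up the secondary field those currents
produce. The forward problem (conductivity map to receiver signals) is
well-posed but computationally heavy; the inverse problem (signals back to
conductivity) is severely ill-conditioned, and classical linearised
inversions (Gauss-Newton, Tikhonov, Landweber) are slow and artefact-prone
for voluminous, weakly conducting bodies in the biological range
(0 to 1 S/m).

`mitnet` implements the complete simulation-plus-learning pipeline for this
setting: a physics-based forward simulator for a torso-sized cuboid body
scanned between an undulator exciter and an array of gradiometric butterfly
receivers, a synthetic corpus generator built to avoid the inverse crime,
a deep residual convolutional regressor that maps differential receiver
signals to a coarse 3D conductivity image, and the metric suite (Huber
loss, MAE, MSE, Pearson CC, global SSIM) used to judge it.

## Forward model

The body (default 50 x 28 x 24 cm, roughly a torso) is voxelised at 1 cm
and filled with a 0.5 S/m background; cuboid perturbations of 6-10 cm edge
length carry 0 or 1 S/m (a pneumothorax or a bleed, at 1.5 MHz). The body
travels through a 256 cm measuring range; at every centimetre the six
receivers record one value, and 25 positions are trimmed from each end,
leaving 206 per receiver.

Under weak coupling the excitation field is unaffected by the body, so the
magnetic vector potential `A` of every coil is computed analytically from
the Biot-Savart closed form for straight segments (`mu0*I/4pi` units; a
1 mm exclusion radius guards the wire singularity). Faraday's law with
`E + i w A = -grad(phi)` turns charge conservation into a scalar-potential
problem, which is discretised by nodal analysis: every voxel is a network
node, face-adjacent voxels are joined by a conductance (harmonic mean of
the two conductivities times face area over distance - the series-resistor
composition), and `w * A` evaluated at the face centre acts as an EMF
source on each edge. One sparse Cholesky factorisation per conductivity
map solves all scan positions simultaneously (the matrix depends only on
sigma; only the right-hand sides change with the scan offset). With real
`A` and real sigma the substitution `phi = -i w psi` makes the whole
system real: eddy currents are purely quadrature,
`J = sigma (w A - grad psi)`, and the receiver signal is the Geselowitz
reciprocity integral `S = integral of J . A_R dV`, evaluated by the
midpoint rule. Storing only the real quadrature amplitudes halves memory
and time with no loss of information; the overall scale sits in a single
`signal_gain` constant because only standardized differential signals ever
reach the network.

Air never enters the network: only body voxels are nodes, and a zero
conductivity voxel simply has zero-conductance edges. Each connected
conducting component is grounded at one reference node (the common
single-component case is tried first and the per-component path is the
fallback). The Kirchhoff current residual is checked against 1e-10 after
every solve.

## Dataset and inverse-crime avoidance

Signals are simulated on the 1 cm grid, but reconstruction targets live on
a 2 cm grid whose voxels average their eight children (so edges take
values like 0.25 or 0.75 S/m), and independent 60 dB white Gaussian noise
is injected into the perturbed signal `S_E` and the background signal
`S_norm` before the differential signal `S_Diff = S_E - S_norm` is formed.
Different discretisations for simulation and inversion plus noise are what
keep the learned inverse honest.

Each geometric placement ("case") is simulated under every conductivity
assignment of its objects - two combinations for one object, four for two
- because 1 S/m objects produce much weaker signals than 0 S/m objects and
would otherwise be under-represented. The reference corpus is 3000
one-object cases and 15000 two-object cases, 66,000 samples. Splits
(65 % training, 25 % test, 10 % validation) are assigned per geometric
case, never per sample, so identical geometry cannot leak between
training and evaluation. (The corpus description and the stated training
set size in the source material are mutually inconsistent - 65 % of
66,000 is 42,900, not 49,500 - so the fractions are taken as
authoritative.) Signals are standardized per feature with the mean and
population standard deviation of the training split only.

## The reconstruction network

The flat 1236-entry signal is reshaped to a 6 x 206 matrix (receivers x
positions) so that each column holds all six receivers at one position. A
5 x 5 convolution stem (64 filters, ELU, batch norm) and a 2 x 2 max pool
compress the strongly correlated neighbouring positions; residual blocks
of three 3 x 5 convolutions (conv - ELU - BN, identity skip) alternate
with bottleneck blocks whose first convolution and whose 1 x 1 projection
skip carry a 1 x 3 stride, shrinking the position axis. After a 2 x 2
average pool, two dense sigmoid layers (5172 units at full scale) feed the
output layer - one hard-sigmoid unit per coarse voxel
(`clip(0.2 x + 0.5, 0, 1)`), which reaches the bounds 0 and 1 exactly.
The number of blocks is not pinned by the reference design; the default
plan alternates residual and bottleneck blocks, doubling filters at each
bottleneck, and is fully configurable.

No deep-learning framework ships with this package's target environment,
so the network engine (im2col convolutions backed by BLAS and a compiled
gather/scatter kernel, batch normalisation, pooling, NADAM, the training
loop) is implemented in the package itself. Gradients are verified against
finite differences in the test suite.

Training follows a two-phase Huber regime: 50 epochs at `delta = 1.0`
with batch 64 (pure quadratic zone - equivalent to half-MSE), then 50
epochs at `delta = 0.05` with batch 32, which weighs voxel errors above
0.05 S/m linearly and is what drives the MAE down. NADAM starts at
learning rate 1e-3; when the validation correlation coefficient fails to
improve for 7 epochs the rate drops by 10x (floored at 1e-5), and
training stops early when the validation loss fails to improve for 15
epochs ("does not decrease" is read as "does not improve"; the literal
reading would stop immediately on any improvement). The best
validation-loss weights (including batch-norm statistics) are kept.

The reference initialisation is N(0, 1) for all weights. At these depths
unit-variance initialisation makes the first forward pass overflow, so the
architecture spec also offers fan-in-scaled (He) initialisation; the
reduced profile uses it, and any use of the fallback is recorded in the
model log.

## Surrogate coil geometry

The reference hardware's exact wire pitch, receiver loop dimensions and
array-to-body distances are published elsewhere and not available here, so
the coil geometry is an explicit, documented surrogate with every
dimension a configuration field: 11 vertical wires with antiparallel
currents (the undulator) in a plane in front of the body, and six
butterfly (figure-eight, counter-wound) receivers stacked vertically
behind it, alternating wide and narrow lobes for depth discrimination.
The butterfly's two lobes couple to the symmetric primary field with
opposite signs, so the exciter's direct contribution cancels
(gradiometric positioning); the test suite quantifies this as at least
20 dB rejection relative to a single-lobe loop of the same size. Within
this surrogate family the dimensions were chosen by maximising the
information the scan carries about the conductivity map - measured as the
test correlation of a simple ridge-regression inverse on a small pilot
corpus - which favoured a 6 cm pitch, a close exciter plane, receivers
close behind the body and 8 cm / 3 cm lobes for the reduced profile. All
acceptance properties are geometry-parametric, so published dimensions
can be substituted without touching code.

## The reduced ("desk") profile

Full-scale corpus generation and training are days of CPU time, so the
package ships a second profile that runs the identical pipeline end to
end at desk scale, used by the test suite and the acceptance script:

* body 24 x 12 x 12 cm, 1 cm simulation grid (3,456 voxels), 2 cm
  reconstruction grid (432 voxels);
* 64 scan positions trimmed by 8 per side (48 kept, input 6 x 48);
* cuboid edges 4-8 cm - two non-overlapping 6-10 cm objects cannot fit in
  a 12 cm axis - with the same 0.5 S/m background, sigma in {0, 1},
  60 dB noise, and every conductivity combination per case;
* 600 one-object + 600 two-object cases = 3,600 samples (the two-object
  class, with its weak-signal combinations, is the harder one and gets the
  larger share), split 65/25/10 by case;
* a narrow network (stem 16; residual 16, bottleneck 32, residual 32;
  dense 512) trained 15 + 30 epochs with the same two-phase Huber
  schedule, plateau factor and early stopping (plateau patience 5, as the
  shorter run leaves fewer epochs to wait).

What the desk profile demonstrates - and what it does not: it exercises
every stage of the method (physics, inverse-crime construction,
standardisation, architecture, two-phase training, metrics) under the
stated noise and conductivity conditions, and shows the learned inverse
recovering unseen bodies with high per-sample correlation. It does not
reproduce the full-scale torso resolution, absolute signal units of the
physical rig, receiver electronics, or any real measurement; cuboid
phantoms in a homogeneous background remain an idealisation of anatomy.

## Numerical choices

* Perturbation edge lengths are drawn as integer centimetres so cuboids
  align to the fine lattice; origins are lattice-aligned; overlap is
  resolved by rejection sampling capped at 1,000 attempts.
* Object count per case is an explicit parameter (1 or 2), not random,
  since the corpus fixes separate case counts per object count. Whether
  objects may touch the body boundary is a margin parameter, default 0.
* Edge EMFs evaluate `A` at the face midpoint; a two-point trapezoid rule
  is selectable (`emf_rule`).
* `grad psi` uses central differences on interior conducting voxels and
  one-sided differences at body or conducting-region boundaries.
* The potential is defined up to a constant per conducting component;
  solutions are made unique by grounding one node per component, and
  reference-node independence is covered by tests.
* SSIM is computed once over the whole volume (the windowless form, with
  K1 = 0.01, K2 = 0.03, L = 1); the reported CC is the mean of per-sample
  correlations, with zero-variance samples excluded and counted rather
  than scored 0.
* Degenerate inputs - all-zero conductivity, all-zero signals, constant
  features - are flagged and handled explicitly (empty network, paired
  RMS reference for noise, floored standard deviations).
* Master seeds fan out to named substreams (placement, noise, split,
  init), so each stage is independently reproducible and below 2^31.

## Known limitations

Displacement currents, charge density and coil self-coupling are outside
the quasistatic, weak-coupling formulation; receiver mutual coupling and
finite wire cross-sections are ignored. Absolute signal units are not
physical - only differential, standardized signals are meaningful. The
full-scale profile is provided and runnable but its training cost is far
beyond a single CPU session; all quantitative statements shipped with the
package are computed by the test suite and the acceptance script at the
reduced scale described above.
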