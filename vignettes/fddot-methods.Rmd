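---
title: "Methods: simulation and dual-route reconstruction of FD-DOT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and dual-route reconstruction of FD-DOT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Frequency-domain diffuse optical tomography (FD-DOT) illuminates tissue with
intensity-modulated near-infrared light and records, at several
source-detector separations, the attenuation of the modulated amplitude and
the phase lag accumulated along the photon paths. Because phase carries
time-of-flight information, FD data constrain absorption (`mu_a`, mm^-1) and
reduced scattering (`mu_s'`, mm^-1) *separately*, enabling absolute
reconstruction of both — the basis for optical characterization of breast
tumors. This package implements, at a scale that runs on a single CPU, the
full simulation-to-evaluation loop for a handheld linescan reflectance probe:
phantom generation, frequency-domain diffusion forward modeling, a
model-based iterative reconstruction, a trainable volumetric network, and the
four image-quality metrics used to compare the two reconstruction routes.

# Geometry and protocol

The tissue is a 104 x 120 x 50 mm slab probed from its top face (z downward,
millimetres, voxel intervals half-open). Two regular grids are used
throughout: a 2 mm cell-centered grid for forward solves and a 4 mm
reconstruction basis restricted to the centered 64 x 64 mm scan region and
the top 32 mm of depth — a 16 x 16 x 8 target block (2048 voxels per
parameter). Nothing below 32 mm is reconstructed (with a 40 mm maximal
source-detector separation there is no usable sensitivity there), but the
full slab participates in every solve so boundary effects are modeled.

The probe carries one source and three in-line detectors at 20 / 30 / 40 mm.
The default linescan visits a 12 (x) x 16 (y) lattice at 4 mm pitch — 192
positions, 576 source/detector pairs, 1152 measurement channels (all natural-
log amplitudes first, then all phases in degrees, position-major, detectors
innermost). The 576-pair count fixes the lattice product, but not its exact
anchoring; we center the mean source-detector midpoint on the scan region and
keep the 40 mm arm at least one step inside the volume. Reduced lattices
(`n_x`, `n_y`, larger step) keep the same centering rule; the protocol file
(YAML) plus a content hash tie every measurement vector, normalization
statistic and trained model to the exact channel layout that produced it.

# Randomized phantoms

Backgrounds are drawn from truncated normals, `mu_a ~ N(0.005, 0.002)` and
`mu_s' ~ N(0.98, 0.20)` mm^-1 (floored at 1e-4 mm^-1), and 0-5 anomalies are
added with uniform radius 5-15 mm, top depth 0-20 mm, shape in {sphere, disk,
cuboid}, and uniform contrast 1.5-3.5 (`mu_a`) / 1.5-2.5 (`mu_s'`); each
anomaly perturbs absorption only, scattering only, or both (uniform thirds —
the split is not pinned down by the study conditions). Where the source
material leaves geometry unstated we chose once and kept it: all three shapes
share a bounding box of 2r per axis (ball, vertical cylinder of height 2r,
cube of edge 2r), and anomalies lie fully inside the lateral footprint of the
scan region. Under these choices the combined anomaly masks cover on average
about 11% of target-grid voxels, matching the dataset statistic the generator
is meant to emulate; the voxel-center membership rule (no partial-volume
weighting) matches how the masks are consumed by the loss and the metrics.
Overlapping anomalies follow a last-drawn-wins rule for voxel values while
masks still OR — overlap is rare at these densities.

The fixed depth test set places exactly three disks (radius 8 mm, thickness
5 mm) per volume — one `mu_a`-only, one `mu_s'`-only, one both — at 120
degrees around the scan-region center (circumradius 18 mm, so disks never
touch), with backgrounds and contrasts resampled per volume.

# Forward model

Photon transport is modeled by the frequency-domain diffusion approximation,

  -div(kappa grad Phi) + (mu_a + i omega / c) Phi = q,
  kappa = 1 / (3 (mu_a + mu_s')),

with the Robin condition `Phi + 2 A kappa dPhi/dn = 0` on all faces (A from
the Fresnel internal-reflection polynomial at n = 1.33; both config-exposed),
140 MHz modulation by default, a collimated source represented as an
isotropic point one transport mean free path (1 / mu_s') below the surface,
and detectors reading the fluence bilinearly interpolated on the first cell
layer. The PDE is discretized by a cell-centered finite volume scheme with
harmonic-mean face diffusivities — a regular-grid discretization of the same
physics that mesh-based FEM packages solve; validated against the analytic
semi-infinite extrapolated-boundary solution, relative (between-detector)
amplitude agrees within a few percent and phase differences within a fraction
of a degree on the default 2 mm grid.

The complex-symmetric system is solved by a preconditioned conjugate-
orthogonal CG (COCG). Two preconditioners are provided: a supernodal Cholesky
factorization of the real part (used directly on small grids, or factored
once for a homogeneous reference background and shared across the phantoms of
a dataset — the imaginary shift `omega/c` and the anomaly perturbations leave
the preconditioned spectrum tightly clustered, so solves need under ten
iterations), and a two-grid V-cycle fallback for one-off large solves. The
default solver tolerance of 1e-6 keeps the dimmest channel's log-amplitude
error near 3e-4, far below the measurement noise; oracle-grade comparisons in
the tests tighten it to 1e-9 or beyond.

Measurement noise follows a two-parameter amplitude-dependent model standing
in for a system-derived calibration: multiplicative Gaussian amplitude noise
(1% proportional plus a floor expressed relative to the brightest channel)
and additive Gaussian phase noise interpolating from 0.2 degrees at the
brightest channel to 1.0 degrees at the dimmest. All of it is config-driven
and seeded.

# Adjoint Jacobian and the iterative baseline

The sensitivity of every channel to every coarse-basis voxel is assembled by
the adjoint method — one direct solve per probe position, one adjoint solve
per distinct detector location (the linescan shares detector nodes between
neighboring positions), and per-cell products of the two fields. Rather than
the usual continuous approximations, the implementation differentiates the
*discrete* operator exactly: absorption acts on the diagonal and, with the
diffusion coefficient, through the harmonic-mean face conductances and the
Robin boundary term; both parameters reach kappa through
`d kappa / d mu = -3 kappa^2`. The payoff is that the Jacobian matches
central finite differences of the full nonlinear forward model to numerical
precision, which the test suite asserts at below 1% per entry.

The model-based baseline is a Levenberg-Marquardt / Tikhonov iteration in the
under-determined form

  delta_mu = J^T (J J^T + lambda I)^{-1} delta_Phi.

(The printed source formula carries a duplicated `J^T`, dimensionally
inconsistent; this is the standard form consistent with its surrounding
description.) Before inversion the system is row-normalized by the measured
data magnitudes and column-normalized by the current optical-property values;
`lambda` starts at 0.01 of the maximum diagonal of the normalized `J J^T`
(the normalization order is unstated in the source; computing `lambda_0` on
the normalized system makes it dimensionless and reproducible) and decays by
`10^0.25` per iteration. Each parameter's update image is smoothed with an
8 mm FWHM Gaussian (truncated at 3 sigma, applied to the update rather than
the cumulative estimate), the estimate is clamped at 10% of the initial
background, and iteration stops when the projection error improves by less
than 2%, at the iteration cap, or after three consecutive divergent steps.
The reconstruction forward grid is 4 mm — deliberately distinct from the 2 mm
simulation grid, mirroring the use of a separate reconstruction mesh to avoid
the inverse crime (we coarsen rather than refine: the reconstruction only
carries 4 mm information, and the cost difference funds the rest of the
study). Because the decaying `lambda` keeps producing >2% improvements while
progressively fitting measurement noise, the convergence rule rarely fires
before the cap on noisy data; the desk preset therefore caps iterations at 8,
bracketing the typical convergence reported for this algorithm class
(5.6 +/- 3.6 iterations), while the module default remains 25.

# Preprocessing

Network inputs are the raw channel vectors z-scored per channel with
statistics fitted on training data only (min-max input scaling is available
behind the same interface for comparison; z-scoring is the final choice as it
is robust to phase outliers). Targets are min-max normalized per parameter
with global training-set extrema; the inverse transform is exact and
predictions are deliberately not clipped to [0, 1]. Target volumes are
produced from the fine rasterization by averaging 2 mm slices into 4 mm slabs
and resampling each slab in-plane with Catmull-Rom bicubic interpolation at
the coarse voxel centers ("bicubic" is a 2D operator; the per-slab reading is
config-switchable to trilinear), then cropping to the 16 x 16 x 8 x 2 tensor
with channels (mu_a, mu_s'). Normalization statistics carry a dataset
fingerprint and the protocol hash so a model can never be applied across
layouts unnoticed.

# The network

The trainable reconstructor has three modules. A fully connected layer maps
the measurement vector to the 16 x 16 x 8 x 2 voxel tensor through a tanh
activation — tanh rather than relu because FD sensitivities change sign with
voxel position relative to the probe. A 3D convolutional encoder-decoder (by
default 4 layers, kernel 3^3, 64 filters, relu, dropout 0.2 after each hidden
layer, linear 2-channel last layer — a linear head keeps normalized
predictions unconstrained, matching the no-clipping convention) refines that
initial inverse into the stage-1 reconstruction. A two-level 3D U-Net (32/64
filters at full scale; 2x max-pooling, stride-2 transposed-convolution
upsampling, skip concatenation, linear 2-channel head) then denoises and
sharpens it. The two-channel treatment of (mu_a, mu_s') as one volume lets
the filters learn cross-parameter structure, which is where crosstalk is won
or lost. Internal layout choices that the architecture description leaves
open (dropout placement, no pooling inside the encoder-decoder, the U-Net
depth compatible with an 8-voxel z axis) are fixed here as the smallest
standard choices and config-exposed.

Training minimizes an ROI-weighted MSE: with `W_ROI = 0.887` (the background
voxel fraction of the training distribution), the loss is `W_ROI` times the
mean squared error over voxels inside the OR-combined anomaly mask (both
channels — so spurious cross-parameter contrast inside anomalies is
penalized) plus `1 - W_ROI` times the mean over background voxels; regional
means are taken over the minibatch, so an anomaly-free example simply
contributes only background terms. Training is two-stage: the FC +
encoder-decoder modules are trained and frozen, then the U-Net is trained on
their outputs under the same loss. Both stages use Adamax with early stopping
on validation loss (up to 500 epochs, patience 50, at full scale) and restore
the best-validation weights; everything is seeded, and single-threaded runs
are bit-reproducible. The convolution inner loops are C++ (im2col plus
single-precision BLAS); gradients are hand-derived and verified against
finite differences in the tests.

A property of this loss worth knowing at small scale: for a model that cannot
yet localize anomalies from the data, the region weights make the optimal
unlocalized prediction a blend of roughly `W_ROI` times the anomaly mean and
`1 - W_ROI` times the background mean, biasing predictions upward until
localization is learned. With the full 1152-channel protocol and 10^4
examples the network localizes well and the bias resolves; at reduced channel
counts it is the dominant error term in the network's absolute values, and
the desk-scale results must be read with that in mind.

# Metrics and comparison

Per volume and parameter: RMSE over the target grid (mm^-1); the
Sorensen-Dice coefficient between the truth ROI mask and the voxels above 0.5
after min-max normalizing the prediction over the volume itself (1 if both
masks are empty, 0 if exactly one is); the contrast ratio — reconstructed
anomaly/background contrast over true contrast, with the background taken as
the complement of the *combined* mask so a co-located anomaly of the other
parameter never contaminates it; and crosstalk — for an anomaly perturbing
only one parameter, `|ratio - 1|` of predicted to true mean of the *other*
parameter over its ROI (the source prints the definition without an explicit
division; `|ratio - 1|` of regional means is the reading consistent with
"closer to 0 is better"). Ratio metrics are computed on physical-unit
volumes; being ratios, the choice is nearly moot. Method comparison uses
paired t-tests per metric and parameter across matched examples at alpha =
0.05, plus group means by anomaly depth.

# Scale presets and problem sizes

The `full` preset declares the headline study conditions (10,000 + 1,000
examples, 192 probe positions, 64 filters, 500-epoch two-stage training) —
generating it is a multi-day single-CPU computation and is not run by the
tests. The `desk` preset is the package's own reduced study: 500 training +
25 validation phantoms, a 2 x 4 probe lattice at 16 mm pitch (48 channels —
the densest lattice a single-CPU afternoon accommodates, chosen because the
network's advantage rests on channel count), 8/16 network filters, up to 25
training epochs per stage (patience 6, Adamax, learning rate 0.003), 51
depth-test volumes (17 each at 5 / 10 / 15 mm), the 8-iteration
reconstruction cap (bracketing the typical convergence of the algorithm
class), and the validation-based lambda calibration. The `tiny` preset
(200 + 40, a 3 x 3 lattice, 30 test volumes) is a smoke-test scale. The
presets change only lattice density, dataset size and network capacity —
geometry, optical-property distributions, physics and loss are identical
across presets. The test suite exercises the end-to-end comparison at the
desk conditions with sample counts reduced to 160 training / 16 validation
phantoms and 30 test volumes, sized so the whole suite completes in well
under half an hour on one CPU; a full desk run of the same seeded pipeline
reproduces the comparison at the larger counts.

One desk-scale run (seed 1) illustrates what the reduced study shows: the
calibrated iterative baseline recovers absorption RMSE well but its
absolute scattering is unstable (mean mu_s' RMSE roughly 0.7 mm^-1 against
the network's 0.39, paired p < 0.01), while its Dice overlap decays
cleanly with anomaly depth; the network wins the scattering comparison for
exactly the reason the method was proposed, and its shallow-depth overlap
is its weakest point. These numbers are recomputed, not asserted, by the
suite's end-to-end test at the reduced counts.

What passing desk-scale tests do and do not show: the synthetic phantoms are
homogeneous slabs with uniform-valued anomalies and an idealized noise model;
real tissue has structured backgrounds, surface-coupling variability and
calibration error, none of which the generator emulates. Desk-scale results
demonstrate that the pipeline's components are correct and that the
comparative machinery reproduces the study's *structure*; they do not
re-establish its full-scale effect sizes.

# Numerical choices and degenerate inputs

Solver tolerances (1e-6 default, tightened in oracle tests), the COCG
breakdown guard, the positivity floors (1e-4 mm^-1 in the generator, 10% of
background in the reconstruction, 1e-12 channel-scale floor with a warning
for dead channels), the phase-unwrap guard at |180| degrees, the exact-zero
residual fixed point (a first update of zero and immediate convergence), and
empty-mask metric conventions are all asserted in the test suite. Random
anomaly placement that cannot fit retries a bounded number of times and then
drops the anomaly with a warning. The z extent (50 mm) is not a multiple of
the 4 mm basis; the reconstruction grid truncates to 48 mm, trimming only
insensitive deep cells.

# Known limitations

The finite-volume forward model carries a small constant phase offset from
the point-source representation (relative between-detector comparisons are
accurate; absolute calibration would absorb it, as it does on real systems).
The network at desk scale under-localizes and therefore inherits the
ROI-loss bias discussed above, which is visible in its absolute scattering
values. The experimental arm of the original study (physical phantoms,
system calibration) is out of scope, as are chromophore unmixing, structural
priors, and hyperparameter search campaigns.
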