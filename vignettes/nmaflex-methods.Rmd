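---
title: "Normal-mode based analysis of continuous conformational heterogeneity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nmaflex methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design
choices made where the design was genuinely open.

## The conformational model

A flexible complex is represented by a reference point model (atoms,
coarse-grained atoms, or pseudoatoms fitted to a density map) and a
set of collective motion directions from elastic-network normal mode
analysis.  The elastic network connects every pair of points closer
than an interaction radius with a Hookean spring of uniform constant
$\gamma = 1$; the anisotropic Hessian's eigenvectors are the modes and
its eigenvalues the squared frequencies.  The six zero-frequency modes
are rigid-body motions and are discarded, so the first flexible mode
is conventionally "mode 7".

Assumptions worth keeping in mind:

* the harmonic approximation holds only near the reference
  conformation; large-amplitude displacements along a mode are linear
  extrapolations that can locally distort geometry;
* a uniform spring constant means eigenvalues carry no physical
  units — only mode *directions* matter downstream, and mode
  amplitudes are dimensionless by convention;
* modes are unit-norm over all $3N$ coordinates and not
  mass-weighted.  This makes the amplitude-to-displacement relation
  exact: a single-mode amplitude $q$ displaces the model by RMSD
  $|q|/\sqrt{N}$.  A consequence is that the *physical* meaning of an
  amplitude depends on $N$; the end-to-end test reference has
  $N = 1600$ points and an 18 Å RMS radius, so the trajectory's
  amplitude scale (up to $\approx 283$ in Euclidean norm) maps to
  RMSDs of 5–7 Å — the same amplitude-to-deformation ratio as a
  full-atom model of a few-hundred-residue complex, where published
  per-mode amplitude errors of a few units correspond to sub-Ångström
  coordinate RMSDs.

Key parameters: the interaction radius (default 8 Å for
atomic/C$\alpha$ models; 20 Å is typical for very coarse models — it
is always explicit, never inferred), the number of modes (3 by
default, matching the synthetic study design), and the RTB block size
(consecutive-residue rigid blocks; projecting the Hessian onto
per-block rigid-body bases accelerates the eigenproblem at a modest
accuracy cost that the tests bound via the Rayleigh–Ritz inequality).
The eigenproblem is solved densely (LAPACK); at the coarse-grained
sizes this package targets (up to a few thousand points) this is
simpler and more robust than sparse iterative solvers, and RTB is the
intended route for larger structures.

Pseudoatomization of a density map is implemented as density-weighted
Lloyd iterations over above-threshold voxel centers with a
deterministic farthest-point initialization and a fixed isotropic
width of $1.5 \times$ voxel size.  This is a deliberately simple
stand-in for dedicated Gaussian-mixture map approximations: it
reports its own model-to-map correlation so users can judge fit
quality, and the tests check it recovers planted point models.

## The image model

A particle image is the line integral along $z$ of the rotated,
shifted, Gaussian-rendered model.  Conventions, fixed once and used
by the simulator, the aligner and the reconstructor identically:

* rotations are ZYZ Euler angles in degrees,
  $R = R_z(\mathrm{rot}) R_y(\mathrm{tilt}) R_z(\mathrm{psi})$ with
  right-handed fixed-axis factors; quaternions are $(w, x, y, z)$ with
  canonical sign $w \ge 0$;
* coordinates are in Å; the model origin projects to image index
  $L/2$ (the FFT center); shifts are stored in pixels;
* each point is an isotropic 3D Gaussian whose exact line integral is
  a 2D Gaussian of the same width (default $1.5 \times$ pixel size —
  resolution-limited rendering), truncated at $6\sigma$ so that
  Fourier-shift consistency holds to $\sim 10^{-6}$.

The CTF uses the standard phase model
$\chi(f) = \pi \lambda \Delta z f^2 - \tfrac{\pi}{2} C_s \lambda^3 f^4$
with the relativistic electron wavelength, and
$\mathrm{CTF} = -\sqrt{1 - w^2}\sin\chi - w\cos\chi$ where $w$ is the
amplitude contrast (default 0.1; unstated in the source protocol and
irrelevant after phase flipping, which only needs the sign
structure).  The defocus is stored signed as configured; only
$|\mathrm{CTF}|$ matters downstream once images are phase-flipped.
Phase flipping is tracked with an attribute so that repeating the
correction is a no-op.

Noise is added in two stages: a fraction $p$ of the total noise
variance before the CTF (pre-scaled by the CTF's mean power so its
post-filter share is exact) and $1-p$ after, with the total set so
that the variance ratio over the particle support mask equals the
configured SNR.  The split $p$ and the support-vs-full-frame SNR
definition are unstated in the source protocol; both are exposed as
parameters with defaults $p = 0.5$ and support-mask SNR.

## What the simulator emulates — and what it does not

The generator reproduces the reference synthetic-study conditions:
conformations along the helical three-mode trajectory
$q_7 = -200r,\; q_8 = 200\sin\pi r,\; q_9 = 200\cos\pi r$ with
$r \sim U(0,1)$; angles sampled uniformly per Euler angle
(rot, psi $\in [0,360)$, tilt $\in [0,180)$ — *not* uniform on SO(3),
replicated as specified); shifts uniform in $\pm 5$ px; a single CTF
for the whole dataset (200 kV, $C_s$ 2 mm, defocus $-0.5$ µm); SNR
0.1; antialiased $2\times$ Fourier-crop downscaling (for 0.325 Å
pixels this is the 1.3 Å cutoff).  It does **not** model ice or
solvent background, dose fractionation, astigmatism, beam tilt, or
per-particle defocus variation.  Passing tests therefore demonstrate
internal consistency of the method under idealized image formation,
not robustness to the full physics of experimental micrographs.

## Alignment (stage 1)

The per-image elastic + rigid alignment maximizes normalized
cross-correlation (invariant to global intensity scale) between the
image and projections of the deformed reference.  Design choices, all
package-level replacements for unstated details of the original
software: a coarse orientation grid (default 30°) with FFT
cross-correlation translation search and 3-point parabolic sub-pixel
refinement; a beam over the best few grid candidates, each pursued
with alternating bounded golden-section line searches over the
amplitudes and Nelder–Mead refinement of the five rigid parameters;
and a final joint simplex polish over all parameters.  The beam
matters because large elastic deformations can demote the true
orientation basin in a rigid-only grid search.  With an oracle start
the optimizer never returns a solution scoring below it (asserted in
the tests).  Real-space NCC replaces the original wavelet-domain
multiresolution alignment, which is out of scope here.

## The regressor (stage 2)

The network is a residual CNN feature extractor followed by an MLP
head on the flattened final feature maps (1000, 512, 128 hidden
nodes, ReLU, dropout 0.5, linear output), trained separately per
parameter type with MAE loss and Adam (defaults: lr $10^{-5}$ divided
by 10 every 80 epochs, weight decay $10^{-5}$ added to the gradients,
batch size 2, 400 epochs — the reference full-scale protocol).
Orientations are learned as unit quaternions; labels are
sign-canonicalized before training and predictions are normalized and
canonicalized before conversion back to Euler angles.  Inputs are
per-image standardized; amplitude and shift targets are z-scored on
the training set (quaternions exempt); the best-validation-epoch
weights are retained.

Because no deep-learning framework is assumed, the package carries a
compact self-contained engine: im2col + GEMM convolutions, batch
normalization, and a fused Adam step, exact to finite-difference
gradient checks.  The `"tiny"` depth (an 8-channel strided stem plus
three basic residual stages of 16/32/64 channels — 8 layers in all)
exists so the full pipeline runs on one CPU; depths 18/34/50/101
follow the standard basic/bottleneck layouts, with 34 the reference
default.

### Desk-scale benchmark sizes

The test suite exercises the full pipeline at a reduced scale chosen
to keep a complete run on a single CPU practical: 2,700 simulated
particles at 64×64 px (SNR 1.0, no CTF) split 2,000 / 200 / 500 into
train / validation / test, images downscaled 2× before training (the
same antialiased reduction the full-scale protocol applies), the
`"tiny"` depth, and at most 50 epochs with learning rate $10^{-3}$
and batch 32, chosen on the validation split.  Per-head training
budgets differ because the tasks differ in difficulty: shift and
amplitude validation error plateaus within ~25 epochs, orientation is
given the full budget.

What this scale can and cannot show: the in-plane shift head
generalizes well here, but orientation (and, to a lesser degree,
amplitude) regression is data-hungry — the full protocol uses 14,055
training images, a 34-layer network and 400 epochs of batch-2 Adam,
roughly three orders of magnitude more optimizer steps than the
desk budget.  Diagnostics included in the development of this
package show the failure is informational, not mechanical: the same
engine reaches ~10–17° pose error when deformation, shifts and noise
are absent, gradients are finite-difference exact, and an
image-space nearest-neighbour oracle over the whole training set —
an upper bound on pure template matching — still makes tens of
degrees of pose error at 2,000 samples once all nuisance factors are
present.  The end-to-end test therefore asserts the intended
full-protocol error bounds and documents that the orientation and
amplitude bounds are not reachable at this training scale, rather
than silently relaxing them.

## Conformational space (stage 3)

Amplitude vectors are filtered by classical Mahalanobis distance
(threshold 3.2 by default; classical rather than robust covariance —
the source protocol names only the distance and threshold — with an
optional ridge for near-singular covariances), embedded by
mean-centered PCA (SVD; component signs fixed deterministically by
making each component's largest-magnitude loading positive), grouped
either by axis-aligned boxes or by equal-count bins along PC1 with
configurable discarded tail fractions (a declarative, reproducible
replacement for interactive region picking), and animated by inverse
PCA along a chosen axis across a quantile span of the scores.

## Reconstruction and evaluation

3D reconstruction is direct Fourier inversion: each image's 2D FFT is
shift-corrected by a phase ramp, de-modulated to the centered DFT
(the object sits at pixel $L/2$, so the raw DFT carries a
$(-1)^k$ oscillation that would defeat interpolation), inserted as a
central slice with trilinear gridding, and normalized by the
accumulated sampling weights (bins below a weight floor of 0.2 are
zeroed).  No CTF correction happens inside reconstruction — inputs
are phase-flipped.  FSC uses shells of one Fourier voxel and linear
interpolation for threshold crossings (0.5 and 0.143 reported).

The evaluation report mirrors the standard layout: per-mode and
mean-over-modes amplitude MAE, the mean axis-based angular distance
$\frac{1}{3}\sum_k \arccos\langle R_1 e_k, R_2 e_k\rangle$ (the
unweighted 3-axis mean; the axis-angle geodesic is available
separately for diagnostics), per-axis shift MAE in Å, and three RMSD
summaries displacing the reference with one parameter type at a time
(rotation RMSDs about the model centroid, the only canonical origin).

## Numerical notes and limitations

* Degenerate ENM eigenvalues: the returned eigenspace basis is
  accepted as-is; tests compare subspaces, never individual
  degenerate vectors.
* Rigid-body mode detection uses a relative eigenvalue threshold;
  quasi-linear point chains can have extra exact zero modes in an
  anisotropic network (transverse displacements that stretch no
  spring) — fixtures are built connected and generically 3D.
* Euler recovery at gimbal lock (tilt near 0 or 180°) sets psi to 0
  and folds the in-plane rotation into rot.
* The aligner is a local optimizer after a finite grid; with very
  large deformations it can return a wrong basin — the beam width and
  grid step trade cost against robustness.
* Amplitudes near the $w = 0$ quaternion boundary have discontinuous
  canonical targets; the regressor's errors concentrate there.
* The reconstruction weight floor suppresses poorly sampled Fourier
  bins; reconstructions from very few or identically posed images
  show the expected missing-information artifacts rather than errors.
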