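---
title: "Rotation-equivariant autoencoding in spherical Fourier space: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation-equivariant autoencoding in spherical Fourier space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvae)
```

This vignette documents the science and the engineering decisions behind
`hvae`: the model and its assumptions, every convention a user might need
to interoperate with (bases, orderings, normalizations), what the
synthetic data emulate, and the choices we made where the design was
genuinely open.

## The model

### Data representation

We model functions distributed around a specified origin in 3D — e.g. the
heavy atoms within a cutoff radius of a residue's Cα, or an image on the
unit sphere. Such a function ρ(r, θ, φ) is projected onto the orthonormal
product basis of 3D Zernike radial polynomials and spherical harmonics
(the Zernike Fourier transform, ZFT), truncated at a maximum degree `L`
and maximum radial frequency `N`. For a point cloud the projection has a
closed form — a sum of basis-function evaluations over the points, one
channel per point label — and needs no spatial discretization. For
spherical images the radial factor is constant and the projection is a
quadrature over a Driscoll–Healy grid.

The coefficients form a *steerable tensor*: a collection of degree-ℓ
blocks, each a `C_ℓ × (2ℓ+1)` matrix of channels by orders, on which a
rotation `R` acts block-diagonally through the real Wigner matrices
`D^ℓ(R)`. All package operations preserve this action; the randomized
equivariance suite in the tests verifies every layer to 1e-6 or better
(in practice machine precision).

### Architecture

The encoder is a stack of Clebsch–Gordan blocks whose maximum degree
*decreases* to 1; the decoder mirrors it, growing degrees from `{0, 1}`
back to `L`. Each block composes, in order:

1. **Lin** — a learned `C_out × C_in` matrix per degree, applied
   identically to every order `m` (channels mix, orders do not);
2. **ETP** — the efficient (channel-wise) Clebsch–Gordan tensor product:
   for each retained degree pair and each channel `c`, the bilinear
   coupling `(h_{ℓ1,c} ⊗ h_{ℓ2,c})_{ℓ3}`, the network's only
   nonlinearity. Inputs pass through alongside the products ("skip");
3. **BN** — batch norm: each (degree, channel) feature is divided by the
   batch-averaged norm of that feature (a rotation invariant), with a
   learned scale; evaluation mode uses running statistics;
4. **SN** — signal norm: each tensor is divided by the square root of its
   total norm (the sum of squared feature norms) and scaled by a learned
   per-degree factor. This keeps decoder activations bounded at
   evaluation time, where batch statistics alone are unreliable.

From the final encoder block, a linear head on the ℓ = 0 channels yields
the invariant latent vector `z` (or a mean and log-variance in the
variational model), and a linear head on the ℓ = 1 channels yields two
3-vectors that Gram–Schmidt orthonormalizes into the frame `g`, the third
row being the cross product of the first two. `z` is *exactly* invariant
and `g` exactly co-rotates (`g(Rx) = g(x) Rᵀ`, frames stored with basis
vectors as rows) because every constituent map is equivariant — no
training is needed for these properties to hold.

Training minimizes `α · MSE(x, x′) + β · KL(q(z|x) ‖ N(0, I))` with Adam.
The MSE is the mean over all coefficients, so `α` is comparable across
signatures; it is pairwise rotation invariant, which is what keeps
gradient descent itself equivariance-preserving. With `β = 0` the model
is a plain autoencoder; with `β > 0` the invariant part of the latent
space becomes an isotropic Gaussian posterior with the standard
reparameterization `z = μ + exp(½ log σ²) ⊙ ε`. The KL applies only to
`z`; the frame is always deterministic. An optional linear β warm-up over
the first 25% of epochs (standard KL annealing) is on by default and
configurable.

## Conventions (interoperability contract)

* **Real harmonics.** All tensors are real. The real basis is built from
  the Condon–Shortley complex harmonics as
  `S_{ℓ,m>0} = √2(−1)^m Re Y_ℓ^m`, `S_{ℓ,0} = Y_ℓ^0`,
  `S_{ℓ,m<0} = √2(−1)^m Im Y_ℓ^{|m|}`, stored in order `m = −ℓ…ℓ`. For
  ℓ = 1 this order corresponds to Cartesian `(y, z, x)`, and
  `D^1(R) = R[p, p]` with the fixed permutation `p = (2, 3, 1)`.
* **Wigner matrices** are defined by the vector identity
  `S_ℓ(R·x̂) = D^ℓ(R)·S_ℓ(x̂)`; blocks rotate as `h → h D^ℓ(R)ᵀ`. They are
  computed from the factorial (Racah-type) formula for the complex
  Wigner-d conjugated into the real basis; ZYZ Euler angles, intrinsic,
  `R = Rz(α) Ry(β) Rz(γ)`, with the gimbal-lock convention γ = 0.
* **Clebsch–Gordan coefficients** are computed from the Racah factorial
  formula at table-build time and cached; factorials up to the degrees
  used are exact in double precision, and the real-basis tables satisfy
  the orthogonality relation to ~1e-15 (asserted at 1e-8 in the tests).
  For odd ℓ1+ℓ2+ℓ3 the real-basis tensor is purely imaginary; we store
  its imaginary part, a global unit phase that affects neither
  equivariance nor orthogonality.
* **Zernike radial polynomials.** We use the closed form
  `R_{nℓ}(r) = √(2n+3) · r^ℓ · P_k^{(0, ℓ+½)}(2r²−1)`, `k = (n−ℓ)/2`,
  orthonormal on the unit ball with weight `r²`; `R_{nℓ} ≡ 0` when
  `n < ℓ` or `n−ℓ` is odd (returned as exact zeros). Radii are divided by
  the cutoff `r_max` (Å for atomic data; the amino-acid configuration
  uses 10 Å) before evaluation; points exactly at `r_max` are included.
  Any orthonormal radial convention reproduces the same coefficient
  counts (e.g. 940 for four atom channels at `L = 4`, `N = 20`); decoded
  shapes would only match another implementation's if its convention
  matched too.
* **Flattening order** is ascending degree, then channel, then
  `m = −ℓ…ℓ`. Within a ZFT degree block, rows are ordered channel label
  first (the configured order, default C, N, O, S), then radial frequency
  ascending.
* **Driscoll–Healy grids** have `2·bw × 2·bw` samples at
  `θ_j = πj/(2·bw)`, `φ_k = πk/bw`, with the classical sampling-theorem
  weights. Their exactness for band-limited integrands is *tested*
  (orthonormality of all harmonics up to the bandwidth), not assumed.

## Design choices where the design was open

* **Block operation order.** Descriptions of CG blocks in the literature
  vary between Lin→ETP→BN→SN and BN→ETP→SN→Lin. We default to
  Lin → ETP → BN → SN and make the order a configuration option.
* **ETP connectivity.** The default path set couples every degree with
  itself into all admissible degrees up to the cap, plus `ℓ × 0 → ℓ` and
  `ℓ × 1 → ℓ−1, ℓ, ℓ+1`. This guarantees a route from every degree down
  to the invariants (encoder) and up from `{0, 1}` (decoder) with a
  product count linear in the number of degrees; it is fully overridable
  via `etp_path_spec()`.
* **Frame injection into the decoder: all three rows.** A subtle
  consequence of *channel-wise* tensor products is that a feature coupled
  with itself loses its antisymmetric part (`v ⊗ v` vanishes at odd
  output degree). If the decoder saw only the two Gram–Schmidt rows, no
  sequence of channel-wise products could recover the pseudo-vector
  `r₃ = r₁ × r₂`, and the reachable output space is measurably
  rank-deficient at high degrees — we observed an architecture-independent
  reconstruction-error floor in exactly this configuration. Injecting all
  three rows as three ℓ = 1 channels restores full rank at every degree
  (and costs nothing, as `r₃` is determined by the frame). Joint
  equivariance is unaffected.
* **Latent heads.** `z` is a learned linear map of *all* final ℓ = 0
  channels; the frame comes from a learned linear map of the final ℓ = 1
  channels to exactly two vectors. These are the minimal realizations of
  the two heads.
* **Cosine loss** is `1 − ⟨x, x′⟩ / (‖x‖‖x′‖)` with a *global*
  normalization over all coefficients (a per-degree variant is available
  behind `per_degree = TRUE`). It is dimensionless, invariant to joint
  rotation and to positive rescaling of either argument, hence
  comparable across datasets and encodings — and unfit for training,
  being blind to magnitudes; training always uses the MSE.
* **Degree schedules.** Encoder caps default to a linear descent
  `L−1, …, 1` and the decoder mirrors it. The toy benchmarks use the
  shortened schedules `(2, 1)` / `(2, 4)`, which preserve a coupling path
  between every pair of degrees while halving depth; both schedules are
  plain configuration.
* **K-means for clustering metrics** uses k = number of true classes with
  10 restarts and a fixed seed; classification uses a standardized
  pipeline (train-statistics standardization → multinomial linear model
  or KNN), with an index-overlap guard against split leakage.

## Numerical choices

* Batch-norm momentum 0.1 and ε = 1e-6; a batch of size 1 falls back to
  running statistics with a warning. Signal-norm ε = 1e-6 guards the
  all-zero tensor (mapped to zero, never NaN).
* Gram–Schmidt degeneracy: `gram_schmidt_frame()` raises an error below a
  1e-8 tolerance; the training-path variant instead perturbs the
  offending sample's vectors by 1e-6 along a fixed orthogonal pair and
  warns, so gradients stay finite near collinearity.
* Weight initialization is Gaussian with variance `1/C_in` per degree,
  keeping feature norms O(1) through depth; all initialization is
  seeded through the model configuration.
* Adam (lr 1e-3 default; the examples use 3–5e-3) with standard moments;
  gradients are hand-derived per layer and verified against central
  finite differences in the test suite.
* Optional early stopping monitors held-out cosine loss with patience 20.

## What the synthetic data do and do not emulate

The cloud generator draws from three geometrically distinct template
classes (a planar ring, a helix-like arc, nested tetrahedra; 8–20 points)
spread over the four atom-type channels, adds isotropic Gaussian noise
(σ = 0.05 in unit-ball coordinates), applies a Haar-random rotation, and
scales into the `r_max` ball, storing the ground-truth rotation of every
sample. The image generator sums von-Mises–Fisher-like bumps at
class-specific center patterns on a Driscoll–Healy grid, again with
stored rotations. Both are bit-reproducible functions of (spec, seed).

These datasets exercise every pipeline property that is *structural*:
equivariance of the transforms, invariance of the latents, recoverability
of known rotations, class separability of invariant features. They do not
emulate the statistics of real protein neighborhoods — chemically
correlated atom positions, variable point counts per channel, density
inhomogeneity — nor real spherical imagery. Passing the toy benchmarks
therefore demonstrates that the machinery is correct and trainable, not
that a given architecture will reach any particular accuracy on real
structures.

## Problem sizes used by the tests and the acceptance script

The toy training benchmark uses 600 three-class clouds (450 train / 150
held out) encoded at `L = 4`, `N = 4` (140 coefficients), a latent of 8,
hidden width 6, 120 epochs of Adam at 3e-3 — a scale chosen so the whole
suite runs comfortably on one CPU while leaving a wide margin on its
quality thresholds. The rotation-augmentation parity check (training on
non-rotated versus rotated data) uses five seeds at a smaller scale,
since the property it verifies — that an equivariant model with an
invariant loss cannot distinguish the two regimes — holds at any scale;
the observed gaps are at the 1e-8 level, i.e. numerically zero.

## Known limitations

* High-degree features are reconstructed less accurately than low-degree
  ones at small widths: all degrees funnel through the same invariant
  bottleneck, and information from low degrees appears to reach ℓ = 0
  more easily. A multiscale latent that encodes degree bands separately
  would address this; it is out of scope here.
* Wigner matrices are built from factorial sums, accurate to ~1e-12 up to
  the default degree cap of 14; far beyond that, recursive constructions
  would be preferable.
* The trainer is plain R: practical on hundreds-to-thousands of samples
  at `L ≤ 6`; it is not a GPU substitute and is not meant to reproduce
  large-scale benchmark training.
* Parity is not modelled: the group is SO(3), not O(3), so mirror images
  are distinct inputs.
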