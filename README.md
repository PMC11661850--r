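# hvae

SO(3)-equivariant (variational) autoencoders in spherical Fourier space,
implemented in pure R.

## The problem

Much of structural biology's data lives in a ball around a distinguished
point: the heavy atoms within 10 Å of a residue's Cα, a ligand-binding
pocket, a spherical image. The absolute orientation of such a neighborhood
is physically meaningless, yet it dominates naive coordinate
representations — a classifier or autoencoder that is not rotation-aware
must either see ~hundreds of augmented copies of every sample or discard
information by hand-picking invariants.

`hvae` takes the representation-theoretic route. Data are encoded by the
**Zernike Fourier transform** (ZFT): a density ρ(r, θ, φ) on the ball
becomes coefficients

  Ẑ_{ℓmn} = ∫ ρ(r) R_{nℓ}(r) S_{ℓm}(θ, φ) dV,

with 3D Zernike radial polynomials R_{nℓ} and real spherical harmonics
S_{ℓm}; for an atomic point cloud the integral collapses to a closed-form
sum over atoms, one channel per atom type. A rotation of the input acts on
the coefficients block-diagonally through the Wigner matrices D^ℓ — the
coefficients form a *steerable tensor*.

On these tensors the package builds a fully equivariant autoencoder:

* **encoder** — a stack of Clebsch–Gordan blocks (degree-wise linear maps,
  channel-wise Clebsch–Gordan tensor products as the nonlinearity, batch
  norm and signal norm) transfers information from high degrees down to
  ℓ ≤ 1. The ℓ = 0 output is a rotation-**invariant** latent vector `z`;
  two learned ℓ = 1 vectors are orthonormalized by Gram–Schmidt into an
  **equivariant** orientation frame `g` (a proper rotation matrix);
* **decoder** — mirror-image CG blocks rebuild the input signature from
  `(z, g)`, so the whole map satisfies `reconstruct(R·x) = R·reconstruct(x)`
  exactly, by construction, at any stage of training;
* training minimizes `α·MSE + β·KL` (β = 0 gives the plain autoencoder;
  β > 0 a variational one with an isotropic Gaussian posterior over `z`),
  with hand-written reverse-mode gradients and Adam — no deep-learning
  framework is required.

The latent space is therefore *disentangled by construction*: `z` carries
what the object looks like, `g` how it is oriented. Decoding with the
identity frame renders any sample in the model's canonical orientation;
summing residue-level `z`'s over a binding pocket gives an SE(3)-invariant
pocket embedding for affinity regression.

## Worked example

```r
library(hvae)

# 1. Synthetic three-class point clouds (ring / helix / tetrahedra) in a 10 A ball
ds <- make_cloud_dataset(n_per_class = 100, seed = 42, r_max = 10)

# 2. Zernike Fourier transform: atom-type channels, L = 4, N = 4
cfg <- zft_config(L = 4, N = 4, r_max = 10)
tensors <- encode_cloud_dataset(ds, cfg)
st_signature(tensors[[1]])
#> <tensor_signature>  l=0:12 l=1:8 l=2:8 l=3:4 l=4:4  | coefficients: 140

# 3. Train a small autoencoder (invariant latent z = 8 plus a frame)
model <- hvae_model(hvae_config(zft_signature(cfg), latent_dim = 8, hidden = 6,
                                encoder_caps = c(2, 1), decoder_caps = c(2, 4),
                                seed = 1))
set.seed(7)
test_idx <- sort(sample(300, 75))
fit <- train_hvae(model, tensors[-test_idx], epochs = 100, batch_size = 64,
                  lr = 3e-3, seed = 7)

# 4. Held-out reconstruction quality and latent-space structure
recs <- reconstruct(fit$model, tensors[test_idx])
mean(mapply(cosine_loss, tensors[test_idx], recs))
#> held-out cosine loss: 0.109
code <- encode(fit$model, tensors[test_idx])
latent_cluster_eval(code$z, ds$labels[test_idx], seed = 1)[c("purity", "v_measure")]
#> k-means purity: 1   V-measure: 1

# 5. The latent code is exactly rotation invariant; the frame co-rotates
x <- tensors[[1]]; R <- random_rotation()
c1 <- encode(fit$model, x); c2 <- encode(fit$model, st_rotate(x, R))
max(abs(c2$z - c1$z))                                  #> 3.2e-12
max(abs(c2$frame[1, , ] - c1$frame[1, , ] %*% t(R)))   #> 4.6e-11
```

A cosine loss of ~0.1 means held-out neighborhoods are reconstructed to
within ~10% angular deviation in coefficient space; purity 1 means the
invariant latents cluster perfectly by shape class even though every
sample was randomly oriented.

A thin command-line interface wraps the same pipeline
(`inst/cli/hvae.R encode|train|reconstruct|generate|evaluate|fixtures`).

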