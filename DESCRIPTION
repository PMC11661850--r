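Package: hvae
Title: SO(3)-Equivariant (Variational) Autoencoders in Spherical Fourier Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Rotation-equivariant (variational) autoencoders for 3D data
    distributed around a specified origin, built entirely in spherical
    Fourier space. Provides exact SO(3) representation-theory kernels
    (real spherical harmonics, 3D Zernike radial polynomials, Wigner-D
    matrices, Clebsch-Gordan coefficients), a steerable-tensor data model,
    forward and inverse Zernike Fourier transforms for labeled point
    clouds and spherical images, equivariant network layers with
    hand-written reverse-mode gradients (degree-wise linearities,
    channel-wise Clebsch-Gordan tensor products, batch and signal
    normalization), an encoder-decoder that disentangles a
    rotation-invariant latent code from an equivariant orientation frame,
    a CPU training loop, evaluation metrics (cosine loss, clustering
    purity, V-measure, latent-space classification), and seeded synthetic
    data generators so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    class,
    nnet
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
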