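Package: diffpes
Title: Denoising Diffusion Models as Relaxers and Boltzmann Samplers on Toy
    Potential Energy Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale study of how denoising diffusion models over atomic
    point clouds behave on a potential energy surface (PES). Provides a
    generator of toy molecular systems with analytic, differentiable energy
    functions and tracked ground states; a variance-preserving diffusion
    process over center-of-mass-free coordinates and one-hot species channels
    with a small E(n)-equivariant learned denoiser and closed-form oracle
    denoisers; inference-trajectory metrics that locate the exploration versus
    relaxation regimes; cosine-alignment statistics of model steps against
    forces and the direct ground-state direction; Metropolis-Hastings and
    fixed-step diffusion chains with a step-to-temperature calibration; and a
    relaxation-initialization speedup benchmark with BFGS step accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
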