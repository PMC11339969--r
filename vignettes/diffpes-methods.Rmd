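---
title: "Diffusion models on toy potential energy surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion models on toy potential energy surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(diffpes)
```

# What this package studies

A denoising diffusion model trained only on *ground-state* molecular
geometries implicitly learns about the shape of the potential energy surface
(PES) around its minima. `diffpes` re-creates that line of investigation at
desk scale, in R, with every quantum-chemistry ingredient replaced by an
analytic stand-in that admits closed forms:

* toy molecules (5–20 atoms, a four-letter species alphabet) with analytic,
  exactly differentiable energy functions and tracked ground states;
* a variance-preserving diffusion process over CoM-free coordinates and
  one-hot species channels, with a small E(n)-equivariant learned denoiser
  and Bayes-optimal *oracle* denoisers for analytic testing;
* the downstream analyses: inference-regime metrics, partial-diffusion
  structure relaxation, cosine alignment of model steps against forces and
  the straight-to-minimum direction, Metropolis–Hastings versus fixed-step
  diffusion chains with a step-to-temperature calibration, and a
  relaxation-initialization speedup benchmark with BFGS step accounting.

Everything is seeded and reproducible; nothing requires a GPU, external data
or a quantum-chemistry backend.

# The synthetic systems

## Topologies and the toy force field

`sample_topology()` draws a random spanning tree over the atoms, respecting
per-species maximum valences (A/B/C/D with max degrees 1/2/3/4, loosely
mimicking H/O/N/C). Angle triples are derived from the bond list.

`build_pes()` attaches one of two analytic surfaces:

* **bonded** — harmonic bond stretches, harmonic angle bends and a soft-core
  repulsion `A (1 - r/r_rep)^2` between topologically distant pairs.
  Equilibrium bond lengths are sums of species radii and the stiffnesses are
  shared across all systems, so the dataset constitutes one consistent toy
  "chemistry" that a denoiser can learn. The surface is exactly rigid-body
  invariant and mildly anharmonic. Defaults: `k_bond = 100` and
  `k_angle = 30` (toy kcal/mol per Å² and rad²). These moderate stiffnesses
  are a deliberate choice: they give minima whose geometric width at
  thermally relevant energies is one-to-a-few tenths of an ångström, the
  same scale as the crude-start offsets and the diffusion noise levels the
  analyses probe, so every stage of the pipeline operates on resolvable
  geometry changes.
* **quadratic** — an exact quadratic form `E = (x - x*)' H (x - x*) / 2`
  over the flattened coordinates with a PSD Hessian (supplied or drawn with
  a configurable condition-number range). It is *not* rigid-body invariant —
  it acts on absolute CoM-free displacements, which is exactly what makes
  every downstream statistic (equipartition, force/ground-state alignment,
  chain stationary distributions) available in closed form.

Every tracked ground state is re-verified at construction: the stored
geometry must satisfy the `fmax` criterion (maximum per-atom force norm,
default 0.05 toy kcal/mol/Å — the analogue of the 0.03 eV/Å criterion used
with quantum-chemistry relaxations, restated in toy units).

## Crude starts

`crude_start()` emulates a structure relaxed with a cheap classical force
field. Rather than adding isotropic jitter, it clones the true PES with
perturbed parameters (equilibrium lengths ×N(1, 0.08), equilibrium angles
×N(1, 0.06), force constants ×N(1, 0.1)) and relaxes the clone starting from
the true ground state. The result is a *systematically offset minimum* — the
defining property of a cheap-force-field geometry — sitting a few toy
kcal/mol above the true ground state (typically 3–10, mean ≈ 6 over the
default generator), with per-atom displacements around 0.1 Å. The
perturbation magnitudes are calibration knobs of the generator, not claims
about any specific force field; the chosen defaults put the offsets in the
"several kcal/mol" range that motivates the relaxation studies while keeping
the geometric signal at a scale a desk-sized denoiser can resolve.

# The diffusion core

## Schedule, forward process, decoding

`make_schedule()` builds the variance-preserving schedule
`alpha_n^2 + sigma_n^2 = 1` with the polynomial form
`alpha_n^2 = (1 - 2s)(1 - (n/N)^2)^2 + s` and a small stability floor
`s = 1e-7` (`alpha_0` is pinned to exactly 1 so that decoding a clean latent
is the identity). The default `N = 1000` matches the step axis used
throughout the regime analysis. Near `n = 0` the noise level grows linearly
(`sigma_n ≈ 1.4 n/N`), so the last ~50 steps cover displacements up to
~0.07 Å — the relaxation regime.

`encode_system()` removes the centre of mass and builds scaled one-hot
channels (`h_scale = 0.25`, balancing coordinate and channel loss terms
1:1). `forward_noise()` draws CoM-projected coordinate noise; the drawn
noise is kept on the state so the training loss can score predictions
against it. `decode_state()` rescales coordinates by `1/alpha_n` so that
intermediate structures along the diffusion path are well-defined at every
step; below `alpha_floor = 0.05` it reports latent-scale coordinates with a
flag instead of dividing by a vanishing signal coefficient (the alternative
— always-raw latents — can be had by setting the floor to infinity; the
choice only affects how early-inference frames are displayed, not any
statistic computed in the relaxation regime). Species decode by channel
argmax, ties broken deterministically toward the lowest channel index.

## Reverse process

`reverse_step()` is standard ancestral sampling with the posterior ("small")
conditional variance, no noise on the final `1 → 0` step, and CoM
re-projection after every update. Stub/control denoisers are deterministic:
no posterior noise is injected for them, which makes the identity stub an
*exact* no-op on decoded coordinates — the benchmark's control closure.

## Oracle denoisers

For data distributed as `x ~ N(m, tau^2 I)` in the CoM-free subspace, the
Bayes-optimal noise prediction is available in closed form
(`oracle_denoiser()`). With `tau^2 = 0` this is the point-mass oracle
`(z - alpha m)/sigma`. These oracles validate the forward/reverse algebra
with zero training: full reverse sampling must reproduce the data
distribution's mean and variance, and the point-mass case must land on the
target structure. The Gaussian-case closed form is cross-checked in the test
suite against a self-normalised importance-sampling estimate of
`E[eps | z]`.

## The learned denoiser

`egnn_denoiser()` is a small equivariant message-passing network over the
complete atom graph. Per layer and per pair, an MLP consumes only invariants
— a radial-basis featurization of the current pair distance, the channel
vectors of both endpoints, and a step embedding — and emits a scalar gate
and a message vector. Coordinates are updated by gated sums of relative
position vectors (exactly rotation/permutation-equivariant); hidden channel
state is updated from aggregated messages (invariant). Three layers are the
default: with coordinate updates *between* layers, later layers see geometry
moved by earlier ones, which is strictly more expressive than a single
central pair field (a one-layer gate can only express fields along
individual pair axes gated by that pair's own distance — it cannot represent
a generic displacement field).

Two numerical choices matter and are worth stating explicitly:

* **Output parameterization.** The network predicts the clean structure and
  clean channels; noise predictions are derived analytically,
  `eps_x = R(z)/sigma_n` and `eps_h = (zh - alpha_n H(z))/sigma_n`. The raw
  noise target has stiffness `1/sigma_n` at low noise — unreachable for a
  small network — whereas `R(z) = z - alpha x_0` is one smooth,
  step-independent displacement field.
* **Training objective.** `train_denoiser()` minimises the noise-space MSE
  with a truncated-SNR weight `w(n) = (sigma_n / max(sigma_n, 0.1))^2`:
  plain MSE above the reference noise level, `sigma^2`-scaled below it. This
  bounds the optimisation stiffness introduced by the `1/sigma_n` output
  gain while keeping full pressure on the small displacement targets of the
  relaxation-regime steps. Training steps are drawn from a uniform /
  log-uniform mixture over `{1..N}` (`low_step_frac = 0.5` by default):
  purely uniform draws visit the low-noise decades so rarely that a small
  model never learns them. The plain unweighted, uniformly-drawn loss of the
  underlying generative objective remains available as `diffusion_loss()`
  and is what the loss-contract tests exercise.

Training is minibatch Adam with hand-written analytic backpropagation
(verified against finite differences in the suite; the whole minibatch is
evaluated as one block-indexed forward/backward pass), a smooth
learning-rate decay, and best-validation checkpoint selection; the
validation draws are fixed once per run, so per-epoch validation losses are
paired and checkpoint selection does not chase draw noise.

For the relaxation studies the package trains a small *deep ensemble*
(`train_denoiser_ensemble()`): three independently initialised members, each
given a main denoising phase (uniform/log-uniform step mixture) followed by
a short low-noise fine-tuning phase (log-uniform draws only, reduced
learning rate) that specialises the shared trunk to the relaxation-regime
steps; predictions are averaged. Averaging preserves equivariance and
cancels the seed-specific component of each member's error field — on the
relaxation benchmark a three-member ensemble clearly outperforms any single
member trained for the combined budget. Typical desk-scale runs — 40
systems of 5–10 atoms, 2500 main + 1200 fine-tuning epochs per member —
take about four minutes per member on one CPU.

# The analyses

## Regime metrics

`metric_series()` computes, per inference step: the step size (L2 norm of
the decoded displacement), the mean absolute bond-length error against the
final frame, the fractions of atoms/molecules whose species are finalized,
bond-order (degree) finalization, and valence validity. *Finalized* uses the
stability definition — equal to the final value at this step and at every
later step — which the data never contradicts and which guarantees monotone
series; the point-in-time variant is available via `stability = FALSE`.
`regime_split()` reports the largest step at which all species are finalized:
the boundary between the exploration regime (species still changing) and the
relaxation regime (only coordinates moving). Bond perception uses the
radius-sum rule `d <= r_i + r_j + tol` with `tol = 0.45` Å, calibrated so
that perceived bonds reproduce the generating topology on ≥95% of
ground-state systems.

## Alignment statistics

A note on training-stage contrasts: the reference investigation compares an
early-training checkpoint (whose steps align better with the forces) against
a converged one (whose steps align better with the straight-to-minimum
direction). The package supports this miniature directly —
`train_denoiser(..., snapshot_epochs = ...)` captures early checkpoints, and
`alignment_analysis()` accepts any denoiser — but no assertion is built on
it: at desk scale the contrast is weak and seed-dependent, so the test suite
instead validates the *inferential machinery* with the two constructed
control denoisers below, which make the expected orderings exact.

For a relaxation trajectory, `delta_k` is the sum of the next `k` decoded
steps; `f` the analytic forces; `gs` the straight direction to the ground
state after CoM alignment (no rotational superposition by default — the
trajectories never rotate far from their start; a Kabsch option exists).
Cosines are averaged per atom by default (atoms with near-zero vectors
excluded at 1e-12), with a flattened-3n mode as an option. On a quadratic
PES `cos(f, gs) = d'Hd/(|Hd||d|)` exactly — 1 for isotropic curvature,
strictly less for anisotropic — and the pipeline reproduces this end to end
to 1e-9. Two constructed control denoisers validate the inferential logic:
a force-follower (steps along `f`) must score `cos(delta, f) ≈ 1`, and a
straight-liner (steps along `gs`) must score `cos(delta, gs) ≈ 1` while its
`cos(delta, f)` collapses onto `cos(f, gs)` — the diagnostic that alignment
with forces can be explained away by force/ground-state alignment.

## Boltzmann chains and the step-temperature calibration

`mh_chain()` is Metropolis–Hastings with an isotropic Gaussian proposal,
initialised at the ground state, with the proposal width tuned toward
30–50% acceptance during burn-in and frozen afterwards (`k_B = 1` in toy
units). On quadratic surfaces its mean energy must equal the equipartition
value `d k_B T / 2` (`equipartition_reference()`), and its energy histogram
the Gamma(d/2, k_B T) law.

`diffusion_chain()` repeatedly applies one reverse step at fixed `n`:
clean-encode at `alpha_n`, one step `n → n-1`, decode at `alpha_{n-1}`. The
re-entry convention is a design choice (the alternative — staying at latent
scale and re-noising to `n` each iteration — is implemented behind
`latent_mode = TRUE` for sensitivity analysis; it behaves similarly on the
toy suite). With the Gaussian-data oracle on a quadratic PES the chain is an
exact linear-Gaussian autoregression whose stationary energy is derived in
closed form and checked within Monte-Carlo error. The repeated isotropic
Gaussian perturbation control (`gaussian_perturbation_chain()`) diverges,
while diffusion chains never do on the toy suite — the qualitative contrast
at the heart of the Boltzmann-sampling claim.

Because the per-step noise scale grows like `n/N` near the low-noise end,
the stationary spread of a fixed-`n` chain grows like `n` and its mean
energy like `n^2`, while the MH chain's mean energy is linear in `T`
(equipartition). `calibrate_n_to_t()` fits both laws (jointly across
systems, with per-system intercepts, when several are supplied) and reports
the single scaling factor `mu = d/b` mapping `T_eff(n) = mu n^2`.
`equalize_offsets()` first removes one constant per system so the two
families agree at their low-noise anchors, warning when the constant exceeds
2 toy kcal/mol. The anchor temperature sits essentially at zero (0.002 toy
units): anchoring at a temperature whose own mean energy is non-negligible
would push a spurious constant into every matched-pair comparison. The
default grids mirror the reference study's shape: 18 temperatures and 14
steps spanning 1–40.

## Partial-diffusion relaxation and the speedup benchmark

`partial_relax()` clean-encodes a structure at `alpha_n` (no forward noise —
the input is an already-built geometry, not a noised one; a `noised = TRUE`
variant exists for sensitivity analysis) and runs reverse steps `n → 0`.
Species channels evolve freely by default with a post-hoc flag if they
change; they can be frozen.

`benchmark_speedup()` runs the two-arm experiment per system: BFGS-relax the
crude start directly, versus partial-diffusion refinement followed by an
identical BFGS relaxation. It records optimizer iteration counts (the unit
of cost; a start already below `fmax` counts zero steps), both starting
energies relative to the ground state, and the energy delta between the two
final relaxed structures (nonzero = the arms fell into different basins).
The benchmark's optimizer uses a conservative per-step trust radius
(`max_disp = 0.01` angstrom in both arms): relaxation workflows built on
expensive force evaluations take deliberately cautious steps, which puts the
iteration count in the path-length-limited regime where a closer start
genuinely saves work. With an aggressive trust radius on these small
analytic systems, quasi-Newton iteration counts are dominated by curvature
learning and are nearly insensitive to the starting point — the benchmark
would then measure nothing. The relaxation-quality statistics (energy
reductions) are independent of this choice.
`summarize_speedup()` reports median/quartile percent step reductions, the
fraction of records with `|delta_E|` above the 0.2 toy kcal/mol exclusion
threshold, and the same statistics on the surviving subset. The identity
stub denoiser closes the accounting: it must give exactly zero speedup and
zero delta.

# Study sizes and what the toy results do and do not show

The default study conditions used by the acceptance script and the test
suite are: datasets of 40 toy systems with 5–10 atoms; `N = 1000` step
schedules for the chain and sampling studies and `N = 2000` for the
trained-model relaxation study (finer late-stage steps inject less
per-step noise at the same entry step, which lowers the endpoint noise
floor); a three-member ensemble trained for 2500 + 1200 epochs per member;
MH chains of 4500–12000 steps and diffusion chains of 2500 steps;
relaxation entry steps `n ∈ {20, 50}`; the reported relaxation reduction is
the `n = 20` arm.

The generator emulates the *role* of a quantum-chemistry corpus — smooth
surfaces with tracked minima, exact forces, systematically offset crude
starts — but not its content: there are no electronic effects, no multiple
conformer basins per system (tree topologies with a single tracked minimum),
no real force-field physics, and the energy scale is a toy calibration.
Passing tests therefore demonstrate that the *methods* behave as claimed on
surfaces where every answer is known analytically — that the samplers,
statistics, calibrations and accounting are correct, and that a small
denoiser trained only on minima acquires usable local-PES information — not
that any particular speedup would be obtained on real molecules with real
quantum chemistry.

# Known limitations

* The learned denoiser is deliberately small; its predictions along soft
  (torsional, rotational) directions are weak, and its relaxation quality
  degrades for entry steps whose noise level much exceeds the crude-start
  displacement scale.
* The quadratic PES style is not rigid-body invariant (by construction); all
  rigid-body-sensitive analyses use the bonded style.
* Bond perception is a geometric rule with a global tolerance; it is
  calibrated for the package's alphabet, not for arbitrary radii.
* `k_B = 1` toy units throughout the chain analyses; temperatures are not
  kelvin.
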