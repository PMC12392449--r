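---
title: "Methods: orientation-marginalized reconstruction from sparse scattering images"
author: "rasta developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orientation-marginalized reconstruction from sparse scattering images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In single-particle X-ray free-electron-laser (XFEL) imaging, each ultrashort
pulse scatters off one copy of a molecule in a random, unknown orientation and
deposits a handful of photons (tens, for a small protein) on the detector.
Classical orientation-determination pipelines fail in this regime: single
images carry far too little information to estimate their orientation. `rasta`
instead maximizes a Bayesian posterior in which the orientation of every image
is marginalized out, and the electron density is optimized directly in real
space, so no phase retrieval step is needed.

## Model

**Density.** The electron density is a mixture of `m` isotropic Gaussian
beads with common height `h` (electrons; each bead integrates to exactly `h`)
and common precision `w` (1/Å):

ρ(r) = Σᵢ h (w/√(2π))³ exp(−½ w² ‖r − yᵢ‖²).

One bead per heavy atom suffices at ≈2 Å target resolution; hydrogens are
folded into `h` (default 7 electrons per heavy atom). The default `w` gives a
bead FWHM of 2 Å. The structure factor is closed-form,
ρ̂(k) = h exp(−‖k‖²/(2w²)) Σᵢ exp(+i k·yᵢ) (the `+i` sign convention is fixed
and documented; intensities are unaffected), and the speckle intensity is
I(k) = |ρ̂(k)|², invariant under global translation and point inversion —
which is why evaluation must align reconstructions over rigid motions *and*
hands.

**Forward model / likelihood.** A photon-sparse image is a list of scattering
vectors on the Ewald sphere (angular convention, ‖k_in‖ = 2π/λ, resolution
d = 2π/‖k‖). Conditional on an orientation R, photon positions follow a
Poisson point process on the recorded Ewald cap with intensity proportional to
I(Rk), so the single-image likelihood is the cap-integral (expected-count)
factor times a product of per-photon intensities, and the full likelihood
marginalizes R over SO(3) with uniform measure.

**Grid approximation.** Two discretizations make this tractable. The
x/y-axis orientation degrees of freedom are handled by a spherical quadrature
over beam-axis directions: rotations R_l with positive weights w_l summing
to 1. The z (beam-axis) rotation is exact: the intensity is tabulated on a
polar grid of the reference cap — uniform in the 3D norm q and in azimuth —
so that rotating an image about the beam axis is a cyclic shift of angular
cell indices, and the likelihood sums over all n_s shifts at negligible cost.
On a sphere through the origin the area element in (q, φ) coordinates is
exactly q dq dφ, so cell areas and the cap total (π·kmax²) are closed-form;
the expected-count integrals λ_l = Σ a_{r,s} I_{l,r,s} are midpoint-rule
estimates whose density of cells is naturally highest where intensity is
highest.

**Gradient.** The log-likelihood gradient with respect to bead positions is
computed by backpropagation: per image, a softmax over the (orientation,
shift) terms yields posterior responsibilities; photons contribute 1/I at
their cells and the expected-count term contributes −i0_eff·a_{r,s}; the
chain rule through the closed-form Gaussian-mixture intensity then gives
per-bead 3-vectors. Everything is evaluated in the log domain with
log-sum-exp; terms more than 36 nats below the per-image maximum are dropped,
which is exact to double rounding. Zero-intensity cells make the raw
likelihood −∞ honestly; the gradient path skips exactly the
zero-responsibility terms, so no flooring constant is needed.

## Resolution annealing

Gradient ascent on the raw log-posterior is hopeless — the landscape has
exponentially many local optima. The annealing idea: a Gaussian blur of the
density (std σ) multiplies the intensity by exp(−σ²k²), and by the thinning
property of Poisson processes, *images of the blurred density are obtained
from real images by keeping each photon with probability exp(−σ²‖k‖²)*. So
the optimizer can target the smoothed posterior at any σ without simulating
anything: thin the batch, widen the beads (1/w′² = 1/w² + σ²), and take the
gradient. σ(t) starts high (coarse, convex-ish problem) and decays to zero;
because thinning is re-randomized every step, every photon is eventually used
and no information is lost. Updates use momentum:
v ← β v + ∇ log posterior; y ← y + η v.

## Priors

Bead positions get two soft constraints (the exact functional forms are this
package's own choice): a compactly supported
repulsion f₁(d) = c₁ max(0, 1 − d/d_rep)², a smooth neighbor indicator
f₂(d) = 1/(1 + exp((d − r_nb)/s_nb)) whose sum "counts" neighbors, and a
one-sided connectivity penalty f₃(x) = c₃ max(0, n_min − x)². All three are
C¹, so the analytic gradient used by the optimizer is continuous; self-pairs
are excluded. Rows of the prior gradient sum to zero exactly (translation
invariance).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `height` | 7 e⁻ | electrons per bead (heavy atom + bonded H) |
| `width` | 1.177 Å⁻¹ | bead precision (FWHM 2 Å) |
| `wavelength` | 2.5 Å | beam wavelength |
| `kmax` | 3 Å⁻¹ | recording cutoff (d ≈ 2.1 Å) |
| `i0_eff` | — | intensity scale; use `calibrate_i0_eff()` for a target photon rate |
| `n_nodes` | 98 | orientation quadrature size (2t², exact to degree 2t−1) |
| `n_r`, `n_s` | 64, 64 | polar grid (radial, angular) |
| `sigma0` | 3 Å | initial smoothing scale |
| `t_anneal` | 0.8 T | step at which σ reaches 0 |
| `sigma_power` | 1 | σ-profile exponent (1 = linear decay) |
| `eta0`, `eta1` | 1e-4, 1e-5 | geometric step-size profile (Å²; note the gradient is scaled to the full image set, so η scales with 1/N) |
| `beta` | 0.9 | momentum |
| `batch_size` | 1000 | images per stochastic step |
| `clip_norm` | Inf | optional gradient-norm cap |
| `average_last` | 0 | Polyak averaging window for the returned model |

The orientation quadrature is a Gauss–Legendre (polar) × uniform (azimuth)
product rule; any positive-weight spherical rule (Lebedev grids included)
works equally well here, since the mapping node → rotation uses the minimal
rotation carrying ẑ to the node and the residual beam-axis angle is summed
exactly. The product rule fixes the supported sizes to 1 and 2t².

## Synthetic data: what it emulates, what it does not

`simulate_imageset()` draws orientations uniformly from SO(3) (uniform
quaternions), photon counts Poisson with rate i0_eff·λ(R), and photon
positions i.i.d. ∝ I(Rk) on the cap, tabulated on a fine polar grid and
sampled uniformly in (q², φ) within cells (uniform with respect to the exact
area element). Photons are stored as transverse (k_x, k_y) pairs, the
detector-realistic two degrees of freedom, with k_z recovered from the Ewald
condition. This is the background-free coherent forward model: no incoherent
or background photons, no shot-to-shot intensity jitter, no polarization or
detector gaps, no preferred orientations. A green test therefore establishes
correctness of the method under its own forward model — not robustness to
experimental nuisances. The helper `physical_i0_eff()` converts a physical
beam description via the Thomson cross-section (fluence · r_e²/K²); treat it
as an order-of-magnitude starting point — `calibrate_i0_eff()` against a
target photon rate is the recommended path and is what the tests use
(30 photons/image for the 8-bead toy, the middle of the 15–79 range typical
of small proteins under realistic pulse parameters).

## Numerical choices

- **Log-sum-exp everywhere**; per-image terms below max − 36 nats are skipped
  (exact at double precision). Verified on 1000-photon images with intensity
  spanning 30+ orders of magnitude.
- **Binning**: right-open bins, top bin closed; photons are binned by their
  3D scattering-vector norm (recovered via the Ewald condition) and azimuth.
- **λ estimates** are midpoint-rule sums; with n_r = 64 the single-bead
  closed form is reproduced to ~5·10⁻⁴ relative.
- **Assignment problems** (EMD, alignment) are solved exactly by a
  shortest-augmenting-path solver (O(n³)), verified against exhaustive
  enumeration; EMD is the mean matched Euclidean distance. Unequal sizes are
  replicated to lcm(n_a, n_b) ≤ 4096, which makes the uniform-marginal
  transport problem an assignment problem exactly.
- **Alignment** iterates exact matching and Kabsch superposition from
  multiple starts (identity, principal-axis combinations, random rotations)
  over both hands; the total rotation is refit against the unrotated source
  at every iteration. Deterministic given its seed.
- **FSC** rasterizes the analytic densities (default voxel 0.5 Å, padding
  10 Å with a truncation guard), correlates Fourier shells one frequency-step
  wide, and interpolates the 0.5 crossing linearly; resolution is d = 2π/k*.
  Conventions vary across the field, so reports state d = 2π/k explicitly.
- **FSC jitter law**: with both models independently jittered by τ the decay
  exp(−k²τ²) is exact only in the speckle regime (shell average of |F|² equal
  to the incoherent sum m h² env²). The exact expectation is
  c²S/(c²S + M(1−c²)) with c = exp(−k²τ²/2); clustered models show
  structure-factor dips where the naive law overshoots. The decay-law tests
  use i.i.d. bead positions, where the simple law holds to shell noise.

## Optimizer engineering beyond the plain update

Two optional devices, both default-off and recorded in provenance, proved
useful on desk-scale problems: a gradient-norm cap (`clip_norm`) guards the
momentum buffer against occasional photon-batch spikes, and Polyak–Ruppert
averaging (`average_last`) removes the stationary jitter of
constant-step-size SGD from the returned model. The recommended desk-scale
recipe (used by the acceptance suite) is a coarse-grid anneal followed by a
short full-resolution polish on a finer angular/orientation grid with
averaging; `run_rasta()` composes naturally since it accepts any initial
model. Stopping is a fixed step count chosen large enough for consistent
results — no adaptive stopping criterion is implemented.

## Known limitations

- The likelihood value is comparable only within one beam/grid configuration
  (constant per-photon factors are dropped).
- Photon storage as transverse components is unambiguous only up to 90°
  scattering (kmax ≤ √2·k_in); the default geometry is well inside this.
- The SO(3) quadrature is a product rule; very anisotropic molecules at high
  resolution may need larger `n_nodes` than the default.
- Reconstruction quality on tiny toys is sensitive to schedule parameters;
  the defaults are tuned for the documented test world, not universal.
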