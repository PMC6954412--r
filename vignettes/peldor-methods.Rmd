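---
title: "Models and methods behind peldor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind peldor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the physical model, the synthetic-data model, the
numerical choices and the known limitations of the package, in the spirit
of a methods section. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The experiment and the forward model

PELDOR/DEER observes the echo of "probe" spins while a "pump" pulse at a
second frequency inverts their dipolar-coupled partners. For an isolated
pair at distance $r$ whose inter-spin vector makes angle $\theta$ with
the static field $B_0$, the secular dipolar coupling is

$$\nu_{dd}(r, \theta) = \frac{D}{r^3}\,(1 - 3\cos^2\theta), \qquad
D = \frac{\mu_0 \mu_B^2 g_A g_B}{4 \pi h} \approx 52\ \mathrm{MHz\,nm^3},$$

computed from CODATA constants and the label's isotropic g value
(`dipolar_constant()`). The weak-coupling (secular) approximation is
excellent for $r \gtrsim 1.5$ nm, where $\nu_{dd}$ is far below the
spectral widths; pseudo-secular terms and exchange coupling ($J = 0$) are
neglected, the standard treatment for long-range nitroxide pairs.

Each nitroxide's resonance offset is first order in the anisotropic
interactions,

$$\nu(\mathbf{n}, m_I) = \frac{\mu_B B_0}{h}\,\bigl(g(\mathbf{n}) -
g_\mathrm{iso}\bigr) + m_I A(\mathbf{n}), \qquad
g(\mathbf{n}) = \Bigl(\sum_i g_{ii}^2 n_i^2\Bigr)^{1/2},$$

with $\mathbf{n}$ the field direction in the label frame and the $^{14}$N
quantum number $m_I \in \{-1, 0, +1\}$ equally populated (high-temperature
limit for nuclear spins at 40–50 K). The g and A tensors are taken
collinear (x along the N–O bond, z normal to the ring plane), with the
CW-validated values g = (2.0088, 2.0065, 2.0027) and A = (15, 15, 98) MHz
as shipped defaults. Nuclear Zeeman, quadrupole and tensor-frame tilts
are neglected; no g-/A-strain line broadening is modelled.

Rectangular pulses excite with the exact two-level (Rabi) profile
$p(\Delta\omega) = \frac{\omega_1^2}{\omega_1^2+\Delta\omega^2}
\sin^2\bigl(\tfrac{t_p}{2}\sqrt{\omega_1^2+\Delta\omega^2}\bigr)$, with
$\omega_1 = $ flip angle / duration. The observer (refocused echo,
$\pi/2$–$\pi$–$\pi$) is weighted by the product
$p_{\pi/2} \cdot p_\pi^2$ evaluated at the probe offset. This
three-profile product is a documented, swappable choice; published
implementations differ in this detail and the acceptance tolerances
absorb the difference.

A time trace is accumulated per ensemble member and per powder
orientation as
$V(t) \mathrel{+}= w_A\,[1 - p_B (1 - \cos 2\pi \nu_{dd} t)]$,
symmetrized over the two labels and averaged over both nuclei's $m_I$
independently (the average factorizes because the expression is linear in
each excitation probability), then normalized to $V(0) = 1$. Each
member's own inter-spin vector and frames enter jointly, which is what
carries orientation selection. The modulation depth is reported as one
minus the minimum over the last 20 % of the window — a plateau
estimator, adequate for the well-developed modulations simulated here.

Pump/probe positioning mirrors experimental practice: at X band the pump
sits at the maximum of the powder absorption spectrum (computed on the
same deterministic grid) and the probe $\nu_n$ MHz above it
(40/55/70/85 MHz for the B-form defaults, 40/50/60/75/90 MHz for the
A-form); at G band the field positions correspond to $B \parallel
g_{xx}, g_{yy}, g_{zz}$ with a fixed 60 MHz probe–pump offset. X-band
modulation depths are never rescaled in comparisons; G-band depths are
fitted per trace (`fit_modulation_depth()`), mirroring how the reference
experiments were processed.

Powder averaging uses a deterministic Fibonacci sphere grid
(default 3000 orientations; `sphere_grid(random = TRUE)` gives a seeded
Monte Carlo mode for convergence checks). Doubling the grid changes
default traces by well under 0.5 % RMS (tested).

## Label frames and conformers

The label frame is built from atom coordinates as: x from the nitrogen
to the oxygen after the oxygen has been orthogonally projected into the
least-squares plane of the isoindoline ring (generic force fields let
the N–O oxygen drift out of plane; the projection restores the physical
geometry for spin calculations); z is the ring-plane normal with its
sign fixed by the ring-atom ordering; the origin is the N–O midpoint —
the standard point approximation for nitroxide spin density. Where the
point spin sits (N, O, or midpoint) is rarely stated in experimental
work; the midpoint shifts distances by at most the 0.065 nm
N–O half-length, and calculated traces are invariant to the z-axis sign
because all spin interactions are even under a 180° frame rotation
(asserted by test).

The d1 dihedral (purine scaffold — amine bridge — isoindoline) is
classified syn for $|d1| < 90°$ and anti otherwise: the rotational
free-energy landscape has minima near 0° and 180°, with substates around
+30°/−35° (syn) and −140°/150° (anti), so the boundary at 90° sits on a
barrier and carries negligible population; the boundary value itself is
assigned to anti by convention. Conformer flips rotate a label's frame
180° about its d1 axis. For synthetic frames the d1 axis is defined as
the in-plane x axis through the spin center (in the real label the N–O
bond lies on the isoindoline C2 axis, which is collinear with the amine
bridge), so flips are exact symmetries of the trace calculation — in
agreement with the observation that d1 rotations do not alter relative
spin orientations.

## The synthetic ensemble generator

The generator emulates the *statistical structure* that the trace
calculation consumes — distances, frame orientations, conformer states —
not helix mechanics:

- **Base geometry.** Base-pair frames on an ideal helix (B: 3.38 Å rise,
  36.0° twist; A: 2.81 Å, 32.7°), one label per abasic site, placed by a
  frozen offset (radial/tangential/axial displacement plus
  tilt/twist/spin Euler angles) relative to its base-pair frame; the
  second label is related by the duplex pseudo-dyad. The shipped
  placements were tuned once and frozen: B-form, sites 9 bp apart →
  r = 3.72 nm with both z-axes at 40.0° to the inter-spin vector;
  A-form → r = 3.75 nm at 40.0°. These are the geometry targets reported
  for this label pair on DNA and RNA duplexes (experimental distribution
  peaks at 37.2 Å and 37.5 Å; z–u angles clustering near 40°).
- **Distance jitter** is Gaussian along the inter-spin vector
  (sd 0.287 nm ≙ FWHM 0.675 nm, the observed broadening), truncated at
  r > 1 nm. Jitter is applied to positions only — re-deriving full helix
  mechanics would add parameters the PELDOR calculation cannot see.
- **Orientational wobble** applies independent small random rotations to
  each frame (isotropic axis, normal angle). The default sd of 15° is
  the one free parameter not fixed by reported values; it represents the
  orientational disorder accumulated between sites 9–10 bp apart
  (per-step twist/roll fluctuations of ~5° compounding over ~9 steps,
  plus label libration in the pocket). It was chosen once on that
  physical argument and frozen.
- **Conformer states** are drawn from configurable weights (equal by
  default — the reference averaging choice; real per-state populations
  are system dependent, so the generator exposes weights rather than
  asserting them) and realized by d1 flips.

What the generator does *not* emulate: sequence-dependent helix
structure, correlated (collective) bending modes, anharmonic pocket
dynamics, and any coupling between distance and orientation
fluctuations. Consequently, passing tests demonstrate the correctness of
the simulation/inversion chain under a realistic disorder model — not
force-field-level fidelity to any particular duplex.

One consequence of the generator's single rigid base geometry deserves
emphasis: its members share one relative frame arrangement (up to
15° wobble), so residual orientation selection in a four-offset X-band
sum is *stronger* than in a heterogeneous molecular-dynamics ensemble.
Inverting such a sum seeds side lobes around the true peak (the
experimental analogue is the low-r shoulder that summed-offset
distributions grow, which should not be interpreted). The worked
examples therefore invert the powder-representative (ideal-excitation)
form factor of the ensemble — the faithful stand-in for the
background-corrected experimental summed traces, which are demonstrably
powder-like — while the orientation-selective sum remains available
through `run_pipeline()`.

## Inversion

- **Background.** A homogeneous 3D distribution of remote spins gives
  $B(t) = e^{-kt}$; k comes from a log-linear fit over the tail window
  (default start: half the trace). The fit presumes the dipolar
  modulation has decayed inside the window; for r ≈ 3.7 nm and a 1.8 µs
  trace that premise fails physically (the form factor is still
  relaxing), a known limitation of short-window DEER processing rather
  than of the implementation — the tests validate the fit on constructs
  that satisfy the premise.
- **Kernel.** $K(t, r) = \int_0^1 \cos[(2\pi D/r^3)(1-3x^2)t]\,dx$ by
  500-node Gauss–Legendre quadrature (exact to machine precision at the
  oscillation counts of the default grids; spot-checked against adaptive
  quadrature at 1e−6). Default r grid 1.5–8.0 nm in 0.02 nm steps.
- **Tikhonov.** $\min \|C\theta - F\|^2 + \alpha^2 \|L P\|^2$ with
  $P \ge 0$, L the discrete second derivative, and C = [K, 1]: the
  modulation depth and unmodulated level enter as two extra linear
  unknowns, so raw form factors are inverted without pre-scaling. The
  final solution uses non-negative least squares on the stacked system.
- **Choosing α.** The default is generalized cross-validation over a
  log grid (1e−3–1e3, 61 points). An L-curve corner criterion is also
  provided (`alpha = "lcurve"`), but with the unpenalized depth/offset
  column the over-smoothed branch of the L-curve degenerates (the
  seminorm stalls once only the penalty null space remains active) and
  the maximum-curvature corner is unreliable on exactly the noiseless
  and low-noise inputs this package is validated on; GCV selected
  correctly across all validation cases (noiseless and noisy Gaussians,
  delta distributions, powder form factors) and is therefore the
  default. A fixed numeric α overrides selection. A tiny identity floor
  (1e−10 of the normal-matrix diagonal scale, far below any selected
  α²) stabilizes the unconstrained scans.
- **Statistics.** The mode is refined by three-point parabolic
  interpolation and reported in Ångström; the FWHM of the main peak by
  linear interpolation at half maximum. Exactly tied separated peaks
  report the lower-r mode and set an ambiguity flag. A fitted modulation
  depth below 2 % flags "no modulation detected" instead of returning a
  spurious peak.

## Problem sizes and determinism

Defaults were chosen so the full test suite and the acceptance script
each run in a few minutes on one core: powder grids of 800–4000
orientations (3000 is the package default), ensembles of 25–2000 members
(the worked examples use 2000; sampling statistics use 20000 cheap
geometry-only draws), 91-point time grids to 1.8 µs, and a 326-point
distance grid. Every stochastic step takes an explicit seed; the
pipeline writes the resolved configuration, its MD5 and the seed into
every artifact header, and identical seeds reproduce outputs
byte-for-byte.

## Known limitations

- First-order spin Hamiltonian only; no nuclear Zeeman/quadrupole, no
  strain broadening, no relaxation, no ESEEM, no multi-spin (>2)
  effects, no "2+1" artifacts.
- The observer-weight expression (product of three pulse profiles) is a
  convention; alternatives shift modulation depths slightly.
- The generator's orientation model is a single rigid geometry plus
  isotropic wobble; orientation-selective observables of heterogeneous
  real ensembles are reproduced qualitatively, not quantitatively (see
  the discussion of the X-band contrast in the test suite).
- The background model is strictly homogeneous-3D exponential; reduced
  dimensionality or excluded-volume backgrounds are out of scope.
- Tikhonov uncertainty is not quantified (no bootstrap/validation
  bands); the ambiguity flag is the only shape diagnostic.
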