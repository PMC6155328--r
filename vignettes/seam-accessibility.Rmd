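---
title: "Zero-point-energy accessibility of conical-intersection seams: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-point-energy accessibility of conical-intersection seams: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciaccess)
```

## The problem

Small peptides carrying a phenylalanine residue absorb near-UV light into the
phenyl $\pi\pi^*$ state. Conformers that look nearly identical on paper can
have excited-state lifetimes differing by more than an order of magnitude, and
the difference tracks a conformational detail: how easily the terminal amide
group distorts out of plane. The mechanistic picture is excitation transfer
from the ring-localized $\pi\pi^*$ state to an amide-localized $n\pi^*$ state
through a seam of conical intersections (CIs). When the molecule is excited at
the band origin it carries only zero-point energy (ZPE), so the question
"how fast does it decay?" becomes "can the vibrationless nuclear wave function
reach the CI seam at all, and with what probability?"

`ciaccess` implements that accessibility analysis as a reusable, tested
pipeline, together with the surrounding machinery needed to exercise it end to
end: normal-mode analysis, CI location on pluggable model surfaces, seam
expansion, surface-hopping dynamics on analytic two-state models, and the
first-order kinetics that turns access probabilities into lifetime ratios.
Because the ab initio surfaces behind the original analysis are not
reproducible at desk scale, the package ships a surrogate-surface generator
with analytically known ground truth; every stage is validated against it.

## The accessibility model

All internal quantities are atomic units (hartree, bohr, electron masses),
converted through one constants table (`au`).

Given a reference excited-state minimum with Hessian-derived normal modes
$\{\omega_i, L_i\}$, a candidate CI geometry is mapped to normal coordinates
$Q = L(R - R_\mathrm{ref})$ in mass-weighted Cartesians (`to_normal_coords()`)
and the harmonic excited-state surface is
$W(Q) = \tfrac12\sum_i \omega_i^2 Q_i^2$. Mode $i$ is *classically
accessible* at the CI when its harmonic energy there does not exceed the mode
ZPE:

$$\alpha_i \;=\; \frac{W_i(Q_{CI,i})}{ZPE_i} \;=\;
  \frac{\tfrac12\omega_i^2 Q_{CI,i}^2}{\tfrac12\omega_i}
  \;=\; \omega_i\, Q_{CI,i}^2 \;\le\; 1 ,$$

with the boundary $\alpha_i = 1$ counted as accessible (and ratios within
1e-12 of 1 snapped to 1 to avoid spurious femto-barriers). A CI geometry is
classically accessible only if *every* mode is.

For a mode beyond its classical turning point $Q_{0,i} = 1/\sqrt{\omega_i}$,
the probability of reaching the CI each time the mode hits the turning point
is semiclassical tunneling through the harmonic barrier, $P_i = e^{2S}$ with
the action

$$S = -\int_{Q_{0,i}}^{Q_{CI,i}} \sqrt{\omega_i^2 Q^2/2 - \omega_i/2}\; dQ .$$

The integrand is taken exactly in this form; substituting
$x = Q\sqrt{\omega_i}$ shows $S$ depends on the mode only through $\alpha_i$:

$$S(\alpha) = -\frac{1}{2\sqrt2}\Big[\sqrt{\alpha(\alpha-1)}
  - \ln\!\big(\sqrt\alpha + \sqrt{\alpha-1}\big)\Big].$$

Two routes to $S$ are implemented. Adaptive quadrature
(`action_integral(method = "quadrature")`, absolute tolerance 1e-12) is the
authoritative oracle; the closed form above is the fast default and is tested
against the quadrature to 1e-8 over $\alpha \in [1, 20]$. The conventional
semiclassical momentum $p = \sqrt{2(V - E)}$ would multiply $S$ by $\sqrt2$;
that variant is available via `convention = "standard"` for sensitivity
checks, but the plain form is the default because it is the definition the
accessibility analysis is built on. The total probability to reach a CI is
the product over modes, $P = \prod_i P_i$; accessible modes contribute
exactly 1, so whether the product runs over all modes or only the tunneling
ones is immaterial (we run it over all).

Useful reference values: $S(2) \approx -0.18839$, $P(2) \approx 0.6861$, and
four modes at a common $\alpha \approx 2.382$ give $P = 0.10$.

## Kinetics: from probabilities to lifetimes

In the diabatic picture, the decay of the initially excited state follows a
first-order rate law whose channel rate constants factor into an electronic
coupling scale times the probability of the nuclear ground state to reach the
corresponding CI seam (`decay_model()`). Since the electronic states involved
are of like character across the systems compared, the couplings are taken as
comparable, and lifetime ratios reduce to reciprocal access-probability
ratios: $\tau_b/\tau_a = P_a / P_b$ (`lifetime_ratio()`). A fully accessible
seam ($P = 1$) against a seam reachable only by tunneling with $P = 0.10$
yields a 10-fold lifetime increase. `integrate_rate_law()` and
`fit_monoexponential()` close the loop: the fitter (nonlinear least squares,
log-linear initialization; `minpack.lm` backend) recovers noiseless rates to
1e-10 and, in a Monte-Carlo calibration at Gaussian noise $\sigma = 0.01$
with 200 points, the lifetime to about 0.2% median error — comfortably
inside the 2% budget used in the tests. Rates carry explicit unit tags
(fs or ns) so simulation and experimental scales cannot be mixed silently.

## Locating and expanding the seam

CI points are located by the sequential penalty method: minimize the seam
objective plus $\sigma\,\Delta E^2/(\Delta E + \alpha_p)$, doubling $\sigma$
(from $\sigma_0 = 3.5$, $\alpha_p = 0.02$ hartree) until the gap falls below
tolerance. No nonadiabatic coupling vectors are needed, which is the point:
the backend contract (`pes_backend()`) only requires energies and,
optionally, gradients. The seam objective is the mean state energy for the
minimum-energy CI (`optimize_meci()`) and the squared distance to a reference
point for the minimum-distance CI (`optimize_mdci()`). On the two-paraboloid
benchmark ($E_1 = (x^2+y^2)/2$, $E_2 = ((x-2)^2+y^2)/2$) the analytic MECI
$(1, 0)$ and the perpendicular-foot MDCIs are recovered to 1e-6 with final
gaps below 1e-5 hartree; the default inner minimizer is BFGS with analytic
gradients where the backend provides them and central differences (step 1e-5)
where it does not.

`expand_seam()` grows a seam set from seeds the way a practitioner maps an
accessible seam region: affine pair combinations at
$\lambda \in \{0.25, 0.5, 0.75\}$ with extrapolations at $\{-0.25, 1.25\}$,
triplet barycenters, refinement of each candidate back to the seam with
`optimize_mdci()` from the candidate itself, then a ZPE filter. The strict
filter (all $\alpha_i \le 1$) is the default; a total-probability threshold
is available because the retention rule "satisfies the ZPE accessibility
condition" admits both readings, and relaxing the filter can only enlarge the
retained set (tested). Gap tolerances follow two shades: strict 1e-5 hartree
(a converged CI) and loose 0.02 eV (seam-map membership); both appear in the
2D occupancy projections (`project_seam_2d()`). Every candidate's fate is
logged — kept, duplicate, gap too large, failed filter, refinement error —
so a seam set is an auditable object, not just a list of points.

## Surface hopping

`propagate_fssh()` implements fewest-switches surface hopping for two-state
diabatic models (per-state constant + linear + diagonal-quadratic surfaces
with a Gaussian or constant coupling — the family that covers both the
surrogate systems and the Landau–Zener benchmark). Nuclei follow velocity
Verlet on the active adiabatic surface at the production step
$\Delta t = 0.25$ fs; electronic amplitudes are integrated in the adiabatic
basis with 100 RK4 substeps per nuclear step, interpolating energies and the
scalar coupling $\dot x \cdot d_{01}$ linearly across the step. Derivative
couplings come analytically from the 2×2 diabatic-to-adiabatic rotation,
with eigenvector phase continuity enforced between steps. Accepted hops
rescale the velocity along the coupling direction to conserve total energy;
frustrated hops leave the velocity unchanged by default (reversal is a flag);
no decoherence correction is applied, matching the baseline algorithm. One
master seed splits deterministically into per-trajectory child seeds, all
recorded, and a fixed (seed, $\Delta t$, model) triple reproduces ensembles
bit-identically. The inner loop is compiled (Rcpp), which is what makes
2000-trajectory validation ensembles cheap.

Validation targets: on a zero-coupling harmonic mode the energy drift stays
below 1e-8 hartree over $10^4$ steps and amplitudes stay normalized to
1e-6; on a linear crossing with constant coupling the ensemble
diabatic-passage fraction matches the Landau–Zener closed form
$P_{LZ} = \exp(-2\pi V_{12}^2 / (v\,|\Delta F|))$ within 3 Monte-Carlo
standard errors at $n = 2000$. The benchmark runs in the fast-passage regime
(slopes $\pm 0.08$, coupling 0.10, crossing velocity $\approx 1.26$
mass-weighted a.u., step 0.005 fs so the coupling region spans many steps)
because that is where the closed form itself is valid; the closed form is
evaluated at the velocity the trajectory actually has at the crossing,
obtained from energy conservation on the lower adiabat.
`classify_passage_events()` implements the diabatic/adiabatic labeling of
close-approach windows: a crossing is "diabatic" when diabatic populations
are preserved across the window (the adiabatic characters swap) and
"adiabatic" when the diabatic character mixes gradually.
`propagate_adiabatic()` covers the hop-free protocol — short runs launched
from a MECI with velocities from the harmonic Wigner distribution
(`wigner_sample()`: position variance $1/2\omega$, momentum variance
$\omega/2$ per mode), logging the minimum gap per trajectory.

## The surrogate systems

`model_spec()` + `make_harmonic_surrogate()` build a three-state analytic
surface over $n$ abstract modes: state A is the harmonic reference
$\tfrac12\sum\omega_i^2Q_i^2$; state B shares the frequencies, sits
`state2_offset` below A along the ray through the prescribed CI point, and
crosses A exactly there; the ground state is a parallel well that plays no
role in the seam analysis. Sharing the frequencies makes the A–B difference
affine, so the seam is exactly a hyperplane — which is what lets pair/triplet
interpolation and the MDCI refinement be checked against exact ground truth.
The per-mode ratios $\alpha_i = \omega_i Q_{CI,i}^2$ are therefore knowable
in closed form, and the CI energy above the minimum is
$\sum_i \alpha_i\omega_i/2$: the barrier is not an independent dial, and a
`barrier_target` inconsistent with the displacement is rejected as an
infeasible spec rather than silently reconciled.

The default study conditions mirror the system contrast the method was built
to explain: eight low-frequency modes (0.0004–0.0060 a.u., roughly 90–1300
cm$^{-1}$), the prescribed CI 0.13 eV above the reference minimum, the second
state 0.69 eV below it (mid-range of the reported 0.62–0.76 eV window), and a
"flexible vs rigid" variant pair (`make_variant_pair()`) in which four
low-frequency modes of the rigid member are displaced past their turning
points, with the common $\alpha$ found by bracketed bisection (tolerance
1e-12) so the total tunneling probability hits a prescribed value — 0.10 for
the MECI-like contrast, 0.15 for the secondary-CI one. The diabatic coupling
is a Gaussian of the distance to the prescribed CI point (width and strength
user-visible in the spec): the true coupling's functional form is unknown,
so it is deliberately a stand-in, consumed only by the dynamics module. Note
one deliberate simplification: a strictly diabatic coupling vanishes at the
CI itself, while the Gaussian peaks there; for model dynamics on the
*diabatic* surfaces this is harmless (the crossing is preserved), and the
seam analysis never sees the coupling at all.

Abstract modes are realized on disk as a chain of fictitious unit-mass atoms
(element "X"), one per mode, displaced along x — this keeps XYZ/Hessian round
trips exact without inventing chemistry. Two practical consequences, both
enforced in the reader: the chain is not a rigid molecule, so the mode basis
is built with `project = "none"` (its mode space overlaps the rigid-body
space, and Eckart projection would corrupt it), and CI candidates are
projected with `align = FALSE` for the same reason. Eckart projection itself
is exercised on synthetic molecular Hessians (random positive matrices
projected onto the vibrational subspace of a bent triatomic), where frequency
invariance under rigid rotation is tested directly.

What the surrogate does *not* emulate: anharmonicity (the real analysis also
rests on a harmonic expansion, but its quality there is an empirical
question), mode–mode coupling in the barrier region, more than two coupled
excited states, and any electronic-structure realism. Passing tests on
surrogates therefore validates the machinery and its contracts, not the
harmonic approximation on real molecules.

## Numerical choices and degenerate inputs

* Quadrature tolerances: action integral to 1e-12 absolute; closed form
  agrees to ≤1e-8 over the tested range and is the default for speed.
* Hessians are symmetrized on read; asymmetry beyond 1e-6 is rejected.
  Near-zero frequencies (|ω| < 1e-6 a.u.) are dropped with a note; any
  projected eigenvalue below −1e-8 raises a "not a minimum" error.
* Mode sign convention: largest-magnitude component positive, for
  platform-independent reproducibility.
* Dihedral interpolation takes the shorter arc; exact 180° ties resolve
  toward the positive direction. Internal-coordinate back-transformation:
  first-order updates with damping 0.5, convergence 1e-8 bohr, 200-iteration
  cap, Wilson B by central differences (the systems here are tiny; analytic
  B would pay only at protein scale).
* RMSD: Kabsch with proper-rotation enforcement; unweighted all-atom by
  default with a mass-weighted flag, since reported RMSDs in this field are
  frequently ambiguous on this point.
* Penalty scheme: $\sigma_0 = 3.5$, growth ×2, $\alpha_p = 0.02$ hartree,
  $\sigma$ capped at 1e9 with a trace-carrying error on failure. The final
  gap scales like $\alpha_p/2\sigma$ for the distance objective, so tighter
  `gap_tol` simply runs more doublings.
* Trajectory termination: runs go to `t_max` by default; a gap-threshold
  stop is deliberately not the default (the minimum encountered gap is
  logged instead), and trajectories whose energy drift exceeds a tolerance
  are flagged `aborted` and excluded from ensemble averages rather than
  killing the run.

## Problem sizes

The shipped tests and the acceptance script use: 8-mode surrogates (100
random 1–8 mode specs for the ground-truth property), two-round seam
expansions from 3 seeds (a few hundred refinements), 2000-trajectory
Landau–Zener ensembles at 0.005 fs over 0.4 fs, single-trajectory
$10^4$-step conservation runs at 0.25 fs, and 100-replicate kinetics
calibrations at 200 points each. These sizes were chosen as the smallest at
which each statistical check is comfortably resolved.

## Known limitations

Tunneling is treated mode-by-mode through one-dimensional harmonic barriers;
multidimensional tunneling paths (instanton-style) and thermal excitation are
out of scope — the analysis addresses the vibrationless state only. The
surface-hopping module is restricted to the analytic two-state model family;
it is a validation instrument, not a production dynamics engine, and the
`pes_backend()` contract is the intended extension point for anything richer.
Coupling scales in the kinetics module default to equal across channels;
when that assumption is wrong, the lifetime factors are wrong with it, and
the package makes the assumption explicit rather than hiding it.
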