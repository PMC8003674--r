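---
title: "Vibronic coupling models, wavepacket dynamics and nonadiabatic spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibronic coupling models, wavepacket dynamics and nonadiabatic spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibronic)
```

## The model

Photoexcitation of heterocycles such as the DNA/RNA nucleobases places
population on a bright $\pi\pi^*$ state inside a crowded Franck–Condon
region containing several dark $n\pi^*$ and Rydberg states. The ensuing
ultrafast internal conversion (tens of femtoseconds) both depletes the
bright state and reshapes the absorption band: inter-state coupling damps
vibronic resolution and broadens the lineshape. This package models that
physics with a linear vibronic coupling (LVC) Hamiltonian in dimensionless
ground-state normal coordinates $q$ with momenta $p$:

$$
H = \sum_i \left[\tfrac12 p^T \Omega p + V^{dia}_{ii}(q)\right]
|d_i\rangle\langle d_i| +
\sum_{i<j} V^{dia}_{ij}(q)\,(|d_i\rangle\langle d_j| + \mathrm{h.c.}),
$$

$$
V^{dia}_{ii}(q) = E^0_i + \lambda_{ii}^T q + \tfrac12 q^T \Omega q,
\qquad
V^{dia}_{ij}(q) = \lambda_{ij}^T q .
$$

Every diabatic surface shares the ground-state frequencies $\Omega$; a
state-specific gradient $\lambda_{ii}$ shifts its minimum, and the
inter-state couplings are linear in $q$. The assumptions inherited from
this form: harmonic surfaces (no anharmonicity, no Duschinsky rotation, no
frequency changes), validity on the $\sim$100 fs timescale before large-
amplitude motion, no decay to the electronic ground state, no triplets.

**Coordinate convention.** We use frequency-weighted dimensionless
coordinates with nuclear ground Hamiltonian
$\tfrac12\sum_\alpha\Omega_\alpha(p_\alpha^2+q_\alpha^2)$, hence
$\langle 0|q_\alpha^2|0\rangle = \tfrac12$, zero-point energy
$\tfrac12\sum_\alpha\Omega_\alpha$, and Huang–Rhys factors
$S_\alpha = \lambda_{ii,\alpha}^2/(2\Omega_\alpha^2)$. Energies are in eV,
times in fs ($\hbar = 0.6582119569$ eV fs), transition dipoles in atomic
units. Imaginary ground-state frequencies (reported as negative numbers)
are replaced by their absolute value at construction with a warning — the
pragmatic treatment of the small out-of-plane imaginary modes of planar-
constrained nucleobase geometries.

## Parameterisation: maximum-overlap diabatization

In practice the $\lambda$ parameters come from electronic-structure scans:
at geometries displaced by $\pm\Delta_\alpha$ along each mode one obtains
adiabatic energies and the overlap matrix $S_{kl}$ between the reference
states (adiabatic states at the expansion point) and the displaced
adiabatic states. `max_overlap_transformation()` computes the orthogonal
matrix closest to $S$ in the Frobenius norm — the orthogonal Procrustes
solution $D = UV^T$ from $S = U\Sigma V^T$, identical to Löwdin symmetric
orthogonalization for near-orthogonal $S$. We chose Procrustes because it
is unique, differentiable and standard; whether it coincides exactly with
every published overlap functional is left open, and documented rather than
asserted. Rotating the adiabatic energies, $V^{dia} = D\,\mathrm{diag}
(E^{ad})\,D^T$, and central-differencing over $\pm\Delta_\alpha$ yields all
$\lambda_{ii,\alpha}$ and $\lambda_{ij,\alpha}$ (`build_lvc_from_scan()`).

Numerical choices:

* **Phase fixing.** Electronic-structure eigenvectors carry arbitrary
  signs; columns of $S$ are flipped so `diag(S) >= 0` before the SVD. (For
  the *result* this is immaterial — $V^{dia}$ is invariant under column
  sign flips — but it keeps the reported $D$ matrices interpretable.)
* **Reflections.** If $\det D = -1$ the reflection is accepted by default;
  `force_rotation = TRUE` flips the direction of the smallest singular
  value instead.
* **Rank deficiency.** A singular value below `svd_tol` (default $10^{-6}$)
  aborts with the offending mode and sign named — the signature of an
  intruder state or a genuine crossing inside the scan step.
* **Step size.** The default $\Delta_\alpha = 0.05$ (dimensionless) is
  small enough for linearity and large enough for numerical stability on
  scan data; the central difference is *exact* for a true LVC potential,
  which is why mock-scan round trips recover generators to machine
  precision.
* **State matching.** Adiabatic states are consumed in ascending energy
  order; no reordering heuristics are applied beyond what Procrustes
  absorbs. Crossings that swap characters within $\Delta$ produce a
  warning from the scan generator, and the algebra still recovers the
  generating model because the similarity transformation is exact
  regardless of labelling.

## Propagation

`propagate()` evolves the doorway state $|d_i;0\rangle$ (vertical
excitation of the vibrational ground state) under $H$ assembled in a
truncated product basis of per-mode harmonic-oscillator functions, with
$q_\alpha = (a_\alpha + a^\dagger_\alpha)/\sqrt2$ and a sparse
(`Matrix::dgCMatrix`) Hamiltonian. The integrator is a short-iterative
Lanczos (Krylov) expansion of $e^{-iH\,\mathrm{d}t/\hbar}$ with full
reorthogonalization, per-step error control (`krylov_tol`, default
$10^{-10}$), and the Hamiltonian spectrum centered by its Gershgorin
midpoint to halve the effective polynomial degree. We preferred Lanczos
over Chebyshev because it needs no a priori spectral bounds and its
per-step cost adapts to the actual wavepacket; exactness at reduced
dimensionality replaces the multilayer tensor machinery that full
30+-mode propagations require. By construction each step maps the state
through an exactly unitary small-space exponential, so norm (and hence
population closure) is conserved to rounding regardless of the Krylov
order; energy conservation is the honest indicator of step accuracy and is
tracked as the per-step Rayleigh quotient.

The autocorrelation $C(t) = \langle\psi(0)|\psi(t)\rangle$ and the
per-state doorway overlaps are phase-referenced to the ground vibrational
level (the zero-point phase is factored out), matching the convention in
which the spectrum is plotted against excitation energy.

**Truncation.** The default per-mode basis is
$n_{max,\alpha} = \max(8, \lceil 4S_\alpha\rceil + 6)$ from the diagonal
gradients — a substitute, not a reproduction, of configuration-selection
policies in multiconfigurational codes, and deliberately user-overridable:

* for *spectra*, where the damping $\Gamma$ suppresses long-time
  recurrences, the default is comfortable;
* for strict autocorrelation accuracy ($<10^{-4}$ over 100 fs) the
  oscillating packet transiently reaches mean occupation $4S_\alpha$ in the
  undisplaced basis, so $\sim\lceil 8S_\alpha\rceil$ plus tail headroom is
  needed (the acceptance suite uses $\lceil 8S\rceil + 14$);
* strongly coupled modes gain vibrational energy through the couplings the
  heuristic does not see; the two-state benchmark needs its coupling mode
  raised to $n_{max}\approx 20$ before populations are converged to
  $10^{-4}$. The convergence procedure is the usual one: raise every
  $n_{max}$ by 4 and require the observable of interest to move less than
  the target tolerance.

`reduce_modes()` ranks modes by
$s_\alpha = \sum_i\lambda_{ii,\alpha}^2 + \sum_{i<j}\lambda_{ij,\alpha}^2$
and keeps the top $k$, reporting the discarded coupling weight — the
desk-scale analogue of assigning more basis functions to strongly coupled
modes. The optional vertical-gradient "dressing" of discarded modes
multiplies the autocorrelation by their closed-form displaced-oscillator
factors; it is exact only while the population stays on the initial state,
is off by default, and is flagged in the metadata when used.

## Spectra

The zero-Kelvin absorption spectrum is the Fourier transform of the damped
autocorrelation, weighted by $|\mu_{gi}|^2$ under the Condon approximation
(coordinate-independent dipoles), with a quadratic damping
$e^{-\Gamma(t/\hbar)^2}$ that is exactly a Gaussian broadening of HWHM
$2\sqrt{\Gamma\ln 2}$ in the energy domain (`hwhm_to_gamma()`). Defaults
mirror common practice for nucleobases: HWHM 0.04 eV for vibronic spectra,
0.25 eV for broadened stick (pure-electronic) spectra. Cross-correlation
terms $(\mu_{gj}\cdot\mu_{gi})\langle d_j;0|\psi_i(t)\rangle$ are
implemented behind `include_cross` and default to off — their contribution
is ordinarily negligible.

Numerical choices:

* The transform is evaluated as a direct semidiscrete sum
  $\rho(E) = \frac{1}{\pi\hbar}\,\mathrm{Re}\sum_k w_k\,
  e^{iEt_k/\hbar} e^{-\Gamma (t_k/\hbar)^2} C(t_k)$ with trapezoid weights
  and the Hermitian extension $C(-t)=C^*(t)$, rather than an FFT; this
  decouples the energy grid from the time grid and makes zero-padding
  unnecessary. $\rho$ integrates to $C(0)=1$, which is what makes the
  "couplings redistribute but do not create intensity" check exact.
* Small negative ripple (finite-window truncation) below $10^{-6}$ of the
  maximum is clipped and logged; anything larger warns.
* The $\omega$ prefactor is applied before any peak normalization by
  default (`omega_prefactor` exposes the other order).
* Absolute units: $\epsilon(E) = k\,E\,|\mu|^2\rho(E)$ in
  M$^{-1}$cm$^{-1}$ with $k = 703.300$ for $E$ in eV, $\mu$ in a.u. and
  $\rho$ in eV$^{-1}$. The constant is fixed by the oscillator-strength
  sum rule ($f = 4.319\times10^{-9}\,\mathrm{M\,cm^2}\int\epsilon\,
  d\tilde\nu$ together with $f = \tfrac23 (E/E_h)|\mu|^2$), evaluated from
  CODATA constants in `R/constants.R`; a literal reading of the textbook
  SI prefactor bundle is ambiguous in its implied volume units, so the sum
  rule — which the test suite verifies numerically — is the calibration of
  record. `units = "relative"` bypasses the constant.

Stick spectra are sums of Gaussians with **areas proportional to the
oscillator strengths** (equal widths, so heights are also proportional to
$f$). Note a consequence the package makes no attempt to hide: for the
uracil CAM-B3LYP table the second band (two sticks 0.26 eV apart, $f$ =
0.045 + 0.170) then peaks *very slightly higher* (0.1934 vs 0.1900 in
units of the height scale) than the isolated first bright stick at 5.50 eV
($f$ = 0.190) — consistent with pure-electronic spectra overestimating the
relative intensity of the second band. Weighting by dipole strength
($f/E$, `weighting = "dipole"`) reverses that ordering.

`shift_normalize_combine()` implements the figure-caption operations:
energy shifts for comparison with experiment, weighted combination (e.g.
50:50 for two tautomers of equal population), and max-to-1 or unit-area
normalization, all recorded in the metadata.

## Population analysis

Diabatic populations $P_i(t) = \sum_{\mathbf n}|c_{i\mathbf n}(t)|^2$ are
stored at every step. `fit_exponential_decay()` performs nonlinear least
squares of $P(t) = b + a\,e^{-t/\tau}$ with a free baseline (population
transfer is often partial) and multi-start initialization
$\tau_0\in\{10,50,200\}$ fs against local minima; traces that do not decay
(fitted $\tau$ beyond 100$\times$ the window or non-positive amplitude)
come back flagged rather than as silent nonsense. The fit window defaults
to the full stored trace; published time constants rarely state their
window or baseline treatment, so ours is documented, not asserted to match
any particular value. `half_transfer_time()` interpolates the first
crossing of $P(0)/2$ linearly — exact for pure exponentials up to the
$O(\mathrm{d}t^2)$ interpolation error. `population_report()` tabulates
$\tau$, $t_{1/2}$, checkpoint populations and the closure residual.

## Synthetic fixtures: what they emulate and what they do not

`make_toy_model()` draws seeded random models: frequencies uniform on
[0.05, 0.4] eV (spanning typical out-of-plane to in-plane vibrational
quanta), vertical energies uniform on a near-UV window, gradients and
couplings Gaussian with scales 0.08/0.05 eV, exercising Huang–Rhys factors
of roughly 0.01–2 — the regime of semi-rigid heteroaromatics. The
nucleobase-like preset (6 states $\times$ 6 modes, 2 bright) mimics the
bright/dark layout of a pyrimidine Franck–Condon region.
`mock_adiabatic_scan()` manufactures diabatization inputs by diagonalizing
a known model, standing in for TD-DFT.

These fixtures validate the *algebra and the dynamics*, not the chemistry:
a green round-trip test establishes that diabatization inverts the mock
scan exactly, and a green conservation test that the propagator is
unitary — neither says anything about how well a particular functional
describes a particular molecule, about anharmonicity, temperature,
Duschinsky rotation, or overlaps computed from truncated CI vectors (whose
non-orthogonality the scan container only logs, at a default tolerance of
$10^{-2}$). The real nucleobase parameter sets live in supplementary
materials of the primary literature and are deliberately not bundled; only
the printed vertical energies and oscillator strengths are
(`nucleobase_states()`).

The two-state, two-mode conical-intersection preset
(`two_state_conical_preset()`) uses the classic pyrazine-like parameters
(tuning mode 0.0739 eV with gradients $-0.0964/+0.1194$ eV, coupling mode
0.1139 eV with $\lambda_{12} = 0.1825$ eV, $E^0$ = 3.94/4.84 eV): visible
population transfer within 100 fs, and a coupled spectrum whose central
variance exceeds the uncoupled one by exactly
$\tfrac12\lambda_{12}^2$ — the moment-level statement of "couplings damp
vibronic resolution".

## Degenerate and edge cases

* Degenerate $E^0$ at the origin are allowed; eigen-sorting at displaced
  geometries is ascending with stable ties, and the diabatization is
  insensitive to basis choice inside a degenerate block.
* Dark doorway states propagate fine but contribute nothing to a molar
  spectrum; requesting one warns.
* A non-uniform or non-zero-based time grid is rejected by the transform.
* The basis-size cap (default $5\times10^5$) converts an accidental
  30-mode request into an error suggesting `reduce_modes()`.

## Known limitations

Exact product-basis propagation scales exponentially with mode count —
six to eight modes is the practical ceiling, which is the price of
replacing multilayer tensor-network propagation; quadratic couplings,
Duschinsky rotation, finite temperature, non-Condon dipoles, triplets,
solvent and decay to the ground state are all out of scope; and HDF5
serialization is substituted by JSON/TSV since no HDF5 R binding is
assumed. The MCTDH-style operator export is best-effort text, not
validated against any external parser.

## A worked example

```{r example, eval = FALSE}
model <- two_state_conical_preset()
res <- propagate(model, make_doorway(model, 2), t_final = 100, dt = 0.1)
population_report(res, checkpoints = c(25, 50, 100))

spec <- autocorrelation_to_spectrum(res, gamma = hwhm_to_gamma(0.04))
spec_vg <- local({
  m0 <- model; m0$lambda_offdiag[] <- 0
  autocorrelation_to_spectrum(
    propagate(m0, make_doorway(m0, 2), t_final = 100, dt = 0.1),
    gamma = hwhm_to_gamma(0.04))
})
c(coupled = spectrum_moments(spec)$var, vg = spectrum_moments(spec_vg)$var)
```

The README shows this example with the numbers it prints.
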