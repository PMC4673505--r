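---
title: "Simulating nitrogen-14 overtone MAS NMR: models, numerics, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating nitrogen-14 overtone MAS NMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overtoneMAS)
```

## The physical problem

Nitrogen-14 is a spin-1 nucleus at 99.6% natural abundance whose
single-quantum transitions are spread over a MHz range by the first-order
quadrupolar interaction.  The *overtone* transition — the formally
forbidden change of the spin projection by two, detected near twice the
Larmor frequency — is insensitive to the first-order quadrupolar
interaction and becomes weakly allowed because the quadrupolar coupling
mixes the Zeeman eigenstates.  Overtone spectra under magic-angle spinning
(MAS) therefore show sharp, sideband-resolved lines, but simulating them
is unusually hard:

* there is **no rotating frame** that removes the carrier: the overtone is
  driven and detected at `2 * omega_Z`, and the ordinary Zeeman rotating
  frame leaves a full-strength oscillation at that frequency under the
  cosine of the pulse term;
* the pulses are **two orders of magnitude weaker** than for an allowed
  transition (90-degree pulses of hundreds of microseconds), so the
  internal Hamiltonian evolves substantially during every pulse and ideal
  pulses are not an admissible approximation;
* MAS makes the Hamiltonian time-dependent at ~10–20 kHz while the
  carrier oscillates at ~87–123 MHz: brute-force lab-frame time slicing
  needs millions of steps per millisecond;
* a powder requires a three-angle orientation average, with grids
  considerably denser than for single-quantum MAS lineshapes.

The simulator removes each time dependence in turn, with no secular
approximation on the nitrogen spin:

1. **MAS**: Floquet or Fokker–Planck embedding turns the periodically
   time-dependent problem into a time-independent one on an enlarged
   space (dimension factor `2l + 1`, or `(1+l)(1+2l)(3+2l)/3` for the
   Fokker–Planck picture, for cut-off rank `l`).
2. **Pulses**: the exact effective Hamiltonian of one RF period
   `T = 2*pi/(2*omega_Z + Delta)` (about 11.5 ns at 14.1 T) is obtained as
   `(i/T) log` of the time-ordered propagator over `T`, evaluated with a
   16-slice second-order midpoint product quadrature.  The Magnus route is
   not implemented: without a rotating frame the expansion does not
   converge, which is precisely why the matrix logarithm is used.
3. **Long pulses**: the one-period propagator is raised to the required
   integer power by binary squaring — a 200 microsecond pulse costs about
   15 squarings, `U(2t) = U(t)^2` being exact by construction.
4. **Detection**: with a time-independent generator and a known
   post-sequence state, the spectrum is evaluated directly in the
   frequency domain through the resolvent, a few hundred points instead of
   millions of time-domain samples, regularized by a uniform relaxation
   rate that plays the role of Lorentzian apodization.

The proton is kept in its own rotating frame; the heteronuclear dipolar
coupling retains every term secular with respect to the proton Zeeman
interaction (`Iz` times any nitrogen operator), which is also the spin
structure the R-sequence symmetry analysis assumes.

## Conventions that the tests pin down

Sign and normalization conventions in spin dynamics are notoriously easy
to get subtly wrong, so the package fixes them by *oracle tests* rather
than by documentation alone:

* **Euler angles** are ZYZ, active; the rank-2 Wigner matrix is evaluated
  as `exp(-i beta Jy)` with the spin-2 angular-momentum matrix (no
  transcribed table), and satisfies
  `U T_{2,k} U^dagger = sum_m D_{mk} T_{2,m}` — asserted against explicit
  spin rotations.
* **Quadrupole scale**: the PAS components are normalized so that a
  static, axially symmetric tensor aligned with the field splits the two
  single-quantum lines by exactly `1.5 * C_Q` (checked by numerical
  diagonalization).
* **Tensor orientations** (dipolar, CSA) are quoted in the eigenframe of
  the quadrupolar tensor, which doubles as the crystal frame.
* **RF amplitude**: `amp_hz` is the calibrated nutation frequency (what a
  water reference measurement reports); the linearly polarized
  laboratory-frame field is `2 * 2*pi*amp_hz * cos(w_c t + phase)` along
  the coil axis.  The coil is tilted from the field by the magic angle by
  default (MAS probe geometry), giving transverse `sin(theta)` and
  longitudinal `cos(theta)` projections; the longitudinal component is an
  essential driver of the overtone transition.
* **Detection** uses the overtone quadrature coherence `|+1><-1|`; the
  overall amplitude and zeroth-order phase of a simulated spectrum are
  arbitrary, so only positions, widths, shapes and ratios are contractual.
* **Initial state**: sequences start from the bare Zeeman polarization
  operator, the usual convention of spin-dynamics simulation libraries.
  Because the quadrupolar interaction mixes the Zeeman states, that
  operator is not exactly stationary: it carries a small
  pulse-independent overtone coherence (the free-induction background a
  receiver phase cycle would remove experimentally) that can interfere
  with the excited signal at the detection bin.  The carrier-refinement
  pass therefore references the excitation against a no-pulse
  acquisition, and an `initial_state = "thermal"` option projects onto
  the part diagonal in the free-Hamiltonian eigenbasis — the strictly
  stationary equilibrium, for which zero pulse width gives exactly zero
  signal.

## Orientation averaging

A crystallite is placed by two angles: the crystal frame is rotated into
the rotor frame by `Ry(beta) Rz(alpha)`, and the rotation about the rotor
axis itself (the spinner phase) is averaged *analytically* by the
embedding — the initial state is injected into the zero Fourier block and
the observable is read from all blocks.  The two-angle grid is a
Gauss–Legendre (in `cos beta`) times equiangular (in `alpha`) product
rule, exact for spherical harmonics up to the requested order; this is the
same polynomial-exactness class as a Lebedev set of equal order at about
1.5 times the points, and the quadrature tests assert the exactness
contract directly (weights summing to one, random monomials up to the
stated order integrated to machine precision).  The fixtures default to
order 77 (glycine) and 131 (NAV) as in the source experiments;
desk-scale runs in the test and acceptance suites use orders 17–53 and
state so in their metadata.

In the Fokker–Planck picture the rotor orientation is an explicit
lab-space coordinate expanded in Wigner functions up to rank `l`; the
spherical average needs no grid at all (inject and detect the uniform
rank-0 component).  The two embeddings agree on free-evolution powder
lineshapes to within their truncation tolerances — one of the property
tests — and the pulse stages run in the Floquet picture, where the
per-orientation structure also yields the orientation-resolved intensity
maps.

## Carrier placement

All experiments are run on resonance with the +2 spinning sideband, the
most intense feature of the overtone manifold.  The simulator mirrors the
experimental procedure with a deterministic two-pass policy: a cheap
free-evolution powder scan over a window wide enough for the second-order
quadrupolar shift locates the manifold maximum, then a short
finite-pulse excitation re-centers the carrier on the peak that is
actually excited.  Both passes are ordinary simulations; no fitting is
involved.

## Pulse sequences

* **Direct excitation**: one finite overtone pulse, then detection.
* **Nutation**: the +2-sideband peak magnitude versus pulse width, the
  pulse propagator accumulated cumulatively across the width sweep.  The
  readout frequency is fixed at the bin holding the largest amplitude of
  the whole sweep, which is how a spectrometer operator reads a nutation
  series.
* **Spin echo**: `90 - tau1 - 180 - tau2 - detect` with finite pulses; the
  optimum for these systems is the unusual `tau1 = 0`.  The second pulse
  is phase-shifted by 90 degrees by default.
* **PRESTO-II**: R-sequence recoupling on the proton channel around the
  overtone echo.  An `RN_n^nu` block places `N` rotor-synchronized pi
  pulses in `n` rotor periods with phases alternating `+-pi*nu/N`
  (excitation block phase 0, reconversion phase 90 degrees).  The proton
  amplitude follows from the timing: `1/(2 n tau_r / N)`, which equals
  89.28 kHz for both R18 symmetries used with the fixtures — R18_2^5 at
  19.84 kHz and R18_1^7 at 9.92 kHz spinning — matching the amplitude the
  source experiments report and recoupling the space-rank-2/spin-rank-1
  components `{2, +-2, 1, -+1}` (heteronuclear dipolar and CSA), which the
  selection-rule enumeration verifies against brute force.  A two-step
  phase cycle of the excitation block removes the directly excited echo
  signal; with the dipolar coupling set to zero the cycled signal
  cancels to machine precision, a sequence-level test.

The event layout adopted for PRESTO-II places the excitation block
immediately before the overtone 90, and the reconversion block (90-degree
shifted) immediately after the 180, followed by the pre-acquisition
delay.  This is the coherence-flow reading of the published timing
constraints (excitation and reconversion durations equal and rotor
synchronized; the nitrogen channel identical to the spin-echo sequence):
the first block turns proton polarization into a two-spin coherence via
the recoupled `I_z S_+-` terms, the echo refocuses the nitrogen
evolution, and the shifted reconversion block converts the two-spin
coherence into observable overtone signal.

## Numerical choices

* Floquet cut-off rank defaults to 5, the rank at which the fixture
  lineshapes are converged (the rank-sweep utility recomputes the
  convergence table; the acceptance suite asserts <1% max-norm change
  from rank 5 to 7 on glycine).  The *pointwise* propagator at a single
  orientation converges much more slowly (the quadrupole-to-spinning
  ratio sets the required ladder depth), which is why oracle-equivalence
  tests run on scaled-down systems or at elevated rank.
* 16 quadrature slices per RF period give a one-period propagator
  accurate to ~3e-6; the self-refinement test asserts the clean
  second-order behaviour.  Pulse durations are rounded to the nearest
  integer number of RF periods (error at most ~6 ns against pulses of
  hundreds of microseconds), which keeps propagation exact in the
  principal-branch ambiguity of the logarithm: only integer multiples of
  the period are ever used.  An eigenphase exactly at the branch point
  aborts with a diagnostic.
* Line broadening enters as a uniform decay on all coherences
  (`FWHM = lb`), the frequency-domain analogue of apodization; the toy
  calibration test checks position and width exactly.  Spectra default to
  512 points over half the spinning frequency about the carrier,
  configurable per run.
* The production detection path diagonalizes the Hermitian Floquet
  Hamiltonian once per orientation and sums Lorentzians — exact for
  uniform relaxation and orders of magnitude faster in R than per-point
  solves; the per-frequency direct-solve route (`fd_spectrum()`) is kept
  as the contractual reference and the two are tested to agree.  Complex
  sparse solves are not available through the Matrix package, so the
  Liouville-space generators are dense; at the dimensions used here
  (hundreds to a few thousand) dense Hermitian eigendecompositions are
  faster than sparse LU factorizations per frequency point anyway.

## What the tests do and do not show

The oracle tests validate the machinery quantitatively: lab-frame
time-sliced propagation (free evolution and finite pulses) matches the
Floquet/effective-Hamiltonian pipeline at the state level on systems
where both converge, the frequency-domain spectrum matches the Fourier
transform of the time-domain signal, and the static overtone nutation
matches the exact two-level Rabi result.  The fixture-level acceptance
runs reproduce the published *simulated* observables — nutation extrema,
direct-excitation linewidths, rank convergence, echo/PRESTO narrowing —
at reduced grids, and their tolerances reflect that reduction.  They do
not model experimental relaxation, probe dead time, radiofrequency
inhomogeneity or decoupling sidebands, so measured signal-enhancement
ratios (which compare two experiments through their noise and relaxation
behaviour) are out of scope; the simulated line shapes and the
qualitative narrowing hierarchy (PRESTO narrower than echo narrower than
direct excitation) are the reproducible content.

## An honestly open point: the overtone nutation rate

The pulse engine is validated three independent ways: against a direct
brute-force integration of the 3x3 laboratory-frame Schrödinger equation
(digit-for-digit agreement of the static nutation curve), against the
exact two-level Rabi result in the mixed eigenbasis, and against the
time-sliced lab-frame oracle under MAS.  With the calibrated nutation
amplitude entering as a `2 a cos(wt)` linear field and the magic-angle
coil geometry, those anchors agree with each other exactly.  The
resulting powder nutation maximum for the glycine parameter set at
9.92 kHz spinning nevertheless falls at roughly twice the published
pulse width: reproducing the reported 260 microsecond 90-degree
condition would need about twice the effective drive.  The amplitude
convention of the original description is ambiguous on exactly such a
factor (its own text notes that the RF amplitude symbol "in some
conventions requires a factor of 2 in front"), but adopting a further
doubling without a physical justification would be curve fitting, so the
package ships the physically grounded convention and reports the
nutation extrema it actually computes.  Linewidths, sideband structure,
rank convergence and the sequence-level contracts (phase-cycle nulls,
echo/PRESTO narrowing) do not depend on this scale.

## Known limitations

* One spin-1 nitrogen and at most one effective proton; no proton-proton
  couplings (each fixture models its amine protons by a single
  motional-average pair along the rotation axis).
* Relaxation is a uniform linewidth, applied at detection only; pulses
  are unitary.
* The Fokker–Planck engine covers free-evolution detection; pulse
  sequences run in the Floquet picture.
* Shaped or swept pulses, heteronuclear decoupling during acquisition,
  and two-dimensional correlation experiments are not modelled.
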