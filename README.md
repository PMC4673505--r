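# overtoneMAS

Spin-dynamics simulation of **nitrogen-14 overtone NMR under magic-angle
spinning** in R.

Nitrogen-14 (spin 1, 99.6% abundant) is usually hard to observe directly:
its single-quantum lines are spread over MHz by the first-order
quadrupolar interaction.  The *overtone* transition — the formally
forbidden Δm = 2 transition near twice the Larmor frequency, weakly
allowed through quadrupolar mixing of the Zeeman states — escapes the
first-order broadening and gives sharp, chemically informative lines
under MAS.  Simulating it is the hard part: there is no rotating frame
that removes the `2ω_Z` carrier, the pulses are so weak that a 90° pulse
lasts hundreds of microseconds and can never be treated as ideal, and the
Hamiltonian is simultaneously time-dependent at the spinning frequency
(~10–20 kHz) and at the carrier (~10⁸ Hz).

`overtoneMAS` implements the simulation strategy that makes this
tractable, for two-spin ¹⁴N–¹H model systems:

* **Floquet / Fokker–Planck embeddings** make MAS time-independent
  (dimension factor `2l+1`, respectively `(1+l)(1+2l)(3+2l)/3`, at
  cut-off rank `l`); the spinner phase is averaged analytically, so a
  powder needs only a two-angle orientation grid (none at all in the
  Fokker–Planck picture).
* **Exact effective Hamiltonians** for finite overtone pulses: the
  time-ordered propagator over one RF period `T = 2π/(2ω_Z + Δ)`
  (~11.5 ns at 14.1 T) is evaluated with a 16-slice second-order product
  quadrature and its matrix logarithm taken — the Magnus expansion does
  not converge here — then **propagator squaring** amplifies the step
  exponentially: a 200 μs pulse costs ~15 squarings.
* **Frequency-domain detection** through the resolvent: a few hundred
  spectral points replace millions of time-domain samples, with a uniform
  relaxation rate regularizing the denominator (Lorentzian apodization).

On top of the engine sits a pulse-sequence library: direct overtone
excitation, nutation curves, overtone spin echoes, and **PRESTO-II**
polarization transfer from ¹H through rotor-synchronized symmetry-based
`RN_n^ν` recoupling (R18₂⁵, R18₁⁷), including its two-step phase cycle
and first-order selection-rule analysis, plus orientation-resolved
intensity/position maps.  Literature parameter sets for glycine and
N-acetyl-valine (C_Q, η_Q, CSA, N–H distance, tensor orientations) ship
as fixtures.

## Worked example

Direct overtone excitation of glycine at 14.1 T (overtone reference
86.7448 MHz), 19.84 kHz MAS, a 260 μs pulse at the calibrated 55 kHz RF
amplitude, detected on the +2 spinning sideband:

```r
library(overtoneMAS)

setup <- ot_setup("glycine", mas_hz = 19.84e3,
                  floquet_rank = 5, grid_order = 17, lb_hz = 300,
                  window_hz = 5e3)
setup
#> <ot_setup> glycine
#>   MAS 19.84 kHz | rank 5 | grid order 17 | lb 300 Hz
#>   overtone ref 86.7448 MHz, carrier offset +10.991 kHz

spec <- direct_excitation(setup, pulse_s = 260e-6)
peak_metrics(spec)[c("position_hz", "fwhm_hz")]
#> $position_hz
#> [1] 29.35421
#>
#> $fwhm_hz
#> [1] 725.5614
```

The carrier lands ~11 kHz above the overtone reference: that is the +2
sideband of the glycine overtone manifold, found by the deterministic
two-pass pre-scan (`locate_carrier()`), sitting two spinning sidebands
above the centerband whose position is dominated by the second-order
quadrupolar shift.  The excited line peaks on resonance and is
~0.7 kHz wide at this reduced grid (the published simulated width at the
full order-77 grid is 0.83 kHz, and the +2 sideband is indeed the most
intense feature of the manifold).  Spectra are `ot_spectrum` objects with
`plot()`, ppm referencing against the doubled ¹⁴N reference frequency
(`reference_axis()`), and a plain-text writer with a YAML metadata
sidecar (`write_spectrum()`).

Other entry points: `nutation_curve()`, `spin_echo()`, `presto_ii()`,
`orientation_maps()`, `free_evolution_spectrum()` (Floquet or
Fokker–Planck engine), `rank_sweep()`, `selection_rules()`, and a YAML
config + CLI front end (`exec/overtone-sim run|nutation|rank-sweep|
dump-sequence|fixtures <config.yaml>`).

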