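Package: overtoneMAS
Title: Simulation of Nitrogen-14 Overtone NMR Spectra under Magic-Angle Spinning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Spin-dynamics simulator for nitrogen-14 overtone (double-quantum)
    NMR spectroscopy of rotating solids. The laboratory-frame spin Hamiltonian
    of a quadrupolar nitrogen-14 coupled to a proton is propagated without a
    rotating-frame approximation: magic-angle spinning is made time-independent
    by Floquet or Fokker-Planck embeddings, finite-duration overtone pulses are
    treated exactly through matrix-logarithm effective Hamiltonians with
    propagator squaring, and spectra are evaluated directly in the frequency
    domain through the resolvent. Ships pulse-sequence models for direct
    overtone excitation, overtone spin echoes and PRESTO-II symmetry-based
    (R-sequence) polarization transfer from protons, together with literature
    parameter sets for glycine and N-acetyl-valine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
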