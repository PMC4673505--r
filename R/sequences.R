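# Pulse-sequence library: direct overtone excitation, nutation curves,
# overtone spin echo, PRESTO-II polarization transfer with symmetry-based
# R-sequences, and orientation-resolved diagnostics.

#' Simulation setup
#'
#' Bundles the spin system with the spectrometer / engine configuration
#' shared by all sequences.
#'
#' @param system a [spin_system()] or a fixture name (`"glycine"`, `"NAV"`).
#' @param mas_hz spinning frequency (Hz).
#' @param overtone_ref_mhz overtone reference frequency (MHz), twice the
#'   nitrogen-14 reference; 86.7448 at 14.1 T, 122.8331 at 20.0 T.  Taken
#'   as a configuration constant, not derived from gamma * B0.
#' @param floquet_rank Floquet cut-off rank l (dimension factor 2l+1).
#' @param grid_order spherical quadrature order for powder averaging.
#' @param lb_hz Lorentzian line broadening (Hz).
#' @param rf overtone-channel [rf_channel()]; its `offset_hz`, when `NULL`
#'   in `carrier_offset_hz`, is replaced by the auto-located +2 sideband.
#' @param carrier_offset_hz carrier offset from the overtone reference
#'   (Hz); `NULL` locates the most intense (+2) spinning sideband with a
#'   coarse free-evolution pre-scan and puts the carrier on resonance with
#'   it (two-pass policy).
#' @param n_slices RF-period quadrature slices for effective Hamiltonians.
#' @param window_hz half-width of the detection window around the carrier
#'   (Hz); default `mas_hz / 4`.
#' @param n_points frequency points across the window (default 512).
#' @param initial_state `"zeeman"` (bare polarization operator, the
#'   reference-simulation convention, default) or `"thermal"` (its part
#'   diagonal in the free-Hamiltonian eigenbasis: the strictly stationary
#'   equilibrium, with no pulse-independent coherence background).
#' @return object of class `"ot_setup"`.
#' @export
ot_setup <- function(system, mas_hz,
                     overtone_ref_mhz = 86.7448,
                     floquet_rank = 5L, grid_order = 29L, lb_hz = 300,
                     rf = rf_channel(55e3),
                     carrier_offset_hz = NULL,
                     n_slices = 16L,
                     window_hz = NULL, n_points = 512L,
                     initial_state = c("zeeman", "thermal")) {
  if (is.character(system)) system <- load_fixture(system)$system
  initial_state <- match.arg(initial_state)
  wz <- 2 * pi * overtone_ref_mhz * 1e6 / 2
  parts <- build_interactions(system, wz)
  setup <- structure(list(
    system = system, parts = parts, omega_z = wz,
    mas_hz = mas_hz, omega_mas = 2 * pi * mas_hz,
    overtone_ref_mhz = overtone_ref_mhz,
    l = as.integer(floquet_rank), grid_order = grid_order, lb_hz = lb_hz,
    rf = rf, n_slices = as.integer(n_slices),
    window_hz = window_hz %||% (mas_hz / 4), n_points = as.integer(n_points),
    initial_state = initial_state
  ), class = "ot_setup")
  setup$carrier_offset_hz <- carrier_offset_hz %||% locate_carrier(setup)
  setup
}

#' @export
print.ot_setup <- function(x, ...) {
  cat("<ot_setup>", x$system$label, "\n")
  cat(sprintf("  MAS %.4g kHz | rank %d | grid order %d | lb %.3g Hz\n",
              x$mas_hz / 1e3, x$l, x$grid_order, x$lb_hz))
  cat(sprintf("  overtone ref %.4f MHz, carrier offset %+.3f kHz\n",
              x$overtone_ref_mhz, x$carrier_offset_hz / 1e3))
  invisible(x)
}

# Initial-state policy.  The default starts from the bare Zeeman
# polarization operator (the usual convention of spin-dynamics simulation
# libraries); because the quadrupolar interaction mixes the Zeeman
# states, that operator is not exactly stationary and carries a small
# pulse-independent overtone coherence that can interfere with the
# excited signal at the detection bin.  The
# "thermal" option projects onto the part diagonal in the free-Hamiltonian
# eigenbasis - the strict equilibrium state, for which zero pulse width
# gives exactly zero signal.
.thermalize <- function(R0, det) {
  P <- Conj(t(det$V)) %*% R0 %*% det$V
  det$V %*% (Re(diag(P)) * Conj(t(det$V)))
}

# default states: thermal nitrogen polarization and the overtone
# (double-quantum) quadrature detection coherence |+1><-1|
.state_szN <- function(parts) {
  .embed_n(spin_operators(1)$Sz, parts$has_h)
}
.state_izH <- function(parts) {
  .embed_h(spin_operators(0.5)$Sz)
}
.state_ot_plus <- function(parts) {
  sp <- matrix(0i, 3, 3); sp[1, 3] <- 1
  .embed_n(sp, parts$has_h) / if (parts$has_h) 2 else 1
}

#' Locate the carrier: two-pass search for the +2 sideband
#'
#' Pass one runs a cheap free-evolution powder spectrum (overtone
#' coherence as the initial state, coarse grid, wide window) to find the
#' most intense feature of the sideband manifold without assuming where
#' the second-order quadrupolar shift puts the centerband.  Pass two
#' re-centers by simulating an actual finite-pulse excitation with the
#' carrier on the pass-one estimate and peak-picking the excited spectrum
#' - mirroring the experimental procedure of placing the carrier on
#' resonance with the observed +2 sideband, the most intense one.
#'
#' @param setup an [ot_setup()] (its `carrier_offset_hz` is ignored).
#' @param span_hz half-width of the pass-one window (Hz); default covers
#'   the second-order quadrupolar shift range plus six sidebands.
#' @param grid_order coarse grid order (default 15).
#' @param n_points pass-one scan points (default 2048).
#' @param refine_pulse_s pulse width for the pass-two excitation scan
#'   (default 100 us: short enough to cover the sideband, long enough to
#'   weight orientations like the production pulse); 0 skips pass two.
#' @return carrier offset in Hz from the overtone reference.
#' @export
locate_carrier <- function(setup, span_hz = NULL, grid_order = 15L,
                           n_points = 2048L, refine_pulse_s = 100e-6) {
  sys <- setup$system
  nu_n <- setup$omega_z / (2 * pi)
  span_hz <- span_hz %||% max(6 * setup$mas_hz, 1.2 * sys$C_Q^2 / (2 * nu_n),
                              4e4)
  freq_rel <- seq(-span_hz, span_hz, length.out = n_points)
  grid <- spherical_grid(grid_order)
  sp <- .state_ot_plus(setup$parts)
  rho0 <- sp + Conj(t(sp))
  omega_abs <- 2 * setup$omega_z + 2 * pi * freq_rel
  acc <- complex(n_points)
  lb_scan <- max(setup$lb_hz, 500)
  for (i in seq_len(nrow(grid))) {
    Hm <- ham_fourier(setup$parts, grid$alpha[i], grid$beta[i])
    fl <- build_floquet_h(Hm, setup$omega_mas, setup$l)
    det <- orient_detector(fl, sp)
    R0 <- .block0(rho0, setup$l)
    acc <- acc + grid$weight[i] * detect_amp(det, R0, omega_abs, lb_scan)
  }
  f1 <- freq_rel[which.max(Mod(acc))]
  if (refine_pulse_s <= 0) return(f1)
  # pass two: excite with the carrier at f1 and re-center on the excited
  # peak.  The pulse response is referenced against a no-pulse acquisition
  # (the receiver-cycled difference), so the small stationary
  # quadrupolar-mixing background of the Zeeman initial state cannot
  # capture the carrier.
  tmp <- setup
  tmp$carrier_offset_hz <- f1
  tmp$grid_order <- min(setup$grid_order, grid_order)
  tmp$lb_hz <- max(setup$lb_hz, 300)
  tmp$window_hz <- 0.75 * setup$mas_hz
  tmp$n_points <- 384L
  cycles <- list(list(events = list(ev_ot_pulse(refine_pulse_s, 0)), recv = 1),
                 list(events = list(), recv = -1))
  sp2 <- powder_run(tmp, cycles)
  f1 + sp2$freq_hz[which.max(Mod(sp2$amp))]
}

# ---- pulse-program events -------------------------------------------------

#' Pulse-program events
#'
#' Constructors for the timed channel events consumed by the sequence
#' executor: a finite overtone pulse (simulated with the effective
#' Hamiltonian engine, never assumed ideal), a free-evolution delay, and a
#' proton R-sequence recoupling block (rotating-frame channel).
#'
#' @param duration event duration (s).
#' @param phase RF phase (radians).
#' @param amp_hz RF amplitude (Hz); `NULL` uses the setup default.
#' @param phases per-element phase schedule (radians) for the proton block.
#' @param element_s single R-element duration (s).
#' @return event list object.
#' @export
ev_ot_pulse <- function(duration, phase = 0, amp_hz = NULL) {
  list(type = "ot_pulse", duration = duration, phase = phase, amp_hz = amp_hz)
}

#' @rdname ev_ot_pulse
#' @export
ev_delay <- function(duration) list(type = "delay", duration = duration)

#' @rdname ev_ot_pulse
#' @export
ev_hblock <- function(phases, element_s, amp_hz) {
  list(type = "hblock", phases = phases, element_s = element_s,
       amp_hz = amp_hz)
}

# Execute an event list at one orientation: returns the Floquet-space
# propagator (product of segment propagators, latest leftmost).  `det`
# supplies the eigendecomposition for delays; `cache` memoizes effective
# pulses and proton element propagators across calls at the same
# orientation.
seq_propagator <- function(fl, det, events, setup, cache = new.env(parent = emptyenv())) {
  U <- NULL
  mul <- function(A) if (is.null(U)) U <<- A else U <<- A %*% U
  for (ev in events) {
    if (ev$type == "ot_pulse") {
      if (ev$duration <= 0) next
      amp <- ev$amp_hz %||% setup$rf$amp_hz
      key <- paste0("ot:", amp, ":", ev$phase)
      ep <- cache[[key]]
      if (is.null(ep)) {
        ch <- rf_channel(amp, offset_hz = setup$carrier_offset_hz,
                         phase = ev$phase, coil_angle = setup$rf$coil_angle)
        ep <- effective_hamiltonian(fl, ch, setup$omega_z, setup$n_slices)
        cache[[key]] <- ep
      }
      mul(pulse_propagator(ep, ev$duration))
    } else if (ev$type == "delay") {
      if (ev$duration <= 0) next
      mul(det$V %*% (exp(-1i * det$lambda * ev$duration) * Conj(t(det$V))))
    } else if (ev$type == "hblock") {
      for (ph in ev$phases) {
        key <- paste0("h:", ev$amp_hz, ":", round(ph, 12), ":", ev$element_s)
        Ue <- cache[[key]]
        if (is.null(Ue)) {
          rr <- list(channel = "h1", phase = ph)
          Wh <- .blockdiag(rf_operator(rr, setup$parts), fl$l)
          Ue <- expm_herm(fl$HF + 2 * pi * ev$amp_hz * Wh, ev$element_s)
          cache[[key]] <- Ue
        }
        mul(Ue)
      }
    } else stop("unknown event type: ", ev$type)
  }
  U %||% diag(nrow(fl$HF)) + 0i
}

# ---- powder driver --------------------------------------------------------

# Core loop: for each grid orientation build the Floquet problem, form the
# (phase-cycled) post-sequence state, and accumulate the detected spectrum.
# `cycles` is a list of list(events = <event list>, recv = <receiver
# weight>); `rho0` the initial state, `tau_acq_pre` a pre-acquisition
# delay folded into detection.  Returns the powder ot_spectrum, optionally
# with a per-orientation table attached.
powder_run <- function(setup, cycles, rho0 = NULL, freq_rel = NULL,
                       grid = NULL, collect_orient = FALSE,
                       progress = FALSE) {
  parts <- setup$parts
  rho0 <- rho0 %||% .state_szN(parts)
  sp <- .state_ot_plus(parts)
  freq_rel <- freq_rel %||% seq(-setup$window_hz, setup$window_hz,
                                length.out = setup$n_points)
  grid <- grid %||% spherical_grid(setup$grid_order)
  omega_abs <- 2 * setup$omega_z + 2 * pi * setup$carrier_offset_hz +
    2 * pi * freq_rel
  acc <- complex(length(freq_rel))
  omap <- if (collect_orient) {
    data.frame(alpha = grid$alpha, beta = grid$beta, weight = grid$weight,
               height = NA_real_, position_hz = NA_real_)
  }
  for (i in seq_len(nrow(grid))) {
    Hm <- ham_fourier(parts, grid$alpha[i], grid$beta[i])
    fl <- build_floquet_h(Hm, setup$omega_mas, setup$l)
    det <- orient_detector(fl, sp)
    cache <- new.env(parent = emptyenv())
    R0 <- .block0(rho0, setup$l)
    if (identical(setup$initial_state, "thermal")) R0 <- .thermalize(R0, det)
    rho_F <- matrix(0i, nrow(fl$HF), ncol(fl$HF))
    for (cy in cycles) {
      W <- seq_propagator(fl, det, cy$events, setup, cache)
      rho_F <- rho_F + cy$recv * (W %*% R0 %*% Conj(t(W)))
    }
    a <- detect_amp(det, rho_F, omega_abs, setup$lb_hz)
    acc <- acc + grid$weight[i] * a
    if (collect_orient) {
      j <- which.max(Mod(a))
      omap$height[i] <- Mod(a)[j]
      omap$position_hz[i] <- freq_rel[j]
    }
    if (progress && i %% 50 == 0) message("orientation ", i, "/", nrow(grid))
  }
  out <- ot_spectrum(freq_rel, acc, meta = list(
    fixture = setup$system$label, mas_hz = setup$mas_hz,
    floquet_rank = setup$l, grid_order = attr(grid, "order"),
    lb_hz = setup$lb_hz,
    carrier_hz = setup$overtone_ref_mhz * 1e6 + setup$carrier_offset_hz,
    carrier_offset_hz = setup$carrier_offset_hz
  ))
  if (collect_orient) attr(out, "orientations") <- omap
  out
}

# ---- sequences ------------------------------------------------------------

#' Direct overtone excitation (pulse-acquire)
#'
#' One finite overtone pulse simulated with the effective-Hamiltonian
#' engine, then frequency-domain detection of the +2 sideband region.
#'
#' @param setup an [ot_setup()].
#' @param pulse_s excitation pulse width (s); 0 returns a zero spectrum.
#' @param phase pulse phase (radians).
#' @param collect_orient also return per-orientation peak data (see
#'   [orientation_maps()]).
#' @param grid optional pre-built orientation grid.
#' @return `ot_spectrum`.
#' @export
direct_excitation <- function(setup, pulse_s = 260e-6, phase = 0,
                              collect_orient = FALSE, grid = NULL) {
  cycles <- list(list(events = list(ev_ot_pulse(pulse_s, phase)), recv = 1))
  sp <- powder_run(setup, cycles, collect_orient = collect_orient, grid = grid)
  sp$meta$sequence <- "direct_excitation"
  sp$meta$pulse_us <- pulse_s * 1e6
  sp
}

#' Overtone nutation curve
#'
#' Signal amplitude at the +2 sideband versus excitation pulse width.
#' Pulse propagators for the width sweep are built cumulatively from the
#' step propagator (widths are rounded to integer RF periods; the
#' accumulated rounding stays below a nanosecond per step).
#'
#' @param setup an [ot_setup()].
#' @param widths_s increasing vector of equally spaced pulse widths (s).
#' @param grid optional orientation grid.
#' @param progress print progress.
#' @return data.frame with `width_s` and `amplitude` (peak magnitude of the
#'   powder spectrum in the detection window; overall scale arbitrary).
#' @export
nutation_curve <- function(setup, widths_s, grid = NULL, progress = FALSE) {
  if (any(diff(widths_s) <= 0)) stop("widths must be increasing")
  step <- widths_s[1]
  if (max(abs(diff(widths_s) - step)) > 1e-12) {
    stop("widths must be equally spaced from the first width")
  }
  parts <- setup$parts
  rho0 <- .state_szN(parts)
  sp <- .state_ot_plus(parts)
  freq_rel <- seq(-setup$window_hz, setup$window_hz,
                  length.out = setup$n_points)
  omega_abs <- 2 * setup$omega_z + 2 * pi * setup$carrier_offset_hz +
    2 * pi * freq_rel
  grid <- grid %||% spherical_grid(setup$grid_order)
  nw <- length(widths_s)
  S <- matrix(0i, length(freq_rel), nw)
  ch <- rf_channel(setup$rf$amp_hz, offset_hz = setup$carrier_offset_hz,
                   phase = 0, coil_angle = setup$rf$coil_angle)
  r <- pi * setup$lb_hz
  for (i in seq_len(nrow(grid))) {
    Hm <- ham_fourier(parts, grid$alpha[i], grid$beta[i])
    fl <- build_floquet_h(Hm, setup$omega_mas, setup$l)
    det <- orient_detector(fl, sp)
    ep <- effective_hamiltonian(fl, ch, setup$omega_z, setup$n_slices)
    Ustep <- pulse_propagator(ep, step)
    R0 <- .block0(rho0, setup$l)
    if (identical(setup$initial_state, "thermal")) R0 <- .thermalize(R0, det)
    # shared Lorentzian kernel across the width sweep (frequencies are
    # width-independent; only the post-pulse state changes)
    wjk <- as.vector(outer(det$lambda, det$lambda, "-"))
    K <- 1 / (r + 1i * outer(wjk, omega_abs, "-"))
    Vh <- Conj(t(det$V))
    U <- Ustep
    for (k in seq_len(nw)) {
      P <- Vh %*% (U %*% R0 %*% Conj(t(U))) %*% det$V
      m <- as.vector(Conj(det$Q) * P)
      S[, k] <- S[, k] + grid$weight[i] * as.vector(crossprod(m, K))
      if (k < nw) U <- Ustep %*% U
    }
    if (progress && i %% 25 == 0) message("orientation ", i, "/", nrow(grid))
  }
  # signal amplitude at the sideband maximum: fix the peak position at the
  # frequency bin holding the largest amplitude across the sweep, then read
  # the magnitude there for every width (the experimental nutation
  # readout).  The search is restricted to the central third of the window
  # - the carrier sits on the +2 sideband by construction.
  central <- abs(freq_rel) <= max(abs(freq_rel)) / 3
  mx <- apply(Mod(S), 1, max)
  mx[!central] <- -Inf
  ipk <- which.max(mx)
  out <- data.frame(width_s = widths_s, amplitude = Mod(S[ipk, ]))
  attr(out, "peak_offset_hz") <- freq_rel[ipk]
  attr(out, "surface") <- S
  attr(out, "freq_rel") <- freq_rel
  out
}

#' Overtone spin echo
#'
#' `90 - tau1 - 180 - tau2 - detect`, all pulses finite and simulated via
#' effective-Hamiltonian propagation; no phase correction is applied to the
#' result.  The optimum reported for these systems is the unusual
#' `tau1 = 0` (no delay between the overtone pulses).
#'
#' @param setup an [ot_setup()].
#' @param t90,t180 overtone pulse durations (s).
#' @param tau1 delay between the pulses (s).
#' @param tau2 pre-acquisition delay (s).
#' @param phase90,phase180 pulse phases (radians).
#' @param collect_orient also record per-orientation peak data.
#' @param grid optional orientation grid.
#' @return `ot_spectrum`.
#' @export
spin_echo <- function(setup, t90 = 360e-6, t180 = 720e-6,
                      tau1 = 0, tau2 = 10e-6,
                      phase90 = 0, phase180 = pi / 2,
                      collect_orient = FALSE, grid = NULL) {
  if (tau1 < 0 || tau2 < 0) stop("delays must be non-negative")
  events <- list(
    ev_ot_pulse(t90, phase90),
    ev_delay(tau1),
    ev_ot_pulse(t180, phase180),
    ev_delay(tau2)
  )
  sp <- powder_run(setup, list(list(events = events, recv = 1)),
                   collect_orient = collect_orient, grid = grid)
  sp$meta$sequence <- "spin_echo"
  sp$meta$pulses_us <- c(t90, t180) * 1e6
  sp$meta$tau_us <- c(tau1, tau2) * 1e6
  sp
}

#' PRESTO-II polarization transfer to the overtone transition
#'
#' Proton-channel R-sequence recoupling blocks (basic element a rotor-
#' synchronized pi pulse, phases alternating +-pi nu/N; excitation block
#' with overall phase 0, reconversion with overall phase 90 degrees) around
#' an overtone spin echo on the nitrogen channel.  A two-step phase cycle
#' of the excitation block (0 / 180 degrees, receiver +/-) removes the
#' directly excited overtone signal, leaving the proton-transferred
#' component; with the dipolar coupling set to zero the cycled signal is
#' identically zero.
#'
#' @param setup an [ot_setup()].
#' @param sym an [r_symmetry()]; its rotor period must match the setup
#'   spinning rate (checked).
#' @param tau_exc excitation-block duration (s); must be an integer number
#'   of R elements (rotor synchronization), reconversion time is kept
#'   equal.
#' @param t90,t180,tau1,tau2 overtone echo parameters as in [spin_echo()].
#' @param phase_cycle apply the two-step cycle (default TRUE); `FALSE`
#'   retains the direct-excitation contribution.
#' @param collect_orient record per-orientation peak data.
#' @param grid optional orientation grid.
#' @return `ot_spectrum`.
#' @export
presto_ii <- function(setup, sym = r_symmetry(18, 2, 5, setup$mas_hz),
                      tau_exc = NULL,
                      t90 = 360e-6, t180 = 720e-6, tau1 = 0, tau2 = 10e-6,
                      phase_cycle = TRUE,
                      collect_orient = FALSE, grid = NULL) {
  tau_r <- 1 / setup$mas_hz
  if (abs(sym$tau_r - tau_r) > 1e-12 * tau_r) {
    stop("R-symmetry rotor period does not match the setup spinning rate")
  }
  tau_exc <- tau_exc %||% (36 * sym$element_s)
  n_el <- tau_exc / sym$element_s
  if (abs(n_el - round(n_el)) > 1e-9) {
    stop("tau_exc must be an integer number of R elements (",
         signif(sym$element_s * 1e6, 4), " us each)")
  }
  n_el <- as.integer(round(n_el))
  ph_exc <- r_phase_list(sym, n_el, block_phase = 0)
  ph_rec <- r_phase_list(sym, n_el, block_phase = pi / 2)
  mk_events <- function(exc_shift) list(
    ev_hblock(ph_exc + exc_shift, sym$element_s, sym$amp_hz),
    ev_ot_pulse(t90, 0),
    ev_delay(tau1),
    ev_ot_pulse(t180, pi / 2),
    ev_hblock(ph_rec, sym$element_s, sym$amp_hz),
    ev_delay(tau2)
  )
  cycles <- if (phase_cycle) {
    list(list(events = mk_events(0), recv = 0.5),
         list(events = mk_events(pi), recv = -0.5))
  } else {
    list(list(events = mk_events(0), recv = 1))
  }
  rho0 <- .state_szN(setup$parts) +
    (nmr_gamma("1H") / nmr_gamma("14N")) * .state_izH(setup$parts)
  sp <- powder_run(setup, cycles, rho0 = rho0,
                   collect_orient = collect_orient, grid = grid)
  sp$meta$sequence <- "presto_ii"
  sp$meta$symmetry <- sprintf("R%d_%d^%d", sym$N, sym$n, sym$nu)
  sp$meta$tau_exc_us <- tau_exc * 1e6
  sp$meta$pulses_us <- c(t90, t180) * 1e6
  sp$meta$phase_cycle <- phase_cycle
  sp
}

#' Orientation-resolved signal maps
#'
#' Per-crystallite peak intensity and position for a sequence, as used to
#' analyze which orientations contribute to the powder signal under direct
#' excitation versus PRESTO.
#'
#' @param setup an [ot_setup()].
#' @param sequence `"direct"`, `"echo"` or `"presto"`.
#' @param ... passed to the sequence function.
#' @return data.frame with `alpha`, `beta`, `weight`, `height`,
#'   `position_hz`; the powder spectrum is attached as attribute
#'   `"spectrum"`.
#' @export
orientation_maps <- function(setup, sequence = c("direct", "echo", "presto"),
                             ...) {
  sequence <- match.arg(sequence)
  sp <- switch(sequence,
    direct = direct_excitation(setup, collect_orient = TRUE, ...),
    echo   = spin_echo(setup, collect_orient = TRUE, ...),
    presto = presto_ii(setup, collect_orient = TRUE, ...)
  )
  out <- attr(sp, "orientations")
  attr(sp, "orientations") <- NULL
  attr(out, "spectrum") <- sp
  out
}
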