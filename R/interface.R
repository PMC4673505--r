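# Configuration files, run dispatch, rank sweeps, sequence dumps, logging.

.known_keys <- c(
  "fixture", "system", "overtone_ref_mhz", "mas_khz", "sequence",
  "engine", "floquet_rank", "grid_order", "lb_hz", "rf_amp_khz",
  "coil_angle_deg", "window_khz", "n_points", "carrier_offset_hz",
  "n_slices", "output", "strict"
)
.known_seq_keys <- c(
  "name", "pulse_us", "phase_deg", "widths_us", "t90_us", "t180_us",
  "tau1_us", "tau2_us", "symmetry", "tau_exc_us", "phase_cycle"
)

#' Read a simulation configuration file
#'
#' YAML key/value text; all physical quantities carry units in their key
#' names (`mas_khz`, `pulse_us`, ...).  Unknown keys are rejected in strict
#' mode (the default; set `strict: false` in the file to downgrade to a
#' warning).
#'
#' @param path YAML file path.
#' @return validated configuration list of class `"ot_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  strict <- !isFALSE(cfg$strict)
  unknown <- setdiff(names(cfg), .known_keys)
  if (length(unknown)) {
    msg <- paste("unknown configuration keys:", paste(unknown, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  if (!is.null(cfg$sequence)) {
    unknown <- setdiff(names(cfg$sequence), .known_seq_keys)
    if (length(unknown)) {
      msg <- paste("unknown sequence keys:", paste(unknown, collapse = ", "))
      if (strict) stop(msg) else warning(msg)
    }
  }
  if (is.null(cfg$fixture) && is.null(cfg$system)) {
    stop("configuration needs either a fixture name or an inline system")
  }
  structure(cfg, class = "ot_config")
}

#' Write a configuration list back to YAML
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# build an ot_setup from a config list
config_setup <- function(cfg) {
  sys <- if (!is.null(cfg$fixture)) {
    fx <- load_fixture(cfg$fixture)
    for (k in c("floquet_rank", "grid_order", "lb_hz", "overtone_ref_mhz")) {
      if (is.null(cfg[[k]])) cfg[[k]] <- fx$defaults[[k]]
    }
    fx$system
  } else {
    do.call(spin_system, cfg$system)
  }
  deg <- pi / 180
  ot_setup(
    sys,
    mas_hz = cfg$mas_khz * 1e3,
    overtone_ref_mhz = cfg$overtone_ref_mhz %||% 86.7448,
    floquet_rank = cfg$floquet_rank %||% 5L,
    grid_order = cfg$grid_order %||% 29L,
    lb_hz = cfg$lb_hz %||% 300,
    rf = rf_channel((cfg$rf_amp_khz %||% 55) * 1e3,
                    coil_angle = (cfg$coil_angle_deg %||%
                                    (magic_angle() / deg)) * deg),
    carrier_offset_hz = if (identical(cfg$carrier_offset_hz, "auto"))
      NULL else if (!is.null(cfg$carrier_offset_hz))
        as.numeric(cfg$carrier_offset_hz),   # YAML 1.1 may read 1.0e4 as text
    n_slices = cfg$n_slices %||% 16L,
    window_hz = if (!is.null(cfg$window_khz)) cfg$window_khz * 1e3,
    n_points = cfg$n_points %||% 512L
  )
}

#' Run a configured simulation
#'
#' Dispatches on `sequence$name`: `"direct"`, `"nutation"`, `"echo"`,
#' `"presto"`, or `"free"` (free-evolution overtone lineshape, the one
#' sequence the Fokker-Planck engine also supports - pulses run in the
#' Floquet picture).  The pipeline contains no stochastic element:
#' identical configurations give bit-identical outputs.  A run log (rank,
#' grid, squaring counts, wall time, policy decisions in force) is written
#' next to the spectrum when `output` is set.
#'
#' @param cfg an `ot_config` (or path to one).
#' @param quiet suppress the log text on the console.
#' @return the result object (`ot_spectrum` or nutation data.frame),
#'   invisibly when `output` is set.
#' @export
run_simulation <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  t0 <- proc.time()
  engine <- cfg$engine %||% "floquet"
  seqc <- cfg$sequence %||% list(name = "direct")
  if (engine == "fokker-planck" && !identical(seqc$name %||% "direct", "free")) {
    stop("the fokker-planck engine drives free-evolution lineshapes; ",
         "pulse sequences run in the floquet picture")
  }
  setup <- config_setup(cfg)
  us <- 1e-6
  deg <- pi / 180
  res <- switch(seqc$name %||% "direct",
    direct = direct_excitation(setup, (seqc$pulse_us %||% 260) * us,
                               phase = (seqc$phase_deg %||% 0) * deg),
    nutation = nutation_curve(setup, (seqc$widths_us %||%
                                        seq(20, 700, by = 20)) * us),
    echo = spin_echo(setup, (seqc$t90_us %||% 360) * us,
                     (seqc$t180_us %||% 720) * us,
                     (seqc$tau1_us %||% 0) * us, (seqc$tau2_us %||% 10) * us),
    presto = {
      symv <- seqc$symmetry %||% c(18, 2, 5)
      sym <- r_symmetry(symv[1], symv[2], symv[3], setup$mas_hz)
      presto_ii(setup, sym,
                tau_exc = if (!is.null(seqc$tau_exc_us)) seqc$tau_exc_us * us,
                t90 = (seqc$t90_us %||% 360) * us,
                t180 = (seqc$t180_us %||% 720) * us,
                tau1 = (seqc$tau1_us %||% 0) * us,
                tau2 = (seqc$tau2_us %||% 10) * us,
                phase_cycle = !isFALSE(seqc$phase_cycle))
    },
    free = free_evolution_spectrum(setup, engine = engine),
    stop("unknown sequence name: ", seqc$name)
  )
  elapsed <- (proc.time() - t0)[[3]]
  logtxt <- c(
    sprintf("sequence: %s | engine: %s", seqc$name %||% "direct", engine),
    sprintf("fixture: %s | MAS %.4g kHz | rank %d | grid order %d | lb %.3g Hz",
            setup$system$label, setup$mas_hz / 1e3, setup$l, setup$grid_order,
            setup$lb_hz),
    sprintf("carrier offset: %+.1f Hz from %.4f MHz",
            setup$carrier_offset_hz, setup$overtone_ref_mhz),
    sprintf("coil angle: %.2f deg | RF period slices: %d | remainder policy: round to RF period",
            setup$rf$coil_angle / deg, setup$n_slices),
    sprintf("wall time: %.1f s", elapsed)
  )
  if (!quiet) message(paste(logtxt, collapse = "\n"))
  if (!is.null(cfg$output)) {
    if (inherits(res, "ot_spectrum")) {
      write_spectrum(res, cfg$output)
    } else {
      utils::write.table(res, cfg$output, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    }
    writeLines(logtxt, paste0(cfg$output, ".log"))
    return(invisible(res))
  }
  res
}

#' Free-evolution overtone lineshape
#'
#' Powder spectrum of the freely evolving overtone coherence (no pulse):
#' the observable on which the Floquet and Fokker-Planck engines are
#' compared, since both embeddings share it exactly.
#'
#' @param setup an [ot_setup()].
#' @param engine `"floquet"` (orientation loop over the spherical grid) or
#'   `"fokker-planck"` (implicit spherical average; `fp_rank` controls the
#'   rotation-space truncation).
#' @param fp_rank Fokker-Planck rotation rank (default: the setup's
#'   Floquet rank).
#' @return `ot_spectrum`.
#' @export
free_evolution_spectrum <- function(setup, engine = c("floquet", "fokker-planck"),
                                    fp_rank = NULL) {
  engine <- match.arg(engine)
  parts <- setup$parts
  sp <- .state_ot_plus(parts)
  rho0 <- sp + Conj(t(sp))
  freq_rel <- seq(-setup$window_hz, setup$window_hz,
                  length.out = setup$n_points)
  omega_abs <- 2 * setup$omega_z + 2 * pi * setup$carrier_offset_hz +
    2 * pi * freq_rel
  if (engine == "floquet") {
    grid <- spherical_grid(setup$grid_order)
    acc <- complex(length(freq_rel))
    for (i in seq_len(nrow(grid))) {
      Hm <- ham_fourier(parts, grid$alpha[i], grid$beta[i])
      fl <- build_floquet_h(Hm, setup$omega_mas, setup$l)
      det <- orient_detector(fl, sp)
      acc <- acc + grid$weight[i] *
        detect_amp(det, .block0(rho0, setup$l), omega_abs, setup$lb_hz)
    }
  } else {
    fp <- build_fokker_planck(parts, setup$omega_mas, fp_rank %||% setup$l)
    acc <- fp_spectrum(fp, rho0, sp, omega_abs, setup$lb_hz)
  }
  ot_spectrum(freq_rel, acc, meta = list(
    sequence = "free_evolution", engine = engine,
    fixture = setup$system$label, mas_hz = setup$mas_hz,
    floquet_rank = setup$l, lb_hz = setup$lb_hz,
    carrier_hz = setup$overtone_ref_mhz * 1e6 + setup$carrier_offset_hz,
    carrier_offset_hz = setup$carrier_offset_hz
  ))
}

#' Floquet rank convergence sweep
#'
#' Computes the direct-excitation spectrum at a series of cut-off ranks on
#' a fixed grid and carrier, and reports the normalized maximum point-wise
#' change between each rank and the next entry (rank + 2 in the default
#' series).  The convergence rank is the smallest rank whose spectrum
#' differs from its successor by less than `tol`.
#'
#' @param setup an [ot_setup()]; its `floquet_rank` is overridden.
#' @param ranks increasing integer ranks (default 1, 3, 5, 7).
#' @param pulse_s excitation pulse width (default 260 us).
#' @param tol convergence threshold on the normalized max-norm change
#'   (default 0.01).
#' @return list with `table` (rank pairs and changes), `converged_rank`,
#'   and the list of spectra.
#' @export
rank_sweep <- function(setup, ranks = c(1L, 3L, 5L, 7L), pulse_s = 260e-6,
                       tol = 0.01) {
  ranks <- sort(as.integer(ranks))
  specs <- list()
  for (l in ranks) {
    s2 <- setup
    s2$l <- l
    specs[[as.character(l)]] <- direct_excitation(s2, pulse_s)
  }
  nrm <- function(a) a / max(Mod(a))
  chg <- vapply(seq_len(length(ranks) - 1L), function(i) {
    max(Mod(nrm(specs[[i]]$amp) - nrm(specs[[i + 1]]$amp)))
  }, numeric(1))
  tab <- data.frame(rank = ranks[-length(ranks)],
                    next_rank = ranks[-1],
                    max_change = chg)
  conv <- tab$rank[tab$max_change < tol]
  list(table = tab,
       converged_rank = if (length(conv)) min(conv) else NA_integer_,
       spectra = specs)
}

#' Resolved event table of a pulse program
#'
#' Expands a sequence configuration into the full timed event list (one
#' row per constant-RF segment) for inspection.
#'
#' @param setup an [ot_setup()].
#' @param sequence `"direct"`, `"echo"` or `"presto"`.
#' @param ... sequence parameters as for the corresponding functions.
#' @return data.frame with `channel`, `start_us`, `duration_us`, `amp_khz`,
#'   `phase_deg`, `kind`.
#' @export
dump_sequence <- function(setup, sequence = c("direct", "echo", "presto"),
                          ...) {
  sequence <- match.arg(sequence)
  us <- 1e-6
  args <- list(...)
  events <- switch(sequence,
    direct = list(ev_ot_pulse(args$pulse_s %||% 260 * us, args$phase %||% 0)),
    echo = list(
      ev_ot_pulse(args$t90 %||% 360e-6, 0),
      ev_delay(args$tau1 %||% 0),
      ev_ot_pulse(args$t180 %||% 720e-6, pi / 2),
      ev_delay(args$tau2 %||% 10e-6)
    ),
    presto = {
      sym <- args$sym %||% r_symmetry(18, 2, 5, setup$mas_hz)
      tau_exc <- args$tau_exc %||% (36 * sym$element_s)
      n_el <- as.integer(round(tau_exc / sym$element_s))
      list(
        ev_hblock(r_phase_list(sym, n_el, 0), sym$element_s, sym$amp_hz),
        ev_ot_pulse(args$t90 %||% 360e-6, 0),
        ev_delay(args$tau1 %||% 0),
        ev_ot_pulse(args$t180 %||% 720e-6, pi / 2),
        ev_hblock(r_phase_list(sym, n_el, pi / 2), sym$element_s, sym$amp_hz),
        ev_delay(args$tau2 %||% 10e-6)
      )
    }
  )
  rows <- list()
  t <- 0
  add <- function(channel, dur, amp, phase, kind) {
    rows[[length(rows) + 1L]] <<- data.frame(
      channel = channel, start_us = t / us, duration_us = dur / us,
      amp_khz = amp / 1e3, phase_deg = phase * 180 / pi, kind = kind)
    t <<- t + dur
  }
  for (ev in events) {
    if (ev$type == "ot_pulse") {
      add("14N-OT", ev$duration, ev$amp_hz %||% setup$rf$amp_hz, ev$phase,
          "overtone pulse")
    } else if (ev$type == "delay") {
      add("-", ev$duration, 0, 0, "delay")
    } else {
      for (ph in ev$phases) add("1H", ev$element_s, ev$amp_hz, ph, "R element")
    }
  }
  do.call(rbind, rows)
}
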