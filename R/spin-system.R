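# Spin system definition and the two literature fixtures.

#' Define a nitrogen-14 (+ optional proton) spin system
#'
#' The observed nucleus is a spin-1 nitrogen-14 held in the laboratory frame;
#' an optional single proton is kept in its own rotating frame.  All
#' interaction-tensor orientations (ZYZ Euler angles, radians) are quoted
#' relative to the eigenframe of the nitrogen-14 quadrupolar tensor, which
#' doubles as the crystal frame of the simulation.
#'
#' @param C_Q quadrupolar coupling constant (Hz).
#' @param eta_Q quadrupolar asymmetry, between 0 and 1.
#' @param sigma_iso isotropic nitrogen shift (ppm relative to the overtone
#'   carrier reference).
#' @param delta_sigma nitrogen shift anisotropy (ppm); 0 disables the CSA.
#' @param eta_csa CSA asymmetry, between 0 and 1.
#' @param euler_csa Euler angles of the CSA PAS in the quadrupole frame.
#' @param r_nh N-H internuclear distance (Angstrom); `NULL` (with
#'   `b_dd = NULL`) drops the proton entirely.
#' @param b_dd dipolar coupling constant (Hz); alternative to `r_nh`.
#' @param euler_dd Euler angles of the N-H vector frame in the quadrupole
#'   frame.
#' @param label free-text name.
#' @return object of class `"spin_system"`.
#' @export
#' @examples
#' sys <- spin_system(C_Q = 1.18e6, eta_Q = 0.53, sigma_iso = 32.4,
#'                    r_nh = 1.28)
spin_system <- function(C_Q, eta_Q, sigma_iso = 0,
                        delta_sigma = 0, eta_csa = 0,
                        euler_csa = c(0, 0, 0),
                        r_nh = NULL, b_dd = NULL, euler_dd = c(0, 0, 0),
                        label = "custom") {
  if (eta_Q < 0 || eta_Q > 1) stop("eta_Q must lie in [0, 1]")
  if (eta_csa < 0 || eta_csa > 1) stop("eta_csa must lie in [0, 1]")
  if (!is.null(r_nh) && r_nh <= 0) stop("r_nh must be positive")
  has_h <- !is.null(r_nh) || !is.null(b_dd)
  if (is.null(b_dd) && has_h) {
    b_dd <- dipolar_constant(r_nh, nmr_gamma("1H"), nmr_gamma("14N"))
  }
  spins <- list(list(isotope = "14N", S = 1))
  if (has_h) spins <- c(spins, list(list(isotope = "1H", S = 0.5)))
  structure(list(
    spins = spins,
    C_Q = C_Q, eta_Q = eta_Q,
    sigma_iso = sigma_iso, delta_sigma = delta_sigma, eta_csa = eta_csa,
    euler_csa = euler_csa,
    r_nh = r_nh, b_dd = b_dd, euler_dd = euler_dd,
    label = label
  ), class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat("<spin_system>", x$label, "\n")
  cat(sprintf("  14N: C_Q = %.4g MHz, eta_Q = %.3g, sigma_iso = %.4g ppm\n",
              x$C_Q / 1e6, x$eta_Q, x$sigma_iso))
  if (x$delta_sigma != 0) {
    cat(sprintf("  CSA: delta_sigma = %.4g ppm, eta = %.3g, euler = [%s] deg\n",
                x$delta_sigma, x$eta_csa,
                paste(round(x$euler_csa * 180 / pi, 1), collapse = ", ")))
  }
  if (!is.null(x$b_dd)) {
    cat(sprintf("  1H:  b = %.4g kHz%s, euler_DD = [%s] deg\n",
                x$b_dd / 1e3,
                if (!is.null(x$r_nh)) sprintf(" (r = %.3g A)", x$r_nh) else "",
                paste(round(x$euler_dd * 180 / pi, 1), collapse = ", ")))
  }
  invisible(x)
}

#' Hilbert-space dimension of a system
#' @param sys `spin_system`.
#' @return integer product of (2S+1).
#' @export
system_dim <- function(sys) {
  as.integer(prod(vapply(sys$spins, function(s) 2 * s$S + 1, numeric(1))))
}

#' Literature parameter sets
#'
#' Simulation fixtures for alpha-glycine and N-acetyl-valine (NAV).  The
#' glycine NH3 group's fast rotation is modelled by a single effective N-H
#' pair of 1.28 Angstrom along the rotation axis; NAV carries a full
#' nitrogen CSA.  `defaults` carries the fixture's recommended engine
#' settings (Floquet cut-off rank 5 for both; spherical-grid order 77 for
#' glycine and 131 for NAV) plus the fields/rates used in the experiments.
#'
#' @param name `"glycine"` or `"NAV"` (case-insensitive).
#' @return list with `system` (a [spin_system()]) and `defaults`.
#' @export
#' @examples
#' load_fixture("glycine")$system
load_fixture <- function(name) {
  key <- tolower(name)
  deg <- pi / 180
  if (key %in% c("glycine", "gly")) {
    sys <- spin_system(
      C_Q = 1.18e6, eta_Q = 0.53, sigma_iso = 32.4,
      r_nh = 1.28, euler_dd = c(0, 0, 0),
      label = "glycine"
    )
    defaults <- list(floquet_rank = 5L, grid_order = 77L, lb_hz = 300,
                     overtone_ref_mhz = 86.7448)
  } else if (key %in% c("nav", "n-acetyl-valine", "n-acetylvaline")) {
    sys <- spin_system(
      C_Q = 3.21e6, eta_Q = 0.32, sigma_iso = 121,
      delta_sigma = 105, eta_csa = 0.23,
      euler_csa = c(-90, -90, -17) * deg,
      r_nh = 1.06, euler_dd = c(0, 90, 0) * deg,
      label = "NAV"
    )
    defaults <- list(floquet_rank = 5L, grid_order = 131L, lb_hz = 2000,
                     overtone_ref_mhz = 86.7448)
  } else {
    stop("unknown fixture '", name, "'; available: glycine, NAV")
  }
  list(system = sys, defaults = defaults)
}

# ---- interaction assembly -------------------------------------------------

# kron embedding: nitrogen first, proton second
.embed_n <- function(op, has_h) if (has_h) kronecker(op, diag(2) + 0i) else op
.embed_h <- function(op) kronecker(diag(3) + 0i, op)

#' Assemble the engine representation of a spin system
#'
#' Turns a [spin_system()] plus a Larmor frequency into the working
#' representation the engines consume: the static (orientation-independent)
#' Hamiltonian - the laboratory-frame nitrogen Zeeman term plus isotropic
#' shift - and one entry per rank-2 interaction holding its crystal-frame
#' spherical components and spin-tensor operator set on the full Hilbert
#' space (quadrupole; CSA when the anisotropy is nonzero; proton-secular
#' heteronuclear dipolar coupling when a proton is present).
#'
#' @param sys a [spin_system()].
#' @param omega_z nitrogen-14 Larmor angular frequency (rad/s), i.e.
#'   `pi * overtone reference frequency`.
#' @return list with `H_static`, `ints`, `dim`, `has_h`.
#' @export
build_interactions <- function(sys, omega_z) {
  has_h <- length(sys$spins) > 1L
  opN <- spin_operators(1)
  T2N <- lapply(irreducible_tensors(1, 2), .embed_n, has_h = has_h)
  SzN <- .embed_n(opN$Sz, has_h)

  # static part: 14N Zeeman (laboratory frame!) + isotropic shift
  H_static <- (omega_z + sys$sigma_iso * 1e-6 * omega_z) * SzN

  ints <- list()

  a_q <- quad_pas_components(sys$C_Q, sys$eta_Q)
  ints$quad <- list(a_cr = as.complex(a_q), Tset = T2N)

  if (sys$delta_sigma != 0) {
    csa <- csa_pas_components(sys$sigma_iso, sys$delta_sigma, sys$eta_csa, omega_z)
    # shift spin tensor (linear in S, field along lab z):
    # T_0 = sqrt(2/3) Sz, T_{+-1} = -+ S+-/2, T_{+-2} = 0
    Tcs <- list(
      `k=-2` = 0 * SzN,
      `k=-1` = +0.5 * .embed_n(opN$Sm, has_h),
      `k=0`  = sqrt(2 / 3) * SzN,
      `k=1`  = -0.5 * .embed_n(opN$Sp, has_h),
      `k=2`  = 0 * SzN
    )
    a_cr <- rotate_components(csa$aniso, sys$euler_csa, new_frame = "crystal")
    ints$csa <- list(a_cr = as.complex(a_cr), Tset = Tcs)
  }

  if (!is.null(sys$b_dd)) {
    opH <- spin_operators(0.5)
    IzSz <- kronecker(opN$Sz, opH$Sz)
    IzSp <- kronecker(opN$Sp, opH$Sz)
    IzSm <- kronecker(opN$Sm, opH$Sz)
    # full heteronuclear T2k truncated to the proton-rotating-frame secular
    # part (Iz x any nitrogen operator): T20 -> 2 Iz Sz / sqrt(6),
    # T2+-1 -> -+ Iz S+- / 2, T2+-2 -> 0.
    Tdd <- list(
      `k=-2` = 0 * IzSz,
      `k=-1` = +0.5 * IzSm,
      `k=0`  = 2 / sqrt(6) * IzSz,
      `k=1`  = -0.5 * IzSp,
      `k=2`  = 0 * IzSz
    )
    a_dd <- dipolar_pas_components(sys$b_dd)
    a_cr <- rotate_components(a_dd, sys$euler_dd, new_frame = "crystal")
    ints$dd <- list(a_cr = as.complex(a_cr), Tset = Tdd)
  }

  list(H_static = H_static, ints = ints, dim = system_dim(sys), has_h = has_h)
}
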