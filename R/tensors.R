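# Irreducible spherical components of rank-2 spin interactions.
#
# A rank-2 interaction enters the Hamiltonian as
#     H = sum_k (-1)^k a_k T_{2,-k}
# with spatial components {a_k}, k = -2..2 (angular-frequency units), and
# spin tensor operators T_{2,k}.  Hermiticity requires
# a_{-k} = (-1)^k Conj(a_k).  Under an active rotation R the components map
# to a'_q = (-1)^q sum_k (-1)^k a_k D^2_{-q,-k}(R), which is the coefficient
# match of U H U^dagger using U T_{2,k} U^dagger = sum_m D^2_{mk} T_{2,m}.

#' Spherical tensor component set
#'
#' Container for the five irreducible spherical components of one rank-2
#' interaction in a stated frame.
#'
#' @param components complex length-5 vector, components k = -2..2 in
#'   angular-frequency units (rad/s).
#' @param frame one of `"pas"`, `"crystal"`, `"rotor"`, `"lab"`.
#' @return object of class `"sph_tensor"` (named complex vector).
#' @export
sph_tensor <- function(components, frame = c("pas", "crystal", "rotor", "lab")) {
  frame <- match.arg(frame)
  if (length(components) != 5L) stop("need 5 components (k = -2..2)")
  x <- as.complex(components)
  names(x) <- paste0("k=", -2:2)
  # Hermiticity of the reconstructed Hamiltonian term
  herm <- sapply(0:2, function(k) {
    abs(x[[tensor_name(-k)]] - (-1)^k * Conj(x[[tensor_name(k)]]))
  })
  if (any(herm > 1e-8 * max(1, max(Mod(x))))) {
    stop("components violate Hermiticity: a_{-k} must equal (-1)^k Conj(a_k)")
  }
  structure(x, frame = frame, class = "sph_tensor")
}

#' @export
print.sph_tensor <- function(x, ...) {
  cat("rank-2 spherical components (rad/s), frame:", attr(x, "frame"), "\n")
  print(unclass(x))
  invisible(x)
}

#' Quadrupolar interaction components in its principal axis frame
#'
#' Scale convention: for a static crystal with eta = 0 and the unique axis
#' along the field, the first-order splitting between the two single-quantum
#' nitrogen-14 lines is `(3/2) C_Q` (the suite checks this by numerical
#' diagonalization).  That fixes `a_0 = sqrt(6) * 2 pi C_Q / 4` and
#' `a_{+-2} = 2 pi C_Q eta / 4` for S = 1.
#'
#' @param C_Q quadrupolar coupling constant (Hz).
#' @param eta_Q asymmetry parameter, between 0 and 1.
#' @param S spin quantum number; only S = 1 supported.
#' @return `sph_tensor` in the PAS.
#' @export
quad_pas_components <- function(C_Q, eta_Q, S = 1) {
  if (S != 1) stop("quadrupole components implemented for S = 1 only")
  if (eta_Q < 0 || eta_Q > 1) stop("eta_Q must lie in [0, 1]")
  wq <- 2 * pi * C_Q / 4           # = chi / (4 S (2S-1)) for S = 1
  sph_tensor(c(wq * eta_Q, 0, sqrt(6) * wq, 0, wq * eta_Q), frame = "pas")
}

#' Chemical-shift anisotropy components in the shift PAS
#'
#' Parameterization: `delta_sigma = s_zz - (s_xx + s_yy)/2` and
#' `eta = (s_yy - s_xx) / zeta` with `zeta = s_zz - s_iso =
#' (2/3) delta_sigma` (all in ppm on the shift scale).  The anisotropic part
#' returned has `a_0 = sqrt(3/2) zeta_w`, `a_{+-2} = -zeta_w eta / 2`,
#' `a_{+-1} = 0`, with `zeta_w = (2/3) delta_sigma * 1e-6 * omega_z`; the
#' isotropic part is returned separately as a frequency offset
#' `sigma_iso * 1e-6 * omega_z` to be attached to Sz.
#'
#' @param sigma_iso isotropic shift (ppm, relative to the spectrometer
#'   reference).
#' @param delta_sigma shift anisotropy (ppm).
#' @param eta_csa asymmetry, between 0 and 1.
#' @param omega_z signed Larmor angular frequency of the nucleus (rad/s).
#' @return list with `aniso` (`sph_tensor`, PAS) and `iso_offset` (rad/s).
#' @export
csa_pas_components <- function(sigma_iso, delta_sigma, eta_csa, omega_z) {
  if (eta_csa < 0 || eta_csa > 1) stop("eta_csa must lie in [0, 1]")
  zeta_w <- (2 / 3) * delta_sigma * 1e-6 * omega_z
  aniso <- sph_tensor(
    c(-zeta_w * eta_csa / 2, 0, sqrt(3 / 2) * zeta_w, 0, -zeta_w * eta_csa / 2),
    frame = "pas"
  )
  list(aniso = aniso, iso_offset = sigma_iso * 1e-6 * omega_z)
}

#' Dipole-dipole coupling constant
#'
#' `b = -(mu0 / 4 pi) gamma1 gamma2 hbar / r^3`, returned in Hz.  With both
#' gyromagnetic ratios positive (1H-14N) the constant is negative; only
#' line positions and splittings are observable, the sign convention is
#' documented here once.
#'
#' @param r internuclear distance (Angstrom).
#' @param gamma1,gamma2 gyromagnetic ratios (rad s^-1 T^-1).
#' @return dipolar coupling constant in Hz.
#' @export
#' @examples
#' dipolar_constant(1.06, nmr_gamma("1H"), nmr_gamma("14N"))  # about -7.3 kHz
dipolar_constant <- function(r, gamma1, gamma2) {
  if (r <= 0) stop("internuclear distance must be positive")
  r_m <- r * 1e-10
  -.mu0_over_4pi * gamma1 * gamma2 * .hbar / r_m^3 / (2 * pi)
}

#' Dipolar interaction components in its principal axis frame
#'
#' Internuclear vector along the PAS z axis: `a_0 = sqrt(6) * 2 pi b`,
#' all other components zero (b in Hz).
#'
#' @param b dipolar coupling constant (Hz), e.g. from [dipolar_constant()].
#' @return `sph_tensor` in the PAS.
#' @export
dipolar_pas_components <- function(b) {
  sph_tensor(c(0, 0, sqrt(6) * 2 * pi * b, 0, 0), frame = "pas")
}

#' Rotate spherical components
#'
#' Applies an active rotation to a component set:
#' `a'_q = (-1)^q sum_k (-1)^k a_k D^2_{-q,-k}(R)`.  Preserves the
#' Hermiticity structure and the rotational invariant `sum_k |a_k|^2`.
#'
#' @param a `sph_tensor` (or bare length-5 complex vector).
#' @param D rank-2 Wigner matrix from [wigner_d2()], or a list of Euler
#'   angles `c(alpha, beta, gamma)` which is converted internally.
#' @param new_frame frame tag for the result.
#' @return rotated `sph_tensor`.
#' @export
rotate_components <- function(a, D, new_frame = NULL) {
  if (!is.matrix(D)) D <- wigner_d2(D[1], D[2], D[3])
  av <- as.complex(a)
  k <- -2:2
  sgn <- (-1)^k
  # index of component k in the vector: k + 3
  ap <- vapply(k, function(q) {
    sum(sgn * av * D[cbind(rep(-q + 3L, 5L), -k + 3L)]) * (-1)^q
  }, complex(1))
  fr <- new_frame %||% (if (inherits(a, "sph_tensor")) attr(a, "frame") else "lab")
  sph_tensor(ap, frame = fr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Assemble a Hamiltonian term from spherical components
#'
#' `H = sum_k (-1)^k a_k T_{2,-k}` for a supplied spin tensor set.
#'
#' @param a length-5 complex components (k = -2..2).
#' @param Tset list of 5 spin tensor matrices named as in
#'   [irreducible_tensors()].
#' @return complex matrix (Hermitian when `a` satisfies the component
#'   Hermiticity rule and `Tset` is a proper tensor operator set).
#' @export
assemble_term <- function(a, Tset) {
  av <- as.complex(a)
  H <- 0
  for (k in -2:2) {
    H <- H + (-1)^k * av[[k + 3L]] * Tset[[tensor_name(-k)]]
  }
  H
}
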