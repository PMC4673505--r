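# Fokker-Planck embedding: the rotor orientation enters as an explicit
# lab-space degree of freedom.  The density operator becomes a function on
# SO(3), expanded in normalized Wigner functions f_{jmk} = sqrt(2j+1)
# Conj(D^j_{mk}) up to rank l; spinning is the static generator
# omega_mas * (n . L) built from lab-space angular-momentum operators, and
# the spherical (three-angle) powder average is implicit: initial state and
# detection both sit in the uniform j = 0 component.

#' Clebsch-Gordan coefficient
#'
#' `<j1 m1 j2 m2 | J M>` by Racah's closed formula (integer angular
#' momenta are all that the rotation-space algebra here needs, but
#' half-integers work too).
#'
#' @param j1,m1,j2,m2,J,M angular momentum quantum numbers.
#' @return numeric coefficient.
#' @export
clebsch_gordan <- function(j1, m1, j2, m2, J, M) {
  if (M != m1 + m2) return(0)
  if (J < abs(j1 - j2) || J > j1 + j2) return(0)
  if (abs(m1) > j1 || abs(m2) > j2 || abs(M) > J) return(0)
  lf <- function(n) lgamma(n + 1)
  pref <- 0.5 * (log(2 * J + 1) +
    lf(j1 + j2 - J) + lf(j1 - j2 + J) + lf(-j1 + j2 + J) - lf(j1 + j2 + J + 1) +
    lf(j1 + m1) + lf(j1 - m1) + lf(j2 + m2) + lf(j2 - m2) +
    lf(J + M) + lf(J - M))
  kmin <- max(0, j2 - J - m1, j1 + m2 - J)
  kmax <- min(j1 + j2 - J, j1 - m1, j2 + m2)
  if (kmax < kmin) return(0)
  s <- 0
  for (k in kmin:kmax) {
    s <- s + (-1)^k * exp(pref - lf(k) - lf(j1 + j2 - J - k) - lf(j1 - m1 - k) -
                            lf(j2 + m2 - k) - lf(J - j1 - m2 + k) -
                            lf(J - j2 + m1 + k))
  }
  s
}

# basis table |j m k>, j = 0..l
.fp_basis <- function(l) {
  rows <- do.call(rbind, lapply(0:l, function(j) {
    expand.grid(k = -j:j, m = -j:j, j = j)[, c("j", "m", "k")]
  }))
  rows$idx <- seq_len(nrow(rows))
  rows
}

# multiplication operator by D^2_{mu nu}(Omega) in the normalized Wigner
# basis f_{jmk} = sqrt(2j+1) Conj(D^j_{mk}).  From the Gaunt integral of
# three Wigner functions,
#   <j_r m_r k_r| D^2_{mu nu} |j_c m_c k_c> =
#     sqrt((2 j_r + 1)/(2 j_c + 1)) C(j_r m_r 2 mu | j_c m_c)
#                                   C(j_r k_r 2 nu | j_c k_c)
# nonzero for m_c = m_r + mu, k_c = k_r + nu, |j_r - j_c| <= 2.
.fp_mult_d2 <- function(basis, mu, nu) {
  n <- nrow(basis)
  M <- matrix(0, n, n)
  for (row in seq_len(n)) {
    jr <- basis$j[row]; mr <- basis$m[row]; kr <- basis$k[row]
    sel <- which(basis$m == mr + mu & basis$k == kr + nu &
                   abs(basis$j - jr) <= 2)
    for (col in sel) {
      jc <- basis$j[col]
      M[row, col] <- sqrt((2 * jr + 1) / (2 * jc + 1)) *
        clebsch_gordan(jr, mr, 2, mu, jc, mr + mu) *
        clebsch_gordan(jr, kr, 2, nu, jc, kr + nu)
    }
  }
  M
}

# lab-space angular momentum operators in the normalized Wigner basis
# (space-fixed index m):  Lz f_{jmk} = m f_{jmk},
# L+- f_{jmk} = sqrt(j(j+1) - m(m+-1)) f_{j,m+-1,k}
.fp_angmom <- function(basis) {
  n <- nrow(basis)
  Lz <- diag(basis$m) + 0i
  Lp <- matrix(0i, n, n)
  for (col in seq_len(n)) {
    j <- basis$j[col]; m <- basis$m[col]; k <- basis$k[col]
    if (m < j) {
      row <- which(basis$j == j & basis$m == m + 1 & basis$k == k)
      Lp[row, col] <- sqrt(j * (j + 1) - m * (m + 1))
    }
  }
  Lm <- Conj(t(Lp))
  list(Lx = (Lp + Lm) / 2, Ly = (Lp - Lm) / (2i), Lz = Lz)
}

#' Fokker-Planck generator of the spinning problem
#'
#' Builds the time-independent generator on (rotation functions up to rank
#' `l`) x (spin Liouville space): the orientation-dependent Hamiltonian
#' commutation superoperator expanded over Wigner multiplication operators,
#' plus the spinning term `omega_mas * (n . L)` about the magic-angle rotor
#' axis.  The spherical average is built in: inject and detect in the
#' uniform `|j=0>` component and no orientation loop is needed.
#'
#' @param parts interaction set from [build_interactions()].
#' @param omega_mas spinning rate (rad/s).
#' @param l rotation-space cut-off rank; the dimension factor over the spin
#'   Liouville space is `(1+l)(1+2l)(3+2l)/3`.
#' @return list with dense Hermitian generator `LF` (evolution
#'   `exp(-i LF t)`), `basis`, `l`, `d` (spin Hilbert dimension), and the
#'   embedded uniform-component index range.
#' @export
build_fokker_planck <- function(parts, omega_mas, l) {
  basis <- .fp_basis(l)
  nrot <- nrow(basis)
  stopifnot(nrot == (1 + l) * (1 + 2 * l) * (3 + 2 * l) / 3)
  d <- parts$dim
  d2 <- d * d
  Id_rot <- diag(nrot)
  G <- kronecker(Id_rot, commutation_superop(parts$H_static)) + 0i
  # interaction terms: H(Omega) = sum_{q,k} (-1)^k a^cr_k D^2_{-q,-k}(Omega)
  #                                (-1)^q ... assembled as in rotate_components
  for (int in parts$ints) {
    av <- as.complex(int$a_cr)
    for (q in -2:2) {
      Tq <- commutation_superop(int$Tset[[tensor_name(-q)]])
      if (max(Mod(Tq)) == 0) next
      for (k in -2:2) {
        coef <- (-1)^q * (-1)^k * av[[k + 3L]]
        if (Mod(coef) == 0) next
        M <- .fp_mult_d2(basis, -q, -k)
        if (max(abs(M)) == 0) next
        G <- G + coef * kronecker(M, Tq)
      }
    }
  }
  # spinning term about the magic-angle-tilted axis n = (sin tm, 0, cos tm)
  L <- .fp_angmom(basis)
  tm <- magic_angle()
  Ln <- sin(tm) * L$Lx + cos(tm) * L$Lz
  G <- G + omega_mas * kronecker(Ln, diag(d2))
  uniform <- which(basis$j == 0)
  list(LF = G, basis = basis, l = l, d = d, omega_mas = omega_mas,
       uniform = uniform)
}

#' Powder spectrum from the Fokker-Planck generator
#'
#' Free-evolution powder spectrum with the initial state and detection
#' state embedded in the uniform orientation component; each frequency
#' point is a direct resolvent solve (see [fd_spectrum()]).
#'
#' @param fp generator from [build_fokker_planck()].
#' @param rho0,detect spin-space operators (d x d matrices).
#' @param freq_abs absolute angular frequencies (rad/s).
#' @param lb Lorentzian broadening (Hz).
#' @param method `"eig"` (one Hermitian eigendecomposition, then Lorentzian
#'   sums; default) or `"solve"` (per-point resolvent solves).
#' @return complex amplitudes.
#' @export
fp_spectrum <- function(fp, rho0, detect, freq_abs, lb,
                        method = c("eig", "solve")) {
  method <- match.arg(method)
  d2 <- fp$d^2
  n <- nrow(fp$LF)
  i0 <- (fp$uniform - 1L) * d2
  v_rho <- complex(n); v_rho[(i0 + 1):(i0 + d2)] <- vec_op(rho0)
  v_det <- complex(n); v_det[(i0 + 1):(i0 + d2)] <- vec_op(detect)
  if (method == "solve") {
    return(fd_spectrum(fp$LF, lb, v_rho, v_det, freq_abs))
  }
  e <- eigen(fp$LF, symmetric = TRUE)
  c_det <- Conj(t(e$vectors)) %*% v_det
  c_rho <- Conj(t(e$vectors)) %*% v_rho
  m <- Conj(c_det) * c_rho
  r <- pi * lb
  K <- 1 / (r + 1i * outer(e$values, freq_abs, "-"))
  as.vector(crossprod(m, K))
}
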