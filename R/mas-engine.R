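# Magic-angle spinning engine: rotor-frame Fourier components, Floquet
# embeddings (Hilbert and Liouville space), spherical quadrature and the
# brute-force laboratory-frame time-sliced oracle.
#
# Geometry: crystal-frame tensors are rotated into the rotor frame by
# R0 = Ry(beta) Rz(alpha); the rotor-fixed frame spins about its own z axis
# (phase omega_mas * t + gamma, gamma averaged analytically by the
# embedding) and is tilted by the magic angle towards the laboratory z.
# The MAS Hamiltonian is H(t) = H_0 + sum_{m != 0} H_m exp(i m phi(t)) with
# phi = omega_mas t + gamma and H_{-m} = H_m^dagger.

#' Rotor-frame Fourier components of the MAS Hamiltonian
#'
#' @param parts interaction set from [build_interactions()].
#' @param alpha,beta crystallite orientation (radians): crystal-to-rotor
#'   rotation `Ry(beta) Rz(alpha)`.
#' @return list of 5 complex matrices `H_m`, m = -2..2, with the static
#'   (orientation-independent) Hamiltonian folded into `m = 0`.
#' @export
ham_fourier <- function(parts, alpha, beta) {
  d <- parts$dim
  Dtilt <- wigner_d2(0, magic_angle(), 0)
  D0 <- wigner_d2(0, beta, alpha)
  Hm <- rep(list(matrix(0i, d, d)), 5)
  names(Hm) <- paste0("m=", -2:2)
  for (int in parts$ints) {
    a_rot <- rotate_components(int$a_cr, D0, new_frame = "rotor")
    av <- as.complex(a_rot)
    for (m in -2:2) {
      if (Mod(av[[m + 3L]]) == 0) next
      mask <- rep(0i, 5); mask[m + 3L] <- av[[m + 3L]]
      # masked components picked up the tilt rotation only; Hermiticity of
      # the single-m piece does not hold in isolation, so bypass sph_tensor
      a_lab <- .rotate_raw(mask, Dtilt)
      Hm[[m + 3L]] <- Hm[[m + 3L]] + assemble_term(a_lab, int$Tset)
    }
  }
  Hm[[3L]] <- Hm[[3L]] + parts$H_static
  Hm
}

# rotate a bare component vector without Hermiticity validation
.rotate_raw <- function(av, D) {
  k <- -2:2
  sgn <- (-1)^k
  vapply(k, function(q) {
    sum(sgn * av * D[cbind(rep(-q + 3L, 5L), -k + 3L)]) * (-1)^q
  }, complex(1))
}

#' Hilbert-space Floquet Hamiltonian
#'
#' Time-independent embedding of the MAS problem on Fourier space x Hilbert
#' space: block (p, q) of the generator is `H_{p-q}` for `|p-q| <= 2` plus a
#' diagonal ladder `p * omega_mas`.  The physical propagator at spinner
#' phase gamma is recovered as
#' `U(t; gamma) = sum_p exp(i p (omega_mas t + gamma)) <p| exp(-i H_F t) |0>`;
#' detecting with the initial state injected in the p = 0 block and the
#' observable replicated on every block yields the spinner-phase-averaged
#' signal directly.
#'
#' @param Hm Fourier components from [ham_fourier()].
#' @param omega_mas spinning rate (rad/s).
#' @param l Fourier cut-off rank (>= 0); dimension grows by `2l + 1`.
#' @return list with dense Hermitian `HF`, `l`, `d`, `omega_mas`.
#' @export
build_floquet_h <- function(Hm, omega_mas, l) {
  d <- nrow(Hm[[1]])
  nb <- 2L * l + 1L
  HF <- matrix(0i, nb * d, nb * d)
  for (ip in seq_len(nb)) {
    p <- ip - l - 1L
    for (iq in seq_len(nb)) {
      q <- iq - l - 1L
      m <- p - q
      if (abs(m) <= 2L) {
        blk <- Hm[[m + 3L]]
        if (p == q) blk <- blk + diag(p * omega_mas, d)
        HF[((ip - 1L) * d + 1L):(ip * d), ((iq - 1L) * d + 1L):(iq * d)] <- blk
      }
    }
  }
  list(HF = HF, l = l, d = d, omega_mas = omega_mas)
}

#' Liouville-space Floquet generator
#'
#' The commutation-superoperator counterpart of [build_floquet_h()]: block
#' (p, q) is the commutation superoperator of `H_{p-q}` plus the ladder
#' `p * omega_mas` on the diagonal.  Dimension `(2l+1) * d^2`.  This is the
#' generator consumed by [fd_spectrum()]'s resolvent solves and compared
#' against the Fokker-Planck picture.
#'
#' @inheritParams build_floquet_h
#' @return list with dense complex `LF`, `l`, `d`, `omega_mas`.
#' @export
build_floquet <- function(Hm, omega_mas, l) {
  d <- nrow(Hm[[1]])
  d2 <- d * d
  nb <- 2L * l + 1L
  LF <- matrix(0i, nb * d2, nb * d2)
  Lm <- lapply(Hm, commutation_superop)
  for (ip in seq_len(nb)) {
    p <- ip - l - 1L
    for (iq in seq_len(nb)) {
      q <- iq - l - 1L
      m <- p - q
      if (abs(m) <= 2L) {
        blk <- Lm[[m + 3L]]
        if (p == q) blk <- blk + diag(p * omega_mas, d2)
        LF[((ip - 1L) * d2 + 1L):(ip * d2), ((iq - 1L) * d2 + 1L):(iq * d2)] <- blk
      }
    }
  }
  list(LF = LF, l = l, d = d, omega_mas = omega_mas)
}

#' Floquet dimension factors
#'
#' `2l + 1` for the Floquet embedding and `(1 + l)(1 + 2l)(3 + 2l)/3` for
#' the Fokker-Planck embedding.
#' @param l cut-off rank.
#' @return named numeric vector.
#' @export
dimension_factors <- function(l) {
  c(floquet = 2 * l + 1,
    fokker_planck = (1 + l) * (1 + 2 * l) * (3 + 2 * l) / 3)
}

# embed an operator in Fourier block p = 0 (as a full matrix)
.block0 <- function(op, l) {
  nb <- 2L * l + 1L
  d <- nrow(op)
  M <- matrix(0i, nb * d, nb * d)
  i0 <- l * d
  M[(i0 + 1L):(i0 + d), (i0 + 1L):(i0 + d)] <- op
  M
}

# replicate an operator on every Fourier block
.blockdiag <- function(op, l) {
  kronecker(diag(2L * l + 1L), op)
}

#' Physical propagator from a Floquet-space propagator
#'
#' `U(t; gamma) = sum_p exp(i p (omega_mas t + gamma)) <p|U_F|0>` for a
#' Floquet-space propagator `UF` accumulated over total elapsed time
#' `t_end`.  Used by the oracle-equivalence tests; powder detection never
#' needs it.
#'
#' @param UF Floquet-space propagator matrix.
#' @param fl Floquet descriptor (from [build_floquet_h()]).
#' @param t_end total elapsed time (s).
#' @param gamma spinner phase (radians).
#' @return complex d x d matrix.
#' @export
floquet_physical_u <- function(UF, fl, t_end, gamma = 0) {
  d <- fl$d; l <- fl$l
  U <- matrix(0i, d, d)
  i0 <- l * d
  for (p in -l:l) {
    ip <- (p + l) * d
    U <- U + exp(1i * p * (fl$omega_mas * t_end + gamma)) *
      UF[(ip + 1L):(ip + d), (i0 + 1L):(i0 + d)]
  }
  U
}

# Hermitian matrix exponential exp(-i H t) via eigendecomposition
expm_herm <- function(H, t) {
  e <- eigen(H, symmetric = TRUE)
  e$vectors %*% (exp(-1i * e$values * t) * Conj(t(e$vectors)))
}

#' Brute-force laboratory-frame oracle
#'
#' Piecewise-constant time-sliced propagation of the full time-dependent
#' Hamiltonian (MAS modulation and, optionally, the oscillating overtone RF
#' term) at one crystallite orientation and one explicit spinner phase.
#' Used as an independent reference for the Floquet / effective-Hamiltonian
#' pipeline on reduced problems; far too slow for production use, which is
#' exactly why the embedding machinery exists.
#'
#' @param parts interaction set from [build_interactions()].
#' @param alpha,beta crystallite orientation (radians).
#' @param omega_mas spinning rate (rad/s).
#' @param gamma spinner phase at t = 0 (radians).
#' @param t_end propagation time (s).
#' @param dt time step (s); must resolve the fastest oscillation (at least
#'   2 points per overtone RF period when a pulse is active, checked).
#' @param rf optional overtone RF specification from [rf_channel()]; `NULL`
#'   propagates free evolution.
#' @return complex d x d propagator over `[0, t_end]`.
#' @export
lab_frame_oracle <- function(parts, alpha, beta, omega_mas, gamma = 0,
                             t_end, dt, rf = NULL) {
  Hm <- ham_fourier(parts, alpha, beta)
  d <- parts$dim
  if (!is.null(rf)) {
    w_c <- rf$carrier
    if (dt > pi / w_c) {
      stop("time step too coarse: need >= 2 points per overtone RF period (",
           signif(2 * pi / w_c * 1e9, 4), " ns)")
    }
    Wrf <- rf_operator(rf, parts)
  }
  n <- ceiling(t_end / dt)
  dt <- t_end / n
  U <- diag(d) + 0i
  for (j in seq_len(n)) {
    tm <- (j - 0.5) * dt                     # midpoint sampling
    ph <- exp(1i * (-2:2) * (omega_mas * tm + gamma))
    H <- matrix(0i, d, d)
    for (m in 1:5) H <- H + ph[m] * Hm[[m]]
    if (!is.null(rf)) {
      H <- H + rf$a_rf * cos(w_c * tm + rf$phase) * Wrf
    }
    U <- expm_herm(H, dt) %*% U
  }
  U
}

# ---- spherical quadrature -------------------------------------------------

#' Spherical quadrature grid for powder averaging
#'
#' Two-angle grid of crystallite orientations `(alpha, beta)` with weights
#' summing to 1, exact for all spherical harmonics up to the requested
#' order.  The construction is a Gauss-Legendre rule in `cos(beta)`
#' (`ceiling((order+1)/2)` nodes) crossed with an equiangular azimuthal rule
#' (`order + 1` nodes) - the same polynomial-exactness class as a Lebedev
#' set of equal order, at about 1.5x the points.  The third (spinner-phase)
#' angle is averaged analytically by the Floquet / Fokker-Planck embedding,
#' so the powder average over this grid is a full three-angle average.
#'
#' @param order polynomial exactness order (integer >= 1).  The fixtures
#'   request orders 77 (glycine) and 131 (NAV); reduced desk-scale runs use
#'   29-53.
#' @param strict if `FALSE` (default) a non-integer order is rounded up
#'   with a message; `TRUE` rejects it.
#' @return data.frame with columns `alpha`, `beta`, `weight`.
#' @export
#' @examples
#' g <- spherical_grid(29)
#' sum(g$weight)          # 1
spherical_grid <- function(order, strict = FALSE) {
  if (order < 1) stop("order must be >= 1")
  if (order != round(order)) {
    if (strict) stop("non-integer grid order in strict mode: ", order)
    message("rounding grid order up to ", ceiling(order))
    order <- ceiling(order)
  }
  n_beta <- ceiling((order + 1) / 2)
  n_alpha <- order + 1L
  gl <- gauss_legendre(n_beta)
  beta <- acos(gl$nodes)
  alpha <- 2 * pi * (seq_len(n_alpha) - 1L) / n_alpha
  out <- expand.grid(alpha = alpha, beta = beta)
  wb <- rep(gl$weights / 2, each = n_alpha)
  out$weight <- wb / n_alpha
  attr(out, "order") <- order
  out
}

#' Gauss-Legendre nodes and weights on the interval -1 to 1
#'
#' Golub-Welsch: eigen-decomposition of the symmetric Jacobi matrix.
#' @param n number of nodes.
#' @return list with `nodes` (increasing) and `weights` (sum 2).
#' @export
gauss_legendre <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 2))
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * e$vectors[1, idx]^2)
}
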