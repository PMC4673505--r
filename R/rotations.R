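# Rotations: Euler angles, angle-axis, rank-2 Wigner matrices.
#
# Convention (fixed package-wide): ZYZ Euler angles, active rotations,
# R(alpha, beta, gamma) = Rz(alpha) Ry(beta) Rz(gamma).  The corresponding
# unitary on a spin is U = exp(-i alpha Sz) exp(-i beta Sy) exp(-i gamma Sz)
# and the rank-l Wigner matrix is D^l_{mk} = exp(-i m alpha) d^l_{mk}(beta)
# exp(-i k gamma), indices ordered m = -l..l.  With these choices
# U T_{l,k} U^dagger = sum_m D^l_{mk} T_{l,m} and D(R1 %*% R2) = D(R1) D(R2).

# angular momentum matrices for j = 2 (basis m = +2..-2, same phase
# convention as spin_operators); d^2(beta) is evaluated exactly as
# exp(-i beta Jy) rather than from a transcribed closed-form table
.j2_matrices <- function() {
  m <- 2:-2
  n <- 5L
  Jz <- diag(m) + 0i
  Jp <- matrix(0i, n, n)
  for (j in seq_len(n - 1L)) {
    mm <- m[j + 1L]
    Jp[j, j + 1L] <- sqrt(2 * 3 - mm * (mm + 1))
  }
  Jm <- Conj(t(Jp))
  list(Jy = (Jp - Jm) / (2i), Jz = Jz)
}

# eigen-decomposition of Jy (j = 2), cached
.j2y_cache <- new.env(parent = emptyenv())
.j2y_decomp <- function() {
  if (is.null(.j2y_cache$V)) {
    e <- eigen(.j2_matrices()$Jy, symmetric = TRUE)
    .j2y_cache$V <- e$vectors
    .j2y_cache$d <- e$values          # 2,1,0,-1,-2 up to ordering
  }
  .j2y_cache
}

#' Reduced Wigner matrix d^2(beta)
#'
#' Evaluated exactly as `exp(-i beta Jy)` with the spin-2 angular-momentum
#' matrix; real to machine precision.  Rows/columns ordered m = -2..2.
#'
#' @param beta rotation angle about y (radians).
#' @return real 5x5 matrix.
#' @export
wigner_d2_beta <- function(beta) {
  ee <- .j2y_decomp()
  M <- ee$V %*% (exp(-1i * beta * ee$d) * Conj(t(ee$V)))
  # basis of .j2_matrices is m = +2..-2; flip to -2..2
  M <- Re(M)[5:1, 5:1]
  dimnames(M) <- list(paste0("m=", -2:2), paste0("k=", -2:2))
  M
}

#' Rank-2 Wigner rotation matrix
#'
#' `D^2_{mk}(alpha, beta, gamma) = exp(-i m alpha) d^2_{mk}(beta)
#' exp(-i k gamma)`, rows m = -2..2, columns k = -2..2.  Either Euler angles
#' or an angle-axis pair may be given; the two parameterizations agree:
#' `wigner_d2(axis = n, phi = phi)` equals `wigner_d2()` of the equivalent
#' Euler triple.
#'
#' @param alpha,beta,gamma ZYZ Euler angles (radians).
#' @param axis unit 3-vector; alternative angle-axis input.
#' @param phi rotation angle about `axis` (radians).
#' @return complex 5x5 unitary matrix with
#'   `D(R1) %*% D(R2) == D(R1 o R2)`.
#' @export
#' @examples
#' Dz <- wigner_d2(axis = c(0, 0, 1), phi = 0.3)   # diag(exp(-1i*m*0.3))
wigner_d2 <- function(alpha = 0, beta = 0, gamma = 0, axis = NULL, phi = NULL) {
  if (!is.null(axis) || !is.null(phi)) {
    if (is.null(axis) || is.null(phi)) stop("give both axis and phi")
    if (abs(sqrt(sum(axis^2)) - 1) > 1e-10) stop("axis must be unit-norm")
    eul <- axis_angle_to_euler(axis, phi)
    alpha <- eul[1]; beta <- eul[2]; gamma <- eul[3]
  }
  m <- -2:2
  ph_m <- exp(-1i * m * alpha)
  ph_k <- exp(-1i * m * gamma)
  D <- (ph_m %o% ph_k) * wigner_d2_beta(beta)
  dimnames(D) <- list(paste0("m=", m), paste0("k=", m))
  D
}

#' 3x3 rotation matrix from ZYZ Euler angles (active)
#' @param alpha,beta,gamma Euler angles (radians).
#' @return orthogonal 3x3 matrix `Rz(alpha) Ry(beta) Rz(gamma)`.
#' @export
euler_to_rotmat <- function(alpha, beta, gamma) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

#' ZYZ Euler angles from a 3x3 rotation matrix
#' @param R orthogonal matrix with det +1.
#' @return numeric c(alpha, beta, gamma), beta between 0 and pi.
#' @export
rotmat_to_euler <- function(R) {
  cb <- max(-1, min(1, R[3, 3]))
  beta <- acos(cb)
  if (abs(sin(beta)) > 1e-12) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else {
    # beta ~ 0 or pi: only alpha + sign*gamma defined; put it all in alpha
    gamma <- 0
    if (cb > 0) alpha <- atan2(R[2, 1], R[1, 1])
    else        alpha <- atan2(-R[2, 1], -R[1, 1])
  }
  c(alpha = alpha, beta = beta, gamma = gamma)
}

#' Euler angles of a rotation given in angle-axis form
#' @param axis unit 3-vector.
#' @param phi rotation angle (radians).
#' @return numeric c(alpha, beta, gamma).
#' @export
axis_angle_to_euler <- function(axis, phi) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(phi) * K + (1 - cos(phi)) * (K %*% K)
  rotmat_to_euler(R)
}

#' Powder/crystallite orientation
#'
#' A single crystallite orientation with quadrature weight.  The simulator's
#' two-angle convention: the crystal (quadrupole-eigenframe) tensors are
#' rotated into the rotor-fixed frame by `Ry(beta) Rz(alpha)`; the rotation
#' about the rotor axis itself (the spinner phase) is averaged analytically
#' by the Floquet/Fokker-Planck embedding.
#'
#' @param alpha azimuthal angle (radians).
#' @param beta polar angle (radians).
#' @param weight quadrature weight (grid weights sum to 1).
#' @return object of class `"orientation"`.
#' @export
orientation <- function(alpha, beta, weight = 1) {
  structure(list(alpha = alpha, beta = beta, weight = weight),
            class = "orientation")
}
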