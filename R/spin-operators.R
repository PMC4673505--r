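# Angular-momentum operator algebra.
#
# Basis convention throughout the package: Zeeman eigenstates ordered by
# decreasing magnetic quantum number, |S>, |S-1>, ..., |-S>.

#' Cartesian and shift spin operators
#'
#' Standard angular-momentum matrices for a single spin.  Matrix elements
#' follow the Condon-Shortley phase convention,
#' `S+ |S,m> = sqrt(S(S+1) - m(m+1)) |S,m+1>`.
#'
#' @param S spin quantum number; 1/2 and 1 are supported (the simulator's
#'   systems are a spin-1 nitrogen-14 and spin-1/2 protons).
#' @return a list with complex matrices `Sx`, `Sy`, `Sz`, `Sp`, `Sm`, `Id`
#'   of dimension `2S+1`, plus the spin quantum number `S`.
#' @export
#' @examples
#' ops <- spin_operators(1)
#' ops$Sx %*% ops$Sy - ops$Sy %*% ops$Sx   # equals 1i * Sz
spin_operators <- function(S) {
  if (!isTRUE(S %in% c(0.5, 1))) {
    stop("unsupported spin quantum number S = ", S, "; supported: 1/2, 1")
  }
  m <- seq(S, -S)                      # decreasing m
  n <- length(m)
  Sz <- diag(m) + 0i
  Sp <- matrix(0i, n, n)
  # S+ raises m: couples |m> (column j) to |m+1> (row j-1)
  for (j in seq_len(n - 1L)) {
    mm <- m[j + 1L]
    Sp[j, j + 1L] <- sqrt(S * (S + 1) - mm * (mm + 1))
  }
  Sm <- Conj(t(Sp))
  list(
    Sx = (Sp + Sm) / 2,
    Sy = (Sp - Sm) / (2i),
    Sz = Sz,
    Sp = Sp,
    Sm = Sm,
    Id = diag(n) + 0i,
    S  = S
  )
}

#' Irreducible spherical tensor operators
#'
#' Spherical tensor operators T_{l,k} for a single spin, built by repeated
#' lowering from the maximal component
#' `T_{l,l} = (-1)^l sqrt((2l)! ) / (2^l l!) * Sp^l` (up to the fixed overall
#' normalization below), so that `[Sz, T_{l,k}] = k T_{l,k}` and
#' `[S-, T_{l,k}] = sqrt(l(l+1) - k(k-1)) T_{l,k-1}`.
#'
#' Normalization is fixed so that `T_{2,0} = (3 Sz^2 - S(S+1) Id) / sqrt(6)`,
#' `T_{2,+-1} = -+ (Sz S+- + S+- Sz) / 2`, `T_{2,+-2} = S+-^2 / 2`, and
#' `T_{1,0} = Sz`, `T_{1,+-1} = -+ S+- / sqrt(2)`.  The convention is private;
#' the public contract is the set of commutation properties above and the
#' first-order quadrupolar splitting oracle tested in the suite.
#'
#' @param S spin quantum number (1/2 or 1).
#' @param l tensor rank, `l <= 2S`.
#' @return named list of complex matrices, names `"k=-l"` ... `"k=+l"`, in
#'   increasing k order; access components with the `tensor_name()` helper.
#' @export
irreducible_tensors <- function(S, l) {
  if (l > 2 * S) stop("rank l = ", l, " exceeds 2S = ", 2 * S)
  if (l < 0 || l != round(l)) stop("rank l must be a non-negative integer")
  ops <- spin_operators(S)
  n <- nrow(ops$Sz)
  out <- vector("list", 2 * l + 1)
  names(out) <- paste0("k=", seq(-l, l))
  if (l == 0) {
    out[[1]] <- ops$Id
    return(out)
  }
  # top component, fixed normalization
  Tk <- if (l == 1) {
    -ops$Sp / sqrt(2)
  } else {                                   # l == 2
    ops$Sp %*% ops$Sp / 2
  }
  out[[tensor_name(l, l)]] <- Tk
  for (k in seq(l, -l + 1L)) {
    # [S-, T_{l,k}] = sqrt(l(l+1) - k(k-1)) T_{l,k-1}
    Tk <- (ops$Sm %*% Tk - Tk %*% ops$Sm) / sqrt(l * (l + 1) - k * (k - 1))
    out[[tensor_name(k - 1L, l)]] <- Tk
  }
  out
}

#' Index helper for tensor component lists
#' @param k component index, -l..l.
#' @param l rank (used only for validation).
#' @return the list name `"k=<k>"`.
#' @export
tensor_name <- function(k, l = 2L) {
  if (abs(k) > l) stop("component |k| > l")
  paste0("k=", k)
}

#' Hamiltonian commutation superoperator
#'
#' Returns the matrix of `rho -> H rho - rho H` acting on column-stacked
#' (column-major `vec`) density matrices.
#'
#' @param H square (Hermitian) matrix.
#' @return dense complex matrix of dimension `n^2`.
#' @export
commutation_superop <- function(H) {
  if (!is.matrix(H) || nrow(H) != ncol(H)) stop("H must be a square matrix")
  n <- nrow(H)
  Id <- diag(n)
  kronecker(Id, H) - kronecker(t(H), Id)
}

# vec / unvec helpers (column-major)
vec_op <- function(A) as.vector(A)
unvec_op <- function(v) {
  n <- as.integer(round(sqrt(length(v))))
  matrix(v, n, n)
}
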