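# Symmetry-based RN_n^nu recoupling: rotor-synchronized phase-alternated
# pi-pulse trains and their first-order selection rules.

#' R-symmetry specification
#'
#' `N` pi-pulse elements fit exactly in `n` rotor periods; the element
#' phase is `phi_R = pi nu / N`, alternated between `+phi_R` and `-phi_R`
#' (the repeating unit is the two-element composite
#' `180_{+phi} 180_{-phi}`, carrying an overall block phase of 0 or 90
#' degrees for the excitation and reconversion blocks respectively).  The
#' proton RF amplitude follows from rotor synchronization: a pi rotation in
#' one element slot of `n tau_r / N` requires `1 / (2 n tau_r / N)` Hz -
#' 89.28 kHz for both R18 symmetries used with the fixtures (R18_2^5 at
#' 19.84 kHz and R18_1^7 at 9.92 kHz spinning).
#'
#' @param N even number of R elements per cycle.
#' @param n number of rotor periods per cycle.
#' @param nu winding number fixing the phase `pi nu / N`.
#' @param mas_hz spinning frequency (Hz).
#' @return object of class `"r_symmetry"` with `element_s` (single-element
#'   duration), `phi_r`, `amp_hz`, `tau_r`.
#' @export
#' @examples
#' r_symmetry(18, 2, 5, 19.84e3)$amp_hz   # 89.28 kHz
r_symmetry <- function(N, n, nu, mas_hz) {
  if (N %% 2 != 0) stop("N must be even")
  if (n < 1 || n != round(n)) stop("n must be a positive integer")
  tau_r <- 1 / mas_hz
  element_s <- n * tau_r / N
  structure(list(N = as.integer(N), n = as.integer(n), nu = as.integer(nu),
                 tau_r = tau_r, element_s = element_s,
                 phi_r = pi * nu / N, amp_hz = 1 / (2 * element_s)),
            class = "r_symmetry")
}

#' @export
print.r_symmetry <- function(x, ...) {
  cat(sprintf("R%d_%d^%d: phi_R = %.1f deg, element %.4g us, 1H amplitude %.4g kHz\n",
              x$N, x$n, x$nu, x$phi_r * 180 / pi, x$element_s * 1e6,
              x$amp_hz / 1e3))
  invisible(x)
}

#' Phase schedule of an R block
#'
#' Alternating `+phi_R, -phi_R, ...` plus an overall block phase, wrapped
#' to `[0, 2 pi)`.  The sum of any consecutive pair equals twice the block
#' phase (mod 2 pi).
#'
#' @param sym [r_symmetry()].
#' @param n_elements number of elements (must be even: whole composite
#'   units).
#' @param block_phase overall phase added to every element (radians);
#'   0 for the excitation block, `pi/2` for reconversion.
#' @return numeric vector of phases (radians) in `[0, 2 pi)`.
#' @export
r_phase_list <- function(sym, n_elements, block_phase = 0) {
  if (n_elements %% 2 != 0) stop("n_elements must be even (whole composite units)")
  ph <- rep(c(sym$phi_r, -sym$phi_r), length.out = n_elements) + block_phase
  ph %% (2 * pi)
}

#' First-order selection rules of an R symmetry
#'
#' Exhaustively enumerates interaction components `{l, m, lambda, mu}`
#' (space rank/component, spin rank/component) with `|m| <= l <= l_max`
#' and `|mu| <= lambda <= lambda_max` and marks the ones recoupled to
#' first order: those with `m n - mu nu = (N/2) Z` for an integer witness
#' `Z` of the same parity as `lambda`.  For the R18 symmetries used here
#' (R18_2^5, R18_1^7) the recoupled space-rank-2 / spin-rank-1 set is
#' `{2, +-2, 1, -+1}` - CSA and heteronuclear dipole-dipole terms.
#'
#' @param N,n,nu symmetry numbers (N even).
#' @param l_max,lambda_max enumeration bounds (default 2).
#' @return data.frame with columns `l`, `m`, `lambda`, `mu`, `recoupled`,
#'   `Z` (the witness, NA when not recoupled).
#' @export
selection_rules <- function(N, n, nu, l_max = 2L, lambda_max = 2L) {
  if (N %% 2 != 0) stop("N must be even")
  rows <- list()
  for (l in 0:l_max) for (m in -l:l) {
    for (lambda in 0:lambda_max) for (mu in -lambda:lambda) {
      lhs <- m * n - mu * nu
      z <- lhs / (N / 2)
      ok <- abs(z - round(z)) < 1e-12 && (round(z) - lambda) %% 2 == 0
      rows[[length(rows) + 1L]] <- data.frame(
        l = l, m = m, lambda = lambda, mu = mu,
        recoupled = ok, Z = if (ok) as.integer(round(z)) else NA_integer_
      )
    }
  }
  do.call(rbind, rows)
}
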