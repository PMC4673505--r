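# Shared fixtures for the test suite: scaled-down spin systems for which
# the brute-force laboratory-frame oracle is affordable, and small helpers.

# single nitrogen-14, reduced Larmor frequency so that lab-frame time
# slicing is cheap; quadrupole small enough for low Floquet ranks
toy_system_1spin <- function(C_Q = 5e3, eta_Q = 0.4) {
  spin_system(C_Q = C_Q, eta_Q = eta_Q, label = "toy-1spin")
}

# two-spin toy (N-H) for pulse-oracle and transfer tests
toy_system_2spin <- function(C_Q = 1e5, eta_Q = 0.3, b_dd = -4e3) {
  spin_system(C_Q = C_Q, eta_Q = eta_Q, b_dd = b_dd, label = "toy-2spin")
}

# exact spherical-monomial integral over the unit sphere (normalized):
# mean of x^a y^b z^c = (a-1)!!(b-1)!!(c-1)!! / (a+b+c+1)!! for all even
# exponents, 0 otherwise.  Independent oracle for quadrature exactness.
sphere_monomial_mean <- function(a, b, c) {
  if (a %% 2 || b %% 2 || c %% 2) return(0)
  dfact <- function(n) if (n <= 0) 1 else prod(seq(n, 1, by = -2))
  dfact(a - 1) * dfact(b - 1) * dfact(c - 1) / dfact(a + b + c + 1)
}

# random Hermitian matrix
rand_herm <- function(n) {
  A <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  (A + Conj(t(A))) / 2
}

# unitary for Euler angles on a spin (active ZYZ)
spin_rotation <- function(S, alpha, beta, gamma) {
  ops <- spin_operators(S)
  ex <- function(G, a) {
    e <- eigen(G, symmetric = TRUE)
    e$vectors %*% (exp(-1i * a * e$values) * Conj(t(e$vectors)))
  }
  ex(ops$Sz, alpha) %*% ex(ops$Sy, beta) %*% ex(ops$Sz, gamma)
}
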