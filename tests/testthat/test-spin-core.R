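# Spin operators, irreducible tensors, interaction components, rotations.

test_that("spin operators satisfy the angular-momentum algebra", {
  for (S in c(1 / 2, 1)) {
    ops <- spin_operators(S)
    expect_equal(sort(Re(diag(ops$Sz))), seq(-S, S), tolerance = 1e-14)
    comm <- ops$Sx %*% ops$Sy - ops$Sy %*% ops$Sx
    expect_lt(max(Mod(comm - 1i * ops$Sz)), 1e-14)
    # ladder coefficient: S+ |S,-S> = sqrt(S(S+1) - (-S)(-S+1)) |S,-S+1>
    n <- nrow(ops$Sz)
    v <- rep(0, n); v[n] <- 1                      # m = -S
    w <- ops$Sp %*% v
    expect_equal(Mod(w[n - 1]), sqrt(S * (S + 1) + S * (-S + 1)),
                 tolerance = 1e-14)
  }
  # S = 1: S+ applied to m = -1 gives sqrt(2) x (m = 0)
  ops <- spin_operators(1)
  v <- c(0, 0, 1)
  expect_equal(as.vector(ops$Sp %*% v), c(0, sqrt(2), 0) + 0i, tolerance = 1e-14)
  expect_error(spin_operators(3 / 2), "unsupported")
})

test_that("irreducible tensors have the documented normalization and ranks", {
  ops <- spin_operators(1)
  Tk <- irreducible_tensors(1, 2)
  T20 <- (3 * ops$Sz %*% ops$Sz - 2 * ops$Id) / sqrt(6)
  expect_lt(max(Mod(Tk[[tensor_name(0)]] - T20)), 1e-14)
  # [Sz, T_{2,k}] = k T_{2,k} for every k
  for (k in -2:2) {
    Tkk <- Tk[[tensor_name(k)]]
    comm <- ops$Sz %*% Tkk - Tkk %*% ops$Sz
    expect_lt(max(Mod(comm - k * Tkk)), 1e-13)
  }
  # identity rotation leaves every component unchanged
  U <- spin_rotation(1, 0, 0, 0)
  for (k in -2:2) {
    expect_lt(max(Mod(U %*% Tk[[tensor_name(k)]] %*% Conj(t(U)) -
                        Tk[[tensor_name(k)]])), 1e-14)
  }
  expect_error(irreducible_tensors(1 / 2, 2), "exceeds")
})

test_that("Wigner matrices are unitary, compose, and rotate tensor operators", {
  set.seed(42)
  Tk <- irreducible_tensors(1, 2)
  for (i in 1:5) {
    eul <- c(runif(1, 0, 2 * pi), runif(1, 0, pi), runif(1, 0, 2 * pi))
    D <- wigner_d2(eul[1], eul[2], eul[3])
    expect_lt(max(Mod(D %*% Conj(t(D)) - diag(5))), 1e-12)
    # U T_{2,k} U^dagger = sum_m D_{mk} T_{2,m}: the convention anchor
    U <- spin_rotation(1, eul[1], eul[2], eul[3])
    for (k in c(-2, 0, 1)) {
      lhs <- U %*% Tk[[tensor_name(k)]] %*% Conj(t(U))
      rhs <- Reduce(`+`, lapply(-2:2, function(m) {
        D[m + 3, k + 3] * Tk[[tensor_name(m)]]
      }))
      expect_lt(max(Mod(lhs - rhs)), 1e-12)
    }
  }
  # composition equals matrix product
  R1 <- euler_to_rotmat(0.3, 1.1, -0.4); R2 <- euler_to_rotmat(2.0, 0.7, 0.9)
  e12 <- rotmat_to_euler(R1 %*% R2)
  expect_lt(max(Mod(wigner_d2(e12[1], e12[2], e12[3]) -
                      wigner_d2(0.3, 1.1, -0.4) %*% wigner_d2(2.0, 0.7, 0.9))),
            1e-12)
  # angle-axis about z is the diagonal phase matrix
  Dz <- wigner_d2(axis = c(0, 0, 1), phi = 0.37)
  expect_lt(max(Mod(Dz - diag(exp(-1i * (-2:2) * 0.37)))), 1e-12)
  # angle-axis agrees with the Euler parameterization for random axes
  set.seed(7)
  for (i in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); phi <- runif(1, -pi, pi)
    eul <- axis_angle_to_euler(ax, phi)
    expect_lt(max(Mod(wigner_d2(axis = ax, phi = phi) -
                        wigner_d2(eul[1], eul[2], eul[3]))), 1e-12)
  }
  expect_error(wigner_d2(axis = c(0, 0, 2), phi = 1), "unit")
})

test_that("quadrupolar components obey axial symmetry and the splitting oracle", {
  expect_error(quad_pas_components(1e6, 1.2), "eta_Q")
  a0 <- quad_pas_components(1e6, 0)
  expect_equal(Mod(a0[[tensor_name(2)]]), 0)
  # glycine inputs give a Hermitian Hamiltonian term
  ag <- quad_pas_components(1.18e6, 0.53)
  H <- assemble_term(ag, irreducible_tensors(1, 2))
  expect_lt(max(Mod(H - Conj(t(H)))), 1e-9 * max(Mod(H)))
  # static crystal, eta = 0, PAS || B0: first-order single-quantum
  # splitting equals (3/2) C_Q, by numerical diagonalization
  C_Q <- 1.18e6
  ops <- spin_operators(1)
  wz <- 2 * pi * 43.3724e6
  Hs <- wz * ops$Sz + assemble_term(quad_pas_components(C_Q, 0),
                                    irreducible_tensors(1, 2))
  E <- sort(Re(eigen(Hs, symmetric = TRUE)$values), decreasing = TRUE)
  f_hi <- (E[1] - E[2]) / (2 * pi)   # (+1 <-> 0)
  f_lo <- (E[2] - E[3]) / (2 * pi)   # (0 <-> -1)
  expect_equal(abs(f_hi - f_lo) / C_Q, 1.5, tolerance = 1e-6)
})

test_that("CSA components scale linearly and vanish for zero anisotropy", {
  wz <- 2 * pi * 43.3724e6
  z <- csa_pas_components(32.4, 0, 0, wz)
  expect_equal(max(Mod(z$aniso)), 0)
  expect_equal(z$iso_offset, 32.4e-6 * wz)
  nav <- csa_pas_components(121, 105, 0.23, wz)
  expect_lt(Mod(nav$aniso[[tensor_name(1)]]), 1e-12)
  nav2 <- csa_pas_components(121, 105, 0.23, 2 * wz)
  expect_equal(as.complex(nav2$aniso), 2 * as.complex(nav$aniso),
               tolerance = 1e-14)
})

test_that("dipolar constant follows the r^-3 law and CODATA magnitude", {
  gH <- nmr_gamma("1H"); gN <- nmr_gamma("14N")
  b1 <- dipolar_constant(1.06, gH, gN)
  b2 <- dipolar_constant(2.12, gH, gN)
  expect_equal(b1 / b2, 8, tolerance = 1e-12)
  # direct evaluation of -(mu0/4pi) gamma1 gamma2 hbar / r^3 in Hz
  expect_equal(b1, -7290.8, tolerance = 1e-4)
  expect_lt(b1, 0)
  expect_error(dipolar_constant(-1, gH, gN), "positive")
})

test_that("rotating components preserves Hermiticity and the invariant", {
  set.seed(11)
  a <- quad_pas_components(1.18e6, 0.53)
  inv <- sum(Mod(a)^2)
  for (i in 1:100) {
    eul <- c(runif(1, 0, 2 * pi), runif(1, 0, pi), runif(1, 0, 2 * pi))
    ar <- rotate_components(a, wigner_d2(eul[1], eul[2], eul[3]))
    expect_equal(sum(Mod(ar)^2), inv, tolerance = 1e-12)
  }
  # identity rotation: unchanged
  ai <- rotate_components(a, wigner_d2(0, 0, 0))
  expect_equal(as.complex(ai), as.complex(a), tolerance = 1e-14)
  # eta = 0 quadrupole tipped by beta = pi/2: analytic d^2 redistribution
  a0 <- quad_pas_components(1e6, 0)
  ar <- rotate_components(a0, wigner_d2(0, pi / 2, 0))
  w0 <- as.complex(a0)[[3]]
  expect_equal(as.complex(ar)[[3]], -w0 / 2, tolerance = 1e-12)   # d2_00 = -1/2
  expect_equal(as.complex(ar)[[5]], sqrt(3 / 8) * w0, tolerance = 1e-12)
})

test_that("commutation superoperator acts as H rho - rho H", {
  set.seed(5)
  H <- rand_herm(3)
  L <- commutation_superop(H)
  for (i in 1:5) {
    r <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3)
    expect_lt(max(Mod(unvec_op(L %*% vec_op(r)) - (H %*% r - r %*% H))), 1e-12)
  }
  # eigenvalues are all pairwise differences of the eigenvalues of H
  ev <- sort(Re(eigen(L)$values))
  eh <- eigen(H, symmetric = TRUE)$values
  expect_equal(ev, sort(as.vector(outer(eh, eh, "-"))), tolerance = 1e-8)
  # linearity and the identity map to zero
  H2 <- rand_herm(3)
  expect_lt(max(Mod(commutation_superop(H + H2) -
                      (L + commutation_superop(H2)))), 1e-12)
  expect_equal(max(Mod(commutation_superop(diag(3) + 0i))), 0)
  expect_error(commutation_superop(matrix(1, 2, 3)), "square")
})
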