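# R-symmetry algebra, selection rules, and the pulse-sequence library on
# reduced systems (full-fixture behaviour is exercised by the acceptance
# suite).

test_that("R-symmetry timing closes: N pi pulses in n rotor periods at 89.28 kHz", {
  s1 <- r_symmetry(18, 2, 5, 19.84e3)
  expect_equal(s1$N * s1$element_s, s1$n * s1$tau_r, tolerance = 1e-12)
  expect_equal(s1$amp_hz, 89.28e3, tolerance = 1e-3)
  expect_equal(s1$phi_r * 180 / pi, 50, tolerance = 1e-12)
  s2 <- r_symmetry(18, 1, 7, 9.92e3)
  expect_equal(s2$amp_hz, 89.28e3, tolerance = 1e-3)
  expect_equal(s2$phi_r * 180 / pi, 70, tolerance = 1e-12)
  expect_error(r_symmetry(17, 2, 5, 19.84e3), "even")
})

test_that("phase schedules alternate about the block phase", {
  sym <- r_symmetry(18, 2, 5, 19.84e3)
  for (bp in c(0, pi / 2)) {
    ph <- r_phase_list(sym, 36, block_phase = bp)
    expect_length(ph, 36)
    expect_true(all(ph >= 0 & ph < 2 * pi))
    # sum of any consecutive pair = 2 x block phase (mod 2 pi)
    pair_sums <- (ph[-36] + ph[-1]) %% (2 * pi)
    expect_true(all(abs(pair_sums - (2 * bp) %% (2 * pi)) < 1e-12 |
                      abs(pair_sums - (2 * bp) %% (2 * pi) - 2 * pi) < 1e-12))
  }
  expect_error(r_phase_list(sym, 7), "even")
})

test_that("selection rules recover the printed recoupled set and brute force", {
  for (nn in list(c(2, 5), c(1, 7))) {
    sr <- selection_rules(18, nn[1], nn[2])
    rec <- sr[sr$recoupled & sr$l == 2 & sr$lambda == 1 & sr$mu != 0, ]
    expect_setequal(rec$m, c(-2, 2))
    expect_setequal(abs(rec$mu), 1)
    # every recoupled term's witness satisfies the rule with matching parity
    ok <- sr[sr$recoupled, ]
    expect_true(all(ok$m * nn[1] - ok$mu * nn[2] == 9 * ok$Z))
    expect_true(all((ok$Z - ok$lambda) %% 2 == 0))
  }
  # nu = 0: the (l, 0, lambda even, 0) terms are recoupled with Z = 0
  sr0 <- selection_rules(8, 1, 0)
  z0 <- sr0[sr0$m == 0 & sr0$mu == 0, ]
  expect_true(all(z0$recoupled == (z0$lambda %% 2 == 0)))
  # nu -> -nu maps the recoupled (m, mu) set to (m, -mu)
  a <- selection_rules(18, 2, 5); b <- selection_rules(18, 2, -5)
  ra <- a[a$recoupled, c("l", "m", "lambda", "mu")]
  rb <- b[b$recoupled, c("l", "m", "lambda", "mu")]
  rb$mu <- -rb$mu
  expect_equal(ra[do.call(order, ra), ], rb[do.call(order, rb), ],
               ignore_attr = TRUE)
  # independent brute force over an explicit witness range, all N <= 20
  for (N in seq(2, 20, by = 2)) for (n in 1:2) for (nu in 0:(N / 2)) {
    sr <- selection_rules(N, n, nu)
    for (r in seq_len(nrow(sr))) {
      hit <- FALSE
      for (Z in -8:8) {
        if ((Z - sr$lambda[r]) %% 2 == 0 &&
            sr$m[r] * n - sr$mu[r] * nu == (N / 2) * Z) hit <- TRUE
      }
      if (hit != sr$recoupled[r]) {
        fail(sprintf("selection mismatch at N=%d n=%d nu=%d row %d", N, n, nu, r))
      }
    }
  }
  succeed()
})

# a fast reduced setup shared by the sequence behaviour tests
reduced_setup <- function(sys, mas_hz = 2e4, rf_amp = 3e4, l = 4,
                          grid_order = 7, lb = 500) {
  ot_setup(sys, mas_hz = mas_hz, overtone_ref_mhz = 8, floquet_rank = l,
           grid_order = grid_order, lb_hz = lb, rf = rf_channel(rf_amp),
           window_hz = 8e3, n_points = 129)
}

test_that("zero pulse width gives zero signal from the equilibrium state", {
  setup <- reduced_setup(toy_system_2spin(), lb = 500)
  setup$initial_state <- "thermal"
  sp0 <- direct_excitation(setup, 0)
  sp1 <- direct_excitation(setup, 40e-6)
  expect_lt(max(Mod(sp0$amp)), 1e-8 * max(Mod(sp1$amp)))
  # the bare Zeeman start (reference-simulation convention) additionally
  # carries the small stationary quadrupolar-mixing background
  setup$initial_state <- "zeeman"
  spz <- direct_excitation(setup, 0)
  expect_gt(max(Mod(spz$amp)), 0)
  expect_lt(max(Mod(spz$amp)), max(Mod(direct_excitation(setup, 40e-6)$amp)))
})

test_that("a degenerate echo reduces to direct excitation", {
  setup <- reduced_setup(toy_system_2spin())
  eko <- spin_echo(setup, t90 = 40e-6, t180 = 0, tau1 = 0, tau2 = 0)
  dir <- direct_excitation(setup, 40e-6)
  expect_lt(max(Mod(eko$amp - dir$amp)) / max(Mod(dir$amp)), 1e-10)
})

test_that("the PRESTO phase cycle nulls the signal without a dipolar coupling", {
  sys0 <- spin_system(C_Q = 1e5, eta_Q = 0.3, b_dd = 0, label = "b0")
  setup <- reduced_setup(sys0, mas_hz = 2e4, l = 3, grid_order = 3)
  sym <- r_symmetry(18, 2, 5, setup$mas_hz)
  cy <- presto_ii(setup, sym, tau_exc = 18 * sym$element_s,
                  t90 = 40e-6, t180 = 80e-6)
  un <- presto_ii(setup, sym, tau_exc = 18 * sym$element_s,
                  t90 = 40e-6, t180 = 80e-6, phase_cycle = FALSE)
  # cycled signal is zero at machine precision relative to the uncycled one
  expect_lt(max(Mod(cy$amp)) / max(Mod(un$amp)), 1e-10)
})

test_that("PRESTO transfers polarization through the dipolar coupling", {
  sys <- toy_system_2spin(C_Q = 1e5, b_dd = -8e3)
  setup <- reduced_setup(sys, mas_hz = 2e4, l = 3, grid_order = 3)
  sym <- r_symmetry(18, 2, 5, setup$mas_hz)
  cy <- presto_ii(setup, sym, tau_exc = 18 * sym$element_s,
                  t90 = 40e-6, t180 = 80e-6)
  expect_gt(max(Mod(cy$amp)), 0)
  # rotor synchronization is enforced
  expect_error(presto_ii(setup, sym, tau_exc = 18.5 * sym$element_s),
               "integer number of R elements")
})

test_that("orientation maps are consistent with the powder spectrum", {
  setup <- reduced_setup(toy_system_2spin(), grid_order = 7)
  om <- orientation_maps(setup, "direct", pulse_s = 40e-6)
  expect_true(all(c("alpha", "beta", "weight", "height", "position_hz") %in%
                    names(om)))
  expect_equal(sum(om$weight), 1, tolerance = 1e-12)
  sp <- attr(om, "spectrum")
  # weighted mean of per-orientation positions lies within the powder line
  pm <- peak_metrics(sp, component = "mod")
  wmean <- sum(om$weight * om$height * om$position_hz) /
    sum(om$weight * om$height)
  expect_lt(abs(wmean - pm$position_hz), max(3 * pm$fwhm_hz, 2e3))
})

test_that("the pulse program satisfies rotor synchronization exactly", {
  setup <- reduced_setup(toy_system_2spin())
  sym <- r_symmetry(18, 2, 5, setup$mas_hz)
  tab <- dump_sequence(setup, "presto", sym = sym,
                       tau_exc = 36 * sym$element_s)
  h <- tab[tab$channel == "1H", ]
  expect_equal(nrow(h), 72)                        # two 36-element blocks
  block <- h$duration_us[1:36] * 1e-6
  expect_equal(sum(block), 4 * sym$tau_r, tolerance = 1e-12 * sym$tau_r)
  # events are contiguous and non-overlapping per construction
  expect_true(all(diff(tab$start_us) >= 0))
})
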