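# Frequency-domain detection: resolvent solves, Lorentzian calibration,
# axis referencing, powder assembly, peak metrics.

make_toy_detector <- function(split_hz = 5e3, lb = 300) {
  w0 <- 2 * pi * split_hz
  H <- diag(c(w0 / 2, -w0 / 2)) + 0i
  Hm <- rep(list(matrix(0i, 2, 2)), 5); Hm[[3]] <- H
  fl <- build_floquet_h(Hm, 0, 0)
  sp <- matrix(0i, 2, 2); sp[1, 2] <- 1
  list(fl = fl, sp = sp, rho0 = sp + Conj(t(sp)), Hm = Hm)
}

test_that("an isolated line appears at its frequency with FWHM = lb", {
  toy <- make_toy_detector()
  det <- orient_detector(toy$fl, toy$sp)
  fr <- seq(2e3, 8e3, by = 5)
  for (lb in c(300, 600)) {
    amp <- detect_amp(det, toy$rho0, 2 * pi * fr, lb)
    pm <- peak_metrics(ot_spectrum(fr, amp))
    expect_equal(pm$position_hz, 5000, tolerance = 1e-3)
    expect_equal(pm$fwhm_hz, lb, tolerance = 0.01)   # +-1%
  }
  expect_error(relaxation_superop(0, 4), "positive")
})

test_that("resolvent solves equal the spectral route", {
  toy <- make_toy_detector()
  LF <- build_floquet(toy$Hm, 0, 0)$LF
  det <- orient_detector(toy$fl, toy$sp)
  om <- 2 * pi * seq(3e3, 7e3, by = 20)
  a_eig <- detect_amp(det, toy$rho0, om, 300)
  a_slv <- fd_spectrum(LF, 300, vec_op(toy$rho0), vec_op(toy$sp), om)
  expect_lt(max(Mod(a_eig - a_slv)) / max(Mod(a_eig)), 1e-9)
  # and on a genuinely spinning small system (Liouville-Floquet generator)
  sys <- toy_system_1spin()
  wz <- 2 * pi * 5e5
  parts <- build_interactions(sys, wz)
  Hm <- ham_fourier(parts, 0.6, 1.0)
  l <- 2
  fl <- build_floquet_h(Hm, 2 * pi * 1e4, l)
  LF <- build_floquet(Hm, 2 * pi * 1e4, l)$LF
  sp <- matrix(0i, 3, 3); sp[1, 3] <- 1
  rho0 <- sp + Conj(t(sp))
  det <- orient_detector(fl, sp)
  om <- 2 * wz + 2 * pi * seq(-3e4, 3e4, length.out = 101)
  a_eig <- detect_amp(det, overtoneMAS:::.block0(rho0, l), om, 500)
  nb <- 2 * l + 1
  v_rho <- as.vector(vapply(seq_len(nb), function(b) {
    if (b == l + 1) vec_op(rho0) else complex(9)
  }, complex(9)))
  v_det <- as.vector(vapply(seq_len(nb), function(b) vec_op(sp), complex(9)))
  a_slv <- fd_spectrum(LF, 500, v_rho, v_det, om)
  # the two embeddings truncate the Fourier ladder differently (operator
  # products spill outside rank l), so finite-rank agreement is at the
  # truncation level, not machine precision
  expect_lt(max(Mod(a_eig - a_slv)) / max(Mod(a_eig)), 2e-3)
  l2 <- 4
  fl2 <- build_floquet_h(Hm, 2 * pi * 1e4, l2)
  det2 <- orient_detector(fl2, sp)
  a_eig2 <- detect_amp(det2, overtoneMAS:::.block0(rho0, l2), om, 500)
  LF2 <- build_floquet(Hm, 2 * pi * 1e4, l2)$LF
  nb2 <- 2 * l2 + 1
  v_rho2 <- as.vector(vapply(seq_len(nb2), function(b) {
    if (b == l2 + 1) vec_op(rho0) else complex(9)
  }, complex(9)))
  v_det2 <- as.vector(vapply(seq_len(nb2), function(b) vec_op(sp), complex(9)))
  a_slv2 <- fd_spectrum(LF2, 500, v_rho2, v_det2, om)
  d2 <- max(Mod(a_eig2 - a_slv2)) / max(Mod(a_eig2))
  d1 <- max(Mod(a_eig - a_slv)) / max(Mod(a_eig))
  expect_lt(d2, d1)   # and it shrinks as the rank grows
})

test_that("frequency-domain spectrum equals the FFT of the time-domain FID", {
  sys <- toy_system_1spin(C_Q = 2e4, eta_Q = 0.5)
  wz <- 2 * pi * 5e5
  parts <- build_interactions(sys, wz)
  Hm <- ham_fourier(parts, 0.9, 0.7)
  l <- 3
  fl <- build_floquet_h(Hm, 2 * pi * 1e4, l)
  sp <- matrix(0i, 3, 3); sp[1, 3] <- 1
  rho0 <- sp + Conj(t(sp))
  det <- orient_detector(fl, sp)
  lb <- 2000                      # heavy broadening: FID decays in-window
  # time-domain route: stepwise propagation of the Floquet state, sampled
  # FID demodulated at 2 wz, decay applied, zero-filled discrete FT
  n_t <- 4096; dt <- 4e-6
  Ustep <- expm_herm(fl$HF, dt)
  R0 <- overtoneMAS:::.block0(rho0, l)
  Sbar <- overtoneMAS:::.blockdiag(sp, l)
  fid <- complex(n_t)
  rho <- R0
  for (k in seq_len(n_t)) {
    fid[k] <- sum(Conj(Sbar) * rho) * exp(1i * 2 * wz * (k - 1) * dt) *
      exp(-pi * lb * (k - 1) * dt)
    rho <- Ustep %*% rho %*% Conj(t(Ustep))
  }
  fid[1] <- fid[1] / 2                   # one-sided FT endpoint rule
  freqs <- seq(-4e4, 4e4, by = 500)      # Hz relative to 2 wz
  ft <- vapply(freqs, function(f) {
    sum(fid * exp(1i * 2 * pi * f * (seq_len(n_t) - 1) * dt)) * dt
  }, complex(1))
  a_fd <- detect_amp(det, R0, 2 * wz + 2 * pi * freqs, lb)
  nrm <- function(x) x / max(Mod(x))
  expect_lt(max(Mod(nrm(ft) - nrm(a_fd))), 0.01)
})

test_that("axis referencing doubles the nitrogen reference, round-trips", {
  sp <- ot_spectrum(seq(-1e3, 1e3, by = 100), complex(21, real = 1),
                    meta = list(carrier_hz = 86.7448e6 + 1e4))
  s1 <- reference_axis(sp, "carrier")
  expect_equal(s1$ppm[11], 0, tolerance = 1e-12)
  nuN <- 86.7448e6 / 2
  s2 <- reference_axis(sp, "overtone", nitrogen_ref_hz = nuN)
  # ppm offset of the carrier from the doubled reference
  expect_equal(s2$ppm[11], 1e4 / 86.7448e6 * 1e6, tolerance = 1e-9)
  # Hz -> ppm -> Hz is the identity
  back <- s2$ppm * 2 * nuN / 1e6 + 2 * nuN - sp$meta$carrier_hz
  expect_equal(back, sp$freq_hz, tolerance = 1e-9)
  expect_error(reference_axis(ot_spectrum(1:3, 1:3 + 0i)), "carrier")
})

test_that("powder averaging is linear, deterministic and validates axes", {
  ax <- seq(0, 100, by = 10)
  s1 <- ot_spectrum(ax, complex(real = rnorm(11), imaginary = rnorm(11)))
  s2 <- ot_spectrum(ax, complex(real = rnorm(11), imaginary = rnorm(11)))
  pw <- powder_average(list(s1, s2), c(0.3, 0.7))
  expect_equal(pw$amp, 0.3 * s1$amp + 0.7 * s2$amp)
  expect_identical(powder_average(list(s1), 1)$amp, s1$amp)
  rep1 <- powder_average(list(s1, s2, s1), c(0.2, 0.5, 0.3))
  rep2 <- powder_average(list(s1, s2, s1), c(0.2, 0.5, 0.3))
  expect_identical(rep1$amp, rep2$amp)
  s3 <- ot_spectrum(ax + 1, s1$amp)
  expect_error(powder_average(list(s1, s3), c(0.5, 0.5)), "common")
})

test_that("peak metrics are exact on an analytic Lorentzian and scale linearly", {
  fr <- seq(-3e3, 3e3, by = 10)
  lor <- 1 / (pi * 300 + 1i * 2 * pi * (150 - fr))
  sp <- ot_spectrum(fr, lor)
  pm <- peak_metrics(sp)
  expect_equal(pm$position_hz, 150, tolerance = 11)   # axis resolution
  expect_equal(pm$fwhm_hz, 300, tolerance = 2)
  pm3 <- peak_metrics(ot_spectrum(fr, 3 * lor))
  expect_equal(pm3$height / pm$height, 3, tolerance = 1e-9)
  expect_equal(pm3$area / pm$area, 3, tolerance = 1e-9)
  expect_error(peak_metrics(ot_spectrum(fr, complex(length(fr)))), "peak")
})

test_that("spectra round-trip through the text writer", {
  withr::with_tempdir({
    sp <- ot_spectrum(seq(-100, 100, by = 20),
                      complex(real = rnorm(11), imaginary = rnorm(11)),
                      meta = list(sequence = "test", lb_hz = 300))
    write_spectrum(sp, "spec.tsv")
    expect_true(file.exists("spec.tsv.meta.yaml"))
    rt <- read_spectrum("spec.tsv")
    expect_equal(rt$freq_hz, sp$freq_hz)
    expect_equal(rt$amp, sp$amp, tolerance = 1e-12)
    expect_equal(rt$meta$lb_hz, 300)
  })
})
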