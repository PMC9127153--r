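test_that("viscosity follows the hematocrit law with its documented limits", {
  expect_equal(viscosity_from_hematocrit(0), 1.2e-3)
  expect_equal(viscosity_from_hematocrit(0.45), 4.33605e-3, tolerance = 1e-12)
  expect_equal(viscosity_from_hematocrit(NULL), 3.5e-3)
  expect_equal(viscosity_from_hematocrit(NA), 3.5e-3)
  expect_error(viscosity_from_hematocrit(0.7), "0.65")
  expect_error(viscosity_from_hematocrit(-0.1), "0.65")
})

test_that("waveform construction enforces the sampling contract", {
  expect_error(velocity_waveform(rep(1, 16), 1), "32 samples")
  expect_error(velocity_waveform(rep(1, 64), -1), "positive")
  tt <- seq(0, 1, length.out = 65)[1:64]
  tt[10] <- tt[10] + 1e-4
  expect_error(velocity_waveform(rep(1, 64), 1, t = tt), "non-uniform")
  expect_error(velocity_waveform(rep(1, 64), 1, t = tt[1:64] + 0.5), "non-uniform|t = 0")
  w <- velocity_waveform(rep(1, 64), 0.8)
  expect_equal(diff(range(diff(w$t))), 0)
  expect_equal(w$t[1], 0)
})

test_that("fourier decomposition matches trivial identities and a brute-force DFT", {
  w <- velocity_waveform(rep(0.4, 64), 1)
  sp <- fourier_decompose(w, 4)
  expect_equal(sp$c0, 0.4)
  expect_equal(max(Mod(sp$cn)), 0, tolerance = 1e-14)

  t64 <- (0:63) / 64
  w2 <- velocity_waveform(0.4 + 0.1 * cos(2 * pi * t64), 1)
  sp2 <- fourier_decompose(w2, 2)
  expect_equal(sp2$cn[1], 0.05 + 0i, tolerance = 1e-12)
  expect_equal(Mod(sp2$cn[2]), 0, tolerance = 1e-14)

  for (seed in c(3, 17, 101)) {
    set.seed(seed)
    v <- runif(64, 0.2, 1.5)
    sp3 <- fourier_decompose(velocity_waveform(v, 0.9), 8)
    oracle <- dft_oracle(v)
    expect_equal(sp3$c0, Re(oracle[1]), tolerance = 1e-12)
    expect_equal(sp3$cn, oracle[2:9], tolerance = 1e-12)
  }
  expect_error(fourier_decompose(w, 40), "exceeds")
})

test_that("band-limited spectra reconstruct their samples to machine precision", {
  t <- (0:127) / 128
  v <- 1 + 0.4 * cos(2 * pi * t + 0.3) + 0.2 * sin(6 * pi * t)
  w <- velocity_waveform(v, 1)
  sp <- fourier_decompose(w, 8)
  expect_equal(harmonic_reconstruct(sp, w$t), v, tolerance = 1e-12)
})

test_that("Womersley number has the closed form and its scalings", {
  expect_equal(womersley_number(0.003, 2 * pi * 70 / 60, 1060, 3.5e-3),
               4.47, tolerance = 1e-3)
  a1 <- womersley_number(0.003, 5, 1060, 3.5e-3)
  expect_equal(womersley_number(0.003, 10, 1060, 3.5e-3) / a1, sqrt(2))
  expect_error(womersley_number(0.003, -1, 1060, 3.5e-3), "positive")
})

test_that("harmonic wall shear collapses to Poiseuille at small alpha", {
  tau <- harmonic_wall_shear(0.05 + 0i, 0.05, 0.003, 3.5e-3)
  quasi <- 2 * 3.5e-3 * 0.05 / 0.003
  expect_lt(abs(Mod(tau) - quasi) / quasi, 0.01)
  expect_equal(Arg(tau), 0, tolerance = 1e-3)
  expect_equal(harmonic_wall_shear(0 + 0i, 2, 0.003, 3.5e-3), 0 + 0i)
  expect_error(harmonic_wall_shear(0.05, 1e-8, 0.003, 3.5e-3), "degenerate")
})

test_that("harmonic wall shear matches the profile-gradient oracle", {
  for (alpha in c(1, 3, 4.47, 8, 12)) {
    got <- harmonic_wall_shear(0.05 + 0.02i, alpha, 0.003, 3.5e-3)
    want <- womersley_shear_oracle(0.05 + 0.02i, alpha, 0.003, 3.5e-3)
    expect_lt(Mod(got - want) / Mod(want), 1e-4)
  }
})

test_that("ess_waveform reproduces steady Poiseuille flow and zero flow", {
  w <- velocity_waveform(rep(0.4, 64), 1)
  sr <- ess_waveform(w, vessel_geometry(0.006), blood_properties())
  expect_equal(sr$mean_ess, 2 * 3.5e-3 * 0.4 / 0.003 * 10, tolerance = 1e-12)
  expect_equal(sr$peak_ess, sr$mean_ess, tolerance = 1e-9)

  w0 <- velocity_waveform(rep(0, 64), 1)
  sr0 <- ess_waveform(w0, vessel_geometry(0.006), blood_properties())
  expect_equal(sr0$mean_ess, 0)
  expect_equal(sr0$peak_ess, 0)
})

test_that("ESS is exactly linear in a uniform velocity scaling", {
  w <- canonical_waveform(70)
  g <- default_geometry(); b <- default_blood()
  s1 <- ess_waveform(w, g, b)
  s2 <- ess_waveform(velocity_waveform(2 * w$v, w$period), g, b)
  expect_equal(s2$tau, 2 * s1$tau, tolerance = 1e-12)
  expect_equal(s2$mean_ess, 2 * s1$mean_ess, tolerance = 1e-12)
})

test_that("shear-result invariants hold: time-average and harmonic alpha scaling", {
  w <- canonical_waveform(100)
  sr <- ess_waveform(w, default_geometry(), default_blood())
  expect_equal(sr$mean_ess, mean(sr$tau), tolerance = 1e-12)
  expect_equal(sr$alpha / sr$alpha[1], sqrt(seq_along(sr$alpha)), tolerance = 1e-9)
})

test_that("quasi-steady (alpha <= 0.1) waveforms reduce to time-resolved Poiseuille", {
  # tiny vessel + viscous blood keeps every alpha_n below 0.1
  w <- canonical_waveform(60)
  g <- suppressWarnings(vessel_geometry(4e-5))
  b <- blood_properties(viscosity = 0.01)
  sr <- ess_waveform(w, g, b)
  expect_lt(max(sr$alpha), 0.1)
  quasi_mean <- mean(2 * b$viscosity * w$v / g$radius * 10)
  expect_lt(abs(sr$mean_ess - quasi_mean) / quasi_mean, 0.01)
  # pointwise, against the same 8-harmonic band so truncation drops out
  v8 <- harmonic_reconstruct(fourier_decompose(w, 8), w$t)
  quasi_t <- 2 * b$viscosity * v8 / g$radius * 10
  expect_lt(max(abs(sr$tau - quasi_t)) / quasi_mean, 0.01)
})

test_that("Reynolds number follows its closed form and scalings", {
  expect_equal(reynolds_number(1.1, 0.006, 1060, 3.5e-3), 1060 * 1.1 * 0.006 / 3.5e-3)
  expect_equal(reynolds_number(0, 0.006, 1060, 3.5e-3), 0)
  expect_equal(reynolds_number(1, 0.006, 1060, 3.5e-3 / 2),
               2 * reynolds_number(1, 0.006, 1060, 3.5e-3))
  expect_error(reynolds_number(1, -0.006, 1060, 3.5e-3), "positive")
})

test_that("flow classification uses the documented thresholds, monotonically", {
  expect_equal(classify_flow(150)$regime, "undisturbed_laminar")
  expect_equal(classify_flow(2500)$regime, "turbulent")
  expect_equal(classify_flow(1900)$regime, "indeterminate")
  expect_equal(classify_flow(200)$regime, "disturbed")
  expect_equal(classify_flow(1800)$regime, "disturbed")
  expect_equal(classify_flow(2000)$regime, "indeterminate")
  expect_error(classify_flow(-5), "non-negative")
  # regimes appear in a fixed order as Re sweeps upward
  regimes <- classify_flow(seq(0, 3000, by = 10))
  order_seen <- unique(regimes)
  expect_equal(order_seen, c("undisturbed_laminar", "disturbed",
                             "indeterminate", "turbulent"))
  expect_false(is.unsorted(match(regimes, order_seen)))
})
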