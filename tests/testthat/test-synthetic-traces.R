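test_that("SSO traces put their FFT peak at f_osc and QUIES traces look Gaussian", {
  tr <- gen_unstimulated_trace(signal_spec("SSO", f_osc = 350, amp = 400,
                                           noise_rms = 4, seed = 1))
  n <- length(tr$samples)
  mag <- Mod(fft(tr$samples - mean(tr$samples)))[1:(n / 2)]
  f_peak <- (which.max(mag) - 1) * tr$fs / n
  expect_lt(abs(f_peak - 350), 1 + 1e-9) # 1 Hz bins for a 1-s window

  q <- gen_unstimulated_trace(signal_spec("QUIES", noise_rms = 1, seed = 2))
  sw <- shapiro.test(q$samples[seq(1, length(q$samples), length.out = 1000)])
  expect_gt(sw$p.value, 0.05)
})

test_that("degenerate amplitude settings give an identically zero trace", {
  tr <- gen_unstimulated_trace(signal_spec("SSO", amp = 0, noise_rms = 0, seed = 1))
  expect_true(all(tr$samples == 0))
})

test_that("generator rejects Nyquist violations and bad amplitudes", {
  expect_error(signal_spec("SSO", f_osc = 6000, fs = 10000), "Nyquist")
  expect_error(signal_spec("SSO", amp = -1), "amp")
  expect_error(signal_spec("TRANSIENT", alpha_target = 1.5), "alpha_target")
})

test_that("chirp stimulus has a linear instantaneous frequency and mirror symmetry", {
  up <- gen_chirp_stimulus(0, 1000, 1, 10000)
  expect_equal(chirp_frequency(up, 0.5), 500)
  down <- gen_chirp_stimulus(1000, 0, 1, 10000)
  # time reversal up to phase: compare magnitude spectra
  expect_equal(Mod(fft(up$samples)), Mod(fft(rev(down$samples))), tolerance = 1e-6)
  expect_error(gen_chirp_stimulus(0, 1000, 1, 1500), "Nyquist")
})

test_that("envelope-mode chirp response peaks at the analytic resonance", {
  p <- make_chirp_pair(f0 = 400, zeta = 0.5, accel = 1000)
  env <- attr(p$response, "true_envelope_nm")
  t_pk <- (which.max(env) - 1) / p$stimulus$fs
  f_pk <- chirp_frequency(p$stimulus, t_pk)
  expect_lt(abs(f_pk - 400 * sqrt(1 - 2 * 0.5^2)), 5)

  # near-undamped limit: peak at f0
  p0 <- make_chirp_pair(f0 = 400, zeta = 1e-3, accel = 1000)
  env0 <- attr(p0$response, "true_envelope_nm")
  f_pk0 <- chirp_frequency(p0$stimulus, (which.max(env0) - 1) / p0$stimulus$fs)
  expect_lt(abs(f_pk0 - 400), 2)
})

test_that("zero forcing gives a zero (noise-only) response in both modes", {
  ch <- gen_chirp_stimulus(0, 1000, 1, 10000)
  osc <- oscillator_spec(400, 0.2, accel = 1e-30, noise_rms = 0)
  for (mode in c("envelope", "ode")) {
    resp <- gen_chirp_response(osc, ch, mode = mode)
    expect_lt(max(abs(resp$samples)), 1e-12)
  }
})

test_that("ODE and envelope modes agree on the normalized envelope for slow sweeps", {
  for (zeta in c(0.05, 0.2, 0.7)) {
    p <- make_chirp_pair(f0 = 400, zeta = zeta, accel = 1000)
    ode <- gen_chirp_response(p$osc, p$stimulus, mode = "ode")
    e_env <- snip_envelope(p$response, p$stimulus)
    e_ode <- snip_envelope(ode, p$stimulus)
    a1 <- e_env$amps / max(e_env$amps)
    a2 <- approx(e_ode$freqs, e_ode$amps, e_env$freqs, rule = 2)$y / max(e_ode$amps)
    expect_lt(sqrt(mean((a1 - a2)^2)), 0.05)
  }
})

test_that("force-step responses settle to force/K within 1%", {
  tr <- gen_force_step_response(K = 195e-6, force = 1.56e-9, m = 2e-11,
                                zeta = 0.6, duration = 1, fs = 10000, t_on = 0.1)
  tail_mean <- mean(tr$samples[9001:10000])
  expect_equal(tail_mean, 8000, tolerance = 0.01)
  expect_equal(attr(tr, "x_ss_nm"), 8000, tolerance = 1e-12)

  # linearity: doubling K halves x_ss
  tr2 <- gen_force_step_response(K = 390e-6, force = 1.56e-9, m = 2e-11,
                                 zeta = 0.6, t_on = 0.1)
  expect_equal(attr(tr2, "x_ss_nm"), 4000, tolerance = 1e-12)

  z <- gen_force_step_response(K = 195e-6, force = 0, m = 2e-11, zeta = 0.6)
  expect_true(all(z$samples == 0))
  expect_error(gen_force_step_response(K = -1, force = 1e-9, m = 2e-11, zeta = 0.5),
               "positive")
})

test_that("every generator is deterministic given its seed", {
  s1 <- gen_unstimulated_trace(signal_spec("TRANSIENT", seed = 7))
  s2 <- gen_unstimulated_trace(signal_spec("TRANSIENT", seed = 7))
  expect_identical(s1$samples, s2$samples)

  ch <- gen_chirp_stimulus(0, 1000, 1, 10000)
  osc <- oscillator_spec(400, 0.2, 1000, noise_rms = 10)
  expect_identical(gen_chirp_response(osc, ch, seed = 3)$samples,
                   gen_chirp_response(osc, ch, seed = 3)$samples)

  e1 <- gen_experiment(make_design(), seed = 11)
  e2 <- gen_experiment(make_design(), seed = 11)
  expect_identical(lapply(e1$runs, function(r) r$unstim$samples),
                   lapply(e2$runs, function(r) r$unstim$samples))
  expect_identical(e1$truth, e2$truth)
})

test_that("gen_experiment emits the right run count, ground truth and state mixture", {
  des <- make_design(n_animals = 3, runs_per_animal = 4)
  ex <- gen_experiment(des, seed = 5)
  expect_length(ex$runs, 2 * 3 * 4)
  expect_equal(nrow(ex$truth), 24)

  pure <- data.frame(group = "sso_only", n_animals = 2, runs_per_animal = 3,
                     p_quies = 0, p_sso = 1, p_transient = 0,
                     f_osc = 350, sso_amp = 400, noise_rms = 4,
                     f0 = 400, zeta = 0.3, accel = 800)
  exp2 <- gen_experiment(pure, seed = 2)
  expect_true(all(exp2$truth$true_state == "SSO"))

  bad <- make_design(); bad$p_sso[2] <- NA
  expect_error(gen_experiment(bad, seed = 1), "row 2")
})
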