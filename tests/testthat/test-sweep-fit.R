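test_that("SNIP recovers a known modulation envelope within 5% RMS", {
  p <- make_chirp_pair(f0 = 400, zeta = 0.2, accel = 1000)
  env <- snip_envelope(p$response, p$stimulus)
  truth <- attr(p$response, "true_envelope_nm")
  t_grid <- (env$freqs - p$stimulus$f_start) /
    (p$stimulus$f_end - p$stimulus$f_start) * p$stimulus$duration
  truth_i <- approx((seq_along(truth) - 1) / p$stimulus$fs, truth, t_grid)$y
  rel_rms <- sqrt(mean((env$amps - truth_i)^2)) / max(truth_i)
  expect_lt(rel_rms, 0.05)
})

test_that("a constant-amplitude sinusoid yields a flat envelope at its amplitude", {
  fs <- 10000
  x <- 200 * sin(2 * pi * 300 * (0:9999) / fs)
  ch <- gen_chirp_stimulus(0, 1000, 1, fs) # supplies the frequency mapping
  env <- snip_envelope(ldv_trace(x, fs), ch)
  mid <- env$amps[env$freqs > 100 & env$freqs < 900]
  expect_lt(max(abs(mid - 200)) / 200, 0.02)
})

test_that("down-chirp envelopes reorder onto the up-chirp curve", {
  up <- make_chirp_pair(f0 = 400, zeta = 0.2, accel = 1000, seed = 1)
  down <- make_chirp_pair(f0 = 400, zeta = 0.2, accel = 1000, seed = 1, down = TRUE)
  e_up <- snip_envelope(up$response, up$stimulus)
  e_dn <- snip_envelope(down$response, down$stimulus)
  expect_equal(e_dn$direction, "down")
  expect_true(all(diff(e_dn$freqs) > 0))
  a_dn <- approx(e_dn$freqs, e_dn$amps, e_up$freqs, rule = 2)$y
  expect_lt(sqrt(mean((e_up$amps - a_dn)^2)) / max(e_up$amps), 0.05)
})

test_that("oscillator parameters are recovered from noisy envelopes", {
  p <- make_chirp_pair(f0 = 400, zeta = 0.2, accel = 1000, noise_frac = 0.05,
                       seed = 3)
  fit <- fit_driven_oscillator(snip_envelope(p$response, p$stimulus))
  expect_true(fit$converged)
  expect_equal(fit$f0, 400, tolerance = 0.02)
  expect_equal(fit$zeta, 0.2, tolerance = 0.10)
  expect_equal(fit$accel, 1000, tolerance = 0.10)
  expect_equal(fit$q_factor, 1 / (2 * fit$zeta))
})

test_that("envelope scaling scales accel and leaves f0, zeta unchanged", {
  p <- make_chirp_pair(f0 = 350, zeta = 0.3, accel = 500)
  env <- snip_envelope(p$response, p$stimulus)
  f1 <- fit_driven_oscillator(env, background = FALSE)
  env2 <- env; env2$amps <- env$amps * 7
  f2 <- fit_driven_oscillator(env2, background = FALSE)
  expect_equal(f2$accel / f1$accel, 7, tolerance = 1e-6)
  expect_equal(f2$f0, f1$f0, tolerance = 1e-6)
  expect_equal(f2$zeta, f1$zeta, tolerance = 1e-6)
})

test_that("an envelope of pure noise does not masquerade as a resonance", {
  set.seed(8)
  env <- list(freqs = seq(20, 1000, length.out = 300),
              amps = abs(rnorm(300, 100, 30)), direction = "up")
  fit <- fit_driven_oscillator(env)
  # either refuses outright or explains almost none of the variance
  expect_true(!fit$converged || fit$band_limited ||
                fit$rss > 0.5 * sum((env$amps - mean(env$amps))^2))
})

test_that("Q-factor follows 1/(2 zeta) and decreases in zeta", {
  expect_equal(q_factor(0.5), 1)
  expect_equal(q_factor(0.05), 10)
  expect_equal(q_factor(0.25), 2)
  z <- seq(0.01, 0.9, by = 0.01)
  expect_true(all(diff(q_factor(z)) < 0))
  expect_error(q_factor(0), "positive")
})

test_that("both peak-frequency conventions behave as documented", {
  expect_equal(peak_frequency(400, 0.1), 400 / sqrt(1 - 0.02))
  expect_equal(peak_frequency(400, 0.1, "analytic_argmax"), 400 * sqrt(0.98))
  # zeta -> 0: both converge to f0
  expect_equal(peak_frequency(400, 1e-6), 400, tolerance = 1e-9)
  expect_equal(peak_frequency(400, 1e-6, "analytic_argmax"), 400, tolerance = 1e-9)
  expect_error(peak_frequency(400, 0.8), "no finite peak")
})

test_that("analytic_argmax matches a dense-grid argmax of the magnitude response", {
  for (zeta in c(0.05, 0.2, 0.5)) {
    f0 <- 400; w0 <- 2 * pi * f0
    fgrid <- seq(10, 1000, by = 0.01)
    w <- 2 * pi * fgrid
    X <- 1 / sqrt((w0^2 - w^2)^2 + (2 * zeta * w0 * w)^2)
    expect_equal(peak_frequency(f0, zeta, "analytic_argmax"),
                 fgrid[which.max(X)], tolerance = 1e-4)
  }
})

test_that("hysteresis is the up-minus-down parameter difference and needs convergence", {
  up <- make_chirp_pair(f0 = 400, zeta = 0.2, accel = 1000, seed = 2)
  dn <- make_chirp_pair(f0 = 400, zeta = 0.2, accel = 1000, seed = 2, down = TRUE)
  f_up <- fit_driven_oscillator(snip_envelope(up$response, up$stimulus))
  f_dn <- fit_driven_oscillator(snip_envelope(dn$response, dn$stimulus))
  h <- hysteresis(f_up, f_dn)
  expect_lt(abs(h$delta_f0), 2)

  f_shift <- f_dn; f_shift$f0 <- f_dn$f0 + 10; f_shift$f_peak <- f_dn$f_peak + 10
  h2 <- hysteresis(f_up, f_shift)
  expect_equal(h2$delta_f0, h$delta_f0 - 10)

  bad <- f_dn; bad$converged <- FALSE
  expect_error(hysteresis(f_up, bad), "converged")
})
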