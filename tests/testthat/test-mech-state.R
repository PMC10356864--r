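test_that("mixed density reduces to its closed-form components", {
  x <- seq(-3, 3, by = 0.1)
  # alpha = 0: exactly normal
  expect_equal(mixed_pdf(x, 0, -1, 1, 0.3, 0.7), dnorm(x, 0.3, 0.7))
  # alpha = 1 at the centre of [-1, 1]: arcsine closed form 1/pi
  expect_equal(mixed_pdf(0, 1, -1, 1, 0, 1), 1 / pi)
  # unbounded only at the support endpoints
  expect_identical(mixed_pdf(c(-1, 1), 1, -1, 1, 0, 1), c(Inf, Inf))
  expect_equal(mixed_pdf(2, 1, -1, 1, 0, 1), 0)
})

test_that("mixed density integrates to 1 for randomized valid parameter sets", {
  set.seed(42)
  for (i in 1:10) {
    alpha <- runif(1)
    a_min <- runif(1, -500, -10); a_max <- runif(1, 10, 500)
    mu <- runif(1, -50, 50); sigma <- runif(1, 0.5, 100)
    f <- function(x) mixed_pdf(x, alpha, a_min, a_max, mu, sigma)
    # piecewise quadrature: the arcsine endpoints are integrable singularities
    # piecewise so the arcsine singularities sit exactly at interval limits,
    # where adaptive quadrature handles them as integrable endpoints
    lo <- min(a_min - sigma, mu - 9 * sigma)
    hi <- max(a_max + sigma, mu + 9 * sigma)
    total <- integrate(f, lo, a_min, rel.tol = 1e-10)$value +
      integrate(f, a_min, a_max, rel.tol = 1e-10)$value +
      integrate(f, a_max, hi, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("fitted alpha separates the three generated states", {
  tr <- gen_unstimulated_trace(signal_spec("SSO", f_osc = 350, amp = 400,
                                           noise_rms = 4, seed = 21))
  fit_sso <- fit_amplitude_distribution(tr$samples)
  expect_gte(fit_sso$alpha, 0.9)

  q <- gen_unstimulated_trace(signal_spec("QUIES", noise_rms = 1, seed = 22))
  fit_q <- fit_amplitude_distribution(q$samples)
  expect_lte(fit_q$alpha, 0.1)

  tt <- gen_unstimulated_trace(signal_spec("TRANSIENT", alpha_target = 0.5,
                                           amp = 400, noise_rms = 4, seed = 23))
  fit_t <- fit_amplitude_distribution(tt$samples)
  expect_gt(fit_t$alpha, 0.1)
  expect_lt(fit_t$alpha, 0.9)
})

test_that("fitted alpha increases with the burst duty cycle", {
  med_alpha <- vapply(c(0.1, 0.4, 0.7, 1), function(d) {
    a <- vapply(1:3, function(s) {
      tr <- gen_unstimulated_trace(signal_spec("TRANSIENT", alpha_target = d,
                                               amp = 400, noise_rms = 4,
                                               seed = 100 * s + round(10 * d)))
      fit_amplitude_distribution(tr$samples)$alpha
    }, numeric(1))
    median(a)
  }, numeric(1))
  expect_true(all(diff(med_alpha) >= -1e-6))
})

test_that("degenerate inputs are rejected with diagnostics", {
  expect_error(fit_amplitude_distribution(rep(1, 2000)), "zero variance")
  expect_error(fit_amplitude_distribution(rnorm(500)), "1000 samples")
})

test_that("classification applies the alpha cut-offs and the goodness-of-fit gate", {
  mk <- function(alpha, gof) structure(
    list(alpha = alpha, a_min = -1, a_max = 1, mu = 0, sigma = 1, gof = gof,
         n_samples = 1000, loglik = 0, converged = TRUE), class = "mixamp_fit")
  expect_equal(classify_state(mk(0.05, 0.999)), "QUIES")
  expect_equal(classify_state(mk(0.95, 0.990)), "UNCLASSIFIED")
  expect_equal(classify_state(mk(0.5, 0.999)), "TRANSIENT")
  # closed intervals at the printed cut-offs
  expect_equal(classify_state(mk(0.1, 0.999)), "QUIES")
  expect_equal(classify_state(mk(0.9, 0.999)), "SSO")
})

test_that("the persistence rule demotes short SSO streaks and never creates SSO", {
  expect_equal(apply_sso_persistence(rep("SSO", 4)), rep("SSO", 4))
  expect_equal(apply_sso_persistence(c("SSO", "QUIES", "SSO", "QUIES")),
               c("TRANSIENT", "QUIES", "TRANSIENT", "QUIES"))
  expect_equal(apply_sso_persistence(c("SSO", "SSO")), c("TRANSIENT", "TRANSIENT"))
  set.seed(1)
  for (i in 1:20) {
    labs <- sample(c("QUIES", "SSO", "TRANSIENT"), 10, replace = TRUE)
    out <- apply_sso_persistence(labs)
    expect_true(all(which(out == "SSO") %in% which(labs == "SSO")))
  }
})

test_that("state time fractions sum to one over classified runs per group", {
  labs <- c("SSO", "SSO", "QUIES", "TRANSIENT")
  fr <- state_time_fractions(labs)
  expect_equal(fr$SSO, 0.5); expect_equal(fr$QUIES, 0.25)
  expect_equal(fr$TRANSIENT, 0.25)

  labs2 <- c(labs, "UNCLASSIFIED", "QUIES", "QUIES", "SSO")
  grp <- c(rep("a", 4), rep("b", 4))
  fr2 <- state_time_fractions(labs2, grp)
  expect_equal(rowSums(fr2[, c("QUIES", "SSO", "TRANSIENT")]), c(1, 1),
               ignore_attr = TRUE)
  expect_equal(fr2$n_unclassified, c(0, 1))
  expect_error(state_time_fractions(c("UNCLASSIFIED", "UNCLASSIFIED")), "UNCLASSIFIED")
})
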