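#' Specification of a synthetic unstimulated flagellar signal
#'
#' Describes one of the three mechanical states of the mosquito flagellum as a
#' generative model: quiescent receivers are band-limited Gaussian noise with a
#' best frequency near 500 Hz; self-sustained oscillation (SSO) is a
#' near-sinusoidal oscillation around 350 Hz, roughly three orders of magnitude
#' larger; transient states interpolate between the two as gated sinusoid
#' bursts.
#'
#' @param state_label one of `"QUIES"`, `"SSO"`, `"TRANSIENT"`.
#' @param f_osc oscillation frequency in Hz (SSO component).
#' @param amp SSO displacement amplitude in nm.
#' @param noise_rms RMS of the additive Gaussian noise, nm.
#' @param band_center,band_width centre and width (Hz) of the quiescent noise
#'   band.
#' @param alpha_target for `TRANSIENT`: fraction of time the oscillation is on,
#'   in \[0, 1\].
#' @param fs sampling rate, Hz.
#' @param duration trace duration, s.
#' @param seed integer seed; every generator is deterministic given the seed.
#'
#' @return A `signal_spec` object (list).
#' @export
signal_spec <- function(state_label = c("QUIES", "SSO", "TRANSIENT"),
                        f_osc = 350, amp = 400, noise_rms = 1,
                        band_center = 500, band_width = 200,
                        alpha_target = 0.5, fs = 10000, duration = 1,
                        seed = NULL) {
  state_label <- match.arg(state_label)
  if (duration <= 0) stop("duration must be positive")
  if (amp < 0) stop("amp must be non-negative")
  if (noise_rms < 0) stop("noise_rms must be non-negative")
  if (alpha_target < 0 || alpha_target > 1) stop("alpha_target must lie in [0, 1]")
  nyq_need <- switch(state_label,
                     QUIES = band_center + band_width / 2,
                     SSO = f_osc,
                     TRANSIENT = max(f_osc, band_center + band_width / 2))
  if (fs <= 2 * nyq_need) {
    stop("Nyquist violation: fs = ", fs, " Hz cannot represent content up to ",
         nyq_need, " Hz")
  }
  structure(list(state_label = state_label, f_osc = f_osc, amp = amp,
                 noise_rms = noise_rms, band_center = band_center,
                 band_width = band_width, alpha_target = alpha_target,
                 fs = fs, duration = duration, seed = seed),
            class = "signal_spec")
}

# Band-limited zero-mean Gaussian noise via spectral shaping: white noise is
# transformed, weighted by a Gaussian band profile centred on band_center, and
# inverted, then rescaled to the requested RMS.
band_limited_noise <- function(n, fs, band_center, band_width, rms) {
  if (rms == 0) return(numeric(n))
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f) # fold to [0, fs/2]
  g <- exp(-(f - band_center)^2 / (2 * (band_width / 2)^2))
  x <- Re(stats::fft(spec * g, inverse = TRUE)) / n
  x <- x - mean(x)
  x * rms / sqrt(mean(x^2))
}

#' Generate an unstimulated free-fluctuation trace
#'
#' Produces a 1-s (by default) flagellar displacement record in a known
#' mechanical state, to stand in for unstimulated LDV sections.
#'
#' @param spec a [signal_spec()].
#' @return An [ldv_trace()] with attribute `state_label`.
#' @export
#' @examples
#' tr <- gen_unstimulated_trace(signal_spec("SSO", f_osc = 350, amp = 400,
#'                                          noise_rms = 4, seed = 1))
gen_unstimulated_trace <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- round(spec$fs * spec$duration)
  t <- (seq_len(n) - 1L) / spec$fs
  x <- switch(
    spec$state_label,
    QUIES = band_limited_noise(n, spec$fs, spec$band_center, spec$band_width,
                               spec$noise_rms),
    SSO = {
      phase <- stats::runif(1, 0, 2 * pi)
      spec$amp * sin(2 * pi * spec$f_osc * t + phase) +
        (if (spec$noise_rms > 0) stats::rnorm(n, sd = spec$noise_rms) else 0)
    },
    TRANSIENT = {
      phase <- stats::runif(1, 0, 2 * pi)
      gate <- burst_gate(n, spec$alpha_target, n_bursts = 4L)
      gate * spec$amp * sin(2 * pi * spec$f_osc * t + phase) +
        (if (spec$noise_rms > 0) stats::rnorm(n, sd = spec$noise_rms) else 0)
    })
  tr <- ldv_trace(x, spec$fs)
  attr(tr, "state_label") <- spec$state_label
  tr
}

# Contiguous on/off gating: the duration is split into n_bursts equal blocks
# and the oscillation is on for the first alpha_target fraction of each block,
# so the on-time fraction equals alpha_target while staying in contiguous runs.
burst_gate <- function(n, alpha_target, n_bursts = 4L) {
  if (alpha_target <= 0) return(numeric(n))
  if (alpha_target >= 1) return(rep(1, n))
  block <- ceiling(n / n_bursts)
  idx <- ((seq_len(n) - 1L) %% block) < alpha_target * block
  as.numeric(idx)
}

#' Specification of a driven damped harmonic oscillator
#'
#' The flagellum under chirp stimulation is modelled as
#' \eqn{x'' + 2 \zeta \omega_0 x' + \omega_0^2 x = a \, s(t)}, with natural
#' frequency `f0` (Hz, \eqn{\omega_0 = 2\pi f_0}), damping ratio `zeta` and
#' forcing acceleration `accel` (the driving force per unit effective mass,
#' m/s^2).
#'
#' @param f0 natural frequency, Hz.
#' @param zeta damping ratio (> 0).
#' @param accel forcing amplitude per unit mass, m/s^2.
#' @param noise_rms additive Gaussian measurement noise, nm.
#' @return An `oscillator_spec` object.
#' @export
oscillator_spec <- function(f0, zeta, accel, noise_rms = 0) {
  if (f0 <= 0) stop("f0 must be positive")
  if (zeta <= 0) stop("zeta must be positive")
  if (accel < 0) stop("accel must be non-negative")
  if (noise_rms < 0) stop("noise_rms must be non-negative")
  structure(list(f0 = f0, zeta = zeta, accel = accel, noise_rms = noise_rms),
            class = "oscillator_spec")
}

#' Generate a linear chirp stimulus
#'
#' Unit-amplitude linear frequency sweep; the mirrored (down) stimulus is
#' obtained by swapping `f_start` and `f_end`.
#'
#' @param f_start,f_end start and end instantaneous frequencies, Hz.
#' @param duration sweep duration, s.
#' @param fs sampling rate, Hz; must exceed twice the highest frequency.
#' @return A `chirp_stimulus` object: list with `samples`, `fs`, `f_start`,
#'   `f_end`, `duration`.
#' @export
gen_chirp_stimulus <- function(f_start, f_end, duration, fs) {
  if (duration <= 0) stop("duration must be positive")
  if (fs <= 2 * max(f_start, f_end)) {
    stop("Nyquist violation: fs = ", fs, " Hz for a sweep reaching ",
         max(f_start, f_end), " Hz")
  }
  n <- round(fs * duration)
  t <- (seq_len(n) - 1L) / fs
  # phase of a linear sweep: 2*pi*(f_start*t + (f_end - f_start) t^2 / (2T))
  phase <- 2 * pi * (f_start * t + (f_end - f_start) * t^2 / (2 * duration))
  structure(list(samples = sin(phase), fs = fs, f_start = f_start,
                 f_end = f_end, duration = duration),
            class = "chirp_stimulus")
}

#' Instantaneous frequency of a chirp at given times
#' @param stimulus a `chirp_stimulus`.
#' @param t times in seconds.
#' @export
chirp_frequency <- function(stimulus, t) {
  stimulus$f_start + (stimulus$f_end - stimulus$f_start) * t / stimulus$duration
}

#' Generate the flagellar response to a chirp stimulus
#'
#' Two modes share one contract. `"envelope"` amplitude-modulates the chirp by
#' the steady-state magnitude response
#' \eqn{X(\omega) = a / \sqrt{(\omega_0^2-\omega^2)^2 + (2\zeta\omega_0\omega)^2}}
#' evaluated at the instantaneous sweep frequency (valid for slow sweeps);
#' `"ode"` integrates the equation of motion numerically. Gaussian noise of
#' `noise_rms` nm is added after synthesis.
#'
#' @param osc an [oscillator_spec()].
#' @param stimulus a `chirp_stimulus` from [gen_chirp_stimulus()].
#' @param mode `"envelope"` or `"ode"`.
#' @param seed optional integer seed for the additive noise.
#' @return An [ldv_trace()] (displacement in nm) with attribute
#'   `true_envelope_nm`, the noise-free modulation envelope.
#' @export
gen_chirp_response <- function(osc, stimulus, mode = c("envelope", "ode"),
                               seed = NULL) {
  stopifnot(inherits(osc, "oscillator_spec"), inherits(stimulus, "chirp_stimulus"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  n <- length(stimulus$samples)
  t <- (seq_len(n) - 1L) / stimulus$fs
  w0 <- 2 * pi * osc$f0
  w <- 2 * pi * chirp_frequency(stimulus, t)
  env_m <- osc$accel / sqrt((w0^2 - w^2)^2 + (2 * osc$zeta * w0 * w)^2)
  env_nm <- env_m * 1e9
  if (mode == "envelope") {
    x_nm <- stimulus$samples * env_nm
  } else {
    force <- stats::approxfun(t, osc$accel * stimulus$samples, rule = 2)
    deriv <- function(tt, y, parms) {
      list(c(y[2], force(tt) - 2 * osc$zeta * w0 * y[2] - w0^2 * y[1]))
    }
    sol <- deSolve::ode(y = c(x = 0, v = 0), times = t, func = deriv,
                        parms = NULL, method = "lsoda")
    x_m <- sol[, "x"]
    if (any(!is.finite(x_m))) stop("ODE integration failed: non-finite displacement")
    x_nm <- x_m * 1e9
  }
  if (osc$noise_rms > 0) x_nm <- x_nm + stats::rnorm(n, sd = osc$noise_rms)
  tr <- ldv_trace(x_nm, stimulus$fs)
  attr(tr, "true_envelope_nm") <- env_nm
  tr
}

#' Generate a force-step displacement response
#'
#' Closed-form step response of a damped second-order system with stiffness
#' `K`, mass `m` and damping ratio `zeta`, settling to the steady-state
#' displacement `force / K`.
#'
#' @param K stiffness, N/m.
#' @param force applied force, N (may be 0).
#' @param m effective mass, kg.
#' @param zeta damping ratio (> 0).
#' @param duration total record duration, s.
#' @param fs sampling rate, Hz.
#' @param t_on step onset time, s (displacement is zero before onset).
#' @param noise_rms additive Gaussian noise, nm.
#' @param seed optional seed for the noise.
#' @return An [ldv_trace()] in nm with attribute `x_ss_nm` (true steady state).
#' @export
gen_force_step_response <- function(K, force, m, zeta, duration = 1,
                                    fs = 10000, t_on = 0.1, noise_rms = 0,
                                    seed = NULL) {
  if (K <= 0 || m <= 0) stop("K and m must be positive")
  if (force < 0) stop("force must be non-negative")
  if (zeta <= 0) stop("zeta must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- round(fs * duration)
  t <- (seq_len(n) - 1L) / fs
  x_ss <- force / K # metres
  w0 <- sqrt(K / m)
  tau <- pmax(t - t_on, 0)
  on <- t >= t_on
  if (zeta < 1) {
    wd <- w0 * sqrt(1 - zeta^2)
    resp <- 1 - exp(-zeta * w0 * tau) *
      (cos(wd * tau) + zeta / sqrt(1 - zeta^2) * sin(wd * tau))
  } else if (zeta == 1) {
    resp <- 1 - exp(-w0 * tau) * (1 + w0 * tau)
  } else {
    s1 <- -w0 * (zeta - sqrt(zeta^2 - 1))
    s2 <- -w0 * (zeta + sqrt(zeta^2 - 1))
    resp <- 1 - (s2 * exp(s1 * tau) - s1 * exp(s2 * tau)) / (s2 - s1)
  }
  x_nm <- ifelse(on, x_ss * resp, 0) * 1e9
  if (noise_rms > 0) x_nm <- x_nm + stats::rnorm(n, sd = noise_rms)
  tr <- ldv_trace(x_nm, fs)
  attr(tr, "x_ss_nm") <- x_ss * 1e9
  tr
}
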