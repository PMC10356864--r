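#' Steady-state displacement of a force-step response
#'
#' Baseline-corrected mean displacement over the tail of the on-step
#' interval. The baseline is the pre-step mean; the analysis window is the
#' final `window_fraction` of `[step_on, step_off]`. Settling is verified by
#' requiring the drift fitted across the window to stay below `settle_tol`
#' of the steady-state value; unsettled responses are flagged (and excluded
#' from group statistics by default downstream), never silently accepted.
#'
#' @param trace an [ldv_trace()] of a force-step response, nm.
#' @param step_on,step_off step onset and offset times, s (relative to trace
#'   start).
#' @param window_fraction fraction of the on-interval used for averaging, in
#'   (0, 0.5\] (default 0.1).
#' @param settle_tol maximum tolerated drift across the window, as a fraction
#'   of |x_ss| (default 0.01).
#' @return List with `x_ss` (nm), `settled` (logical), `baseline` (nm),
#'   `drift` (nm across the window).
#' @export
steady_state_displacement <- function(trace, step_on, step_off,
                                      window_fraction = 0.1,
                                      settle_tol = 0.01) {
  stopifnot(inherits(trace, "ldv_trace"))
  if (window_fraction <= 0 || window_fraction > 0.5) {
    stop("window_fraction must lie in (0, 0.5]")
  }
  fs <- trace$fs
  n <- length(trace$samples)
  if (step_on < 0 || step_off * fs > n || step_off <= step_on) {
    stop("step interval must lie inside the trace")
  }
  i_on <- floor(step_on * fs) + 1L
  i_off <- floor(step_off * fs)
  baseline <- if (i_on > 1L) mean(trace$samples[1:(i_on - 1L)]) else 0
  win_start <- i_off - max(2L, round(window_fraction * (i_off - i_on + 1L))) + 1L
  win <- trace$samples[win_start:i_off]
  x_ss <- mean(win) - baseline
  tt <- seq_along(win) / fs
  lmfit <- stats::lm(win ~ tt)
  drift <- stats::coef(lmfit)[["tt"]] * (length(win) / fs) # nm over the window
  # residual spread catches undecayed ringing, which a drift check alone
  # misses because oscillations average out of the slope
  ripple <- stats::sd(stats::residuals(lmfit))
  settled <- abs(drift) <= settle_tol * max(abs(x_ss), 1e-9) &&
    ripple <= 10 * settle_tol * max(abs(x_ss), 1e-9)
  list(x_ss = x_ss, settled = settled, baseline = baseline, drift = drift,
       ripple = ripple)
}

#' Steady-state stiffness from displacement and force
#'
#' The flagellar steady-state stiffness is the force required to hold the
#' flagellum at a given steady displacement: `K = force / x_ss` in SI.
#' Returned in N/m; multiply by 1e6 for the conventional micro-newton per
#' metre reporting.
#'
#' @param x_ss steady-state displacement, nm (must be positive).
#' @param force applied force, N (> 0).
#' @return Stiffness in N/m.
#' @export
#' @examples
#' steady_state_stiffness(1e4, 1e-9) * 1e6 # 100 uN/m
steady_state_stiffness <- function(x_ss, force) {
  if (any(x_ss <= 0)) stop("x_ss must be positive")
  if (any(force <= 0)) stop("force must be positive")
  force / (x_ss * 1e-9)
}

#' Calibrate the force-step drive to a target displacement
#'
#' Force-step stimulation is calibrated so the maximum flagellar displacement
#' reaches approximately +/- 8000 nm. Given trial drives and their measured
#' maximum |displacement|, the drive achieving the target is found by linear
#' interpolation; extrapolation beyond 20% outside the trial range is
#' refused.
#'
#' @param trials data frame with columns `drive` and `max_disp_nm`, at least
#'   two rows; `max_disp_nm` must increase with `drive`.
#' @param target target maximum displacement, nm (default 8000).
#' @return The interpolated drive setting.
#' @export
calibrate_step_force <- function(trials, target = 8000) {
  stopifnot(is.data.frame(trials), all(c("drive", "max_disp_nm") %in% names(trials)))
  if (nrow(trials) < 2) stop("need at least two trial drives")
  trials <- trials[order(trials$drive), ]
  if (any(diff(trials$max_disp_nm) <= 0)) {
    stop("non-monotone drive-displacement relation")
  }
  rng <- range(trials$max_disp_nm)
  span <- diff(rng)
  if (target < rng[1] - 0.2 * span || target > rng[2] + 0.2 * span) {
    stop("target ", target, " nm is more than 20% outside the trial range [",
         rng[1], ", ", rng[2], "]")
  }
  stats::approx(trials$max_disp_nm, trials$drive, xout = target, rule = 2,
                ties = "ordered")$y
}

#' Apparent flagellar mass from stiffness and natural frequency
#'
#' Simple-oscillator relation `m = K / (2 pi f0)^2`. This is the package's
#' own derivation from the fitted stiffness and natural frequency; an
#' externally supplied mass can be passed through `override` and is returned
#' verbatim.
#'
#' @param stiffness N/m (> 0).
#' @param f0 natural frequency, Hz (> 0).
#' @param override optional externally determined mass, kg.
#' @return Mass in kg.
#' @export
#' @examples
#' apparent_mass(100e-6, 400) # ~1.58e-11 kg
apparent_mass <- function(stiffness, f0, override = NULL) {
  if (!is.null(override)) return(override)
  if (any(stiffness <= 0) || any(f0 <= 0)) stop("stiffness and f0 must be positive")
  stiffness / (2 * pi * f0)^2
}
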