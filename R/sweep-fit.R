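#' SNIP envelope of a chirp response
#'
#' Extracts the upper envelope of a chirp-stimulated displacement record by
#' statistic-sensitive nonlinear iterative peak clipping (SNIP) applied to the
#' rectified signal: over `n_iterations` passes with a clipping window that
#' decreases from `window_samples` to 1, each point is raised to the mean of
#' its two neighbours at the current window distance whenever it lies below
#' it, filling the valleys between oscillation peaks. The envelope is then
#' mapped from time to frequency through the chirp's linear time-frequency
#' law; down-chirp curves are reordered to ascending frequency.
#'
#' @param trace chirp-response [ldv_trace()].
#' @param stimulus the `chirp_stimulus` that drove it (supplies the
#'   time-frequency law and direction).
#' @param n_iterations clipping passes (default 24).
#' @param window_samples initial clipping half-window; default
#'   `fs / (2 * min_resonance_width_hz)`.
#' @param min_resonance_width_hz narrowest resonance the envelope must
#'   preserve (default 50 Hz); sets the default window.
#' @param min_freq lowest frequency kept (default 10 Hz; the near-DC region of
#'   the sweep is ill-defined).
#' @param n_grid number of points of the output frequency grid (default 400;
#'   envelope values are bin-averaged onto the grid).
#' @return An `envelope_curve`: list with `freqs` (Hz, strictly increasing),
#'   `amps` (nm, >= 0) and `direction` (`"up"` or `"down"`).
#' @export
snip_envelope <- function(trace, stimulus, n_iterations = 24,
                          window_samples = NULL,
                          min_resonance_width_hz = 50, min_freq = 10,
                          n_grid = 400) {
  stopifnot(inherits(trace, "ldv_trace"), inherits(stimulus, "chirp_stimulus"))
  fs <- trace$fs
  if (is.null(window_samples)) {
    window_samples <- max(2L, round(fs / (2 * min_resonance_width_hz)))
  }
  y <- abs(trace$samples)
  if (all(y == 0)) stop("envelope identically zero")
  n <- length(y)
  windows <- unique(pmax(1L, round(seq(window_samples, 1, length.out = n_iterations))))
  for (w in windows) {
    idx <- (w + 1L):(n - w)
    lifted <- 0.5 * (y[idx - w] + y[idx + w])
    y[idx] <- pmax(y[idx], lifted)
  }
  t <- (seq_len(n) - 1L) / fs
  f <- chirp_frequency(stimulus, t)
  direction <- if (stimulus$f_end >= stimulus$f_start) "up" else "down"
  keep <- f >= min_freq
  f <- f[keep]; y <- y[keep]
  o <- order(f)
  f <- f[o]; y <- y[o]
  # bin-average onto an ascending grid
  breaks <- seq(min(f), max(f), length.out = n_grid + 1L)
  bin <- findInterval(f, breaks, rightmost.closed = TRUE)
  amps <- as.numeric(tapply(y, bin, mean))
  freqs <- as.numeric(tapply(f, bin, mean))
  ok <- !is.na(amps)
  structure(list(freqs = freqs[ok], amps = amps[ok], direction = direction),
            class = "envelope_curve")
}

#' Fit the driven damped harmonic oscillator to an envelope
#'
#' Nonlinear least squares of the magnitude response
#' \deqn{X(\omega) = \frac{a}{\sqrt{(\omega_0^2 - \omega^2)^2 +
#'   (2\zeta\omega_0\omega)^2}}}
#' to an envelope curve, in angular frequency, with the driving force and
#' effective mass absorbed into the single acceleration parameter `a` (m/s^2;
#' the model is evaluated in metres and the envelope is in nm). Initial
#' values: f0 from the envelope argmax, zeta from the half-power width, accel
#' from the peak amplitude. Bounds: zeta in (1e-4, 0.9), f0 in (10, 1000) Hz.
#'
#' @param env an `envelope_curve` from [snip_envelope()] (or any list with
#'   `freqs` in Hz and `amps` in nm; >= 20 points spanning the peak).
#' @param peak_convention convention passed to [peak_frequency()] for the
#'   reported `f_peak` (default `"as_printed"`).
#' @param background if `TRUE` (default) an additive non-negative constant is
#'   co-estimated as a nuisance parameter: rectification and peak clipping
#'   lift the envelope of a noisy record by a roughly constant floor, which
#'   would otherwise bias the damping estimate.
#' @return An `oscillator_fit`: list with `f0` (Hz), `zeta`, `accel` (m/s^2),
#'   `q_factor`, `f_peak` (Hz), `rss` (nm^2), `converged`, `band_limited`
#'   (TRUE when the envelope peak sits on the grid boundary), `direction`,
#'   `peak_convention`, `message`.
#' @export
fit_driven_oscillator <- function(env, peak_convention = c("as_printed", "analytic_argmax"),
                                  background = TRUE) {
  peak_convention <- match.arg(peak_convention)
  stopifnot(!is.null(env$freqs), !is.null(env$amps))
  f <- env$freqs
  a <- env$amps
  if (length(f) < 20) stop("need at least 20 envelope points")
  ipk <- which.max(a)
  band_limited <- ipk == 1L || ipk == length(f)
  f0_0 <- min(max(f[ipk], 10.5), 999.5)
  # half-power width -> zeta
  half <- a >= a[ipk] / sqrt(2)
  df_half <- diff(range(f[half]))
  zeta0 <- min(max(df_half / (2 * f0_0), 0.02), 0.7)
  w0_0 <- 2 * pi * f0_0
  accel0 <- max(a[ipk], 1e-6) * 1e-9 * 2 * zeta0 * w0_0^2
  dat <- data.frame(w = 2 * pi * f, y = a)
  fit <- tryCatch(
    if (background) {
      minpack.lm::nlsLM(
        y ~ 1e9 * accel / sqrt((w0^2 - w^2)^2 + (2 * zeta * w0 * w)^2) + b,
        data = dat,
        start = list(accel = accel0, w0 = w0_0, zeta = zeta0, b = min(a)),
        lower = c(accel = 0, w0 = 2 * pi * 10, zeta = 1e-4, b = 0),
        upper = c(accel = Inf, w0 = 2 * pi * 1000, zeta = 0.9, b = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        y ~ 1e9 * accel / sqrt((w0^2 - w^2)^2 + (2 * zeta * w0 * w)^2),
        data = dat,
        start = list(accel = accel0, w0 = w0_0, zeta = zeta0),
        lower = c(accel = 0, w0 = 2 * pi * 10, zeta = 1e-4),
        upper = c(accel = Inf, w0 = 2 * pi * 1000, zeta = 0.9),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(f0 = NA_real_, zeta = NA_real_, accel = NA_real_,
                          q_factor = NA_real_, f_peak = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          band_limited = band_limited,
                          direction = env$direction %||% NA_character_,
                          peak_convention = peak_convention,
                          message = conditionMessage(fit)),
                     class = "oscillator_fit"))
  }
  p <- stats::coef(fit)
  f0 <- p[["w0"]] / (2 * pi)
  zeta <- p[["zeta"]]
  fpk <- tryCatch(peak_frequency(f0, zeta, peak_convention), error = function(e) NA_real_)
  structure(list(f0 = f0, zeta = zeta, accel = p[["accel"]],
                 background = if (background) p[["b"]] else 0,
                 q_factor = q_factor(zeta), f_peak = fpk,
                 rss = sum(stats::residuals(fit)^2), converged = TRUE,
                 band_limited = band_limited,
                 direction = env$direction %||% NA_character_,
                 peak_convention = peak_convention, message = ""),
            class = "oscillator_fit")
}

#' @export
print.oscillator_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<oscillator_fit> NOT CONVERGED:", x$message, "\n")
  } else {
    cat(sprintf(
      "<oscillator_fit> f0 %.1f Hz, zeta %.3f (Q %.2f), accel %.3g m/s^2, f_peak %.1f Hz [%s]%s\n",
      x$f0, x$zeta, x$q_factor, x$accel, x$f_peak, x$peak_convention,
      if (isTRUE(x$band_limited)) " band-limited" else ""))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Q-factor of a damped oscillator
#'
#' \eqn{Q = 1 / (2\zeta)}: the sharpness of the resonant tuning.
#'
#' @param zeta damping ratio (> 0).
#' @return Dimensionless Q.
#' @export
#' @examples
#' q_factor(0.5) # 1
q_factor <- function(zeta) {
  if (any(zeta <= 0)) stop("zeta must be positive")
  1 / (2 * zeta)
}

#' Peak frequency of the driven damped oscillator
#'
#' Two conventions are provided. `"as_printed"` follows the field's commonly
#' quoted expression \eqn{f_{opt} = f_0 / \sqrt{1 - 2\zeta^2}}, which shifts
#' the peak above the natural frequency as damping grows. `"analytic_argmax"`
#' is the frequency that maximises the magnitude response itself,
#' \eqn{f_0 \sqrt{1 - 2\zeta^2}}, which lies below \eqn{f_0}. The two agree in
#' the limit \eqn{\zeta \to 0}, where both equal the natural frequency; they
#' are both reported because they answer slightly different questions and the
#' package does not adjudicate between them.
#'
#' @param f0 natural frequency, Hz.
#' @param zeta damping ratio; must be below \eqn{1/\sqrt{2}}, beyond which no
#'   finite response peak exists.
#' @param convention `"as_printed"` (default) or `"analytic_argmax"`.
#' @return Peak frequency in Hz.
#' @export
#' @examples
#' peak_frequency(400, 0.1)                      # 404.06...
#' peak_frequency(400, 0.1, "analytic_argmax")   # 395.98...
peak_frequency <- function(f0, zeta, convention = c("as_printed", "analytic_argmax")) {
  convention <- match.arg(convention)
  if (zeta >= 1 / sqrt(2)) stop("no finite peak: zeta >= 1/sqrt(2)")
  if (f0 <= 0) stop("f0 must be positive")
  if (zeta <= 0) stop("zeta must be positive")
  if (convention == "as_printed") f0 / sqrt(1 - 2 * zeta^2) else f0 * sqrt(1 - 2 * zeta^2)
}

#' Hysteresis between mirrored sweep fits
#'
#' Each up-chirp run is followed by its mirrored down-chirp; comparing the two
#' fits exposes any latency-induced hysteresis. Differences are up minus down.
#'
#' @param up_fit,down_fit converged `oscillator_fit` objects.
#' @return List with `delta_f0` and `delta_peak` (Hz).
#' @export
hysteresis <- function(up_fit, down_fit) {
  stopifnot(inherits(up_fit, "oscillator_fit"), inherits(down_fit, "oscillator_fit"))
  if (!isTRUE(up_fit$converged) || !isTRUE(down_fit$converged)) {
    stop("hysteresis requires both fits to have converged")
  }
  list(delta_f0 = up_fit$f0 - down_fit$f0,
       delta_peak = up_fit$f_peak - down_fit$f_peak)
}
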