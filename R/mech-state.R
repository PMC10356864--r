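#' Mixed arcsine-normal amplitude density
#'
#' Density of the flagellar displacement-amplitude mixture used to classify
#' mechanical states. A fully quiescent flagellum has normally distributed
#' displacements; a self-sustained oscillator follows the arcsine law of a
#' sinusoid's amplitude distribution. The mixture
#' \deqn{D(\alpha, x) = \alpha \frac{1}{\pi\sqrt{(x - A_{min})(A_{max} - x)}}
#'   + (1-\alpha) \frac{1}{\sqrt{2\pi}\sigma} e^{-(x-\mu)^2 / 2\sigma^2}}
#' interpolates between the two, with weight \eqn{\alpha = 0} purely quiescent
#' and \eqn{\alpha = 1} purely oscillating.
#'
#' The arcsine term is zero outside `[a_min, a_max]` and diverges at the two
#' endpoints (an integrable singularity); evaluation there returns `Inf`.
#'
#' @param x displacement values, nm.
#' @param alpha mixture weight in \[0, 1\].
#' @param a_min,a_max arcsine support endpoints, nm (`a_min < a_max`).
#' @param mu,sigma normal location and scale, nm (`sigma > 0`).
#' @return Density values (1/nm), non-negative everywhere.
#' @export
#' @examples
#' mixed_pdf(0, alpha = 1, a_min = -1, a_max = 1, mu = 0, sigma = 1) # 1/pi
mixed_pdf <- function(x, alpha, a_min, a_max, mu, sigma) {
  if (a_min >= a_max) stop("a_min must be < a_max")
  if (sigma <= 0) stop("sigma must be positive")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  out <- (1 - alpha) * stats::dnorm(x, mu, sigma)
  if (alpha > 0) {
    arc <- numeric(length(x))
    inside <- x > a_min & x < a_max
    arc[inside] <- 1 / (pi * sqrt((x[inside] - a_min) * (a_max - x[inside])))
    arc[x == a_min | x == a_max] <- Inf
    out <- out + alpha * arc
  }
  out
}

#' Mixed arcsine-normal cumulative distribution
#'
#' @inheritParams mixed_pdf
#' @return CDF values in \[0, 1\].
#' @export
mixed_cdf <- function(x, alpha, a_min, a_max, mu, sigma) {
  z <- pmin(pmax((x - a_min) / (a_max - a_min), 0), 1)
  arc <- 2 / pi * asin(sqrt(z))
  alpha * arc + (1 - alpha) * stats::pnorm(x, mu, sigma)
}

#' Fit the mixed arcsine-normal amplitude distribution
#'
#' Fits the five parameters (alpha, a_min, a_max, mu, sigma) of [mixed_pdf()]
#' to the raw displacement samples of a 1-s unstimulated section by maximum
#' likelihood. Support endpoints are initialised from the robust extremes
#' (0.1/99.9 percentiles widened by 1%) and refined together with the other
#' parameters; samples are clamped strictly inside the support by half an
#' amplitude-resolution step when evaluating the arcsine term, since the
#' likelihood is unbounded at the endpoints. Goodness of fit is the
#' coefficient of determination between the empirical CDF and the model CDF
#' at the sample points.
#'
#' @param samples displacement values, nm (>= 1000 required).
#' @param max_fit_samples cap on the number of samples used in the likelihood
#'   (deterministic thinning; the goodness of fit is always computed on the
#'   full sample set). Default 2500.
#' @return A `mixamp_fit` object: list with `alpha`, `a_min`, `a_max`, `mu`,
#'   `sigma`, `gof`, `n_samples`, `loglik`, `converged`.
#' @export
fit_amplitude_distribution <- function(samples, max_fit_samples = 2500) {
  x_all <- as.numeric(samples)
  if (length(x_all) < 1000) stop("need at least 1000 samples, got ", length(x_all))
  if (stats::sd(x_all) == 0) stop("zero variance: constant signal cannot be classified")
  n <- length(x_all)
  # deterministic thinning keeps the fit fast without a random subsample
  x <- if (n > max_fit_samples) {
    x_all[unique(round(seq(1, n, length.out = max_fit_samples)))]
  } else x_all
  m <- length(x)
  q <- stats::quantile(x_all, c(0.001, 0.999), names = FALSE)
  rng <- diff(range(x_all))
  width0 <- q[2] - q[1]
  a_min0 <- q[1] - 0.01 * width0
  a_max0 <- q[2] + 0.01 * width0
  mu0 <- mean(x)
  sd0 <- stats::sd(x)
  # clamp step: half the amplitude resolution of the sample set
  delta <- 0.5 * rng / n

  arc_dens <- function(a_min, a_max) {
    xc <- pmin(pmax(x, a_min + delta), a_max - delta)
    arc <- 1 / (pi * sqrt((xc - a_min) * (a_max - xc)))
    arc[x <= a_min | x >= a_max] <- 0
    arc
  }
  nll <- function(p) {
    alpha <- p[1]; a_min <- p[2]; a_max <- p[3]; mu <- p[4]; sigma <- p[5]
    if (a_max - a_min < 4 * delta || sigma <= 0) return(1e12)
    d <- alpha * arc_dens(a_min, a_max) + (1 - alpha) * stats::dnorm(x, mu, sigma)
    v <- -sum(log(pmax(d, 1e-300)))
    if (!is.finite(v)) 1e12 else v
  }

  # bounds: alpha in [0,1]; support endpoints stay on their own side of the
  # sample mid-range; mu within the sample range; sigma positive
  lo <- c(0, min(x_all) - 0.5 * rng, mu0, min(x_all), 1e-6 * sd0)
  hi <- c(1, mu0, max(x_all) + 0.5 * rng, max(x_all), 2 * rng)

  # EM on (alpha, mu, sigma) with the support held at the robust extremes:
  # cheap and lands near the global optimum; two sigma regimes are tried
  # because the narrow-noise and broad-normal optima are well separated
  em_start <- function(sigma0, iter = 30) {
    arc <- arc_dens(a_min0, a_max0)
    alpha <- 0.5; mu <- mu0; sigma <- sigma0
    for (it in seq_len(iter)) {
      da <- alpha * arc
      dn <- (1 - alpha) * stats::dnorm(x, mu, sigma)
      r <- da / pmax(da + dn, 1e-300)
      alpha <- mean(r)
      wn <- pmax(1 - r, 1e-12)
      mu <- sum(wn * x) / sum(wn)
      sigma <- sqrt(sum(wn * (x - mu)^2) / sum(wn))
      if (!is.finite(sigma) || sigma <= 0) sigma <- sd0
    }
    c(min(max(alpha, 1e-6), 1 - 1e-6), a_min0, a_max0, mu, sigma)
  }
  starts <- lapply(unique(c(sd0, sd0 / 30)), em_start)
  # refine every EM candidate (bounded quasi-Newton, then a Nelder-Mead
  # polish that tolerates the kinks the clamping introduces) and keep the
  # best final likelihood: the two sigma regimes are separate local optima
  # and either can win
  nll_box <- function(p) if (any(p < lo) || any(p > hi)) 1e12 else nll(p)
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lo + 1e-12), hi - 1e-12)
    cand <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(cand) || cand$convergence != 0 || nll(p0) < cand$value) {
      # the clamped likelihood is kinked; fall back to Nelder-Mead when the
      # quasi-Newton line search gives up
      from <- if (is.null(cand) || nll(p0) < cand$value) p0 else cand$par
      cand <- tryCatch(
        stats::optim(from, nll_box, method = "Nelder-Mead",
                     control = list(maxit = 1200, reltol = 1e-8)),
        error = function(e) cand)
    }
    if (!is.null(cand) && (is.null(best) || cand$value < best$value)) best <- cand
  }
  if (is.null(best)) {
    return(structure(list(alpha = NA_real_, a_min = NA_real_, a_max = NA_real_,
                          mu = NA_real_, sigma = NA_real_, gof = 0,
                          n_samples = n, loglik = NA_real_, converged = FALSE),
                     class = "mixamp_fit"))
  }
  p <- best$par
  # CDF R^2 between the empirical CDF and the fitted model CDF (full sample)
  xs <- sort(x_all)
  ecdf_v <- (seq_len(n) - 0.5) / n
  mcdf <- mixed_cdf(xs, p[1], p[2], p[3], p[4], p[5])
  gof <- 1 - sum((ecdf_v - mcdf)^2) / sum((ecdf_v - mean(ecdf_v))^2)
  structure(list(alpha = p[1], a_min = p[2], a_max = p[3], mu = p[4],
                 sigma = p[5], gof = max(0, min(1, gof)), n_samples = n,
                 loglik = -best$value, converged = best$convergence == 0),
            class = "mixamp_fit")
}

#' @export
print.mixamp_fit <- function(x, ...) {
  cat(sprintf(
    "<mixamp_fit> alpha %.3f, support [%.3g, %.3g] nm, mu %.3g, sigma %.3g, gof %.4f (n = %d)\n",
    x$alpha, x$a_min, x$a_max, x$mu, x$sigma, x$gof, x$n_samples))
  invisible(x)
}

#' Classify the mechanical state from a fitted amplitude model
#'
#' States: weight alpha in \[0, 0.1\] is quiescent (QUIES), \[0.9, 1\] is
#' self-sustained oscillation (SSO), anything between is TRANSIENT — both
#' cut-off intervals closed. A fit must account for at least the
#' `gof_threshold` fraction of the data (default 99.7%, as coefficient of
#' determination on the CDF) or the run is UNCLASSIFIED.
#'
#' @param model a `mixamp_fit` from [fit_amplitude_distribution()].
#' @param gof_threshold minimum goodness of fit (default 0.997).
#' @param quies_max upper alpha cut-off for QUIES (default 0.1).
#' @param sso_min lower alpha cut-off for SSO (default 0.9).
#' @return One of `"QUIES"`, `"SSO"`, `"TRANSIENT"`, `"UNCLASSIFIED"`.
#' @export
classify_state <- function(model, gof_threshold = 0.997, quies_max = 0.1,
                           sso_min = 0.9) {
  stopifnot(inherits(model, "mixamp_fit"))
  if (!isTRUE(model$converged) || !is.finite(model$gof) ||
      model$gof < gof_threshold) {
    return("UNCLASSIFIED")
  }
  if (model$alpha <= quies_max) return("QUIES")
  if (model$alpha >= sso_min) return("SSO")
  "TRANSIENT"
}

#' Enforce the SSO persistence criterion
#'
#' An animal is only classed as SSO when it sustained oscillation for at least
#' `min_consecutive` consecutive runs (default 3, i.e. six seconds of the
#' alternating 1-s + 1-s run structure). SSO labels not belonging to such a
#' streak are demoted to TRANSIENT. The rule never creates SSO labels.
#'
#' @param labels character vector of per-run state labels, in temporal order
#'   within one animal/stage.
#' @param min_consecutive minimum streak length (default 3).
#' @return Character vector of final labels.
#' @export
apply_sso_persistence <- function(labels, min_consecutive = 3) {
  is_sso <- labels == "SSO"
  r <- rle(is_sso)
  demote <- rep(r$values & r$lengths < min_consecutive, r$lengths)
  labels[demote] <- "TRANSIENT"
  labels
}

#' Fraction of time spent in each mechanical state, per group
#'
#' @param labels character state labels per run.
#' @param group grouping factor/vector, same length.
#' @return Data frame (group, QUIES, SSO, TRANSIENT, n_classified,
#'   n_unclassified); fractions sum to 1 over classified runs, UNCLASSIFIED
#'   runs are excluded from the fractions and reported separately.
#' @export
state_time_fractions <- function(labels, group = rep("all", length(labels))) {
  stopifnot(length(labels) == length(group))
  states <- c("QUIES", "SSO", "TRANSIENT")
  out <- lapply(split(labels, group), function(lb) {
    cl <- lb[lb != "UNCLASSIFIED"]
    if (length(cl) == 0) stop("all runs UNCLASSIFIED in a group")
    fr <- vapply(states, function(s) mean(cl == s), numeric(1))
    c(fr, n_classified = length(cl), n_unclassified = sum(lb == "UNCLASSIFIED"))
  })
  df <- as.data.frame(do.call(rbind, out))
  df <- cbind(group = names(out), df)
  rownames(df) <- NULL
  df
}
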