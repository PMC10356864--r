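#' Spectral peak of an unstimulated section
#'
#' Frequency and displacement amplitude of the dominant oscillation in a 1-s
#' free-fluctuation trace, by FFT. The signal is mean-detrended; the peak is
#' the largest magnitude bin within the search band; the amplitude uses the
#' sinusoid convention `2*|X(f)| / N`, so a pure sinusoid of amplitude A
#' reports A. Quiescent receivers produce no periodic signal, so a spectrum
#' without a dominant component (peak below `min_peak_ratio` times the in-band
#' median magnitude) is refused rather than assigned a frequency.
#'
#' @param trace an [ldv_trace()]; intended for runs classified SSO or
#'   TRANSIENT (enforced by the calling pipeline, not here).
#' @param band numeric length-2 search band in Hz (default 100-1000).
#' @param min_peak_ratio minimum peak-to-median spectral ratio (default 3).
#' @param taper `"none"` (rectangular, default — favours resolution for 1-s
#'   near-stationary sinusoids) or `"hann"`.
#' @return List with `f_sso` (Hz), `amplitude` (nm), `resolution` (Hz, =
#'   1/duration), `peak_ratio`, `taper`.
#' @export
spectral_peak <- function(trace, band = c(100, 1000), min_peak_ratio = 3,
                          taper = c("none", "hann")) {
  stopifnot(inherits(trace, "ldv_trace"))
  taper <- match.arg(taper)
  x <- trace$samples - mean(trace$samples)
  n <- length(x)
  w <- if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)) else rep(1, n)
  # amplitude correction for the window's coherent gain
  X <- stats::fft(x * w)
  half <- seq_len(floor(n / 2))
  freqs <- (half - 1L) * trace$fs / n
  mag <- 2 * Mod(X[half]) / sum(w)
  in_band <- freqs >= band[1] & freqs <= band[2] & freqs < trace$fs / 2
  if (!any(in_band)) stop("search band contains no frequency bins")
  mb <- mag[in_band]
  fb <- freqs[in_band]
  i <- which.max(mb)
  # dominance is judged on a lightly smoothed spectrum within the peak's
  # neighbourhood: raw noise bins are Rayleigh-distributed and their global
  # max/median ratio hovers near 3 regardless of level, so an unsmoothed or
  # whole-band ratio cannot separate a sinusoid from band-limited noise
  ms <- stats::filter(mb, rep(1 / 5, 5), sides = 2)
  ms[is.na(ms)] <- mb[is.na(ms)]
  nbr <- abs(fb - fb[i]) <= 150
  ratio <- max(ms[nbr]) / stats::median(ms[nbr])
  if (ratio < min_peak_ratio) {
    stop("no dominant component: peak-to-median spectral ratio ",
         format(ratio, digits = 3), " < ", min_peak_ratio)
  }
  list(f_sso = fb[i], amplitude = mb[i], resolution = trace$fs / n,
       peak_ratio = ratio, taper = taper)
}

#' Group summaries of SSO frequency and amplitude
#'
#' Median and (unscaled) median absolute deviation of the spontaneous
#' oscillation frequency and amplitude per experimental group, with n the
#' number of runs, matching the run-level n of figure tables.
#'
#' @param peaks data frame with columns `f_sso` and `amplitude` plus grouping
#'   columns.
#' @param by character vector of grouping column names.
#' @return Data frame with one row per non-empty group: n, median and MAD of
#'   each measure. Empty groups are omitted with a warning.
#' @export
summarize_sso <- function(peaks, by) {
  stopifnot(all(c("f_sso", "amplitude") %in% names(peaks)),
            all(by %in% names(peaks)))
  key <- interaction(peaks[by], drop = FALSE, sep = " / ")
  empty <- setdiff(levels(key), levels(droplevels(key)))
  if (length(empty)) warning("empty groups omitted: ", paste(empty, collapse = ", "))
  rows <- lapply(split(peaks, droplevels(key)), function(g) {
    cbind(g[1, by, drop = FALSE],
          data.frame(n = nrow(g),
                     f_sso_median = stats::median(g$f_sso),
                     f_sso_mad = stats::mad(g$f_sso, constant = 1),
                     amplitude_median = stats::median(g$amplitude),
                     amplitude_mad = stats::mad(g$amplitude, constant = 1)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
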