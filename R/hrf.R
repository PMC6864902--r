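#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF: a positive gamma density peaking near 5-6 s
#' minus a scaled gamma density peaking near 15-16 s that models the
#' post-stimulus undershoot. The function is scaled so its maximum is 1.
#'
#' @param t Time in seconds (vector); values before stimulus onset (t < 0)
#'   return 0.
#' @param shape1,shape2 Gamma shape parameters of the response and
#'   undershoot components (defaults 6 and 16, unit rate).
#' @param undershoot_ratio Relative amplitude of the undershoot (default 1/6).
#' @return Numeric vector of HRF values, peak-normalised to 1.
#' @examples
#' t <- seq(0, 30, by = 0.5)
#' h <- hrf_double_gamma(t)
#' t[which.max(h)]  # peak near 5 s
#' @export
hrf_double_gamma <- function(t, shape1 = 6, shape2 = 16,
                             undershoot_ratio = 1 / 6) {
  h <- ifelse(t < 0, 0,
              dgamma(t, shape = shape1, rate = 1) -
                undershoot_ratio * dgamma(t, shape = shape2, rate = 1))
  # peak-normalise on a fine grid so scaling does not depend on `t`
  tf <- seq(0, 32, by = 0.01)
  peak <- max(dgamma(tf, shape = shape1, rate = 1) -
                undershoot_ratio * dgamma(tf, shape = shape2, rate = 1))
  h / peak
}

#' Hemodynamic response to a boxcar stimulus
#'
#' Convolves a boxcar of given duration with the canonical double-gamma HRF
#' and evaluates the result at arbitrary times. The response is
#' peak-normalised to 1 so that planted signal amplitudes are expressed at
#' the response peak.
#'
#' @param t Times in seconds relative to stimulus onset (vector; t < 0
#'   gives 0).
#' @param duration Boxcar (stimulus) duration in seconds (default 3, the
#'   video-clip length of the emulated task).
#' @param dt Convolution grid step in seconds.
#' @return Numeric vector of response values with maximum 1.
#' @export
hrf_boxcar_response <- function(t, duration = 3, dt = 0.05) {
  tmax <- max(40, max(t, 0) + dt)
  grid <- seq(0, tmax, by = dt)
  h <- hrf_double_gamma(grid)
  box <- as.numeric(grid < duration)
  resp <- stats::convolve(box, rev(h), type = "open")[seq_along(grid)] * dt
  resp <- resp / max(resp)
  out <- rep(0, length(t))
  ok <- t >= 0
  out[ok] <- stats::approx(grid, resp, xout = t[ok], rule = 2)$y
  out
}

#' Expected lag profile of a jittered trial window
#'
#' The trial-window extraction samples the hemodynamic response at scan
#' times, with the window anchored at the scan at or before each onset.
#' Because onsets are jittered off the scan grid, the planted (expected)
#' response at lag \eqn{l} is the average of the boxcar response over onset
#' phases uniform in one repetition time: the mean of the response over the
#' interval \eqn{[(l-1) TR, l TR]}. Lag 0 (the reference scan) is therefore
#' essentially 0, which matches the percent-signal-change convention where
#' the onset scan is the baseline.
#'
#' @param n_lags Number of post-onset time points (default 6).
#' @param tr_s Repetition time in seconds (default 3).
#' @param duration Stimulus duration in seconds (default 3).
#' @param phase_average Average over uniform onset phase within one TR
#'   (default TRUE); if FALSE the response is sampled exactly at lag times.
#' @return Numeric vector of length `n_lags` (lags 0 .. n_lags-1), maximum 1.
#' @export
hrf_lag_profile <- function(n_lags = 6, tr_s = 3, duration = 3,
                            phase_average = TRUE) {
  lags <- seq_len(n_lags) - 1
  if (!phase_average) {
    prof <- hrf_boxcar_response(lags * tr_s, duration = duration)
  } else {
    phases <- seq(0, tr_s, length.out = 61)[-61]
    prof <- vapply(lags, function(l) {
      mean(hrf_boxcar_response(l * tr_s - phases, duration = duration))
    }, numeric(1))
  }
  prof / max(prof)
}
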