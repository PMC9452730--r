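#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF used throughout the simulator: a positive gamma
#' density peaking near 6 s minus one sixth of a gamma density peaking
#' near 16 s (the post-stimulus undershoot). The sampled kernel is
#' normalised to unit time-integral so that the response to a sustained
#' block plateaus at the block amplitude.
#'
#' @param t Numeric vector of times in seconds (t >= 0).
#' @param peak Time-to-peak of the positive lobe in seconds (default 6).
#' @param undershoot Time-to-peak of the undershoot lobe (default 16).
#' @param ratio Undershoot amplitude ratio (default 1/6).
#' @return Numeric vector of HRF values at \code{t} (unnormalised; see
#'   [convolve_regressor()] for the normalised use).
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  stopifnot(is.numeric(t))
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h[t < 0] <- 0
  h
}

#' Convolve a condition boxcar with the canonical HRF
#'
#' Builds the 0/1 boxcar of a condition on a fine time grid, convolves it
#' with the canonical double-gamma HRF (normalised to unit integral on the
#' fine grid), and samples the result at volume onsets.
#'
#' @param labels Per-volume condition labels (character).
#' @param condition The condition whose boxcar to convolve.
#' @param tr Repetition time in seconds.
#' @param dt Fine time step for the convolution (default 0.1 s).
#' @param hrf_duration Length of the sampled HRF kernel in seconds
#'   (default 32).
#' @return Numeric vector, one expected-response value per volume. A
#'   sustained block plateaus at 1.
#' @export
convolve_regressor <- function(labels, condition, tr, dt = 0.1,
                               hrf_duration = 32) {
  convolve_indicator(as.numeric(labels == condition), tr, dt, hrf_duration)
}

#' @rdname convolve_regressor
#' @param indicator Per-volume 0/1 (or graded) stimulus indicator.
#' @export
convolve_indicator <- function(indicator, tr, dt = 0.1, hrf_duration = 32) {
  stopifnot(length(indicator) >= 1L, tr > 0, dt > 0)
  n <- length(indicator)
  up <- as.integer(round(tr / dt))
  if (abs(up * dt - tr) > 1e-9)
    stop("'dt' must divide the TR exactly")
  box <- rep(as.numeric(indicator), each = up)
  tk <- seq(0, hrf_duration, by = dt)
  kern <- hrf_double_gamma(tk)
  kern <- kern / (sum(kern) * dt)          # unit time-integral
  resp <- stats::convolve(box, rev(kern), type = "open")[seq_along(box)] * dt
  resp[1L + (seq_len(n) - 1L) * up]        # sample at volume onsets
}
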