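#' Subject profiles for the BOLD simulator
#'
#' A subject profile bundles everything the simulator needs to emit runs
#' for one person: the two condition activation patterns (in percent of
#' baseline), the baseline field, and the noise, drift and learning
#' parameters. Patterns may be given directly, or derived from a tutor
#' template with a stated \emph{pattern fidelity} -- the spatial
#' correlation between the subject's patterns and the template.
#'
#' @param pattern_happy,pattern_motor 3-D amplitude fields in percent of
#'   baseline; zero outside the brain support.
#' @param baseline Positive 3-D baseline field (arbitrary scanner units).
#' @param grid The \code{nf_grid} the fields live on.
#' @param pattern_fidelity Spatial correlation of this subject's patterns
#'   with the tutor template, in [0, 1].
#' @param noise_sigma Marginal standard deviation of the AR(1) noise, in
#'   percent of baseline.
#' @param ar1_coefficient Lag-1 autocorrelation of the noise, in [0, 1).
#' @param drift_amplitude Standard deviation of the per-voxel linear drift
#'   slope, in percent of baseline over the full run; 0 disables drift.
#' @param learning_rate Per-session increment of pattern fidelity
#'   (capped at 1).
#' @return An object of class \code{nf_subject}.
#' @export
subject_profile <- function(pattern_happy, pattern_motor, baseline, grid,
                            pattern_fidelity = 1, noise_sigma = 1,
                            ar1_coefficient = 0.3, drift_amplitude = 0.5,
                            learning_rate = 0) {
  stopifnot(inherits(grid, "nf_grid"))
  for (f in list(pattern_happy, pattern_motor, baseline))
    if (!is.array(f) || !identical(dim(f), as.integer(grid$dim)))
      stop("pattern and baseline fields must be 3-D arrays on the grid (",
           paste(grid$dim, collapse = "x"), ")")
  pars <- c(pattern_fidelity, noise_sigma, ar1_coefficient,
            drift_amplitude, learning_rate)
  if (any(!is.finite(pars)))
    stop("profile parameters must all be finite")
  if (any(!is.finite(pattern_happy)) || any(!is.finite(pattern_motor)) ||
      any(!is.finite(baseline)))
    stop("profile fields must be finite everywhere")
  if (pattern_fidelity < 0 || pattern_fidelity > 1)
    stop("'pattern_fidelity' must lie in [0, 1]")
  if (noise_sigma < 0) stop("'noise_sigma' must be non-negative")
  if (ar1_coefficient < 0 || ar1_coefficient >= 1)
    stop("'ar1_coefficient' must lie in [0, 1)")
  if (drift_amplitude < 0) stop("'drift_amplitude' must be non-negative")
  if (learning_rate < 0) stop("'learning_rate' must be non-negative")
  structure(list(pattern_happy = pattern_happy,
                 pattern_motor = pattern_motor,
                 baseline = baseline, grid = grid,
                 pattern_fidelity = pattern_fidelity,
                 noise_sigma = noise_sigma,
                 ar1_coefficient = ar1_coefficient,
                 drift_amplitude = drift_amplitude,
                 learning_rate = learning_rate,
                 template = NULL, idio = NULL, amplitude = NULL),
            class = "nf_subject")
}

#' Tutor profile: patterns identical to the template
#'
#' @param template An \code{nf_template} from [tutor_template()].
#' @param amplitude Peak-scaling of the unit-norm template patterns, in
#'   percent of baseline (default 30; with the default grid this puts the
#'   strongest voxels near a 1\% BOLD effect).
#' @inheritParams subject_profile
#' @return An \code{nf_subject} with \code{pattern_fidelity = 1}.
#' @export
tutor_profile <- function(template = tutor_template(), amplitude = 30,
                          noise_sigma = 1, ar1_coefficient = 0.3,
                          drift_amplitude = 0.5) {
  p <- subject_profile(amplitude * template$pattern_happy,
                       amplitude * template$pattern_motor,
                       template$baseline, template$grid,
                       pattern_fidelity = 1, noise_sigma = noise_sigma,
                       ar1_coefficient = ar1_coefficient,
                       drift_amplitude = drift_amplitude,
                       learning_rate = 0)
  p$template <- template
  p$amplitude <- amplitude
  p
}

# Draw a random smooth field on the support, orthogonal (over the
# support) to every field in `against`, unit L2 norm.
random_orthogonal_pattern <- function(template, against) {
  d <- template$grid$dim
  support <- template$support
  raw <- array(stats::rnorm(prod(d)), dim = d)
  # mild smoothing for spatial coherence
  raw <- smooth_volume(raw, fwhm_mm = 2 * template$grid$voxel_mm,
                       voxel_mm = template$grid$voxel_mm)
  v <- raw[support]
  v <- v - mean(v)
  for (g in against) {
    gv <- g[support]
    v <- v - sum(v * gv) * gv
  }
  out <- array(0, dim = d)
  out[support] <- v / sqrt(sum(v^2))
  out
}

#' Patient profile: imperfect copy of the tutor template
#'
#' During each task block the patient's instantaneous activation pattern
#' is a fidelity-weighted mixture of the tutor template and a random
#' pattern orthogonal to both template patterns:
#' \deqn{P_b = a (f T + \sqrt{1 - f^2} R_b)}
#' so that the spatial correlation between the instantaneous pattern and
#' the template equals the fidelity \eqn{f} exactly. The orthogonal
#' component \eqn{R_b} is drawn afresh for every block: it models
#' fluctuating, task-unrelated cognitive state rather than a stable
#' individual map, which is what lets a fidelity-0 subject classify at
#' chance against the tutor model. A positive \code{learning_rate} raises
#' the effective fidelity by that amount per training session (capped at
#' 1), emulating neurofeedback learning.
#'
#' @inheritParams tutor_profile
#' @param pattern_fidelity Initial spatial correlation with the template.
#' @param learning_rate Per-session fidelity increment.
#' @param seed Integer seed (kept for interface stability; block-level
#'   draws use the run seed of [simulate_run()]).
#' @return An \code{nf_subject} carrying the template, so fidelity can be
#'   re-mixed per session and per block.
#' @export
patient_profile <- function(template = tutor_template(),
                            pattern_fidelity = 0.3, learning_rate = 0.1,
                            seed = 1, amplitude = 30, noise_sigma = 1,
                            ar1_coefficient = 0.3, drift_amplitude = 0.5) {
  mix <- list(happy = amplitude * pattern_fidelity * template$pattern_happy,
              motor = amplitude * pattern_fidelity * template$pattern_motor)
  p <- subject_profile(mix$happy, mix$motor, template$baseline,
                       template$grid,
                       pattern_fidelity = pattern_fidelity,
                       noise_sigma = noise_sigma,
                       ar1_coefficient = ar1_coefficient,
                       drift_amplitude = drift_amplitude,
                       learning_rate = learning_rate)
  p$template <- template
  p$amplitude <- amplitude
  p$profile_seed <- seed
  p
}

#' Draw one instantaneous block pattern for a subject
#'
#' The realised activation pattern of a single task block: template part
#' weighted by the session fidelity plus a freshly drawn orthogonal
#' component. Exposed mainly so the fidelity-correlation contract can be
#' checked directly.
#'
#' @param profile An \code{nf_subject} built by [patient_profile()] (or
#'   [tutor_profile()], whose fidelity-1 patterns have no random part).
#' @param condition \code{"HAPPY"} or \code{"MOTOR"}.
#' @param session 1-based session number.
#' @return 3-D pattern field in percent of baseline. Draws from the
#'   current RNG stream; seed it (or use inside [with_seed] semantics of
#'   [simulate_run()]) for reproducibility.
#' @export
draw_block_pattern <- function(profile, condition = c("HAPPY", "MOTOR"),
                               session = 1) {
  condition <- match.arg(condition)
  stopifnot(inherits(profile, "nf_subject"))
  tpl <- profile$template
  if (is.null(tpl))
    return(if (condition == "HAPPY") profile$pattern_happy
           else profile$pattern_motor)
  f <- session_fidelity(profile, session)
  base <- if (condition == "HAPPY") tpl$pattern_happy else tpl$pattern_motor
  w <- sqrt(max(0, 1 - f^2))
  out <- profile$amplitude * f * base
  if (w > 0) {
    R <- random_orthogonal_pattern(
      tpl, list(tpl$pattern_happy, tpl$pattern_motor))
    out <- out + profile$amplitude * w * R
  }
  out
}

#' Effective pattern fidelity at a given training session
#'
#' @param profile An \code{nf_subject}.
#' @param session 1-based session number.
#' @return \code{min(1, pattern_fidelity + (session - 1) * learning_rate)}.
#' @export
session_fidelity <- function(profile, session = 1) {
  stopifnot(inherits(profile, "nf_subject"), session >= 1)
  min(1, profile$pattern_fidelity + (session - 1) * profile$learning_rate)
}

# Expected (template-aligned) patterns in effect at a session; the
# orthogonal per-block component is drawn inside simulate_run.
session_patterns <- function(profile, session = 1) {
  if (is.null(profile$template))
    return(list(happy = profile$pattern_happy, motor = profile$pattern_motor))
  f <- session_fidelity(profile, session)
  list(happy = profile$amplitude * f * profile$template$pattern_happy,
       motor = profile$amplitude * f * profile$template$pattern_motor)
}
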