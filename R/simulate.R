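#' 4-D BOLD run container
#'
#' @param data 4-D numeric array (x, y, z, t).
#' @param affine 4x4 voxel-to-world transform.
#' @param tr Repetition time in seconds.
#' @param labels Per-volume condition labels (length = t extent).
#' @return An object of class \code{nf_bold_run}.
#' @export
bold_run <- function(data, affine, tr, labels) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("'data' must be a 4-D array (x, y, z, t)")
  if (!is.matrix(affine) || !identical(dim(affine), c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a positive duration in seconds")
  if (length(labels) != dim(data)[4])
    stop("label sequence length (", length(labels),
         ") must equal the number of volumes (", dim(data)[4], ")")
  if (any(!is.finite(data))) stop("run intensities must all be finite")
  structure(list(data = data, affine = affine, tr_seconds = tr,
                 labels = as.character(labels)),
            class = "nf_bold_run")
}

#' @export
print.nf_bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD run: %dx%dx%d voxels, %d volumes at TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr_seconds))
  counts <- table(factor(x$labels, levels = nf_conditions()))
  cat("  volumes per condition: ",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}

#' Number of volumes in a run
#' @param run An \code{nf_bold_run}.
#' @return Integer count of volumes.
#' @export
n_volumes <- function(run) {
  stopifnot(inherits(run, "nf_bold_run"))
  dim(run$data)[4]
}

#' Simulate a block-design BOLD run
#'
#' Generates one run for a subject as
#' \deqn{Y_v(t) = B_v \left(1 + \sum_c \frac{P_{c,v}}{100}\, (x_c \ast h)(t)\right)
#'   + \mathrm{drift}_v(t) + \varepsilon_v(t)}
#' where \eqn{B} is the baseline field, \eqn{P_c} the condition pattern in
#' percent of baseline, \eqn{x_c \ast h} the condition boxcar convolved
#' with the canonical double-gamma HRF (plateau 1), drift a per-voxel
#' linear trend and \eqn{\varepsilon} AR(1) noise with marginal standard
#' deviation \code{noise_sigma} percent of baseline. Drift and noise are
#' confined to the brain support (voxels with positive baseline).
#' Identical seed and inputs give bit-identical output.
#'
#' @param paradigm An \code{nf_paradigm}.
#' @param profile An \code{nf_subject}.
#' @param session 1-based training session; with a positive
#'   \code{learning_rate} the subject's effective pattern fidelity is
#'   \code{min(1, pattern_fidelity + (session - 1) * learning_rate)}.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return An \code{nf_bold_run}.
#' @export
simulate_run <- function(paradigm, profile, session = 1, seed = 1) {
  stopifnot(inherits(paradigm, "nf_paradigm"), inherits(profile, "nf_subject"))
  labels <- volume_labels(paradigm)
  nt <- paradigm$n_volumes
  d <- profile$grid$dim
  b <- as.vector(profile$baseline)
  nv <- length(b)
  f <- session_fidelity(profile, session)
  per_block <- !is.null(profile$template) && f < 1
  ymat <- matrix(b, nrow = nv, ncol = nt)
  if (!per_block) {
    pat <- session_patterns(profile, session)
    conv_h <- convolve_regressor(labels, "HAPPY", paradigm$tr_seconds)
    conv_m <- convolve_regressor(labels, "MOTOR", paradigm$tr_seconds)
    # signal: baseline x (1 + happy + motor), voxels x time
    ymat <- b * (1 + outer(as.vector(pat$happy) / 100, conv_h) +
                   outer(as.vector(pat$motor) / 100, conv_m))
  }
  inside <- b > 0
  with_seed(seed, {
    if (per_block) {
      # instantaneous per-block patterns: template part at the session
      # fidelity plus a fresh orthogonal component every block
      block <- volume_blocks(paradigm)
      cond <- paradigm$blocks$condition
      resp <- matrix(0, nrow = nv, ncol = nt)
      for (bi in which(cond %in% c("HAPPY", "MOTOR"))) {
        pat_b <- draw_block_pattern(profile, cond[bi], session)
        ind <- as.numeric(block == bi)
        conv_b <- convolve_indicator(ind, paradigm$tr_seconds)
        live <- which(abs(conv_b) > 1e-9)        # block window + HRF tail
        resp[, live] <- resp[, live] +
          outer(as.vector(pat_b) / 100, conv_b[live])
      }
      ymat <- b * (1 + resp)
    }
    if (profile$drift_amplitude > 0) {
      slope <- stats::rnorm(nv, sd = profile$drift_amplitude)
      tt <- seq(-0.5, 0.5, length.out = nt)
      ymat[inside, ] <- ymat[inside, ] +
        (b[inside] / 100) * outer(slope[inside], tt)
    }
    if (profile$noise_sigma > 0) {
      rho <- profile$ar1_coefficient
      innov_sd <- profile$noise_sigma * sqrt(1 - rho^2)
      nin <- sum(inside)
      eps <- matrix(stats::rnorm(nin * nt, sd = innov_sd), nrow = nt)
      if (rho > 0) {
        eps[1, ] <- eps[1, ] / sqrt(1 - rho^2)   # stationary start
        for (t in 2:nt) eps[t, ] <- rho * eps[t - 1, ] + eps[t, ]
      }
      ymat[inside, ] <- ymat[inside, ] + (b[inside] / 100) * t(eps)
    }
  })
  bold_run(array(ymat, dim = c(d, nt)), profile$grid$affine,
           paradigm$tr_seconds, labels)
}
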