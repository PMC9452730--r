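# Offline preprocessing for classifier construction and the abbreviated
# online variant driven by dummy-run normalisation parameters.

#' Discard initial volumes of a run
#'
#' Removes the first \code{n} volumes (gradient-stabilisation artifact
#' window) and trims the label sequence consistently.
#'
#' @param run An \code{nf_bold_run}.
#' @param n Number of initial volumes to discard (default 10).
#' @return The shortened \code{nf_bold_run}.
#' @export
discard_initial <- function(run, n = 10) {
  stopifnot(inherits(run, "nf_bold_run"))
  nt <- n_volumes(run)
  if (n < 0 || n != round(n)) stop("'n' must be a non-negative integer")
  if (n >= nt)
    stop("cannot discard ", n, " volumes from a ", nt, "-volume run")
  if (n == 0) return(run)
  keep <- (n + 1):nt
  bold_run(run$data[, , , keep, drop = FALSE], run$affine,
           run$tr_seconds, run$labels[keep])
}

## ---- Gaussian smoothing -------------------------------------------------

gaussian_kernel_1d <- function(fwhm_mm, voxel_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm   # in voxels
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# Banded convolution matrix (zero padding at the edges).
conv_band_matrix <- function(n, kernel, sparse = FALSE) {
  r <- (length(kernel) - 1L) / 2L
  i <- rep(seq_len(n), each = length(kernel))
  j <- i + rep(-r:r, times = n)
  v <- rep(kernel, times = n)
  ok <- j >= 1 & j <= n
  if (sparse)
    Matrix::sparseMatrix(i = i[ok], j = j[ok], x = v[ok], dims = c(n, n))
  else {
    m <- matrix(0, n, n)
    m[cbind(i[ok], j[ok])] <- v[ok]
    m
  }
}

#' Gaussian smoothing of a 3-D volume
#'
#' Separable Gaussian convolution with the stated full width at half
#' maximum; \code{fwhm_mm = 0} is the identity. Edges use zero padding, so
#' total intensity is conserved for mass away from the boundary.
#'
#' @param volume 3-D numeric array.
#' @param fwhm_mm Kernel FWHM in millimetres.
#' @param voxel_mm Isotropic voxel size in millimetres (default 3).
#' @return The smoothed 3-D array.
#' @export
smooth_volume <- function(volume, fwhm_mm, voxel_mm = 3) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  if (!is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("'fwhm_mm' must be a non-negative number")
  if (fwhm_mm == 0) return(volume)
  d <- dim(volume)
  k <- gaussian_kernel_1d(fwhm_mm, voxel_mm)
  out <- volume
  for (axis in 1:3) {
    K <- conv_band_matrix(d[axis], k)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(out, perm), nrow = d[axis])
    m <- K %*% m
    out <- aperm(array(m, dim = d[perm]), order(perm))
  }
  out
}

# Sparse 3-D smoothing operator on a flattened grid; `rows` restricts the
# output to selected voxel indices (used by the online engine, which only
# needs smoothed values at the model's informative voxels). Results are
# memoised: the closed feedback loop requests the same operator for every
# volume of every run.
.smooth_op_cache <- new.env(parent = emptyenv())

smoothing_operator <- function(dim, fwhm_mm, voxel_mm = 3, rows = NULL) {
  key <- paste(c(dim, fwhm_mm, voxel_mm, length(rows),
                 if (length(rows)) sum(as.double(rows))), collapse = "|")
  hit <- .smooth_op_cache[[key]]
  if (!is.null(hit) && identical(hit$rows, rows)) return(hit$S)
  S <- smoothing_operator_build(dim, fwhm_mm, voxel_mm, rows)
  .smooth_op_cache[[key]] <- list(rows = rows, S = S)
  S
}

smoothing_operator_build <- function(dim, fwhm_mm, voxel_mm = 3,
                                     rows = NULL) {
  if (fwhm_mm == 0) {
    S <- Matrix::Diagonal(prod(dim))
    return(if (is.null(rows)) S else S[rows, , drop = FALSE])
  }
  k <- gaussian_kernel_1d(fwhm_mm, voxel_mm)
  Kx <- conv_band_matrix(dim[1], k, sparse = TRUE)
  Ky <- conv_band_matrix(dim[2], k, sparse = TRUE)
  Kz <- conv_band_matrix(dim[3], k, sparse = TRUE)
  S <- Matrix::kronecker(Kz, Matrix::kronecker(Ky, Kx))
  if (is.null(rows)) S else S[rows, , drop = FALSE]
}

## ---- resampling ---------------------------------------------------------

# Trilinear sampling of `vol` at 0-based voxel coordinates (3 x N matrix);
# points outside the grid sample to 0.
trilinear_sample <- function(vol, coords) {
  d <- dim(vol)
  x <- coords[1, ]; y <- coords[2, ]; z <- coords[3, ]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- numeric(length(x))
  at <- function(i, j, k) {
    ok <- i >= 0 & i < d[1] & j >= 0 & j < d[2] & k >= 0 & k < d[3]
    v <- numeric(length(i))
    idx <- 1 + i[ok] + d[1] * (j[ok] + d[2] * k[ok])
    v[ok] <- vol[idx]
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    val <- val + w * at(x0 + dx, y0 + dy, z0 + dz)
  }
  val
}

# 0-based voxel index grid of a 3-D array, as a 4 x N homogeneous matrix.
voxel_grid_hom <- function(dim) {
  g <- as.matrix(expand.grid(x = 0:(dim[1] - 1), y = 0:(dim[2] - 1),
                             z = 0:(dim[3] - 1)))
  t(cbind(g, 1))
}

#' Resample a volume onto a target grid through a world-space affine
#'
#' @param volume 3-D array on the source grid.
#' @param src_affine 4x4 voxel-to-world transform of the source.
#' @param target_dim Integer length-3 target grid dimensions.
#' @param target_affine 4x4 voxel-to-world transform of the target.
#' @param world_affine 4x4 source-world to target-world transform
#'   (default identity).
#' @return 3-D array on the target grid (trilinear interpolation, zero
#'   outside the source field of view).
#' @export
resample_volume <- function(volume, src_affine, target_dim, target_affine,
                            world_affine = diag(4)) {
  hom <- voxel_grid_hom(target_dim)
  src_vox <- solve(src_affine) %*% solve(world_affine) %*% target_affine %*% hom
  array(trilinear_sample(volume, src_vox[1:3, , drop = FALSE]),
        dim = target_dim)
}

## ---- rigid realignment --------------------------------------------------

rotation_matrix <- function(rx, ry, rz) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# World-space rigid transform (rotation about `centre`, then translation)
# as a 4x4 matrix. p = (tx, ty, tz in mm, rx, ry, rz in radians).
rigid_affine <- function(p, centre) {
  R <- rotation_matrix(p[4], p[5], p[6])
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- centre + p[1:3] - R %*% centre
  A
}

#' Rigid-body realignment of a run to its first volume
#'
#' Estimates 6 rigid-body parameters (3 translations in mm, 3 rotations in
#' radians, about the grid centre) per volume by minimising the mean
#' squared intensity difference to volume 1 under trilinear resampling,
#' then resamples each volume with its estimated transform. Volumes are
#' initialised from the previous volume's estimate, so drift-free runs
#' converge immediately.
#'
#' @param run An \code{nf_bold_run} with at least 2 volumes.
#' @return A list with \code{run} (the realigned \code{nf_bold_run}) and
#'   \code{report}, a data frame of class \code{nf_preproc_report} with
#'   one row per volume: \code{tx, ty, tz, rx, ry, rz} and the per-volume
#'   wall time \code{elapsed_s}.
#' @export
realign <- function(run) {
  stopifnot(inherits(run, "nf_bold_run"))
  nt <- n_volumes(run)
  if (nt < 2) stop("realignment needs at least 2 volumes")
  d <- dim(run$data)[1:3]
  ref <- run$data[, , , 1]
  if (all(ref == 0)) stop("degenerate reference volume (all zero)")
  centre <- (run$affine %*% c((d - 1) / 2, 1))[1:3]
  hom <- voxel_grid_hom(d)
  world <- run$affine %*% hom            # world coords of each voxel
  inv_vox <- solve(run$affine)
  mask <- abs(ref) > 0.05 * max(abs(ref))
  resampled_at <- function(vol, p) {
    moved <- rigid_affine(p, centre) %*% world
    trilinear_sample(vol, (inv_vox %*% moved)[1:3, , drop = FALSE])
  }
  # valid flag: transformed coordinates inside the moving volume, so
  # content lost at the field-of-view boundary does not bias the fit
  valid_at <- function(p) {
    vox <- (inv_vox %*% (rigid_affine(p, centre) %*% world))[1:3, ,
                                                             drop = FALSE]
    vox[1, ] >= 0 & vox[1, ] <= d[1] - 1 &
      vox[2, ] >= 0 & vox[2, ] <= d[2] - 1 &
      vox[3, ] >= 0 & vox[3, ] <= d[3] - 1
  }
  out <- run$data
  pars <- matrix(0, nrow = nt, ncol = 6,
                 dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
  elapsed <- numeric(nt)
  p0 <- rep(0, 6)
  for (t in 2:nt) {
    vol <- run$data[, , , t]
    if (all(vol == 0)) stop("degenerate volume (all zero) at index ", t)
    t0 <- proc.time()[["elapsed"]]
    cost <- function(p) {
      use <- mask & valid_at(p)
      if (sum(use) < 0.5 * sum(mask)) return(Inf)
      s <- resampled_at(vol, p)
      mean((s[use] - ref[use])^2)
    }
    ps <- c(1, 1, 1, 0.02, 0.02, 0.02)
    starts <- if (max(abs(p0)) > 1e-8) list(rep(0, 6), p0) else list(rep(0, 6))
    fit <- NULL
    for (s in starts) {
      f <- stats::optim(s, cost, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-9,
                                       parscale = ps))
      f <- stats::optim(f$par, cost, method = "BFGS",
                        control = list(maxit = 50, reltol = 1e-12,
                                       parscale = ps))
      if (is.null(fit) || f$value < fit$value) fit <- f
    }
    pars[t, ] <- fit$par
    out[, , , t] <- array(resampled_at(vol, fit$par), dim = d)
    elapsed[t] <- proc.time()[["elapsed"]] - t0
    p0 <- fit$par
  }
  report <- data.frame(volume = seq_len(nt), pars, elapsed_s = elapsed)
  class(report) <- c("nf_preproc_report", "data.frame")
  list(run = bold_run(out, run$affine, run$tr_seconds, run$labels),
       report = report)
}

## ---- slice-timing correction --------------------------------------------

slice_acquisition_order <- function(n_slices, slice_order) {
  if (is.numeric(slice_order)) {
    ord <- as.integer(slice_order)
    if (!setequal(ord, seq_len(n_slices)))
      stop("numeric slice order must be a permutation of 1..", n_slices)
    return(ord)
  }
  switch(as.character(slice_order),
         ascending = seq_len(n_slices),
         descending = rev(seq_len(n_slices)),
         interleaved_ascending = c(seq(1, n_slices, by = 2),
                                   seq(2, n_slices, by = 2)),
         stop("unknown slice order token: '", slice_order, "'"))
}

# Shift each column of a time x series matrix by `delta` samples
# (positive = evaluate the underlying signal later) via Fourier
# interpolation; exact for band-limited signals.
fourier_shift <- function(mat, delta) {
  n <- nrow(mat)
  if (delta == 0) return(mat)
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
  phase <- exp(2i * pi * k * delta / n)
  if (n %% 2 == 0) phase[n / 2 + 1] <- cos(pi * delta)  # real Nyquist bin
  Re(stats::mvfft(stats::mvfft(mat) * phase, inverse = TRUE) / n)
}

#' Slice-timing correction
#'
#' Resamples every voxel's time series to a common reference slice time by
#' Fourier interpolation, given the slice acquisition order along the
#' third (z) axis. Slices are assumed equally spaced within the TR.
#'
#' @param run An \code{nf_bold_run} with at least 2 volumes.
#' @param slice_order \code{"interleaved_ascending"} (default),
#'   \code{"ascending"}, \code{"descending"}, or an integer permutation
#'   giving the acquisition order of the slices.
#' @param ref_slice Slice whose acquisition time is the temporal reference
#'   (default 1).
#' @return The corrected \code{nf_bold_run}.
#' @export
slice_time_correct <- function(run, slice_order = "interleaved_ascending",
                               ref_slice = 1) {
  stopifnot(inherits(run, "nf_bold_run"))
  nt <- n_volumes(run)
  if (nt < 2) stop("slice-timing correction needs at least 2 volumes")
  d <- dim(run$data)
  nsl <- d[3]
  ord <- slice_acquisition_order(nsl, slice_order)
  acq_time <- numeric(nsl)
  acq_time[ord] <- (seq_len(nsl) - 1) / nsl * run$tr_seconds
  out <- run$data
  for (s in seq_len(nsl)) {
    delta <- (acq_time[ref_slice] - acq_time[s]) / run$tr_seconds
    if (delta == 0) next
    m <- matrix(run$data[, , s, ], nrow = d[1] * d[2], ncol = nt)
    out[, , s, ] <- array(t(fourier_shift(t(m), delta)), dim = c(d[1], d[2], nt))
  }
  bold_run(out, run$affine, run$tr_seconds, run$labels)
}

## ---- spatial normalisation ----------------------------------------------

#' Normalisation parameters
#'
#' @param affine_to_template 4x4 source-world to template-world transform.
#' @param target_dim,target_affine Template grid shape and voxel-to-world
#'   transform.
#' @param smoothing_fwhm_mm Gaussian FWHM applied after resampling
#'   (default 6, the online default).
#' @param voxel_mm Template voxel size in millimetres.
#' @return An object of class \code{nf_norm_params}.
#' @export
norm_params <- function(affine_to_template, target_dim, target_affine,
                        smoothing_fwhm_mm = 6, voxel_mm = 3) {
  if (!is.matrix(affine_to_template) ||
      !identical(dim(affine_to_template), c(4L, 4L)) ||
      abs(det(affine_to_template)) < 1e-12)
    stop("'affine_to_template' must be an invertible 4x4 matrix")
  if (smoothing_fwhm_mm < 0) stop("'smoothing_fwhm_mm' must be >= 0")
  structure(list(affine_to_template = affine_to_template,
                 target_dim = as.integer(target_dim),
                 target_affine = target_affine,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 voxel_mm = voxel_mm),
            class = "nf_norm_params")
}

# Decompose 12 parameters into a world affine:
# translation (3), rotation (3), log-scale (3), shear (3).
affine_from_params <- function(p) {
  A <- diag(4)
  S <- diag(exp(p[7:9]))
  Sh <- diag(3); Sh[1, 2] <- p[10]; Sh[1, 3] <- p[11]; Sh[2, 3] <- p[12]
  A[1:3, 1:3] <- rotation_matrix(p[4], p[5], p[6]) %*% Sh %*% S
  A[1:3, 4] <- p[1:3]
  A
}

#' Estimate normalisation parameters from a dummy run
#'
#' Averages the dummy run over time and registers the mean image to the
#' template with a 12-parameter world-space affine (translation, rotation,
#' scale, shear), optimised in stages (translation, then rigid, then full
#' affine) by Nelder-Mead on 1 - spatial correlation. Deterministic given
#' its inputs.
#'
#' @param dummy_run An \code{nf_bold_run}; a 1-minute acquisition (30
#'   volumes at TR 2 s) is the intended use.
#' @param template 3-D template field.
#' @param template_affine Voxel-to-world transform of the template grid.
#' @param smoothing_fwhm_mm FWHM stored in the returned parameters
#'   (default 6).
#' @return An \code{nf_norm_params}.
#' @export
estimate_norm_params <- function(dummy_run, template, template_affine,
                                 smoothing_fwhm_mm = 6) {
  stopifnot(inherits(dummy_run, "nf_bold_run"), is.array(template),
            length(dim(template)) == 3L)
  mean_img <- apply(dummy_run$data, 1:3, mean)
  tdim <- dim(template)
  hom <- voxel_grid_hom(tdim)
  tpl_world <- template_affine %*% hom
  inv_src <- solve(dummy_run$affine)
  tmask <- abs(template) > 0.05 * max(abs(template))
  if (!any(tmask)) stop("registration failure: empty template support")
  tvals <- template[tmask]
  midx <- which(as.vector(tmask))
  sdim <- dim(mean_img)
  cost <- function(p) {
    M <- affine_from_params(p)
    src_vox <- (inv_src %*% solve(M) %*% tpl_world[, midx, drop = FALSE])
    v <- src_vox[1:3, , drop = FALSE]
    ok <- v[1, ] >= 0 & v[1, ] <= sdim[1] - 1 &
      v[2, ] >= 0 & v[2, ] <= sdim[2] - 1 &
      v[3, ] >= 0 & v[3, ] <= sdim[3] - 1
    if (sum(ok) < 0.5 * length(midx)) return(2)
    s <- trilinear_sample(mean_img, v[, ok, drop = FALSE])
    if (stats::sd(s) == 0) return(2)
    1 - stats::cor(s, tvals[ok])
  }
  p <- rep(0, 12)
  stages <- list(1:3, 1:6, 1:12)
  scale <- c(1, 1, 1, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02)
  for (idx in stages) {
    fit <- stats::optim(p[idx], function(q) { pp <- p; pp[idx] <- q; cost(pp) },
                        method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-12,
                                       parscale = scale[idx]))
    p[idx] <- fit$par
  }
  if (cost(p) > 0.5)
    stop("registration failure: residual correlation below 0.5 between ",
         "mean dummy image and template")
  norm_params(affine_from_params(p), tdim, template_affine,
              smoothing_fwhm_mm = smoothing_fwhm_mm,
              voxel_mm = abs(template_affine[1, 1]))
}

#' Normalise and smooth a single volume (shared offline/online core)
#'
#' Resamples a volume onto the template grid through the stored affine and
#' applies the stored Gaussian smoothing. This is the whole per-volume
#' online path; the offline path applies the identical operation per
#' volume, so the two agree voxel-wise by construction.
#'
#' @param volume 3-D array on the source grid.
#' @param params An \code{nf_norm_params}; online mode must never
#'   re-estimate, so this argument is mandatory.
#' @param src_affine Voxel-to-world transform of the source volume.
#' @return 3-D array on the template grid.
#' @export
online_preprocess <- function(volume, params, src_affine) {
  if (missing(params) || is.null(params))
    stop("normalisation parameters are required (estimate them from the ",
         "dummy run first; online mode never re-estimates)")
  stopifnot(inherits(params, "nf_norm_params"))
  out <- resample_volume(volume, src_affine, params$target_dim,
                         params$target_affine,
                         world_affine = params$affine_to_template)
  smooth_volume(out, params$smoothing_fwhm_mm, params$voxel_mm)
}

#' Normalise and smooth every volume of a run (offline path)
#'
#' @param run An \code{nf_bold_run}.
#' @param params An \code{nf_norm_params}.
#' @return An \code{nf_bold_run} on the template grid.
#' @export
normalize_run <- function(run, params) {
  stopifnot(inherits(run, "nf_bold_run"), inherits(params, "nf_norm_params"))
  nt <- n_volumes(run)
  d <- dim(run$data)[1:3]
  identity_map <- identical(as.integer(d), params$target_dim) &&
    max(abs(params$affine_to_template - diag(4))) < 1e-12 &&
    max(abs(params$target_affine - run$affine)) < 1e-12
  if (identity_map) {
    # pure smoothing: one sparse operator applied to all volumes at once
    S <- smoothing_operator(d, params$smoothing_fwhm_mm, params$voxel_mm)
    out <- as.matrix(S %*% matrix(run$data, ncol = nt))
    return(bold_run(array(out, dim = c(d, nt)), params$target_affine,
                    run$tr_seconds, run$labels))
  }
  out <- array(0, dim = c(params$target_dim, nt))
  for (t in seq_len(nt))
    out[, , , t] <- online_preprocess(run$data[, , , t], params, run$affine)
  bold_run(out, params$target_affine, run$tr_seconds, run$labels)
}
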