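# Simulation grid, brain support and the tutor activation template.

#' Define a simulation grid
#'
#' @param dim Integer length-3 voxel dimensions (default 20 x 24 x 20,
#'   a desk-scale stand-in for a whole-brain EPI matrix).
#' @param voxel_mm Isotropic voxel size in millimetres (default 3).
#' @return A list of class \code{nf_grid} with \code{dim}, \code{voxel_mm}
#'   and a voxel-to-world \code{affine} (RAS, centred on the grid).
#' @export
sim_grid <- function(dim = c(20L, 24L, 20L), voxel_mm = 3) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 2L), voxel_mm > 0)
  affine <- diag(4)
  diag(affine)[1:3] <- voxel_mm
  affine[1:3, 4] <- -voxel_mm * (dim - 1) / 2
  structure(list(dim = dim, voxel_mm = voxel_mm, affine = affine),
            class = "nf_grid")
}

#' Ellipsoidal brain support of a grid
#'
#' @param grid An \code{nf_grid}.
#' @param shrink Fraction of each half-dimension used as the ellipsoid
#'   semi-axis (default 0.9).
#' @return Logical 3-D array, TRUE inside the simulated brain.
#' @export
brain_support <- function(grid, shrink = 0.9) {
  stopifnot(inherits(grid, "nf_grid"))
  d <- grid$dim
  cx <- (d + 1) / 2
  ax <- shrink * (d - 1) / 2
  ix <- (seq_len(d[1]) - cx[1]) / ax[1]
  iy <- (seq_len(d[2]) - cx[2]) / ax[2]
  iz <- (seq_len(d[3]) - cx[3]) / ax[3]
  r2 <- outer(outer(ix^2, iy^2, "+"), iz^2, "+")
  array(r2 <= 1, dim = d)
}

# Smooth Gaussian bump centred at voxel `centre` with sd `width` voxels.
gaussian_bump <- function(dim, centre, width) {
  ix <- (seq_len(dim[1]) - centre[1]) / width
  iy <- (seq_len(dim[2]) - centre[2]) / width
  iz <- (seq_len(dim[3]) - centre[3]) / width
  exp(-0.5 * outer(outer(ix^2, iy^2, "+"), iz^2, "+"))
}

# Centre a field over the support and scale it to unit L2 norm there;
# zero outside the support.
normalise_pattern <- function(field, support) {
  v <- field[support]
  v <- v - mean(v)
  n <- sqrt(sum(v^2))
  if (n == 0) stop("degenerate (constant) pattern field")
  out <- array(0, dim = dim(field))
  out[support] <- v / n
  out
}

#' The tutor activation template
#'
#' Deterministic two-condition spatial template on a simulation grid: the
#' happy-imagery pattern is a pair of anterior/ventral Gaussian clusters,
#' the motor-imagery pattern a pair of dorsal clusters (a schematic
#' emotional network versus motor strip). Both patterns are mean-centred
#' over the brain support, mutually orthogonalised and scaled to unit L2
#' norm, so that pattern fidelity can be expressed as an exact spatial
#' correlation.
#'
#' @param grid An \code{nf_grid} (default [sim_grid()]).
#' @return A list of class \code{nf_template} with the grid, the brain
#'   \code{support}, a positive \code{baseline} field (100 inside the
#'   support, 0 outside) and unit-norm pattern fields
#'   \code{pattern_happy}, \code{pattern_motor}.
#' @export
tutor_template <- function(grid = sim_grid()) {
  stopifnot(inherits(grid, "nf_grid"))
  d <- grid$dim
  support <- brain_support(grid)
  baseline <- array(0, dim = d)
  baseline[support] <- 100
  frac <- function(f) 1 + round(f * (d - 1))
  happy <- gaussian_bump(d, frac(c(0.30, 0.25, 0.35)), width = 2) +
    gaussian_bump(d, frac(c(0.70, 0.25, 0.35)), width = 2) +
    0.6 * gaussian_bump(d, frac(c(0.50, 0.40, 0.25)), width = 2.5)
  motor <- gaussian_bump(d, frac(c(0.35, 0.55, 0.80)), width = 2) +
    gaussian_bump(d, frac(c(0.65, 0.55, 0.80)), width = 2)
  happy[!support] <- 0
  motor[!support] <- 0
  h0 <- normalise_pattern(happy, support)
  # orthogonalise motor against happy over the support, then renormalise
  m <- motor
  m[support] <- motor[support] - sum(motor[support] * h0[support]) * h0[support]
  m0 <- normalise_pattern(m, support)
  structure(list(grid = grid, support = support, baseline = baseline,
                 pattern_happy = h0, pattern_motor = m0),
            class = "nf_template")
}

# Spatial (Pearson) correlation of two fields over a support mask.
#' Spatial correlation of two pattern fields over a support mask
#' @param a,b 3-D arrays of matching dimension.
#' @param support Logical array; correlation is computed over TRUE voxels.
#' @return Pearson correlation coefficient.
#' @export
pattern_correlation <- function(a, b, support) {
  stats::cor(a[support], b[support])
}
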