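#' Read and write BOLD runs as NIfTI-1 with a YAML label sidecar
#'
#' Runs are stored as standard NIfTI-1 images (\code{.nii} or
#' \code{.nii.gz}); the per-volume condition labels and the TR are kept in
#' a YAML sidecar named \code{<image>.labels.yaml} next to the image; the
#' sidecar is authoritative for both.
#'
#' @param run An \code{nf_bold_run}.
#' @param path Image path ending in \code{.nii} or \code{.nii.gz}.
#' @return \code{write_run} returns \code{path} invisibly;
#'   \code{read_run} returns an \code{nf_bold_run}.
#' @name run_io
NULL

sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".labels.yaml")
}

#' @rdname run_io
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "nf_bold_run"))
  img <- RNifti::asNifti(run$data)
  img <- RNifti::`sform<-`(img, structure(run$affine, code = 2L))
  # spatial pixdims follow from the sform; the TR is authoritative in the
  # sidecar (and is re-read from there)
  RNifti::writeNifti(img, path)
  yaml::write_yaml(list(tr_seconds = run$tr_seconds,
                        labels = as.list(run$labels)),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname run_io
#' @export
read_run <- function(path) {
  if (!file.exists(path)) stop("no such image: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("malformed NIfTI header: field 'dim' does not describe a 4-D ",
         "image (got ", length(d), " dimensions)")
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing label sidecar: ", sc)
  meta <- yaml::read_yaml(sc)
  labels <- unlist(meta$labels)
  if (length(labels) != d[4])
    stop("sidecar label sequence length (", length(labels),
         ") does not match the image t-dimension (", d[4], ")")
  tr <- meta$tr_seconds
  if (is.null(tr) || !is.numeric(tr) || tr <= 0)
    stop("malformed sidecar: field 'tr_seconds' missing or non-positive")
  affine <- unclass(RNifti::xform(img))
  bold_run(array(as.numeric(img), dim = d), affine, tr, labels)
}
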