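#' Block-design paradigms
#'
#' A paradigm is an ordered, contiguous sequence of condition blocks
#' (\code{REST}, \code{HAPPY}, \code{MOTOR}) sampled at a fixed repetition
#' time (TR). The default scheme reproduces a 7-minute neurofeedback run:
#' 20 s of rest followed by 4 repetitions of (40 s happy autobiographical
#' imagery, 40 s motor imagery, 20 s rest), i.e. 420 s = 210 volumes at
#' TR = 2 s.
#'
#' @name paradigm
NULL

#' Conditions recognised by the paradigm
#' @return Character vector of the three condition labels.
#' @export
nf_conditions <- function() c("REST", "HAPPY", "MOTOR")

#' Default block scheme
#'
#' 20 s rest, then 4 repetitions of 40 s HAPPY, 40 s MOTOR, 20 s REST.
#'
#' @return A data frame with columns \code{condition} and \code{duration}
#'   (seconds), one row per block.
#' @export
default_block_scheme <- function() {
  cond <- c("REST", rep(c("HAPPY", "MOTOR", "REST"), 4L))
  dur <- c(20, rep(c(40, 40, 20), 4L))
  data.frame(condition = cond, duration = dur, stringsAsFactors = FALSE)
}

#' Build a block-design paradigm
#'
#' @param tr Repetition time in seconds (default 2).
#' @param scheme Data frame with columns \code{condition} (one of
#'   \code{REST}, \code{HAPPY}, \code{MOTOR}) and \code{duration} in
#'   seconds. Defaults to [default_block_scheme()].
#' @return An object of class \code{nf_paradigm} with fields
#'   \code{tr_seconds}, \code{blocks} (condition, onset, duration) and
#'   \code{n_volumes}.
#' @examples
#' p <- build_paradigm()
#' p$n_volumes            # 210
#' table(volume_labels(p))
#' @export
build_paradigm <- function(tr = 2, scheme = default_block_scheme()) {
  stopifnot(is.numeric(tr), length(tr) == 1L, is.finite(tr))
  if (tr <= 0) stop("'tr' must be a positive duration in seconds")
  if (!is.data.frame(scheme) ||
      !all(c("condition", "duration") %in% names(scheme)))
    stop("'scheme' must be a data frame with columns 'condition', 'duration'")
  if (nrow(scheme) == 0L) stop("'scheme' must contain at least one block")
  cond <- as.character(scheme$condition)
  bad <- setdiff(unique(cond), nf_conditions())
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "))
  dur <- as.numeric(scheme$duration)
  if (any(!is.finite(dur)) || any(dur <= 0))
    stop("block durations must be positive and finite")
  # each block must hold a whole number of volumes
  ratio <- dur / tr
  if (any(abs(ratio - round(ratio)) > 1e-9))
    stop("every block duration must be a positive multiple of tr (",
         tr, " s); offending duration(s): ",
         paste(dur[abs(ratio - round(ratio)) > 1e-9], collapse = ", "))
  onset <- cumsum(c(0, dur[-length(dur)]))
  total <- sum(dur)
  n_volumes <- as.integer(round(total / tr))
  structure(
    list(
      tr_seconds = tr,
      blocks = data.frame(condition = cond, onset = onset, duration = dur,
                          stringsAsFactors = FALSE),
      n_volumes = n_volumes
    ),
    class = "nf_paradigm"
  )
}

#' Per-volume condition labels of a paradigm
#'
#' Volume \code{i} (0-based acquisition index) is labelled with the
#' condition of the block containing its onset time \code{i * tr}.
#'
#' @param paradigm An \code{nf_paradigm}.
#' @return Character vector of length \code{n_volumes}.
#' @export
volume_labels <- function(paradigm) {
  stopifnot(inherits(paradigm, "nf_paradigm"))
  reps <- as.integer(round(paradigm$blocks$duration / paradigm$tr_seconds))
  rep(paradigm$blocks$condition, reps)
}

#' Per-volume block index of a paradigm
#'
#' @param paradigm An \code{nf_paradigm}.
#' @return Integer vector of length \code{n_volumes}; 1-based index into
#'   \code{paradigm$blocks}.
#' @export
volume_blocks <- function(paradigm) {
  stopifnot(inherits(paradigm, "nf_paradigm"))
  reps <- as.integer(round(paradigm$blocks$duration / paradigm$tr_seconds))
  rep(seq_along(reps), reps)
}

#' @export
print.nf_paradigm <- function(x, ...) {
  cat(sprintf("Block-design paradigm: %d blocks, %d volumes at TR %.3g s (%.3g s total)\n",
              nrow(x$blocks), x$n_volumes, x$tr_seconds,
              x$n_volumes * x$tr_seconds))
  counts <- table(factor(volume_labels(x), levels = nf_conditions()))
  cat("  volumes per condition: ",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}
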