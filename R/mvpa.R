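# Subject-independent brain-state classifier: intensity masking, linear
# detrending, linear SVM, effect-value mapping, informative-voxel
# selection and the leave-one-run-out cross-validation report.

#' Intensity-based brain mask
#'
#' A voxel enters the mask iff its mean intensity exceeds
#' \code{threshold_fraction} times the grand mean of the strictly positive
#' voxels.
#'
#' @param mean_volume 3-D array of mean intensities.
#' @param threshold_fraction Fraction in (0, 1) (default 0.5).
#' @return Logical 3-D array.
#' @export
make_mask <- function(mean_volume, threshold_fraction = 0.5) {
  stopifnot(is.array(mean_volume), length(dim(mean_volume)) == 3L)
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("'threshold_fraction' must lie strictly between 0 and 1")
  pos <- mean_volume[mean_volume > 0]
  if (length(pos) == 0) stop("mask is empty: no positive voxels")
  mask <- mean_volume > threshold_fraction * mean(pos)
  if (!any(mask)) stop("mask is empty at threshold fraction ",
                       threshold_fraction)
  mask
}

#' Remove per-run linear trends from voxel time series
#'
#' Least-squares removal of intercept and slope, independently per voxel
#' and per run; output series have mean (numerically) zero.
#'
#' @param series Numeric matrix, time points x voxels.
#' @param run_id Run identifier per time point (row). Required: trends are
#'   fit within runs.
#' @return Matrix of detrended series, same shape.
#' @export
detrend_linear <- function(series, run_id) {
  series <- as.matrix(series)
  if (missing(run_id) || is.null(run_id))
    stop("run boundaries are required: pass 'run_id' (one value per row)")
  if (length(run_id) != nrow(series))
    stop("'run_id' must have one entry per time point")
  out <- series
  for (r in unique(run_id)) {
    rows <- which(run_id == r)
    if (length(rows) < 3)
      stop("detrending needs at least 3 time points per run (run '", r, "')")
    X <- cbind(1, seq_along(rows))
    beta <- qr.solve(X, series[rows, , drop = FALSE])
    out[rows, ] <- series[rows, , drop = FALSE] - X %*% beta
  }
  out
}

#' Feature matrix for classifier training
#'
#' Extracts masked voxel time series from one or more preprocessed runs,
#' removes per-run linear trends, and keeps the task (HAPPY/MOTOR)
#' volumes as samples. An optional hemodynamic label shift assigns volume
#' \code{i} the condition of volume \code{i - label_shift}.
#'
#' @param runs A list of \code{nf_bold_run}s (or a single run).
#' @param mask Logical 3-D array selecting the voxels.
#' @param label_shift Hemodynamic delay in volumes (default 0).
#' @param detrend Remove per-run linear trends first (default TRUE).
#' @return A list of class \code{nf_features}: \code{x} (samples x
#'   voxels), \code{y} (factor HAPPY/MOTOR), \code{run} (run id per
#'   sample), \code{voxel_index} (grid indices of the mask voxels),
#'   \code{mask}.
#' @export
extract_features <- function(runs, mask, label_shift = 0, detrend = TRUE) {
  if (inherits(runs, "nf_bold_run")) runs <- list(runs)
  stopifnot(length(runs) >= 1L, is.array(mask))
  vidx <- which(as.vector(mask))
  if (length(vidx) == 0) stop("empty mask")
  xs <- list(); ys <- list(); rs <- list()
  for (r in seq_along(runs)) {
    run <- runs[[r]]
    stopifnot(inherits(run, "nf_bold_run"))
    nt <- n_volumes(run)
    mat <- t(matrix(run$data, ncol = nt)[vidx, , drop = FALSE]) # time x vox
    if (detrend) mat <- detrend_linear(mat, rep(r, nt))
    lab <- run$labels
    if (label_shift > 0)
      lab <- c(rep("REST", label_shift), lab[seq_len(nt - label_shift)])
    keep <- lab %in% c("HAPPY", "MOTOR")
    xs[[r]] <- mat[keep, , drop = FALSE]
    ys[[r]] <- lab[keep]
    rs[[r]] <- rep(r, sum(keep))
  }
  x <- do.call(rbind, xs)
  if (any(!is.finite(x))) stop("non-finite feature values")
  structure(list(x = x,
                 y = factor(unlist(ys), levels = c("HAPPY", "MOTOR")),
                 run = unlist(rs), voxel_index = vidx, mask = mask),
            class = "nf_features")
}

#' Train a linear SVM
#'
#' Linear-kernel support vector machine with unit cost; features are used
#' as given (standardise beforehand). The decision rule is
#' \code{sign(w . x + b)} with HAPPY coded +1 and MOTOR -1.
#'
#' @param x Samples x voxels matrix.
#' @param y Factor or character vector of labels (HAPPY/MOTOR).
#' @param cost Regularisation cost (default 1).
#' @return List with \code{weights} (per column of \code{x}) and
#'   \code{bias}.
#' @export
train_svm <- function(x, y, cost = 1) {
  y <- factor(as.character(y), levels = c("HAPPY", "MOTOR"))
  if (any(is.na(y))) stop("labels must be HAPPY or MOTOR")
  if (nlevels(droplevels(y)) < 2)
    stop("both classes must be present to train the classifier")
  fit <- e1071::svm(x = x, y = y, kernel = "linear", cost = cost,
                    scale = FALSE, type = "C-classification")
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # e1071 orients the decision value towards the first factor level
  # (HAPPY), matching the +1 coding.
  list(weights = as.numeric(w), bias = as.numeric(b))
}

#' Map of effect values
#'
#' Per-voxel importance combining the SVM weight with the voxel's
#' class-conditional activation difference:
#' \deqn{e_j = w_j \, (\bar{x}_j^{HAPPY} - \bar{x}_j^{MOTOR}).}
#'
#' @param weights Per-voxel SVM weights.
#' @param x Samples x voxels matrix the weights were trained on.
#' @param y Labels per sample.
#' @return Numeric vector of effect values, one per voxel.
#' @export
effect_map <- function(weights, x, y) {
  y <- factor(as.character(y), levels = c("HAPPY", "MOTOR"))
  if (!any(y == "HAPPY", na.rm = TRUE) || !any(y == "MOTOR", na.rm = TRUE))
    stop("class-conditional means undefined: both classes required")
  stopifnot(length(weights) == ncol(x))
  diff <- colMeans(x[y == "HAPPY", , drop = FALSE]) -
    colMeans(x[y == "MOTOR", , drop = FALSE])
  e <- weights * diff
  if (any(!is.finite(e))) stop("non-finite effect values")
  e
}

#' Select informative voxels from an effect map
#'
#' @param e Effect values.
#' @param rule \code{"top_fraction"} (default) or \code{"threshold"}.
#' @param fraction Fraction of voxels kept under \code{"top_fraction"}
#'   (default 0.05); at least one voxel is always kept.
#' @param threshold Absolute-effect cut under \code{"threshold"}.
#' @return Integer indices into \code{e}, ordered by decreasing |e|.
#' @export
select_voxels <- function(e, rule = c("top_fraction", "threshold"),
                          fraction = 0.05, threshold = NULL) {
  rule <- match.arg(rule)
  ord <- order(abs(e), decreasing = TRUE)
  sel <- switch(rule,
    top_fraction = {
      if (fraction <= 0 || fraction > 1)
        stop("'fraction' must lie in (0, 1]")
      ord[seq_len(max(1L, ceiling(fraction * length(e))))]
    },
    threshold = {
      if (is.null(threshold)) stop("'threshold' required for this rule")
      ord[abs(e)[ord] > threshold]
    })
  if (length(sel) == 0)
    stop("selection rule selected 0 voxels (threshold above max |e|?)")
  sel
}

standardise_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

standardise_apply <- function(x, st) {
  sweep(sweep(x, 2, st$mu, "-"), 2, st$sd, "/")
}

#' Train the effect-map classifier model
#'
#' The full training pipeline behind every fold and the final model:
#' per-voxel standardisation (training statistics only), linear SVM over
#' the whole mask, effect-value mapping, informative-voxel selection, and
#' a final linear SVM retrained on the selected voxels.
#'
#' @param features An \code{nf_features}.
#' @param fraction Fraction of mask voxels kept (default 0.05).
#' @param cost SVM regularisation cost (default 1).
#' @return An object of class \code{nf_model}: \code{weights} and
#'   \code{bias} (on the selected voxels), \code{effect} (per mask voxel),
#'   \code{selected} (indices into the mask vector), \code{mask},
#'   \code{voxel_index}, standardisation constants and the class coding.
#' @export
train_effect_map_model <- function(features, fraction = 0.05, cost = 1) {
  stopifnot(inherits(features, "nf_features"))
  st <- standardise_fit(features$x)
  xs <- standardise_apply(features$x, st)
  full <- train_svm(xs, features$y, cost = cost)
  e <- effect_map(full$weights, xs, features$y)
  sel <- select_voxels(e, fraction = fraction)
  fin <- train_svm(xs[, sel, drop = FALSE], features$y, cost = cost)
  structure(list(weights = fin$weights, bias = fin$bias, effect = e,
                 selected = sel, mask = features$mask,
                 voxel_index = features$voxel_index,
                 standardise = st, fraction = fraction, cost = cost,
                 class_coding = c(HAPPY = 1, MOTOR = -1)),
            class = "nf_model")
}

#' Decision values and predicted classes for a feature matrix
#'
#' @param model An \code{nf_model}.
#' @param x Samples x mask-voxels matrix (unstandardised, full mask).
#' @return List with \code{decision} values and \code{predicted} factor;
#'   a decision value of exactly 0 is classified HAPPY.
#' @export
predict_model <- function(model, x) {
  stopifnot(inherits(model, "nf_model"))
  if (ncol(x) != length(model$voxel_index))
    stop("feature voxel count (", ncol(x), ") does not match the model (",
         length(model$voxel_index), ")")
  xs <- standardise_apply(x, model$standardise)[, model$selected, drop = FALSE]
  d <- drop(xs %*% model$weights) + model$bias
  list(decision = d,
       predicted = factor(ifelse(d >= 0, "HAPPY", "MOTOR"),
                          levels = c("HAPPY", "MOTOR")))
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cross-validation report
#'
#' @param folds Data frame with columns \code{accuracy},
#'   \code{sensitivity}, \code{specificity}, one row per fold. Confusion
#'   counts (\code{tp}, \code{fn}, \code{tn}, \code{fp}) are carried along
#'   when present.
#' @return An object of class \code{nf_cv_report} with the folds, the raw
#'   arithmetic \code{mean} of each column and the 2-decimal
#'   \code{average} (rounded half away from zero, the convention of the
#'   printed report).
#' @export
cv_report <- function(folds) {
  stopifnot(is.data.frame(folds),
            all(c("accuracy", "sensitivity", "specificity") %in% names(folds)))
  cols <- c("accuracy", "sensitivity", "specificity")
  vals <- as.matrix(folds[, cols])
  if (any(vals < 0 | vals > 1)) stop("fold rates must lie in [0, 1]")
  m <- colMeans(vals)
  structure(list(folds = folds, mean = m,
                 average = round_half_up(m, 2)),
            class = "nf_cv_report")
}

#' @export
print.nf_cv_report <- function(x, ...) {
  cat("Cross-validation report (", nrow(x$folds), " folds)\n", sep = "")
  print(round(x$folds[, c("accuracy", "sensitivity", "specificity")], 3))
  cat(sprintf("Average: accuracy %.2f, sensitivity %.2f, specificity %.2f\n",
              x$average["accuracy"], x$average["sensitivity"],
              x$average["specificity"]))
  invisible(x)
}

#' Leave-one-run-out cross-validation
#'
#' For each fold, the whole training pipeline (standardisation, SVM,
#' effect map, voxel selection, retrained SVM) is fit on the remaining
#' runs and evaluated on the held-out run. HAPPY is the positive class
#' for sensitivity/specificity.
#'
#' @param features An \code{nf_features} spanning >= 2 runs (4 in the
#'   standard protocol).
#' @inheritParams train_effect_map_model
#' @return An \code{nf_cv_report}.
#' @export
cross_validate <- function(features, fraction = 0.05, cost = 1) {
  stopifnot(inherits(features, "nf_features"))
  runs <- sort(unique(features$run))
  if (length(runs) < 2)
    stop("cross-validation needs at least 2 runs (leave-one-run-out)")
  rows <- lapply(runs, function(r) {
    tr <- features$run != r
    te <- !tr
    ftr <- structure(list(x = features$x[tr, , drop = FALSE],
                          y = droplevels(features$y[tr]),
                          run = features$run[tr],
                          voxel_index = features$voxel_index,
                          mask = features$mask),
                     class = "nf_features")
    ftr$y <- factor(as.character(ftr$y), levels = c("HAPPY", "MOTOR"))
    model <- train_effect_map_model(ftr, fraction = fraction, cost = cost)
    pred <- predict_model(model, features$x[te, , drop = FALSE])$predicted
    truth <- features$y[te]
    tp <- sum(pred == "HAPPY" & truth == "HAPPY")
    fn <- sum(pred == "MOTOR" & truth == "HAPPY")
    tn <- sum(pred == "MOTOR" & truth == "MOTOR")
    fp <- sum(pred == "HAPPY" & truth == "MOTOR")
    data.frame(fold = r, accuracy = (tp + tn) / length(truth),
               sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
               tp = tp, fn = fn, tn = tn, fp = fp)
  })
  cv_report(do.call(rbind, rows))
}

#' Pick the best classifier from a set of cross-validation reports
#'
#' Maximal mean accuracy; ties broken by higher mean sensitivity, then by
#' lowest index.
#'
#' @param reports List of \code{nf_cv_report}s.
#' @return Integer index of the winning report.
#' @export
select_best_classifier <- function(reports) {
  if (length(reports) == 0) stop("no reports to choose from")
  acc <- vapply(reports, function(r) r$mean[["accuracy"]], numeric(1))
  sen <- vapply(reports, function(r) r$mean[["sensitivity"]], numeric(1))
  best <- which(acc == max(acc))
  if (length(best) > 1) best <- best[sen[best] == max(sen[best])]
  best[1]
}
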