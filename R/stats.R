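# Learning and clinical statistics: exact one-sample Wilcoxon signed-rank
# test, one-sample z-test, learning deltas and slopes, clinical-change
# tables, eligibility screening and severity banding.

#' Exact one-sample Wilcoxon signed-rank test against zero
#'
#' Computes the signed-rank statistic W (sum of ranks of the positive
#' differences; zeros dropped, ties mid-ranked) and its exact p-value
#' from the null distribution over all \code{2^n} equiprobable sign
#' assignments of the observed absolute ranks -- no normal approximation.
#' For n > 25 the normal approximation with continuity correction is used
#' and tagged as such.
#'
#' @param differences Numeric vector of differences (versus zero).
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}. Two-sided p-values sum the probability of all W at
#'   least as far from the null mean n(n+1)/4 as observed.
#' @return An object of class \code{htest} with \code{statistic} (W),
#'   \code{p.value}, \code{parameter} (n after dropping zeros) and
#'   \code{method}.
#' @examples
#' wilcoxon_signed_rank_exact(c(2, 3, 5, 7, 9, 12, 15))$p.value  # 2/128
#' @export
wilcoxon_signed_rank_exact <- function(differences,
                                       alternative = c("two.sided",
                                                       "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.numeric(differences) || length(differences) == 0 ||
      any(!is.finite(differences)))
    stop("'differences' must be a non-empty finite numeric vector")
  d <- differences[differences != 0]
  if (length(d) == 0)
    stop("all differences are zero: the signed-rank test is undefined")
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 25) {
    dist <- signed_rank_distribution(r)
    p_ge <- function(x) sum(dist$prob[dist$w >= x - 1e-9])
    p_le <- function(x) sum(dist$prob[dist$w <= x + 1e-9])
    p <- switch(alternative,
                greater = p_ge(w),
                less = p_le(w),
                two.sided = min(1, sum(dist$prob[abs(dist$w - mu) >=
                                                   abs(w - mu) - 1e-9])))
    method <- "Exact one-sample Wilcoxon signed-rank test (sign enumeration)"
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w - mu - sign(w - mu) * 0.5) / sigma
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    method <- "One-sample Wilcoxon signed-rank test (normal approximation)"
  }
  structure(list(statistic = c(W = w), p.value = min(1, p),
                 parameter = c(n = n), alternative = alternative,
                 method = method,
                 data.name = deparse(substitute(differences))),
            class = "htest")
}

# Exact null distribution of W over all 2^n sign assignments of the
# observed ranks, by iterative convolution on a half-integer grid
# (mid-ranks make W a multiple of 1/2).
signed_rank_distribution <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))     # work on the doubled grid
  total <- sum(r2)
  f <- numeric(total + 1)                # index = 2W + 1
  f[1] <- 1
  for (x in r2) {
    g <- f
    g[(x + 1):(total + 1)] <- g[(x + 1):(total + 1)] + f[1:(total + 1 - x)]
    g[1:x] <- f[1:x]
    f <- g
  }
  list(w = (0:total) / 2, prob = f / 2^length(ranks))
}

#' One-sample z-test
#'
#' @param values Sample values, or NULL when summary statistics are given.
#' @param mean,sd,n Summary statistics (used when \code{values} is NULL).
#' @param null_value Null-hypothesis mean (default 0).
#' @param alternative \code{"greater"}, \code{"less"} or
#'   \code{"two.sided"}.
#' @return An \code{htest} with \code{statistic} (z) and \code{p.value}
#'   from the standard normal.
#' @examples
#' ztest_one_sample(mean = 56.19, sd = 6.07, n = 7, null_value = 50,
#'                  alternative = "greater")
#' @export
ztest_one_sample <- function(values = NULL, mean = NULL, sd = NULL, n = NULL,
                             null_value = 0,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.null(values)) {
    if (length(values) < 2) stop("need at least 2 values")
    mean <- base::mean(values)
    sd <- stats::sd(values)
    n <- length(values)
  }
  if (is.null(mean) || is.null(sd) || is.null(n))
    stop("provide either 'values' or all of 'mean', 'sd', 'n'")
  if (n < 2) stop("'n' must be at least 2")
  if (!is.finite(sd) || sd <= 0) stop("'sd' must be positive")
  z <- (mean - null_value) / (sd / sqrt(n))
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  structure(list(statistic = c(z = z), p.value = p,
                 parameter = c(n = n), null.value = c(mean = null_value),
                 alternative = alternative,
                 method = "One-sample z-test", data.name = "values"),
            class = "htest")
}

#' Accuracy table over the training protocol
#'
#' @param accuracy Numeric matrix, participants x 16 runs (4 days of 4
#'   runs), entries in percent.
#' @param runs_per_day Runs per training day (default 4).
#' @return An object of class \code{nf_accuracy_table} with the run
#'   matrix and the per-day means.
#' @export
accuracy_table <- function(accuracy, runs_per_day = 4) {
  accuracy <- as.matrix(accuracy)
  if (any(!is.finite(accuracy)) || any(accuracy < 0 | accuracy > 100))
    stop("accuracies must lie in [0, 100]")
  if (ncol(accuracy) %% runs_per_day != 0)
    stop("number of runs must be a multiple of runs_per_day")
  days <- ncol(accuracy) / runs_per_day
  day_means <- sapply(seq_len(days), function(d) {
    cols <- (d - 1) * runs_per_day + seq_len(runs_per_day)
    rowMeans(accuracy[, cols, drop = FALSE])
  })
  day_means <- matrix(day_means, nrow = nrow(accuracy))
  colnames(day_means) <- paste0("day", seq_len(days))
  structure(list(runs = accuracy, day_means = day_means,
                 runs_per_day = runs_per_day),
            class = "nf_accuracy_table")
}

#' Per-participant learning deltas
#'
#' Three contrasts per participant: last minus first run
#' (\code{run16_1}), mean of the last two minus mean of the first two
#' runs (\code{run15_16_1_2}), and mean of the last day minus mean of the
#' first day (\code{day4_1}). Each column is suitable input for
#' [wilcoxon_signed_rank_exact()].
#'
#' @param table An \code{nf_accuracy_table} with complete rows.
#' @return Data frame with one row per participant.
#' @export
learning_deltas <- function(table) {
  stopifnot(inherits(table, "nf_accuracy_table"))
  a <- table$runs
  if (any(!is.finite(a))) stop("missing runs in the accuracy table")
  nr <- ncol(a)
  if (nr < 2) stop("need at least 2 runs")
  dm <- table$day_means
  data.frame(
    run16_1 = a[, nr] - a[, 1],
    run15_16_1_2 = (a[, nr - 1] + a[, nr] - a[, 1] - a[, 2]) / 2,
    day4_1 = dm[, ncol(dm)] - dm[, 1]
  )
}

#' Ordinary least-squares learning slope
#'
#' Slope of accuracy against the 1-based run or session index.
#'
#' @param accuracies Numeric vector of accuracies in chronological order.
#' @param unit \code{"run"} or \code{"session"} (informational; the
#'   index is 1-based in either unit).
#' @return Slope in percent per unit (plain numeric).
#' @export
learning_slope <- function(accuracies, unit = c("run", "session")) {
  unit <- match.arg(unit)
  if (length(accuracies) < 2) stop("need at least 2 points to fit a slope")
  x <- seq_along(accuracies)
  unname(stats::coef(stats::lm(accuracies ~ x))[2])
}

#' Clinical change deltas and group tests
#'
#' For each instrument the three contrasts CE2-CE1, CE3-CE2 and CE3-CE1
#' are computed per participant as \emph{earlier minus later} score, so a
#' positive delta means improvement (symptom score decreased). A group
#' exact Wilcoxon signed-rank test against zero is run on each contrast;
#' a contrast whose deltas are all zero, or with fewer than 2
#' participants, is reported without a test (with a warning).
#'
#' @param records Data frame with columns \code{participant},
#'   \code{instrument} (e.g. "BDI-II", "HDRS") and \code{ce1}, \code{ce2},
#'   \code{ce3}. Participants with a missing timepoint are excluded with a
#'   warning.
#' @return A list of class \code{nf_clinical_deltas}: \code{deltas} (long
#'   data frame) and \code{tests} (one row per instrument x contrast with
#'   W, p and n; NA where the test is undefined).
#' @export
clinical_deltas <- function(records) {
  need <- c("participant", "instrument", "ce1", "ce2", "ce3")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("'records' must have columns ", paste(need, collapse = ", "))
  complete <- stats::complete.cases(records[, c("ce1", "ce2", "ce3")])
  if (any(!complete)) {
    warning(sum(!complete), " participant record(s) excluded: missing ",
            "clinical timepoint")
    records <- records[complete, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no complete clinical records")
  deltas <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    data.frame(participant = r$participant, instrument = r$instrument,
               contrast = c("CE2-CE1", "CE3-CE2", "CE3-CE1"),
               delta = c(r$ce1 - r$ce2, r$ce2 - r$ce3, r$ce1 - r$ce3))
  }))
  tests <- do.call(rbind, lapply(split(deltas,
                                       list(deltas$instrument,
                                            deltas$contrast), drop = TRUE),
    function(g) {
      res <- data.frame(instrument = g$instrument[1],
                        contrast = g$contrast[1],
                        n = nrow(g), median = stats::median(g$delta),
                        min = min(g$delta), max = max(g$delta),
                        W = NA_real_, p.value = NA_real_)
      if (nrow(g) >= 2 && any(g$delta != 0)) {
        ht <- wilcoxon_signed_rank_exact(g$delta)
        res$W <- unname(ht$statistic)
        res$p.value <- ht$p.value
      } else {
        warning("group test skipped for ", g$instrument[1], " ",
                g$contrast[1], ": ",
                if (nrow(g) < 2) "single record" else "all deltas zero")
      }
      res
    }))
  rownames(tests) <- NULL
  structure(list(deltas = deltas, tests = tests),
            class = "nf_clinical_deltas")
}

#' Eligibility screening for the neurofeedback protocol
#'
#' Eligible participants have mild-to-moderate depressive symptoms (10 to
#' 29 points on the BDI-II, inclusive) and no moderate suicidal risk
#' (fewer than 2 points on the BDI-II suicidality item and fewer than 5
#' on Okasha's suicidality scale). Risk exclusion takes precedence over
#' severity exclusion.
#'
#' @param bdi_total BDI-II total score (0--63).
#' @param bdi_suicide_item BDI-II suicidality item score (0--3).
#' @param okasha Okasha suicidality scale score (0--12).
#' @return \code{"eligible"}, \code{"excluded_severity"} or
#'   \code{"excluded_risk"}.
#' @export
screen_eligibility <- function(bdi_total, bdi_suicide_item, okasha) {
  if (bdi_total < 0 || bdi_total > 63)
    stop("BDI-II total must lie in 0..63")
  if (bdi_suicide_item < 0 || bdi_suicide_item > 3)
    stop("BDI-II suicidality item must lie in 0..3")
  if (okasha < 0 || okasha > 12)
    stop("Okasha score must lie in 0..12")
  if (bdi_suicide_item >= 2 || okasha >= 5) return("excluded_risk")
  if (bdi_total < 10 || bdi_total > 29) return("excluded_severity")
  "eligible"
}

#' BDI-II severity band
#'
#' Bands: none (< 10), mild (10--19), moderate (20--29), severe (> 29).
#'
#' @param bdi_total BDI-II total score (0--63).
#' @return One of \code{"none"}, \code{"mild"}, \code{"moderate"},
#'   \code{"severe"}.
#' @export
severity_band <- function(bdi_total) {
  if (bdi_total < 0 || bdi_total > 63)
    stop("BDI-II total must lie in 0..63")
  if (bdi_total < 10) "none"
  else if (bdi_total <= 19) "mild"
  else if (bdi_total <= 29) "moderate"
  else "severe"
}

#' Group statistics report for a training cohort
#'
#' Aggregates an accuracy table into the study's summary statistics: per
#' day group mean and SD, the one-tailed z-test of the last day against
#' 50 percent, the three learning contrasts with exact Wilcoxon tests,
#' and per-participant slopes across runs and sessions.
#'
#' @param table An \code{nf_accuracy_table}.
#' @return A list of class \code{nf_stats_report}.
#' @export
stats_report <- function(table) {
  stopifnot(inherits(table, "nf_accuracy_table"))
  dm <- table$day_means
  day_summary <- data.frame(day = seq_len(ncol(dm)),
                            mean = colMeans(dm),
                            sd = apply(dm, 2, stats::sd))
  zt <- if (nrow(dm) >= 2 && day_summary$sd[nrow(day_summary)] > 0)
    ztest_one_sample(values = dm[, ncol(dm)], null_value = 50,
                     alternative = "greater") else NULL
  ld <- learning_deltas(table)
  wtests <- lapply(ld, function(d) {
    if (length(d) >= 1 && any(d != 0)) wilcoxon_signed_rank_exact(d)
    else NULL
  })
  slopes_run <- apply(table$runs, 1, learning_slope, unit = "run")
  slopes_session <- apply(dm, 1, learning_slope, unit = "session")
  structure(list(day_summary = day_summary, day4_ztest = zt,
                 learning_deltas = ld, wilcoxon = wtests,
                 slopes_run = slopes_run,
                 slopes_session = slopes_session),
            class = "nf_stats_report")
}

#' @export
print.nf_stats_report <- function(x, ...) {
  cat("Neurofeedback cohort report\n")
  for (i in seq_len(nrow(x$day_summary)))
    cat(sprintf("  Average, Day %d = %.2f%%; SD = %.2f\n",
                x$day_summary$day[i], x$day_summary$mean[i],
                x$day_summary$sd[i]))
  if (!is.null(x$day4_ztest))
    cat(sprintf("  one-sample z-test (50), last day: z = %.3f, p = %.4f\n",
                x$day4_ztest$statistic, x$day4_ztest$p.value))
  for (nm in names(x$wilcoxon)) {
    ht <- x$wilcoxon[[nm]]
    d <- x$learning_deltas[[nm]]
    if (!is.null(ht))
      cat(sprintf(
        "  %s: Median = %.3f; Range = %.2f to %.2f; Wilcoxon (0), 2-tailed p = %.4g\n",
        nm, stats::median(d), min(d), max(d), ht$p.value))
  }
  cat(sprintf("  slopes across runs: median %.3f (range %.3f to %.3f)\n",
              stats::median(x$slopes_run), min(x$slopes_run),
              max(x$slopes_run)))
  invisible(x)
}
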