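# Simulated real-time session engine: per-volume classification against
# the tutor model, thermometer feedback with the rest-reset rule, run
# accuracy and the tiered monetary reward.

#' Tiered monetary reward for a run
#'
#' 1.5 USD at accuracy 50 percent or less, then 2 USD more for every
#' started 5-percent step above 50: 3.5 USD for 51--55, 5.5 for 56--60,
#' 7.5 for 61--65, and so on (21.5 USD at 100).
#'
#' @param accuracy_percent Accuracy in [0, 100].
#' @return Reward in USD.
#' @export
reward <- function(accuracy_percent) {
  if (!is.numeric(accuracy_percent) || any(!is.finite(accuracy_percent)) ||
      any(accuracy_percent < 0 | accuracy_percent > 100))
    stop("'accuracy_percent' must lie in [0, 100]")
  ifelse(accuracy_percent <= 50, 1.5,
         1.5 + 2 * ceiling((accuracy_percent - 50) / 5))
}

#' Thermometer feedback state
#'
#' @param max_bars Number of bars on the display (default 10); the bar
#'   count is clamped to [0, max_bars].
#' @return A list of class \code{nf_feedback_state}; the session starts at
#'   the midpoint of the bar range.
#' @export
feedback_state <- function(max_bars = 10) {
  stopifnot(max_bars >= 1)
  structure(list(bar_count = round(max_bars / 2), max_bars = max_bars),
            class = "nf_feedback_state")
}

#' Classify a single volume against the model
#'
#' @param x Feature vector over the model's mask voxels (preprocessed and
#'   detrended like the training data).
#' @param model An \code{nf_model}.
#' @param expected The condition of the current block.
#' @return List with \code{predicted}, \code{expected}, \code{correct} and
#'   the SVM \code{decision} value. A decision value of exactly 0 is
#'   classified HAPPY.
#' @export
classify_volume <- function(x, model, expected) {
  pr <- predict_model(model, matrix(x, nrow = 1))
  predicted <- as.character(pr$predicted)
  list(predicted = predicted, expected = expected,
       correct = identical(predicted, expected),
       decision = pr$decision)
}

#' Update the thermometer after a task-volume classification
#'
#' One bar added on a correct classification, one subtracted otherwise,
#' clamped to the bar range. Must not be called on rest volumes (the
#' thermometer is frozen during rest; see [rest_reset()]).
#'
#' @param state An \code{nf_feedback_state}.
#' @param outcome An outcome from [classify_volume()], or a logical
#'   correct flag.
#' @return The updated state.
#' @export
update_thermometer <- function(state, outcome) {
  stopifnot(inherits(state, "nf_feedback_state"))
  if (is.list(outcome)) {
    if (identical(outcome$expected, "REST"))
      stop("the thermometer is not updated on REST volumes")
    correct <- outcome$correct
  } else correct <- isTRUE(outcome)
  state$bar_count <- min(state$max_bars,
                         max(0, state$bar_count + if (correct) 1 else -1))
  state
}

#' Reset the thermometer on entering a rest block
#'
#' The bar count becomes the rounded mean of the bar-count trajectory over
#' the previous task block (R's round: half rounds to even, so a mean of
#' 2.5 resets to 2). With no prior task block the bar count is the
#' midpoint of the range.
#'
#' @param state An \code{nf_feedback_state}.
#' @param previous_trajectory Numeric vector of bar counts over the
#'   previous task block, or NULL at session start.
#' @return The updated state.
#' @export
rest_reset <- function(state, previous_trajectory = NULL) {
  stopifnot(inherits(state, "nf_feedback_state"))
  state$bar_count <- if (is.null(previous_trajectory) ||
                         length(previous_trajectory) == 0)
    round(state$max_bars / 2)
  else
    min(state$max_bars, max(0, round(mean(previous_trajectory))))
  state
}

#' Run accuracy
#'
#' The printed formula: 100 x (number of correct classifications) / total
#' volumes of the run (210 in the standard paradigm). With rest volumes
#' counted as never-correct the attainable ceiling is 100 x 160/210.
#'
#' @param correct Logical vector, one entry per volume of the run.
#' @param n_expected Required number of outcome slots (default 210).
#' @return Accuracy in percent.
#' @export
run_accuracy <- function(correct, n_expected = 210) {
  if (length(correct) != n_expected)
    stop("expected ", n_expected, " outcome slots, got ", length(correct))
  100 * sum(correct) / n_expected
}

# Causal per-voxel linear detrending: the residual of volume t under the
# least-squares line fit to volumes 1..t (running-fit online variant of
# the offline detrending). Input/output: voxels x time.
causal_detrend <- function(mat) {
  nt <- ncol(mat)
  tt <- seq_len(nt)
  St <- cumsum(tt)
  Stt <- cumsum(tt^2)
  Sy <- t(apply(mat, 1, cumsum))
  Sty <- t(apply(sweep(mat, 2, tt, "*"), 1, cumsum))
  n <- tt
  denom <- n * Stt - St^2
  out <- mat
  for (t in seq_len(nt)) {
    if (t < 3) {
      out[, t] <- mat[, t] - Sy[, t] / t
    } else {
      slope <- (t * Sty[, t] - St[t] * Sy[, t]) / denom[t]
      intercept <- (Sy[, t] - slope * St[t]) / t
      out[, t] <- mat[, t] - (intercept + slope * t)
    }
  }
  out
}

#' Simulate one closed-loop neurofeedback run
#'
#' Streams the volumes of a (raw, simulated) run through the abbreviated
#' online path -- resampling to the template grid where needed, Gaussian
#' smoothing restricted to the model's mask, causal linear detrending --
#' classifies every volume against the tutor model, and drives the
#' thermometer: task volumes add or subtract one bar, rest onsets reset
#' the bar to the rounded mean of the previous block's trajectory.
#'
#' @param run An \code{nf_bold_run} on the template grid (use
#'   [normalize_run()] first otherwise).
#' @param model An \code{nf_model}.
#' @param smoothing_fwhm_mm Online smoothing FWHM (default 6).
#' @param voxel_mm Voxel size in millimetres (default 3).
#' @param max_bars Thermometer bars (default 10).
#' @param scoring \code{"all_volumes"} (default; denominator = all volumes
#'   with rest never correct, the printed formula) or \code{"task_only"}
#'   (denominator = task volumes).
#' @return An object of class \code{nf_run_result}: \code{outcomes} (one
#'   row per volume: expected, predicted, correct, decision, bar_count),
#'   \code{accuracy_percent}, \code{task_accuracy_percent},
#'   \code{reward_usd}, \code{events} and timing fields.
#' @export
nf_run <- function(run, model, smoothing_fwhm_mm = 6, voxel_mm = 3,
                   max_bars = 10, scoring = c("all_volumes", "task_only")) {
  stopifnot(inherits(run, "nf_bold_run"), inherits(model, "nf_model"))
  scoring <- match.arg(scoring)
  t_start <- proc.time()[["elapsed"]]
  nt <- n_volumes(run)
  d <- dim(run$data)[1:3]
  if (!identical(as.integer(d), as.integer(dim(model$mask))))
    stop("run grid does not match the model mask grid")
  # per-voxel operations are independent, so the loop only ever needs the
  # model's selected voxels: smooth, detrend and standardise those rows
  sel_grid <- model$voxel_index[model$selected]
  S <- smoothing_operator(d, smoothing_fwhm_mm, voxel_mm, rows = sel_grid)
  raw <- matrix(run$data, ncol = nt)              # voxels x time
  feats <- causal_detrend(as.matrix(S %*% raw))   # selected voxels x time
  mu <- model$standardise$mu[model$selected]
  sd <- model$standardise$sd[model$selected]
  z <- (feats - mu) / sd
  decision <- drop(crossprod(z, model$weights)) + model$bias
  pr <- list(decision = decision,
             predicted = factor(ifelse(decision >= 0, "HAPPY", "MOTOR"),
                                levels = c("HAPPY", "MOTOR")))
  predicted <- as.character(pr$predicted)
  labels <- run$labels
  correct <- predicted == labels                  # REST never matches
  state <- feedback_state(max_bars)
  bar <- integer(nt)
  block <- volume_blocks_from_labels(labels)
  traj <- numeric(0)
  for (t in seq_len(nt)) {
    if (labels[t] == "REST") {
      if (t > 1 && labels[t - 1] != "REST") {
        state <- rest_reset(state, traj)
        traj <- numeric(0)
      }
    } else {
      state <- update_thermometer(state, correct[t])
      traj <- c(traj, state$bar_count)
    }
    bar[t] <- state$bar_count
  }
  n_task <- sum(labels != "REST")
  acc_all <- 100 * sum(correct) / nt
  acc_task <- if (n_task > 0) 100 * sum(correct & labels != "REST") / n_task
              else NA_real_
  accuracy <- if (scoring == "all_volumes") acc_all else acc_task
  rew <- reward(accuracy)
  elapsed <- proc.time()[["elapsed"]] - t_start
  structure(list(
    outcomes = data.frame(volume = seq_len(nt) - 1L, block = block,
                          expected = labels, predicted = predicted,
                          correct = correct, decision = pr$decision,
                          bar_count = bar),
    accuracy_percent = accuracy,
    all_volume_accuracy_percent = acc_all,
    task_accuracy_percent = acc_task,
    reward_usd = rew,
    scoring = scoring,
    events = data.frame(time_s = (nt - 1.5) * run$tr_seconds,
                        event = sprintf("reward_display: %.1f USD", rew)),
    elapsed_s = elapsed, per_volume_s = elapsed / nt),
    class = "nf_run_result")
}

volume_blocks_from_labels <- function(labels) {
  cumsum(c(1L, as.integer(labels[-1] != labels[-length(labels)])))
}

#' @export
print.nf_run_result <- function(x, ...) {
  cat(sprintf(
    "Neurofeedback run: accuracy %.2f%% (%s scoring), reward %.1f USD\n",
    x$accuracy_percent, x$scoring, x$reward_usd))
  invisible(x)
}

#' Simulate a full neurofeedback training protocol for one subject
#'
#' Runs \code{days x runs_per_day} closed-loop runs (default 4 x 4 = 16).
#' Each day is one training session: with a positive learning rate the
#' subject's pattern fidelity rises between sessions, emulating
#' neurofeedback learning.
#'
#' @param profile An \code{nf_subject} (the patient).
#' @param model An \code{nf_model} (the tutor classifier).
#' @param paradigm An \code{nf_paradigm}.
#' @param days,runs_per_day Protocol shape (defaults 4 and 4).
#' @param seed Integer seed; each run draws from an independently derived
#'   sub-seed.
#' @inheritParams nf_run
#' @return A list of class \code{nf_session_log}: \code{results} (list of
#'   \code{nf_run_result}, day-major order), \code{accuracy} (matrix days
#'   x runs), \code{rewards} (same shape).
#' @export
run_protocol <- function(profile, model, paradigm = build_paradigm(),
                         days = 4, runs_per_day = 4, seed = 1,
                         smoothing_fwhm_mm = 6, voxel_mm = 3,
                         max_bars = 10,
                         scoring = c("all_volumes", "task_only")) {
  stopifnot(inherits(profile, "nf_subject"), inherits(model, "nf_model"))
  scoring <- match.arg(scoring)
  results <- vector("list", days * runs_per_day)
  acc <- matrix(NA_real_, nrow = days, ncol = runs_per_day)
  rew <- matrix(NA_real_, nrow = days, ncol = runs_per_day)
  k <- 0
  for (day in seq_len(days)) {
    for (r in seq_len(runs_per_day)) {
      k <- k + 1
      run <- simulate_run(paradigm, profile, session = day,
                          seed = derive_seed(seed, day, r))
      res <- nf_run(run, model, smoothing_fwhm_mm = smoothing_fwhm_mm,
                    voxel_mm = voxel_mm, max_bars = max_bars,
                    scoring = scoring)
      results[[k]] <- res
      acc[day, r] <- res$accuracy_percent
      rew[day, r] <- res$reward_usd
    }
  }
  structure(list(results = results, accuracy = acc, rewards = rew,
                 days = days, runs_per_day = runs_per_day, seed = seed),
            class = "nf_session_log")
}
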