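test_that("reward tiers match the printed schedule and step structure", {
  expect_equal(reward(0), 1.5)
  expect_equal(reward(50), 1.5)
  expect_equal(reward(53), 3.5)
  expect_equal(reward(58), 5.5)
  expect_equal(reward(63), 7.5)
  expect_equal(reward(100), 21.5)
  # non-decreasing step function with 2 USD steps at 50 + 5k boundaries
  acc <- seq(0, 100, by = 0.5)
  r <- reward(acc)
  expect_true(all(diff(r) >= 0))
  steps <- acc[which(diff(r) > 0)]               # last value before a jump
  expect_true(all(steps %% 5 == 0 & steps >= 50))
  expect_true(all(diff(r)[diff(r) > 0] == 2))
  expect_error(reward(101), "\\[0, 100\\]")
  expect_error(reward(-1), "\\[0, 100\\]")
})

test_that("thermometer updates, clamps and rejects rest volumes", {
  s <- feedback_state(10)
  expect_equal(s$bar_count, 5)                    # session-start midpoint
  s$bar_count <- 0
  for (i in 1:5) s <- update_thermometer(s, TRUE)
  expect_equal(s$bar_count, 5)
  s$bar_count <- 0
  s <- update_thermometer(s, TRUE)
  s <- update_thermometer(s, FALSE)
  s <- update_thermometer(s, TRUE)
  expect_equal(s$bar_count, 1)
  s$bar_count <- 0
  for (i in 1:3) s <- update_thermometer(s, FALSE)
  expect_equal(s$bar_count, 0)                    # floor clamp
  s$bar_count <- 10
  s <- update_thermometer(s, TRUE)
  expect_equal(s$bar_count, 10)                   # ceiling clamp
  expect_error(update_thermometer(s, list(expected = "REST",
                                          correct = TRUE)), "REST")
})

test_that("rest reset takes the rounded mean of the previous block", {
  s <- feedback_state(10)
  s <- rest_reset(s, c(1, 2, 3, 4))
  expect_equal(s$bar_count, 2)                    # mean 2.5, half to even
  s <- rest_reset(s, c(2, 3, 4, 5))
  expect_equal(s$bar_count, 4)                    # mean 3.5, half to even
  s <- rest_reset(s, NULL)
  expect_equal(s$bar_count, 5)                    # session start midpoint
  # all-correct 20-volume block from 0 with max 10: trajectory clamps
  traj <- pmin(10, cumsum(rep(1, 20)))
  s <- rest_reset(s, traj)
  expect_equal(s$bar_count, round(mean(traj)))
})

test_that("run accuracy follows the fixed-denominator formula", {
  correct <- rep(FALSE, 210)
  labs <- volume_labels(build_paradigm())
  correct[labs != "REST"] <- TRUE
  expect_equal(run_accuracy(correct), 100 * 160 / 210)
  expect_equal(run_accuracy(c(rep(TRUE, 105), rep(FALSE, 105))), 50)
  expect_equal(run_accuracy(rep(FALSE, 210)), 0)
  expect_error(run_accuracy(rep(TRUE, 200)), "210")
})

test_that("volume classification: signs, ties and antisymmetry", {
  trained <- small_trained()
  model <- trained$model
  # class-mean feature vectors classify to their own class
  runs <- lapply(1:2, function(r) {
    run <- simulate_run(trained$paradigm, trained$tutor, seed = 500 + r)
    normalize_run(discard_initial(run, 10),
                  norm_params(diag(4), dim(model$mask),
                              trained$tutor$grid$affine,
                              smoothing_fwhm_mm = 8))
  })
  feats <- extract_features(runs, model$mask)
  mu_h <- colMeans(feats$x[feats$y == "HAPPY", ])
  mu_m <- colMeans(feats$x[feats$y == "MOTOR", ])
  expect_equal(classify_volume(mu_h, model, "HAPPY")$predicted, "HAPPY")
  expect_equal(classify_volume(mu_m, model, "MOTOR")$predicted, "MOTOR")
  expect_true(classify_volume(mu_h, model, "HAPPY")$correct)
  # a point exactly on the hyperplane goes to HAPPY (documented tie rule)
  x0 <- mu_h * 0
  flip <- model
  flip$bias <- 0
  flip$standardise$mu <- flip$standardise$mu * 0
  out0 <- classify_volume(x0, flip, "HAPPY")
  expect_equal(out0$decision, 0)
  expect_equal(out0$predicted, "HAPPY")
  # flipping the weight signs inverts every prediction off the boundary
  neg <- model
  neg$weights <- -model$weights
  neg$bias <- -model$bias
  for (x in list(mu_h, mu_m)) {
    a <- classify_volume(x, model, "HAPPY")
    b <- classify_volume(x, neg, "HAPPY")
    expect_true(a$predicted != b$predicted)
  }
  expect_error(classify_volume(mu_h[-1], model, "HAPPY"), "voxel count")
})

test_that("self-classification of the tutor's own preprocessed runs exceeds 90%", {
  trained <- small_trained()
  run <- simulate_run(trained$paradigm, trained$tutor, seed = 888)
  pre <- normalize_run(discard_initial(run, 10),
                       norm_params(diag(4), dim(trained$model$mask),
                                   trained$tutor$grid$affine,
                                   smoothing_fwhm_mm = 8))
  feats <- extract_features(pre, trained$model$mask)
  pred <- predict_model(trained$model, feats$x)$predicted
  expect_gt(100 * mean(pred == feats$y), 90)
})

test_that("a closed-loop run on the tutor's own near-noiseless data is accurate", {
  trained <- small_trained()
  quiet <- tutor_profile(trained$template, noise_sigma = 0.01,
                         drift_amplitude = 0)
  run <- simulate_run(trained$paradigm, quiet, seed = 77)
  res <- nf_run(run, trained$model)
  # per-volume scoring against instantaneous block labels caps below 100:
  # the BOLD response lags each block switch by several volumes
  expect_gt(res$task_accuracy_percent, 80)
  # thermometer conservation inside every task block
  oc <- res$outcomes
  for (b in unique(oc$block[oc$expected != "REST"])) {
    rows <- oc[oc$block == b, ]
    start <- if (rows$volume[1] == 0) 5
             else oc$bar_count[oc$volume == rows$volume[1] - 1]
    running <- start
    for (i in seq_len(nrow(rows))) {
      running <- min(10, max(0, running + ifelse(rows$correct[i], 1, -1)))
      expect_equal(rows$bar_count[i], running)
    }
  }
  # deterministic replay
  res2 <- nf_run(simulate_run(trained$paradigm, quiet, seed = 77),
                 trained$model)
  expect_identical(res$outcomes, res2$outcomes)
  expect_identical(res$accuracy_percent, res2$accuracy_percent)
})

test_that("the selected-voxel loop equals the full-mask classification path", {
  trained <- small_trained()
  model <- trained$model
  run <- simulate_run(trained$paradigm, trained$tutor, seed = 321)
  res <- nf_run(run, model)
  # reference: smooth every mask voxel, causal-detrend, standardise, dot
  d <- dim(run$data)[1:3]
  S <- rtnf:::smoothing_operator(d, 6, 3, rows = model$voxel_index)
  feats <- rtnf:::causal_detrend(as.matrix(S %*% matrix(run$data,
                                                        ncol = 210)))
  ref <- predict_model(model, t(feats))
  expect_equal(res$outcomes$decision, unname(ref$decision),
               tolerance = 1e-10)
  expect_identical(res$outcomes$predicted, as.character(ref$predicted))
})

test_that("accuracy ceiling under rest-never-correct scoring", {
  trained <- small_trained()
  quiet <- tutor_profile(trained$template, noise_sigma = 0.01,
                         drift_amplitude = 0)
  run <- simulate_run(trained$paradigm, quiet, seed = 78)
  res <- nf_run(run, trained$model)
  n <- length(run$labels)
  n_task <- sum(run$labels != "REST")
  expect_lte(res$all_volume_accuracy_percent, 100 * n_task / n)
  # task-only scoring can reach 100
  res_t <- nf_run(run, trained$model, scoring = "task_only")
  expect_equal(res_t$accuracy_percent, res_t$task_accuracy_percent)
})

test_that("a full protocol returns the right shape and is reproducible", {
  trained <- small_trained()
  patient <- patient_profile(trained$template, pattern_fidelity = 0.4,
                             learning_rate = 0.2, seed = 9)
  log <- run_protocol(patient, trained$model, trained$paradigm,
                      days = 2, runs_per_day = 2, seed = 5)
  expect_length(log$results, 4)
  expect_equal(dim(log$accuracy), c(2, 2))
  expect_true(all(log$rewards >= 1.5))
  log2 <- run_protocol(patient, trained$model, trained$paradigm,
                       days = 2, runs_per_day = 2, seed = 5)
  expect_identical(log$accuracy, log2$accuracy)
})
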