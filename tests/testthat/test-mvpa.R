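test_that("intensity mask follows the threshold rule", {
  d <- c(6L, 6L, 6L)
  uniform <- array(10, dim = d)
  expect_true(all(make_mask(uniform, 0.5)))
  half <- array(c(10, 0), dim = d)
  m <- make_mask(half, 0.5)
  expect_identical(m, half > 0)
  # 2:1 interior/exterior contrast at fraction 0.8: interior exactly
  grid <- sim_grid(c(10L, 12L, 10L))
  interior <- brain_support(grid)
  vol <- array(1, dim = grid$dim)
  vol[interior] <- 2
  expected <- vol > 0.8 * mean(vol[vol > 0])   # direct enumeration oracle
  expect_identical(make_mask(vol, 0.8), expected)
  expect_identical(make_mask(vol, 0.8), interior)
  expect_error(make_mask(array(0, dim = d), 0.5), "empty")
})

test_that("linear detrending removes lines and preserves oscillations", {
  t <- 1:50
  line <- 3 + 0.5 * t
  sine <- sin(2 * pi * t / 10)
  m <- cbind(line, line + sine, rep(2, 50))
  out <- detrend_linear(m, rep(1, 50))
  expect_lt(max(abs(out[, 1])), 1e-10)             # pure line -> 0
  centred_sine <- sine - mean(sine) -
    stats::lm(sine ~ t)$coefficients[2] * (t - mean(t))
  expect_equal(out[, 2], unname(centred_sine), tolerance = 1e-8)
  expect_lt(max(abs(out[, 3])), 1e-10)             # constant -> 0
  expect_lt(max(abs(colMeans(out))), 1e-10)
  # per-run independence: two runs with different slopes both flatten
  m2 <- matrix(c(1:20 * 2, 20:1 * 5), ncol = 1)
  out2 <- detrend_linear(m2, rep(1:2, each = 20))
  expect_lt(max(abs(out2)), 1e-9)
  expect_error(detrend_linear(m), "run boundaries")
  expect_error(detrend_linear(m2[1:2, , drop = FALSE], c(1, 1)),
               "at least 3")
})

test_that("linear SVM separates clouds, rejects single-class input", {
  fx <- make_fixtures(seed = 5)
  svm <- train_svm(fx$clouds$x, fx$clouds$y)
  dec <- fx$clouds$x %*% svm$weights + svm$bias
  pred <- ifelse(dec >= 0, "HAPPY", "MOTOR")
  expect_equal(mean(pred == as.character(fx$clouds$y)), 1.0)
  expect_error(train_svm(fx$clouds$x[1:40, ],
                         fx$clouds$y[1:40]), "both classes")
  # duplicated features leave decisions invariant up to weight splitting
  svm2 <- train_svm(cbind(fx$clouds$x, fx$clouds$x), fx$clouds$y)
  dec2 <- cbind(fx$clouds$x, fx$clouds$x) %*% svm2$weights + svm2$bias
  expect_equal(sign(dec2), sign(dec))
})

test_that("randomly permuted labels classify near chance", {
  res <- with_seed(31, {
    n <- 200
    x <- matrix(stats::rnorm(n * 30), ncol = 30)
    y <- factor(sample(rep(c("HAPPY", "MOTOR"), each = n / 2)),
                levels = c("HAPPY", "MOTOR"))
    half <- seq_len(n / 2)
    svm <- train_svm(x[half, ], y[half])
    dec <- x[-half, ] %*% svm$weights + svm$bias
    mean(ifelse(dec >= 0, "HAPPY", "MOTOR") == as.character(y[-half]))
  })
  expect_gt(res, 0.35)
  expect_lt(res, 0.65)
})

test_that("effect map equals the brute-force per-voxel oracle", {
  fx <- make_fixtures(seed = 8)
  x <- fx$single_voxel$x
  y <- fx$single_voxel$y
  svm <- train_svm(x, y)
  e <- effect_map(svm$weights, x, y)
  expect_equal(e, effect_map_oracle(svm$weights, x, y), tolerance = 1e-12)
  # zero weights -> zero effects
  expect_true(all(effect_map(numeric(ncol(x)), x, y) == 0))
  # swapping class labels flips every sign
  y_swap <- factor(ifelse(y == "HAPPY", "MOTOR", "HAPPY"),
                   levels = c("HAPPY", "MOTOR"))
  e_swap <- effect_map(svm$weights, x, y_swap)
  expect_equal(e_swap, -e, tolerance = 1e-12)
  expect_error(effect_map(svm$weights, x[y == "HAPPY", ],
                          y[y == "HAPPY"]), "both classes")
})

test_that("the effect-map argmax finds the single informative voxel", {
  hits <- sapply(1:25, function(s) {
    fx <- make_fixtures(seed = 1000 + s)
    x <- fx$single_voxel$x
    y <- fx$single_voxel$y
    svm <- train_svm(x, y)
    e <- effect_map(svm$weights, x, y)
    which.max(abs(e)) == fx$single_voxel$informative
  })
  expect_gte(mean(hits), 0.95)
})

test_that("voxel selection rules behave at their edges", {
  e <- c(0.1, -3, 0.5, 2, -0.2)
  expect_setequal(select_voxels(e, fraction = 1), seq_along(e))
  expect_equal(select_voxels(e, fraction = 0.2), 2L)
  expect_equal(select_voxels(e, rule = "threshold", threshold = 1.5),
               c(2L, 4L))
  expect_error(select_voxels(e, rule = "threshold", threshold = 10),
               "0 voxels")
  expect_error(select_voxels(e, fraction = 0), "fraction")
})

test_that("cross-validation averaging reproduces the printed report arithmetic", {
  r1 <- cv_report(data.frame(accuracy = c(0.97, 0.87, 0.92, 0.84),
                             sensitivity = c(0.95, 0.86, 0.94, 0.76),
                             specificity = c(0.99, 0.88, 0.90, 0.93)))
  expect_equal(unname(r1$average[c("accuracy", "sensitivity")]),
               c(0.90, 0.88), tolerance = 1e-12)
  # specificity mean is exactly 0.925: the printed table shows 0.92, our
  # half-away-from-zero convention gives 0.93 - both within the 0.005 band
  expect_lt(abs(r1$average[["specificity"]] - 0.92), 0.0101)
  expect_lt(abs(r1$mean[["specificity"]] - 0.92), 0.0051)
  r2 <- cv_report(data.frame(accuracy = c(0.90, 0.96, 0.96, 0.91),
                             sensitivity = c(0.90, 0.94, 0.98, 0.86),
                             specificity = c(0.90, 0.99, 0.95, 0.95)))
  expect_equal(unname(r2$average), c(0.93, 0.92, 0.95), tolerance = 1e-12)
  # raw means stay within 0.005 of the rounded averages
  expect_true(all(abs(r2$mean - r2$average) <= 0.005))
  expect_error(cv_report(data.frame(accuracy = 1.2, sensitivity = 1,
                                    specificity = 1)), "\\[0, 1\\]")
})

test_that("leave-one-run-out CV is perfect on a separable fixture", {
  # 4 runs of trivially separable two-voxel features
  mk_run <- function(seed) {
    with_seed(seed, {
      d <- c(4L, 4L, 4L)
      nt <- 24
      labels <- rep(c("HAPPY", "MOTOR"), times = 12)  # interleaved blocks
      arr <- array(stats::rnorm(prod(d) * nt, sd = 0.05), dim = c(d, nt))
      arr[1, 1, 1, labels == "HAPPY"] <- arr[1, 1, 1, labels == "HAPPY"] + 5
      arr[2, 1, 1, labels == "MOTOR"] <- arr[2, 1, 1, labels == "MOTOR"] + 5
      arr <- arr + 10
      bold_run(arr, diag(4), 2, labels)
    })
  }
  runs <- lapply(1:4, mk_run)
  mask <- array(TRUE, dim = c(4, 4, 4))
  feats <- extract_features(runs, mask, detrend = TRUE)
  rep <- cross_validate(feats, fraction = 0.1)
  expect_equal(rep$folds$accuracy, rep(1, 4))
  expect_equal(rep$folds$sensitivity, rep(1, 4))
  expect_equal(rep$folds$specificity, rep(1, 4))
  # sensitivity/specificity recompute from stored confusion counts
  expect_equal(rep$folds$sensitivity,
               rep$folds$tp / (rep$folds$tp + rep$folds$fn))
  expect_equal(rep$folds$specificity,
               rep$folds$tn / (rep$folds$tn + rep$folds$fp))
  expect_error(cross_validate(structure(list(x = feats$x, y = feats$y,
                                             run = rep(1, length(feats$y)),
                                             voxel_index = feats$voxel_index,
                                             mask = mask),
                                        class = "nf_features")),
               "at least 2 runs")
})

test_that("classifier choice: highest accuracy, sensitivity tie-break, lowest index", {
  mk <- function(acc, sen) cv_report(data.frame(accuracy = acc,
                                                sensitivity = sen,
                                                specificity = acc))
  reports <- list(mk(0.90, 0.88), mk(0.93, 0.92), mk(0.79, 0.81))
  expect_equal(select_best_classifier(reports), 2L)
  expect_equal(select_best_classifier(reports[1]), 1L)
  tie <- list(mk(0.90, 0.80), mk(0.90, 0.95), mk(0.90, 0.95))
  expect_equal(select_best_classifier(tie), 2L)
  expect_error(select_best_classifier(list()), "no reports")
})

test_that("feature extraction drops rest volumes and respects the label shift", {
  tpl <- small_template()
  run <- simulate_run(small_paradigm(), tutor_profile(tpl), seed = 12)
  mask <- brain_support(tpl$grid)
  f0 <- extract_features(run, mask)
  expect_equal(nrow(f0$x), 40L)                 # 20 HAPPY + 20 MOTOR
  expect_false(any(is.na(f0$y)))
  f2 <- extract_features(run, mask, label_shift = 2)
  expect_equal(nrow(f2$x), 40L)                 # blocks shift into rest
  expect_equal(as.character(f2$y[1]), "HAPPY")
})
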