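test_that("exact Wilcoxon reproduces the small-sample reference cases", {
  # n = 7, all positive: only W = 28 and W = 0 are as extreme
  ht <- wilcoxon_signed_rank_exact(c(2, 3, 5, 7, 9, 12, 15))
  expect_equal(unname(ht$statistic), 28)
  expect_equal(ht$p.value, 2 / 128)
  expect_equal(round(ht$p.value, 3), 0.016)
  # six positive, one negative of strictly smallest magnitude
  ht2 <- wilcoxon_signed_rank_exact(c(-1, 3, 5, 8, 10, 12, 15))
  expect_equal(unname(ht2$statistic), 27)
  expect_equal(ht2$p.value, 4 / 128)
  expect_equal(round(ht2$p.value, 3), 0.031)
  # single nonzero difference: both tails saturate
  expect_equal(wilcoxon_signed_rank_exact(3)$p.value, 1)
  # zeros are dropped before ranking
  ht3 <- wilcoxon_signed_rank_exact(c(0, 0, 2, 3, 5, 7, 9, 12, 15))
  expect_equal(ht3$p.value, 2 / 128)
  expect_equal(unname(ht3$parameter), 7)
  expect_error(wilcoxon_signed_rank_exact(c(0, 0, 0)), "all differences")
})

test_that("exact Wilcoxon equals brute-force sign enumeration (n <= 12)", {
  set.seed(424242)
  for (rep in 1:120) {
    n <- sample(1:12, 1)
    d <- round(stats::rnorm(n, sd = 4), 1)
    # inject occasional exact ties and zeros
    if (n > 3 && rep %% 3 == 0) d[2] <- d[1]
    if (rep %% 5 == 0) d[n] <- 0
    if (all(d == 0)) d[1] <- 1
    for (alt in c("two.sided", "greater", "less")) {
      got <- wilcoxon_signed_rank_exact(d, alternative = alt)$p.value
      want <- wilcoxon_bruteforce(d, alternative = alt)
      expect_equal(got, want, tolerance = 1e-12,
                   info = sprintf("n=%d alt=%s d=%s", n, alt,
                                  paste(d, collapse = ",")))
    }
  }
})

test_that("untied cases agree with the base-R exact Wilcoxon test", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(3:15, 1)
    d <- stats::rnorm(n)                    # continuous, no ties
    got <- wilcoxon_signed_rank_exact(d)$p.value
    want <- stats::wilcox.test(d, mu = 0, exact = TRUE)$p.value
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("z-test matches the closed-form normal tail", {
  ht <- ztest_one_sample(mean = 56.19, sd = 6.07, n = 7, null_value = 50,
                         alternative = "greater")
  expect_equal(unname(ht$statistic), (56.19 - 50) / (6.07 / sqrt(7)),
               tolerance = 1e-12)
  expect_equal(ht$p.value,
               stats::pnorm((56.19 - 50) / (6.07 / sqrt(7)),
                            lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(round(ht$p.value, 4), 0.0035)
  # mean at the null: z = 0, one-tailed p = 0.5
  ht0 <- ztest_one_sample(mean = 50, sd = 2, n = 5, null_value = 50,
                          alternative = "greater")
  expect_equal(unname(ht0$statistic), 0)
  expect_equal(ht0$p.value, 0.5)
  # sign symmetry
  up <- ztest_one_sample(mean = 53, sd = 2, n = 5, null_value = 50,
                         alternative = "greater")
  dn <- ztest_one_sample(mean = 47, sd = 2, n = 5, null_value = 50,
                         alternative = "greater")
  expect_equal(unname(dn$statistic), -unname(up$statistic))
  expect_equal(dn$p.value, 1 - up$p.value, tolerance = 1e-12)
  expect_error(ztest_one_sample(mean = 1, sd = 0, n = 5), "positive")
  expect_error(ztest_one_sample(values = 3), "at least 2")
})

test_that("learning deltas follow the run arithmetic", {
  flat <- accuracy_table(matrix(50, nrow = 2, ncol = 16))
  expect_true(all(as.matrix(learning_deltas(flat)) == 0))
  rising <- accuracy_table(matrix(40 + 1 * (0:15), nrow = 1, ncol = 16,
                                  byrow = TRUE))
  ld <- learning_deltas(rising)
  expect_equal(ld$run16_1, 15)
  expect_equal(ld$run15_16_1_2, (14 + 15 - 0 - 1) / 2)
  expect_equal(ld$day4_1, 12)                      # mean day4 - mean day1
  # antisymmetry: reversing the run order negates the deltas
  rev_tab <- accuracy_table(matrix(40 + 1 * (15:0), nrow = 1, ncol = 16,
                                   byrow = TRUE))
  expect_equal(as.numeric(as.matrix(learning_deltas(rev_tab))),
               -as.numeric(as.matrix(ld)))
})

test_that("day means recompute from the run matrix", {
  set.seed(3)
  m <- matrix(runif(7 * 16, 30, 70), nrow = 7)
  tab <- accuracy_table(m)
  for (d in 1:4)
    expect_equal(tab$day_means[, d],
                 rowMeans(m[, (d - 1) * 4 + 1:4]))
  expect_error(accuracy_table(matrix(120, 1, 16)), "\\[0, 100\\]")
})

test_that("learning slopes: constants, two points, positive-learning cohort", {
  expect_equal(unname(learning_slope(rep(42, 8))), 0, tolerance = 1e-12)
  expect_equal(unname(learning_slope(c(40, 50), unit = "session")), 10)
  expect_error(learning_slope(50), "at least 2")
  # cohort with learning: all slopes positive
  set.seed(11)
  accs <- t(sapply(1:7, function(i) 40 + 1.2 * (1:16) + rnorm(16, sd = 2)))
  slopes <- apply(accs, 1, learning_slope)
  expect_true(all(slopes > 0))
})

test_that("clinical deltas use improvement-positive sign and group tests", {
  rec <- data.frame(participant = 1:7,
                    instrument = "HDRS",
                    ce1 = c(16, 18, 15, 19, 14, 17, 13),
                    ce2 = c(14, 10, 5, 8, 9, 8, 11),
                    ce3 = c(14, 10, 5, 8, 9, 8, 11))
  expect_warning(clinical_deltas(rec), "all deltas zero")
  out <- suppressWarnings(clinical_deltas(rec))
  d21 <- out$deltas$delta[out$deltas$contrast == "CE2-CE1"]
  expect_equal(d21, rec$ce1 - rec$ce2)             # positive = improvement
  expect_true(all(d21 >= 2 & d21 <= 15))
  t21 <- out$tests[out$tests$contrast == "CE2-CE1", ]
  expect_equal(t21$p.value, 2 / 128)               # all-improved, n = 7
  # identical CE2 and CE3: all-zero contrast is reported without a test
  t32 <- out$tests[out$tests$contrast == "CE3-CE2", ]
  expect_true(is.na(t32$p.value))
  expect_equal(t32$median, 0)
  # a missing timepoint excludes that participant with a warning
  rec$ce3[3] <- NA
  warns <- character(0)
  out2 <- withCallingHandlers(
    clinical_deltas(rec),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("missing", warns)))
  expect_equal(sort(unique(out2$deltas$participant)), setdiff(1:7, 3))
  # single record: deltas computed, group tests skipped
  one <- suppressWarnings(clinical_deltas(rec[1, ]))
  expect_equal(nrow(one$deltas), 3)
  expect_true(all(is.na(one$tests$p.value)))
})

test_that("eligibility screening enforces the severity and risk rules", {
  expect_equal(screen_eligibility(18, 0, 1), "eligible")
  expect_equal(screen_eligibility(10, 0, 0), "eligible")
  expect_equal(screen_eligibility(29, 1, 4), "eligible")
  expect_equal(screen_eligibility(30, 0, 0), "excluded_severity")
  expect_equal(screen_eligibility(9, 0, 0), "excluded_severity")
  expect_equal(screen_eligibility(15, 2, 0), "excluded_risk")
  expect_equal(screen_eligibility(15, 0, 5), "excluded_risk")
  expect_equal(screen_eligibility(35, 3, 0), "excluded_risk")  # risk first
  expect_error(screen_eligibility(64, 0, 0), "0\\.\\.63")
})

test_that("severity bands split at 10, 20 and 30", {
  expect_equal(severity_band(9), "none")
  expect_equal(severity_band(10), "mild")
  expect_equal(severity_band(19), "mild")
  expect_equal(severity_band(20), "moderate")
  expect_equal(severity_band(29), "moderate")
  expect_equal(severity_band(30), "severe")
  expect_error(severity_band(-1), "0\\.\\.63")
})

test_that("the cohort report aggregates days, tests and slopes coherently", {
  set.seed(21)
  m <- t(sapply(1:7, function(i) 42 + 0.9 * (1:16) + rnorm(16, sd = 3)))
  tab <- accuracy_table(m)
  rep <- stats_report(tab)
  expect_equal(nrow(rep$day_summary), 4)
  expect_equal(rep$day_summary$mean[4], mean(tab$day_means[, 4]))
  expect_equal(rep$day4_ztest$alternative, "greater")
  expect_length(rep$slopes_run, 7)
  expect_true(all(rep$slopes_run > 0))
  expect_s3_class(rep$wilcoxon$day4_1, "htest")
  txt <- capture.output(print(rep))
  expect_true(any(grepl("z-test", txt)))
})
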