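test_that("segment metrics reproduce worked confusion and AUC cases", {
  m <- segment_metrics(c(.9, .8, .2, .1),
                       c("preictal", "preictal", "interictal", "interictal"),
                       threshold = 0.5)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$auc, 1)
  rev_ <- segment_metrics(c(.1, .2, .8, .9),
                          c("preictal", "preictal", "interictal", "interictal"))
  expect_equal(rev_$auc, 0)
  # midrank handling of ties, by hand: two tied pairs -> AUC 1/2
  tie <- segment_metrics(c(.6, .4, .6, .4),
                         c("preictal", "interictal", "interictal", "preictal"))
  expect_equal(tie$auc, 0.5)
  expect_error(segment_metrics(c(.1, .2), "preictal"), "length")
  expect_true(is.na(segment_metrics(c(.1, .2),
                                    c("preictal", "preictal"))$auc))
})

test_that("rank AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(51)
  for (i in 1:5) {
    sc <- round(stats::runif(60), 2)  # rounding forces ties
    lb <- sample(c("preictal", "interictal"), 60, replace = TRUE)
    ours <- segment_metrics(sc, lb)$auc
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
      response = factor(lb, c("interictal", "preictal")), predictor = sc,
      direction = "<"))))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("ROC trapezoid integration equals the rank statistic", {
  set.seed(52)
  sc <- round(stats::runif(200), 2)
  lb <- sample(c("preictal", "interictal"), 200, replace = TRUE)
  r <- roc_report(sc, lb)
  expect_equal(r$auc, segment_metrics(sc, lb)$auc, tolerance = 1e-9)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(utils::tail(r$curve$tpr, 1), 1)
  dir <- withr::local_tempdir()
  roc_report(sc, lb, out_dir = dir, name = "check")
  expect_true(file.exists(file.path(dir, "roc_check.csv")))
  expect_true(file.exists(file.path(dir, "roc_check.png")))
})

test_that("the regime matrix degenerates correctly when synthetic = real", {
  imgs <- stripe_images(20, size = 16, seed = 61)
  cfg <- cesp_config(lr = 1e-3, epochs = 3, folds = 2, seed = 3,
                     batch_size = 16)
  tab <- run_regime_matrix(imgs, imgs, cfg, regimes = c("TRTR", "TSTR"))
  expect_equal(tab$auc[tab$regime == "TRTR"], tab$auc[tab$regime == "TSTR"])
  expect_equal(tab$accuracy[1], tab$accuracy[2])
  expect_error(run_regime_matrix(imgs, NULL, cfg,
                                 regimes = c("TRTR", "TSTR")),
               "synthetic images are required")
})

test_that("train/test partitions are disjoint in time", {
  imgs <- stripe_images(20, size = 16, seed = 62)
  sp <- asNamespace("spectrogan")$.time_split(imgs, 0.25, seed = 1)
  tr_t <- vapply(sp$train, function(im) im$t_start, 0)
  te_t <- vapply(sp$test, function(im) im$t_start, 0)
  expect_gt(min(te_t), max(tr_t))
  expect_length(c(sp$train, sp$test), length(imgs))
})

test_that("alarm evaluation implements the SPH/SOP window definitions", {
  tl <- list(seizure_onsets = 20 * 60, duration_h = 2)
  cfg <- alarm_config(sph_min = 10, sop_min = 30)
  # alarm at t = 0, onset at 20 min: 10 <= 20 <= 40 -> predicted
  ev <- alarm_evaluate(tl, data.frame(t_start = 0, score = 0.9), cfg)
  expect_equal(ev$n_predicted, 1L)
  expect_equal(ev$false_alarms, 0L)
  expect_equal(ev$sensitivity_event, 1)
  # onset at 5 min violates the SPH: alarm counts as false
  tl5 <- list(seizure_onsets = 5 * 60, duration_h = 2)
  ev5 <- alarm_evaluate(tl5, data.frame(t_start = 0, score = 0.9), cfg)
  expect_equal(ev5$n_predicted, 0L)
  expect_equal(ev5$false_alarms, 1L)
  # no alarms at all
  tl2 <- list(seizure_onsets = c(18000, 28800), duration_h = 10)
  ev0 <- alarm_evaluate(tl2, data.frame(t_start = c(0, 3600),
                                        score = c(.1, .2)), cfg)
  expect_equal(ev0$sensitivity_event, 0)
  expect_equal(ev0$fpr_per_h, 0)
  expect_error(alarm_evaluate(tl, data.frame(t_start = c(10, 0),
                                             score = c(.9, .9)), cfg),
               "sorted")
})

test_that("every raised alarm is counted exactly once", {
  set.seed(63)
  tl <- list(seizure_onsets = c(5.5, 8) * 3600, duration_h = 10)
  scores <- data.frame(t_start = seq(0, 10 * 3600 - 600, by = 600),
                       score = stats::runif(60))
  cfg <- alarm_config(threshold = 0.7)
  ev <- alarm_evaluate(tl, scores, cfg)
  expect_equal(nrow(ev$alarms), sum(ev$alarms$true_prediction) +
                 ev$false_alarms)
  # refractory: consecutive alarms are separated by at least the SOP
  if (nrow(ev$alarms) > 1)
    expect_true(all(diff(ev$alarms$t) >= cfg$refractory_min * 60))
  # interictal hours exclude the merged pre-onset windows
  expect_equal(ev$interictal_hours, 10 - 2 * (40 / 60))
})

test_that("chance probability follows 1 - exp(-FPR x SOP) with unit care", {
  expect_equal(chance_probability(0, 30), 0)
  expect_gt(chance_probability(1e6, 30), 1 - 1e-9)
  expect_equal(chance_probability(0.27, 30), 1 - exp(-0.135))
  expect_equal(chance_probability(0.27, 30), 0.12628, tolerance = 1e-4)
  # monotone in both arguments
  expect_true(all(diff(chance_probability(seq(0, 2, .1), 30)) > 0))
  expect_true(all(diff(vapply(c(10, 30, 60, 120), function(s)
    chance_probability(0.3, s), 0)) > 0))
  expect_error(chance_probability(-1, 30), "non-negative")
})

test_that("the binomial tail matches enumeration and pbinom", {
  expect_equal(chance_pvalue(0, 5, 0.3), 1)
  expect_equal(chance_pvalue(1, 1, 0.42), 0.42)
  expect_equal(chance_pvalue(2, 3, 0.2), 3 * 0.04 * 0.8 + 0.008,
               tolerance = 1e-12)
  set.seed(64)
  for (i in 1:20) {
    N <- sample(1:12, 1)
    n <- sample(0:N, 1)
    P <- stats::runif(1)
    expect_equal(chance_pvalue(n, N, P),
                 stats::pbinom(n - 1, N, P, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(chance_pvalue(4, 3, 0.5), "n <= N")
  expect_error(chance_pvalue(1, 3, 1.5), "0, 1")
})

test_that("chance_test wires FPR, SOP and counts into one decision", {
  ev <- list(n_predicted = 5, n_seizures = 6, fpr_per_h = 0.2)
  ct <- chance_test(ev, sop_min = 30)
  P <- 1 - exp(-0.1)
  expect_equal(ct$P, P)
  expect_equal(ct$p_value, stats::pbinom(4, 6, P, lower.tail = FALSE))
  expect_true(ct$reject_null)
})

test_that("the chance test is calibrated under a random alarm process", {
  # seizures "predicted" by alarms raised at random at the stated FPR:
  # the per-event hit probability is exactly P, so the rejection rate at
  # level alpha must not exceed alpha (binomial discreteness makes the
  # test conservative)
  set.seed(65)
  alpha <- 0.05
  N <- 8
  P <- chance_probability(0.3, 30)
  rejections <- mean(replicate(2000, {
    n <- stats::rbinom(1, N, P)
    chance_pvalue(n, N, P) < alpha
  }))
  expect_lte(rejections, alpha + 2 * sqrt(alpha * (1 - alpha) / 2000))
  # a predictor well above the random rate is detected essentially always
  expect_lt(chance_pvalue(N, N, P), 1e-6)
})

test_that("Hanley-McNeil comparison behaves at its analytic anchors", {
  r <- hanley_mcneil_compare(0.8, 30, 30, 0.8, 30, 30)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 0.5)
  # closed form at A = 0.5: Q1 = Q2 = 1/3
  hm <- asNamespace("spectrogan")$.hm_se
  for (n in c(10, 25, 80)) {
    se2 <- (0.25 + (n - 1) * (1 / 3 - 0.25) * 2) / n^2
    expect_equal(hm(0.5, n, n)^2, se2, tolerance = 1e-12)
  }
  # growing samples at a fixed AUC gap shrink the p-value monotonically
  ps <- vapply(c(20, 40, 80, 160), function(n)
    hanley_mcneil_compare(0.75, n, n, 0.65, n, n)$p_value, 0)
  expect_true(all(diff(ps) < 0))
  expect_error(hanley_mcneil_compare(1, 10, 10, 0.5, 10, 10), "degenerate")
  # Bonferroni adjustment for four comparisons
  r4 <- hanley_mcneil_compare(0.9, 50, 50, 0.6, 50, 50, alpha = 0.05, m = 4)
  expect_equal(r4$alpha_adjusted, 0.0125)
  expect_true(r4$significant)
})
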