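# ---- protocol machinery: regimes, alarms, chance statistics ----------------

#' Segment-level classification metrics
#'
#' Confusion counts at a probability threshold (positive class:
#' `"preictal"`) and the area under the ROC curve computed as the
#' Mann-Whitney rank statistic with midranks for ties. With a single class
#' present the AUC is reported as `NA`.
#'
#' @param scores per-image pre-ictal probabilities.
#' @param labels class labels (`"preictal"` / `"interictal"`), same length.
#' @param threshold decision cutoff (default 0.5).
#' @return A `segment_metrics` list: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`, `auc`.
#' @export
segment_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  pos <- labels == "preictal"
  pred <- scores >= threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos); fn <- sum(!pred & pos)
  auc <- if (any(pos) && any(!pos)) {
    r <- rank(scores)  # midranks
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  } else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 accuracy = (tp + tn) / length(scores), auc = auc,
                 threshold = threshold),
            class = "segment_metrics")
}

#' @export
print.segment_metrics <- function(x, ...) {
  cat(sprintf("<segment_metrics> sens=%.3f spec=%.3f acc=%.3f auc=%s\n",
              x$sensitivity, x$specificity, x$accuracy,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

# Time-disjoint train/test partition: test takes the latest time sections.
.time_split <- function(images, test_frac, seed) {
  ts <- vapply(images, function(im) im$t_start, 0)
  if (all(is.finite(ts))) {
    cut <- stats::quantile(ts, 1 - test_frac, type = 1)
    test <- ts > cut
    if (!any(test)) test <- ts >= cut
  } else {
    test <- with_seed(seed, seq_along(images) %in%
                        sample.int(length(images),
                                   max(1L, round(test_frac * length(images)))))
  }
  list(train = images[!test], test = images[test])
}

# Fill the missing class of a single-class synthetic set with real images,
# optionally upsampling the minority class (with replacement) so the two
# classes are balanced for training.
.complete_with_real <- function(synth, real, balance = FALSE, seed = 1L) {
  have <- unique(image_labels(synth))
  missing <- setdiff(.sg_labels, have)
  if (length(missing))
    synth <- c(synth, Filter(function(im) im$label %in% missing, real))
  if (!balance) return(synth)
  lab <- image_labels(synth)
  n <- table(factor(lab, .sg_labels))
  if (min(n) == 0 || min(n) == max(n)) return(synth)
  minority <- .sg_labels[which.min(n)]
  extra <- with_seed(seed, sample(which(lab == minority),
                                  max(n) - min(n), replace = TRUE))
  c(synth, synth[extra])
}

#' Run the TRTR/TSTR/TRTS/TSTS regime matrix
#'
#' Trains and evaluates the CESP under the four train/test source
#' combinations: Real/Real (TRTR), Synthetic/Real (TSTR), Real/Synthetic
#' (TRTS) and Synthetic/Synthetic (TSTS). Test partitions are drawn from
#' time sections disjoint from training (split on `t_start` before any
#' shuffling; default test fraction 0.25) and are shared across regimes
#' with the same test source. One model is fitted per training source
#' (regimes sharing a training source reuse it). If the synthetic set
#' contains a single class, its other class is completed with real
#' partition images of the missing label, and the synthetic training set is
#' balanced by upsampling the minority class with replacement.
#'
#' @param real list of real [spectrogram_image()] objects (both classes).
#' @param synthetic list of generated [spectrogram_image()] objects;
#'   required for the regimes involving synthetic data.
#' @param cfg a [cesp_config()].
#' @param regimes subset of `c("TRTR", "TSTR", "TRTS", "TSTS")`.
#' @param test_frac held-out fraction (default 0.25).
#' @param threshold decision cutoff for the confusion counts.
#' @return Data frame with one row per regime: sources, training size and
#'   the [segment_metrics()] fields; score vectors are attached as the
#'   `"scores"` attribute for downstream ROC reporting.
#' @export
run_regime_matrix <- function(real, synthetic = NULL, cfg = cesp_config(),
                              regimes = c("TRTR", "TSTR", "TRTS", "TSTS"),
                              test_frac = 0.25, threshold = 0.5) {
  regimes <- match.arg(regimes, several.ok = TRUE)
  needs_synth <- any(regimes != "TRTR")
  if (needs_synth && !length(synthetic))
    stop("synthetic images are required for regimes other than TRTR")
  rs <- .time_split(real, test_frac, cfg$seed)
  if (length(rs$train) < cfg$folds || !length(rs$test))
    stop("insufficient real data for a time-disjoint split")
  ss <- if (length(synthetic)) {
    s <- .time_split(synthetic, test_frac, cfg$seed + 1L)
    list(train = .complete_with_real(s$train, rs$train, balance = TRUE,
                                     seed = cfg$seed + 2L),
         test = .complete_with_real(s$test, rs$test))
  } else NULL
  train_sets <- list(real = rs$train, synthetic = ss$train)
  test_sets <- list(real = rs$test, synthetic = ss$test)
  models <- list()
  rows <- list()
  scores <- list()
  for (rg in regimes) {
    tr_src <- if (rg %in% c("TRTR", "TRTS")) "real" else "synthetic"
    te_src <- if (rg %in% c("TRTR", "TSTR")) "real" else "synthetic"
    if (is.null(models[[tr_src]]))
      models[[tr_src]] <- train_cesp(train_sets[[tr_src]], cfg, cv = FALSE)
    pr <- predict_cesp(models[[tr_src]], test_sets[[te_src]])
    m <- segment_metrics(pr$p_preictal, image_labels(test_sets[[te_src]]),
                         threshold)
    rows[[rg]] <- data.frame(regime = rg, train_source = tr_src,
                             test_source = te_src,
                             n_train = length(train_sets[[tr_src]]),
                             n_test = length(test_sets[[te_src]]),
                             sensitivity = m$sensitivity,
                             specificity = m$specificity,
                             accuracy = m$accuracy, auc = m$auc)
    scores[[rg]] <- data.frame(score = pr$p_preictal,
                               label = image_labels(test_sets[[te_src]]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scores") <- scores
  attr(out, "models") <- models
  out
}

#' Alarm-scoring configuration
#'
#' @param sph_min seizure prediction horizon in minutes (default 10): the
#'   minimum lead time between an alarm and the onset for a correct
#'   prediction.
#' @param sop_min seizure occurrence period in minutes (default 30): the
#'   window after the SPH within which the seizure must occur.
#' @param threshold alarm probability cutoff (default 0.5).
#' @param refractory_min silence period after an alarm (defaults to the
#'   SOP, preventing double counting of alarms for one event).
#' @return An `alarm_config` object.
#' @export
alarm_config <- function(sph_min = 10, sop_min = 30, threshold = 0.5,
                         refractory_min = sop_min) {
  stopifnot(sph_min > 0, sop_min > 0)
  structure(list(sph_min = sph_min, sop_min = sop_min, threshold = threshold,
                 refractory_min = refractory_min), class = "alarm_config")
}

#' Event-level alarm evaluation against a seizure timeline
#'
#' An alarm is raised at segment time `t` when the score reaches the
#' threshold and no previous alarm is within the refractory period. A
#' seizure with onset `o` counts as predicted when some alarm satisfies
#' `t + SPH <= o <= t + SPH + SOP`; an alarm whose occurrence window
#' contains no onset is a false alarm — including alarms raised less than
#' one SPH before an onset, which violate the required lead time. The
#' false-prediction rate per hour divides false alarms by the interictal
#' hours, i.e. the time outside all `(onset - SPH - SOP, onset]` windows.
#'
#' @param timeline a `seizure_timeline` (or any list with `seizure_onsets`
#'   in seconds and `duration_h`).
#' @param scores data frame with `t_start` (seconds, sorted increasing) and
#'   `score` columns, e.g. model probabilities on the timeline's segments.
#' @param cfg an [alarm_config()].
#' @return An `alarm_evaluation`: `n_seizures`, `n_predicted`,
#'   `false_alarms`, `interictal_hours`, `fpr_per_h`, `sensitivity_event`,
#'   and the alarm table (time + classification).
#' @export
alarm_evaluate <- function(timeline, scores, cfg = alarm_config()) {
  stopifnot(all(c("t_start", "score") %in% names(scores)))
  if (is.unsorted(scores$t_start))
    stop("scores must be sorted by t_start")
  onsets <- timeline$seizure_onsets
  sph <- cfg$sph_min * 60
  sop <- cfg$sop_min * 60
  alarms <- numeric(0)
  last <- -Inf
  for (i in seq_len(nrow(scores))) {
    t <- scores$t_start[i]
    if (scores$score[i] >= cfg$threshold && t - last >= cfg$refractory_min * 60) {
      alarms <- c(alarms, t)
      last <- t
    }
  }
  alarm_true <- vapply(alarms, function(t)
    any(onsets >= t + sph & onsets <= t + sph + sop), TRUE)
  predicted <- vapply(onsets, function(o)
    any(alarms + sph <= o & o <= alarms + sph + sop), TRUE)
  dur_s <- timeline$duration_h * 3600
  # merge the pre-onset exclusion windows (onset - sph - sop, onset]
  excl <- 0
  if (length(onsets)) {
    iv <- cbind(pmax(0, onsets - sph - sop), pmin(onsets, dur_s))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    cur <- iv[1, ]
    for (r in seq_len(nrow(iv))[-1]) {
      if (iv[r, 1] <= cur[2]) cur[2] <- max(cur[2], iv[r, 2])
      else { excl <- excl + cur[2] - cur[1]; cur <- iv[r, ] }
    }
    excl <- excl + cur[2] - cur[1]
  }
  inter_h <- (dur_s - excl) / 3600
  fa <- sum(!alarm_true)
  structure(list(n_seizures = length(onsets), n_predicted = sum(predicted),
                 false_alarms = fa, interictal_hours = inter_h,
                 fpr_per_h = if (inter_h > 0) fa / inter_h else NA_real_,
                 sensitivity_event = if (length(onsets))
                   sum(predicted) / length(onsets) else NA_real_,
                 alarms = data.frame(t = alarms, true_prediction = alarm_true)),
            class = "alarm_evaluation")
}

#' @export
print.alarm_evaluation <- function(x, ...) {
  cat(sprintf(paste0("<alarm_evaluation> %d/%d seizures predicted, ",
                     "%d false alarms in %.2f interictal h (FPR %.3f/h)\n"),
              x$n_predicted, x$n_seizures, x$false_alarms,
              x$interictal_hours, x$fpr_per_h))
  invisible(x)
}

#' Per-SOP alarm probability of a chance-level predictor
#'
#' `P = 1 - exp(-FPR * SOP)`: the probability that a random alarm process
#' with the given false-prediction rate raises at least one alarm during
#' one seizure-occurrence period. The SOP is converted to hours so the
#' exponent is dimensionless.
#'
#' @param fpr_per_h false alarms per interictal hour (>= 0).
#' @param sop_min seizure occurrence period in minutes (> 0).
#' @return Probability in `[0, 1]`.
#' @export
chance_probability <- function(fpr_per_h, sop_min) {
  if (any(fpr_per_h < 0)) stop("fpr_per_h must be non-negative")
  if (any(sop_min <= 0)) stop("sop_min must be positive")
  1 - exp(-fpr_per_h * sop_min / 60)
}

#' Binomial tail probability of predicting n of N seizures by chance
#'
#' `p = sum_{k >= n} C(N, k) P^k (1 - P)^(N - k)`, evaluated term by term
#' with log binomial coefficients for numerical stability. This is the
#' p-value of the observed prediction count under a chance-level alarm
#' process with per-event success probability `P` (see
#' [chance_probability()]).
#'
#' @param n predicted seizure count (`0 <= n <= N`).
#' @param N total seizure count.
#' @param P per-event probability in `[0, 1]`.
#' @return Tail probability in `[0, 1]`.
#' @export
chance_pvalue <- function(n, N, P) {
  if (n < 0 || N < 0 || n > N) stop("need 0 <= n <= N")
  if (P < 0 || P > 1) stop("P must lie in [0, 1]")
  if (n == 0) return(1)
  if (P == 0) return(0)
  if (P == 1) return(1)
  k <- n:N
  sum(exp(lchoose(N, k) + k * log(P) + (N - k) * log1p(-P)))
}

#' Chance-level significance test of an alarm evaluation
#'
#' Combines [chance_probability()] and [chance_pvalue()]: the null
#' hypothesis is that the predictor performs no better than a random alarm
#' process with the observed false-prediction rate.
#'
#' @param eval_result an [alarm_evaluate()] result (or any list with
#'   `n_predicted`, `n_seizures`, `fpr_per_h`).
#' @param sop_min seizure occurrence period in minutes.
#' @param alpha significance level (default 0.05).
#' @return A `chance_test` list: `P`, `p_value`, `alpha`, `reject_null`.
#' @export
chance_test <- function(eval_result, sop_min = 30, alpha = 0.05) {
  P <- chance_probability(eval_result$fpr_per_h, sop_min)
  p <- chance_pvalue(eval_result$n_predicted, eval_result$n_seizures, P)
  structure(list(P = P, p_value = p, alpha = alpha,
                 reject_null = p < alpha), class = "chance_test")
}

# Hanley-McNeil standard error of one AUC
.hm_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Hanley-McNeil comparison of two AUCs
#'
#' Single-tailed z-test on the difference of two independent areas under
#' ROC curves, with the Hanley-McNeil standard error
#' `SE^2 = [A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)] / (n_pos n_neg)`
#' where `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`. A Bonferroni-adjusted
#' significance flag at `alpha / m` supports multiple comparisons (e.g.
#' four competing models at `0.05 / 4`).
#'
#' @param auc1,auc2 the two AUCs, strictly inside `(0, 1)`.
#' @param n_pos1,n_neg1,n_pos2,n_neg2 positive/negative counts behind each.
#' @param alpha base significance level.
#' @param m number of comparisons for the Bonferroni correction.
#' @return List with `z`, `p_value` (single-tailed), the two standard
#'   errors, `alpha_adjusted` and `significant`.
#' @export
hanley_mcneil_compare <- function(auc1, n_pos1, n_neg1, auc2, n_pos2, n_neg2,
                                  alpha = 0.05, m = 1) {
  if (any(c(auc1, auc2) <= 0) || any(c(auc1, auc2) >= 1))
    stop("degenerate AUC of exactly 0 or 1: use exact methods instead")
  stopifnot(n_pos1 > 0, n_neg1 > 0, n_pos2 > 0, n_neg2 > 0)
  se1 <- .hm_se(auc1, n_pos1, n_neg1)
  se2 <- .hm_se(auc2, n_pos2, n_neg2)
  z <- (auc1 - auc2) / sqrt(se1^2 + se2^2)
  p <- stats::pnorm(-abs(z))
  list(z = z, p_value = p, se1 = se1, se2 = se2,
       alpha_adjusted = alpha / m, significant = p < alpha / m)
}

#' ROC curve data and report files
#'
#' Sweeps all score thresholds to produce ROC points, integrates the curve
#' with the trapezoid rule (which equals the Mann-Whitney AUC), and
#' optionally writes a CSV of curve points and a PNG plot.
#'
#' @param scores numeric prediction scores.
#' @param labels class labels (positive class `"preictal"`).
#' @param out_dir optional directory for `roc.csv` / `roc.png`.
#' @param name curve label used in file content and the plot title.
#' @return Invisibly, a list with the curve data frame (`fpr`, `tpr`,
#'   `threshold`) and `auc`.
#' @export
roc_report <- function(scores, labels, out_dir = NULL, name = "model") {
  pos <- labels == "preictal"
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(th) mean(scores[pos] >= th), 0)
  fpr <- vapply(thr, function(th) mean(scores[!pos] >= th), 0)
  curve <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cbind(name = name, curve),
                     file.path(out_dir, paste0("roc_", name, ".csv")),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, paste0("roc_", name, ".png")),
                   width = 480, height = 480)
    graphics::plot(fpr, tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "False positive rate", ylab = "True positive rate",
                   main = sprintf("%s (AUC = %.3f)", name, auc))
    graphics::abline(0, 1, lty = 2)
    grDevices::dev.off()
  }
  invisible(list(curve = curve, auc = auc))
}
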