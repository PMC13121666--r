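# Discrimination, calibration and clinical-utility metrics: ROC/AUROC with
# DeLong variance and confidence intervals, paired DeLong tests, threshold
# metrics, Hosmer-Lemeshow calibration, and decision-curve analysis.
# "Positive" throughout is GB; scores are P(GB).

#' @noRd
as_binary <- function(labels, positive = "GB") {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) return(as.integer(labels != 0))
  as.integer(labels == positive)
}

#' AUROC and ROC curve
#'
#' AUROC via the rank (Mann-Whitney) formula: concordant pairs plus half
#' the tied pairs over all positive-negative pairs. The ROC curve is a
#' threshold sweep over the unique scores.
#'
#' @param scores numeric classifier scores (larger = more positive).
#' @param labels class labels (positive class `"GB"`, or 0/1).
#' @param positive positive-class label.
#' @return list with `auc` and `roc` (data.frame threshold, sensitivity,
#'   specificity).
#' @export
roc_auc <- function(scores, labels, positive = "GB") {
  y <- as_binary(labels, positive)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes are required for ROC analysis")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1)),
    specificity = vapply(thr, function(t) mean(scores[y == 0] < t), numeric(1))
  )
  list(auc = auc, roc = roc)
}

# DeLong structural components: V10 (per positive) and V01 (per negative),
# via midranks so the computation is O(n log n).
#' @noRd
delong_components <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  n1 <- length(pos); n0 <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - r_pos) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_neg) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance and confidence interval of an AUROC
#'
#' @param scores,labels as in [roc_auc()].
#' @param level confidence level (default 0.95).
#' @param positive positive-class label.
#' @return list with `auc`, `variance`, `ci` (clipped to \[0, 1\]),
#'   `degenerate` (TRUE when the variance collapses to 0).
#' @export
delong_variance_ci <- function(scores, labels, level = 0.95, positive = "GB") {
  y <- as_binary(labels, positive)
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stopf("need at least 2 cases per class for the DeLong variance")
  dc <- delong_components(scores, y)
  v <- var(dc$v10) / length(dc$v10) + var(dc$v01) / length(dc$v01)
  z <- qnorm(1 - (1 - level) / 2)
  ci <- dc$auc + c(-1, 1) * z * sqrt(v)
  list(auc = dc$auc, variance = v, ci = pmin(pmax(ci, 0), 1),
       degenerate = v <= 0)
}

#' Paired DeLong test for two correlated AUROCs
#'
#' @param scores_a,scores_b paired score vectors on the same rows.
#' @param labels shared class labels.
#' @param positive positive-class label.
#' @return list with `auc_a`, `auc_b`, `z`, `p` (two-sided).
#' @export
delong_test <- function(scores_a, scores_b, labels, positive = "GB") {
  y <- as_binary(labels, positive)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(y))
    stopf("paired DeLong test requires identically indexed score vectors")
  a <- delong_components(scores_a, y)
  b <- delong_components(scores_b, y)
  n1 <- length(a$v10); n0 <- length(a$v01)
  s10 <- cov(cbind(a$v10, b$v10)); s01 <- cov(cbind(a$v01, b$v01))
  vdiff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
           (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- a$auc - b$auc
  if (vdiff <= 0) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else z <- d / sqrt(vdiff)
  p <- if (is.infinite(z)) 0 else 2 * pnorm(-abs(z))
  list(auc_a = a$auc, auc_b = b$auc, z = z, p = p)
}

#' Confusion-matrix metrics at a threshold
#'
#' Scores at or above the threshold are called positive. Ratios with a zero
#' denominator are reported as NA, not 0.
#'
#' @param scores,labels as in [roc_auc()].
#' @param threshold decision threshold.
#' @param positive positive-class label.
#' @return named vector: accuracy, sensitivity, specificity, ppv, npv.
#' @export
threshold_metrics <- function(scores, labels, threshold, positive = "GB") {
  y <- as_binary(labels, positive)
  if (!any(y == 1) || !any(y == 0)) stopf("both classes required")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = (tp + tn) / length(y),
    sensitivity = rat(tp, tp + fn),
    specificity = rat(tn, tn + fp),
    ppv = rat(tp, tp + fp),
    npv = rat(tn, tn + fn))
}

#' Hosmer-Lemeshow calibration test
#'
#' Deciles-of-risk binning: predicted probabilities are grouped into `g`
#' equal-count bins (ties kept together); the statistic is
#' `sum((O - E)^2 / (n * pbar * (1 - pbar)))` with p-value from chi-squared
#' on `g - 2` degrees of freedom (using the realized bin count).
#'
#' @param probs predicted probabilities.
#' @param labels class labels.
#' @param g requested bin count (default 10).
#' @param positive positive-class label.
#' @return list with `bins` (data.frame n, mean_predicted, observed_rate),
#'   `statistic`, `df`, `p`, `flagged` (any bin guarded by eps).
#' @export
calibration_hosmer_lemeshow <- function(probs, labels, g = 10, positive = "GB") {
  if (g < 2) stopf("g must be >= 2")
  y <- as_binary(labels, positive)
  qs <- quantile(probs, seq(0, 1, length.out = g + 1), type = 7)
  brk <- unique(qs)
  if (length(brk) < 3) brk <- c(-Inf, mean(range(probs)), Inf)
  bin <- cut(probs, breaks = brk, include.lowest = TRUE)
  eps <- 1e-10
  flagged <- FALSE
  per <- lapply(levels(bin), function(b) {
    sel <- bin == b
    n <- sum(sel)
    if (n == 0) return(NULL)
    pbar <- mean(probs[sel])
    o <- sum(y[sel])
    if (pbar <= 0 || pbar >= 1) { flagged <<- TRUE; pbar <- min(max(pbar, eps), 1 - eps) }
    data.frame(n = n, mean_predicted = pbar, observed = o,
               observed_rate = o / n,
               contrib = (o - n * pbar)^2 / (n * pbar * (1 - pbar)))
  })
  bins <- do.call(rbind, per)
  stat <- sum(bins$contrib)
  df <- max(1, nrow(bins) - 2)
  list(bins = bins, statistic = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE), flagged = flagged)
}

#' Decision-curve analysis
#'
#' Net benefit of the model, treat-all and treat-none strategies over a
#' threshold-probability grid:
#' `NB_model(t) = TP/n - FP/n * t/(1-t)`, `NB_all(t) = pi - (1-pi) t/(1-t)`,
#' `NB_none = 0`. Thresholds outside (0, 1) are dropped.
#'
#' @param probs predicted probabilities.
#' @param labels class labels.
#' @param thresholds threshold grid (default 0.01..0.99 step 0.01).
#' @param positive positive-class label.
#' @return data.frame: threshold, nb_model, nb_all, nb_none.
#' @export
decision_curve <- function(probs, labels, thresholds = seq(0.01, 0.99, by = 0.01),
                           positive = "GB") {
  y <- as_binary(labels, positive)
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  n <- length(y); prev <- mean(y)
  out <- lapply(thresholds, function(t) {
    pos <- probs >= t
    tp <- sum(pos & y == 1); fp <- sum(pos & y == 0)
    data.frame(threshold = t,
               nb_model = tp / n - fp / n * t / (1 - t),
               nb_all = prev - (1 - prev) * t / (1 - t),
               nb_none = 0)
  })
  do.call(rbind, out)
}

#' Evaluate a set of models across datasets
#'
#' Emits the full performance table (one row per model x dataset: accuracy,
#' AUROC with DeLong 95% CI, sensitivity, specificity, PPV, NPV at the
#' model's frozen training threshold), ROC curves, Hosmer-Lemeshow
#' calibration, decision curves (full 0.01-0.99 grid; the clinically
#' plausible 0.15-0.35 window is a view of the same curve), and the pairwise
#' DeLong matrix per dataset.
#'
#' @param predictions nested list `predictions[[dataset]][[model]]` of
#'   probability vectors.
#' @param labels list `labels[[dataset]]` of class labels.
#' @param thresholds named per-model decision thresholds.
#' @param hl_bins Hosmer-Lemeshow bin count.
#' @return object of class `evaluation_report` with `table` (the metrics
#'   data.frame), `roc`, `calibration`, `dca`, `delong` (per dataset:
#'   matrix of pairwise p-values).
#' @export
evaluate_models <- function(predictions, labels, thresholds, hl_bins = 10) {
  tab <- list(); roc <- list(); cal <- list(); dca <- list(); dl <- list()
  for (ds in names(predictions)) {
    y <- labels[[ds]]
    models <- names(predictions[[ds]])
    for (mn in models) {
      p <- predictions[[ds]][[mn]]
      ra <- roc_auc(p, y)
      ci <- delong_variance_ci(p, y)
      tm <- threshold_metrics(p, y, thresholds[[mn]])
      tab[[length(tab) + 1L]] <- data.frame(
        model = mn, dataset = ds, accuracy = tm[["accuracy"]],
        auroc = ra$auc, ci_lower = ci$ci[1], ci_upper = ci$ci[2],
        sensitivity = tm[["sensitivity"]], specificity = tm[["specificity"]],
        ppv = tm[["ppv"]], npv = tm[["npv"]], stringsAsFactors = FALSE)
      roc[[ds]][[mn]] <- ra$roc
      cal[[ds]][[mn]] <- calibration_hosmer_lemeshow(p, y, hl_bins)
      dca[[ds]][[mn]] <- decision_curve(p, y)
    }
    m <- matrix(NA_real_, length(models), length(models),
                dimnames = list(models, models))
    for (i in seq_along(models)) for (j in seq_along(models)) {
      if (i < j) {
        dt <- delong_test(predictions[[ds]][[models[i]]],
                          predictions[[ds]][[models[j]]], y)
        m[i, j] <- m[j, i] <- dt$p
      }
    }
    dl[[ds]] <- m
  }
  structure(list(table = do.call(rbind, tab), roc = roc, calibration = cal,
                 dca = dca, delong = dl), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' @param report an `evaluation_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$table, file.path(dir, "performance_table.csv"), row.names = FALSE)
  for (ds in names(report$delong))
    write.csv(report$delong[[ds]], file.path(dir, sprintf("delong_%s.csv", ds)))
  json <- list(
    table = report$table,
    calibration = lapply(report$calibration, function(ms)
      lapply(ms, function(h) h[c("statistic", "df", "p")])),
    dca = report$dca
  )
  jsonlite::write_json(json, file.path(dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
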