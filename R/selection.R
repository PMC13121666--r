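# Four-stage feature-selection chain: median imputation (training
# statistics only), Mann-Whitney univariate screen (p < alpha, no
# multiplicity correction), greedy Pearson correlation pruning (|r| >
# threshold, smaller univariate p wins), mRMR ranking (F-statistic
# relevance, mean-|r| redundancy, difference scheme), and L1-penalized
# logistic regression with stratified cross-validated lambda.

#' Configure the selection chain
#'
#' @param alpha univariate significance level (default 0.05).
#' @param r_threshold absolute Pearson correlation cutoff (default 0.9).
#' @param mrmr_top number of mRMR-ranked features kept (default 32).
#' @param lasso_folds cross-validation folds (default 10).
#' @param lambda_n,lambda_min_ratio LASSO grid: `lambda_n` log-spaced values
#'   from `lambda_max` (smallest all-zero lambda) down to
#'   `lambda_max * lambda_min_ratio`.
#' @param seed integer seed (fold assignment).
#' @return object of class `selection_config`.
#' @export
selection_config <- function(alpha = 0.05, r_threshold = 0.9, mrmr_top = 32,
                             lasso_folds = 10, lambda_n = 50,
                             lambda_min_ratio = 1e-4, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (r_threshold <= 0 || r_threshold > 1) stopf("r_threshold must be in (0, 1]")
  if (mrmr_top < 1) stopf("mrmr_top must be >= 1")
  if (lasso_folds < 2) stopf("lasso_folds must be >= 2")
  structure(list(alpha = alpha, r_threshold = r_threshold, mrmr_top = mrmr_top,
                 lasso_folds = lasso_folds, lambda_n = lambda_n,
                 lambda_min_ratio = lambda_min_ratio, seed = as.integer(seed)),
            class = "selection_config")
}

#' Impute missing feature values with training medians
#'
#' Columns missing in more than half of the training rows are dropped (and
#' recorded); remaining missing cells — in any split — are filled with the
#' training-column median, so validation/test statistics never leak in.
#'
#' @param table data.frame of features (rows = patients).
#' @param train_idx indices (or logical) of training rows.
#' @return list with `table` (imputed), `dropped` (character), `medians`
#'   (named numeric).
#' @export
impute_missing <- function(table, train_idx) {
  tr <- table[train_idx, , drop = FALSE]
  frac_missing <- colMeans(is.na(tr))
  dropped <- names(tr)[frac_missing > 0.5]
  keep <- setdiff(names(table), dropped)
  table <- table[, keep, drop = FALSE]
  meds <- vapply(table[train_idx, , drop = FALSE], median, numeric(1), na.rm = TRUE)
  for (cn in keep) {
    miss <- is.na(table[[cn]])
    if (any(miss)) table[[cn]][miss] <- meds[[cn]]
  }
  list(table = table, dropped = dropped, medians = meds)
}

#' Univariate Mann-Whitney screen
#'
#' Two-sided Mann-Whitney U test per feature; survivors have p < alpha. No
#' multiplicity correction (matching the stated selection rule). Constant
#' features get p = 1 and are removed.
#'
#' @param X data.frame or matrix of features (training rows).
#' @param y two-level factor or character class labels.
#' @param alpha significance level.
#' @return list with `survivors` (character) and `p_values` (named numeric).
#' @export
univariate_filter <- function(X, y, alpha = 0.05) {
  y <- factor(y)
  if (nlevels(y) != 2) stopf("exactly two classes required")
  if (min(table(y)) < 3) stopf("each class needs >= 3 rows")
  X <- as.data.frame(X)
  p <- vapply(X, function(col) {
    if (length(unique(col)) < 2) return(1)
    suppressWarnings(wilcox.test(col ~ y)$p.value)
  }, numeric(1))
  p[!is.finite(p)] <- 1
  list(survivors = names(p)[p < alpha], p_values = p)
}

#' Greedy Pearson correlation pruning
#'
#' Scans features in order of increasing univariate p; a feature is dropped
#' iff its absolute Pearson correlation with any already-kept feature
#' exceeds the threshold.
#'
#' @param X data.frame/matrix of features (training rows).
#' @param survivors candidate feature names.
#' @param p_values named univariate p-values (scan order).
#' @param r_threshold absolute correlation cutoff.
#' @return character vector of kept features (in scan order).
#' @export
correlation_prune <- function(X, survivors, p_values, r_threshold = 0.9) {
  if (!length(survivors)) return(character(0))
  ord <- survivors[order(p_values[survivors])]
  Xm <- as.matrix(as.data.frame(X)[ord])
  kept <- character(0)
  for (f in ord) {
    if (!length(kept)) { kept <- f; next }
    r <- suppressWarnings(abs(cor(Xm[, f], Xm[, kept, drop = FALSE])))
    r[!is.finite(r)] <- 0
    if (all(r <= r_threshold)) kept <- c(kept, f)
  }
  kept
}

# one-way F statistic of a two-class difference (mRMR relevance)
#' @noRd
f_statistic <- function(x, y) {
  n <- length(x)
  g <- split(x, y)
  gm <- mean(x)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, numeric(1)))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  k <- length(g)
  if (ssw <= 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' mRMR ranking (difference scheme)
#'
#' Greedy forward selection: relevance is the one-way F statistic of the
#' class difference, normalized by the largest F among the candidates;
#' redundancy is the mean absolute Pearson correlation with the
#' already-selected set; the criterion is `relevance_norm - redundancy`.
#' The first pick is the maximum-relevance feature. A candidate perfectly
#' correlated (|r| = 1, within 1e-12) with an already-selected feature
#' carries no new information and is ineligible at that step.
#'
#' @param X data.frame/matrix of candidate features (training rows).
#' @param y two-level labels.
#' @param m number of features to select (capped at the candidate count).
#' @return list with `selected` (in selection order), `scores` (criterion at
#'   selection), `relevance` (named F statistics).
#' @export
mrmr_rank <- function(X, y, m = 32) {
  X <- as.data.frame(X)
  if (!ncol(X)) stopf("no candidate features for mRMR")
  y <- factor(y)
  rel <- vapply(X, f_statistic, numeric(1), y = y)
  rel_max <- max(rel[is.finite(rel)], 1)
  rel_n <- ifelse(is.finite(rel), rel / rel_max, 1)
  names(rel_n) <- names(X)
  Xm <- as.matrix(X)
  m <- min(m, ncol(X))
  selected <- character(0); scores <- numeric(0)
  remaining <- names(X)
  for (step in seq_len(m)) {
    crit <- if (!length(selected)) rel_n[remaining] else {
      rmat <- matrix(abs(suppressWarnings(
        cor(Xm[, selected, drop = FALSE], Xm[, remaining, drop = FALSE]))),
        nrow = length(selected))
      rmat[!is.finite(rmat)] <- 1
      red <- colMeans(rmat)
      out <- rel_n[remaining] - red
      out[apply(rmat, 2, max) >= 1 - 1e-12] <- -Inf  # duplicates ineligible
      out
    }
    if (all(!is.finite(crit))) break
    pick <- remaining[which.max(crit)]
    selected <- c(selected, pick)
    scores <- c(scores, max(crit))
    remaining <- setdiff(remaining, pick)
    if (!length(remaining)) break
  }
  list(selected = selected, scores = scores, relevance = rel)
}

#' LASSO logistic selection with cross-validated lambda
#'
#' Features are standardized with training statistics; the lambda grid runs
#' log-spaced from `lambda_max` (the smallest lambda shrinking every
#' coefficient to zero) down by `lambda_min_ratio`; folds are stratified by
#' class and seeded; lambda is chosen by minimum mean cross-validated
#' binomial deviance; the model is refit on all training rows at the chosen
#' lambda. The rad-score of a case is the linear predictor
#' `intercept + sum(beta_i * z(x_i))` over the nonzero coefficients.
#'
#' @param X data.frame/matrix of features (training rows).
#' @param y two-level labels; the second factor level is the positive class.
#' @param config a [selection_config()].
#' @return list with `selected`, `coefficients` (incl. intercept on the
#'   standardized scale), `lambda`, `lambda_grid`, `cv_deviance`, `scaler`,
#'   and `radscore(newdata)`.
#' @export
lasso_select <- function(X, y, config = selection_config()) {
  X <- as.matrix(as.data.frame(X))
  y <- factor(y)
  if (nlevels(y) != 2) stopf("exactly two classes required")
  if (min(table(y)) < config$lasso_folds)
    stopf("need >= %d rows per class for %d-fold stratified CV",
          config$lasso_folds, config$lasso_folds)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl <= 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  yn <- as.integer(y) - 1L
  n <- nrow(Z)
  lambda_max <- max(abs(crossprod(Z, yn - mean(yn)))) / n
  grid <- exp(seq(log(lambda_max), log(lambda_max * config$lambda_min_ratio),
                  length.out = config$lambda_n))
  # stratified, seeded fold assignment
  set.seed(config$seed)
  foldid <- integer(n)
  for (cl in levels(y)) {
    rows <- which(y == cl)
    foldid[rows] <- sample(rep_len(seq_len(config$lasso_folds), length(rows)))
  }
  cv <- glmnet::cv.glmnet(Z, yn, family = "binomial", lambda = grid,
                          foldid = foldid, type.measure = "deviance",
                          standardize = FALSE)
  lam <- cv$lambda.min
  fit <- glmnet::glmnet(Z, yn, family = "binomial", lambda = grid,
                        standardize = FALSE)
  beta <- as.numeric(coef(fit, s = lam))
  names(beta) <- c("(Intercept)", colnames(Z))
  nz <- names(beta)[-1][beta[-1] != 0]
  if (!length(nz))
    stopf(paste("LASSO selected no features at the cross-validated lambda;",
                "extend the lambda grid (smaller lambda_min_ratio) or revisit",
                "the upstream stages"))
  coefs <- beta[c("(Intercept)", nz)]
  radscore <- function(newdata) {
    Zn <- sweep(sweep(as.matrix(as.data.frame(newdata)[, nz, drop = FALSE]),
                      2, ctr[nz]), 2, scl[nz], "/")
    as.numeric(coefs[1] + Zn %*% coefs[-1])
  }
  list(selected = nz, coefficients = coefs, lambda = lam, lambda_grid = grid,
       cv_deviance = setNames(cv$cvm, signif(cv$lambda, 8)),
       scaler = list(center = ctr[nz], scale = scl[nz]), radscore = radscore)
}

#' Run the full four-stage selection chain
#'
#' Imputation, univariate screen, correlation pruning, mRMR, LASSO — all
#' decided on training rows only — and an audit trail of the survivors and
#' statistics at every stage.
#'
#' @param table feature data.frame (all rows).
#' @param labels class labels aligned with `table` rows.
#' @param train_idx training row indices.
#' @param config a [selection_config()].
#' @return object of class `selection_report`: per-stage survivor lists and
#'   statistics, the imputed table, and the LASSO rad-score.
#' @export
select_features <- function(table, labels, train_idx, config = selection_config()) {
  imp <- impute_missing(table, train_idx)
  Xtr <- imp$table[train_idx, , drop = FALSE]
  ytr <- labels[train_idx]
  uni <- univariate_filter(Xtr, ytr, config$alpha)
  pruned <- correlation_prune(Xtr, uni$survivors, uni$p_values, config$r_threshold)
  mr <- if (length(pruned)) mrmr_rank(Xtr[, pruned, drop = FALSE], ytr, config$mrmr_top)
        else list(selected = character(0), scores = numeric(0), relevance = numeric(0))
  if (!length(mr$selected)) stopf("no features survived to the mRMR stage")
  las <- lasso_select(Xtr[, mr$selected, drop = FALSE], ytr, config)
  structure(list(
    stages = list(
      input = names(table),
      imputed = list(kept = names(imp$table), dropped = imp$dropped),
      univariate = list(survivors = uni$survivors, p_values = uni$p_values),
      correlation = list(survivors = pruned),
      mrmr = list(survivors = mr$selected, scores = mr$scores,
                  relevance = mr$relevance),
      lasso = list(survivors = las$selected, coefficients = las$coefficients,
                   lambda = las$lambda)
    ),
    table = imp$table, medians = imp$medians, radscore = las$radscore,
    lasso = las, config = config
  ), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  s <- x$stages
  cat(sprintf(paste0("<selection_report> %d -> univariate %d -> correlation %d",
                     " -> mRMR %d -> LASSO %d\n"),
              length(s$input), length(s$univariate$survivors),
              length(s$correlation$survivors), length(s$mrmr$survivors),
              length(s$lasso$survivors)))
  invisible(x)
}
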