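# Four-stage selection chain: imputation, Mann-Whitney screen, greedy
# correlation pruning, mRMR (vs an exhaustive greedy oracle), LASSO (vs an
# IRLS logistic oracle in the small-penalty limit), and the nesting /
# no-leakage invariants.

test_that("imputation uses training medians only and drops mostly-missing columns", {
  tb <- data.frame(a = c(1, 2, NA, 4, 100), b = c(NA, NA, NA, 1, 2),
                   c = c(0.3, 0.5, 0.4, NA, NA))
  train <- 1:4
  out <- impute_missing(tb, train)
  expect_equal(out$dropped, "b")                 # 3/4 training rows missing
  expect_equal(out$table$a[3], median(c(1, 2, 4), na.rm = TRUE))
  # validation rows get training medians, never their own statistics
  expect_equal(out$table$c[5], median(c(0.3, 0.5, 0.4)))
  expect_equal(out$table$c[4], median(c(0.3, 0.5, 0.4)))
  # nothing to do -> unchanged
  clean <- data.frame(x = 1:4)
  expect_equal(impute_missing(clean, 1:2)$table, clean)
})

test_that("the univariate screen keeps separated features and rejects flat ones", {
  set.seed(1)
  y <- rep(c("GB", "SBM"), each = 20)
  X <- data.frame(
    flat = rep(1, 40),
    same = rnorm(40),
    sep = c(rnorm(20, 0), rnorm(20, 10)))   # complete separation
  out <- univariate_filter(X, y, 0.05)
  expect_false("flat" %in% out$survivors)
  expect_true("sep" %in% out$survivors)
  expect_lt(out$p_values[["sep"]], 1e-6)    # exact U tail at U = 0
  expect_equal(out$p_values[["flat"]], 1)
})

test_that("univariate type-I error is nominal under the null", {
  set.seed(42)
  n <- 50
  y <- rep(c("GB", "SBM"), each = n)
  X <- as.data.frame(matrix(rnorm(2 * n * 400), 2 * n, 400))
  out <- univariate_filter(X, y, 0.05)
  expect_lt(abs(length(out$survivors) / 400 - 0.05), 0.025)
})

test_that("correlation pruning follows the greedy smaller-p-wins rule", {
  set.seed(2)
  n <- 200
  f1 <- rnorm(n)
  f2 <- 2 * f1                                  # r = 1 with f1
  p <- c(f1 = 0.001, f2 = 0.01, f3 = 0.02)
  X <- data.frame(f1 = f1, f2 = f2, f3 = rnorm(n))
  expect_equal(correlation_prune(X, names(p), p, 0.9), c("f1", "f3"))

  # all pairwise |r| below threshold -> everything kept
  X2 <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  p2 <- c(a = 0.01, b = 0.02, c = 0.03)
  expect_equal(correlation_prune(X2, names(p2), p2, 0.9), c("a", "b", "c"))

  # constructed correlation pattern: |r(f1,f2)| > 0.9, |r(f1,f3)| ~ 0.5,
  # |r(f2,f3)| ~ 0.6 -> f2 dropped against f1, f3 kept (only compared to f1)
  S <- matrix(c(1, 0.95, 0.5,
                0.95, 1, 0.6,
                0.5, 0.6, 1), 3, 3)
  L <- chol(S)
  Z <- matrix(rnorm(3 * 5000), 5000, 3) %*% L
  X3 <- data.frame(f1 = Z[, 1], f2 = Z[, 2], f3 = Z[, 3])
  p3 <- c(f1 = 0.001, f2 = 0.005, f3 = 0.01)
  expect_equal(correlation_prune(X3, names(p3), p3, 0.9), c("f1", "f3"))
})

test_that("mRMR picks max relevance first and never selects a duplicate second", {
  set.seed(3)
  n <- 120
  y <- rep(c("GB", "SBM"), each = n / 2)
  top <- c(rnorm(n / 2, 0), rnorm(n / 2, 3))
  X <- data.frame(top = top, dup = top, weak = c(rnorm(n / 2, 0), rnorm(n / 2, 0.8)),
                  noise = rnorm(n))
  out <- mrmr_rank(X, y, 3)
  rel <- vapply(X, function(col) habitatrad:::f_statistic(col, factor(y)), numeric(1))
  expect_equal(out$selected[1], names(which.max(rel)))
  expect_false(out$selected[2] == "dup")
  # fewer candidates than m -> all (informative) candidates returned
  expect_length(mrmr_rank(X[, c("top", "weak")], y, 10)$selected, 2)
})

test_that("greedy mRMR matches the exhaustive greedy oracle on small tables", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 80
    y <- factor(rep(c("GB", "SBM"), each = n / 2))
    X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    X[, 1] <- X[, 1] + as.integer(y == "GB") * seed / 2
    X[, 4] <- X[, 1] * 0.8 + rnorm(n) * 0.3
    got <- mrmr_rank(X, y, 6)$selected

    # oracle: recompute the criterion from scratch at every step
    rel <- vapply(X, function(col) {
      g <- split(col, y); gm <- mean(col)
      ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, numeric(1)))
      ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
      (ssb / 1) / (ssw / (n - 2))
    }, numeric(1))
    rel_n <- rel / max(rel)
    sel <- character(0); rem <- names(X)
    while (length(rem)) {
      crit <- vapply(rem, function(f) {
        if (!length(sel)) return(rel_n[[f]])
        rr <- abs(vapply(sel, function(s) cor(X[[f]], X[[s]]), numeric(1)))
        if (max(rr) >= 1 - 1e-12) return(-Inf)   # duplicate: ineligible
        rel_n[[f]] - mean(rr)
      }, numeric(1))
      pick <- rem[which.max(crit)]
      sel <- c(sel, pick); rem <- setdiff(rem, pick)
    }
    expect_equal(got, sel, label = sprintf("seed %d", seed))
  }
})

test_that("LASSO at vanishing penalty matches an IRLS logistic oracle", {
  set.seed(4)
  n <- 300
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  eta <- 0.8 * X[, 1] - 0.5 * X[, 2]
  y <- rbinom(n, 1, plogis(eta))
  Z <- scale(X)
  lam_max <- max(abs(crossprod(Z, y - mean(y)))) / n
  grid <- exp(seq(log(lam_max), log(lam_max * 1e-7), length.out = 80))
  fit <- glmnet::glmnet(Z, y, family = "binomial", lambda = grid, standardize = FALSE)
  beta_glmnet <- as.numeric(coef(fit, s = min(grid)))
  beta_oracle <- oracle_logistic(Z, y)
  expect_equal(beta_glmnet, beta_oracle, tolerance = 1e-3)
})

test_that("LASSO selection errors when everything is shrunk away, recovers support otherwise", {
  set.seed(5)
  n <- 60
  X <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  y <- rep(c("GB", "SBM"), each = n / 2)   # labels independent of X
  cfg <- selection_config(lasso_folds = 5, lambda_n = 3, lambda_min_ratio = 0.9)
  expect_error(suppressWarnings(lasso_select(X, y, cfg)), "lambda")

  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 200
    X <- as.data.frame(matrix(rnorm(n * 32), n, 32))
    names(X) <- c("inf1", "inf2", sprintf("noise%02d", 1:30))
    eta <- 1.5 * X$inf1 - 1.5 * X$inf2
    yy <- ifelse(rbinom(n, 1, plogis(eta)) == 1, "GB", "SBM")
    if (min(table(yy)) < 10) next
    las <- lasso_select(X, yy, selection_config(seed = seed))
    if (all(c("inf1", "inf2") %in% las$selected)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("the full chain yields nested survivor sets and a leakage-free audit", {
  res <- fixture_pipeline()
  for (fam in c("habitat", "radiomics")) {
    s <- res$selection[[fam]]$stages
    expect_true(all(s$univariate$survivors %in% s$imputed$kept))
    expect_true(all(s$correlation$survivors %in% s$univariate$survivors))
    expect_true(all(s$mrmr$survivors %in% s$correlation$survivors))
    expect_true(all(s$lasso$survivors %in% s$mrmr$survivors))
    expect_lte(length(s$mrmr$survivors), res$config$selection$mrmr_top)
  }

  # leakage: rerunning the chain on training rows alone reproduces the
  # stage statistics bit for bit
  man <- res$manifest
  fam <- "habitat"
  tb <- res$features$habitat[man$patient_id, ]
  train_idx <- which(man$split == "training")
  cfg <- res$config$selection; cfg$seed <- res$config$seed + 4L
  cfg$lasso_folds <- res$selection[[fam]]$config$lasso_folds
  extra <- setdiff(seq_len(nrow(tb)), train_idx)[1]
  redo <- suppressWarnings(   # glmnet small-fold note at this fixture scale
    select_features(tb[c(train_idx, extra), ],
                    setNames(man$diagnosis, man$patient_id)[c(train_idx, extra)],
                    seq_along(train_idx), cfg))
  expect_identical(redo$stages$univariate$p_values,
                   res$selection[[fam]]$stages$univariate$p_values)
  expect_identical(redo$stages$lasso$coefficients,
                   res$selection[[fam]]$stages$lasso$coefficients)
})
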