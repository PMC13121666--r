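# The five model families: per-subregion, fused habitat, whole-ROI
# radiomics, clinical, and the combined logistic nomogram. Positive class =
# GB throughout; the decision threshold is the training-ROC Youden optimum,
# frozen for validation/test.

MODEL_CLASSIFIERS <- c("linear_svm", "random_forest", "extra_trees",
                       "gradient_boosting", "logistic")

#' Specify a model
#'
#' @param name model family label (e.g. `"habitat"`, `"habitat_h2"`,
#'   `"radiomics"`, `"clinical"`, `"combined"`).
#' @param classifier one of `r paste0('"', MODEL_CLASSIFIERS, '"', collapse = ", ")`.
#' @param features feature column names the model consumes.
#' @param seed integer seed.
#' @param hyper optional named list of hyperparameter overrides.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name, classifier = "linear_svm", features = NULL,
                       seed = 1L, hyper = list()) {
  classifier <- match.arg(classifier, MODEL_CLASSIFIERS)
  structure(list(name = name, classifier = classifier, features = features,
                 seed = as.integer(seed), hyper = hyper), class = "model_spec")
}

# Platt scaling: fit sigmoid p = 1/(1+exp(A*f+B)) on decision values with
# smoothed targets (Platt 1999), by BFGS on the cross-entropy.
#' @noRd
platt_fit <- function(f, y01) {
  np <- sum(y01 == 1); nn <- sum(y01 == 0)
  t <- ifelse(y01 == 1, (np + 1) / (np + 2), 1 / (nn + 2))
  obj <- function(ab) {
    z <- ab[1] * f + ab[2]
    p <- plogis(-z)
    -sum(t * log(pmax(p, 1e-12)) + (1 - t) * log(pmax(1 - p, 1e-12)))
  }
  res <- optim(c(-1, 0), obj, method = "BFGS")
  res$par
}

#' @noRd
platt_predict <- function(ab, f) plogis(-(ab[1] * f + ab[2]))

#' Youden-optimal threshold on a score vector
#' @noRd
youden_threshold <- function(scores, y01) {
  cand <- sort(unique(scores))
  cand <- c(cand, max(cand) + 1e-9)
  best <- cand[1]; bestj <- -Inf
  for (t in cand) {
    sens <- mean(scores[y01 == 1] >= t)
    spec <- mean(scores[y01 == 0] < t)
    j <- sens + spec - 1
    if (j > bestj) { bestj <- j; best <- t }
  }
  best
}

#' Train a classifier
#'
#' Fits the requested classifier with seeded determinism. Features are
#' standardized with training statistics for the linear SVM and logistic
#' regression; tree ensembles see raw features. The linear SVM's margins are
#' converted to probabilities by Platt scaling fitted on the training
#' decision values; the other classifiers emit native probabilities.
#'
#' @param spec a [model_spec()].
#' @param X data.frame of training features.
#' @param y class labels (`"GB"` = positive, `"SBM"` = negative).
#' @return object of class `fitted_model` with stored scaler and
#'   training-Youden decision threshold.
#' @export
train_model <- function(spec, X, y) {
  X <- as.data.frame(X)
  if (!is.null(spec$features)) X <- X[, spec$features, drop = FALSE]
  y <- factor(y, levels = c("SBM", "GB"))
  if (nlevels(droplevels(y)) < 2) stopf("training labels contain a single class")
  y01 <- as.integer(y) - 1L
  ctr <- vapply(X, mean, numeric(1))
  scl <- vapply(X, stats::sd, numeric(1)); scl[scl <= 0 | !is.finite(scl)] <- 1
  Z <- as.data.frame(sweep(sweep(as.matrix(X), 2, ctr), 2, scl, "/"))
  set.seed(spec$seed)
  h <- spec$hyper
  fit <- switch(spec$classifier,
    linear_svm = {
      sv <- e1071::svm(as.matrix(Z), y, kernel = "linear",
                       cost = h$cost %||% 1, scale = FALSE)
      dv <- as.numeric(attr(predict(sv, as.matrix(Z), decision.values = TRUE),
                            "decision.values"))
      # orient decision values so larger = more GB-like
      sgn <- if (isTRUE(suppressWarnings(cor(dv, y01)) < 0)) -1 else 1
      ab <- platt_fit(sgn * dv, y01)
      list(svm = sv, sign = sgn, platt = ab)
    },
    random_forest = randomForest::randomForest(
      x = Z, y = y, ntree = h$ntree %||% 500),
    extra_trees = ranger::ranger(
      x = Z, y = y, probability = TRUE, num.trees = h$ntree %||% 500,
      splitrule = "extratrees", num.random.splits = 1, seed = spec$seed,
      num.threads = 1),
    gradient_boosting = {
      dm <- xgboost::xgb.DMatrix(as.matrix(Z), label = y01)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = h$eta %||% 0.1,
                      max_depth = h$max_depth %||% 3,
                      subsample = h$subsample %||% 0.8,
                      colsample_bytree = h$colsample %||% 0.8,
                      tree_method = "exact", nthread = 1, seed = spec$seed),
        data = dm, nrounds = h$nrounds %||% 150, verbose = 0)
    },
    logistic = suppressWarnings(
      glm(y01 ~ ., data = cbind(Z, y01 = y01), family = binomial()))
  )
  model <- structure(list(spec = spec, fit = fit, center = ctr, scale = scl,
                          feature_names = names(X), threshold = NA_real_),
                     class = "fitted_model")
  p_train <- predict(model, X)$probability
  model$threshold <- youden_threshold(p_train, y01)
  model
}

#' Predict GB probabilities and hard labels
#'
#' @param object a `fitted_model`.
#' @param newdata data.frame carrying the model's feature columns.
#' @param ... unused.
#' @return list with `probability` (P(GB)) and `label` (`"GB"`/`"SBM"` via
#'   the stored training threshold).
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss))
    stopf("newdata is missing required column(s): %s", paste(miss, collapse = ", "))
  X <- newdata[, object$feature_names, drop = FALSE]
  Z <- as.data.frame(sweep(sweep(as.matrix(X), 2, object$center), 2,
                           object$scale, "/"))
  p <- switch(object$spec$classifier,
    linear_svm = {
      dv <- as.numeric(attr(predict(object$fit$svm, as.matrix(Z),
                                    decision.values = TRUE), "decision.values"))
      platt_predict(object$fit$platt, object$fit$sign * dv)
    },
    random_forest = unname(predict(object$fit, Z, type = "prob")[, "GB"]),
    extra_trees = unname(predict(object$fit, data = Z,
                                 num.threads = 1)$predictions[, "GB"]),
    gradient_boosting = as.numeric(predict(object$fit, as.matrix(Z))),
    logistic = as.numeric(predict(object$fit, newdata = Z, type = "response"))
  )
  p <- pmin(pmax(p, 0), 1)
  lab <- ifelse(!is.na(object$threshold) & p >= object$threshold, "GB", "SBM")
  list(probability = p, label = lab)
}

#' Build the combined clinical + habitat model and its nomogram
#'
#' Clinical covariates (age, sex) are screened univariately on the training
#' rows (Mann-Whitney for age, chi-squared for sex) at `alpha`; the
#' survivors join the habitat rad-score in a multivariate logistic model,
#' from which a points-based nomogram is derived. If no covariate survives,
#' the combined model reduces to the rad-score logistic fit (recorded).
#'
#' @param radscore numeric habitat rad-score per training row.
#' @param clinical data.frame with `age` (years) and `sex`
#'   (`"male"`/`"female"`) for the training rows.
#' @param y class labels.
#' @param alpha screening level (default 0.05).
#' @param seed integer seed.
#' @return list with `model` (a `fitted_model` wrapping the logistic fit),
#'   `nomogram`, `screen` (covariate p-values and survivors).
#' @export
build_combined <- function(radscore, clinical, y, alpha = 0.05, seed = 1L) {
  y <- factor(y, levels = c("SBM", "GB"))
  p_age <- suppressWarnings(wilcox.test(clinical$age ~ y)$p.value)
  sex_tab <- table(clinical$sex, y)
  p_sex <- if (nrow(sex_tab) < 2) 1 else
    suppressWarnings(chisq.test(sex_tab)$p.value)
  keep <- character(0)
  if (is.finite(p_age) && p_age < alpha) keep <- c(keep, "age")
  if (is.finite(p_sex) && p_sex < alpha) keep <- c(keep, "sex")
  df <- data.frame(radscore = radscore)
  if ("age" %in% keep) df$age <- clinical$age
  if ("sex" %in% keep) df$sex <- as.integer(clinical$sex == "male")
  spec <- model_spec("combined", "logistic", features = names(df), seed = seed)
  model <- train_model(spec, df, as.character(y))
  nomo <- build_nomogram(model, df)
  list(model = model, nomogram = nomo,
       screen = list(p_age = p_age, p_sex = p_sex, survivors = keep,
                     radscore_only = !length(keep)))
}

#' Derive a points-based nomogram from a logistic `fitted_model`
#'
#' Each variable's points run linearly over its observed training range; the
#' variable with the largest |coefficient| x range spans exactly 100 points.
#' The total-points-to-probability mapping is monotone by construction.
#'
#' @param model a logistic `fitted_model`.
#' @param data training data (observed variable ranges).
#' @return object of class `nomogram`: per-variable point tables and a
#'   `total_points_to_prob(points)` function.
#' @export
build_nomogram <- function(model, data) {
  if (model$spec$classifier != "logistic")
    stopf("nomograms are derived from the logistic combined model")
  cf <- coef(model$fit)
  vars <- setdiff(names(cf), "(Intercept)")
  # coefficients are on the standardized scale; express per raw unit
  beta_raw <- cf[vars] / model$scale[sub("^`|`$", "", vars)]
  names(beta_raw) <- sub("^`|`$", "", vars)
  rng <- vapply(names(beta_raw), function(v) range(data[[v]]), numeric(2))
  span <- abs(beta_raw) * (rng[2, ] - rng[1, ])
  scale_pts <- 100 / max(span)
  tables <- lapply(names(beta_raw), function(v) {
    # x at 0 points: the end of the range where the linear predictor is lowest
    x0 <- if (beta_raw[v] >= 0) rng[1, v] else rng[2, v]
    data.frame(variable = v,
               x = seq(rng[1, v], rng[2, v], length.out = 11),
               points = abs(beta_raw[v]) * abs(seq(rng[1, v], rng[2, v],
                                                   length.out = 11) - x0) * scale_pts)
  })
  # linear predictor at the 0-point corner
  lp0 <- cf[["(Intercept)"]] +
    sum(vapply(names(beta_raw), function(v) {
      x0 <- if (beta_raw[v] >= 0) rng[1, v] else rng[2, v]
      cf[[v]] * (x0 - model$center[v]) / model$scale[v]
    }, numeric(1)))
  total_to_prob <- function(points) plogis(lp0 + points / scale_pts)
  structure(list(tables = do.call(rbind, tables), points_per_lp = scale_pts,
                 lp0 = lp0, total_points_to_prob = total_to_prob,
                 max_points = sum(vapply(seq_along(beta_raw), function(i)
                   span[i] * scale_pts, numeric(1)))),
            class = "nomogram")
}
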