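# End-to-end orchestration: simulate -> split -> cluster -> extract ->
# select -> train -> evaluate, seeded and reproducible, with artifacts
# written under a run directory.

#' Configure a pipeline run
#'
#' @param cohort a [cohort_spec()] (or preset) for simulation.
#' @param split_ratio training fraction of the non-test rows.
#' @param k_range candidate habitat counts.
#' @param fit_scope `"cohort"` (pool every case for clustering, the default)
#'   or `"train_only"` (leakage-safe: pool training cases only). Note the
#'   cohort scope lets validation/test voxels influence the clustering
#'   geometry; it mirrors cohort-level habitat construction, not a deployable
#'   model.
#' @param cluster_cap per-case voxel cap for the pooled clustering matrix.
#' @param extraction an [extraction_config()].
#' @param selection a [selection_config()].
#' @param classifier classifier for the radiomic models (the combined model
#'   is always logistic).
#' @param knn_k,knn_min_component label-cleanup parameters
#'   ([propagate_labels_knn()]).
#' @param out_dir optional artifact directory.
#' @param seed global seed; stage seeds derive from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_preset("desk"), split_ratio = 0.7,
                       k_range = 2:10, fit_scope = "cohort",
                       cluster_cap = 1000,
                       extraction = extraction_config(),
                       selection = selection_config(),
                       classifier = "linear_svm",
                       knn_k = 5, knn_min_component = 8,
                       out_dir = NULL, seed = 1L) {
  structure(list(cohort = cohort, split_ratio = split_ratio, k_range = k_range,
                 fit_scope = fit_scope, cluster_cap = cluster_cap,
                 extraction = extraction, selection = selection,
                 classifier = classifier, knn_k = knn_k,
                 knn_min_component = knn_min_component,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full habitat-radiomics pipeline
#'
#' @param config a [run_config()].
#' @param verbose log stage progress and timing.
#' @return list with `manifest`, `habitat_model`, `labelmaps`, `features`,
#'   `selection` (per model family), `models`, `predictions`, `evaluation`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  t_all <- Sys.time()
  log_stage <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  cfg_hash <- hash32(deparse(config[setdiff(names(config), "out_dir")]))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  # --- simulate ------------------------------------------------------------
  t0 <- Sys.time()
  spec <- config$cohort
  spec$seed <- (config$seed * 1000L + spec$seed) %% 2147483647L
  sim <- generate_cohort(spec)
  cases <- sim$cases
  manifest <- split_cohort(sim$manifest, ratio = config$split_ratio,
                           seed = config$seed + 1L)
  log_stage("[simulate] %d cases (%.1fs)", nrow(manifest),
            as.numeric(Sys.time() - t0, units = "secs"))

  # --- cluster -------------------------------------------------------------
  t0 <- Sys.time()
  pool_ids <- if (config$fit_scope == "train_only")
    manifest$patient_id[manifest$split == "training"] else manifest$patient_id
  vm <- build_voxel_matrix(cases[pool_ids], standardize = TRUE,
                           max_voxels_per_case = config$cluster_cap,
                           seed = config$seed + 2L)
  model <- select_k(vm, k_range = config$k_range, seed = config$seed + 3L,
                    fit_scope = config$fit_scope)
  labelmaps <- lapply(cases, function(cs) {
    propagate_labels_knn(assign_labels(cs, model), cs$grid$spacing,
                         k = config$knn_k,
                         min_component = config$knn_min_component)
  })
  log_stage("[cluster] K = %d selected by Calinski-Harabasz (%.1fs)",
            model$K, as.numeric(Sys.time() - t0, units = "secs"))

  # --- extract -------------------------------------------------------------
  t0 <- Sys.time()
  feats <- extract_cohort_features(cases, labelmaps, config$extraction,
                                   K = model$K)
  log_stage("[extract] %d features per region, %d fused (%.1fs)",
            ncol(feats$ROI), ncol(feats$habitat),
            as.numeric(Sys.time() - t0, units = "secs"))

  # --- select + train ------------------------------------------------------
  t0 <- Sys.time()
  ord <- manifest$patient_id
  labels <- setNames(manifest$diagnosis, ord)
  splits <- setNames(manifest$split, ord)
  train_idx <- which(splits == "training")
  sel_cfg <- config$selection
  sel_cfg$seed <- config$seed + 4L
  min_class <- min(table(labels[train_idx]))
  if (sel_cfg$lasso_folds > min_class) {
    log_stage("[select] reducing LASSO folds %d -> %d (smallest training class)",
              sel_cfg$lasso_folds, min_class)
    sel_cfg$lasso_folds <- max(2L, as.integer(min_class))
  }

  families <- c(setNames(paste0("H", seq_len(min(model$K, 3))),
                         paste0("habitat_h", seq_len(min(model$K, 3)))),
                habitat = "habitat", radiomics = "ROI")
  selection <- list(); models <- list(); predictions_all <- list()
  for (fam in names(families)) {
    tb <- feats[[families[[fam]]]][ord, , drop = FALSE]
    selrep <- select_features(tb, labels, train_idx, sel_cfg)
    selection[[fam]] <- selrep
    spec_m <- model_spec(fam, config$classifier,
                         features = selrep$stages$lasso$survivors,
                         seed = config$seed + 5L)
    models[[fam]] <- train_model(spec_m, selrep$table[train_idx, , drop = FALSE],
                                 labels[train_idx])
    predictions_all[[fam]] <- predict(models[[fam]], selrep$table)$probability
  }

  clinical <- data.frame(age = manifest$age,
                         sex = as.integer(manifest$sex == "male"),
                         row.names = ord)
  spec_c <- model_spec("clinical", config$classifier,
                       features = c("age", "sex"), seed = config$seed + 5L)
  models$clinical <- train_model(spec_c, clinical[train_idx, , drop = FALSE],
                                 labels[train_idx])
  predictions_all$clinical <- predict(models$clinical, clinical)$probability

  radscore_all <- selection$habitat$radscore(selection$habitat$table)
  comb <- build_combined(radscore_all[train_idx],
                         data.frame(age = manifest$age[train_idx],
                                    sex = manifest$sex[train_idx]),
                         labels[train_idx], alpha = sel_cfg$alpha,
                         seed = config$seed + 6L)
  models$combined <- comb$model
  comb_df <- data.frame(radscore = radscore_all)
  if ("age" %in% comb$screen$survivors) comb_df$age <- manifest$age
  if ("sex" %in% comb$screen$survivors)
    comb_df$sex <- as.integer(manifest$sex == "male")
  predictions_all$combined <- predict(models$combined, comb_df)$probability
  log_stage("[select+train] %d model families (%.1fs)", length(models),
            as.numeric(Sys.time() - t0, units = "secs"))

  # --- evaluate ------------------------------------------------------------
  t0 <- Sys.time()
  datasets <- intersect(c("training", "validation", "test"), unique(splits))
  predictions <- lapply(setNames(datasets, datasets), function(ds) {
    rows <- splits == ds
    lapply(predictions_all, function(p) p[rows])
  })
  ds_labels <- lapply(setNames(datasets, datasets),
                      function(ds) labels[splits == ds])
  thresholds <- vapply(models, function(m) m$threshold, numeric(1))
  evaluation <- evaluate_models(predictions, ds_labels, thresholds)
  log_stage("[evaluate] %d models x %d datasets (%.1fs)",
            length(models), length(datasets),
            as.numeric(Sys.time() - t0, units = "secs"))

  result <- list(manifest = manifest, habitat_model = model,
                 labelmaps = labelmaps, features = feats,
                 selection = selection, models = models, nomogram = comb$nomogram,
                 combined_screen = comb$screen,
                 predictions = predictions, labels = ds_labels,
                 evaluation = evaluation, config = config,
                 config_hash = cfg_hash)

  if (!is.null(out)) {
    write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)
    write.csv(data.frame(K = as.integer(names(model$ch_scores)),
                         ch_score = as.numeric(model$ch_scores),
                         config_hash = cfg_hash),
              file.path(out, "ch_scores.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(K = model$K, centroids = model$centroids,
           scaler = model$scaler, ch_scores = as.list(model$ch_scores),
           ordering = model$ordering, seed = model$seed,
           fit_scope = model$fit_scope, config_hash = cfg_hash),
      file.path(out, "habitat_model.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    for (fam in names(feats)) {
      if (fam == "missing") next
      write.csv(feats[[fam]], file.path(out, sprintf("features_%s.csv", fam)))
    }
    jsonlite::write_json(
      lapply(selection, function(rep) {
        s <- rep$stages
        list(univariate = s$univariate$survivors,
             correlation = s$correlation$survivors,
             mrmr = s$mrmr$survivors, lasso = s$lasso$survivors,
             lambda = s$lasso$lambda,
             coefficients = as.list(s$lasso$coefficients))
      }),
      file.path(out, "selection_reports.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    write_evaluation_report(evaluation, out)
  }
  log_stage("[done] total %.1fs", as.numeric(Sys.time() - t_all, units = "secs"))
  result
}

# ---- plots (base graphics, written by the analysis drivers) ---------------

#' Plot ROC curves of several models
#' @param roc_list named list of ROC data.frames (from [roc_auc()]).
#' @param main plot title.
#' @export
plot_roc <- function(roc_list, main = "ROC") {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "1 - specificity", ylab = "Sensitivity", main = main)
  cols <- grDevices::hcl.colors(length(roc_list), "Dark 3")
  for (i in seq_along(roc_list)) {
    r <- roc_list[[i]]
    o <- order(1 - r$specificity, r$sensitivity)
    graphics::lines((1 - r$specificity)[o], r$sensitivity[o], col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", legend = names(roc_list), col = cols,
                   lwd = 2, bty = "n", cex = 0.8)
}

#' Plot a calibration curve
#' @param hl a [calibration_hosmer_lemeshow()] result.
#' @param main plot title.
#' @export
plot_calibration <- function(hl, main = "Calibration") {
  b <- hl$bins
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "Mean predicted probability", ylab = "Observed rate",
                 main = sprintf("%s (HL p = %.3f)", main, hl$p))
  graphics::points(b$mean_predicted, b$observed_rate, pch = 19)
  graphics::lines(b$mean_predicted, b$observed_rate)
}

#' Plot decision curves
#' @param dca_list named list of [decision_curve()] data.frames.
#' @param window optional threshold window to shade (e.g. `c(0.15, 0.35)`).
#' @param main plot title.
#' @export
plot_dca <- function(dca_list, window = c(0.15, 0.35), main = "Decision curves") {
  d1 <- dca_list[[1]]
  ylim <- range(c(-0.05, unlist(lapply(dca_list, function(d) d$nb_model)),
                  d1$nb_all), finite = TRUE)
  graphics::plot(d1$threshold, d1$nb_all, type = "l", col = "grey40", lwd = 2,
                 xlab = "Threshold probability", ylab = "Net benefit",
                 ylim = c(max(-0.1, ylim[1]), ylim[2]), main = main)
  graphics::abline(h = 0, lty = 2)
  if (!is.null(window))
    graphics::rect(window[1], -1, window[2], 1, col = grDevices::adjustcolor("grey", 0.2),
                   border = NA)
  cols <- grDevices::hcl.colors(length(dca_list), "Dark 3")
  for (i in seq_along(dca_list))
    graphics::lines(dca_list[[i]]$threshold, dca_list[[i]]$nb_model,
                    col = cols[i], lwd = 2)
  graphics::legend("topright", legend = c("treat all", names(dca_list)),
                   col = c("grey40", cols), lwd = 2, bty = "n", cex = 0.8)
}

#' Plot a nomogram as stacked point scales
#' @param nomogram a [build_nomogram()] result.
#' @export
plot_nomogram <- function(nomogram) {
  tabs <- split(nomogram$tables, nomogram$tables$variable)
  nv <- length(tabs)
  graphics::plot(NULL, xlim = c(0, 100), ylim = c(0, nv + 1), axes = FALSE,
                 xlab = "Points", ylab = "", main = "Nomogram")
  graphics::axis(1)
  for (i in seq_along(tabs)) {
    tb <- tabs[[i]]
    graphics::lines(tb$points, rep(nv + 1 - i, nrow(tb)))
    graphics::text(tb$points[c(1, nrow(tb))], nv + 1 - i + 0.25,
                   signif(tb$x[c(1, nrow(tb))], 3), cex = 0.7)
    graphics::text(-2, nv + 1 - i, names(tabs)[i], adj = 1, xpd = TRUE, cex = 0.8)
  }
}
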