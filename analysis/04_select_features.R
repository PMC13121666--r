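#!/usr/bin/env Rscript
# Four-stage feature selection per model family (H1, H2, H3, habitat,
# whole-ROI radiomics): Mann-Whitney screen (p < 0.05), Pearson pruning
# (|r| > 0.9, smaller p wins), mRMR top-32, LASSO logistic with 10-fold
# stratified cross-validated lambda. Training rows only; the audit trail
# and rad-score coefficients land in results/selection.

suppressMessages(library(habitatrad))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

man <- read.csv("results/cohort/manifest.csv")
labels <- setNames(man$diagnosis, man$patient_id)
train_idx <- which(man$split == "training")
cfg <- selection_config(seed = seed + 4L)
cfg$lasso_folds <- min(cfg$lasso_folds, min(table(labels[train_idx])))

out <- "results/selection"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
reports <- list()
for (fam in c("H1", "H2", "H3", "habitat", "ROI")) {
  tb <- read.csv(sprintf("results/features/features_%s.csv", fam),
                 row.names = 1, check.names = FALSE)[man$patient_id, ]
  rep <- suppressWarnings(select_features(tb, labels, train_idx, cfg))
  reports[[fam]] <- rep
  print(rep)
  s <- rep$stages
  write.csv(data.frame(stage = c(rep("univariate", length(s$univariate$survivors)),
                                 rep("correlation", length(s$correlation$survivors)),
                                 rep("mrmr", length(s$mrmr$survivors)),
                                 rep("lasso", length(s$lasso$survivors))),
                       feature = c(s$univariate$survivors, s$correlation$survivors,
                                   s$mrmr$survivors, s$lasso$survivors)),
            file.path(out, sprintf("survivors_%s.csv", fam)), row.names = FALSE)
}
jsonlite::write_json(
  lapply(reports, function(rep) {
    s <- rep$stages
    list(n_univariate = length(s$univariate$survivors),
         n_correlation = length(s$correlation$survivors),
         n_mrmr = length(s$mrmr$survivors),
         lasso = s$lasso$survivors, lambda = s$lasso$lambda,
         coefficients = as.list(s$lasso$coefficients))
  }),
  file.path(out, "selection_reports.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
saveRDS(reports, file.path(out, "selection_reports.rds"))  # for 05/06
message("selection reports written to ", out)
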