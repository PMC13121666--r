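#!/usr/bin/env Rscript
# Train the seven models: one per habitat subregion, the fused habitat
# model, the whole-ROI radiomics model, the clinical (age + sex) model —
# all with the Platt-calibrated linear SVM by default — and the combined
# logistic model (habitat rad-score + screened clinical covariates) with
# its nomogram.

suppressMessages(library(habitatrad))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

man <- read.csv("results/cohort/manifest.csv")
labels <- setNames(man$diagnosis, man$patient_id)
train_idx <- which(man$split == "training")
reports <- readRDS("results/selection/selection_reports.rds")

models <- list(); predictions <- list()
fam_model <- c(H1 = "habitat_h1", H2 = "habitat_h2", H3 = "habitat_h3",
               habitat = "habitat", ROI = "radiomics")
for (fam in names(fam_model)) {
  rep <- reports[[fam]]
  spec <- model_spec(fam_model[[fam]], "linear_svm",
                     features = rep$stages$lasso$survivors, seed = seed + 5L)
  m <- train_model(spec, rep$table[train_idx, , drop = FALSE], labels[train_idx])
  models[[fam_model[[fam]]]] <- m
  predictions[[fam_model[[fam]]]] <- predict(m, rep$table)$probability
}

clinical <- data.frame(age = man$age, sex = as.integer(man$sex == "male"),
                       row.names = man$patient_id)
m_clin <- train_model(model_spec("clinical", "linear_svm",
                                 features = c("age", "sex"), seed = seed + 5L),
                      clinical[train_idx, ], labels[train_idx])
models$clinical <- m_clin
predictions$clinical <- predict(m_clin, clinical)$probability

rs <- reports$habitat$radscore(reports$habitat$table)
comb <- build_combined(rs[train_idx],
                       data.frame(age = man$age[train_idx], sex = man$sex[train_idx]),
                       labels[train_idx], seed = seed + 6L)
models$combined <- comb$model
comb_df <- data.frame(radscore = rs)
if ("age" %in% comb$screen$survivors) comb_df$age <- man$age
if ("sex" %in% comb$screen$survivors) comb_df$sex <- as.integer(man$sex == "male")
predictions$combined <- predict(comb$model, comb_df)$probability
message("clinical covariates surviving the univariate screen: ",
        if (length(comb$screen$survivors)) paste(comb$screen$survivors, collapse = ", ")
        else "none (rad-score only)")

out <- "results/models"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
saveRDS(models, file.path(out, "models.rds"))
saveRDS(predictions, file.path(out, "predictions.rds"))
write.csv(comb$nomogram$tables, file.path(out, "nomogram_points.csv"),
          row.names = FALSE)
grDevices::png(file.path(out, "nomogram.png"), 900, 600, res = 120)
plot_nomogram(comb$nomogram)
grDevices::dev.off()
message("models, predictions and nomogram written to ", out)
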