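#!/usr/bin/env Rscript
# Evaluation stack: the model x dataset performance table (accuracy, AUROC
# with DeLong 95% CI, sensitivity/specificity/PPV/NPV at the frozen
# training threshold), ROC / calibration / decision-curve figures, and the
# pairwise DeLong matrices.

suppressMessages(library(habitatrad))

man <- read.csv("results/cohort/manifest.csv")
labels <- setNames(man$diagnosis, man$patient_id)
splits <- setNames(man$split, man$patient_id)
models <- readRDS("results/models/models.rds")
predictions_all <- readRDS("results/models/predictions.rds")

datasets <- intersect(c("training", "validation", "test"), unique(splits))
predictions <- lapply(setNames(datasets, datasets), function(ds)
  lapply(predictions_all, function(p) p[splits == ds]))
ds_labels <- lapply(setNames(datasets, datasets), function(ds) labels[splits == ds])
thresholds <- vapply(models, function(m) m$threshold, numeric(1))

ev <- evaluate_models(predictions, ds_labels, thresholds)
print(ev)

out <- "results/evaluation"
write_evaluation_report(ev, out)

for (ds in datasets) {
  grDevices::png(file.path(out, sprintf("roc_%s.png", ds)), 800, 800, res = 120)
  plot_roc(ev$roc[[ds]], main = sprintf("ROC (%s)", ds))
  grDevices::dev.off()
  grDevices::png(file.path(out, sprintf("calibration_%s.png", ds)), 800, 800, res = 120)
  plot_calibration(ev$calibration[[ds]]$combined,
                   main = sprintf("Combined model (%s)", ds))
  grDevices::dev.off()
  grDevices::png(file.path(out, sprintf("dca_%s.png", ds)), 800, 800, res = 120)
  plot_dca(ev$dca[[ds]], main = sprintf("Decision curves (%s)", ds))
  grDevices::dev.off()
}
message("evaluation artifacts written to ", out)
for (ds in datasets) {
  message("DeLong pairwise p-values (", ds, "):")
  print(round(ev$delong[[ds]], 3))
}
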