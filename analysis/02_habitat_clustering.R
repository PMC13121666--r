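#!/usr/bin/env Rscript
# Cohort-level habitat clustering: pool ROI voxels of every case (ICVF,
# ISOVF, ODI channels, z-scored), scan K = 2..10 with k-means and pick the
# Calinski-Harabasz maximum, then write per-patient habitat label maps
# (nearest-centroid assignment + KNN cleanup of fragments).

suppressMessages(library(habitatrad))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

man <- read.csv("results/cohort/manifest.csv")
cases <- setNames(lapply(seq_len(nrow(man)), function(i) load_case(man[i, ])),
                  man$patient_id)

vm <- build_voxel_matrix(cases, standardize = TRUE,
                         max_voxels_per_case = 1000, seed = seed + 2L)
message("pooled voxel matrix: ", nrow(vm$X), " voxels x 3 channels")
model <- select_k(vm, k_range = 2:10, seed = seed + 3L)
message("Calinski-Harabasz scores by K:")
print(round(model$ch_scores, 1))
message("selected K = ", model$K)

out <- "results/habitats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
write.csv(data.frame(K = as.integer(names(model$ch_scores)),
                     ch_score = as.numeric(model$ch_scores)),
          file.path(out, "ch_scores.csv"), row.names = FALSE)
jsonlite::write_json(
  list(K = model$K, centroids = model$centroids, scaler = model$scaler,
       ordering = model$ordering, ch_scores = as.list(model$ch_scores),
       seed = model$seed),
  file.path(out, "habitat_model.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

for (pid in names(cases)) {
  lm <- propagate_labels_knn(assign_labels(cases[[pid]], model),
                             cases[[pid]]$grid$spacing)
  write_volume(array(as.numeric(lm), dim(lm)), cases[[pid]]$grid,
               file.path(out, sprintf("%s_habitats.nii.gz", pid)))
}
message("label maps written to ", out)
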