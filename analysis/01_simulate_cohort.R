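#!/usr/bin/env Rscript
# Simulate the synthetic two-center NODDI tumor cohort (desk preset:
# 40 GB + 20 SBM across centers A and B, 48^3 1-mm grids, three planted
# habitat shells per tumor) and write the volumes + manifest.
#
# Downstream scripts (02..06) read results/cohort/. Pass a different
# --seed to regenerate a fresh cohort.

suppressMessages(library(habitatrad))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

out <- "results/cohort"
spec <- cohort_preset("desk")
spec$seed <- seed
message("simulating ", spec$n_gb, " GB + ", spec$n_sbm, " SBM cases...")
coh <- generate_cohort(spec, out_dir = out)
man <- split_cohort(coh$manifest, ratio = 0.7, seed = seed + 1L)
write.csv(man, file.path(out, "manifest.csv"), row.names = FALSE)

message("cohort written to ", out, ":")
print(table(man$diagnosis, man$split))
message("age (GB):  ", round(mean(man$age[man$diagnosis == "GB"]), 1), " +/- ",
        round(sd(man$age[man$diagnosis == "GB"]), 1))
message("age (SBM): ", round(mean(man$age[man$diagnosis == "SBM"]), 1), " +/- ",
        round(sd(man$age[man$diagnosis == "SBM"]), 1))
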