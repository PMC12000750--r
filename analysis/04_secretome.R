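#!/usr/bin/env Rscript
# Cytokine/chemokine secretome: sample clustering and analyte co-variation.
#
# Simulates the paired MFI and concentration datasets of the 48-sample
# multiplex design (2 sexes x 2 conditions x 2 compartment outlets x 2 days
# x 3 units), drops one emulated compromised sample, and runs the full
# pipeline: imputation, spiked-analyte exclusion, z-scoring, sample PCA
# with PC1/PC2 contributors, and correlation-distance complete-linkage
# clustering of analytes.

suppressPackageStartupMessages(library(osteochip))
seed <- 20260927L
out_dir <- "results/04_secretome"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

mfi <- generate_cytokine_table(mode = "MFI", seed = seed)
conc <- generate_cytokine_table(seed = seed + 1L)
write_cytokine_csv(mfi, file.path(out_dir, "mfi_table.csv"))
write_cytokine_csv(conc, file.path(out_dir, "concentration_table.csv"))

# one chondrocyte/control/day-7 sample lost to a technical issue
drop <- which(mfi$sample_meta$condition == "baseline" &
                mfi$sample_meta$compartment == "chondrocyte" &
                mfi$sample_meta$day == 7)[1]
mfi47 <- cytokine_table(mfi$values[-drop, ], mfi$sample_meta[-drop, ],
                        mode = "MFI")
conc47 <- cytokine_table(conc$values[-drop, ], conc$sample_meta[-drop, ])
message(sprintf("dropped sample %s; %d samples enter the pipeline",
                mfi$sample_meta$sample_id[drop], nrow(mfi47$values)))

res <- run_secretome_pipeline(mfi47, conc47, analysis_config())

scores <- data.frame(res$pca$scores[, 1:4], mfi47$sample_meta)
write.csv(scores, file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
write.csv(data.frame(analyte = rownames(res$pca$loadings),
                     res$pca$loadings[, 1:4]),
          file.path(out_dir, "pca_loadings.csv"), row.names = FALSE)
write.csv(res$contributions, file.path(out_dir, "pc12_contributions.csv"),
          row.names = FALSE)
write.csv(res$clusters$correlation,
          file.path(out_dir, "analyte_correlation.csv"))
write_cluster_newick(res$clusters, file.path(out_dir, "analyte_tree.nwk"))
writeLines(c(sprintf("samples: %d", nrow(res$pca$scores)),
             sprintf("excluded from PCA: %s",
                     paste(res$report$excluded_from_pca, collapse = ", ")),
             sprintf("removed (variance < %.1f): %s",
                     res$report$variance_threshold,
                     paste(res$report$removed_low_variance,
                           collapse = ", ")),
             res$report$note),
           file.path(out_dir, "report.txt"))
write_run_manifest(file.path(out_dir, "manifest.yml"), seed = seed)

message(sprintf("PC1 + PC2 explain %.1f%% of the variance",
                100 * sum(res$pca$explained[1:2])))
message("top PC1-2 contributors: ",
        paste(head(res$contributions$analyte, 3), collapse = ", "))
message("analyte leaf order: ",
        paste(res$clusters$order, collapse = ", "))
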