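#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study inputs.
#
# Emulates the three data modalities of the study design: confocal
# z-stacks of wild-type glomeruli (8 glomeruli, ~11 reporter-positive
# cells each), flow-cytometry event tables for wild-type and Alport
# glomerular digests (20,000 events each), and a 4-group x 3-replicate
# expression count matrix with planted differential, inverse and
# exclusive expression. Everything downstream reads these files.

suppressPackageStartupMessages(library(gecpop))

seed <- 20240101
data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

# imaging (wild type)
img <- gen_image_stack(sim_config("WT"), seed = stage_seed(seed, "imaging"))
for (g in seq_along(img$stacks))
  write_stack_tiff(img$stacks[[g]], NULL,
                   file.path(data_dir, sprintf("stack_g%02d.tif", g)))
write.table(img$rois, file.path(data_dir, "rois.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(img$truth, file.path(data_dir, "imaging_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(sprintf("pixel_size_um: %g\nz_step_um: %g",
                   img$pixel_size_um, img$z_step_um),
           file.path(data_dir, "stack_geometry.yaml"))

# cytometry (both genotypes)
for (preset in c("WT", "AS")) {
  sim <- gen_facs_events(sim_config(preset),
                         seed = stage_seed(seed, paste0("facs_", preset)))
  write.table(sim$events,
              file.path(data_dir, sprintf("facs_events_%s.tsv", preset)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth,
              file.path(data_dir, sprintf("facs_truth_%s.tsv", preset)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

# expression (4 sorted GEC groups x 3 replicates)
ex <- gen_expression(sim_config("WT"), seed = stage_seed(seed, "expression"))
write.table(data.frame(gene_id = rownames(ex$counts), ex$counts,
                       check.names = FALSE),
            file.path(data_dir, "counts.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(gene_id = names(ex$lengths), length_bp = ex$lengths),
            file.path(data_dir, "gene_lengths.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = names(ex$sample_groups),
                       group = unname(ex$sample_groups)),
            file.path(data_dir, "sample_groups.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ex$truth, file.path(data_dir, "expression_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "simulated: %d stacks (%d cells, %.0f%% dim in truth), 2 x %d events, %d x %d counts\n",
  length(img$stacks), nrow(img$truth), 100 * mean(img$truth$class == "dim"),
  sim_config("WT")$cytometry$n_events, nrow(ex$counts), ncol(ex$counts)))
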