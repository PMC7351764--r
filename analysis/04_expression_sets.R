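#!/usr/bin/env Rscript
# Stage 4 — subpopulation-resolved differential-expression set algebra.
#
# Runs the stand-in DE test on the four study contrasts
#   A: WT bright over dim        B: AS bright over dim
#   C: bright, AS over WT        D: dim, AS over WT
# then applies the published cutoff policy (p < 0.05, logCPM > 1,
# |log2FC| >= 1.5) to decompose the C/D pair into Venn regions, finds
# inversely regulated genes between A and B (p-only policy), and calls
# transcripts solely expressed in one wild-type subpopulation (RPKM >= 1
# in every replicate of one side, < 1 in every replicate of the other).

suppressPackageStartupMessages(library(gecpop))

data_dir <- "results/data"
out_dir <- "results/expression"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

counts_df <- read.delim(file.path(data_dir, "counts.tsv"),
                        check.names = FALSE)
counts <- as.matrix(counts_df[, -1])
rownames(counts) <- counts_df$gene_id
lengths_df <- read.delim(file.path(data_dir, "gene_lengths.tsv"))
lengths <- setNames(lengths_df$length_bp, lengths_df$gene_id)
grp_df <- read.delim(file.path(data_dir, "sample_groups.tsv"))
sample_groups <- setNames(grp_df$group, grp_df$sample_id)
truth <- read.delim(file.path(data_dir, "expression_truth.tsv"))

contrasts <- list(A = c("WT_bright", "WT_dim"), B = c("AS_bright", "AS_dim"),
                  C = c("AS_bright", "WT_bright"), D = c("AS_dim", "WT_dim"))
dge <- lapply(contrasts, function(ct) simple_de(counts, sample_groups, ct))
for (nm in names(dge))
  write.table(dge[[nm]], file.path(out_dir, sprintf("dge_%s.tsv", nm)),
              sep = "\t", quote = FALSE, row.names = FALSE)

pol <- cutoff_policy()
labels <- lapply(dge, apply_cutoffs, policy = pol)
for (nm in c("A", "B"))
  cat(sprintf("contrast %s: %d significant of %d genes (%.1f%%)\n", nm,
              sum(labels[[nm]] != "ns"), length(labels[[nm]]),
              100 * mean(labels[[nm]] != "ns")))

venn <- venn_decompose(labels$C, labels$D)
write.table(data.frame(region = names(venn$counts),
                       n = as.integer(venn$counts)),
            file.path(out_dir, "venn_C_vs_D.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Venn (C = bright AS/WT vs D = dim AS/WT):",
    paste(names(venn$counts), venn$counts, collapse = ", "), "\n")

inverse <- find_inverse_regulated(dge$A, dge$B)
write.table(inverse, file.path(out_dir, "inverse_regulated.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
planted_inv <- truth$gene_id[truth$status == "inverse"]
cat(sprintf("inversely regulated: %d found; %d/%d planted recovered\n",
            nrow(inverse), sum(planted_inv %in% inverse$gene_id),
            length(planted_inv)))

rpkm <- cpm_rpkm(counts, lengths)$rpkm
sole <- solely_expressed(rpkm, sample_groups, c("WT_dim", "WT_bright"))
write.table(data.frame(gene_id = c(sole$x_only, sole$y_only),
                       side = rep(c("dim_only", "bright_only"),
                                  c(length(sole$x_only), length(sole$y_only)))),
            file.path(out_dir, "solely_expressed.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("solely expressed (WT): %d dim-only, %d bright-only (planted %d/%d)\n",
            length(sole$x_only), length(sole$y_only),
            sum(truth$status == "dim_only"), sum(truth$status == "bright_only")))
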