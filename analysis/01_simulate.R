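#!/usr/bin/env Rscript
# Stage 1: simulate the study panel.
#
# A DGRP-like design: 40 inbred lines, both sexes, 3 replicates, 200
# metabolites with three planted correlation modules, 5,000 biallelic
# variants (MAF >= 0.1), 50 transcripts, and 4 organismal traits. A few
# strong mQTLs/eQTLs and one sparse metabolite-driven trait give the later
# stages known ground truth. All downstream stages read only the TSVs
# written here.

suppressPackageStartupMessages(library(metaboqg))

panel_dir <- "results/panel"
dir.create(panel_dir, recursive = TRUE, showWarnings = FALSE)
write_tsv <- function(d, name)
  write.table(d, file.path(panel_dir, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
write_mat <- function(m, name)
  write_tsv(data.frame(line = rownames(m), m, check.names = FALSE), name)

cfg <- sim_config(
  n_lines = 40, n_variants = 5000, maf_min = 0.1,
  n_metabolites = 200,
  module_spec = data.frame(size = c(30, 20, 10), rho = c(0.7, 0.6, 0.5)),
  h2_target = 0.43, n_reps = 3, n_genes = 50, n_traits = 4,
  mqtl_spec = data.frame(variant = c(1, 2, 3, 4),
                         metabolite = c(101, 102, 150, 151),
                         effect = c(2.5, 2.5, 2.5, 2.5)),
  eqtl_spec = data.frame(variant = c(1, 3), gene = c(1, 2),
                         effect = c(2.5, 2.5)),
  trait_spec = list(
    list(metabolites = c(101, 102), weights = c(1, 1), h2 = 0.6),
    list(metabolites = c(150, 151), weights = c(1, -1), h2 = 0.6),
    list(metabolites = 1:30, weights = rep(1, 30), h2 = 0.5),
    list(metabolites = c(5, 60, 120), weights = c(2, -1, 1), h2 = 0.4)),
  seed = 20240101)

panel <- simulate_panel(cfg)

write_genotypes_tsv(panel$genotypes, file.path(panel_dir, "genotypes.tsv"))
write_tsv(panel$metabolome, "metabolome.tsv")
write_tsv(panel$annotation, "annotation.tsv")
write_tsv(panel$gene_model, "gene_model.tsv")
for (sx in c("F", "M")) {
  write_mat(panel$transcripts[[sx]], paste0("transcripts_", sx, ".tsv"))
  write_mat(panel$traits[[sx]], paste0("traits_", sx, ".tsv"))
}

cat("panel written to", panel_dir, "\n")
cat(sprintf("lines: %d  variants: %d  metabolites: %d  genes: %d  traits: %d\n",
            nrow(panel$genotypes), ncol(panel$genotypes),
            length(unique(panel$metabolome$analyte)),
            ncol(panel$transcripts$F), ncol(panel$traits$F)))
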