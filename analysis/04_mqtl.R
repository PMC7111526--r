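#!/usr/bin/env Rscript
# Stage 4: mQTL mapping.
#
# Per sex: metabolite line means and module PC scores are regressed on every
# variant whose minor genotype class covers at least 4 lines; hits at the
# Bonferroni-corrected genome-wide threshold are annotated against the gene
# model (intergenic hits merged within 2 kb) and summarized for pleiotropy.

suppressPackageStartupMessages(library(metaboqg))

G <- read_genotypes("results/panel/genotypes.tsv")
met <- read_replicate_table("results/panel/metabolome.tsv")
gene_model <- read.delim("results/panel/gene_model.tsv")

kept <- filter_variants(G, min_minor_lines = 4)
cat(sprintf("variants kept: %d / %d\n", length(kept), ncol(G)))

for (sx in c("F", "M")) {
  lm_mat <- line_means(met, sx)
  n_tests <- length(kept) * ncol(lm_mat)
  thr <- bonferroni_threshold(n_tests, 0.05)
  cat(sprintf("%s: %d tests, genome-wide threshold %.3g\n", sx, n_tests, thr))

  hits <- map_associations_all(lm_mat, G, kept, threshold = thr)
  hits <- annotate_hits(hits, gene_model, merge_dist = 2000)
  write.table(hits, file.path("results", paste0("mqtl_hits_", sx, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  pl <- pleiotropy_summary(hits)
  cat(sprintf("  %d hits; %.1f%% of variants single-metabolite\n",
              nrow(hits), pl$pct_single))

  pcs <- read_line_matrix(file.path("results", paste0("module_pcs_", sx, ".tsv")))
  pc_thr <- bonferroni_threshold(length(kept) * ncol(pcs), 0.05)
  pc_hits <- map_associations_all(pcs, G, kept, threshold = pc_thr)
  write.table(pc_hits, file.path("results", paste0("mqtl_pc_hits_", sx, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("  module-PC hits: %d\n", nrow(pc_hits)))
}
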