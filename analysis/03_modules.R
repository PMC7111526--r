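#!/usr/bin/env Rscript
# Stage 3: metabolite modules and module principal components.
#
# Per sex: Pearson correlations of line means over the genetically variable
# metabolites, modularity-maximizing clustering on sigmoid-weighted |r|, and
# per-module PCA with the >4% / cumulative >90% retention rule.

suppressPackageStartupMessages(library(metaboqg))

met <- read_replicate_table("results/panel/metabolome.tsv")

for (sx in c("F", "M")) {
  vt <- read.delim(file.path("results", paste0("varcomp_", sx, ".tsv")))
  variable <- vt$analyte[vt$variable %in% TRUE]
  lm_mat <- line_means(met, sx)[, variable, drop = FALSE]

  part <- cluster_modules(metabolite_correlations(lm_mat))
  ptab <- data.frame(analyte = names(part$assignment),
                     module = unname(part$assignment))
  write.table(ptab, file.path("results", paste0("modules_", sx, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  mpcs <- module_pca(lm_mat, part)
  pcs <- pc_score_matrix(mpcs)
  write.table(data.frame(line = rownames(pcs), pcs, check.names = FALSE),
              file.path("results", paste0("module_pcs_", sx, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cat(sprintf("%s: %d variable metabolites, %d modules, %d retained PCs\n",
              sx, length(variable), nrow(part$modules), ncol(pcs)))
  print(part$modules)
}
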