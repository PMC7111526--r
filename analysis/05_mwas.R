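#!/usr/bin/env Rscript
# Stage 5: metabolome-wide association of organismal traits.
#
# Per sex: Spearman screen of each trait against metabolite line means and
# module PCs at nominal P < 0.05, super-pathway composition of the
# significant metabolites, and clustering of traits on their signed
# correlation profiles (Newick dendrogram).

suppressPackageStartupMessages(library(metaboqg))

met <- read_replicate_table("results/panel/metabolome.tsv")
annotation <- read.delim("results/panel/annotation.tsv")

for (sx in c("F", "M")) {
  traits <- read_line_matrix(file.path("results/panel",
                                       paste0("traits_", sx, ".tsv")))
  lm_mat <- line_means(met, sx)
  pcs <- read_line_matrix(file.path("results", paste0("module_pcs_", sx, ".tsv")))

  scr_met <- spearman_screen(traits, lm_mat)
  scr_pc <- spearman_screen(traits, pcs)
  scr <- rbind(scr_met, scr_pc)
  write.table(scr, file.path("results", paste0("mwas_", sx, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d significant trait-feature pairs of %d\n",
              sx, sum(scr$significant), nrow(scr)))

  spt <- superpathway_table(scr_met, annotation)
  write.table(as.data.frame(spt),
              file.path("results", paste0("superpathways_", sx, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cl <- tryCatch(suppressWarnings(cluster_traits(scr, k = 2)),
                 error = function(e) NULL)
  if (!is.null(cl)) {
    writeLines(cl$newick,
               file.path("results", paste0("trait_dendrogram_", sx, ".nwk")))
    print(cl$clusters)
  }
}
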