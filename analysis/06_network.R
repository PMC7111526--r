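#!/usr/bin/env Rscript
# Stage 6: integrated variant-transcript-metabolite-trait networks.
#
# Per trait and sex: trait-associated metabolites (nominal P < 0.05) are
# linked to transcripts at |Spearman rho| > 0.45; each metabolite's mQTLs are
# tested against the linked transcripts at the metabolite-specific Bonferroni
# threshold (meQTLs, labeled cis/trans with a 1-kb window); the typed graph
# is written as GraphML plus a flat edge list.

suppressPackageStartupMessages(library(metaboqg))

G <- read_genotypes("results/panel/genotypes.tsv")
met <- read_replicate_table("results/panel/metabolome.tsv")
annotation <- read.delim("results/panel/annotation.tsv")
gene_model <- read.delim("results/panel/gene_model.tsv")

for (sx in c("F", "M")) {
  lm_mat <- line_means(met, sx)
  expr <- read_line_matrix(file.path("results/panel",
                                     paste0("transcripts_", sx, ".tsv")))
  traits <- read_line_matrix(file.path("results/panel",
                                       paste0("traits_", sx, ".tsv")))
  mqtl_hits <- read.delim(file.path("results", paste0("mqtl_hits_", sx, ".tsv")))
  scr <- read.delim(file.path("results", paste0("mwas_", sx, ".tsv")))

  for (tr in colnames(traits)) {
    mets <- select_trait_metabolites(scr, tr)
    links <- suppressMessages(link_transcripts(mets, lm_mat, expr, r_min = 0.45))
    meq <- find_meqtls(mqtl_hits, links, expr, G)
    meq <- classify_cis_trans(meq, gene_model)
    g <- assemble_network(mets, links, meq, annotation = annotation,
                          trait = tr, sex = sx)
    key <- paste0(tr, "_", sx)
    if (igraph::vcount(g) > 0) {
      write_network_graphml(g, file.path("results",
                                         paste0("network_", key, ".graphml")))
      write.table(network_edges(g),
                  file.path("results", paste0("network_edges_", key, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    cat(sprintf("%s: %d metabolites, %d links, %d meQTLs (%s)\n",
                key, length(mets), nrow(links), nrow(meq),
                if (nrow(meq)) paste(table(meq$cis_trans), collapse = "/")
                else "-"))
  }
}
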