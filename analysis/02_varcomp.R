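#!/usr/bin/env Rscript
# Stage 2: variance components and broad-sense heritability.
#
# Per metabolite: the full mixed model (sexes pooled; line and line-by-sex
# random, sex fixed) and the within-sex reduced models, REML fits with
# boundary-corrected likelihood-ratio tests and BH-adjusted line-term
# q-values. H2 = (sigma2_L + sigma2_LxS) / total.

suppressPackageStartupMessages(library(metaboqg))

met <- read_replicate_table("results/panel/metabolome.tsv")
dir.create("results", showWarnings = FALSE)

for (scope in c("full", "F", "M")) {
  vt <- varcomp_table(met, scope)
  write.table(vt, file.path("results", paste0("varcomp_", scope, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf(
    "%-4s  mean H2 = %.3f   genetically variable (q < 0.05): %d / %d\n",
    scope, mean(vt$H2), sum(vt$variable, na.rm = TRUE), nrow(vt)))
}
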