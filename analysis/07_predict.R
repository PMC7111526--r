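#!/usr/bin/env Rscript
# Stage 7: metabolome-based trait prediction.
#
# For the sparse metabolite-driven traits (trait_01, trait_02), per sex:
# leave-one-out kernel BLUP on all metabolite line means, the combined
# MWAS-BLUP (fold-internal selection at P < x for x in 0.5 ... 0.05), and an
# elastic net over an (alpha, lambda) grid. Accuracy is the Pearson
# correlation of predicted and observed line values.

suppressPackageStartupMessages(library(metaboqg))

met <- read_replicate_table("results/panel/metabolome.tsv")
set.seed(1)

rows <- list()
for (sx in c("F", "M")) {
  lm_mat <- line_means(met, sx)
  traits <- read_line_matrix(file.path("results/panel",
                                       paste0("traits_", sx, ".tsv")))
  for (tr in c("trait_01", "trait_02")) {
    y <- setNames(traits[, tr], rownames(traits))
    blup <- loocv_blup(y, lm_mat, model = "blup all metabolites")
    enr <- suppressMessages(mwas_enriched_loocv(y, lm_mat))
    enet <- elastic_net_loocv(y, lm_mat, alpha_grid = c(0.1, 0.5, 1),
                              nlambda = 30)
    accs <- c(blup_all = blup$accuracy,
              setNames(vapply(enr, `[[`, 0, "accuracy"),
                       paste0("mwas_blup_", names(enr))),
              enet = enet$accuracy)
    rows[[paste(tr, sx)]] <- data.frame(trait = tr, sex = sx,
                                        model = names(accs),
                                        accuracy = unname(accs))
    cat(sprintf("%s %s: blup %.3f | best enriched %.3f | enet %.3f (a=%g)\n",
                tr, sx, blup$accuracy,
                max(vapply(enr, `[[`, 0, "accuracy")), enet$accuracy,
                enet$alpha))
  }
}

ptab <- do.call(rbind, rows)
rownames(ptab) <- NULL
write.table(ptab, "results/prediction_accuracy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/prediction_accuracy.tsv\n")
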