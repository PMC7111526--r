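# File formats and the end-to-end pipeline ----------------------------------
#
# Tidy TSV is the canonical interchange format; VCF is read at the boundary
# (inbred lines: homozygous GT collapsed to 0/1), GraphML and Newick are
# written at the boundary. All writes are atomic (temp file + rename) and a
# JSON manifest records every output with its checksum.

#' Read a genotype matrix from TSV or minimal VCF
#'
#' TSV: lines x variants, first column the line id, header of variant ids.
#' VCF: biallelic records only (others skipped with a warning); GT `0/0` or
#' `0|0` maps to 0, `1/1`/`1|1` to 1, and heterozygous or half-missing calls
#' to NA (count reported).
#'
#' @param path input file.
#' @param format "auto" (by extension), "tsv", or "vcf".
#' @return line-by-variant matrix with entries in `{0, 1, NA}`.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    d <- read.delim(path, check.names = FALSE)
    G <- as.matrix(d[, -1, drop = FALSE])
    rownames(G) <- d[[1]]
    storage.mode(G) <- "integer"
    if (!all(G[!is.na(G)] %in% c(0L, 1L)))
      stop("genotype TSV entries must be 0, 1 or NA")
    return(G)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  multi <- grepl(",", fx[, "ALT"])
  if (any(multi)) {
    warning(sum(multi), " multi-allelic records skipped")
    v <- v[!multi, ]
    fx <- fx[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v)
  num <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  num[gt %in% c("0/0", "0|0", "0")] <- 0L
  num[gt %in% c("1/1", "1|1", "1")] <- 1L
  n_bad <- sum(!is.na(gt) & is.na(num))
  if (n_bad > 0)
    warning(n_bad, " heterozygous or half-missing calls set to NA")
  ids <- paste0(fx[, "CHROM"], "_", fx[, "POS"], "_", fx[, "REF"], "/",
                fx[, "ALT"])
  G <- t(num)
  colnames(G) <- ids
  G
}

#' Write a genotype matrix as TSV
#'
#' @param genotypes line-by-variant matrix.
#' @param path output file.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  d <- data.frame(line = rownames(genotypes), genotypes, check.names = FALSE)
  write_tsv_atomic(d, path)
}

#' Read a replicate-level metabolite table
#'
#' @param path TSV with columns line, sex, replicate, analyte, abundance.
#' @return validated data frame.
#' @export
read_replicate_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("line", "sex", "replicate", "analyte", "abundance")
  if (!all(need %in% names(d)))
    stop("replicate table must have columns: ", paste(need, collapse = ", "))
  key <- paste(d$line, d$sex, d$replicate, d$analyte)
  if (anyDuplicated(key)) stop("(line, sex, replicate, analyte) not unique")
  d
}

#' Read a line-by-column matrix from TSV (line ids in the first column)
#'
#' @param path TSV file.
#' @return numeric matrix.
#' @export
read_line_matrix <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

write_line_matrix <- function(m, path) {
  write_tsv_atomic(data.frame(line = rownames(m), m, check.names = FALSE), path)
}

#' Pipeline configuration
#'
#' Thresholds default to the analysis constants: FDR 0.05 for genetic
#' variability, nominal 0.05 for trait screens, |rho| > 0.45 for transcript
#' links, minor-class minimum of 4 lines, 2000-bp intergenic merge, module-PC
#' retention at 4% / 90%, and enrichment thresholds 0.5 ... 0.05.
#'
#' @param simulate a [sim_config()] to generate the panel (or NULL to read
#'   inputs from `paths`).
#' @param paths named list of input files (genotypes, metabolome,
#'   annotation, transcripts_F/M, traits_F/M, gene_model) used when
#'   `simulate` is NULL.
#' @param out_dir output directory.
#' @param fdr,alpha,r_min,min_minor_lines,merge_dist,pc_min_frac,pc_cum_target,enrichment_thresholds
#'   analysis thresholds.
#' @param prediction_traits trait ids to run LOOCV prediction on (NULL: the
#'   first trait).
#' @param seed integer seed for any stochastic step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL, out_dir = "results",
                            fdr = 0.05, alpha = 0.05, r_min = 0.45,
                            min_minor_lines = 4, merge_dist = 2000,
                            pc_min_frac = 0.04, pc_cum_target = 0.90,
                            enrichment_thresholds = c(0.5, 0.4, 0.3, 0.2, 0.1, 0.05),
                            prediction_traits = NULL, seed = 1L) {
  stopifnot(fdr > 0, fdr < 1, alpha > 0, alpha < 1, r_min >= 0, r_min < 1,
            min_minor_lines >= 1, merge_dist >= 0,
            pc_min_frac >= 0, pc_min_frac < 1,
            pc_cum_target > 0, pc_cum_target <= 1,
            all(enrichment_thresholds > 0 & enrichment_thresholds <= 1))
  if (is.null(simulate) && is.null(paths))
    stop("either a simulation config or input paths must be given")
  if (!is.null(paths)) {
    missing <- !vapply(paths, file.exists, TRUE)
    if (any(missing))
      stop("input path does not exist: ",
           paste(names(paths)[missing], collapse = ", "))
  }
  structure(list(simulate = simulate, paths = paths, out_dir = out_dir,
                 fdr = fdr, alpha = alpha, r_min = r_min,
                 min_minor_lines = min_minor_lines, merge_dist = merge_dist,
                 pc_min_frac = pc_min_frac, pc_cum_target = pc_cum_target,
                 enrichment_thresholds = enrichment_thresholds,
                 prediction_traits = prediction_traits,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments
#'   (`simulate` is passed to [sim_config()]).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    if (!is.null(y$simulate$module_spec))
      y$simulate$module_spec <- as.data.frame(do.call(rbind, lapply(
        y$simulate$module_spec, as.data.frame)))
    y$simulate <- do.call(sim_config, y$simulate)
  }
  do.call(pipeline_config, y)
}

stage_log <- function(log, stage, t0) {
  elapsed <- round(as.numeric(proc.time()[3] - t0), 3)
  message(sprintf("[%s] done in %.2fs", stage, elapsed))
  c(log, setNames(elapsed, stage))
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) the panel, then: variance components and H2 per sex ->
#' module detection and module PCs on the genetically variable metabolites ->
#' mQTL mapping of metabolites and module PCs -> trait screens (MWAS),
#' super-pathway tables and trait clustering -> integrated networks per trait
#' -> LOOCV prediction (kernel BLUP, enriched MWAS-BLUP, elastic net) for the
#' configured traits. Every output file is recorded with an md5 checksum in
#' `manifest.json`.
#'
#' @param cfg a [pipeline_config()].
#' @return manifest (invisibly): list of outputs, checksums, stage timings.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  timings <- numeric(0)
  files <- character(0)
  add <- function(path) files <<- c(files, path)
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    timings <<- stage_log(timings, stage, t0)
    r
  }

  panel <- run_stage("input", {
    if (!is.null(cfg$simulate)) {
      p <- simulate_panel(cfg$simulate)
      add(write_genotypes_tsv(p$genotypes, file.path(out, "genotypes.tsv")))
      add(write_tsv_atomic(p$metabolome, file.path(out, "metabolome.tsv")))
      add(write_tsv_atomic(p$annotation, file.path(out, "annotation.tsv")))
      add(write_tsv_atomic(p$gene_model, file.path(out, "gene_model.tsv")))
      p
    } else {
      pa <- cfg$paths
      list(genotypes = read_genotypes(pa$genotypes),
           metabolome = read_replicate_table(pa$metabolome),
           annotation = read.delim(pa$annotation, stringsAsFactors = FALSE),
           gene_model = read.delim(pa$gene_model, stringsAsFactors = FALSE),
           transcripts = list(F = read_line_matrix(pa$transcripts_F),
                              M = read_line_matrix(pa$transcripts_M)),
           traits = list(F = read_line_matrix(pa$traits_F),
                         M = read_line_matrix(pa$traits_M)))
    }
  })

  vc <- run_stage("varcomp", {
    v <- list(full = varcomp_table(panel$metabolome, "full"),
              F = varcomp_table(panel$metabolome, "F"),
              M = varcomp_table(panel$metabolome, "M"))
    for (sc in names(v))
      add(write_tsv_atomic(v[[sc]], file.path(out, paste0("varcomp_", sc, ".tsv"))))
    v
  })

  lm_by_sex <- list(F = line_means(panel$metabolome, "F"),
                    M = line_means(panel$metabolome, "M"))

  mods <- run_stage("modules", {
    res <- lapply(c(F = "F", M = "M"), function(sx) {
      variable <- vc[[sx]]$analyte[vc[[sx]]$variable %in% TRUE]
      if (length(variable) < 2) variable <- colnames(lm_by_sex[[sx]])
      R <- metabolite_correlations(lm_by_sex[[sx]][, variable, drop = FALSE])
      part <- cluster_modules(R)
      mpcs <- module_pca(lm_by_sex[[sx]][, variable, drop = FALSE], part,
                         cfg$pc_min_frac, cfg$pc_cum_target)
      ptab <- data.frame(analyte = names(part$assignment),
                         module = unname(part$assignment))
      ptab$module_mean_abs_r <-
        part$modules$mean_abs_r[match(ptab$module, part$modules$module)]
      add(write_tsv_atomic(ptab, file.path(out, paste0("modules_", sx, ".tsv"))))
      pcs <- pc_score_matrix(mpcs)
      add(write_line_matrix(pcs, file.path(out, paste0("module_pcs_", sx, ".tsv"))))
      list(partition = part, mpcs = mpcs, pcs = pcs)
    })
    res
  })

  kept <- filter_variants(panel$genotypes, cfg$min_minor_lines)
  n_tests <- length(kept)
  gw_thr <- bonferroni_threshold(n_tests * 1, cfg$alpha)

  mqtl <- run_stage("mqtl", {
    res <- lapply(c(F = "F", M = "M"), function(sx) {
      hits <- map_associations_all(lm_by_sex[[sx]], panel$genotypes, kept)
      sig <- hits[hits$p <= gw_thr, , drop = FALSE]
      sig <- annotate_hits(sig, panel$gene_model, cfg$merge_dist)
      add(write_tsv_atomic(sig, file.path(out, paste0("mqtl_hits_", sx, ".tsv"))))
      pc_hits <- map_associations_all(mods[[sx]]$pcs, panel$genotypes, kept)
      pc_sig <- pc_hits[pc_hits$p <= gw_thr, , drop = FALSE]
      add(write_tsv_atomic(pc_sig, file.path(out, paste0("mqtl_pc_hits_", sx, ".tsv"))))
      list(hits = hits, sig = sig, pc_sig = pc_sig)
    })
    res
  })

  mwas <- run_stage("mwas", {
    res <- lapply(c(F = "F", M = "M"), function(sx) {
      scr_met <- spearman_screen(panel$traits[[sx]], lm_by_sex[[sx]],
                                 alpha = cfg$alpha)
      scr_pc <- spearman_screen(panel$traits[[sx]], mods[[sx]]$pcs,
                                alpha = cfg$alpha)
      add(write_tsv_atomic(rbind(scr_met, scr_pc),
                           file.path(out, paste0("mwas_", sx, ".tsv"))))
      spt <- superpathway_table(scr_met, panel$annotation)
      add(write_tsv_atomic(as.data.frame(spt),
                           file.path(out, paste0("superpathways_", sx, ".tsv"))))
      cl <- tryCatch(
        suppressWarnings(cluster_traits(rbind(scr_met, scr_pc), k = 2)),
        error = function(e) NULL)
      if (!is.null(cl) && !is.null(cl$newick))
        add(write_text_atomic(cl$newick,
                              file.path(out, paste0("trait_dendrogram_", sx, ".nwk"))))
      list(met = scr_met, pc = scr_pc, clusters = cl)
    })
    res
  })

  nets <- run_stage("network", {
    res <- list()
    for (sx in c("F", "M")) for (tr in colnames(panel$traits[[sx]])) {
      mets <- select_trait_metabolites(mwas[[sx]]$met, tr, cfg$alpha)
      links <- suppressMessages(link_transcripts(
        mets, lm_by_sex[[sx]], panel$transcripts[[sx]], cfg$r_min))
      meq <- find_meqtls(mqtl[[sx]]$sig, links, panel$transcripts[[sx]],
                         panel$genotypes, cfg$alpha)
      meq <- classify_cis_trans(meq, panel$gene_model)
      yv <- setNames(panel$traits[[sx]][, tr],
                     rownames(panel$traits[[sx]]))
      ta <- NULL
      cand <- unique(c(meq$variant, links$gene))
      if (length(cand) > 0) {
        va <- suppressMessages(suppressWarnings(
          map_associations(yv, panel$genotypes,
                           intersect(cand, colnames(panel$genotypes)))))
        ga <- suppressMessages(spearman_screen(
          matrix(yv, dimnames = list(names(yv), tr), ncol = 1),
          panel$transcripts[[sx]][, intersect(cand, colnames(panel$transcripts[[sx]])),
                                  drop = FALSE]))
        ta <- rbind(data.frame(node = va$variant, p = va$p),
                    data.frame(node = ga$feature, p = ga$p))
      }
      g <- assemble_network(mets, links, meq, ta, panel$annotation,
                            trait = tr, sex = sx, alpha = cfg$alpha)
      key <- paste0(tr, "_", sx)
      if (igraph::vcount(g) > 0) {
        add(write_network_graphml(g, file.path(out, paste0("network_", key, ".graphml"))))
        add(write_tsv_atomic(network_edges(g),
                             file.path(out, paste0("network_edges_", key, ".tsv"))))
      }
      res[[key]] <- g
    }
    res
  })

  pred <- run_stage("prediction", {
    set.seed(cfg$seed)
    traits_to_run <- cfg$prediction_traits %||%
      colnames(panel$traits$F)[1]
    rows <- list()
    for (tr in traits_to_run) for (sx in c("F", "M")) {
      y <- setNames(panel$traits[[sx]][, tr], rownames(panel$traits[[sx]]))
      met <- lm_by_sex[[sx]]
      r_all <- loocv_blup(y, met, model = "blup metabolites")
      r_enr <- suppressMessages(
        mwas_enriched_loocv(y, met, cfg$enrichment_thresholds))
      r_enet <- elastic_net_loocv(y, met,
                                  alpha_grid = c(0.1, 0.5, 1), nlambda = 20)
      accs <- c(setNames(r_all$accuracy, "blup_all"),
                setNames(vapply(r_enr, `[[`, 0, "accuracy"),
                         paste0("mwas_blup_", names(r_enr))),
                setNames(r_enet$accuracy, "enet"))
      rows[[paste(tr, sx)]] <- data.frame(trait = tr, sex = sx,
                                          model = names(accs),
                                          accuracy = unname(accs))
    }
    ptab <- do.call(rbind, rows); rownames(ptab) <- NULL
    add(write_tsv_atomic(ptab, file.path(out, "prediction_accuracy.tsv")))
    ptab
  })

  manifest <- list(
    seed = cfg$seed,
    outputs = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE),
    timings = as.list(timings))
  mpath <- file.path(out, "manifest.json")
  tmp <- tempfile(tmpdir = out, fileext = ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  file.rename(tmp, mpath)
  invisible(manifest)
}
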