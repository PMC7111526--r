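# Integrated variant-transcript-metabolite-trait networks -------------------
#
# For one trait and sex: metabolites correlated with the trait (nominal
# P < 0.05) are linked to transcripts at |Spearman rho| > 0.45; each
# metabolite's mQTLs are then tested against its linked transcripts and kept
# at the metabolite-specific Bonferroni threshold 0.05 / (that metabolite's
# mQTL count), giving meQTLs. Nodes are flagged when directly associated with
# the focal trait at nominal P < 0.05.

#' Metabolites correlated with a trait
#'
#' @param screen output of [spearman_screen()] of the trait(s) against
#'   metabolite line means.
#' @param trait trait id.
#' @param alpha nominal threshold.
#' @return character vector of metabolite ids.
#' @export
select_trait_metabolites <- function(screen, trait, alpha = 0.05) {
  sub <- screen[screen$trait == trait & screen$p < alpha, , drop = FALSE]
  sort(unique(sub$feature))
}

#' Transcript-metabolite links above an absolute Spearman threshold
#'
#' @param metabolites metabolite ids to link.
#' @param met_lm line-by-metabolite matrix.
#' @param transcript_lm line-by-gene matrix (lines matched by name; pairs
#'   with fewer than `min_pairs` complete lines are skipped with a message).
#' @param r_min absolute Spearman rho threshold (kept iff `|rho| > r_min`).
#' @param min_pairs minimum complete pairs.
#' @return data frame (gene, metabolite, rho).
#' @export
link_transcripts <- function(metabolites, met_lm, transcript_lm,
                             r_min = 0.45, min_pairs = 5) {
  common <- intersect(rownames(met_lm), rownames(transcript_lm))
  met_lm <- met_lm[common, intersect(metabolites, colnames(met_lm)), drop = FALSE]
  transcript_lm <- transcript_lm[common, , drop = FALSE]
  out <- list(); skipped <- 0L
  for (m in colnames(met_lm)) for (g in colnames(transcript_lm)) {
    x <- met_lm[, m]; y <- transcript_lm[, g]
    use <- !is.na(x) & !is.na(y)
    if (sum(use) < min_pairs || var(x[use]) == 0 || var(y[use]) == 0) {
      skipped <- skipped + 1L; next
    }
    rho <- spearman_rho(x[use], y[use])
    if (abs(rho) > r_min)
      out[[length(out) + 1]] <- data.frame(gene = g, metabolite = m, rho = rho,
                                           stringsAsFactors = FALSE)
  }
  if (skipped > 0) message(skipped, " gene-metabolite pairs skipped")
  if (length(out) == 0)
    return(data.frame(gene = character(), metabolite = character(),
                      rho = numeric()))
  res <- do.call(rbind, out)
  stopifnot(all(abs(res$rho) > r_min))
  res[order(res$gene, res$metabolite), , drop = FALSE]
}

#' meQTLs: mQTLs also associated with linked transcripts
#'
#' For each metabolite, each of its mQTLs is tested against each linked
#' gene's expression with the same OLS used for mQTL mapping, and kept when
#' P < 0.05 / (the metabolite's mQTL count). Metabolites without mQTLs are
#' skipped.
#'
#' @param mqtl_hits association data frame of significant mQTLs (variant,
#'   phenotype = metabolite).
#' @param links output of [link_transcripts()].
#' @param transcript_lm line-by-gene matrix.
#' @param genotypes line-by-variant matrix.
#' @param alpha numerator of the metabolite-specific Bonferroni rule.
#' @param min_class minimum lines per genotype class.
#' @return data frame (variant, gene, metabolite, effect, p, threshold).
#' @export
find_meqtls <- function(mqtl_hits, links, transcript_lm, genotypes,
                        alpha = 0.05, min_class = 4) {
  out <- list()
  for (m in unique(links$metabolite)) {
    vq <- unique(mqtl_hits$variant[mqtl_hits$phenotype == m])
    if (length(vq) == 0) next
    thr <- alpha / length(vq)
    genes <- links$gene[links$metabolite == m]
    for (g in genes) {
      y <- setNames(transcript_lm[, g], rownames(transcript_lm))
      assoc <- suppressMessages(
        map_associations(y, genotypes, variants = vq, min_class = min_class,
                         phenotype = g))
      hit <- assoc[assoc$p < thr, , drop = FALSE]
      if (nrow(hit) > 0)
        out[[length(out) + 1]] <- data.frame(
          variant = hit$variant, gene = g, metabolite = m,
          effect = hit$effect, p = hit$p, threshold = thr,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(variant = character(), gene = character(),
                      metabolite = character(), effect = numeric(),
                      p = numeric(), threshold = numeric()))
  res <- unique(do.call(rbind, out))
  stopifnot(all(res$p < res$threshold))
  res[order(res$variant, res$gene, res$metabolite), , drop = FALSE]
}

#' Assemble the integrated network for one trait and sex
#'
#' Typed nodes (metabolite with super pathway, gene, variant) and typed,
#' signed edges: gene-metabolite correlation edges weighted by rho,
#' variant-gene and variant-metabolite association edges. Nodes are flagged
#' when their direct trait-association P is below `alpha`. Isolated nodes are
#' removed and nodes/edges are ordered deterministically.
#'
#' @param metabolites selected metabolite ids (all flagged trait-associated).
#' @param links output of [link_transcripts()].
#' @param meqtls output of [find_meqtls()].
#' @param trait_assoc optional data frame (node, p) of direct trait
#'   associations for genes and variants.
#' @param annotation metabolite annotation (analyte, super_pathway).
#' @param trait,sex graph attributes.
#' @param alpha nominal trait-association threshold for node flags.
#' @return an igraph graph.
#' @export
assemble_network <- function(metabolites, links, meqtls, trait_assoc = NULL,
                             annotation = NULL, trait = NA, sex = NA,
                             alpha = 0.05) {
  # keep meQTL-supported variant edges; variant-metabolite edges follow the
  # meQTL variants' mQTL association with the metabolite
  edges <- list()
  if (nrow(links) > 0)
    edges$corr <- data.frame(from = links$gene, to = links$metabolite,
                             type = "correlation",
                             sign = ifelse(links$rho > 0, "positive", "negative"),
                             weight = links$rho, p = NA_real_,
                             stringsAsFactors = FALSE)
  if (nrow(meqtls) > 0) {
    edges$vg <- data.frame(from = meqtls$variant, to = meqtls$gene,
                           type = "variant_gene", sign = NA_character_,
                           weight = meqtls$effect, p = meqtls$p,
                           stringsAsFactors = FALSE)
    edges$vm <- data.frame(from = meqtls$variant, to = meqtls$metabolite,
                           type = "variant_metabolite", sign = NA_character_,
                           weight = NA_real_, p = NA_real_,
                           stringsAsFactors = FALSE)
  }
  edf <- if (length(edges) > 0) unique(do.call(rbind, edges)) else
    data.frame(from = character(), to = character(), type = character(),
               sign = character(), weight = numeric(), p = numeric())
  nodes <- data.frame(name = metabolites, type = "metabolite",
                      stringsAsFactors = FALSE)
  if (nrow(edf) > 0) {
    others <- setdiff(unique(c(edf$from, edf$to)), metabolites)
    gene_nodes <- intersect(others, unique(links$gene))
    var_nodes <- setdiff(others, gene_nodes)
    nodes <- rbind(nodes,
                   data.frame(name = gene_nodes,
                              type = rep("gene", length(gene_nodes))),
                   data.frame(name = var_nodes,
                              type = rep("variant", length(var_nodes))))
  }
  nodes <- nodes[order(nodes$type, nodes$name), , drop = FALSE]
  nodes$super_pathway <- NA_character_
  if (!is.null(annotation)) {
    i <- match(nodes$name, annotation$analyte)
    nodes$super_pathway <- annotation$super_pathway[i]
  }
  nodes$trait_flag <- nodes$type == "metabolite"   # selected by P < alpha
  if (!is.null(trait_assoc) && nrow(trait_assoc) > 0) {
    i <- match(nodes$name, trait_assoc$node)
    extra <- !is.na(i) & trait_assoc$p[i] < alpha
    nodes$trait_flag <- nodes$trait_flag | extra
  }
  edf <- edf[order(edf$type, edf$from, edf$to), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = nodes)
  iso <- which(igraph::degree(g) == 0)
  if (length(iso) > 0) g <- igraph::delete_vertices(g, iso)
  g <- igraph::set_graph_attr(g, "trait", as.character(trait))
  g <- igraph::set_graph_attr(g, "sex", as.character(sex))
  g
}

#' Label meQTLs as cis or trans to their linked gene
#'
#' cis iff the variant lies within the gene body extended by `window` bp on
#' both sides (same chromosome); genes missing from the model are labeled
#' "unknown".
#'
#' @param meqtls output of [find_meqtls()].
#' @param gene_model data frame with chrom, start, end, gene_id.
#' @param window bp extension around the gene body.
#' @return `meqtls` with a `cis_trans` column.
#' @export
classify_cis_trans <- function(meqtls, gene_model, window = 1000) {
  if (nrow(meqtls) == 0) { meqtls$cis_trans <- character(); return(meqtls) }
  loc <- parse_variant_id(meqtls$variant)
  i <- match(meqtls$gene, gene_model$gene_id)
  lab <- rep("unknown", nrow(meqtls))
  known <- !is.na(i)
  cis <- known &
    loc$chrom == gene_model$chrom[i] &
    loc$pos >= gene_model$start[i] - window &
    loc$pos <= gene_model$end[i] + window
  lab[known] <- ifelse(cis[known], "cis", "trans")
  meqtls$cis_trans <- lab
  meqtls
}

#' Flat edge list of an integrated network
#'
#' @param g igraph graph from [assemble_network()].
#' @return data frame of edges with attributes.
#' @export
network_edges <- function(g) {
  if (igraph::ecount(g) == 0)
    return(data.frame(from = character(), to = character(), type = character(),
                      sign = character(), weight = numeric(), p = numeric()))
  e <- igraph::as_data_frame(g, what = "edges")
  rownames(e) <- NULL
  e
}

#' Write a network as GraphML
#'
#' @param g igraph graph.
#' @param path output file.
#' @export
write_network_graphml <- function(g, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  igraph::write_graph(g, tmp, format = "graphml")
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  invisible(path)
}
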