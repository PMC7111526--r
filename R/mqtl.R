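# Association mapping on inbred-line genotypes ------------------------------
#
# Phenotype line values are regressed on the two homozygous genotype classes
# (0/1) by OLS, equivalent to a pooled-variance two-sample t test. With a
# panel of unrelated, inversion-free, Wolbachia-free lines the usual panel
# covariates vanish, so plain regression is the faithful reduction of the
# standard panel GWA pipeline.

#' Filter variants by minor-class line count
#'
#' Keeps a variant iff its minor genotype class is carried by at least
#' `min_minor_lines` non-missing lines (default 4, i.e. MAF >= 0.1 in a
#' 40-line panel).
#'
#' @param genotypes line-by-variant matrix with entries in `{0, 1, NA}`.
#' @param min_minor_lines minimum minor-class line count.
#' @return character vector of kept variant ids, with per-variant minor
#'   counts as the `minor_count` attribute.
#' @export
filter_variants <- function(genotypes, min_minor_lines = 4) {
  vals <- genotypes[!is.na(genotypes)]
  if (!all(vals %in% c(0, 1))) stop("genotype entries must be 0, 1 or NA")
  n1 <- colSums(genotypes == 1, na.rm = TRUE)
  n0 <- colSums(genotypes == 0, na.rm = TRUE)
  minor <- pmin(n0, n1)
  keep <- minor >= min_minor_lines
  structure(colnames(genotypes)[keep], minor_count = minor[keep])
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

# Vectorized two-class OLS over the columns of G (no missing entries):
# effect = minor-coded class-1 mean minus class-0 mean, pooled-variance t.
ols_scan <- function(y, G) {
  n <- length(y)
  n1 <- colSums(G); n0 <- n - n1
  s1 <- as.vector(crossprod(G, y))
  m1 <- s1 / n1
  m0 <- (sum(y) - s1) / n0
  ssw <- sum(y^2) - n1 * m1^2 - n0 * m0^2
  s2 <- ssw / (n - 2)
  se <- sqrt(pmax(s2, 0) * (1 / n1 + 1 / n0))
  eff <- m1 - m0
  tt <- ifelse(se > 0, eff / se, ifelse(eff == 0, 0, Inf * sign(eff)))
  p <- ifelse(is.finite(tt), t_pvalue(tt, n - 2), 0)
  data.frame(effect = eff, se = se, t = tt, p = p, n = n, n_minor = pmin(n0, n1))
}

#' Map associations of one phenotype on a set of variants
#'
#' Per-variant OLS of line phenotype values on the 0/1 genotype class, with a
#' two-sided t P-value. Lines with missing phenotype are removed first;
#' missing genotypes are excluded per variant and the class-minimum
#' re-checked, skipping (with a message) variants whose smaller class falls
#' below `min_class`.
#'
#' @param y named vector of line phenotype values.
#' @param genotypes line-by-variant matrix, entries in `{0, 1, NA}`.
#' @param variants variant ids to test (default: all columns).
#' @param min_class minimum lines per genotype class.
#' @param phenotype label stored in the output.
#' @return data frame (variant, phenotype, effect, se, t, p, n, n_minor),
#'   sorted by P.
#' @export
map_associations <- function(y, genotypes, variants = colnames(genotypes),
                             min_class = 4, phenotype = "phenotype") {
  keep_lines <- names(y)[!is.na(y)]
  if (is.null(names(y))) stop("phenotype vector must be named by line")
  y <- y[keep_lines]
  G <- genotypes[keep_lines, variants, drop = FALSE]
  const <- var(y) == 0
  if (const) warning("phenotype is constant; all P set to 1")
  has_na <- colSums(is.na(G)) > 0
  res <- vector("list", 2)
  if (any(!has_na)) {
    Gc <- G[, !has_na, drop = FALSE]
    n1 <- colSums(Gc); n0 <- nrow(Gc) - n1
    ok <- pmin(n0, n1) >= min_class
    if (any(!ok)) message(sum(!ok), " variants skipped: class below minimum")
    r <- ols_scan(y, Gc[, ok, drop = FALSE])
    r$variant <- colnames(Gc)[ok]
    res[[1]] <- r
  }
  if (any(has_na)) {
    rows <- lapply(colnames(G)[has_na], function(v) {
      g <- G[, v]
      use <- !is.na(g)
      n1 <- sum(g[use] == 1); n0 <- sum(g[use] == 0)
      if (min(n0, n1) < min_class) return(NULL)
      r <- ols_scan(y[use], matrix(g[use], ncol = 1))
      r$variant <- v
      r
    })
    dropped <- sum(vapply(rows, is.null, TRUE))
    if (dropped > 0) message(dropped, " variants skipped: class below minimum")
    res[[2]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out) || nrow(out) == 0)
    return(data.frame(variant = character(), phenotype = character(),
                      effect = numeric(), se = numeric(), t = numeric(),
                      p = numeric(), n = integer(), n_minor = integer()))
  if (const) { out$p <- 1; out$t <- 0 }
  out$phenotype <- phenotype
  out <- out[order(out$p, out$variant),
             c("variant", "phenotype", "effect", "se", "t", "p", "n", "n_minor")]
  rownames(out) <- NULL
  out
}

#' Map associations for every column of a phenotype matrix
#'
#' @param phenos line-by-phenotype matrix.
#' @inheritParams map_associations
#' @param threshold optional P-value cutoff applied to the combined output.
#' @return combined association data frame.
#' @export
map_associations_all <- function(phenos, genotypes,
                                 variants = colnames(genotypes),
                                 min_class = 4, threshold = NULL) {
  out <- do.call(rbind, lapply(colnames(phenos), function(ph)
    map_associations(setNames(phenos[, ph], rownames(phenos)), genotypes,
                     variants, min_class, phenotype = ph)))
  if (!is.null(threshold)) out <- out[out$p < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse `chrom_pos_ref/alt` variant ids
#'
#' @param ids character vector of variant ids.
#' @return data frame with variant, chrom, pos.
#' @export
parse_variant_id <- function(ids) {
  parts <- regmatches(ids, regexec("^(.+)_([0-9]+)_([ACGTacgt-]+)/([ACGTacgt-]+)$", ids))
  bad <- vapply(parts, length, 0L) != 5
  if (any(bad)) stop("unparseable variant ids: ", paste(head(ids[bad]), collapse = ", "))
  data.frame(variant = ids,
             chrom = vapply(parts, `[`, "", 2),
             pos = as.integer(vapply(parts, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Annotate association hits with genes or intergenic regions
#'
#' A variant inside a gene span (1-based, closed) is labeled with the gene
#' id(s) (and site class when supplied); intergenic variants are merged by
#' single linkage into regions whenever consecutive hits on a chromosome are
#' at most `merge_dist` bp apart.
#'
#' @param hits association data frame with a `variant` column (ids
#'   `chrom_pos_ref/alt`) or explicit `chrom`/`pos` columns.
#' @param gene_model data frame with chrom, start, end, gene_id.
#' @param merge_dist intergenic merge distance in bp.
#' @param site_classes optional data frame (variant, site_class).
#' @return `hits` with annotation, genes, region columns.
#' @export
annotate_hits <- function(hits, gene_model, merge_dist = 2000,
                          site_classes = NULL) {
  if (nrow(hits) == 0) {
    hits$annotation <- character(); hits$genes <- character()
    hits$region <- character()
    return(hits)
  }
  if (!all(c("chrom", "pos") %in% names(hits))) {
    loc <- parse_variant_id(hits$variant)
    hits$chrom <- loc$chrom; hits$pos <- loc$pos
  }
  hits$genes <- NA_character_
  for (i in seq_len(nrow(hits))) {
    inside <- gene_model$chrom == hits$chrom[i] &
      gene_model$start <= hits$pos[i] & gene_model$end >= hits$pos[i]
    if (any(inside))
      hits$genes[i] <- paste(sort(gene_model$gene_id[inside]), collapse = ",")
  }
  hits$annotation <- ifelse(is.na(hits$genes), "intergenic", "gene")
  hits$region <- NA_character_
  ig <- which(hits$annotation == "intergenic")
  if (length(ig) > 0) {
    # one region id per variant position; single-linkage merge within chrom
    upos <- unique(hits[ig, c("chrom", "pos")])
    upos <- upos[order(upos$chrom, upos$pos), ]
    new_region <- c(TRUE, diff(upos$pos) > merge_dist |
                      upos$chrom[-1] != upos$chrom[-nrow(upos)])
    rid <- cumsum(new_region)
    upos$region <- sprintf("igr_%s_%03d", upos$chrom, rid)
    key <- paste(hits$chrom[ig], hits$pos[ig])
    hits$region[ig] <- upos$region[match(key, paste(upos$chrom, upos$pos))]
  }
  if (!is.null(site_classes))
    hits$site_class <- site_classes$site_class[match(hits$variant,
                                                     site_classes$variant)]
  hits
}

#' Pleiotropy summary of association hits
#'
#' @param hits data frame with `variant` and `phenotype` columns (one row per
#'   significant variant-phenotype pair).
#' @return list with `per_variant` (phenotypes per variant),
#'   `per_phenotype` (hits per phenotype, with mean and median),
#'   `pct_single`: percentage of variants associated with exactly one
#'   phenotype.
#' @export
pleiotropy_summary <- function(hits) {
  if (nrow(hits) == 0)
    return(list(per_variant = data.frame(variant = character(),
                                         n_phenotypes = integer()),
                per_phenotype = data.frame(phenotype = character(),
                                           n_hits = integer()),
                pct_single = NA_real_, mean_per_phenotype = NA_real_,
                median_per_phenotype = NA_real_))
  u <- unique(hits[, c("variant", "phenotype")])
  pv <- aggregate(phenotype ~ variant, u, length)
  names(pv) <- c("variant", "n_phenotypes")
  pp <- aggregate(variant ~ phenotype, u, length)
  names(pp) <- c("phenotype", "n_hits")
  list(per_variant = pv, per_phenotype = pp,
       pct_single = 100 * mean(pv$n_phenotypes == 1),
       mean_per_phenotype = mean(pp$n_hits),
       median_per_phenotype = median(pp$n_hits))
}

#' Relaxed threshold capturing a fixed number of top associations
#'
#' Rank-based selection of the `n_target` smallest P-values; the implied
#' threshold (the `n_target`-th smallest P) is reported alongside.
#'
#' @param hits association data frame with a `p` column.
#' @param n_target number of associations to capture.
#' @return list with `threshold` and the selected `hits` rows.
#' @export
relaxed_threshold <- function(hits, n_target) {
  stopifnot(n_target >= 1)
  p <- sort(hits$p)
  thr <- p[min(n_target, length(p))]
  list(threshold = thr,
       hits = hits[hits$p <= thr, , drop = FALSE])
}

#' @importFrom stats median
NULL
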