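# Metabolome-wide association screens ---------------------------------------
#
# Organismal traits are screened against metabolite line means and module PCs
# with Spearman rank correlations at a nominal P < 0.05; significant hits are
# summarized by metabolic super pathway, and traits are clustered on their
# signed correlation profiles.

# Spearman rho with average-rank ties.
spearman_rho <- function(x, y) cor(rank(x), rank(y))

# Exact two-sided permutation P for Spearman rho at small n:
# Pr(|rho_perm| >= |rho_obs|) over all n! permutations.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

spearman_exact_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  P <- all_perms(n)
  rhos <- apply(P, 1, function(ix) cor(rx[ix], ry))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

spearman_t_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  t_pvalue(tt, n - 2)
}

#' Spearman screen of traits against features
#'
#' Every trait column is correlated with every feature column over pairwise
#' complete lines. Requires at least `min_pairs` complete pairs (default 5);
#' constant traits or features are skipped with a message. P-values use the t
#' approximation, or exact permutation enumeration when `n <= exact_max_n`.
#'
#' @param traits line-by-trait matrix.
#' @param features line-by-feature matrix (metabolite line means or module
#'   PC scores), rows matched to `traits` by line name.
#' @param alpha nominal significance threshold for the `significant` flag.
#' @param min_pairs minimum complete pairs per test.
#' @param exact_max_n enumerate the exact permutation null when the number of
#'   complete pairs is at most this (0 disables).
#' @return data frame (trait, feature, rho, p, n, significant).
#' @export
spearman_screen <- function(traits, features, alpha = 0.05, min_pairs = 5,
                            exact_max_n = 8) {
  common <- intersect(rownames(traits), rownames(features))
  if (length(common) < min_pairs) stop("fewer than min_pairs shared lines")
  traits <- traits[common, , drop = FALSE]
  features <- features[common, , drop = FALSE]
  skipped <- 0L
  out <- vector("list", ncol(traits) * ncol(features))
  k <- 0L
  for (i in seq_len(ncol(traits))) for (j in seq_len(ncol(features))) {
    x <- traits[, i]; y <- features[, j]
    use <- !is.na(x) & !is.na(y)
    n <- sum(use)
    if (n < min_pairs) { skipped <- skipped + 1L; next }
    if (var(x[use]) == 0 || var(y[use]) == 0) { skipped <- skipped + 1L; next }
    rho <- spearman_rho(x[use], y[use])
    p <- if (n <= exact_max_n) spearman_exact_p(x[use], y[use])
         else spearman_t_p(rho, n)
    k <- k + 1L
    out[[k]] <- data.frame(trait = colnames(traits)[i],
                           feature = colnames(features)[j],
                           rho = rho, p = p, n = n,
                           stringsAsFactors = FALSE)
  }
  if (skipped > 0)
    message(skipped, " trait-feature pairs skipped (constant or too few pairs)")
  res <- if (k == 0) data.frame(trait = character(), feature = character(),
                                rho = numeric(), p = numeric(), n = integer())
         else do.call(rbind, out[seq_len(k)])
  res$significant <- res$p < alpha
  rownames(res) <- NULL
  res
}

#' Super-pathway counts of significant trait correlates
#'
#' @param screen output of [spearman_screen()] (only rows flagged significant
#'   are counted).
#' @param annotation data frame with analyte, super_pathway.
#' @return trait-by-super-pathway count matrix (as a table); row sums equal
#'   each trait's number of significant metabolites.
#' @export
superpathway_table <- function(screen, annotation) {
  sig <- screen[screen$significant, , drop = FALSE]
  if (nrow(sig) == 0) return(table(trait = character(), super_pathway = character()))
  sp <- annotation$super_pathway[match(sig$feature, annotation$analyte)]
  if (any(is.na(sp))) {
    warning(sum(is.na(sp)), " unannotated analytes counted as 'unknown'")
    sp[is.na(sp)] <- "unknown"
  }
  table(trait = sig$trait, super_pathway = sp)
}

#' Cluster traits on their metabolome correlation profiles
#'
#' Each trait is represented by its signed Spearman rho across the union of
#' screened features, zeroed where the correlation is not significant
#' (`profile = "full"` keeps all rho). Distance is 1 minus the Pearson
#' correlation of profiles; the hierarchy uses the requested linkage.
#'
#' @param screen output of [spearman_screen()] over traits x features.
#' @param cut_height optional dendrogram cut height for cluster assignment.
#' @param k optional number of clusters (alternative to `cut_height`).
#' @param profile "signed_significant" (default) or "full".
#' @param linkage linkage rule for [stats::hclust()].
#' @return list with `hclust`, `clusters` (named integer vector or NULL),
#'   `newick` (dendrogram as a Newick string), `profiles`.
#' @export
cluster_traits <- function(screen, cut_height = NULL, k = NULL,
                           profile = c("signed_significant", "full"),
                           linkage = "average") {
  profile <- match.arg(profile)
  traits <- sort(unique(screen$trait))
  feats <- sort(unique(screen$feature))
  if (length(traits) < 1) stop("no traits in screen")
  M <- matrix(0, length(traits), length(feats), dimnames = list(traits, feats))
  use <- if (profile == "signed_significant") screen$significant else
    rep(TRUE, nrow(screen))
  sub <- screen[use, , drop = FALSE]
  M[cbind(sub$trait, sub$feature)] <- sub$rho
  zero <- apply(M, 1, function(r) all(r == 0))
  if (any(zero)) {
    warning("traits excluded (all-zero profile): ",
            paste(traits[zero], collapse = ", "))
    M <- M[!zero, , drop = FALSE]
  }
  if (nrow(M) == 1) {
    return(list(hclust = NULL, clusters = setNames(1L, rownames(M)),
                newick = paste0("(", rownames(M), ");"), profiles = M))
  }
  D <- as.dist(1 - cor(t(M)))
  hc <- hclust(D, method = linkage)
  clusters <- NULL
  if (!is.null(cut_height)) clusters <- cutree(hc, h = cut_height)
  else if (!is.null(k)) clusters <- cutree(hc, k = k)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, clusters = clusters, newick = newick, profiles = M)
}
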