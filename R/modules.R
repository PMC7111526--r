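# Metabolite correlation modules and module PCs ----------------------------
#
# Modules are found by weighted-modularity maximization on a sigmoid
# transform of the absolute correlation matrix, with the transform chosen
# over a fixed (steepness, midpoint) grid to maximize modularity. Modules are
# then ordered by descending mean within-module |r|, and each module is
# summarized by the principal components of its standardized line means,
# retaining every PC that explains more than 4% of the module variance and
# extending the set, in decreasing order, until the retained PCs cumulatively
# explain more than 90%.

#' Correlation matrix of metabolite line means
#'
#' Pairwise-complete correlations across lines. Analytes that are constant
#' (correlation undefined) get 0 off-diagonal with a warning.
#'
#' @param lm_mat line-by-analyte matrix of line means.
#' @param method "pearson" (default) or "spearman".
#' @return symmetric correlation matrix with unit diagonal.
#' @export
metabolite_correlations <- function(lm_mat, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(lm_mat) < 3) stop("need at least 3 lines")
  R <- suppressWarnings(cor(lm_mat, use = "pairwise.complete.obs",
                            method = method))
  if (any(is.na(R))) {
    warning(sum(is.na(R[upper.tri(R)])),
            " undefined correlations (constant analyte) recorded as 0")
    R[is.na(R)] <- 0
  }
  diag(R) <- 1
  R
}

check_corr_matrix <- function(R) {
  if (!isSymmetric(unname(R), tol = 1e-8)) stop("correlation matrix must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-8)) stop("correlation matrix must have unit diagonal")
  if (any(abs(R) > 1 + 1e-8)) stop("correlation entries must be in [-1, 1]")
  invisible(TRUE)
}

#' Partition analytes into correlation modules
#'
#' Builds edge weights `w_ij = 1 / (1 + exp(-s (|r_ij| - t)))` for every pair
#' with `|r_ij| > 0` and maximizes weighted modularity with a deterministic
#' agglomerative algorithm; the `(s, t)` pair is chosen over a fixed grid by
#' the modularity it achieves. Modules are relabeled 1..K in decreasing order
#' of mean within-module |r| (singletons have mean 0; ties broken by size,
#' then by smallest member id).
#'
#' @param R correlation matrix (symmetric, unit diagonal).
#' @param steepness_grid sigmoid steepness values to scan.
#' @param midpoint_grid sigmoid midpoint values to scan.
#' @return a `module_partition`: list with `assignment` (named integer
#'   vector), `modules` (per-module size and mean |r|, in module order),
#'   `params`, `modularity`.
#' @export
cluster_modules <- function(R, steepness_grid = c(5, 10, 20),
                            midpoint_grid = c(0.3, 0.5, 0.7)) {
  check_corr_matrix(R)
  A <- abs(R); diag(A) <- 0
  n <- ncol(R)
  ids <- colnames(R) %||% paste0("a", seq_len(n))
  best <- NULL
  for (s in steepness_grid) for (t in midpoint_grid) {
    W <- 1 / (1 + exp(-s * (A - t)))
    W[A <= 0] <- 0
    diag(W) <- 0
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    if (igraph::ecount(g) == 0) { memb <- seq_len(n); q <- -Inf }
    else {
      fg <- igraph::cluster_fast_greedy(g)
      # choose the cut of the merge tree with maximal modularity ourselves
      # (ties broken toward fewer modules), robust to floating-point ties
      hc <- stats::as.hclust(fg)
      qs <- vapply(seq_len(n), function(k)
        igraph::modularity(g, cutree(hc, k = k),
                           weights = igraph::E(g)$weight), 0)
      k_best <- which(qs > max(qs) - 1e-12)[1]
      memb <- cutree(hc, k = k_best)
      q <- qs[k_best]
    }
    if (is.null(best) || q > best$q + 1e-12)
      best <- list(q = q, memb = as.integer(memb), s = s, t = t)
  }
  memb <- best$memb
  # order modules by mean within-module |r|
  stats_by <- lapply(sort(unique(memb)), function(k) {
    members <- which(memb == k)
    mr <- if (length(members) < 2) 0 else
      mean(A[members, members][upper.tri(A[members, members])])
    list(k = k, size = length(members), mean_abs_r = mr, first = min(members))
  })
  ord <- order(-vapply(stats_by, `[[`, 0, "mean_abs_r"),
               -vapply(stats_by, `[[`, 0, "size"),
               vapply(stats_by, `[[`, 0, "first"))
  relabel <- integer(max(memb))
  relabel[vapply(stats_by, function(x) as.integer(x$k), 0L)[ord]] <- seq_along(ord)
  assignment <- setNames(relabel[memb], ids)
  modules <- data.frame(
    module = seq_along(ord),
    size = vapply(stats_by, `[[`, 0, "size")[ord],
    mean_abs_r = vapply(stats_by, `[[`, 0, "mean_abs_r")[ord])
  structure(list(assignment = assignment, modules = modules,
                 params = c(steepness = best$s, midpoint = best$t),
                 modularity = best$q),
            class = "module_partition")
}

# PC retention: all PCs with variance fraction > min_frac, extended in
# decreasing order until the retained set cumulatively explains > cum_target.
retained_pcs <- function(frac, min_frac = 0.04, cum_target = 0.90) {
  keep <- which(frac > min_frac)
  k <- length(keep)           # fractions are in decreasing order
  while (sum(frac[seq_len(max(k, 1L))]) <= cum_target && k < length(frac))
    k <- k + 1L
  seq_len(max(k, 1L))
}

#' Principal components of each metabolite module
#'
#' PCA on the standardized (z-scored) line means of each module's analytes.
#' PC scores are centered across lines and signs are fixed so the loading
#' element with the largest absolute value is positive. Retention follows the
#' >4% / cumulative >90% rule (see [cluster_modules()]).
#'
#' @param lm_mat line-by-analyte matrix of line means.
#' @param partition a `module_partition` (or named integer vector).
#' @param min_frac per-PC variance-fraction retention threshold.
#' @param cum_target cumulative variance fraction the retained set must
#'   exceed.
#' @return a `module_pcs`: per-module list with loadings, scores, variance
#'   fractions and retained index set.
#' @export
module_pca <- function(lm_mat, partition, min_frac = 0.04, cum_target = 0.90) {
  assignment <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  analytes <- intersect(colnames(lm_mat), names(assignment))
  if (length(analytes) == 0) stop("no analytes shared between matrix and partition")
  out <- list()
  for (k in sort(unique(assignment[analytes]))) {
    members <- analytes[assignment[analytes] == k]
    X <- scale(lm_mat[, members, drop = FALSE])
    X[is.na(X)] <- 0   # constant analytes contribute nothing after z-scoring
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    rank_used <- sum(pc$sdev > 1e-12)
    if (rank_used < length(members))
      message("module ", k, ": rank ", rank_used, " < ", length(members),
              " analytes; PCs truncated at rank")
    frac <- pc$sdev^2 / sum(pc$sdev^2)
    keepn <- max(rank_used, 1L)
    frac <- frac[seq_len(keepn)]
    load <- pc$rotation[, seq_len(keepn), drop = FALSE]
    score <- pc$x[, seq_len(keepn), drop = FALSE]
    for (j in seq_len(ncol(load))) {        # sign convention
      i_max <- which.max(abs(load[, j]))
      if (load[i_max, j] < 0) { load[, j] <- -load[, j]; score[, j] <- -score[, j] }
    }
    ret <- retained_pcs(frac, min_frac, cum_target)
    stopifnot(sum(frac[ret]) > cum_target || length(ret) == length(frac))
    out[[as.character(k)]] <- list(module = k, analytes = members,
                                   loadings = load, scores = score,
                                   frac = frac, retained = ret)
  }
  structure(out, class = "module_pcs")
}

#' Matrix of retained module-PC scores
#'
#' @param mpcs a `module_pcs` object.
#' @param retained_only keep only retained PCs.
#' @return line-by-PC matrix, columns named `M<module>.PC<index>`.
#' @export
pc_score_matrix <- function(mpcs, retained_only = TRUE) {
  cols <- list()
  for (m in mpcs) {
    idx <- if (retained_only) m$retained else seq_along(m$frac)
    sc <- m$scores[, idx, drop = FALSE]
    colnames(sc) <- sprintf("M%d.PC%d", m$module, idx)
    cols[[length(cols) + 1]] <- sc
  }
  do.call(cbind, cols)
}
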