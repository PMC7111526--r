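# Synthetic inbred-line panel generator -----------------------------------
#
# Emulates a DGRP-style design: fully inbred lines (two homozygous genotype
# classes, coded 0/1), two sexes, replicated metabolite profiles, transcript
# line means, and organismal traits that are noisy linear functions of a few
# metabolites. All planted effects are recorded as ground truth.

SUPER_PATHWAYS <- c("lipid", "amino acid", "carbohydrate", "nucleotide",
                    "energy", "xenobiotics", "cofactors and vitamins",
                    "peptide")

#' Simulation configuration for a synthetic inbred-line panel
#'
#' Defaults reflect the emulated study design: 40 inbred lines, two sexes,
#' three replicate pools per line and sex, a mean broad-sense heritability of
#' 0.43 per metabolite, and a minor-allele floor of 10% of lines.
#'
#' @param n_lines number of inbred lines.
#' @param n_variants number of biallelic variants.
#' @param maf_min minimum minor-class frequency per variant, in (0, 0.5].
#' @param n_metabolites number of metabolites.
#' @param module_spec data frame with columns `size` and `rho`: block sizes
#'   and within-block correlations (in `[0,1)`) of the line-level metabolite
#'   residuals. Metabolites are assigned to blocks in order; the remainder
#'   are uncorrelated singletons.
#' @param h2_target target broad-sense heritability per metabolite (scalar or
#'   length `n_metabolites`).
#' @param sex_effect_sd SD of the fixed sex effect across metabolites, in
#'   abundance units.
#' @param lxs_fraction fraction of the genetic variance assigned to the
#'   line-by-sex interaction.
#' @param n_reps replicates per line and sex.
#' @param n_genes number of transcripts.
#' @param n_traits number of organismal traits (used when `trait_spec` is
#'   NULL).
#' @param mqtl_spec data frame with columns `variant`, `metabolite`, `effect`
#'   (effect in residual-SD units) giving planted metabolite QTLs.
#' @param eqtl_spec data frame with columns `variant`, `gene`, `effect`
#'   giving planted expression QTLs.
#' @param trait_spec list of lists with elements `metabolites` (indices),
#'   `weights`, and `h2` (fraction of line-mean trait variance explained by
#'   the metabolite signal).
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 40, n_variants = 1000, maf_min = 0.1,
                       n_metabolites = 200, module_spec = NULL,
                       h2_target = 0.43, sex_effect_sd = 1,
                       lxs_fraction = 0.2, n_reps = 3,
                       n_genes = 50, n_traits = 4,
                       mqtl_spec = NULL, eqtl_spec = NULL,
                       trait_spec = NULL, seed = 1L) {
  stopifnot(n_lines >= 2, n_variants >= 1, n_metabolites >= 1, n_reps >= 1)
  if (!(maf_min > 0 && maf_min <= 0.5))
    stop("maf_min must be in (0, 0.5]")
  if (maf_min * n_lines < 1)
    stop("infeasible maf_min: maf_min * n_lines must be >= 1")
  if (any(h2_target < 0) || any(h2_target >= 1))
    stop("h2_target must be in [0, 1)")
  if (lxs_fraction < 0 || lxs_fraction > 1)
    stop("lxs_fraction must be in [0, 1]")
  if (!is.null(module_spec)) {
    module_spec <- as.data.frame(module_spec)
    stopifnot(all(c("size", "rho") %in% names(module_spec)))
    if (any(module_spec$rho < 0) || any(module_spec$rho >= 1))
      stop("module correlations must be in [0, 1)")
    if (sum(module_spec$size) > n_metabolites)
      stop("module sizes sum to more than n_metabolites")
  }
  if (!is.null(mqtl_spec)) {
    mqtl_spec <- as.data.frame(mqtl_spec)
    stopifnot(all(c("variant", "metabolite", "effect") %in% names(mqtl_spec)))
    if (any(mqtl_spec$variant > n_variants) || any(mqtl_spec$metabolite > n_metabolites))
      stop("mqtl_spec index out of range")
  }
  if (!is.null(eqtl_spec)) {
    eqtl_spec <- as.data.frame(eqtl_spec)
    stopifnot(all(c("variant", "gene", "effect") %in% names(eqtl_spec)))
    if (any(eqtl_spec$variant > n_variants) || any(eqtl_spec$gene > n_genes))
      stop("eqtl_spec index out of range")
  }
  if (!is.null(trait_spec)) {
    for (ts in trait_spec) {
      stopifnot(all(c("metabolites", "weights", "h2") %in% names(ts)))
      if (any(ts$metabolites > n_metabolites) || any(ts$metabolites < 1))
        stop("trait_spec metabolite index out of range")
      if (length(ts$weights) != length(ts$metabolites))
        stop("trait_spec weights/metabolites length mismatch")
      if (ts$h2 <= 0 || ts$h2 > 1) stop("trait h2 must be in (0, 1]")
    }
  }
  structure(list(
    n_lines = n_lines, n_variants = n_variants, maf_min = maf_min,
    n_metabolites = n_metabolites, module_spec = module_spec,
    h2_target = rep_len(h2_target, n_metabolites),
    sex_effect_sd = sex_effect_sd, lxs_fraction = lxs_fraction,
    n_reps = n_reps, n_genes = n_genes, n_traits = n_traits,
    mqtl_spec = mqtl_spec, eqtl_spec = eqtl_spec, trait_spec = trait_spec,
    seed = as.integer(seed)
  ), class = "sim_config")
}

line_ids <- function(n) sprintf("line_%03d", seq_len(n))

#' Simulate inbred-line genotypes
#'
#' Each variant is biallelic with two homozygous classes coded 0/1; the
#' minor-class line count is guaranteed to be at least
#' `ceiling(maf_min * n_lines)`. Variant ids follow `chrom_pos_ref/alt`.
#'
#' @param cfg a [sim_config()].
#' @return an `n_lines x n_variants` matrix with entries in `{0, 1}`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_lines
  m <- cfg$n_variants
  kmin <- ceiling(cfg$maf_min * n)
  kmax <- floor(n / 2)
  if (kmin > kmax)
    stop("infeasible maf_min for n_lines: required minor count exceeds n/2")
  chroms <- c("2L", "2R", "3L", "3R", "X")
  chrom <- sort(chroms[((seq_len(m) - 1) %% length(chroms)) + 1])
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(23e6, length(ix)))), use.names = FALSE)
  chrom <- sort(chrom)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  G <- matrix(0L, n, m, dimnames = list(
    line_ids(n), paste0(chrom, "_", pos, "_", ref, "/", alt)))
  k <- if (kmin == kmax) rep(kmin, m) else sample(seq(kmin, kmax), m, replace = TRUE)
  for (j in seq_len(m)) G[sample.int(n, k[j]), j] <- 1L
  G
}

# Assign metabolites to correlation blocks per module_spec; 0 = singleton.
module_assignment <- function(cfg) {
  mod <- integer(cfg$n_metabolites)
  if (!is.null(cfg$module_spec)) {
    at <- 1L
    for (b in seq_len(nrow(cfg$module_spec))) {
      sz <- cfg$module_spec$size[b]
      mod[at:(at + sz - 1L)] <- b
      at <- at + sz
    }
  }
  mod
}

#' Simulate a replicate-level metabolome
#'
#' Abundance of metabolite m for line l, sex s, replicate r is
#' `mu_m + sex_m(s) + L_lm + I_lsm + e`, with the line effect `L` composed of
#' planted mQTL contributions plus a block-correlated residual, the
#' interaction `I` an independent line-by-sex deviation, and unit residual
#' variance. Variance components are scaled so the expected broad-sense
#' heritability equals `h2_target`.
#'
#' @param genotypes matrix from [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @return list with `replicates` (the replicate table: line, sex, replicate,
#'   analyte, abundance) and `truth` (planted and realized components).
#' @export
simulate_metabolome <- function(genotypes, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_lines; p <- cfg$n_metabolites; r <- cfg$n_reps
  lines <- rownames(genotypes)
  analytes <- sprintf("met_%03d", seq_len(p))
  sigma2_e <- 1
  h2 <- cfg$h2_target
  sigma2_G <- h2 / (1 - h2) * sigma2_e
  sigma2_LxS <- cfg$lxs_fraction * sigma2_G
  sigma2_L <- (1 - cfg$lxs_fraction) * sigma2_G

  mod <- module_assignment(cfg)
  mu <- rnorm(p, 10, 1)
  sex_eff <- rnorm(p, 0, cfg$sex_effect_sd)

  # planted mQTL contributions to the line effect (residual-SD units)
  Q <- matrix(0, n, p)
  if (!is.null(cfg$mqtl_spec)) {
    for (i in seq_len(nrow(cfg$mqtl_spec))) {
      v <- cfg$mqtl_spec$variant[i]; m <- cfg$mqtl_spec$metabolite[i]
      Q[, m] <- Q[, m] + cfg$mqtl_spec$effect[i] * sqrt(sigma2_e) * genotypes[, v]
    }
  }

  # block-correlated residual line effects, exchangeable within module
  Zres <- matrix(rnorm(n * p), n, p)
  if (!is.null(cfg$module_spec)) {
    for (b in seq_len(nrow(cfg$module_spec))) {
      members <- which(mod == b)
      rho <- cfg$module_spec$rho[b]
      f <- rnorm(n)
      Zres[, members] <- sqrt(rho) * f +
        sqrt(1 - rho) * Zres[, members, drop = FALSE]
    }
  }
  # scale the residual part so total line variance hits sigma2_L
  L <- Q
  for (m in seq_len(p)) {
    vq <- if (any(Q[, m] != 0)) var(Q[, m]) else 0
    rem <- max(0, sigma2_L[m] - vq)
    L[, m] <- Q[, m] + sqrt(rem) * Zres[, m]
  }

  sexes <- c("F", "M")
  I_F <- matrix(rnorm(n * p, 0, rep(sqrt(sigma2_LxS), each = n)), n, p)
  I_M <- matrix(rnorm(n * p, 0, rep(sqrt(sigma2_LxS), each = n)), n, p)

  tab <- expand.grid(replicate = seq_len(r), line = lines, sex = sexes,
                     stringsAsFactors = FALSE)
  tab <- tab[order(tab$line, tab$sex, tab$replicate), c("line", "sex", "replicate")]
  nrow_base <- nrow(tab)
  out <- vector("list", p)
  li <- match(tab$line, lines)
  sgn <- ifelse(tab$sex == "M", 0.5, -0.5)
  for (m in seq_len(p)) {
    ii <- ifelse(tab$sex == "M", I_M[li, m], I_F[li, m])
    ab <- mu[m] + sgn * sex_eff[m] + L[li, m] + ii +
      rnorm(nrow_base, 0, sqrt(sigma2_e))
    out[[m]] <- data.frame(tab, analyte = analytes[m], abundance = ab,
                           stringsAsFactors = FALSE)
  }
  replicates <- do.call(rbind, out)
  rownames(replicates) <- NULL

  realized <- data.frame(
    analyte = analytes,
    sigma2_L = apply(L, 2, var),
    sigma2_LxS = (apply(I_F, 2, var) + apply(I_M, 2, var)) / 2,
    sigma2_e = sigma2_e,
    target_h2 = h2
  )
  realized$H2 <- with(realized,
    ifelse(sigma2_L + sigma2_LxS + sigma2_e > 0,
           (sigma2_L + sigma2_LxS) / (sigma2_L + sigma2_LxS + sigma2_e), 0))

  list(replicates = replicates,
       truth = list(mu = setNames(mu, analytes),
                    sex_effect = setNames(sex_eff, analytes),
                    line_effects = `dimnames<-`(L, list(lines, analytes)),
                    module = setNames(mod, analytes),
                    mqtl_spec = cfg$mqtl_spec,
                    realized = realized))
}

#' Simulate transcript line means per sex
#'
#' Expression is a sum of planted eQTL effects on the 0/1 genotype plus unit
#' normal line-level noise, drawn independently per sex.
#'
#' @inheritParams simulate_metabolome
#' @return list with `F` and `M` line-by-gene matrices and `truth`.
#' @export
simulate_transcripts <- function(genotypes, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n <- cfg$n_lines; g <- cfg$n_genes
  genes <- sprintf("gene_%03d", seq_len(g))
  B <- matrix(0, ncol(genotypes), g)
  if (!is.null(cfg$eqtl_spec)) {
    for (i in seq_len(nrow(cfg$eqtl_spec)))
      B[cfg$eqtl_spec$variant[i], cfg$eqtl_spec$gene[i]] <-
        B[cfg$eqtl_spec$variant[i], cfg$eqtl_spec$gene[i]] + cfg$eqtl_spec$effect[i]
  }
  signal <- genotypes %*% B
  mk <- function() {
    X <- signal + matrix(rnorm(n * g), n, g)
    dimnames(X) <- list(rownames(genotypes), genes)
    X
  }
  list(F = mk(), M = mk(),
       truth = list(eqtl_spec = cfg$eqtl_spec, genes = genes))
}

#' Simulate organismal traits from metabolite line means
#'
#' Each trait is a weighted sum of metabolite line means plus normal noise
#' scaled so the metabolite signal explains a fraction `h2` of the trait's
#' line-mean variance. Noise is drawn independently per sex.
#'
#' @param met_line_means list with `F` and `M` line-by-metabolite matrices.
#' @param cfg a [sim_config()]; if `cfg$trait_spec` is NULL, `n_traits`
#'   traits are planted, each on 5 random metabolites with unit weights and
#'   h2 = 0.6.
#' @return list with `F` and `M` line-by-trait matrices and `truth`.
#' @export
simulate_traits <- function(met_line_means, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  spec <- cfg$trait_spec
  if (is.null(spec)) {
    spec <- lapply(seq_len(cfg$n_traits), function(i) list(
      metabolites = sample.int(cfg$n_metabolites, min(5, cfg$n_metabolites)),
      weights = rep(1, min(5, cfg$n_metabolites)),
      h2 = 0.6))
  }
  traits <- sprintf("trait_%02d", seq_along(spec))
  mk <- function(lm_mat) {
    out <- sapply(spec, function(ts) {
      sig <- as.vector(lm_mat[, ts$metabolites, drop = FALSE] %*% ts$weights)
      if (ts$h2 >= 1) return(sig)
      noise_sd <- sqrt(var(sig) * (1 - ts$h2) / ts$h2)
      sig + rnorm(nrow(lm_mat), 0, noise_sd)
    })
    dimnames(out) <- list(rownames(lm_mat), traits)
    out
  }
  list(F = mk(met_line_means$F), M = mk(met_line_means$M),
       truth = list(trait_spec = setNames(spec, traits)))
}

#' Simulate a gene model consistent with the panel's variant coordinates
#'
#' Non-overlapping gene spans (1-based, closed) placed along the same
#' chromosomes used by [simulate_genotypes()].
#'
#' @param cfg a [sim_config()].
#' @return data frame with chrom, start, end, gene_id.
#' @export
simulate_gene_model <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 4L)
  chroms <- c("2L", "2R", "3L", "3R", "X")
  g <- cfg$n_genes
  chrom <- sort(chroms[((seq_len(g) - 1) %% length(chroms)) + 1])
  out <- do.call(rbind, lapply(unique(chrom), function(ch) {
    k <- sum(chrom == ch)
    start <- sort(sample.int(22e6, k)) + seq_len(k) * 20000L  # enforce spacing
    width <- sample(2000:10000, k, replace = TRUE)
    data.frame(chrom = ch, start = start, end = start + width,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), ]
  out$gene_id <- sprintf("gene_%03d", seq_len(g))
  rownames(out) <- NULL
  out
}

#' Assign metabolites to super pathways, coherent with module structure
#'
#' Metabolites in the same planted module share a dominant super pathway with
#' probability 0.8; singletons are assigned uniformly.
#'
#' @param cfg a [sim_config()].
#' @return data frame with analyte, super_pathway.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 5L)
  mod <- module_assignment(cfg)
  analytes <- sprintf("met_%03d", seq_len(cfg$n_metabolites))
  sp <- sample(SUPER_PATHWAYS, cfg$n_metabolites, replace = TRUE)
  if (any(mod > 0)) {
    for (b in unique(mod[mod > 0])) {
      members <- which(mod == b)
      dominant <- sample(SUPER_PATHWAYS, 1)
      keep <- runif(length(members)) < 0.8
      sp[members[keep]] <- dominant
    }
  }
  data.frame(analyte = analytes, super_pathway = sp, stringsAsFactors = FALSE)
}

#' Simulate a full synthetic panel
#'
#' Runs all generators and returns genotypes, the replicate-level metabolome,
#' transcript line means, traits, gene model, metabolite annotation, and the
#' recorded ground truth.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `synthetic_panel`.
#' @export
simulate_panel <- function(cfg) {
  G <- simulate_genotypes(cfg)
  met <- simulate_metabolome(G, cfg)
  tr <- simulate_transcripts(G, cfg)
  lmF <- line_means(met$replicates, "F")
  lmM <- line_means(met$replicates, "M")
  traits <- simulate_traits(list(F = lmF, M = lmM), cfg)
  gm <- simulate_gene_model(cfg)
  ann <- simulate_annotation(cfg)
  structure(list(
    genotypes = G, metabolome = met$replicates,
    transcripts = tr[c("F", "M")], traits = traits[c("F", "M")],
    gene_model = gm, annotation = ann,
    truth = list(metabolome = met$truth, transcripts = tr$truth,
                 traits = traits$truth),
    config = cfg
  ), class = "synthetic_panel")
}
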