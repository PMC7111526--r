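test_that("variant filtering applies the minor-class line-count rule", {
  G <- matrix(0L, 40, 3, dimnames = list(
    paste0("L", 1:40), c("2L_100_A/G", "2L_200_C/T", "2L_300_G/A")))
  G[1:3, 1] <- 1L   # minor count 3: dropped
  G[1:4, 2] <- 1L   # minor count 4: kept
  # column 3 monomorphic: dropped
  kept <- filter_variants(G)
  expect_equal(as.character(kept), "2L_200_C/T")
  G[1, 1] <- 2L
  expect_error(filter_variants(G), "0, 1 or NA")
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(signif(bonferroni_threshold(1561516, 0.05), 2), 3.2e-8)
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(20, 0.05), 2.5e-3)
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("associations match a brute-force lm() oracle", {
  set.seed(12)
  worst <- 0
  for (i in 1:100) {
    n <- sample(12:40, 1)
    g <- integer(n); g[sample.int(n, sample(4:(n - 4), 1))] <- 1L
    y <- setNames(rnorm(n) + g * rnorm(1), paste0("L", 1:n))
    G <- matrix(g, n, 1, dimnames = list(names(y), "2L_1_A/G"))
    a <- map_associations(y, G, min_class = 4)
    o <- summary(lm(y ~ g))$coefficients
    worst <- max(worst,
                 abs(a$p - o[2, 4]),
                 abs(a$effect - o[2, 1]),
                 abs(a$se - o[2, 2]))
  }
  expect_lt(worst, 1e-10)
})

test_that("effect sign flips under genotype recoding; P unchanged", {
  set.seed(2)
  n <- 30
  g <- integer(n); g[1:10] <- 1L
  y <- setNames(rnorm(n) + g, paste0("L", 1:n))
  G <- matrix(g, n, 1, dimnames = list(names(y), "2L_5_A/G"))
  a1 <- map_associations(y, G)
  a2 <- map_associations(y, 1L - G)
  expect_equal(a1$effect, -a2$effect)
  expect_equal(a1$p, a2$p)
})

test_that("separated classes give essentially zero P; constants warn", {
  g <- rep(0:1, each = 10)
  y <- setNames(ifelse(g == 1, 5, 1), paste0("L", 1:20))
  G <- matrix(g, 20, 1, dimnames = list(names(y), "X_9_T/C"))
  a <- map_associations(y, G)
  expect_lt(a$p, 1e-12)
  expect_equal(a$effect, 4)
  expect_warning(map_associations(setNames(rep(1, 20), names(y)), G),
                 "constant")
})

test_that("null association P-values are uniform", {
  set.seed(5)
  G <- matrix(0L, 40, 10)
  for (j in 1:10) G[sample.int(40, 15), j] <- 1L
  dimnames(G) <- list(paste0("L", 1:40), paste0("2L_", 1:10, "_A/G"))
  Y <- matrix(rnorm(40 * 100), 40, 100,
              dimnames = list(rownames(G), paste0("ph", 1:100)))
  hits <- map_associations_all(Y, G)
  ks <- suppressWarnings(stats::ks.test(hits$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # Bonferroni-significant set nests inside the nominal set
  thr <- bonferroni_threshold(nrow(hits))
  expect_true(all(hits$p[hits$p <= thr] < 0.05))
})

test_that("gene and intergenic annotation with the 2-kb merge rule", {
  gm <- data.frame(chrom = "2L", start = 10000, end = 12000, gene_id = "gA")
  hits <- data.frame(
    variant = c("2L_11000_A/G",        # inside gA
                "2L_20000_C/T", "2L_21999_G/A",  # 1999 apart: one region
                "2L_30000_T/A", "2L_32001_A/C"), # 2001 apart: two regions
    phenotype = "m", p = 1e-9)
  ann <- annotate_hits(hits, gm)
  expect_equal(ann$annotation, c("gene", rep("intergenic", 4)))
  expect_equal(ann$genes[1], "gA")
  expect_equal(ann$region[2], ann$region[3])
  expect_false(ann$region[4] == ann$region[5])
})

test_that("pleiotropy summary reproduces printed-count arithmetic", {
  # 921 variants, 808 single-metabolite
  hits_f <- rbind(
    data.frame(variant = paste0("v", 1:808), phenotype = "m1"),
    data.frame(variant = paste0("w", 1:113), phenotype = "m1"),
    data.frame(variant = paste0("w", 1:113), phenotype = "m2"))
  expect_equal(round(pleiotropy_summary(hits_f)$pct_single, 1), 87.7)
  hits_m <- rbind(
    data.frame(variant = paste0("v", 1:1115), phenotype = "m1"),
    data.frame(variant = paste0("w", 1:107), phenotype = "m1"),
    data.frame(variant = paste0("w", 1:107), phenotype = "m2"))
  expect_equal(round(pleiotropy_summary(hits_m)$pct_single, 1), 91.2)

  hits3 <- data.frame(variant = c("A", "B", "B", "C"),
                      phenotype = c("m1", "m1", "m2", "m1"))
  expect_equal(round(pleiotropy_summary(hits3)$pct_single, 1), 66.7)
  hits4 <- data.frame(variant = paste0("v", 1:22),
                      phenotype = rep(c("a", "b", "c"), c(5, 5, 12)))
  expect_equal(pleiotropy_summary(hits4)$median_per_phenotype, 5)
  empty <- pleiotropy_summary(data.frame(variant = character(),
                                         phenotype = character()))
  expect_true(is.na(empty$pct_single))
})

test_that("planted effects are detected and power is monotone in effect size", {
  detect_rate <- function(effect, nsim = 30) {
    hits <- sapply(seq_len(nsim), function(i) {
      cfg <- sim_config(n_lines = 40, n_variants = 2, n_metabolites = 1,
                        n_reps = 3, h2_target = 0.43, seed = 5000 + i,
                        mqtl_spec = data.frame(variant = 1, metabolite = 1,
                                               effect = effect))
      G <- simulate_genotypes(cfg)
      # fix minor count at 10/40 for the causal variant
      G[, 1] <- 0L; G[1:10, 1] <- 1L
      met <- simulate_metabolome(G, cfg)
      y <- line_means(met$replicates, "F")[, 1]
      a <- map_associations(y, G[, 1, drop = FALSE])
      a$p[1] <= 3.2e-8
    })
    mean(hits)
  }
  p2 <- detect_rate(2)
  p05 <- detect_rate(0.5)
  expect_gte(p2, 0.5)
  expect_lte(p05, p2)
})

test_that("relaxed threshold captures the requested number of hits", {
  hits <- data.frame(p = c(1e-9, 1e-7, 1e-5, 1e-3, 0.1))
  rt <- relaxed_threshold(hits, 3)
  expect_equal(rt$threshold, 1e-5)
  expect_equal(nrow(rt$hits), 3)
})
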