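test_that("trait metabolites honor the 0.05 boundary strictly", {
  scr <- data.frame(trait = "t", feature = c("a", "b", "c"),
                    rho = 0.5, p = c(0.049, 0.051, 0.05),
                    significant = c(TRUE, FALSE, FALSE))
  expect_equal(select_trait_metabolites(scr, "t"), "a")
  expect_equal(select_trait_metabolites(scr, "absent"), character(0))
})

test_that("transcript links enforce |rho| > 0.45 exactly", {
  # ranks chosen to give rho just above / below the cut on 10 lines
  ln <- paste0("L", 1:10)
  met <- matrix(1:10, 10, 1, dimnames = list(ln, "m1"))
  # rho of these two against 1:10: computed below, one each side of 0.45
  g_hi <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)        # rho ~ 0.939
  g_lo <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)        # rho = -1
  g_mid <- c(5, 1, 7, 2, 9, 3, 10, 4, 8, 6)
  tr <- cbind(hi = g_hi, lo = g_lo, mid = g_mid)
  rownames(tr) <- ln
  rho_mid <- metaboqg:::spearman_rho(1:10, g_mid)
  links <- link_transcripts("m1", met, tr, r_min = 0.45)
  expect_true(all(abs(links$rho) > 0.45))
  expect_setequal(links$gene,
                  c("hi", "lo", if (abs(rho_mid) > 0.45) "mid"))
  expect_equal(links$rho[links$gene == "lo"], -1)
  # tightening the threshold to exactly |rho| excludes the boundary pair
  links2 <- link_transcripts("m1", met, tr, r_min = 1)
  expect_equal(nrow(links2), 0)
})

test_that("the meQTL threshold is alpha over the metabolite's mQTL count", {
  set.seed(6)
  ln <- paste0("L", 1:40)
  G <- matrix(0L, 40, 12, dimnames = list(ln, paste0("2L_", 1:12 * 100, "_A/G")))
  for (j in 1:12) G[sample.int(40, 20), j] <- 1L
  expr <- matrix(rnorm(40), 40, 1, dimnames = list(ln, "g1"))
  expr[, 1] <- expr[, 1] + 3 * G[, 1]   # strong variant 1 -> g1 effect
  links <- data.frame(gene = "g1", metabolite = "m1", rho = 0.9)
  # m1 has 10 mQTLs: threshold 0.05/10 = 0.005
  hits10 <- data.frame(variant = colnames(G)[1:10], phenotype = "m1")
  meq <- find_meqtls(hits10, links, expr, G)
  expect_true(all(meq$threshold == 0.005))
  expect_true(colnames(G)[1] %in% meq$variant)
  expect_true(all(meq$p < 0.005))
  # with a single mQTL the threshold is 0.05
  hits1 <- data.frame(variant = colnames(G)[1], phenotype = "m1")
  meq1 <- find_meqtls(hits1, links, expr, G)
  expect_equal(unique(meq1$threshold), 0.05)
  # a metabolite absent from the hit list contributes nothing
  expect_equal(nrow(find_meqtls(hits1[0, ], links, expr, G)), 0)
})

test_that("a planted variant-gene-metabolite chain is assembled exactly", {
  links <- data.frame(gene = "gene1", metabolite = "met1", rho = 0.8)
  meqtls <- data.frame(variant = "2L_500_A/G", gene = "gene1",
                       metabolite = "met1", effect = 1.2, p = 1e-4,
                       threshold = 0.005)
  ann <- data.frame(analyte = "met1", super_pathway = "lipid")
  g <- assemble_network("met1", links, meqtls,
                        trait_assoc = data.frame(node = "gene1", p = 0.01),
                        annotation = ann, trait = "t1", sex = "F")
  expect_setequal(igraph::V(g)$name, c("met1", "gene1", "2L_500_A/G"))
  expect_equal(igraph::ecount(g), 3)
  edges <- network_edges(g)
  expect_setequal(edges$type,
                  c("correlation", "variant_gene", "variant_metabolite"))
  expect_equal(edges$sign[edges$type == "correlation"], "positive")
  v <- igraph::V(g)
  expect_equal(v$type[v$name == "met1"], "metabolite")
  expect_equal(v$super_pathway[v$name == "met1"], "lipid")
  expect_true(v$trait_flag[v$name == "met1"])
  expect_true(v$trait_flag[v$name == "gene1"])     # p = 0.01 < 0.05
  expect_false(v$trait_flag[v$name == "2L_500_A/G"])
  expect_equal(igraph::graph_attr(g, "trait"), "t1")

  # isolated metabolites (no links, no meQTLs) are dropped
  g2 <- assemble_network(c("met1", "met_orphan"), links, meqtls)
  expect_false("met_orphan" %in% igraph::V(g2)$name)
})

test_that("cis/trans classification uses the 1-kb window boundary", {
  gm <- data.frame(chrom = "2L", start = 5000, end = 6000, gene_id = "gA")
  meq <- data.frame(variant = c("2L_4001_A/G",  # 999 bp upstream: cis
                                "2L_3999_A/G",  # 1001 bp upstream: trans
                                "2L_7000_A/G",  # exactly end + window: cis
                                "3R_5500_A/G"), # wrong chromosome: trans
                    gene = "gA", metabolite = "m", effect = 1,
                    p = 1e-4, threshold = 0.005)
  cc <- classify_cis_trans(meq, gm, window = 1000)
  expect_equal(cc$cis_trans, c("cis", "trans", "cis", "trans"))
  meq$gene <- "missing"
  expect_equal(unique(classify_cis_trans(meq, gm)$cis_trans), "unknown")
})

test_that("null data rarely produce meQTL links", {
  # family-wise: with the per-metabolite Bonferroni rule, the chance of any
  # false meQTL among a metabolite's variants is about alpha
  set.seed(14)
  ln <- paste0("L", 1:40)
  n_false <- sapply(1:400, function(i) {
    G <- matrix(0L, 40, 5, dimnames = list(ln, paste0("2L_", 1:5, "_A/G")))
    for (j in 1:5) G[sample.int(40, 20), j] <- 1L
    expr <- matrix(rnorm(40), 40, 1, dimnames = list(ln, "g1"))
    hits <- data.frame(variant = colnames(G), phenotype = "m1")
    links <- data.frame(gene = "g1", metabolite = "m1", rho = 0.9)
    nrow(find_meqtls(hits, links, expr, G)) > 0
  })
  expect_lte(mean(n_false), 0.10)
})

test_that("GraphML round-trips the network", {
  links <- data.frame(gene = "g1", metabolite = "m1", rho = -0.7)
  g <- assemble_network("m1", links, meqtls = data.frame(
    variant = character(), gene = character(), metabolite = character(),
    effect = numeric(), p = numeric(), threshold = numeric()))
  path <- file.path(tempdir(), "net.graphml")
  write_network_graphml(g, path)
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_equal(sort(igraph::E(g2)$weight), sort(igraph::E(g)$weight))
  unlink(path)
})
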