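test_that("Spearman rho hits the monotone extremes and handles ties", {
  x <- c(1, 4, 9, 16, 25)
  expect_equal(metaboqg:::spearman_rho(1:5, x), 1)
  expect_equal(metaboqg:::spearman_rho(1:5, -x), -1)
  # average ties: matches cor(..., method = "spearman")
  a <- c(1, 2, 2, 3, 5, 5, 5)
  b <- c(2, 1, 4, 4, 6, 8, 7)
  expect_equal(metaboqg:::spearman_rho(a, b),
               cor(a, b, method = "spearman"))
})

test_that("exact small-n P matches an independent enumeration oracle", {
  # independent oracle: insertion-built permutation list + rank correlation
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (p in perms(v[-length(v)]))
      for (pos in 0:length(p))
        out[[length(out) + 1]] <- append(p, v[length(v)], after = pos)
    out
  }
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    obs <- abs(cor(rank(x), rank(y)))
    ref <- mean(vapply(perms(rank(x)),
                       function(px) abs(cor(px, rank(y))) >= obs - 1e-12, TRUE))
    expect_equal(metaboqg:::spearman_exact_p(x, y), ref)
  }
  # perfectly concordant n = 5: P = 2 * 2/120 (both extreme orders)
  expect_equal(metaboqg:::spearman_exact_p(1:5, 2^(1:5)), 2 / 120)
})

test_that("the nominal flag rate is calibrated under the null", {
  set.seed(17)
  tr <- matrix(rnorm(40), 40, 1, dimnames = list(paste0("L", 1:40), "t"))
  fe <- matrix(rnorm(40 * 4000), 40, 4000,
               dimnames = list(rownames(tr), paste0("m", 1:4000)))
  scr <- spearman_screen(tr, fe)
  expect_equal(nrow(scr), 4000)
  rate <- mean(scr$significant)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})

test_that("the screen is invariant to monotone transforms", {
  set.seed(8)
  tr <- matrix(rnorm(12), 12, 1, dimnames = list(paste0("L", 1:12), "t"))
  fe <- matrix(abs(rnorm(12 * 3)) + 1, 12, 3,
               dimnames = list(rownames(tr), paste0("m", 1:3)))
  s1 <- spearman_screen(tr, fe)
  s2 <- spearman_screen(tr, log(fe))
  expect_equal(s1$rho, s2$rho)
  expect_equal(s1$p, s2$p)
})

test_that("constant and short columns are skipped with a message", {
  tr <- matrix(rnorm(10), 10, 1, dimnames = list(paste0("L", 1:10), "t"))
  fe <- cbind(m1 = rnorm(10), m2 = rep(2, 10))
  rownames(fe) <- rownames(tr)
  expect_message(scr <- spearman_screen(tr, fe), "skipped")
  expect_equal(scr$feature, "m1")
  fe2 <- fe
  fe2[1:7, "m1"] <- NA
  expect_message(spearman_screen(tr, fe2), "skipped")
  expect_error(spearman_screen(tr[1:3, , drop = FALSE], fe[1:3, ]),
               "min_pairs")
})

test_that("super-pathway table counts significant hits per trait", {
  scr <- data.frame(
    trait = c("t1", "t1", "t1", "t2", "t2"),
    feature = c("a", "b", "c", "a", "d"),
    rho = 0.9, p = c(0.01, 0.01, 0.5, 0.01, 0.01),
    significant = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  ann <- data.frame(analyte = c("a", "b", "c"),
                    super_pathway = c("amino acid", "lipid", "lipid"))
  expect_warning(tab <- superpathway_table(scr, ann), "unannotated")
  expect_equal(unname(tab["t1", "amino acid"]), 1)
  expect_equal(unname(tab["t1", "lipid"]), 1)
  expect_equal(unname(tab["t2", "unknown"]), 1)
  expect_equal(unname(rowSums(tab)), c(2, 2))
})

test_that("identical traits merge at zero distance; planted groups recover", {
  set.seed(21)
  n_feat <- 30
  base <- rnorm(n_feat)
  scr <- do.call(rbind, lapply(c("tA", "tB", "tC"), function(tr) {
    rho <- if (tr == "tC") rnorm(n_feat) * 0.2 else base
    data.frame(trait = tr, feature = paste0("m", 1:n_feat),
               rho = rho, p = 0.01, significant = TRUE)
  }))
  cl <- cluster_traits(scr, cut_height = 0.1)
  expect_equal(cl$clusters[["tA"]], cl$clusters[["tB"]])
  expect_false(cl$clusters[["tA"]] == cl$clusters[["tC"]])
  expect_match(cl$newick, "^\\(.*\\);$")

  # planted two-group recovery across replicates
  ok <- sapply(1:20, function(i) {
    set.seed(400 + i)
    f1 <- rnorm(n_feat); f2 <- rnorm(n_feat)
    scr2 <- do.call(rbind, lapply(1:4, function(j) {
      sig <- if (j <= 2) f1 else f2
      data.frame(trait = paste0("t", j), feature = paste0("m", 1:n_feat),
                 rho = sig + 0.3 * rnorm(n_feat), p = 0.01,
                 significant = TRUE)
    }))
    cl2 <- cluster_traits(scr2, k = 2)$clusters
    cl2[["t1"]] == cl2[["t2"]] && cl2[["t3"]] == cl2[["t4"]] &&
      cl2[["t1"]] != cl2[["t3"]]
  })
  expect_gte(mean(ok), 0.9)
})

test_that("degenerate clustering inputs are handled", {
  scr1 <- data.frame(trait = "only", feature = c("a", "b"),
                     rho = c(0.5, -0.2), p = 0.01, significant = TRUE)
  cl <- cluster_traits(scr1)
  expect_equal(cl$clusters, c(only = 1L))
  expect_equal(cl$newick, "(only);")
  scr0 <- data.frame(trait = c("x", "y"), feature = "a",
                     rho = c(0.9, 0.8), p = c(0.01, 0.2),
                     significant = c(TRUE, FALSE))
  expect_warning(cl0 <- cluster_traits(scr0), "all-zero")
  expect_equal(rownames(cl0$profiles), "x")
})
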