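test_that("the kernel matches a hand computation and its invariants", {
  X <- matrix(c(1, 2, 3, 4, 6, 8), 3, 2,
              dimnames = list(paste0("L", 1:3), c("a", "b")))
  K <- build_kernel(X)
  # both scaled columns are (-1, 0, 1): K = WW'/2 by hand
  expect_equal(unclass(K)[, ],
               matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3,
                      dimnames = list(rownames(X), rownames(X))),
               ignore_attr = TRUE)
  expect_equal(sum(diag(K)), nrow(X) - 1)   # trace is n - 1 under SD scaling
  expect_equal(attr(K, "p"), 2)

  # duplicating every feature leaves the kernel unchanged
  K2 <- build_kernel(cbind(X, X))
  expect_equal(unclass(K2)[, ], unclass(K)[, ], ignore_attr = TRUE)

  # constant features are dropped with a warning
  expect_warning(K3 <- build_kernel(cbind(X, const = rep(5, 3))), "constant")
  expect_equal(attr(K3, "p"), 2)

  set.seed(2)
  Xr <- matrix(rnorm(20 * 15), 20, 15, dimnames = list(paste0("L", 1:20), NULL))
  Kr <- build_kernel(Xr)
  expect_equal(sum(diag(Kr)), 19)
  expect_no_error(metaboqg:::check_kernel_psd(Kr))
  bad <- diag(3); bad[1, 1] <- -1
  expect_error(metaboqg:::check_kernel_psd(bad), "semidefinite")
})

test_that("the REML criterion matches an independent dense-algebra oracle", {
  set.seed(10)
  n <- 15
  X1 <- matrix(rnorm(n * 8), n, 8, dimnames = list(paste0("L", 1:n), NULL))
  K <- build_kernel(X1)
  y <- rnorm(n)
  Xd <- matrix(1, n, 1)
  oracle <- function(theta) {
    V <- theta[1] * unclass(K) + diag(theta[2], n)
    Vi <- solve(V)
    P <- Vi - Vi %*% Xd %*% solve(t(Xd) %*% Vi %*% Xd) %*% t(Xd) %*% Vi
    as.numeric(determinant(V)$modulus +
                 determinant(t(Xd) %*% Vi %*% Xd)$modulus +
                 t(y) %*% P %*% y)
  }
  for (th in list(c(1, 1), c(0.3, 2), c(4, 0.1)))
    expect_equal(metaboqg:::reml_nll(th, y, Xd, list(unclass(K))),
                 oracle(th), tolerance = 1e-10)
})

test_that("BLUPs at fixed components match the mixed-model-equation oracle", {
  set.seed(11)
  n <- 12
  F1 <- matrix(rnorm(n * 6), n, 6, dimnames = list(paste0("L", 1:n), NULL))
  K <- build_kernel(F1)
  y <- setNames(rnorm(n, 5), rownames(F1))
  sg <- 1.5; se <- 0.7
  fit <- fit_blup(y, K, fixed = c(sg, se))
  # dense oracle
  V <- sg * unclass(K) + diag(se, n)
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  g <- sg * unclass(K) %*% Vi %*% (y - mu)
  expect_equal(fit$mu, mu, tolerance = 1e-8)
  expect_equal(unname(fit$g[[1]]), as.vector(g), tolerance = 1e-8)

  # two identical kernels with split components reproduce the single fit
  fit2 <- fit_blup(y, list(K, K), fixed = c(sg / 2, sg / 2, se))
  expect_equal(fit2$mu, fit$mu, tolerance = 1e-10)
  expect_equal(unname(fit2$g[[1]] + fit2$g[[2]]), unname(fit$g[[1]]),
               tolerance = 1e-10)
})

test_that("holdout prediction equals the conditional-mean oracle and guards leakage", {
  set.seed(12)
  n <- 15
  F1 <- matrix(rnorm(n * 10), n, 10, dimnames = list(paste0("L", 1:n), NULL))
  tr <- 1:(n - 1)
  Kfull <- metaboqg:::fold_kernel(F1, tr)
  y <- setNames(2 + F1[, 1] + rnorm(n, 0, 0.5), rownames(F1))
  sg <- 1.2; se <- 0.4
  fit <- fit_blup(y[tr], Kfull[tr, tr], fixed = c(sg, se))
  pred <- predict_holdout(fit, list(Kfull[n, tr]), line = rownames(F1)[n])
  # oracle: Gaussian conditional mean from the joint covariance
  Vtr <- sg * Kfull[tr, tr] + diag(se, n - 1)
  Vi <- solve(Vtr)
  mu <- sum(Vi %*% y[tr]) / sum(Vi)
  oracle <- mu + sg * Kfull[n, tr] %*% Vi %*% (y[tr] - mu)
  expect_equal(pred, as.numeric(oracle), tolerance = 1e-8)
  expect_error(predict_holdout(fit, list(Kfull[1, tr]), line = "L1"),
               "leakage|present")
})

test_that("kernel BLUP with fixed components equals ridge regression", {
  set.seed(13)
  n <- 20; p <- 12
  F1 <- matrix(rnorm(n * p), n, p, dimnames = list(paste0("L", 1:n), NULL))
  y <- setNames(rnorm(n), rownames(F1))
  sg <- 2; se <- 0.8
  K <- build_kernel(F1)
  fit <- fit_blup(y, K, fixed = c(sg, se))
  # ridge oracle on the scaled features, penalty p * se / sg
  W <- scale(F1)
  lambda <- ncol(W) * se / sg
  beta <- solve(crossprod(W) + diag(lambda, p), crossprod(W, y - fit$mu))
  expect_equal(unname(fit$g[[1]]), as.vector(W %*% beta), tolerance = 1e-8)
})

test_that("accuracy arithmetic, affine invariance and degeneracy", {
  expect_equal(round(accuracy(c(1, 2, 3), c(1, 2, 4)), 3), 0.982)
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 4)),
               accuracy(10 - 2 * c(1, 2, 3), 10 - 2 * c(1, 2, 4)))
  expect_warning(a0 <- accuracy(rep(1, 5), rnorm(5)), "constant")
  expect_equal(as.numeric(a0), 0)
  expect_error(accuracy(1:2, 1:2), "3 pairs")
  expect_error(accuracy(1:3, 1:4), "length")
})

test_that("LOOCV recovers a strong genetic signal and is leakage-safe", {
  set.seed(14)
  n <- 30; p <- 40
  F1 <- matrix(rnorm(n * p), n, p,
               dimnames = list(paste0("L", 1:n), paste0("m", 1:p)))
  g_true <- as.vector(scale(F1[, 1:5]) %*% rep(1, 5))
  y <- setNames(g_true + rnorm(n, 0, 0.5), rownames(F1))
  cv <- loocv_blup(y, F1)
  expect_s3_class(cv, "cv_result")
  expect_equal(nrow(cv$predictions), n)
  expect_gt(cv$accuracy, 0.3)
  expect_output(print(cv), "accuracy")
})

test_that("threshold 1 enrichment reproduces the all-metabolite BLUP", {
  set.seed(15)
  n <- 18; p <- 10
  F1 <- matrix(rnorm(n * p), n, p,
               dimnames = list(paste0("L", 1:n), paste0("m", 1:p)))
  y <- setNames(F1[, 1] + rnorm(n, 0, 0.7), rownames(F1))
  plain <- loocv_blup(y, F1)
  enr <- mwas_enriched_loocv(y, F1, thresholds = 1)
  expect_equal(enr[["x1"]]$predictions$predicted,
               plain$predictions$predicted, tolerance = 1e-10)
  # tighter thresholds select fewer metabolites but still return results
  multi <- suppressMessages(
    mwas_enriched_loocv(y, F1, thresholds = c(0.5, 0.05)))
  expect_named(multi, c("x0.5", "x0.05"))
  expect_true(all(is.finite(multi[["x0.05"]]$predictions$predicted)))
})

test_that("fold-internal selection never sees the held-out line", {
  # a feature equal to y only at the held-out line cannot influence its fold
  set.seed(16)
  n <- 15
  F1 <- matrix(rnorm(n * 5), n, 5,
               dimnames = list(paste0("L", 1:n), paste0("m", 1:5)))
  y <- setNames(rnorm(n), rownames(F1))
  # feature 1 copies y exactly at line 1 but is noise elsewhere
  F2 <- F1; F2[1, 1] <- y[1] * 1000
  e1 <- suppressMessages(mwas_enriched_loocv(y, F1, thresholds = 0.3))
  e2 <- suppressMessages(mwas_enriched_loocv(y, F2, thresholds = 0.3))
  # fold 1's selection P-values are computed on lines 2..n, identical in both
  p1 <- metaboqg:::feature_regression_p(y[-1], F1[-1, ])
  p2 <- metaboqg:::feature_regression_p(y[-1], F2[-1, ])
  expect_equal(p1, p2)
})

test_that("elastic net grid selection is consistent and finds planted signal", {
  set.seed(17)
  n <- 25; p <- 12
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("L", 1:n), paste0("f", 1:p)))
  y <- setNames(2 * X[, 1] - X[, 2] + rnorm(n, 0, 0.4), rownames(X))
  cv <- elastic_net_loocv(y, X, alpha_grid = c(0.25, 1), nlambda = 30)
  expect_equal(cv$accuracy, max(cv$grid, na.rm = TRUE), tolerance = 1e-12)
  expect_gt(cv$accuracy, 0.8)
  expect_true(cv$alpha %in% c(0.25, 1))
  expect_equal(dim(cv$grid), c(2, 30))
  nest <- elastic_net_loocv(y, X, alpha_grid = 1, nlambda = 15, nested = TRUE)
  expect_gt(nest$accuracy, 0.6)
  expect_error(elastic_net_loocv(y, X, alpha_grid = 0), "alpha")
})
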