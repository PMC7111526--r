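# Metabolome- and genome-based phenotype prediction --------------------------
#
# Kernel BLUP: y = 1 mu + g_K (+ g_K2) + e with g_K ~ N(0, K sigma2_K),
# K = WW'/p from column-centered, column-scaled (sample SD) features.
# Variance components by restricted maximum likelihood with non-negativity
# bounds; prediction of a held-out line via the estimated cross-covariance.
# All model selection (including the fold-internal single-metabolite
# regressions of the combined MWAS-BLUP) happens strictly inside the
# training fold.

#' Build a line-similarity kernel K = WW'/p
#'
#' Columns are centered and scaled to unit sample SD (n-1 denominator);
#' constant columns are dropped with a warning and `p` adjusted.
#'
#' @param features line-by-feature matrix (n >= 3).
#' @param tag provenance label (e.g. "metabolites", "SNPs").
#' @return n-by-n kernel with attributes `tag` and `p`.
#' @export
build_kernel <- function(features, tag = "features") {
  features <- as.matrix(features)
  if (nrow(features) < 3) stop("need at least 3 lines")
  sds <- apply(features, 2, sd)
  if (any(sds == 0 | is.na(sds))) {
    warning(sum(sds == 0 | is.na(sds)), " constant columns dropped")
    features <- features[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  p <- ncol(features)
  if (p < 1) stop("no non-constant features left")
  W <- scale(features)
  K <- tcrossprod(W) / p
  dimnames(K) <- list(rownames(features), rownames(features))
  structure(K, tag = tag, p = p)
}

check_kernel_psd <- function(K) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * sum(diag(K)) / nrow(K))
    stop("kernel is not positive semidefinite")
  invisible(TRUE)
}

# REML criterion (-2 restricted log-likelihood, dropping constants) for
# V = sum_k theta_k K_k + theta_e I with fixed-effect design X.
reml_nll <- function(theta, y, X, Ks) {
  nk <- length(Ks)
  V <- diag(theta[nk + 1], length(y))
  for (k in seq_len(nk)) V <- V + theta[k] * Ks[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(Vi_X, y))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  as.numeric(logdetV + determinant(XtViX, logarithm = TRUE)$modulus +
               crossprod(r, Vi_r))
}

#' Fit a one- or two-kernel BLUP model by REML
#'
#' `y = 1 mu + g_K1 (+ g_K2) + e`. Variance components are estimated by
#' bounded REML (multiple starts); mu by GLS; random effects by BLUP at the
#' estimated components.
#'
#' @param y named vector of line phenotypes (complete).
#' @param kernels a kernel matrix or list of one or two kernels (see
#'   [build_kernel()]).
#' @param fixed optional fixed variance components
#'   `c(sigma2_K [, sigma2_K2], sigma2_e)`; skips REML estimation.
#' @return a `blup_fit`: mu, sigma2 (per kernel), sigma2_e, g (per-kernel
#'   BLUPs), lines, converged.
#' @export
fit_blup <- function(y, kernels, fixed = NULL) {
  if (is.matrix(kernels)) kernels <- list(kernels)
  stopifnot(length(kernels) %in% 1:2, !any(is.na(y)))
  lines <- names(y)
  n <- length(y)
  for (K in kernels) {
    stopifnot(nrow(K) == n)
    check_kernel_psd(K)
  }
  X <- matrix(1, n, 1)
  nk <- length(kernels)
  vy <- var(y)
  if (!is.null(fixed)) {
    stopifnot(length(fixed) == nk + 1, all(fixed >= 0), fixed[nk + 1] > 0)
    best <- list(par = fixed, value = reml_nll(fixed, y, X, kernels),
                 convergence = 0)
    return(blup_from_theta(best, y, kernels, converged = TRUE))
  }
  lower <- c(rep(0, nk), 1e-6 * vy)
  starts <- list(c(rep(vy / (nk + 1), nk), vy / (nk + 1)),
                 c(rep(0.05 * vy, nk), 0.9 * vy),
                 c(rep(0.45 * vy, nk), 0.1 * vy))
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    o <- tryCatch(
      optim(s, reml_nll, y = y, X = X, Ks = kernels, method = "L-BFGS-B",
            lower = lower, upper = rep(10 * vy + 1e-12, nk + 1),
            control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) {
      best <- o
      converged <- o$convergence == 0
    }
  }
  if (is.null(best)) stop("REML optimization failed")
  blup_from_theta(best, y, kernels, converged)
}

blup_from_theta <- function(best, y, kernels, converged) {
  n <- length(y)
  nk <- length(kernels)
  theta <- best$par
  V <- diag(theta[nk + 1], n)
  for (k in seq_len(nk)) V <- V + theta[k] * kernels[[k]]
  Vi <- chol2inv(chol(V))
  mu <- as.numeric(colSums(Vi %*% y)) / sum(Vi)
  r <- y - mu
  Vi_r <- as.vector(Vi %*% r)
  g <- lapply(seq_len(nk), function(k) theta[k] * as.vector(kernels[[k]] %*% Vi_r))
  tags <- vapply(seq_len(nk), function(k)
    attr(kernels[[k]], "tag") %||% paste0("K", k), "")
  structure(list(mu = mu, sigma2 = setNames(theta[seq_len(nk)], tags),
                 sigma2_e = theta[nk + 1], g = setNames(g, tags),
                 Vi_r = Vi_r, lines = names(y), reml = best$value,
                 converged = converged),
            class = "blup_fit")
}

#' Predict the phenotype of a held-out line
#'
#' `mu + sum_k sigma2_k k_new_k' V^-1 (y - mu)` using the components
#' estimated on the training lines. Errors if the held-out line appears in
#' the training fit (leakage guard).
#'
#' @param fit a `blup_fit` estimated without the held-out line.
#' @param k_new list (one per kernel) of cross-covariance vectors between the
#'   held-out line and the training lines, ordered as `fit$lines`.
#' @param line id of the held-out line (for the leakage check).
#' @return predicted value.
#' @export
predict_holdout <- function(fit, k_new, line = NULL) {
  if (!is.list(k_new)) k_new <- list(k_new)
  stopifnot(length(k_new) == length(fit$sigma2))
  if (!is.null(line) && line %in% fit$lines)
    stop("held-out line is present in the training fit")
  pred <- fit$mu
  for (k in seq_along(k_new)) {
    v <- k_new[[k]]
    if (!is.null(names(v))) v <- v[fit$lines]
    pred <- pred + fit$sigma2[k] * sum(v * fit$Vi_r)
  }
  unname(pred)
}

#' Prediction accuracy
#'
#' Pearson correlation of predicted and observed values; 0 (with a
#' `degenerate` attribute and warning) when either vector is constant.
#'
#' @param predicted,observed numeric vectors of equal length >= 3.
#' @return correlation coefficient.
#' @export
accuracy <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(predicted) < 3) stop("need at least 3 pairs")
  if (sd(predicted) == 0 || sd(observed) == 0) {
    warning("constant predictions or observations; accuracy reported as 0")
    return(structure(0, degenerate = TRUE))
  }
  cor(predicted, observed)
}

# Build fold kernels: center/scale on training rows only, apply to all rows.
fold_kernel <- function(features, train, tag = "features") {
  Xtr <- features[train, , drop = FALSE]
  mu <- colMeans(Xtr)
  sds <- apply(Xtr, 2, sd)
  keep <- sds > 0 & !is.na(sds)
  if (!any(keep)) return(NULL)
  W <- sweep(sweep(features[, keep, drop = FALSE], 2, mu[keep]), 2,
             sds[keep], "/")
  structure(tcrossprod(W) / sum(keep), tag = tag, p = sum(keep),
            dimnames = list(rownames(features), rownames(features)))
}

#' Leave-one-out cross-validated kernel BLUP
#'
#' For each line: features are re-centered and re-scaled on the training
#' lines only, the kernel rebuilt, variance components re-estimated by REML
#' on the training lines, and the held-out line predicted from the estimated
#' cross-covariance.
#'
#' @param y named vector of line phenotypes.
#' @param feature_sets a line-by-feature matrix or a list of one or two such
#'   matrices (two-kernel model).
#' @param model label stored in the result.
#' @return a `cv_result`: data frame of per-line predictions, `accuracy`,
#'   `model`.
#' @export
loocv_blup <- function(y, feature_sets, model = "blup") {
  if (is.matrix(feature_sets) || is.data.frame(feature_sets))
    feature_sets <- list(as.matrix(feature_sets))
  lines <- names(y)
  stopifnot(!is.null(lines),
            all(vapply(feature_sets, function(f)
              identical(rownames(f), lines), TRUE)))
  n <- length(y)
  pred <- setNames(numeric(n), lines)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    Ks <- lapply(seq_along(feature_sets), function(k)
      fold_kernel(feature_sets[[k]], train,
                  tag = attr(feature_sets[[k]], "tag") %||% paste0("K", k)))
    if (any(vapply(Ks, is.null, TRUE))) { pred[i] <- mean(y[train]); next }
    fit <- fit_blup(y[train], lapply(Ks, function(K) K[train, train]))
    pred[i] <- predict_holdout(fit, lapply(Ks, function(K) K[i, train]),
                               line = lines[i])
  }
  cv_result(pred, y, model)
}

cv_result <- function(pred, obs, model) {
  acc <- suppressWarnings(accuracy(unname(pred), unname(obs)))
  structure(list(
    predictions = data.frame(line = names(obs), observed = unname(obs),
                             predicted = unname(pred)),
    accuracy = as.numeric(acc),
    degenerate = isTRUE(attr(acc, "degenerate")),
    model = model), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("LOOCV", x$model, "- n =", nrow(x$predictions),
      "accuracy r =", round(x$accuracy, 3), "\n")
  invisible(x)
}

# Vectorized per-feature simple-regression P-values (training lines only).
feature_regression_p <- function(y, X) {
  n <- length(y)
  r <- suppressWarnings(cor(y, X))
  r[is.na(r)] <- 0
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  as.vector(t_pvalue(tt, n - 2))
}

#' Combined MWAS-BLUP: fold-internal enrichment of the metabolite kernel
#'
#' At each leave-one-out round, a single-metabolite linear regression is run
#' in the training set; metabolites with P below each threshold are selected,
#' a kernel is built from them (training-fold centering/scaling), variance
#' components re-estimated, and the held-out line predicted. Selection never
#' sees the held-out line. Folds in which no metabolite passes fall back to
#' the training mean.
#'
#' @param y named vector of line phenotypes.
#' @param met_lm line-by-metabolite matrix of line means.
#' @param thresholds nominal selection thresholds.
#' @return named list of `cv_result`, one per threshold.
#' @export
mwas_enriched_loocv <- function(y, met_lm,
                                thresholds = c(0.5, 0.4, 0.3, 0.2, 0.1, 0.05)) {
  lines <- names(y)
  stopifnot(identical(rownames(met_lm), lines))
  n <- length(y)
  preds <- matrix(NA_real_, n, length(thresholds),
                  dimnames = list(lines, paste0("x", thresholds)))
  fallbacks <- 0L
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    pv <- feature_regression_p(y[train], met_lm[train, , drop = FALSE])
    for (j in seq_along(thresholds)) {
      sel <- which(pv < thresholds[j])
      if (length(sel) == 0) {
        preds[i, j] <- mean(y[train]); fallbacks <- fallbacks + 1L; next
      }
      K <- fold_kernel(met_lm[, sel, drop = FALSE], train, tag = "enriched")
      if (is.null(K)) { preds[i, j] <- mean(y[train]); next }
      fit <- fit_blup(y[train], K[train, train])
      preds[i, j] <- predict_holdout(fit, list(K[i, train]), line = lines[i])
    }
  }
  if (fallbacks > 0)
    message(fallbacks, " fold/threshold combinations fell back to the training mean")
  out <- lapply(seq_along(thresholds), function(j)
    cv_result(preds[, j], y, model = sprintf("mwas-blup x=%g", thresholds[j])))
  names(out) <- paste0("x", thresholds)
  out
}

#' Leave-one-out cross-validated elastic net with grid search
#'
#' For each `alpha` on the grid, glmnet is fit per fold along a shared lambda
#' path (50 values, 4 decades below the full-data lambda_max), and each
#' held-out line is predicted at every lambda. The reported model is the
#' `(alpha, lambda)` grid point with the highest LOOCV accuracy (non-nested
#' selection); `nested = TRUE` instead selects the grid point inside each
#' training fold (inner LOOCV) and reports the outer accuracy of that rule.
#'
#' @param y named vector of line phenotypes.
#' @param features line-by-feature matrix.
#' @param alpha_grid elastic-net mixing values in (0, 1].
#' @param nlambda number of lambda values.
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max.
#' @param nested use nested (fold-internal) grid selection.
#' @return a `cv_result` with `alpha`, `lambda`, and the full accuracy grid
#'   in `grid`.
#' @export
elastic_net_loocv <- function(y, features, alpha_grid = seq(0.05, 1, by = 0.05),
                              nlambda = 50, lambda_min_ratio = 1e-4,
                              nested = FALSE) {
  stopifnot(length(alpha_grid) > 0, all(alpha_grid > 0 & alpha_grid <= 1))
  X <- as.matrix(features)
  lines <- names(y)
  stopifnot(identical(rownames(X), lines))
  n <- length(y)
  # shared lambda path anchored at the smallest alpha (largest lambda_max)
  Xs <- scale(X); Xs[is.na(Xs)] <- 0
  lmax <- max(abs(crossprod(Xs, y - mean(y)))) / (n * min(alpha_grid))
  lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                     length.out = nlambda))
  pred_grid <- array(NA_real_, c(n, length(alpha_grid), nlambda))
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    for (a in seq_along(alpha_grid)) {
      fit <- glmnet::glmnet(X[train, , drop = FALSE], y[train],
                            alpha = alpha_grid[a], lambda = lambdas,
                            standardize = TRUE)
      pred_grid[i, a, ] <- as.vector(
        glmnet::predict.glmnet(fit, X[i, , drop = FALSE], s = lambdas))
    }
  }
  acc_grid <- matrix(NA_real_, length(alpha_grid), nlambda,
                     dimnames = list(paste0("alpha", alpha_grid), NULL))
  for (a in seq_along(alpha_grid)) for (l in seq_len(nlambda)) {
    pr <- pred_grid[, a, l]
    acc_grid[a, l] <- if (sd(pr) == 0) 0 else cor(pr, y)
  }
  if (!nested) {
    best <- arrayInd(which.max(acc_grid), dim(acc_grid))
    pr <- setNames(pred_grid[, best[1], best[2]], lines)
    out <- cv_result(pr, y, model = sprintf("enet alpha=%g lambda=%.4g",
                                            alpha_grid[best[1]],
                                            lambdas[best[2]]))
    out$alpha <- alpha_grid[best[1]]; out$lambda <- lambdas[best[2]]
    out$grid <- acc_grid; out$lambdas <- lambdas
    return(out)
  }
  # nested: inner LOOCV on each training fold picks (alpha, lambda)
  pr <- setNames(numeric(n), lines)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    inner <- matrix(NA_real_, length(alpha_grid), nlambda)
    inner_pred <- array(NA_real_, c(length(train), length(alpha_grid), nlambda))
    for (jj in seq_along(train)) {
      j <- train[jj]
      tr2 <- setdiff(train, j)
      for (a in seq_along(alpha_grid)) {
        fit <- glmnet::glmnet(X[tr2, , drop = FALSE], y[tr2],
                              alpha = alpha_grid[a], lambda = lambdas,
                              standardize = TRUE)
        inner_pred[jj, a, ] <- as.vector(
          glmnet::predict.glmnet(fit, X[j, , drop = FALSE], s = lambdas))
      }
    }
    for (a in seq_along(alpha_grid)) for (l in seq_len(nlambda)) {
      p2 <- inner_pred[, a, l]
      inner[a, l] <- if (sd(p2) == 0) 0 else cor(p2, y[train])
    }
    best <- arrayInd(which.max(inner), dim(inner))
    fit <- glmnet::glmnet(X[train, , drop = FALSE], y[train],
                          alpha = alpha_grid[best[1]], lambda = lambdas)
    pr[i] <- as.vector(glmnet::predict.glmnet(fit, X[i, , drop = FALSE],
                                              s = lambdas[best[2]]))
  }
  out <- cv_result(pr, y, model = "enet nested")
  out$grid <- acc_grid
  out
}
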