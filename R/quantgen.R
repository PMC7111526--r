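# Variance components and broad-sense heritability -------------------------
#
# Replicate-level model, both sexes:   Y = mu + L + S + LxS + e
# (line L and line-by-sex LxS random, sex S fixed)
# Reduced model, one sex:              Y = mu + L + e
#
# REML fits via lme4; for balanced designs the method-of-moments (expected
# mean squares) estimators are available both as a fast alternative and as
# the oracle the REML path is checked against. Broad-sense heritability is
# H2 = (sigma2_L + sigma2_LxS) / (sigma2_L + sigma2_LxS + sigma2_e).

#' Broad-sense heritability from variance components
#'
#' @param sigma2_L line variance (or a `varcomp` object).
#' @param sigma2_LxS line-by-sex interaction variance.
#' @param sigma2_e residual variance.
#' @return H2 in `[0, 1]`; 0 when the total variance is 0.
#' @export
heritability <- function(sigma2_L, sigma2_LxS = 0, sigma2_e = 0) {
  if (inherits(sigma2_L, "varcomp")) {
    vc <- sigma2_L
    return(heritability(vc$sigma2_L, vc$sigma2_LxS %||% 0, vc$sigma2_e))
  }
  if (is.na(sigma2_L) || is.na(sigma2_e)) return(NA_real_)
  if (sigma2_L < 0 || sigma2_LxS < 0 || sigma2_e < 0)
    stop("variance components must be non-negative")
  tot <- sigma2_L + sigma2_LxS + sigma2_e
  if (tot == 0) return(0)
  (sigma2_L + sigma2_LxS) / tot
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' @param p vector of P-values in `[0, 1]`.
#' @param fdr flag threshold on the adjusted values.
#' @return data frame with `p`, `q`, `significant`.
#' @export
bh_adjust <- function(p, fdr = 0.05) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("P-values must be in [0, 1] and non-missing")
  q <- p.adjust(p, method = "BH")
  data.frame(p = p, q = q, significant = q < fdr)
}

subset_analyte <- function(tbl, analyte) {
  stopifnot(all(c("line", "sex", "replicate", "analyte", "abundance") %in% names(tbl)))
  d <- tbl[tbl$analyte == analyte & !is.na(tbl$abundance), , drop = FALSE]
  if (nrow(d) == 0) stop("no observations for analyte ", analyte)
  d
}

# lme4's REML criterion (-2 restricted log-likelihood) for the null linear
# model y ~ X, needed for the boundary LRT when the only random term is
# dropped. Matches lme4::REMLcrit up to the same constant.
reml_crit_lm <- function(y, X) {
  n <- length(y); p <- ncol(X)
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  s2 <- rss / (n - p)
  (n - p) * log(2 * pi * s2) + (n - p) +
    determinant(crossprod(X), logarithm = TRUE)$modulus[1]
}

# P-value for dropping one random term: 50:50 mixture of chi2_0 and chi2_1.
lrt_boundary_p <- function(stat) {
  if (is.na(stat)) return(NA_real_)
  if (stat <= 0) return(1)
  0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
}

# Balanced two-way mixed ANOVA by expected mean squares. l lines, s sexes,
# r reps. E[MSE] = s2e; E[MS_LxS] = s2e + r*s2lxs; E[MS_L] = s2e + r*s2lxs +
# s*r*s2l. F_L = MS_L/MS_LxS, F_S = MS_S/MS_LxS, F_LxS = MS_LxS/MSE.
ems_full <- function(d) {
  l <- length(unique(d$line)); s <- length(unique(d$sex))
  r <- nrow(d) / (l * s)
  if (r != round(r)) stop("EMS estimators require a balanced design")
  gm <- mean(d$abundance)
  ml <- tapply(d$abundance, d$line, mean)
  ms <- tapply(d$abundance, d$sex, mean)
  mls <- tapply(d$abundance, list(d$line, d$sex), mean)
  ss_L <- s * r * sum((ml - gm)^2)
  ss_S <- l * r * sum((ms - gm)^2)
  ss_LS <- r * sum((sweep(sweep(mls, 1, ml), 2, ms) + gm)^2)
  ss_E <- sum((d$abundance - mls[cbind(d$line, d$sex)])^2)
  df <- c(L = l - 1, S = s - 1, LS = (l - 1) * (s - 1), E = l * s * (r - 1))
  MS <- c(L = ss_L, S = ss_S, LS = ss_LS, E = ss_E) / df
  sigma2_e <- MS["E"]
  sigma2_lxs <- max(0, (MS["LS"] - MS["E"]) / r)
  sigma2_l <- max(0, (MS["L"] - MS["LS"]) / (s * r))
  p_L <- pf_safe(MS["L"] / MS["LS"], df["L"], df["LS"])
  p_S <- pf_safe(MS["S"] / MS["LS"], df["S"], df["LS"])
  p_LxS <- if (df["E"] > 0) pf_safe(MS["LS"] / MS["E"], df["LS"], df["E"]) else NA_real_
  list(sigma2_L = unname(sigma2_l), sigma2_LxS = unname(sigma2_lxs),
       sigma2_e = unname(sigma2_e), p_L = p_L, p_S = p_S, p_LxS = p_LxS,
       MS = MS, df = df)
}

pf_safe <- function(f, df1, df2) {
  if (!is.finite(f)) return(if (is.nan(f)) 1 else 0)
  unname(stats::pf(f, df1, df2, lower.tail = FALSE))
}

ems_reduced <- function(d) {
  l <- length(unique(d$line))
  r <- nrow(d) / l
  if (r != round(r)) stop("EMS estimators require a balanced design")
  gm <- mean(d$abundance)
  ml <- tapply(d$abundance, d$line, mean)
  ss_L <- r * sum((ml - gm)^2)
  ss_E <- sum((d$abundance - ml[d$line])^2)
  df <- c(L = l - 1, E = l * (r - 1))
  MS <- c(L = ss_L, S = NA, LS = NA, E = ss_E) / c(df["L"], 1, 1, df["E"])
  names(MS) <- c("L", "S", "LS", "E")
  sigma2_e <- unname(MS["E"])
  sigma2_l <- max(0, unname((MS["L"] - MS["E"]) / r))
  p_L <- if (df["E"] > 0) pf_safe(MS["L"] / MS["E"], df["L"], df["E"]) else NA_real_
  list(sigma2_L = sigma2_l, sigma2_e = sigma2_e, p_L = p_L, MS = MS, df = df)
}

varcomp_record <- function(..., scope, method, converged = TRUE) {
  rec <- list(...)
  rec$scope <- scope; rec$method <- method; rec$converged <- converged
  rec$H2 <- heritability(rec$sigma2_L, rec$sigma2_LxS %||% 0, rec$sigma2_e)
  structure(rec, class = "varcomp")
}

#' Fit the full replicate-level model for one analyte
#'
#' `Y = mu + L + S + LxS + e` with line and line-by-sex random and sex fixed.
#' REML estimates are constrained non-negative; random-term P-values come
#' from restricted likelihood-ratio tests against the model without the term
#' using the 50:50 `chi2_0`/`chi2_1` boundary mixture, and the fixed sex
#' effect from a t test with `n_lines - 1` denominator degrees of freedom.
#' `method = "ems"` instead uses the balanced-design expected-mean-squares
#' estimators with their exact F tests.
#'
#' @param tbl replicate table (line, sex, replicate, analyte, abundance).
#' @param analyte analyte id to fit.
#' @param method `"reml"` (default) or `"ems"` (balanced designs only).
#' @param tests compute P-values (REML path refits the model; skipping them
#'   is much faster when only variances and H2 are needed).
#' @return a `varcomp` object: sigma2_L, sigma2_LxS, sigma2_e, p_L, p_S,
#'   p_LxS, H2, n_lines, converged.
#' @export
fit_full_model <- function(tbl, analyte, method = c("reml", "ems"), tests = TRUE) {
  method <- match.arg(method)
  d <- subset_analyte(tbl, analyte)
  d$line <- factor(d$line); d$sex <- factor(d$sex)
  if (nlevels(d$line) < 2) stop("need at least 2 lines")
  if (nlevels(d$sex) < 2) stop("need both sexes for the full model")
  n_lines <- nlevels(d$line)
  if (var(d$abundance) == 0)
    return(varcomp_record(analyte = analyte, sigma2_L = 0, sigma2_LxS = 0,
                          sigma2_e = 0, p_L = 1, p_S = 1, p_LxS = 1,
                          n_lines = n_lines, scope = "full", method = method))
  if (method == "ems") {
    e <- ems_full(d)
    return(varcomp_record(analyte = analyte, sigma2_L = e$sigma2_L,
                          sigma2_LxS = e$sigma2_LxS, sigma2_e = e$sigma2_e,
                          p_L = e$p_L, p_S = e$p_S, p_LxS = e$p_LxS,
                          n_lines = n_lines, scope = "full", method = method))
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      abundance ~ sex + (1 | line) + (1 | line:sex), data = d,
      REML = TRUE, control = ctrl)),
    error = function(e) NULL)
  if (is.null(fit))
    return(varcomp_record(analyte = analyte, sigma2_L = NA_real_,
                          sigma2_LxS = NA_real_, sigma2_e = NA_real_,
                          p_L = NA_real_, p_S = NA_real_, p_LxS = NA_real_,
                          n_lines = n_lines, scope = "full", method = method,
                          converged = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2 <- setNames(vc$vcov, vc$grp)
  p_L <- p_S <- p_LxS <- NA_real_
  if (tests) {
    crit_full <- lme4::REMLcrit(fit)
    drop_crit <- function(form) {
      f2 <- tryCatch(suppressMessages(lme4::lmer(form, data = d, REML = TRUE,
                                                 control = ctrl)),
                     error = function(e) NULL)
      if (is.null(f2)) NA_real_ else lme4::REMLcrit(f2)
    }
    p_L <- lrt_boundary_p(drop_crit(abundance ~ sex + (1 | line:sex)) - crit_full)
    p_LxS <- lrt_boundary_p(drop_crit(abundance ~ sex + (1 | line)) - crit_full)
    cf <- summary(fit)$coefficients
    tS <- cf[2, "t value"]
    p_S <- t_pvalue(tS, df = n_lines - 1)
  }
  varcomp_record(analyte = analyte, sigma2_L = unname(s2["line"]),
                 sigma2_LxS = unname(s2["line:sex"]),
                 sigma2_e = unname(s2["Residual"]),
                 p_L = p_L, p_S = p_S, p_LxS = p_LxS,
                 n_lines = n_lines, scope = "full", method = method)
}

#' Fit the reduced one-sex model for one analyte
#'
#' `Y = mu + L + e` within one sex; see [fit_full_model()] for estimation
#' and testing details.
#'
#' @inheritParams fit_full_model
#' @param sex `"F"` or `"M"`.
#' @return a `varcomp` object with sigma2_L, sigma2_e, p_L, H2.
#' @export
fit_reduced_model <- function(tbl, analyte, sex, method = c("reml", "ems"),
                              tests = TRUE) {
  method <- match.arg(method)
  d <- subset_analyte(tbl, analyte)
  d <- d[d$sex == sex, , drop = FALSE]
  if (nrow(d) == 0) stop("no observations for sex ", sex)
  d$line <- factor(d$line)
  if (nlevels(d$line) < 2) stop("need at least 2 lines")
  n_lines <- nlevels(d$line)
  if (var(d$abundance) == 0)
    return(varcomp_record(analyte = analyte, sigma2_L = 0, sigma2_e = 0,
                          p_L = 1, n_lines = n_lines, scope = sex,
                          method = method))
  if (method == "ems") {
    e <- ems_reduced(d)
    return(varcomp_record(analyte = analyte, sigma2_L = e$sigma2_L,
                          sigma2_e = e$sigma2_e, p_L = e$p_L,
                          n_lines = n_lines, scope = sex, method = method))
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- tryCatch(
    suppressMessages(lme4::lmer(abundance ~ (1 | line), data = d,
                                REML = TRUE, control = ctrl)),
    error = function(e) NULL)
  if (is.null(fit))
    return(varcomp_record(analyte = analyte, sigma2_L = NA_real_,
                          sigma2_e = NA_real_, p_L = NA_real_,
                          n_lines = n_lines, scope = sex, method = method,
                          converged = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2 <- setNames(vc$vcov, vc$grp)
  p_L <- NA_real_
  if (tests) {
    crit_null <- reml_crit_lm(d$abundance, matrix(1, nrow(d), 1))
    p_L <- lrt_boundary_p(crit_null - lme4::REMLcrit(fit))
  }
  varcomp_record(analyte = analyte, sigma2_L = unname(s2["line"]),
                 sigma2_e = unname(s2["Residual"]), p_L = p_L,
                 n_lines = n_lines, scope = sex, method = method)
}

#' Variance components for all analytes, with FDR flags
#'
#' Fits [fit_full_model()] (scope "full") or [fit_reduced_model()] (scope
#' "F"/"M") per analyte and appends Benjamini-Hochberg q-values and a
#' genetic-variability flag on the line term.
#'
#' @param tbl replicate table.
#' @param scope "full", "F", or "M".
#' @param fdr FDR level for the flag.
#' @inheritParams fit_full_model
#' @return data frame, one row per analyte.
#' @export
varcomp_table <- function(tbl, scope = c("full", "F", "M"), fdr = 0.05,
                          method = c("reml", "ems"), tests = TRUE) {
  scope <- match.arg(scope); method <- match.arg(method)
  analytes <- sort(unique(tbl$analyte))
  rows <- lapply(analytes, function(a) {
    vc <- if (scope == "full") fit_full_model(tbl, a, method, tests)
          else fit_reduced_model(tbl, a, scope, method, tests)
    data.frame(analyte = a, scope = scope,
               sigma2_L = vc$sigma2_L, sigma2_LxS = vc$sigma2_LxS %||% NA_real_,
               sigma2_e = vc$sigma2_e,
               p_L = vc$p_L, p_S = vc$p_S %||% NA_real_,
               p_LxS = vc$p_LxS %||% NA_real_,
               H2 = vc$H2, converged = vc$converged)
  })
  out <- do.call(rbind, rows)
  if (tests) {
    ok <- !is.na(out$p_L)
    out$q_L <- NA_real_; out$variable <- NA
    if (any(ok)) {
      adj <- bh_adjust(out$p_L[ok], fdr)
      out$q_L[ok] <- adj$q
      out$variable[ok] <- adj$significant
    }
  }
  out
}

#' Line means per sex
#'
#' Arithmetic mean over replicates for one sex; missing replicates are
#' skipped, and an entry is missing only if all replicates are missing.
#'
#' @param tbl replicate table.
#' @param sex "F" or "M".
#' @return line-by-analyte matrix.
#' @export
line_means <- function(tbl, sex) {
  stopifnot(all(c("line", "sex", "analyte", "abundance") %in% names(tbl)))
  d <- tbl[tbl$sex == sex, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for sex ", sex)
  m <- tapply(d$abundance, list(d$line, d$analyte), mean, na.rm = TRUE)
  nmiss <- sum(is.nan(m))
  if (nmiss > 0) {
    message(nmiss, " line/analyte cells have no non-missing replicates")
    m[is.nan(m)] <- NA_real_
  }
  m[, order(colnames(m)), drop = FALSE]
}
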