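# Statistical comparison pipeline: log-standardization of skewed imaging
# metrics, correlation matrices, covariate-adjusted univariate OLS, ridge
# regression with a data-driven penalty, nested-model likelihood ratio
# tests, biomarker preprocessing, and the heterogeneity-phenotype scan.

#' Log-transform, center and scale a metric column
#'
#' `z = (ln(x + c) - mean) / sd`. Imaging metrics are right-skewed, so they
#' are natural-log transformed before centering/scaling; standardization
#' puts all metrics on a common scale so regression coefficients are
#' directly comparable. If the column contains zeros, an offset `c` equal
#' to half the smallest positive value is applied (and recorded);
#' otherwise `c = 0`.
#'
#' @param values Non-negative numeric vector.
#' @return List with `z` (mean 0, sd 1), `offset`, `log_mean`, `log_sd`.
#' @export
log_standardize <- function(values) {
  values <- as.numeric(values)
  if (any(values < 0, na.rm = TRUE)) stop("values must be non-negative")
  offset <- 0
  if (any(values == 0, na.rm = TRUE)) {
    pos <- values[values > 0 & !is.na(values)]
    if (length(pos) == 0L) stop("all values are zero; cannot standardize")
    offset <- min(pos) / 2
  }
  lx <- log(values + offset)
  s <- stats::sd(lx, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("constant column; standard deviation is zero")
  m <- mean(lx, na.rm = TRUE)
  list(z = (lx - m) / s, offset = offset, log_mean = m, log_sd = s)
}

#' Pearson and Spearman correlation matrices of metric columns
#'
#' Pairwise-complete observations; both matrices are symmetric with unit
#' diagonal.
#'
#' @param metrics Data frame (or matrix) of numeric metric columns.
#' @return List with `pearson` and `spearman` matrices.
#' @export
correlation_matrix <- function(metrics) {
  m <- as.matrix(metrics)
  if (!is.numeric(m)) stop("'metrics' must be numeric columns")
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    stop("constant column(s): ", paste(colnames(m)[!is.finite(sds) | sds == 0],
                                       collapse = ", "))
  list(pearson = stats::cor(m, use = "pairwise.complete.obs", method = "pearson"),
       spearman = stats::cor(m, use = "pairwise.complete.obs", method = "spearman"))
}

# Build the covariate model frame used by every clinical model.
covariate_frame <- function(cohort) {
  data.frame(age = cohort$age,
             sex_male = as.numeric(cohort$sex == "male"),
             bmi = cohort$bmi, height = cohort$height,
             smoker = as.numeric(cohort$smoker))
}

#' Covariate-adjusted univariate regression of an outcome on one metric
#'
#' Ordinary least squares of the outcome on the standardized (log) metric
#' plus the demographic adjustment set (age, sex, BMI, height, current
#' smoking). The reported coefficient is the standardized coefficient for
#' the metric.
#'
#' @param outcome Numeric outcome vector.
#' @param metric_z Standardized metric column (see [log_standardize()]).
#' @param covariates Data frame of adjustment covariates.
#' @return Object of class `regression_result`: `coef`, `se`, `p_value`,
#'   `r_squared`, `adj_r_squared`, `n`, `term`, `formula`.
#' @export
fit_univariate <- function(outcome, metric_z, covariates) {
  df <- data.frame(y = outcome, metric = metric_z, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  p <- ncol(df) - 1L
  if (nrow(df) < p + 2L) stop("too few complete cases")
  X <- stats::model.matrix(~ ., data = df[, -1, drop = FALSE])
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  co <- sm$coefficients["metric", ]
  structure(list(coef = unname(co[1]), se = unname(co[2]),
                 p_value = unname(co[4]), r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared, n = nrow(df),
                 term = "metric", formula = "y ~ metric + age + sex + bmi + height + smoker"),
            class = "regression_result")
}

#' Ridge penalty estimators
#'
#' Data-driven choices of the ridge constant `k` computed from the OLS fit
#' on the standardized design: per-coefficient candidates
#' `k_i = sigma^2 / beta_i^2` combined by different rules. Implemented
#' methods: `"HK"` (largest-coefficient rule `sigma^2 / max beta_i^2`),
#' `"HKB"` (`p * sigma^2 / sum(beta_i^2)`), `"LW"`
#' (`p * sigma^2 / sum((X beta)^2)`-style Lawless-Wang rule), `"KAM"`
#' (arithmetic mean of `k_i`), `"KGM"` (geometric mean of `k_i`; default),
#' `"KMED"` (median of `k_i`), `"MK-max"` (max of `1 / m_i` with
#' `m_i = sqrt(k_i)`), `"MK-gm"` (geometric mean of `1 / m_i`). The method
#' tag is recorded in every downstream result.
#'
#' @param design Numeric matrix of standardized predictors (no intercept
#'   column).
#' @param response Numeric response vector.
#' @param method Estimator tag; see above.
#' @return `k >= 0` with attribute `method`.
#' @export
estimate_ridge_k <- function(design, response,
                             method = c("KGM", "HK", "HKB", "LW", "KAM",
                                        "KMED", "MK-max", "MK-gm")) {
  method <- match.arg(method)
  X <- as.matrix(design)
  y <- as.numeric(response) - mean(response)
  n <- nrow(X); p <- ncol(X)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  if (anyNA(beta)) stop("rank-deficient design; cannot estimate ridge k")
  sigma2 <- sum(fit$residuals^2) / (n - p - 1L)
  ki <- sigma2 / beta^2
  mi <- sqrt(ki)
  k <- switch(method,
    "HK" = sigma2 / max(beta^2),
    "HKB" = p * sigma2 / sum(beta^2),
    "LW" = {
      lam <- eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values
      p * sigma2 / sum(lam * beta^2)
    },
    "KAM" = mean(ki),
    "KGM" = exp(mean(log(ki))),
    "KMED" = stats::median(ki),
    "MK-max" = max(1 / mi),
    "MK-gm" = exp(mean(log(1 / mi))))
  structure(k, method = method)
}

#' Ridge regression with standardized predictors
#'
#' `beta = (X'X + kI)^{-1} X'y` with the penalty applied to all slopes and
#' never to the intercept (predictors are z-scored internally; the
#' response is centered, and the intercept is its mean). Standard errors
#' use the sandwich form
#' `sigma^2 (X'X + kI)^{-1} X'X (X'X + kI)^{-1}`; t-tests use
#' `n - p - 1` degrees of freedom, and the adjusted R^2 uses the raw
#' predictor count.
#'
#' @param outcome Numeric response.
#' @param predictors Data frame / matrix of predictors (metric z-columns
#'   first, then covariates); standardized internally.
#' @param k Ridge constant (>= 0), e.g. from [estimate_ridge_k()].
#' @return Object of class `ridge_fit`: `coefficients` table (term,
#'   estimate, se, t, p), `k`, `k_method`, `r_squared`, `adj_r_squared`,
#'   `n`, `sigma2`.
#' @export
fit_ridge <- function(outcome, predictors, k = 0) {
  if (k < 0) stop("'k' must be non-negative")
  df <- data.frame(y = outcome, predictors)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  y <- df$y
  X <- as.matrix(df[, -1, drop = FALSE])
  n <- nrow(X); p <- ncol(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant predictor column")
  Xs <- scale(X)
  yc <- y - mean(y)
  XtX <- crossprod(Xs)
  A <- XtX + diag(k, p)
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("singular penalized design (k = ", k, ")"))
  beta <- drop(Ainv %*% crossprod(Xs, yc))
  fitted <- drop(Xs %*% beta)
  rss <- sum((yc - fitted)^2)
  sigma2 <- rss / (n - p - 1L)
  V <- sigma2 * Ainv %*% XtX %*% Ainv
  se <- sqrt(diag(V))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p - 1L)
  tss <- sum(yc^2)
  r2 <- 1 - rss / tss
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = beta, se = se,
                              t = tval, p_value = pval,
                              stringsAsFactors = FALSE, row.names = NULL),
    k = as.numeric(k), k_method = attr(k, "method"),
    r_squared = r2, adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - p - 1),
    n = n, sigma2 = sigma2), class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat("<ridge_fit> k = ", signif(x$k, 4), ", n = ", x$n,
      ", adj R^2 = ", signif(x$adj_r_squared, 4), "\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Adjusted R-squared gain from adding the cluster-size metric
#'
#' Fits two ridge models — the full metric set and the set without ACS —
#' each with its own estimated ridge constant, and reports both adjusted
#' R^2 values and their difference.
#'
#' @param outcome Numeric response.
#' @param full_predictors,reduced_predictors Predictor data frames (metric
#'   z-columns plus covariates) for the full and reduced models.
#' @param method Ridge-k estimator tag, see [estimate_ridge_k()].
#' @return List with `adj_r2_full`, `adj_r2_reduced`, `gain`, `k_full`,
#'   `k_reduced`.
#' @export
adjusted_r2_gain <- function(outcome, full_predictors, reduced_predictors,
                             method = "KGM") {
  cc <- stats::complete.cases(data.frame(y = outcome, full_predictors))
  y <- outcome[cc]
  Xf <- scale(as.matrix(full_predictors[cc, , drop = FALSE]))
  Xr <- scale(as.matrix(reduced_predictors[cc, , drop = FALSE]))
  kf <- estimate_ridge_k(Xf, y, method = method)
  kr <- if (identical(colnames(Xf), colnames(Xr))) kf else
    estimate_ridge_k(Xr, y, method = method)
  ff <- fit_ridge(y, as.data.frame(Xf), k = kf)
  fr <- fit_ridge(y, as.data.frame(Xr), k = kr)
  gain <- if (identical(colnames(Xf), colnames(Xr))) 0 else
    ff$adj_r_squared - fr$adj_r_squared
  list(adj_r2_full = ff$adj_r_squared, adj_r2_reduced = fr$adj_r_squared,
       gain = gain, k_full = as.numeric(kf), k_reduced = as.numeric(kr))
}

#' Likelihood ratio test between nested regression models
#'
#' For Gaussian `lm` fits the maximum-likelihood statistic
#' `n * ln(RSS_reduced / RSS_full)` is used; for `glm` fits the deviance
#' difference. The reference distribution is chi-square with degrees of
#' freedom equal to the parameter-count difference.
#'
#' @param full,reduced Fitted `lm` or `glm` models on the same rows, with
#'   the reduced model nested in the full one.
#' @return Object of class `lrt_result`: `statistic`, `df`, `p_value`,
#'   `full`, `reduced` (formula descriptors).
#' @export
likelihood_ratio_test <- function(full, reduced) {
  n_full <- stats::nobs(full)
  if (n_full != stats::nobs(reduced))
    stop("models were fit on different row sets")
  p_full <- length(stats::coef(full)) - sum(is.na(stats::coef(full)))
  p_red <- length(stats::coef(reduced)) - sum(is.na(stats::coef(reduced)))
  if (p_full < p_red) stop("'reduced' has more parameters than 'full'")
  df <- p_full - p_red
  is_glm <- inherits(full, "glm")
  if (is_glm != inherits(reduced, "glm"))
    stop("models must be of the same family")
  if (is_glm) {
    stat <- reduced$deviance - full$deviance
  } else {
    rss_f <- sum(stats::residuals(full)^2)
    rss_r <- sum(stats::residuals(reduced)^2)
    stat <- n_full * log(rss_r / rss_f)
  }
  stat <- max(stat, 0)
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = max(df, 1L), p_value = p,
                 full = deparse(stats::formula(full)),
                 reduced = deparse(stats::formula(reduced))),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("<lrt> X2 = ", signif(x$statistic, 4), ", df = ", x$df,
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Classify and transform plasma biomarkers by LLOQ censoring
#'
#' Markers with more than 95% of values below their lower limit of
#' quantitation are excluded; markers with a below-LLOQ fraction in
#' (0.10, 0.95] become binary present/absent indicators; the remainder are
#' given an empirical normal quantile transform,
#' `qnorm((rank - 0.5) / n)`, with average ranks for ties and below-LLOQ
#' values occupying the lowest ranks (any constant reported below the LLOQ
#' gives the same result).
#'
#' @param raw Data frame of raw abundances, one column per marker.
#' @param lloq Data frame with columns `marker` and `lloq`.
#' @return Object of class `biomarker_set`: `values` (transformed data
#'   frame; excluded markers dropped), `class` (named character:
#'   excluded/binary/continuous), `below_frac` (named numeric).
#' @export
preprocess_biomarkers <- function(raw, lloq) {
  raw <- as.data.frame(raw)
  if (!all(c("marker", "lloq") %in% names(lloq)))
    stop("'lloq' needs columns 'marker' and 'lloq'")
  missing_lloq <- setdiff(names(raw), lloq$marker)
  if (length(missing_lloq) > 0L)
    stop("missing LLOQ for marker(s): ", paste(missing_lloq, collapse = ", "))
  lim <- stats::setNames(lloq$lloq, lloq$marker)
  classes <- character(0)
  fracs <- numeric(0)
  out <- list()
  for (m in names(raw)) {
    v <- raw[[m]]
    below <- v < lim[[m]]
    frac <- mean(below, na.rm = TRUE)
    fracs[m] <- frac
    if (frac > 0.95) {
      classes[m] <- "excluded"
    } else if (frac > 0.10) {
      classes[m] <- "binary"
      out[[m]] <- as.numeric(!below)  # 1 = present (quantifiable)
    } else {
      classes[m] <- "continuous"
      vv <- v
      vv[below] <- min(v, na.rm = TRUE) - 1  # ties at the bottom rank
      r <- rank(vv, ties.method = "average", na.last = "keep")
      out[[m]] <- stats::qnorm((r - 0.5) / sum(!is.na(vv)))
    }
  }
  structure(list(values = as.data.frame(out), class = classes,
                 below_frac = fracs), class = "biomarker_set")
}

#' Emphysema-heterogeneity-phenotype biomarker scan
#'
#' For every preprocessed marker (as outcome), three nested models are
#' fit: a base model with demographics plus the standardized burden
#' (%LAA); the base model plus the two-variable heterogeneity phenotype
#' EHP2 = {NJC, D}; and the base model plus the four-variable
#' EHP4 = {NJC, D, ACS, NC}. Linear regression is used for continuous
#' markers and logistic regression for binary ones. Likelihood ratio tests
#' of each expanded model against the base give two p-value columns, each
#' adjusted separately by Benjamini-Hochberg; significance is flagged at
#' the given FDR.
#'
#' @param cohort Cohort data frame with demographics and metric columns
#'   `pct_laa`, `njc`, `d`, `acs`, `nc`.
#' @param markers A `biomarker_set` from [preprocess_biomarkers()].
#' @param fdr False discovery rate threshold (default 0.10).
#' @return Object of class `biomarker_scan`: data frame `results` with one
#'   row per scanned marker (class, p/q-values and significance flags for
#'   EHP2 and EHP4), plus `n_ehp2_hits`, `n_ehp4_hits`, `fdr`.
#' @export
run_ehp_biomarker_scan <- function(cohort, markers, fdr = 0.10) {
  stopifnot(inherits(markers, "biomarker_set"))
  covs <- covariate_frame(cohort)
  z <- lapply(cohort[c("pct_laa", "njc", "d", "acs", "nc")],
              function(x) log_standardize(x)$z)
  base_df <- data.frame(covs, z_laa = z$pct_laa)
  ehp2_df <- data.frame(base_df, z_njc = z$njc, z_d = z$d)
  ehp4_df <- data.frame(ehp2_df, z_acs = z$acs, z_nc = z$nc)
  scanned <- names(markers$values)
  skipped <- names(markers$class)[markers$class == "excluded"]
  if (length(skipped) > 0L)
    message("skipping excluded marker(s): ", paste(skipped, collapse = ", "))
  res <- lapply(scanned, function(m) {
    y <- markers$values[[m]]
    binary <- markers$class[[m]] == "binary"
    cc <- stats::complete.cases(data.frame(y, ehp4_df))
    fit_one <- function(df) {
      d <- data.frame(y = y, df)[cc, , drop = FALSE]
      if (binary) stats::glm(y ~ ., data = d, family = stats::binomial())
      else stats::lm(y ~ ., data = d)
    }
    m_base <- fit_one(base_df)
    p2 <- likelihood_ratio_test(fit_one(ehp2_df), m_base)$p_value
    p4 <- likelihood_ratio_test(fit_one(ehp4_df), m_base)$p_value
    data.frame(marker = m, class = markers$class[[m]],
               p_ehp2 = p2, p_ehp4 = p4, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_ehp2 <- bh_adjust(res$p_ehp2)
  res$q_ehp4 <- bh_adjust(res$p_ehp4)
  res$sig_ehp2 <- res$q_ehp2 < fdr
  res$sig_ehp4 <- res$q_ehp4 < fdr
  structure(list(results = res, n_ehp2_hits = sum(res$sig_ehp2),
                 n_ehp4_hits = sum(res$sig_ehp4), fdr = fdr,
                 skipped = skipped), class = "biomarker_scan")
}

#' @export
print.biomarker_scan <- function(x, ...) {
  cat("<biomarker_scan> ", nrow(x$results), " markers; EHP2 hits ",
      x$n_ehp2_hits, ", EHP4 hits ", x$n_ehp4_hits, " at FDR ", x$fdr,
      "\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; `q >= p` elementwise and the output is
#' invariant to input order.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(!is.na(p) & (p <= 0 | p > 1))) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}
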