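test_that("log-standardization centers, scales, and offsets zeros", {
  set.seed(51)
  x <- exp(rnorm(200, 1, 0.8))
  z <- log_standardize(x)
  expect_equal(mean(z$z), 0, tolerance = 1e-12)
  expect_equal(sd(z$z), 1, tolerance = 1e-12)
  expect_equal(z$offset, 0)
  x0 <- c(0, 1, 2, 4, 8)
  z0 <- log_standardize(x0)
  expect_equal(z0$offset, 0.5)
  expect_equal(mean(z0$z), 0, tolerance = 1e-12)
  expect_error(log_standardize(rep(3, 10)), "constant")
  expect_error(log_standardize(c(-1, 2)), "non-negative")
})

test_that("log transform improves normality of lognormal samples", {
  set.seed(52)
  raw_p <- replicate(200, shapiro.test(exp(rnorm(50, 0, 1)))$p.value)
  log_p <- replicate(200, shapiro.test(log_standardize(exp(rnorm(50, 0, 1)))$z)$p.value)
  expect_gt(mean(log_p > 0.05), mean(raw_p > 0.05))
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(53)
  df <- data.frame(a = rnorm(50))
  df$b <- -df$a
  df$c <- rnorm(50)
  cm <- correlation_matrix(df)
  expect_equal(diag(cm$pearson), c(a = 1, b = 1, c = 1))
  expect_equal(cm$pearson["a", "b"], -1)
  expect_equal(cm$spearman["a", "b"], -1)
  expect_identical(cm$pearson, t(cm$pearson))
  df$k <- 1
  expect_error(correlation_matrix(df), "constant")
})

test_that("univariate OLS recovers a planted standardized coefficient", {
  set.seed(54)
  n <- 1000
  covs <- data.frame(age = rnorm(n, 60, 8), sex_male = rbinom(n, 1, 0.5),
                     bmi = rnorm(n, 28, 5), height = rnorm(n, 170, 9),
                     smoker = rbinom(n, 1, 0.25))
  z <- scale(rnorm(n))[, 1]
  y <- 2 * z + 0.01 * covs$age + rnorm(n, 0, 0.01)
  r <- fit_univariate(y, z, covs)
  expect_equal(r$coef, 2, tolerance = 0.01)
  expect_gt(r$r_squared, 0.99)
  expect_equal(r$n, n)
  # duplicated covariate -> rank-deficient design
  covs_bad <- cbind(covs, age2 = covs$age)
  expect_error(fit_univariate(y, z, covs_bad), "rank-deficient")
})

test_that("ridge-k estimators include the HKB closed form and reject unknowns", {
  set.seed(55)
  n <- 60
  X <- scale(matrix(rnorm(n * 3), n, 3))
  beta <- c(1, -2, 0.5)
  y <- drop(X %*% beta) + rnorm(n, 0, 1)
  ols <- lm.fit(X, y - mean(y))
  sigma2 <- sum(ols$residuals^2) / (n - 3 - 1)
  expect_equal(as.numeric(estimate_ridge_k(X, y, method = "HKB")),
               3 * sigma2 / sum(ols$coefficients^2), tolerance = 1e-12)
  expect_equal(as.numeric(estimate_ridge_k(X, y, method = "KGM")),
               exp(mean(log(sigma2 / ols$coefficients^2))), tolerance = 1e-12)
  expect_error(estimate_ridge_k(X, y, method = "unknown"))
  # huge true coefficients relative to noise -> k small
  y_big <- drop(X %*% (beta * 100)) + rnorm(n, 0, 1)
  expect_lt(as.numeric(estimate_ridge_k(X, y_big, method = "HKB")), 0.01)
})

test_that("ridge with k = 0 equals OLS and shrinks monotonically with k", {
  set.seed(56)
  n <- 80
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  X$b <- X$b + 0.8 * X$a  # correlated design
  y <- 1.5 * X$a - 1 * X$b + 0.3 * X$c + rnorm(n, 0, 0.7)
  ridge0 <- fit_ridge(y, X, k = 0)
  Xs <- scale(as.matrix(X))
  ols <- lm(I(y - mean(y)) ~ Xs - 1)
  expect_equal(ridge0$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-10)
  norms <- vapply(c(0, 1, 5, 20, 100, 1000), function(k)
    sqrt(sum(fit_ridge(y, X, k)$coefficients$estimate^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[length(norms)], 0.05 * norms[1])
  expect_error(fit_ridge(y, X, k = -1), "non-negative")
})

test_that("adjusted R^2 gain is zero for identical sets and positive for real effects", {
  set.seed(57)
  n <- 300
  z <- as.data.frame(scale(matrix(rnorm(n * 4), n, 4)))
  names(z) <- c("pct_laa", "d", "njc", "acs")
  covs <- data.frame(age = rnorm(n))
  y <- 2 * z$acs + 0.3 * z$d + rnorm(n)
  full <- data.frame(z, covs)
  red <- data.frame(z[c("pct_laa", "d", "njc")], covs)
  g <- adjusted_r2_gain(y, full, red)
  expect_gt(g$gain, 0)
  g0 <- adjusted_r2_gain(y, full, full)
  expect_identical(g0$gain, 0)
  # no ACS effect -> gain near zero
  y_null <- 0.5 * z$d + rnorm(n)
  g_null <- adjusted_r2_gain(y_null, full, red)
  expect_lt(abs(g_null$gain), 0.05)
})

test_that("likelihood ratio tests handle nesting, identity, and factor df", {
  set.seed(58)
  n <- 200
  df <- data.frame(y = rnorm(n), x = rnorm(n),
                   g = factor(sample(c("absent", "trace", "mild", "moderate",
                                       "confluent", "advanced"), n, TRUE)))
  full <- lm(y ~ x + g, df)
  red <- lm(y ~ x, df)
  r <- likelihood_ratio_test(full, red)
  expect_equal(r$df, 5L)  # 6-level factor dropped -> 5 df
  expect_gte(r$statistic, 0)
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(likelihood_ratio_test(red, full), "more parameters")
  red2 <- lm(y ~ x, df[1:100, ])
  expect_error(likelihood_ratio_test(full, red2), "different row")
  glm_full <- glm(I(y > 0) ~ x + g, df, family = binomial())
  glm_red <- glm(I(y > 0) ~ x, df, family = binomial())
  rg <- likelihood_ratio_test(glm_full, glm_red)
  expect_equal(rg$statistic, glm_red$deviance - glm_full$deviance)
  expect_error(likelihood_ratio_test(glm_full, red), "family")
})

test_that("biomarker preprocessing applies the LLOQ classification rules", {
  set.seed(59)
  n <- 100
  raw <- data.frame(
    excl = c(rep(0.1, 97), 5, 6, 7),          # 97% below LLOQ = 1
    bin = c(rep(0.1, 50), rnorm(50, 5)),      # 50% below
    cont = rnorm(n, 10, 2))                   # none below
  lloq <- data.frame(marker = c("excl", "bin", "cont"), lloq = c(1, 1, 0))
  mk <- preprocess_biomarkers(raw, lloq)
  expect_equal(unname(mk$class[c("excl", "bin", "cont")]),
               c("excluded", "binary", "continuous"))
  expect_false("excl" %in% names(mk$values))
  expect_setequal(unique(mk$values$bin), c(0, 1))
  expect_error(preprocess_biomarkers(raw, lloq[1:2, ]), "missing LLOQ")
})

test_that("the normal quantile transform maps 5 distinct values to known z-scores", {
  raw <- data.frame(m = c(30, 10, 50, 20, 40))
  lloq <- data.frame(marker = "m", lloq = 0)
  mk <- preprocess_biomarkers(raw, lloq)
  expect_equal(sort(mk$values$m), qnorm(c(0.1, 0.3, 0.5, 0.7, 0.9)),
               tolerance = 1e-12)
  # any constant below the LLOQ yields the same transform
  raw2 <- data.frame(m = c(0.01, 0.4, 3, 4, 5))
  raw3 <- data.frame(m = c(0.2, 0.39, 3, 4, 5))
  lloq2 <- data.frame(marker = "m", lloq = 0.5)
  expect_equal(preprocess_biomarkers(raw2, lloq2)$values$m,
               preprocess_biomarkers(raw3, lloq2)$values$m)
})

test_that("BH adjustment reproduces the step-up toy case and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.01, 0.8, 0.04)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p[perm]), q[perm])
  expect_error(bh_adjust(c(0, 0.5)), "0, 1")
  # discoveries non-increasing as the threshold tightens
  expect_true(sum(q < 0.05) <= sum(q < 0.10))
})

test_that("the EHP scan separates effect routes and is column-permutation safe", {
  sim <- simulate_cohort(cohort_spec(n_subjects = 350), seed = 60)
  mk <- preprocess_biomarkers(sim$biomarkers, sim$lloq)
  scan <- run_ehp_biomarker_scan(sim$cohort, mk)
  expect_true(all(scan$results$q_ehp2 >= scan$results$p_ehp2))
  expect_true(all(scan$results$sig_ehp4 == (scan$results$q_ehp4 < 0.10)))
  # permuting marker columns permutes results identically
  permuted <- mk
  ord <- rev(names(mk$values))
  permuted$values <- mk$values[ord]
  permuted$class <- mk$class[c(ord, setdiff(names(mk$class), ord))]
  scan_p <- run_ehp_biomarker_scan(sim$cohort, permuted)
  merged <- merge(scan$results, scan_p$results, by = "marker")
  expect_equal(merged$p_ehp2.x, merged$p_ehp2.y)
  expect_equal(merged$p_ehp4.x, merged$p_ehp4.y)
})
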