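test_that("homogeneous likelihood reproduces the closed form", {
  w <- rect_window(10, 10, c(0.5, 0.5))  # |W| = 100 mm^2
  set.seed(41)
  pts <- cbind(runif(10, 0, 10), runif(10, 0, 10))
  p <- slice_pattern(pts, w$window, w$spacing)
  expect_equal(sncp_log_likelihood(p, sncp_state(epsilon = 0.5)),
               10 * log(0.5) - 50, tolerance = 1e-12)
  expect_identical(sncp_log_likelihood(p, sncp_state(epsilon = 0)), -Inf)
})

test_that("likelihood agrees with fine-grid numeric integration", {
  set.seed(42)
  for (i in 1:8) {
    w <- if (i %% 2) rect_window(30, 25, c(0.5, 0.6)) else
      ellipse_window(c(15, 12), c(0.5, 0.5))
    K <- sample(1:3, 1)
    ctr <- cbind(runif(K, 8, 18), runif(K, 8, 16))
    sig <- runif(K, 2, 4)
    st <- sncp_state(ctr, runif(K, 30, 80),
                     cbind(sig^2, sig^2 * runif(K, -0.2, 0.2),
                           sig^2 * runif(K, 0.8, 1.2)),
                     epsilon = runif(1, 0.01, 0.05))
    sim <- simulate_slice_pattern(st, w, seed = i)
    ll <- sncp_log_likelihood(sim$pattern, st)
    oracle <- oracle_sncp_loglik(sim$pattern, st)
    expect_equal(ll, oracle, tolerance = 1e-3)
  }
})

test_that("window mass integrates interior kernels to one and splits edge kernels", {
  w <- rect_window(60, 60, c(0.6, 0.6))
  dummy <- slice_pattern(matrix(numeric(0), ncol = 2), w$window, w$spacing)
  interior <- sncp_state(matrix(c(30, 30), 1), 1, matrix(c(9, 0, 9), 1), 0)
  expect_equal(sncp_window_mass(dummy, interior), 1, tolerance = 1e-6)
  on_edge <- sncp_state(matrix(c(0, 30), 1), 1, matrix(c(9, 0, 9), 1), 0)
  expect_equal(sncp_window_mass(dummy, on_edge), 0.5, tolerance = 0.02)
})

test_that("state validation rejects inconsistent or non-PD inputs", {
  expect_error(sncp_state(matrix(c(1, 1), 1), numeric(0),
                          matrix(c(1, 0, 1), 1), 0.1), "length")
  expect_error(sncp_state(matrix(c(1, 1), 1), 1,
                          matrix(c(1, 2, 1), 1), 0.1), "positive definite")
  expect_error(sncp_state(epsilon = -1), "non-negative")
  expect_error(sncp_chain(n_iter = 100, burn_in = 100), "burn_in")
})

test_that("same seed gives a bit-identical draw sequence", {
  w <- rect_window(40, 40, c(0.8, 0.8))
  tr <- random_sncp_state(2, 60, 3, 0.2, w, seed = 43)
  sim <- simulate_slice_pattern(tr, w, seed = 43)
  ch <- sncp_chain(n_iter = 400, burn_in = 100, thin = 3)
  a <- fit_sncp_slice(sim$pattern, chain = ch, seed = 7)
  b <- fit_sncp_slice(sim$pattern, chain = ch, seed = 7)
  expect_identical(a$k, b$k)
  expect_identical(a$eps, b$eps)
  expect_identical(a$states, b$states)
  c2 <- fit_sncp_slice(sim$pattern, chain = ch, seed = 8)
  expect_false(identical(a$k, c2$k) && identical(a$eps, c2$eps))
})

test_that("with a constant likelihood the K-chain samples its Poisson prior", {
  w <- rect_window(30, 30, c(0.6, 0.6))
  tr <- random_sncp_state(2, 40, 3, 0.2, w, seed = 44)
  sim <- simulate_slice_pattern(tr, w, seed = 44)
  post <- fit_sncp_slice(sim$pattern,
                         chain = sncp_chain(n_iter = 12000, burn_in = 2000,
                                            thin = 2),
                         seed = 45, likelihood = "constant")
  # mean of truncated Poisson(5) is 5 up to negligible truncation
  mc_se <- sd(post$k) / sqrt(length(post$k) / 20)  # conservative ESS guess
  expect_lt(abs(mean(post$k) - 5), max(3 * mc_se, 0.5))
})

test_that("a pure-noise pattern concentrates posterior mass on small K", {
  w <- rect_window(60, 60, c(0.6, 0.6))
  st <- sncp_state(epsilon = 200 / 3600)
  sim <- simulate_slice_pattern(st, w, seed = 46)
  post <- fit_sncp_slice(sim$pattern,
                         chain = sncp_chain(n_iter = 2000, burn_in = 500,
                                            thin = 5), seed = 47)
  k_mode <- as.integer(names(which.max(table(post$k))))
  expect_lte(k_mode, 1L)
  expect_lte(mean(post$k), 1.5)
})

test_that("posterior recovers a known 4-cluster truth on one slice", {
  w <- rect_window(60, 60, c(0.6, 0.6))
  tr <- random_sncp_state(4, 150, 3, 0.15, w, seed = 48)
  sim <- simulate_slice_pattern(tr, w, seed = 48)
  post <- fit_sncp_slice(sim$pattern, seed = 49)
  s <- summarize_slice(post, sim$pattern)
  # single-slice check; the chain occasionally splits one cluster, so the
  # tolerance here is looser than the multi-run acceptance benchmark
  expect_lt(abs(mean(post$k) - 4), 1.5)
  expect_lt(abs(s$pct_diffuse - 15), 7)
  truth_acs <- 150 * 0.36
  expect_lt(abs(s$acs - truth_acs) / truth_acs, 0.25)
  truth_aca <- pi * qchisq(0.90, 2) * 9
  expect_lt(abs(s$aca - truth_aca) / truth_aca, 0.35)
})

test_that("slice summaries apply the documented closed forms", {
  # single draw with K = 3, lung area 150 cm^2 -> NC = 2.0 per 100 cm^2
  w <- rect_window(30, 30, c(0.6, 0.6))
  p <- slice_pattern(cbind(15, 15), w$window, w$spacing)
  fake <- structure(list(
    k = 3L, eps = 0,
    states = list(list(centers = matrix(c(10, 10, 20, 20, 15, 15), 3, 2),
                       weights = c(10, 20, 30),
                       covs = matrix(rep(c(25, 0, 25), each = 3), 3),
                       masses = c(1, 1, 1))),
    flagged = FALSE), class = "sncp_posterior")
  fake_pattern <- p
  fake_pattern$lung_area <- 150 * 100  # mm^2
  s <- summarize_slice(fake, fake_pattern)
  expect_equal(s$nc_rate, 2.0)
  # ACA for Sigma = 25 I: pi * q90 * 25
  expect_equal(s$aca, pi * qchisq(0.90, 2) * 25, tolerance = 1e-12)
  expect_equal(s$acs, mean(c(10, 20, 30)) * 0.36)
  # diffuse share from eps|W| = 20 vs clustered 80
  fake2 <- fake
  fake2$eps <- 20 / fake_pattern$lung_area
  fake2$states[[1]]$weights <- c(80 / 3, 80 / 3, 80 / 3)
  s2 <- summarize_slice(fake2, fake_pattern)
  expect_equal(s2$pct_diffuse, 20, tolerance = 1e-10)
})

test_that("all-noise posteriors yield missing ACS/ACA and 100% diffuse", {
  w <- rect_window(20, 20, c(0.5, 0.5))
  p <- slice_pattern(matrix(numeric(0), ncol = 2), w$window, w$spacing)
  post <- fit_sncp_slice(p, seed = 50)
  expect_true(post$flagged)
  expect_true(all(post$k == 0L))
  s <- summarize_slice(post, p)
  expect_equal(s$nc_rate, 0)
  expect_equal(s$pct_diffuse, 100)
  expect_true(is.na(s$acs) && is.na(s$aca))
})

test_that("subject aggregation averages slices and honors missing ACS", {
  mk <- function(nc, acs, dif, aca) {
    structure(list(nc_rate = nc, acs = acs, pct_diffuse = dif, aca = aca,
                   n_points = 10L, lung_area = 100, n_draws = 5L,
                   flagged = FALSE), class = "slice_cluster_summary")
  }
  same <- aggregate_subject(list(mk(2, 10, 30, 50), mk(2, 10, 30, 50)), "a")
  expect_equal(same$nc_rate, 2)
  expect_equal(same$acs, 10)
  two <- aggregate_subject(list(mk(1, 10, 20, 40), mk(3, 30, 40, 60)), "b")
  expect_equal(two$acs, 20)
  expect_equal(two$nc_rate, 2)
  miss <- aggregate_subject(list(mk(1, NA, 100, NA), mk(3, 30, 40, 60)), "c",
                            scalars = list(pct_laa = 5))
  expect_equal(miss$acs, 30)
  expect_equal(miss$n_slices, 2L)
  expect_equal(miss$n_slices_acs, 1L)
  expect_equal(miss$pct_laa, 5)
  none <- aggregate_subject(list(), "d")
  expect_true(none$flagged)
  expect_true(is.na(none$nc_rate))
})

test_that("reported summaries are invariant to cluster relabeling", {
  w <- rect_window(30, 30, c(0.6, 0.6))
  p <- slice_pattern(cbind(15, 15), w$window, w$spacing)
  st <- list(centers = matrix(c(10, 20, 10, 20), 2, 2),
             weights = c(10, 40),
             covs = matrix(c(9, 0, 9, 16, 0, 16), 2, 3, byrow = TRUE),
             masses = c(1, 1))
  perm <- list(centers = st$centers[2:1, ], weights = st$weights[2:1],
               covs = st$covs[2:1, ], masses = st$masses[2:1])
  mk_post <- function(s) structure(list(k = 2L, eps = 0.01, states = list(s),
                                        flagged = FALSE),
                                   class = "sncp_posterior")
  a <- summarize_slice(mk_post(st), p)
  b <- summarize_slice(mk_post(perm), p)
  expect_equal(a[c("nc_rate", "acs", "pct_diffuse", "aca")],
               b[c("nc_rate", "acs", "pct_diffuse", "aca")])
})
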