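test_that("connectivity conventions separate or join diagonal neighbors", {
  m <- array(FALSE, c(2, 2, 1))
  m[1, 1, 1] <- m[2, 2, 1] <- TRUE  # share only an edge in 3D terms
  expect_equal(label_connected_components(m, "faces")$n_clusters, 2L)
  expect_equal(label_connected_components(m, "faces-edges")$n_clusters, 1L)
  single <- array(FALSE, c(3, 3, 3))
  single[2, 2, 2] <- TRUE
  lab <- label_connected_components(single, "faces")
  expect_equal(lab$n_clusters, 1L)
  expect_equal(cluster_size_distribution(lab)$sizes, 1L)
  expect_error(label_connected_components(single, "diagonal-only"), "unknown")
})

test_that("labels are deterministic and raster-ordered", {
  set.seed(31)
  m <- random_mask(c(8, 8, 3), 0.35)
  a <- label_connected_components(m, "faces")
  b <- label_connected_components(m, "faces")
  expect_identical(a$labels, b$labels)
  firsts <- vapply(seq_len(a$n_clusters),
                   function(l) min(which(a$labels == l)), numeric(1))
  expect_true(all(diff(firsts) > 0))
})

test_that("cluster sizes match flood-fill enumeration on random masks", {
  set.seed(32)
  for (i in 1:50) {
    m <- random_mask(c(8, 8, 4), runif(1, 0.2, 0.6))
    conn <- sample(c("faces", "faces-edges", "faces-edges-corners"), 1)
    lab <- label_connected_components(m, conn)
    sizes <- cluster_size_distribution(lab)$sizes
    expect_equal(sort(sizes), sort(oracle_cluster_sizes(m, conn)))
    expect_equal(sum(sizes), sum(m))  # conservation
  }
})

test_that("an L-shaped cluster and a singleton give sizes {3, 1}", {
  m <- array(FALSE, c(4, 4, 1))
  m[1, 1, 1] <- m[2, 1, 1] <- m[2, 2, 1] <- TRUE
  m[4, 4, 1] <- TRUE
  sizes <- cluster_size_distribution(label_connected_components(m, "faces"))$sizes
  expect_equal(sort(sizes), c(1L, 3L))
  empty <- cluster_size_distribution(
    label_connected_components(array(FALSE, c(3, 3, 1)), "faces"))
  expect_length(empty$sizes, 0L)
})

test_that("continuous-MLE alpha equals the closed form", {
  sizes <- c(1, 1, 1, 1, 2, 4, 8)
  fit <- fit_power_law(sizes, method = "continuous-MLE", min_tail = 2)
  expect_equal(fit$alpha, 1 + 7 / (6 * log(2)), tolerance = 1e-12)
  expect_equal(fit$d, fit$alpha - 1)
  fit_a <- fit_power_law(sizes, method = "continuous-MLE", min_tail = 2,
                         d_convention = "alpha")
  expect_equal(fit_a$d, fit_a$alpha)
  set.seed(33)
  for (i in 1:5) {
    s <- sample(1:50, 30, replace = TRUE)
    f <- fit_power_law(s, method = "continuous-MLE")
    expect_equal(f$alpha, 1 + length(s) / sum(log(s)), tolerance = 1e-10)
  }
})

test_that("discrete-MLE alpha matches a likelihood grid-search oracle", {
  set.seed(34)
  for (i in 1:4) {
    s <- sample_zipf(500, alpha = runif(1, 1.8, 3), cutoff = 1e4)
    f <- fit_power_law(s, method = "discrete-MLE")
    expect_equal(f$alpha, oracle_discrete_alpha(s), tolerance = 1e-4)
  }
})

test_that("degenerate size lists are flagged with D missing", {
  f <- fit_power_law(rep(1L, 20), method = "discrete-MLE")
  expect_true(f$degenerate)
  expect_true(is.na(f$d))
  f2 <- fit_power_law(c(2L, 3L), min_tail = 5)
  expect_true(f2$degenerate)
})

test_that("the KS x_min estimator recovers a shifted tail threshold", {
  set.seed(35)
  # power-law tail above 5, flat noise below
  s <- c(sample(1:4, 600, replace = TRUE),
         sample_zipf(800, 2.5, cutoff = 1e4) + 4L)
  f <- fit_power_law(s, x_min_policy = "ks", method = "discrete-MLE")
  expect_gte(f$x_min, 3L)
  expect_false(f$degenerate)
})

test_that("join counts match the toy enumerations", {
  lung <- array(TRUE, c(3, 3, 1))
  laa <- array(FALSE, c(3, 3, 1))
  laa[1, 1, 1] <- laa[1, 2, 1] <- laa[3, 3, 1] <- TRUE
  jc <- compute_join_counts(laa, lung)
  expect_equal(jc$n_joins, 12L)
  expect_equal(jc$j_ll, 1L)
  expect_equal(jc$njc, 100 / 12)
  slab <- array(TRUE, c(2, 2, 1))
  jc2 <- compute_join_counts(slab, slab)
  expect_equal(jc2$j_ll, 4L)
  expect_equal(jc2$njc, 100)
  one <- array(TRUE, c(1, 1, 1))
  expect_warning(jc3 <- compute_join_counts(one, one), "no internal joins")
  expect_true(is.na(jc3$njc))
})

test_that("join counts match brute-force enumeration and conserve totals", {
  set.seed(36)
  for (i in 1:40) {
    dims <- c(sample(3:9, 1), sample(3:9, 1), sample(1:4, 1))
    lung <- random_mask(dims, runif(1, 0.5, 1))
    laa <- lung & random_mask(dims, runif(1, 0.1, 0.6))
    jc <- compute_join_counts(laa, lung)
    oj <- oracle_join_counts(laa, lung)
    expect_equal(c(jc$j_ll, jc$j_nl, jc$j_nn), unname(oj))
    expect_equal(jc$j_ll + jc$j_nl + jc$j_nn, jc$n_joins)
    # symmetry: swapping LAA and normal swaps LL and NN, fixes NL
    swapped <- compute_join_counts(lung & !laa, lung)
    expect_equal(swapped$j_ll, jc$j_nn)
    expect_equal(swapped$j_nn, jc$j_ll)
    expect_equal(swapped$j_nl, jc$j_nl)
  }
})

test_that("rectangular lungs have the analytic number of joins", {
  for (dims in list(c(4, 5, 3), c(2, 2, 2), c(7, 1, 1))) {
    lung <- array(TRUE, dims)
    jc <- compute_join_counts(array(FALSE, dims), lung)
    analytic <- (dims[1] - 1) * dims[2] * dims[3] +
      dims[1] * (dims[2] - 1) * dims[3] +
      dims[1] * dims[2] * (dims[3] - 1)
    expect_equal(jc$n_joins, analytic)
    expect_equal(jc$j_nn, analytic)
  }
})

test_that("compacting a fixed number of LAA voxels never lowers NJC", {
  lung <- array(TRUE, c(10, 10, 1))
  # 9 voxels scattered with no adjacencies
  scattered <- array(FALSE, c(10, 10, 1))
  scattered[cbind(c(1, 1, 1, 5, 5, 5, 9, 9, 9), c(1, 5, 9, 1, 5, 9, 1, 5, 9), 1)] <- TRUE
  # same 9 voxels as one 3x3 block
  block <- array(FALSE, c(10, 10, 1))
  block[4:6, 4:6, 1] <- TRUE
  njc_s <- compute_join_counts(scattered, lung)$njc
  njc_b <- compute_join_counts(block, lung)$njc
  expect_equal(njc_s, 0)
  expect_gt(njc_b, njc_s)
})

test_that("LAA outside the lung is rejected", {
  lung <- array(FALSE, c(2, 2, 1))
  lung[1, 1, 1] <- TRUE
  laa <- array(FALSE, c(2, 2, 1))
  laa[2, 2, 1] <- TRUE
  expect_error(compute_join_counts(laa, lung), "subset")
})
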