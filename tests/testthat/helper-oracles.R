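# Independent brute-force oracles and fixture generators used across tests.
# These deliberately share no code with the package implementation.

# Random 3D logical mask with given occupancy probability.
random_mask <- function(dims, p = 0.4) {
  array(runif(prod(dims)) < p, dims)
}

# Symmetric neighbor offsets for a connectivity tag (full set, both signs).
oracle_offsets <- function(connectivity) {
  all_off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  all_off <- all_off[!(all_off$dx == 0 & all_off$dy == 0 & all_off$dz == 0), ]
  nz <- abs(all_off$dx) + abs(all_off$dy) + abs(all_off$dz)
  keep <- switch(connectivity,
                 "faces" = nz == 1,
                 "faces-edges" = nz <= 2,
                 "faces-edges-corners" = nz <= 3)
  as.matrix(all_off[keep, ])
}

# Flood-fill connected components: returns the multiset of cluster sizes.
oracle_cluster_sizes <- function(mask, connectivity = "faces") {
  d <- dim(mask)
  off <- oracle_offsets(connectivity)
  visited <- array(FALSE, d)
  sizes <- integer(0)
  idx_all <- which(mask)
  for (start in idx_all) {
    if (visited[start]) next
    queue <- start
    visited[start] <- TRUE
    size <- 0L
    while (length(queue) > 0L) {
      cur <- queue[1]
      queue <- queue[-1]
      size <- size + 1L
      pos <- arrayInd(cur, d)
      for (r in seq_len(nrow(off))) {
        nb <- pos + off[r, ]
        if (any(nb < 1L) || any(nb > d)) next
        lin <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (mask[lin] && !visited[lin]) {
          visited[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# Stride-arithmetic enumeration of within-lung face joins.
oracle_join_counts <- function(laa, lung) {
  d <- dim(lung)
  ll <- nl <- nn <- 0L
  for (axis in 1:3) {
    stride <- c(1L, d[1], d[1] * d[2])[axis]
    coord <- slice.index(array(seq_len(prod(d)), d), axis)
    valid <- which(coord < d[axis])
    a <- valid[lung[valid] & lung[valid + stride]]
    b <- a + stride
    ll <- ll + sum(laa[a] & laa[b])
    nn <- nn + sum(!laa[a] & !laa[b])
    nl <- nl + sum(xor(laa[a], laa[b]))
  }
  c(ll = ll, nl = nl, nn = nn)
}

# Grid-search maximizer of the discrete power-law likelihood.
oracle_discrete_alpha <- function(sizes, x_min = 1L) {
  ll <- function(a) {
    z <- pracma::zeta(a)
    if (x_min > 1) z <- z - sum(seq_len(x_min - 1)^(-a))
    -length(sizes) * log(z) - a * sum(log(sizes))
  }
  grid <- seq(1.01, 6, by = 0.01)
  best <- grid[which.max(vapply(grid, ll, numeric(1)))]
  fine <- seq(max(best - 0.02, 1.0001), best + 0.02, by = 1e-5)
  fine[which.max(vapply(fine, ll, numeric(1)))]
}

# Sample from a discrete power law (Zipf) by inverse CDF on a long table.
sample_zipf <- function(n, alpha, cutoff = 2e6) {
  p <- (seq_len(cutoff))^(-alpha)
  sample.int(cutoff, n, replace = TRUE, prob = p)
}

# Fine-grid Riemann approximation of the SNCP log likelihood.
oracle_sncp_loglik <- function(pattern, state, h = 0.1) {
  win <- pattern$window
  sp <- pattern$spacing
  xs <- seq(h / 2, nrow(win) * sp[1], by = h)
  ys <- seq(h / 2, ncol(win) * sp[2], by = h)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  inw <- win[cbind(ceiling(gx / sp[1]), ceiling(gy / sp[2]))]
  lambda <- function(x, y) {
    v <- rep(state$epsilon, length(x))
    if (state$K > 0) {
      for (j in seq_len(state$K)) {
        S <- matrix(c(state$covs[j, 1], state$covs[j, 2],
                      state$covs[j, 2], state$covs[j, 3]), 2)
        Si <- solve(S)
        ux <- x - state$centers[j, 1]
        uy <- y - state$centers[j, 2]
        q <- Si[1, 1] * ux^2 + 2 * Si[1, 2] * ux * uy + Si[2, 2] * uy^2
        v <- v + state$weights[j] * exp(-q / 2) / (2 * pi * sqrt(det(S)))
      }
    }
    v
  }
  sum(log(lambda(pattern$points[, 1], pattern$points[, 2]))) -
    sum(lambda(gx[inw], gy[inw])) * h * h
}

# Small simulated lung/LAA fixture volume for imaging tests.
toy_subject <- function(seed = 1L) {
  simulate_subject(subject_sim_spec(n_slices = 3L, max_semi_axes = c(16, 12),
                                    k_rate = 30, w = 40, sigma = 2,
                                    noise_share = 0.2),
                   seed = seed)
}
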