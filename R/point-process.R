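#' Shot-noise Cox process state
#'
#' A parameter state of the cluster process: `K` Gaussian cluster kernels
#' (center, expected number of points `w`, 2x2 covariance in mm^2) plus a
#' homogeneous noise intensity `epsilon` (points per mm^2). The process
#' intensity at location x is
#' `lambda(x) = epsilon + sum_j w_j * phi(x; c_j, Sigma_j)`.
#'
#' @param centers K x 2 numeric matrix of cluster centers (mm). A 0-row
#'   matrix gives the purely homogeneous state.
#' @param weights Length-K positive vector of expected points per cluster.
#' @param covs Cluster covariances: either a list of K 2x2 symmetric
#'   positive-definite matrices or a K x 3 matrix of (s11, s12, s22).
#' @param epsilon Homogeneous noise intensity, points per mm^2 (>= 0).
#' @return Object of class `sncp_state`.
#' @export
sncp_state <- function(centers = matrix(numeric(0), ncol = 2), weights = numeric(0),
                       covs = matrix(numeric(0), ncol = 3), epsilon = 0) {
  centers <- as.matrix(centers)
  if (length(centers) == 0L) centers <- matrix(numeric(0), ncol = 2)
  if (ncol(centers) != 2L) stop("'centers' must have two columns")
  K <- nrow(centers)
  weights <- as.numeric(weights)
  if (length(weights) != K) stop("'weights' length must match number of centers")
  if (any(weights <= 0)) stop("'weights' must be positive")
  covs <- normalize_covs(covs, K)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("'epsilon' must be a single non-negative number")
  structure(list(K = K, centers = centers, weights = weights, covs = covs,
                 epsilon = epsilon),
            class = "sncp_state")
}

normalize_covs <- function(covs, K) {
  if (is.list(covs)) {
    covs <- t(vapply(covs, function(S) {
      S <- as.matrix(S)
      if (!identical(dim(S), c(2L, 2L)) || abs(S[1, 2] - S[2, 1]) > 1e-10)
        stop("each covariance must be a symmetric 2x2 matrix")
      c(S[1, 1], S[1, 2], S[2, 2])
    }, numeric(3)))
    if (K == 0L) covs <- matrix(numeric(0), ncol = 3)
  }
  covs <- as.matrix(covs)
  if (length(covs) == 0L) covs <- matrix(numeric(0), ncol = 3)
  if (ncol(covs) != 3L || nrow(covs) != K)
    stop("'covs' must be K x 3 (s11, s12, s22) or a list of 2x2 matrices")
  if (K > 0L) {
    dets <- covs[, 1] * covs[, 3] - covs[, 2]^2
    if (any(covs[, 1] <= 0 | covs[, 3] <= 0 | dets <= 0))
      stop("all covariances must be positive definite")
  }
  covs
}

#' @export
print.sncp_state <- function(x, ...) {
  cat("<sncp_state> K = ", x$K, ", epsilon = ", signif(x$epsilon, 4),
      " pts/mm^2\n", sep = "")
  invisible(x)
}

#' Priors for the shot-noise Cox process
#'
#' Weakly informative defaults: the cluster count is Poisson with mean
#' `kappa` (truncated at `k_max`); weights are Gamma; covariances are
#' inverse-Wishart with an isotropic scale; the noise intensity is Gamma
#' with prior mean of one noise point per window. Fields left `NULL` are
#' filled per slice from the data by [fit_sncp_slice()]: `w_rate` becomes
#' `w_shape / w0` with `w0 = n_points / max(K0, 1)` from the initializer,
#' `iw_scale` becomes `(2 * min in-plane spacing)^2`, and `eps_rate`
#' becomes the window area.
#'
#' @param kappa Prior mean cluster count (default 5).
#' @param k_max Truncation for the cluster count (default 200).
#' @param w_shape,w_rate Gamma prior on cluster weights.
#' @param iw_df,iw_scale Inverse-Wishart prior on covariances
#'   (`Psi = iw_scale * I`, degrees of freedom `iw_df`).
#' @param eps_shape,eps_rate Gamma prior on the noise intensity.
#' @return Object of class `sncp_priors`.
#' @export
sncp_priors <- function(kappa = 5, k_max = 200, w_shape = 2, w_rate = NULL,
                        iw_df = 4, iw_scale = NULL, eps_shape = 1,
                        eps_rate = NULL) {
  stopifnot(kappa > 0, k_max >= 1, w_shape > 0, iw_df > 3, eps_shape > 0)
  structure(list(kappa = kappa, k_max = as.integer(k_max), w_shape = w_shape,
                 w_rate = w_rate, iw_df = iw_df, iw_scale = iw_scale,
                 eps_shape = eps_shape, eps_rate = eps_rate),
            class = "sncp_priors")
}

#' MCMC settings for the birth-death sampler
#'
#' @param n_iter Total iterations (default 5000).
#' @param burn_in Burn-in iterations discarded from output (default 2000).
#' @param thin Keep every `thin`-th post-burn-in state (default 5).
#' @param step_center Random-walk step for cluster centers, mm.
#' @param step_logw Random-walk step for log cluster weights.
#' @param step_sigma Random-walk step for the covariance parametrization
#'   (log standard deviations and atanh correlation).
#' @param step_logeps Random-walk step for the log noise intensity.
#' @return Object of class `sncp_chain`.
#' @export
sncp_chain <- function(n_iter = 5000, burn_in = 2000, thin = 5,
                       step_center = 2.0, step_logw = 0.3, step_sigma = 0.15,
                       step_logeps = 0.3) {
  if (burn_in >= n_iter) stop("'burn_in' must be smaller than 'n_iter'")
  if (thin < 1) stop("'thin' must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), step_center = step_center,
                 step_logw = step_logw, step_sigma = step_sigma,
                 step_logeps = step_logeps),
            class = "sncp_chain")
}

window_grid <- function(pattern) {
  g <- pattern$window
  storage.mode(g) <- "integer"
  g
}

#' Log likelihood of a slice pattern under an SNCP state
#'
#' Inhomogeneous-Poisson log likelihood
#' `sum_i log lambda(x_i) - integral_W lambda(x) dx`, with the window
#' integral of each Gaussian kernel computed by mid-point quadrature over
#' the window voxels. With `epsilon = 0`, a point receiving zero cluster
#' intensity makes the likelihood `-Inf` (returned, not raised).
#'
#' @param pattern A [slice_pattern()].
#' @param state An [sncp_state()].
#' @return Log likelihood (finite, or `-Inf` in the degenerate case).
#' @export
sncp_log_likelihood <- function(pattern, state) {
  stopifnot(inherits(pattern, "slice_pattern"), inherits(state, "sncp_state"))
  if (pattern$lung_area <= 0) stop("degenerate window")
  .sncp_loglik_cpp(pattern$points[, 1], pattern$points[, 2],
                   window_grid(pattern), pattern$spacing[1],
                   pattern$spacing[2], state$centers, state$weights,
                   state$covs, state$epsilon)
}

#' Gaussian window mass of each cluster
#'
#' Fraction of each cluster kernel's mass lying inside the observation
#' window, by the same mid-point quadrature the likelihood uses.
#'
#' @param pattern A [slice_pattern()] (supplies the window).
#' @param state An [sncp_state()].
#' @return Numeric vector of length `state$K` with values in `[0, 1]`.
#' @export
sncp_window_mass <- function(pattern, state) {
  if (state$K == 0L) return(numeric(0))
  .sncp_window_mass_cpp(window_grid(pattern), pattern$spacing[1],
                        pattern$spacing[2], state$centers, state$covs)
}

# Deterministic initialization: connected components (>= min_size voxels) of
# the rasterized pattern give K0 and the centroids. The raster is dilated by
# one voxel before labeling so that near-contiguous fragments of one diffuse
# lesion initialize as a single cluster rather than many slivers.
dilate_mask <- function(mask) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xs <- max(1, 1 + dx):min(nr, nr + dx)
    ys <- max(1, 1 + dy):min(nc, nc + dy)
    out[xs, ys] <- out[xs, ys] | mask[xs - dx, ys - dy]
  }
  out
}

sncp_init <- function(pattern, priors, min_size = 5L) {
  n <- pattern$n_points
  win <- pattern$window
  mask <- array(FALSE, dim(win))
  ix <- pmin(pmax(ceiling(pattern$points[, 1] / pattern$spacing[1]), 1L), nrow(win))
  iy <- pmin(pmax(ceiling(pattern$points[, 2] / pattern$spacing[2]), 1L), ncol(win))
  mask[cbind(ix, iy)] <- TRUE
  lab <- label_connected_components(dilate_mask(mask), "faces")
  # size filter counts occupied (undilated) voxels per dilated component
  lab_flat <- lab$labels
  dim(lab_flat) <- dim(mask)
  occupied <- lab_flat[mask]
  sizes <- tabulate(occupied[occupied > 0L], nbins = lab$n_clusters)
  keep <- which(sizes >= min_size)
  keep <- keep[seq_len(min(length(keep), priors$k_max))]
  K0 <- length(keep)
  sigma0_sq <- (2 * min(pattern$spacing))^2
  if (K0 > 0L) {
    lab2 <- lab_flat
    lab2[!mask] <- 0L  # centroids/covariances from occupied voxels only
    centers <- t(vapply(keep, function(l) {
      idx <- which(lab2 == l, arr.ind = TRUE)
      c(mean((idx[, 1] - 0.5) * pattern$spacing[1]),
        mean((idx[, 2] - 0.5) * pattern$spacing[2]))
    }, numeric(2)))
    covs <- t(vapply(keep, function(l) {
      idx <- which(lab2 == l, arr.ind = TRUE)
      pts <- cbind((idx[, 1] - 0.5) * pattern$spacing[1],
                   (idx[, 2] - 0.5) * pattern$spacing[2])
      if (nrow(pts) >= 3L) {
        S <- stats::cov(pts) + diag(sigma0_sq, 2)
        c(S[1, 1], S[1, 2], S[2, 2])
      } else {
        c(sigma0_sq, 0, sigma0_sq)
      }
    }, numeric(3)))
  } else {
    centers <- matrix(numeric(0), ncol = 2)
    covs <- matrix(numeric(0), ncol = 3)
  }
  w0 <- n / max(K0, 1L)
  # typical within-component variance, used to center the covariance prior
  v_hat <- if (K0 > 0L) max(mean((covs[, 1] + covs[, 3]) / 2), sigma0_sq)
           else sigma0_sq
  list(K0 = K0, centers = centers,
       weights = rep(w0, K0), covs = covs,
       eps = max(0.1 * n / pattern$lung_area, 1e-8),
       w0 = w0, sigma0_sq = sigma0_sq, v_hat = v_hat)
}

fill_priors <- function(priors, pattern, init) {
  if (is.null(priors$w_rate)) priors$w_rate <- priors$w_shape / max(init$w0, 1)
  # center the inverse-Wishart at the initializer's typical kernel variance
  if (is.null(priors$iw_scale))
    priors$iw_scale <- (priors$iw_df - 3) * init$v_hat
  # prior mean n/|W| (all-diffuse intensity) with one point's worth of
  # exposure: weakly informative at any pattern size
  if (is.null(priors$eps_rate))
    priors$eps_rate <- pattern$lung_area / max(pattern$n_points, 1L)
  priors
}

#' Fit the shot-noise Cox process to one slice pattern
#'
#' Birth-death Markov chain Monte Carlo over the number of clusters, with
#' Metropolis-within-Gibbs updates for each cluster's center, weight, and
#' covariance and for the noise intensity. Births propose a uniformly
#' placed center with weight and covariance drawn from their priors; deaths
#' remove a uniformly chosen cluster; both are accepted against the
#' likelihood times the Poisson prior on the cluster count. The sampler is
#' deterministic given `seed`.
#'
#' @param pattern A [slice_pattern()]. An empty pattern short-circuits to a
#'   flagged degenerate posterior (all draws `K = 0`, noise drawn from its
#'   zero-count conditional).
#' @param priors An [sncp_priors()]; `NULL` fields are filled from the data.
#' @param chain An [sncp_chain()].
#' @param seed Integer RNG seed.
#' @param likelihood `"sncp"` for the real model; `"constant"` replaces the
#'   likelihood by a constant so the chain samples the prior (used for
#'   sampler-correctness checks).
#' @return Object of class `sncp_posterior`: vectors `k`, `eps`, `log_lik`
#'   over retained draws, per-draw `states` (centers, weights, covs,
#'   masses), acceptance `counters`, the filled `priors`, `chain`, `seed`,
#'   and a `flagged` marker for degenerate inputs.
#' @export
fit_sncp_slice <- function(pattern, priors = sncp_priors(),
                           chain = sncp_chain(), seed = 1L,
                           likelihood = c("sncp", "constant")) {
  stopifnot(inherits(pattern, "slice_pattern"), inherits(priors, "sncp_priors"),
            inherits(chain, "sncp_chain"))
  likelihood <- match.arg(likelihood)
  init <- sncp_init(pattern, priors)
  priors <- fill_priors(priors, pattern, init)
  n_keep <- ((chain$n_iter - chain$burn_in - 1L) %/% chain$thin) + 1L
  if (pattern$n_points == 0L && likelihood == "sncp") {
    set.seed(seed)
    eps_draws <- stats::rgamma(n_keep, shape = priors$eps_shape,
                               rate = priors$eps_rate + pattern$lung_area)
    return(structure(list(
      k = rep(0L, n_keep), eps = eps_draws, log_lik = rep(NA_real_, n_keep),
      states = replicate(n_keep, list(centers = matrix(numeric(0), ncol = 2),
                                      weights = numeric(0),
                                      covs = matrix(numeric(0), ncol = 3),
                                      masses = numeric(0)),
                         simplify = FALSE),
      counters = NULL, priors = priors, chain = chain, seed = seed,
      pattern_n = 0L, flagged = TRUE), class = "sncp_posterior"))
  }
  set.seed(seed)
  res <- .sncp_mcmc_cpp(pattern$points[, 1], pattern$points[, 2],
                        window_grid(pattern), pattern$spacing[1],
                        pattern$spacing[2],
                        priors[c("kappa", "k_max", "w_shape", "w_rate",
                                 "iw_df", "iw_scale", "eps_shape", "eps_rate")],
                        list(centers = init$centers, weights = init$weights,
                             covs = init$covs, eps = init$eps),
                        unclass(chain),
                        constant_lik = (likelihood == "constant"))
  structure(list(k = res$k, eps = res$eps, log_lik = res$log_lik,
                 states = res$states, counters = res$counters,
                 priors = priors, chain = chain, seed = seed,
                 pattern_n = pattern$n_points, flagged = FALSE),
            class = "sncp_posterior")
}

#' @export
print.sncp_posterior <- function(x, ...) {
  cat("<sncp_posterior> ", length(x$k), " draws, E[K] = ",
      signif(mean(x$k), 4), ", E[eps] = ", signif(mean(x$eps), 4),
      if (x$flagged) " [flagged degenerate]", "\n", sep = "")
  invisible(x)
}

#' Posterior clustering summaries for one slice
#'
#' Posterior means of the four clustering characteristics: cluster rate NC
#' (clusters per 100 cm^2 of lung), average cluster size ACS (expected
#' points per cluster converted to mm^2 via the voxel area), the diffuse
#' share %-Diffuse (expected fraction of points arising from the noise
#' component), and average cluster area ACA (mean area of the 90th
#' percentile ellipse, `pi * q_0.90 * sqrt(det Sigma)` with `q_0.90` the
#' 0.90 quantile of the chi-square distribution with 2 df). Draws with
#' `K = 0` contribute to NC and %-Diffuse but are excluded from the ACS and
#' ACA means. When fewer than `min_support` of the draws contain any
#' cluster, the slice shows no real evidence of clustering and ACS/ACA are
#' reported missing rather than estimated from the few clustered draws; a
#' posterior that is all `K = 0` additionally gives `pct_diffuse = 100`
#' and `nc_rate = 0`.
#'
#' @param posterior An `sncp_posterior` from [fit_sncp_slice()].
#' @param pattern The [slice_pattern()] that was fit.
#' @param min_support Minimum posterior probability of `K >= 1` required
#'   to report ACS/ACA (default 0.5).
#' @return Object of class `slice_cluster_summary` with `nc_rate`, `acs`,
#'   `pct_diffuse`, `aca`, `n_points`, `lung_area`, `n_draws`, `flagged`.
#' @export
summarize_slice <- function(posterior, pattern, min_support = 0.5) {
  stopifnot(inherits(posterior, "sncp_posterior"),
            inherits(pattern, "slice_pattern"))
  q90 <- stats::qchisq(0.90, df = 2)
  area <- pattern$lung_area
  voxel_area <- pattern$voxel_area
  k <- posterior$k
  n_draws <- length(k)
  diffuse <- vapply(seq_len(n_draws), function(i) {
    st <- posterior$states[[i]]
    noise <- posterior$eps[i] * area
    clustered <- if (length(st$weights)) sum(st$weights * st$masses) else 0
    if (noise + clustered <= 0) 1 else noise / (noise + clustered)
  }, numeric(1))
  pos <- which(k > 0L)
  if (length(pos) < min_support * n_draws) pos <- integer(0)
  acs_draws <- vapply(pos, function(i) {
    mean(posterior$states[[i]]$weights) * voxel_area
  }, numeric(1))
  aca_draws <- vapply(pos, function(i) {
    covs <- posterior$states[[i]]$covs
    dets <- covs[, 1] * covs[, 3] - covs[, 2]^2
    mean(pi * q90 * sqrt(dets))
  }, numeric(1))
  structure(list(
    nc_rate = mean(k) / (area / 100) * 100,  # per 100 cm^2; area mm^2 -> cm^2
    acs = if (length(pos)) mean(acs_draws) else NA_real_,
    pct_diffuse = 100 * mean(diffuse),
    aca = if (length(pos)) mean(aca_draws) else NA_real_,
    n_points = pattern$n_points, lung_area = area,
    n_draws = n_draws, flagged = posterior$flagged),
    class = "slice_cluster_summary")
}

#' @export
print.slice_cluster_summary <- function(x, ...) {
  cat("<slice_summary> NC ", signif(x$nc_rate, 4), "/100cm^2, ACS ",
      signif(x$acs, 4), " mm^2, %-Diffuse ", signif(x$pct_diffuse, 4),
      ", ACA ", signif(x$aca, 4), " mm^2\n", sep = "")
  invisible(x)
}

#' Aggregate per-slice summaries to a subject profile
#'
#' Unweighted means across analyzed slices. Slices missing ACS or ACA
#' (all-noise fits) are excluded from those two means only; every valid
#' slice contributes to NC and %-Diffuse. Scalar whole-lung metrics
#' (%LAA, D, NJC, %GT) are carried through unchanged.
#'
#' @param summaries List of `slice_cluster_summary` objects.
#' @param subject_id Identifier stored in the profile.
#' @param scalars Named list of subject-level scalar metrics to attach
#'   (e.g. `pct_laa`, `d`, `njc`, `pct_gt`).
#' @return Object of class `subject_profile`. With zero valid slices the
#'   point-process fields are `NA` and the profile is flagged.
#' @export
aggregate_subject <- function(summaries, subject_id = NA_character_,
                              scalars = list()) {
  stopifnot(is.list(summaries))
  valid <- Filter(function(s) inherits(s, "slice_cluster_summary"), summaries)
  n_slices <- length(valid)
  get <- function(field) vapply(valid, `[[`, numeric(1), field)
  if (n_slices == 0L) {
    prof <- list(subject_id = subject_id, nc_rate = NA_real_, acs = NA_real_,
                 pct_diffuse = NA_real_, aca = NA_real_, n_slices = 0L,
                 n_slices_acs = 0L, flagged = TRUE)
  } else {
    acs <- get("acs")
    aca <- get("aca")
    prof <- list(subject_id = subject_id,
                 nc_rate = mean(get("nc_rate")),
                 acs = if (any(!is.na(acs))) mean(acs, na.rm = TRUE) else NA_real_,
                 pct_diffuse = mean(get("pct_diffuse")),
                 aca = if (any(!is.na(aca))) mean(aca, na.rm = TRUE) else NA_real_,
                 n_slices = n_slices,
                 n_slices_acs = sum(!is.na(acs)),
                 flagged = FALSE)
  }
  structure(c(prof, scalars), class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat("<subject_profile> ", x$subject_id, ": ", x$n_slices,
      " slices; NC ", signif(x$nc_rate, 4), ", ACS ", signif(x$acs, 4),
      ", %-Diffuse ", signif(x$pct_diffuse, 4), ", ACA ",
      signif(x$aca, 4), "\n", sep = "")
  invisible(x)
}
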