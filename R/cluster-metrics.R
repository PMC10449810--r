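# Lattice adjacency offsets (positive half-space only, so each unordered
# neighbor pair is generated exactly once).
connectivity_offsets <- function(connectivity, ndim = 3L) {
  faces3 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  edges3 <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
                  c(1, 0, -1), c(0, 1, 1), c(0, 1, -1))
  corners3 <- rbind(c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  off <- switch(connectivity,
    "faces" = faces3,
    "faces-edges" = rbind(faces3, edges3),
    "faces-edges-corners" = rbind(faces3, edges3, corners3),
    stop("unknown connectivity tag: ", connectivity)
  )
  if (ndim == 2L) off <- off[off[, 3] == 0, 1:2, drop = FALSE]
  off
}

# All unordered neighboring voxel pairs (as linear index columns a, b) for
# which both endpoints are TRUE in `mask`, under the given offsets.
lattice_pairs <- function(mask, offsets) {
  dims <- dim(mask)
  nd <- length(dims)
  a_all <- integer(0)
  b_all <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    off <- as.integer(offsets[r, ])
    idx_from <- vector("list", nd)
    idx_to <- vector("list", nd)
    ok <- TRUE
    for (d in seq_len(nd)) {
      if (off[d] >= 0) {
        lo <- 1L; hi <- dims[d] - off[d]
      } else {
        lo <- 1L - off[d]; hi <- dims[d]
      }
      if (hi < lo) { ok <- FALSE; break }
      idx_from[[d]] <- lo:hi
      idx_to[[d]] <- (lo:hi) + off[d]
    }
    if (!ok) next
    sub_from <- do.call(`[`, c(list(mask), idx_from, list(drop = FALSE)))
    sub_to <- do.call(`[`, c(list(mask), idx_to, list(drop = FALSE)))
    hit <- which(sub_from & sub_to)
    if (length(hit) == 0L) next
    # convert positions within the cropped block back to full-array indices
    block_dims <- vapply(idx_from, length, integer(1))
    arr <- arrayInd(hit, block_dims)
    starts_from <- vapply(idx_from, `[`, integer(1), 1L)
    starts_to <- vapply(idx_to, `[`, integer(1), 1L)
    mult <- cumprod(c(1L, dims[-nd]))
    lin_from <- 1L + as.integer((arr - 1L + rep(starts_from - 1L, each = nrow(arr))) %*% mult)
    lin_to <- 1L + as.integer((arr - 1L + rep(starts_to - 1L, each = nrow(arr))) %*% mult)
    a_all <- c(a_all, lin_from)
    b_all <- c(b_all, lin_to)
  }
  cbind(a = a_all, b = b_all)
}

#' Label contiguous LAA clusters
#'
#' Deterministic connected-component labeling of a binary mask on the voxel
#' lattice. Adjacency is defined on the index grid and ignores anisotropic
#' spacing; the default face connectivity (6-neighbor in 3D, 4-neighbor in
#' 2D) matches the join-count definition of a shared face. Labels are
#' assigned in raster-scan order of each component's first voxel, so the
#' output is reproducible bit-exactly.
#'
#' @param laa A [binary_mask()] or a logical array (2D or 3D).
#' @param connectivity One of `"faces"`, `"faces-edges"`,
#'   `"faces-edges-corners"`.
#' @return Object of class `labeled_clusters`: integer `labels` array
#'   (0 = background), `n_clusters`, `connectivity`.
#' @export
label_connected_components <- function(laa, connectivity = "faces") {
  mask <- if (inherits(laa, "binary_mask")) laa$indicator else as.array(laa)
  storage.mode(mask) <- "logical"
  offsets <- connectivity_offsets(connectivity, ndim = length(dim(mask)))
  voxels <- which(mask)
  labels <- array(0L, dim(mask))
  if (length(voxels) > 0L) {
    pairs <- lattice_pairs(mask, offsets)
    vertex_id <- integer(length(mask))
    vertex_id[voxels] <- seq_along(voxels)
    g <- igraph::make_empty_graph(n = length(voxels), directed = FALSE)
    if (nrow(pairs) > 0L)
      g <- igraph::add_edges(g, rbind(vertex_id[pairs[, "a"]],
                                      vertex_id[pairs[, "b"]]))
    comp <- igraph::components(g)$membership
    # relabel components by the first (raster-order) voxel they contain
    first_seen <- comp[!duplicated(comp)]
    relabel <- integer(max(comp))
    relabel[first_seen] <- seq_along(first_seen)
    labels[voxels] <- relabel[comp]
  }
  structure(list(labels = labels,
                 n_clusters = max(labels),
                 connectivity = connectivity),
            class = "labeled_clusters")
}

#' Cluster-size distribution of labeled components
#'
#' One size (in voxels) per cluster, including singletons; the sizes sum to
#' the number of LAA voxels.
#'
#' @param labels A `labeled_clusters` object from
#'   [label_connected_components()].
#' @return Object of class `cluster_sizes`: integer vector `sizes`.
#' @export
cluster_size_distribution <- function(labels) {
  stopifnot(inherits(labels, "labeled_clusters"))
  sizes <- tabulate(labels$labels[labels$labels > 0L], nbins = labels$n_clusters)
  structure(list(sizes = as.integer(sizes)), class = "cluster_sizes")
}

# zeta(alpha, x_min) = sum_{k >= x_min} k^-alpha. Computed as a direct
# partial sum plus an Euler-Maclaurin tail: subtracting the head from
# pracma::zeta(alpha) cancels catastrophically for large alpha * x_min.
hurwitz_zeta <- function(alpha, x_min) {
  if (x_min == 1) return(pracma::zeta(alpha))
  n_top <- x_min + 1000
  k <- x_min:(n_top - 1)
  sum(k^(-alpha)) + n_top^(1 - alpha) / (alpha - 1) + n_top^(-alpha) / 2 +
    alpha * n_top^(-alpha - 1) / 12
}

discrete_pl_loglik <- function(alpha, sizes, x_min) {
  -length(sizes) * log(hurwitz_zeta(alpha, x_min)) - alpha * sum(log(sizes))
}

fit_pl_tail <- function(tail_sizes, x_min, method) {
  n <- length(tail_sizes)
  if (method == "continuous-MLE") {
    denom <- sum(log(tail_sizes / x_min))
    if (denom <= 0) return(NULL)
    alpha <- 1 + n / denom
    ll <- n * log(alpha - 1) - n * log(x_min) - alpha * denom
    list(alpha = alpha, log_likelihood = ll)
  } else {
    if (length(unique(tail_sizes)) < 2L) return(NULL)
    opt <- stats::optimize(discrete_pl_loglik, interval = c(1 + 1e-8, 25),
                           sizes = tail_sizes, x_min = x_min,
                           maximum = TRUE, tol = 1e-10)
    list(alpha = opt$maximum, log_likelihood = opt$objective)
  }
}

# Kolmogorov-Smirnov distance between the empirical tail CDF and the fitted
# discrete/continuous power law, used by the optional x_min estimator.
pl_ks_distance <- function(tail_sizes, x_min, alpha, method) {
  xs <- sort(unique(tail_sizes))
  ecdf_vals <- cumsum(tabulate(match(sort(tail_sizes), xs))) / length(tail_sizes)
  if (method == "continuous-MLE") {
    model_cdf <- 1 - (xs / x_min)^(1 - alpha)
  } else {
    ks <- seq.int(x_min, max(xs))
    s <- ks^(-alpha)
    beyond <- hurwitz_zeta(alpha, max(xs) + 1L)
    cum_from <- rev(cumsum(rev(s)))          # sum_{k >= x} up to max(xs)
    tail_mass <- beyond + cum_from - s       # zeta(alpha, x + 1)
    z0 <- beyond + cum_from[1L]              # zeta(alpha, x_min)
    model_cdf <- 1 - tail_mass[xs - x_min + 1L] / z0
  }
  max(abs(ecdf_vals - model_cdf))
}

#' Fit a power law to the cluster-size distribution
#'
#' Maximum-likelihood fit of `P(S = s) ~ s^-alpha` for `s >= x_min`. The
#' default follows the original emphysema cluster-size analyses: all sizes
#' down to single voxels enter the fit (`x_min = 1`) and the discrete
#' likelihood is used because sizes are integers. The reported exponent D
#' is by default the slope of the cumulative (CCDF) plot, `alpha - 1`;
#' both conventions are returned.
#'
#' @param sizes A `cluster_sizes` object or an integer vector of sizes.
#' @param x_min_policy `"fixed"` (use `x_min` as given) or `"ks"`
#'   (Kolmogorov-Smirnov minimization over candidate x_min values).
#' @param method `"discrete-MLE"` or `"continuous-MLE"`.
#' @param x_min Tail threshold used when `x_min_policy = "fixed"`.
#' @param d_convention `"alpha-1"` (CCDF slope, default) or `"alpha"`.
#' @param min_tail Minimum number of tail observations for a non-degenerate
#'   fit (default 5).
#' @return Object of class `power_law_fit`: `alpha`, `d`, `x_min`,
#'   `log_likelihood`, `n_tail`, `method`, `d_convention`, `degenerate`.
#'   Degenerate inputs (all sizes equal, or a tail smaller than `min_tail`)
#'   return `degenerate = TRUE` with `d = NA`.
#' @export
fit_power_law <- function(sizes, x_min_policy = c("fixed", "ks"),
                          method = c("discrete-MLE", "continuous-MLE"),
                          x_min = 1L, d_convention = c("alpha-1", "alpha"),
                          min_tail = 5L) {
  x_min_policy <- match.arg(x_min_policy)
  method <- match.arg(method)
  d_convention <- match.arg(d_convention)
  if (inherits(sizes, "cluster_sizes")) sizes <- sizes$sizes
  sizes <- as.numeric(sizes)
  if (any(sizes < 1)) stop("cluster sizes must be >= 1")
  degenerate <- function() {
    structure(list(alpha = NA_real_, d = NA_real_, x_min = x_min,
                   log_likelihood = NA_real_, n_tail = 0L, method = method,
                   d_convention = d_convention, degenerate = TRUE),
              class = "power_law_fit")
  }
  if (length(sizes) == 0L) return(degenerate())
  if (x_min_policy == "ks") {
    cands <- sort(unique(sizes))
    cands <- cands[vapply(cands, function(xm) {
      tl <- sizes[sizes >= xm]
      length(tl) >= min_tail && length(unique(tl)) >= 2L
    }, logical(1))]
    if (length(cands) == 0L) return(degenerate())
    dists <- vapply(cands, function(xm) {
      tl <- sizes[sizes >= xm]
      fit <- fit_pl_tail(tl, xm, method)
      if (is.null(fit)) return(Inf)
      pl_ks_distance(tl, xm, fit$alpha, method)
    }, numeric(1))
    x_min <- cands[which.min(dists)]
  }
  tail_sizes <- sizes[sizes >= x_min]
  if (length(tail_sizes) < min_tail || length(unique(tail_sizes)) < 2L)
    return(degenerate())
  fit <- fit_pl_tail(tail_sizes, x_min, method)
  if (is.null(fit)) return(degenerate())
  d <- if (d_convention == "alpha-1") fit$alpha - 1 else fit$alpha
  structure(list(alpha = fit$alpha, d = d, x_min = as.integer(x_min),
                 log_likelihood = fit$log_likelihood,
                 n_tail = length(tail_sizes), method = method,
                 d_convention = d_convention, degenerate = FALSE),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<power_law_fit> degenerate (D missing)\n")
  } else {
    cat("<power_law_fit> alpha = ", signif(x$alpha, 5), ", D = ",
        signif(x$d, 5), " (", x$d_convention, "), x_min = ", x$x_min,
        ", n_tail = ", x$n_tail, ", ", x$method, "\n", sep = "")
  }
  invisible(x)
}

#' Join counts and the normalized join count (NJC)
#'
#' Classifies every unordered pair of adjacent voxels that both lie inside
#' the lung as LAA-to-LAA, normal-to-LAA, or normal-to-normal, and reports
#' `NJC = 100 * J_LL / (J_LL + J_NL + J_NN)`. Adjacency is a shared face
#' (3D) or shared edge (2D) by default. Pairs crossing the lung boundary
#' are not counted, so out-of-lung air never inflates the normal-normal
#' count.
#'
#' @param laa LAA [binary_mask()] (or logical array), a subset of `lung`.
#' @param lung Lung [binary_mask()] (or logical array).
#' @param connectivity Adjacency tag, see [label_connected_components()].
#' @return Object of class `join_count_result`: `j_ll`, `j_nl`, `j_nn`,
#'   `n_joins`, `njc` (percent), `connectivity`. A lung with no internal
#'   joins yields `njc = NA` with a warning.
#' @export
compute_join_counts <- function(laa, lung, connectivity = "faces") {
  laa_arr <- if (inherits(laa, "binary_mask")) laa$indicator else as.array(laa)
  lung_arr <- if (inherits(lung, "binary_mask")) lung$indicator else as.array(lung)
  storage.mode(laa_arr) <- "logical"
  storage.mode(lung_arr) <- "logical"
  if (!identical(dim(laa_arr), dim(lung_arr)))
    stop("'laa' and 'lung' must have identical shape")
  if (any(laa_arr & !lung_arr)) stop("LAA mask must be a subset of the lung mask")
  offsets <- connectivity_offsets(connectivity, ndim = length(dim(lung_arr)))
  pairs <- lattice_pairs(lung_arr, offsets)
  n_joins <- nrow(pairs)
  if (n_joins == 0L) {
    warning("lung mask has no internal joins; NJC undefined")
    return(structure(list(j_ll = 0L, j_nl = 0L, j_nn = 0L, n_joins = 0L,
                          njc = NA_real_, connectivity = connectivity),
                     class = "join_count_result"))
  }
  a_laa <- laa_arr[pairs[, "a"]]
  b_laa <- laa_arr[pairs[, "b"]]
  j_ll <- sum(a_laa & b_laa)
  j_nn <- sum(!a_laa & !b_laa)
  j_nl <- n_joins - j_ll - j_nn
  structure(list(j_ll = as.integer(j_ll), j_nl = as.integer(j_nl),
                 j_nn = as.integer(j_nn), n_joins = as.integer(n_joins),
                 njc = 100 * j_ll / n_joins, connectivity = connectivity),
            class = "join_count_result")
}

#' @export
print.join_count_result <- function(x, ...) {
  cat("<join_counts> LL ", x$j_ll, ", NL ", x$j_nl, ", NN ", x$j_nn,
      "; NJC = ", signif(x$njc, 4), "%\n", sep = "")
  invisible(x)
}
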