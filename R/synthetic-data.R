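# Ground-truth-known simulation: slice patterns from a known shot-noise Cox
# state, rasterized HU slices, whole subjects, and statistical cohorts that
# emulate the structural relationships the association pipeline assumes.

#' Elliptical or rectangular observation windows
#'
#' The lung region of a simulated axial slice is modeled as an ellipse
#' (analytic area, simple mass computation); a full rectangle is available
#' for benchmarks on square windows.
#'
#' @param semi_axes Ellipse semi-axes (a, b) in mm.
#' @param spacing In-plane voxel spacing (dx, dy) in mm.
#' @return List with `window` (logical matrix) and `spacing`, usable as the
#'   window of a [slice_pattern()].
#' @export
ellipse_window <- function(semi_axes, spacing = c(0.6, 0.6)) {
  a <- semi_axes[1]; b <- semi_axes[2]
  nx <- ceiling(2 * a / spacing[1]) + 2L
  ny <- ceiling(2 * b / spacing[2]) + 2L
  cx <- nx * spacing[1] / 2
  cy <- ny * spacing[2] / 2
  xs <- (seq_len(nx) - 0.5) * spacing[1]
  ys <- (seq_len(ny) - 0.5) * spacing[2]
  win <- outer(xs, ys, function(x, y) ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1)
  list(window = win, spacing = spacing)
}

#' @rdname ellipse_window
#' @param width,height Rectangle dimensions in mm.
#' @export
rect_window <- function(width, height, spacing = c(0.6, 0.6)) {
  nx <- round(width / spacing[1])
  ny <- round(height / spacing[2])
  list(window = matrix(TRUE, nx, ny), spacing = spacing)
}

#' Random well-separated truth state for recovery benchmarks
#'
#' Places `K` isotropic Gaussian clusters uniformly in the window with a
#' margin of `2 * sigma` from the window edge and a minimum pairwise
#' center separation of `4 * sigma` (emulating distinct emphysematous
#' lesions), then sets the noise intensity so that the expected share of
#' points from the homogeneous component equals `noise_share`.
#'
#' @param K Number of clusters.
#' @param w Expected points per cluster.
#' @param sigma Isotropic kernel standard deviation, mm.
#' @param noise_share Expected fraction of points from the noise component,
#'   in `[0, 1)`.
#' @param window Window spec from [ellipse_window()] or [rect_window()].
#' @param seed RNG seed.
#' @return An [sncp_state()].
#' @export
random_sncp_state <- function(K, w, sigma, noise_share, window, seed = 1L) {
  set.seed(seed)
  win <- window$window
  spacing <- window$spacing
  area <- sum(win) * prod(spacing)
  centers <- matrix(numeric(0), ncol = 2)
  if (K > 0) {
    margin <- 2 * sigma
    tries <- 0L
    while (nrow(centers) < K) {
      if ((tries <- tries + 1L) > 10000L)
        stop("could not place ", K, " separated clusters in the window")
      ix <- sample.int(nrow(win) * ncol(win), 1L)
      pos <- arrayInd(ix, dim(win))
      if (!win[ix]) next
      cand <- c((pos[1] - stats::runif(1)) * spacing[1],
                (pos[2] - stats::runif(1)) * spacing[2])
      # margin: all four axis-aligned neighbors at distance `margin` inside
      probe <- rbind(cand + c(margin, 0), cand - c(margin, 0),
                     cand + c(0, margin), cand - c(0, margin))
      pix <- cbind(pmin(pmax(ceiling(probe[, 1] / spacing[1]), 1L), nrow(win)),
                   pmin(pmax(ceiling(probe[, 2] / spacing[2]), 1L), ncol(win)))
      if (!all(win[pix])) next
      if (nrow(centers) > 0 &&
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) < 4 * sigma) next
      centers <- rbind(centers, cand)
    }
  }
  covs <- matrix(rep(c(sigma^2, 0, sigma^2), each = max(K, 0)), ncol = 3)
  state <- sncp_state(centers, rep(w, K), covs, epsilon = 0)
  eps <- 0
  if (noise_share > 0) {
    if (K > 0) {
      dummy <- slice_pattern(matrix(numeric(0), ncol = 2), win, spacing)
      expected_clustered <- sum(w * sncp_window_mass(dummy, state))
      eps <- noise_share / (1 - noise_share) * expected_clustered / area
    } else {
      stop("with K = 0 specify the noise intensity directly via sncp_state()")
    }
  }
  sncp_state(centers, rep(w, K), covs, epsilon = eps)
}

#' Simulate a slice pattern from a known SNCP state
#'
#' Noise points: `Poisson(epsilon * |W|)`, uniform over the window.
#' Per cluster: `Poisson(w_j * mass_j)` points from the Gaussian kernel
#' truncated to the window by rejection.
#'
#' @param truth An [sncp_state()].
#' @param window Window spec from [ellipse_window()] / [rect_window()].
#' @param seed RNG seed.
#' @param slice_index Stored in the resulting pattern.
#' @return List with `pattern` (a [slice_pattern()]) and `truth` (a
#'   `slice_truth`: the state, window spec, realized cluster/noise counts).
#' @export
simulate_slice_pattern <- function(truth, window, seed = 1L,
                                   slice_index = NA_integer_) {
  stopifnot(inherits(truth, "sncp_state"))
  set.seed(seed)
  win <- window$window
  spacing <- window$spacing
  area <- sum(win) * prod(spacing)
  dummy <- slice_pattern(matrix(numeric(0), ncol = 2), win, spacing)
  masses <- sncp_window_mass(dummy, truth)
  pts <- matrix(numeric(0), ncol = 2)
  cluster_counts <- integer(truth$K)
  if (truth$K > 0) {
    for (j in seq_len(truth$K)) {
      nj <- stats::rpois(1L, truth$weights[j] * masses[j])
      cluster_counts[j] <- nj
      if (nj == 0L) next
      L <- chol2x2(truth$covs[j, ])
      got <- matrix(numeric(0), ncol = 2)
      while (nrow(got) < nj) {
        m <- (nj - nrow(got)) * 2L + 10L
        z <- matrix(stats::rnorm(2L * m), ncol = 2L) %*% t(L)
        cand <- sweep(z, 2L, truth$centers[j, ], `+`)
        ok <- points_in_window(cand, win, spacing)
        got <- rbind(got, cand[ok, , drop = FALSE])
      }
      pts <- rbind(pts, got[seq_len(nj), , drop = FALSE])
    }
  }
  n_noise <- stats::rpois(1L, truth$epsilon * area)
  if (n_noise > 0L) {
    cells <- which(win)
    pick <- cells[sample.int(length(cells), n_noise, replace = TRUE)]
    pos <- arrayInd(pick, dim(win))
    noise_pts <- cbind((pos[, 1] - stats::runif(n_noise)) * spacing[1],
                       (pos[, 2] - stats::runif(n_noise)) * spacing[2])
    pts <- rbind(pts, noise_pts)
  }
  pattern <- slice_pattern(pts, win, spacing, slice_index = slice_index)
  truth_info <- structure(list(state = truth, window = window,
                               masses = masses,
                               cluster_counts = cluster_counts,
                               noise_count = n_noise,
                               n_points = nrow(pts)),
                          class = "slice_truth")
  list(pattern = pattern, truth = truth_info)
}

chol2x2 <- function(cov3) {
  S <- matrix(c(cov3[1], cov3[2], cov3[2], cov3[3]), 2, 2)
  t(chol(S))
}

points_in_window <- function(pts, win, spacing) {
  if (nrow(pts) == 0L) return(logical(0))
  ix <- ceiling(pts[, 1] / spacing[1])
  iy <- ceiling(pts[, 2] / spacing[2])
  ok <- ix >= 1 & ix <= nrow(win) & iy >= 1 & iy <= ncol(win)
  ok[ok] <- win[cbind(ix[ok], iy[ok])]
  ok
}

#' Rasterize a point pattern into an HU slice and its masks
#'
#' Voxels containing at least one point become LAA voxels and receive an
#' HU value strictly below -950; remaining window (lung) voxels receive HU
#' in (-950, -600]; voxels outside the lung receive a soft-tissue value.
#' By construction, thresholding the emitted volume at -950 HU inside the
#' emitted lung mask reproduces the emitted LAA mask exactly.
#'
#' @param pattern A [slice_pattern()].
#' @param dz Slice thickness in mm (default 0.5).
#' @param seed RNG seed for the HU noise draws.
#' @return List with `ct` (single-slice [ct_volume()]), `lung` and `laa`
#'   ([binary_mask()]s).
#' @export
rasterize_pattern <- function(pattern, dz = 0.5, seed = 1L) {
  stopifnot(inherits(pattern, "slice_pattern"))
  if (dz <= 0) stop("'dz' must be positive")
  set.seed(seed)
  win <- pattern$window
  spacing3 <- c(pattern$spacing, dz)
  laa2 <- matrix(FALSE, nrow(win), ncol(win))
  if (pattern$n_points > 0L) {
    ix <- pmin(pmax(ceiling(pattern$points[, 1] / pattern$spacing[1]), 1L), nrow(win))
    iy <- pmin(pmax(ceiling(pattern$points[, 2] / pattern$spacing[2]), 1L), ncol(win))
    laa2[cbind(ix, iy)] <- TRUE
  }
  hu <- matrix(40, nrow(win), ncol(win))  # soft tissue outside lung
  normal <- win & !laa2
  hu[normal] <- stats::runif(sum(normal), -949.5, -600)
  hu[laa2] <- stats::runif(sum(laa2), -1000, -950.5)
  list(ct = ct_volume(array(hu, c(dim(win), 1L)), spacing3),
       lung = binary_mask(array(win, c(dim(win), 1L)), spacing3, role = "lung"),
       laa = binary_mask(array(laa2, c(dim(win), 1L)), spacing3, role = "laa"))
}

#' Default per-subject imaging simulation settings
#'
#' Controls [simulate_subject()]: a stack of elliptical axial slices whose
#' semi-axes follow a smooth apex-to-base profile, each carrying an
#' independently drawn truth state.
#'
#' @param n_slices Number of axial slices.
#' @param max_semi_axes Mid-lung ellipse semi-axes (mm).
#' @param spacing Voxel spacing (dx, dy, dz) in mm.
#' @param k_rate Expected clusters per 100 cm^2 of lung in a slice.
#' @param w Expected points per cluster.
#' @param sigma Cluster kernel standard deviation, mm.
#' @param noise_share Expected diffuse point share, `[0, 1)`.
#' @return A list of class `subject_sim_spec`.
#' @export
subject_sim_spec <- function(n_slices = 8L, max_semi_axes = c(35, 25),
                             spacing = c(0.6, 0.6, 0.5), k_rate = 15,
                             w = 80, sigma = 2.5, noise_share = 0.2) {
  structure(list(n_slices = as.integer(n_slices),
                 max_semi_axes = max_semi_axes, spacing = spacing,
                 k_rate = k_rate, w = w, sigma = sigma,
                 noise_share = noise_share),
            class = "subject_sim_spec")
}

#' Simulate a whole subject: HU volume, lung and LAA masks, slice truths
#'
#' Slice ellipse semi-axes follow a half-sine profile along the axial
#' direction (small near apex/base). Each slice's cluster count is drawn
#' from a Poisson law with rate proportional to the slice lung area; the
#' pattern is simulated and rasterized, and all slices are stacked into a
#' single volume on the largest slice grid.
#'
#' @param spec A [subject_sim_spec()].
#' @param seed RNG seed.
#' @return List with `ct`, `lung`, `laa` (volume and masks), `truths`
#'   (per-slice `slice_truth` list), and `truth_metrics` (ground-truth
#'   NC, ACS, %-Diffuse, ACA, %LAA computed from the generating states).
#' @export
simulate_subject <- function(spec = subject_sim_spec(), seed = 1L) {
  stopifnot(inherits(spec, "subject_sim_spec"))
  set.seed(seed)
  slice_seeds <- sample.int(.Machine$integer.max, spec$n_slices)
  base <- ellipse_window(spec$max_semi_axes, spec$spacing[1:2])
  dims2 <- dim(base$window)
  hu <- array(40, c(dims2, spec$n_slices))
  lung <- array(FALSE, c(dims2, spec$n_slices))
  laa <- array(FALSE, c(dims2, spec$n_slices))
  truths <- vector("list", spec$n_slices)
  q90 <- stats::qchisq(0.90, df = 2)
  per_slice <- data.frame(k = integer(spec$n_slices), area = numeric(spec$n_slices),
                          eps = numeric(spec$n_slices), wsum = numeric(spec$n_slices))
  for (s in seq_len(spec$n_slices)) {
    prof <- sin(pi * (s - 0.5) / spec$n_slices) * 0.6 + 0.4
    axes <- spec$max_semi_axes * prof
    win <- ellipse_window(axes, spec$spacing[1:2])
    area <- sum(win$window) * prod(spec$spacing[1:2])
    k_mean <- spec$k_rate * (area / 100) / 100  # rate per 100 cm^2 -> count
    K <- stats::rpois(1L, k_mean)
    st <- if (K > 0) {
      random_sncp_state(K, spec$w, spec$sigma, spec$noise_share, win,
                        seed = slice_seeds[s])
    } else {
      # keep a mild diffuse component so empty-cluster slices are not empty
      sncp_state(epsilon = spec$noise_share * spec$w / area)
    }
    sim <- simulate_slice_pattern(st, win, seed = slice_seeds[s] %% 1000000L + s,
                                  slice_index = s)
    ras <- rasterize_pattern(sim$pattern, dz = spec$spacing[3],
                             seed = slice_seeds[s] %% 999983L + s)
    # embed the (smaller) slice grid centered in the base grid
    sd2 <- dim(win$window)
    off <- pmax((dims2 - sd2) %/% 2L, 0L)
    xi <- seq_len(sd2[1]) + off[1]
    yi <- seq_len(sd2[2]) + off[2]
    hu[xi, yi, s] <- ras$ct$hu[, , 1]
    lung[xi, yi, s] <- ras$lung$indicator[, , 1]
    laa[xi, yi, s] <- ras$laa$indicator[, , 1]
    truths[[s]] <- sim$truth
    per_slice$k[s] <- st$K
    per_slice$area[s] <- area
    per_slice$eps[s] <- st$epsilon
    per_slice$wsum[s] <- if (st$K > 0) sum(st$weights * sim$truth$masses) else 0
  }
  voxel_area <- prod(spec$spacing[1:2])
  with_k <- per_slice$k > 0
  noise_share_sl <- with(per_slice, ifelse(eps * area + wsum > 0,
                                           eps * area / (eps * area + wsum), 1))
  truth_metrics <- list(
    nc_rate = mean(per_slice$k / (per_slice$area / 100) * 100),
    acs = if (any(with_k)) spec$w * voxel_area else NA_real_,
    pct_diffuse = 100 * mean(noise_share_sl),
    aca = if (any(with_k)) pi * q90 * spec$sigma^2 else NA_real_,
    pct_laa = 100 * sum(laa) / sum(lung))
  list(ct = ct_volume(hu, spec$spacing),
       lung = binary_mask(lung, spec$spacing, role = "lung"),
       laa = binary_mask(laa, spec$spacing, role = "laa"),
       truths = truths, truth_metrics = truth_metrics)
}

#' Cohort simulation settings
#'
#' Defines the statistical structure of a simulated study cohort:
#' demographics match a typical heavy-smoker COPD cohort (age 63.5 +/- 8.6,
#' 49% female, BMI 28.3 +/- 5.6, 25% current smokers); the eight imaging
#' metrics are generated from two latent factors (overall severity and
#' clustering tendency) so that their correlation signs mirror the
#' empirically observed pattern (burden and join-count strongly positive,
#' power-law exponent negative, cluster size positive); clinical outcomes
#' are linear in the standardized log metrics plus demographic effects and
#' Gaussian noise, with the average-cluster-size effect dominant by
#' default; biomarkers receive effects routed through configurable metric
#' sets and are then LLOQ-censored.
#'
#' @param n_subjects Cohort size (default 300).
#' @param outcome_betas Named list: per outcome, a named numeric vector of
#'   coefficients on standardized log metrics.
#' @param outcome_sd Named numeric vector of residual SDs.
#' @param n_null,n_laa,n_het,n_njcd Biomarker counts per effect route
#'   (none, burden-only, cluster-size/count-routed, join-count/D-routed).
#' @param n_binary,n_excluded Biomarkers censored into the binary
#'   (40% below LLOQ) and excluded (97% below LLOQ) preprocessing classes.
#' @param marker_effect Effect size on routed biomarkers.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 300L,
                        outcome_betas = NULL, outcome_sd = NULL,
                        n_null = 12L, n_laa = 8L, n_het = 12L, n_njcd = 4L,
                        n_binary = 2L, n_excluded = 2L,
                        marker_effect = 0.45) {
  if (is.null(outcome_betas)) {
    outcome_betas <- list(
      fev1     = c(acs = -0.55, d = 0.12, njc = -0.10),
      fvc      = c(acs = -0.45, d = 0.10, njc = -0.08),
      fev1_fvc = c(acs = -0.10, d = 0.025, njc = -0.015),
      frc      = c(acs = 0.60, d = -0.10, njc = 0.12),
      frc_tlc  = c(acs = 0.055, d = -0.012, njc = 0.010),
      mwd6     = c(acs = -160, d = 40, njc = -25),
      sgrq     = c(acs = 12, d = -3.5, njc = 2.0))
  }
  if (is.null(outcome_sd)) {
    outcome_sd <- c(fev1 = 0.45, fvc = 0.55, fev1_fvc = 0.10, frc = 0.6,
                    frc_tlc = 0.06, mwd6 = 220, sgrq = 16)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 outcome_betas = outcome_betas, outcome_sd = outcome_sd,
                 n_null = n_null, n_laa = n_laa, n_het = n_het,
                 n_njcd = n_njcd, n_binary = n_binary,
                 n_excluded = n_excluded, marker_effect = marker_effect),
            class = "cohort_spec")
}

#' Simulate a study cohort with known generative structure
#'
#' See [cohort_spec()] for the generative model. Visual assessment labels
#' are produced by thresholding a noisy monotone function of the latent
#' (standardized log) cluster size, so they correlate with, but do not
#' duplicate, ACS. Biomarker tables come with an LLOQ sidecar; censored
#' values are reported at half the LLOQ.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed; identical seeds give identical cohorts.
#' @return Object of class `cohort_sim`: `cohort` (data.frame),
#'   `biomarkers` (data.frame, one column per marker), `lloq` (data.frame
#'   marker/lloq), `marker_routes` (named character), `spec`, `seed`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n_subjects
  sev <- stats::rnorm(n)    # latent overall severity
  het <- stats::rnorm(n)    # latent clustering tendency

  pct_laa <- exp(log(6) + 1.0 * sev)
  njc <- exp(log(4) + 1.1 * sev + 0.10 * het + stats::rnorm(n, 0, 0.05))
  d <- 1.70 - 0.07 * sev - 0.06 * het + stats::rnorm(n, 0, 0.07)
  d <- pmax(d, 0.8)
  acs <- exp(log(15) + 0.70 * sev + 0.45 * het + stats::rnorm(n, 0, 0.15))
  nc <- exp(log(14) + 0.55 * sev - 0.20 * het + stats::rnorm(n, 0, 0.15))
  pct_diffuse <- 100 * stats::plogis(stats::qlogis(0.29) - 0.8 * sev -
                                       0.5 * het + stats::rnorm(n, 0, 0.3))
  aca <- exp(log(55) + 0.45 * sev + 0.35 * het + stats::rnorm(n, 0, 0.2))
  pct_gt <- 100 * stats::plogis(stats::qlogis(0.20) + 1.0 * sev +
                                  0.35 * het + stats::rnorm(n, 0, 0.4))

  sex <- ifelse(stats::runif(n) < 0.49, "female", "male")
  age <- stats::rnorm(n, 63.5, 8.6)
  bmi <- stats::rnorm(n, 28.3, 5.6)
  height <- ifelse(sex == "male", stats::rnorm(n, 175, 7),
                   stats::rnorm(n, 163, 7))
  smoker <- as.integer(stats::runif(n) < 0.25)

  metrics <- data.frame(pct_laa = pct_laa, d = d, njc = njc, acs = acs,
                        nc = nc, pct_diffuse = pct_diffuse, aca = aca,
                        pct_gt = pct_gt)
  zmet <- as.data.frame(lapply(metrics, function(x) log_standardize(x)$z))

  cov_eff <- list(
    fev1 = -0.012 * (age - 63.5) + 0.40 * (sex == "male") -
      0.010 * (bmi - 28.3) + 0.015 * (height - 170) - 0.10 * smoker,
    fvc = -0.015 * (age - 63.5) + 0.50 * (sex == "male") -
      0.012 * (bmi - 28.3) + 0.020 * (height - 170) - 0.08 * smoker,
    fev1_fvc = -0.002 * (age - 63.5) - 0.01 * smoker,
    frc = 0.010 * (age - 63.5) + 0.45 * (sex == "male") -
      0.020 * (bmi - 28.3) + 0.020 * (height - 170),
    frc_tlc = 0.002 * (age - 63.5) - 0.002 * (bmi - 28.3),
    mwd6 = -6.0 * (age - 63.5) + 40 * (sex == "male") -
      5.0 * (bmi - 28.3) + 1.0 * (height - 170) - 20 * smoker,
    sgrq = 0.1 * (age - 63.5) + 0.2 * (bmi - 28.3) + 8 * smoker)
  intercepts <- c(fev1 = 2.0, fvc = 3.3, fev1_fvc = 0.59, frc = 3.6,
                  frc_tlc = 0.57, mwd6 = 1460, sgrq = 28)

  outcomes <- lapply(names(spec$outcome_betas), function(o) {
    b <- spec$outcome_betas[[o]]
    lin <- intercepts[[o]] + cov_eff[[o]]
    for (m in names(b)) lin <- lin + b[[m]] * zmet[[m]]
    lin + stats::rnorm(n, 0, spec$outcome_sd[[o]])
  })
  names(outcomes) <- names(spec$outcome_betas)

  cle_latent <- 1.2 * zmet$acs + stats::rnorm(n, 0, 0.8)
  cle_levels <- c("absent", "trace", "mild", "moderate", "confluent",
                  "advanced destructive")
  cle <- cut(cle_latent, breaks = c(-Inf, -1.5, -0.5, 0.3, 1.0, 1.8, Inf),
             labels = cle_levels)
  ps_latent <- 0.5 * zmet$pct_laa + stats::rnorm(n)
  paraseptal <- cut(ps_latent, breaks = c(-Inf, 0.8, 1.6, Inf),
                    labels = c("absent", "mild", "substantial"))

  cohort <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                       age = age, sex = sex, bmi = bmi, height = height,
                       smoker = smoker, metrics,
                       as.data.frame(outcomes),
                       cle = cle, paraseptal = paraseptal,
                       stringsAsFactors = FALSE)

  # biomarkers: null / %LAA-routed / heterogeneity-routed (ACS + NC) /
  # NJC+D-routed, plus censored classes
  routes <- c(rep("null", spec$n_null), rep("laa", spec$n_laa),
              rep("het", spec$n_het), rep("njcd", spec$n_njcd),
              rep("het_binary", spec$n_binary),
              rep("excluded", spec$n_excluded))
  n_mark <- length(routes)
  marker_names <- sprintf("M%03d", seq_len(n_mark))
  names(routes) <- marker_names
  eff <- spec$marker_effect
  raw <- vapply(routes, function(r) {
    base <- stats::rnorm(n)
    switch(r,
      null = base,
      laa = base + eff * zmet$pct_laa,
      het = base + eff * zmet$acs + eff * zmet$nc,
      njcd = base + eff * zmet$njc - eff * zmet$d,
      het_binary = base + eff * zmet$acs,
      excluded = base)
  }, numeric(n))
  censor_frac <- ifelse(routes == "excluded", 0.97,
                        ifelse(routes == "het_binary", 0.40, 0.02))
  lloq <- vapply(seq_len(n_mark), function(j)
    stats::quantile(raw[, j], censor_frac[j], names = FALSE), numeric(1))
  censored <- raw
  for (j in seq_len(n_mark))
    censored[censored[, j] < lloq[j], j] <- lloq[j] - abs(lloq[j]) * 0.5 - 0.5
  biomarkers <- as.data.frame(censored)
  names(biomarkers) <- marker_names
  structure(list(cohort = cohort, biomarkers = biomarkers,
                 lloq = data.frame(marker = marker_names, lloq = lloq,
                                   stringsAsFactors = FALSE),
                 marker_routes = routes, spec = spec, seed = seed),
            class = "cohort_sim")
}
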