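#' Read a CT volume from NIfTI or NRRD
#'
#' Formats are recognized by extension: `.nii` / `.nii.gz` (NIfTI, via
#' RNifti) and `.nrrd` (a built-in reader for attached raw/gzip data).
#' Missing spacing metadata is a hard error: every downstream metric has
#' physical units, so defaulting to 1 mm would silently corrupt results.
#'
#' @param path Path to the volume file.
#' @return A [ct_volume()].
#' @export
load_volume <- function(path) {
  vol <- read_volume_file(path)
  ct_volume(vol$data, vol$spacing)
}

#' Read a binary mask from NIfTI or NRRD
#'
#' Any voxel with a non-zero stored value is part of the mask.
#'
#' @param path Path to the mask file.
#' @param role Mask role tag, see [binary_mask()].
#' @return A [binary_mask()].
#' @export
load_mask <- function(path, role = "lung") {
  vol <- read_volume_file(path)
  binary_mask(vol$data != 0, vol$spacing, role = role)
}

read_volume_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    spacing <- abs(RNifti::pixdim(img))
    data <- as.array(img)
    attributes(data) <- list(dim = dim(data))
    if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
    if (length(dim(data)) != 3L) stop("expected a 3D volume in ", path)
    spacing <- spacing[seq_len(3L)]
    if (any(!is.finite(spacing)) || any(spacing <= 0))
      stop("volume has no usable spacing metadata: ", path)
    list(data = data, spacing = spacing)
  } else if (grepl("\\.nrrd$", lower)) {
    nr <- read_nrrd(path)
    if (length(dim(nr$data)) != 3L) stop("expected a 3D volume in ", path)
    list(data = nr$data, spacing = nr$spacing)
  } else {
    stop("unrecognized volume format (expect .nii, .nii.gz or .nrrd): ", path)
  }
}

#' Write a CT volume or binary mask
#'
#' Masks are stored as 8-bit indicators, HU volumes as floating point.
#' Format follows the file extension as in [load_volume()].
#'
#' @param x A [ct_volume()] or [binary_mask()].
#' @param path Output path (`.nii`, `.nii.gz`, or `.nrrd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  is_mask <- inherits(x, "binary_mask")
  if (!is_mask && !inherits(x, "ct_volume"))
    stop("'x' must be a ct_volume or binary_mask")
  data <- if (is_mask) array(as.integer(x$indicator), dim(x$indicator)) else x$hu
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(data,
                           reference = list(pixdim = c(-1, x$spacing, 1, 1, 1, 1)),
                           datatype = if (is_mask) "uint8" else "double")
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.nrrd$", lower)) {
    write_nrrd(data, x$spacing, path,
               type = if (is_mask) "uint8" else "double")
  } else {
    stop("unrecognized output format: ", path)
  }
  invisible(path)
}

#' Threshold a CT volume into an LAA or gas-trapping mask
#'
#' A lung voxel enters the mask when its density is strictly below
#' `threshold_hu` (the conventional emphysema definition at -950 HU on
#' inspiration; -856 HU on expiration marks gas trapping). Voxels outside
#' the lung mask are never thresholded.
#'
#' @param ct A [ct_volume()].
#' @param lung Lung [binary_mask()] with identical shape and spacing.
#' @param threshold_hu Density threshold in HU; default -950.
#' @return A [binary_mask()] with role `"laa"` (threshold -950) or
#'   `"gas-trapping"` (threshold -856).
#' @export
make_threshold_mask <- function(ct, lung, threshold_hu = -950) {
  stopifnot(inherits(ct, "ct_volume"), inherits(lung, "binary_mask"))
  if (!same_geometry(ct, lung))
    stop("'ct' and 'lung' must share shape and spacing")
  role <- if (isTRUE(all.equal(threshold_hu, -856))) "gas-trapping" else "laa"
  binary_mask(lung$indicator & (ct$hu < threshold_hu), ct$spacing, role = role)
}

#' Percentage of lung voxels that are LAA
#'
#' The overall emphysema burden: `100 * #LAA / #lung`.
#'
#' @param laa LAA [binary_mask()], a subset of `lung`.
#' @param lung Lung [binary_mask()].
#' @return Percentage in `[0, 100]`.
#' @export
compute_pct_laa <- function(laa, lung) {
  stopifnot(inherits(laa, "binary_mask"), inherits(lung, "binary_mask"))
  if (!same_geometry(laa, lung)) stop("masks must share shape and spacing")
  n_lung <- sum(lung$indicator)
  if (n_lung == 0L) stop("empty lung mask")
  if (any(laa$indicator & !lung$indicator))
    stop("LAA mask must be a subset of the lung mask")
  100 * sum(laa$indicator) / n_lung
}

#' Percentage of gas trapping on an expiratory scan
#'
#' Percent of lung voxels with HU below -856 in the expiratory volume.
#'
#' @param exp_ct Expiratory [ct_volume()].
#' @param lung Expiratory lung [binary_mask()].
#' @return Percentage in `[0, 100]`.
#' @export
compute_pct_gas_trapping <- function(exp_ct, lung) {
  gt <- make_threshold_mask(exp_ct, lung, threshold_hu = -856)
  compute_pct_laa(gt, lung)
}

#' Extract analyzable 2D axial slice patterns
#'
#' Converts each axial slice (third array axis) into a point pattern of LAA
#' voxel centers within the in-slice lung window. Slices with fewer than
#' `min_lung_voxels` lung voxels are dropped to avoid unstable model fits
#' near the lung apices and bases.
#'
#' @param laa LAA [binary_mask()].
#' @param lung Lung [binary_mask()] with identical geometry.
#' @param min_lung_voxels Minimum lung voxels a slice needs to be retained
#'   (default 100).
#' @param verbose Print a note for each omitted slice.
#' @return List of [slice_pattern()] objects (possibly empty).
#' @export
extract_slice_patterns <- function(laa, lung, min_lung_voxels = 100,
                                   verbose = FALSE) {
  stopifnot(inherits(laa, "binary_mask"), inherits(lung, "binary_mask"))
  if (!same_geometry(laa, lung)) stop("masks must share shape and spacing")
  dims <- dim(lung$indicator)
  spacing2 <- lung$spacing[1:2]
  out <- vector("list", dims[3])
  keep <- logical(dims[3])
  for (k in seq_len(dims[3])) {
    win <- lung$indicator[, , k, drop = TRUE]
    dim(win) <- dims[1:2]
    n_lung <- sum(win)
    if (n_lung < min_lung_voxels) {
      if (verbose)
        message("slice ", k, " omitted (", n_lung, " lung voxels < ",
                min_lung_voxels, ")")
      next
    }
    sl <- laa$indicator[, , k, drop = TRUE]
    dim(sl) <- dims[1:2]
    idx <- which(sl, arr.ind = TRUE)
    pts <- cbind((idx[, 1] - 0.5) * spacing2[1],
                 (idx[, 2] - 0.5) * spacing2[2])
    out[[k]] <- slice_pattern(pts, win, spacing2, slice_index = k)
    keep[k] <- TRUE
  }
  out[keep]
}
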