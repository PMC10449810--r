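#' CT volume container
#'
#' Holds a 3D grid of Hounsfield units together with its physical voxel
#' spacing. Axial slices are always along the third stored axis; readers are
#' responsible for normalizing orientation so that this holds.
#'
#' @param hu 3D numeric array of Hounsfield units (air is about -1000,
#'   water 0).
#' @param spacing Numeric vector of length 3, voxel edge lengths in mm for
#'   each stored axis (dx, dy, dz). Must be strictly positive.
#' @param axis_order Character tag recording the axis convention of the
#'   stored array; purely informational.
#'
#' @return An object of class `ct_volume` with elements `hu`, `spacing`,
#'   `axis_order`.
#' @export
ct_volume <- function(hu, spacing, axis_order = "xyz-axial3") {
  hu <- as.array(hu)
  if (length(dim(hu)) == 2L) dim(hu) <- c(dim(hu), 1L)
  if (length(dim(hu)) != 3L) stop("'hu' must be a 2D or 3D array")
  if (length(hu) == 0L) stop("'hu' must be non-empty")
  if (!all(is.finite(hu))) stop("'hu' must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  structure(list(hu = hu, spacing = spacing, axis_order = axis_order),
            class = "ct_volume")
}

#' Binary voxel mask sharing CT geometry
#'
#' @param indicator 3D logical array; `TRUE` marks voxels belonging to the
#'   region (lung, LAA or gas-trapping).
#' @param spacing Voxel spacing in mm, as in [ct_volume()].
#' @param role One of `"lung"`, `"laa"`, `"gas-trapping"`.
#'
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(indicator, spacing, role = c("lung", "laa", "gas-trapping")) {
  role <- match.arg(role)
  indicator <- as.array(indicator)
  if (length(dim(indicator)) == 2L) dim(indicator) <- c(dim(indicator), 1L)
  if (length(dim(indicator)) != 3L) stop("'indicator' must be a 2D or 3D array")
  if (anyNA(indicator)) stop("'indicator' must not contain NA")
  storage.mode(indicator) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  structure(list(indicator = indicator, spacing = spacing, role = role),
            class = "binary_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$hu), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, HU range [", min(x$hu), ", ", max(x$hu), "]\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask:", x$role, "> ",
      paste(dim(x$indicator), collapse = " x "), " voxels, ",
      sum(x$indicator), " set\n", sep = "")
  invisible(x)
}

#' 2D point pattern of LAA voxel centers in an axial slice
#'
#' Coordinates are physical (mm): a voxel at 1-based grid index (i, j) has
#' its center at ((i - 0.5) * dx, (j - 0.5) * dy). The observation window is
#' the in-slice lung region.
#'
#' @param points Two-column numeric matrix of point coordinates in mm
#'   (may have zero rows). Duplicated points are dropped.
#' @param window Logical matrix, the lung region of the slice.
#' @param spacing In-plane spacing (dx, dy) in mm.
#' @param slice_index 1-based index of the axial slice of origin.
#'
#' @return Object of class `slice_pattern` with fields `points`, `window`,
#'   `spacing`, `voxel_area` (mm^2), `lung_area` (mm^2), `n_points`,
#'   `slice_index`.
#' @export
slice_pattern <- function(points, window, spacing, slice_index = NA_integer_) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) points <- matrix(numeric(0), ncol = 2L)
  if (ncol(points) != 2L) stop("'points' must have two columns (x, y in mm)")
  points <- unique(points)
  window <- as.matrix(window)
  storage.mode(window) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(spacing <= 0))
    stop("'spacing' must be 2 positive values (mm)")
  voxel_area <- spacing[1] * spacing[2]
  if (nrow(points) > 0L) {
    ix <- pmin(pmax(ceiling(points[, 1] / spacing[1]), 1L), nrow(window))
    iy <- pmin(pmax(ceiling(points[, 2] / spacing[2]), 1L), ncol(window))
    if (!all(window[cbind(ix, iy)]))
      stop("all points must lie inside the window")
  }
  structure(list(points = points, window = window, spacing = spacing,
                 voxel_area = voxel_area,
                 lung_area = sum(window) * voxel_area,
                 n_points = nrow(points),
                 slice_index = as.integer(slice_index)),
            class = "slice_pattern")
}

#' @export
print.slice_pattern <- function(x, ...) {
  cat("<slice_pattern> slice ", x$slice_index, ": ", x$n_points,
      " points, lung area ", signif(x$lung_area, 5), " mm^2\n", sep = "")
  invisible(x)
}

same_geometry <- function(a, b) {
  grid_a <- if (inherits(a, "ct_volume")) a$hu else a$indicator
  grid_b <- if (inherits(b, "ct_volume")) b$hu else b$indicator
  identical(dim(grid_a), dim(grid_b)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8))
}
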