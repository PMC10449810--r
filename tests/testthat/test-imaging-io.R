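test_that("volumes round-trip through NIfTI and NRRD with spacing intact", {
  set.seed(11)
  hu <- array(runif(5 * 4 * 3, -1000, 100), c(5, 4, 3))
  ct <- ct_volume(hu, c(0.6, 0.6, 0.5))
  nii <- tempfile(fileext = ".nii.gz")
  nrrd <- tempfile(fileext = ".nrrd")
  write_volume(ct, nii)
  write_volume(ct, nrrd)
  r_nii <- load_volume(nii)
  r_nrrd <- load_volume(nrrd)
  # NIfTI stores pixdim in 32-bit floats; spacing agrees to that precision
  expect_equal(r_nii$spacing, c(0.6, 0.6, 0.5), tolerance = 1e-6)
  expect_identical(r_nii$hu, hu)
  expect_identical(r_nrrd$hu, hu)
  expect_identical(r_nii$hu, r_nrrd$hu)
  expect_equal(r_nii$spacing, r_nrrd$spacing, tolerance = 1e-6)
  expect_identical(r_nrrd$spacing, c(0.6, 0.6, 0.5))
})

test_that("binary masks round-trip bit-exactly in both formats", {
  set.seed(12)
  m <- binary_mask(array(runif(120) < 0.3, c(6, 5, 4)), c(0.7, 0.7, 0.6),
                   role = "laa")
  for (ext in c(".nii.gz", ".nrrd")) {
    f <- tempfile(fileext = ext)
    write_volume(m, f)
    r <- load_mask(f, role = "laa")
    expect_identical(r$indicator, m$indicator)
    expect_equal(r$spacing, m$spacing, tolerance = 1e-6)
  }
})

test_that("unreadable or non-volumetric input fails loudly", {
  expect_error(load_volume(tempfile(fileext = ".nii")), "not found")
  junk <- tempfile(fileext = ".nrrd")
  writeLines("this is not a volume", junk)
  expect_error(load_volume(junk), "NRRD")
  txt <- tempfile(fileext = ".txt")
  writeLines("x", txt)
  expect_error(load_volume(txt), "unrecognized")
})

test_that("NRRD without spacing metadata is rejected, never defaulted", {
  f <- tempfile(fileext = ".nrrd")
  con <- file(f, "wb")
  writeLines(c("NRRD0004", "type: uint8", "dimension: 3", "sizes: 2 2 2",
               "encoding: raw", ""), con)
  writeBin(as.raw(rep(1L, 8)), con)
  close(con)
  expect_error(load_volume(f), "spacing")
})

test_that("thresholding uses a strict inequality at the HU cutoff", {
  hu <- array(-800, c(3, 3, 1))
  hu[1, 1, 1] <- -951   # below threshold: in
  hu[1, 2, 1] <- -950   # exactly at threshold: out
  hu[1, 3, 1] <- -949.999
  lung <- binary_mask(array(TRUE, c(3, 3, 1)), c(1, 1, 1), "lung")
  laa <- make_threshold_mask(ct_volume(hu, c(1, 1, 1)), lung, -950)
  expect_true(laa$indicator[1, 1, 1])
  expect_false(laa$indicator[1, 2, 1])
  expect_false(laa$indicator[1, 3, 1])
  expect_identical(laa$role, "laa")
})

test_that("threshold mask matches direct enumeration and never leaves the lung", {
  hu <- array(c(-960, -955, -951, -950, -940, -900, -970, -800, -500),
              c(3, 3, 1))
  lung_ind <- array(TRUE, c(3, 3, 1))
  lung_ind[3, 3, 1] <- FALSE  # the -500 voxel is outside the lung
  lung <- binary_mask(lung_ind, c(1, 1, 1), "lung")
  laa <- make_threshold_mask(ct_volume(hu, c(1, 1, 1)), lung, -950)
  expect_equal(sum(laa$indicator), 4L)  # -960, -955, -951, -970
  expect_true(all(laa$indicator[hu < -950 & lung_ind]))
  expect_false(any(laa$indicator & !lung_ind))
  # mask conservation: |LAA| + |lung \ LAA| = |lung|
  expect_equal(sum(laa$indicator) + sum(lung_ind & !laa$indicator),
               sum(lung_ind))
})

test_that("raising the threshold never shrinks the mask", {
  set.seed(13)
  hu <- array(runif(200, -1000, -700), c(10, 10, 2))
  lung <- binary_mask(array(TRUE, c(10, 10, 2)), c(1, 1, 1), "lung")
  ct <- ct_volume(hu, c(1, 1, 1))
  counts <- vapply(c(-980, -950, -900, -856, -800),
                   function(th) sum(make_threshold_mask(ct, lung, th)$indicator),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("%LAA is the LAA share of lung voxels in percent", {
  lung <- binary_mask(array(TRUE, c(3, 3, 1)), c(1, 1, 1), "lung")
  none <- binary_mask(array(FALSE, c(3, 3, 1)), c(1, 1, 1), "laa")
  expect_equal(compute_pct_laa(none, lung), 0)
  all_laa <- binary_mask(array(TRUE, c(3, 3, 1)), c(1, 1, 1), "laa")
  expect_equal(compute_pct_laa(all_laa, lung), 100)
  four <- array(FALSE, c(3, 3, 1))
  four[1:4] <- TRUE
  expect_equal(compute_pct_laa(binary_mask(four, c(1, 1, 1), "laa"), lung),
               100 * 4 / 9)
  empty <- binary_mask(array(FALSE, c(3, 3, 1)), c(1, 1, 1), "lung")
  expect_error(compute_pct_laa(none, empty), "empty lung")
})

test_that("gas trapping thresholds expiratory scans at -856 HU", {
  lung <- binary_mask(array(TRUE, c(2, 2, 2)), c(1, 1, 1), "lung")
  expect_equal(compute_pct_gas_trapping(
    ct_volume(array(-800, c(2, 2, 2)), c(1, 1, 1)), lung), 0)
  expect_equal(compute_pct_gas_trapping(
    ct_volume(array(-900, c(2, 2, 2)), c(1, 1, 1)), lung), 100)
  hu <- array(-800, c(2, 2, 2))
  hu[1:4] <- -900
  expect_equal(compute_pct_gas_trapping(ct_volume(hu, c(1, 1, 1)), lung), 50)
})

test_that("slice extraction applies the minimum lung-voxel filter", {
  dims <- c(20, 20, 3)
  lung <- array(FALSE, dims)
  lung[seq_len(50)] <- TRUE                      # slice 1: 50 lung voxels
  lung[400 + seq_len(150)] <- TRUE               # slice 2: 150
  lung[800 + seq_len(200)] <- TRUE               # slice 3: 200
  laa <- array(FALSE, dims)
  laa[401] <- TRUE
  lungm <- binary_mask(lung, c(0.6, 0.6, 0.5), "lung")
  laam <- binary_mask(laa, c(0.6, 0.6, 0.5), "laa")
  pats <- extract_slice_patterns(laam, lungm, min_lung_voxels = 100)
  expect_length(pats, 2L)
  expect_equal(vapply(pats, `[[`, integer(1), "slice_index"), c(2L, 3L))
  # boundary: exactly 100 voxels passes, 99 does not
  lung99 <- array(FALSE, c(20, 20, 1))
  lung99[seq_len(99)] <- TRUE
  expect_length(extract_slice_patterns(
    binary_mask(array(FALSE, c(20, 20, 1)), c(1, 1, 1), "laa"),
    binary_mask(lung99, c(1, 1, 1), "lung")), 0L)
  lung100 <- array(FALSE, c(20, 20, 1))
  lung100[seq_len(100)] <- TRUE
  pats100 <- extract_slice_patterns(
    binary_mask(array(FALSE, c(20, 20, 1)), c(1, 1, 1), "laa"),
    binary_mask(lung100, c(1, 1, 1), "lung"))
  expect_length(pats100, 1L)
  expect_equal(pats100[[1]]$n_points, 0L)
})

test_that("slice patterns carry voxel-center coordinates and exact areas", {
  lung <- array(TRUE, c(4, 4, 1))
  laa <- array(FALSE, c(4, 4, 1))
  laa[2, 3, 1] <- TRUE
  pats <- extract_slice_patterns(binary_mask(laa, c(0.5, 0.8, 1), "laa"),
                                 binary_mask(lung, c(0.5, 0.8, 1), "lung"),
                                 min_lung_voxels = 1)
  p <- pats[[1]]
  expect_equal(p$points, cbind(1.5 * 0.5, 2.5 * 0.8), ignore_attr = TRUE)
  expect_equal(p$lung_area, 16 * 0.5 * 0.8)
  expect_equal(p$voxel_area, 0.4)
})

test_that("summed slice areas reproduce the 3D lung volume when all slices pass", {
  sub <- toy_subject(seed = 21)
  pats <- extract_slice_patterns(sub$laa, sub$lung, min_lung_voxels = 1)
  vol_from_slices <- sum(vapply(pats, `[[`, numeric(1), "lung_area")) *
    sub$lung$spacing[3]
  vol_3d <- sum(sub$lung$indicator) * prod(sub$lung$spacing)
  expect_equal(vol_from_slices, vol_3d)
})
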