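# Trans-PSD module detection: surface sheets, contact rule, table summaries.

test_that("box surface sheets are its two broad faces", {
  m <- make_box_mask(c(5, 10, 20), 1, c(5, 10, 20))  # 20 x 10 x 5 nm box
  sheets <- classify_surface_voxels(m)
  expect_equal(nrow(sheets$top), 200)
  expect_equal(nrow(sheets$bottom), 200)
  # thickness axis is z, so the sheets are the z = 5 and z = 1 layers
  expect_setequal(unique(sheets$top[, "z"]), 5L)
  expect_setequal(unique(sheets$bottom[, "z"]), 1L)
})

test_that("a single-voxel-thick sheet is its own top and bottom", {
  m <- make_box_mask(c(1, 12, 18), 1, c(1, 12, 18))
  sheets <- classify_surface_voxels(m)
  expect_equal(nrow(sheets$top), 12 * 18)
  expect_equal(nrow(sheets$bottom), 12 * 18)
  expect_identical(sheets$top[order(sheets$top[, 2], sheets$top[, 3]), ],
                   sheets$bottom[order(sheets$bottom[, 2], sheets$bottom[, 3]), ])
})

test_that("per-cell extrema match a brute-force column sweep on a cap", {
  # hemispherical cap: top and bottom sheets disjoint except at the rim
  dims <- c(16, 32, 32)
  vox <- 1
  zc <- (seq_len(dims[1]) - 0.5); yc <- (seq_len(dims[2]) - 0.5)
  xc <- (seq_len(dims[3]) - 0.5)
  arr <- array(FALSE, dim = dims)
  for (z in seq_len(dims[1]))
    arr[z, , ] <- outer((yc - 16)^2, (xc - 16)^2, "+") + zc[z]^2 <= 14^2
  m <- binary_mask(arr, vox)
  ax <- principal_axes(m)
  # thickness axis should be z for a flat cap
  expect_gt(abs(ax$axes[1, 3]), 0.99)
  sheets <- classify_surface_voxels(m, ax)
  # brute force: per (y, x) column take min/max z (cap columns are z-aligned
  # because the thickness axis is z and the cell pitch is 1 voxel)
  overlap <- merge(as.data.frame(sheets$top), as.data.frame(sheets$bottom),
                   by = c("z", "y", "x"))
  # shared cells (rim, where the column has one voxel) are a minority
  expect_lt(nrow(overlap) / nrow(sheets$top), 0.35)
  # every bottom voxel of an interior column lies at z = 1
  deep <- sheets$bottom[sheets$bottom[, "y"] %in% 10:22 &
                        sheets$bottom[, "x"] %in% 10:22, , drop = FALSE]
  expect_true(all(deep[, "z"] == 1L))
})

test_that("only the full-thickness cylinder is trans among stacked blobs", {
  # thin along z (thickness axis) and mirror-symmetric about the y mid-plane
  # and z mid-plane, so the principal axes coincide with the grid axes
  dims <- c(12, 40, 60)
  vox <- 1
  arr <- array(0L, dim = dims)
  # cylinder label 1 spanning all z
  yc <- seq_len(dims[2]) - 0.5; xc <- seq_len(dims[3]) - 0.5
  cyl <- outer((yc - 20)^2, (xc - 15)^2, "+") <= 8^2
  for (z in 1:12) { sl <- arr[z, , ]; sl[cyl] <- 1L; arr[z, , ] <- sl }
  # two stacked pairs of half-thickness blobs sharing footprints (labels 2-5)
  blob <- outer((yc - 20)^2, (xc - 38)^2, "+") <= 7^2
  for (z in 1:6) { sl <- arr[z, , ]; sl[blob & sl == 0L] <- 2L; arr[z, , ] <- sl }
  for (z in 7:12) { sl <- arr[z, , ]; sl[blob & sl == 0L] <- 3L; arr[z, , ] <- sl }
  blob2 <- outer((yc - 20)^2, (xc - 50)^2, "+") <= 5^2
  for (z in 1:6) { sl <- arr[z, , ]; sl[blob2 & sl == 0L] <- 4L; arr[z, , ] <- sl }
  for (z in 7:12) { sl <- arr[z, , ]; sl[blob2 & sl == 0L] <- 5L; arr[z, , ] <- sl }
  lab <- label_volume(arr, vox)
  psd <- measure_psd(binary_mask(arr > 0L, vox))
  tr <- find_trans_modules(lab, psd, min_contact_voxels = 1L)
  expect_identical(tr$trans_label_ids, 1L)
  expect_equal(tr$n_trans, 1L)
  # fractions are percentages of the PSD volume and sum to the total
  expect_equal(tr$total_trans_volume_percent,
               sum(tr$modules$fraction_of_psd_volume))
  expect_equal(tr$modules$volume_nm3 / psd$volume_nm3 * 100,
               tr$modules$fraction_of_psd_volume)
})

test_that("a quarter-thickness slab is not trans", {
  dims <- c(10, 24, 24)
  arr <- array(0L, dim = dims)
  arr[1:10, 2:23, 2:23] <- 1L          # full-thickness block (thin along z)
  arr[1:3, 8:17, 8:17] <- 2L           # quarter-thickness slab at the bottom
  lab <- label_volume(arr, 1)
  psd <- measure_psd(binary_mask(arr > 0L, 1))
  tr <- find_trans_modules(lab, psd, 1L)
  expect_false(2L %in% tr$trans_label_ids)
  expect_true(1L %in% tr$trans_label_ids)
})

test_that("phantom ground truth yields exactly the constructed trans count", {
  sp <- small_psd_spec(seed = 1, noise_sigma = 0, z_blur_sigma_nm = 0)
  ph <- generate_phantom(sp)
  psd <- measure_psd(binary_mask(ph$truth$labels$data > 0L, sp$voxel_size_nm))
  tr <- find_trans_modules(ph$truth$labels, psd, min_contact_voxels = 100L)
  expect_equal(tr$n_trans, 2L)
  expect_setequal(tr$trans_label_ids,
                  ph$truth$manifest$label[ph$truth$manifest$is_trans])
})

test_that("reference-table trans summaries reproduce the printed ranges", {
  t1 <- psd_reference_table()
  t2 <- trans_reference_table()
  s <- trans_summary_from_table(t2, t1)
  expect_equal(s$control$n_trans, 16L)
  expect_equal(round(s$control$size_range_nm_raw), c(93, 141))
  expect_equal(s$sonicated$n_trans, 5L)
  expect_equal(round(s$sonicated$size_range_nm_raw), c(105, 169))
  expect_equal(signif(s$control$volume_range_nm3_raw, 2), c(6.0e4, 5.2e5))
  expect_equal(signif(s$sonicated$volume_range_nm3_raw, 2), c(1.0e5, 4.6e5))
  expect_equal(signif(s$control$total_percent_range_raw, 2), c(6.3, 19))
  expect_equal(signif(s$sonicated$total_percent_range_raw, 2), c(3.1, 18))
  expect_equal(signif(s$sonicated$individual_percent_range_raw[1], 2), 1.4)
  # per-PSD totals never exceed 100%
  expect_true(all(s$control$per_psd_total_percent <= 100))
})

test_that("one module at 10% of its PSD reports 10% individually and in total", {
  psd <- data.frame(psd_id = "P", group = "g", area_1e4nm2 = 1,
                    thickness_nm = 100, volume_1e4nm3 = 100)
  tt <- data.frame(psd_id = "P", group = "g", module_id = 1,
                   volume_1e4nm3 = 10, size_nm = 120)
  s <- trans_summary_from_table(tt, psd)
  expect_equal(s$g$total_percent_range_raw, c(10, 10))
  expect_equal(s$g$individual_percent_range_raw, c(10, 10))
  # orphan PSD ids are rejected
  bad <- tt; bad$psd_id <- "Q"
  expect_error(trans_summary_from_table(bad, psd), "unknown PSDs")
})
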