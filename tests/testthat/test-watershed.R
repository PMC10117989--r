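# Marker-controlled watershed: oracle agreement on two-sphere toys,
# conservation, determinism, parameter monotonicity, small-label merging.

test_that("two overlapping spheres are split at their density valley", {
  dims <- c(40, 40, 64)
  r <- 15                                        # voxels (voxel size 1 nm)
  centers <- rbind(c(20, 20, 20), c(20, 20, 45)) # overlap by 5 voxels
  ts <- two_sphere_density(dims, 1, centers, r, gap = 0.5)
  lab <- segment_modules(ts$volume, ts$mask,
                         watershed_params(smoothing_sigma_nm = 2))
  expect_length(lab$label_ids, 2L)
  # centroids near the sphere centers
  for (k in 1:2) {
    w <- which(lab$data == k, arr.ind = TRUE)
    ctr <- colMeans(w) - 0.5
    m <- which.min(colSums((t(centers) - ctr)^2))
    expect_lt(sqrt(sum((centers[m, ] - ctr)^2)), 1.5)
  }
  # >= 95% of voxels agree with nearest-center assignment (the oracle)
  w <- which(ts$mask$data, arr.ind = TRUE)
  d1 <- rowSums(sweep(w - 0.5, 2L, centers[1, ])^2)
  d2 <- rowSums(sweep(w - 0.5, 2L, centers[2, ])^2)
  oracle <- ifelse(d1 <= d2, 1L, 2L)
  got <- lab$data[w]
  # label ids may be swapped; align by majority
  map <- c(as.integer(names(which.max(table(got[oracle == 1L])))),
           as.integer(names(which.max(table(got[oracle == 2L])))))
  expect_gt(mean(got == map[oracle]), 0.95)
})

test_that("a single convex blob yields one label equal to the mask", {
  m <- make_sphere_mask(c(24, 24, 24), 1, 8)
  vol <- density_volume(array(as.numeric(m$data), dim = dim(m$data)), 1)
  lab <- segment_modules(vol, m)
  expect_length(lab$label_ids, 1L)
  expect_identical(unname(lab$data == 1L), unname(m$data))
})

test_that("watershed is conservative and deterministic", {
  sp <- small_psd_spec(seed = 3)
  ph <- generate_phantom(sp)
  mask <- binary_mask(ph$truth$labels$data > 0L, sp$voxel_size_nm)
  lab1 <- segment_modules(ph$volume, mask)
  lab2 <- segment_modules(ph$volume, mask)
  expect_identical(lab1$data, lab2$data)
  expect_equal(sum(lab1$data > 0L), sum(mask$data))      # conservation
  # labels ordered by descending size
  sizes <- tabulate(lab1$data[lab1$data > 0L])
  expect_true(all(diff(sizes) <= 0))
})

test_that("increasing h_depth never increases the label count", {
  sp <- small_psd_spec(seed = 1)
  ph <- generate_phantom(sp)
  mask <- binary_mask(ph$truth$labels$data > 0L, sp$voxel_size_nm)
  counts <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8), function(h)
    length(segment_modules(ph$volume, mask,
                           watershed_params(h_depth = h))$label_ids),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("flat relief and h_depth = 1 give a single-label partition", {
  m <- make_box_mask(c(10, 10, 10), 1, c(6, 6, 6), c(3, 3, 3))
  flat <- density_volume(array(1, dim = c(10, 10, 10)), 1)
  lab <- segment_modules(flat, m)
  expect_length(lab$label_ids, 1L)
  expect_equal(sum(lab$data > 0L), sum(m$data))
})

test_that("the distance-transform variant splits touching binary spheres", {
  dims <- c(32, 32, 56)
  ts <- two_sphere_density(dims, 1, rbind(c(16, 16, 16), c(16, 16, 40)), 13,
                           gap = 0)                       # binary density
  lab <- segment_modules(ts$volume, ts$mask,
                         watershed_params(method = "distance",
                                          smoothing_sigma_nm = 0))
  expect_length(lab$label_ids, 2L)
  expect_equal(sum(lab$data > 0L), sum(ts$mask$data))
})

test_that("merge_small_labels folds specks into their largest neighbor", {
  arr <- array(0L, dim = c(6, 6, 20))
  arr[2:5, 2:5, 2:11] <- 1L                       # 4 x 4 x 10 = 160 voxels
  arr[3, 3, 12] <- 2L                             # 1-voxel neighbor
  lab <- label_volume(arr, 1)
  merged <- merge_small_labels(lab, 10L)
  expect_length(merged$label_ids, 1L)
  expect_equal(sum(merged$data == 1L), 161)
  expect_identical(merge_small_labels(lab, 1L)$data, lab$data)  # identity
  expect_error(merge_small_labels(lab, 10000L), "exceeds")
})

test_that("equal boundary contact merges a tiny label into the smaller id", {
  # chain A | B | C with B tiny and sharing one face with each of A and C;
  # sizes of A and C differ so renumbering is unambiguous
  arr <- array(0L, dim = c(3, 3, 9))
  arr[1:3, 1:3, 1:3] <- 1L                        # 27 voxels
  arr[2, 2, 4] <- 3L                              # tiny middle
  arr[1:3, 1:3, 5:7] <- 2L
  arr[1:2, 1:3, 8] <- 2L                          # 33 voxels: label 2 biggest
  lab <- label_volume(arr, 1)
  # after construction: ids 1 (27 vox), 2 (33 vox), 3 (1 vox); contact of 3
  # with 1 and 2 is one face each -> tie -> merge into smaller id (1)
  merged <- merge_small_labels(lab, 5L)
  sizes <- tabulate(merged$data[merged$data > 0L])
  expect_equal(sort(sizes), c(28, 33))
  # the tiny voxel joined the 27-voxel block (smaller id on tie)
  expect_equal(merged$data[2, 2, 4], merged$data[1, 1, 1])
})

test_that("partition conservation holds through merging on phantoms", {
  sp <- small_psd_spec(seed = 6)
  ph <- generate_phantom(sp)
  mask <- binary_mask(ph$truth$labels$data > 0L, sp$voxel_size_nm)
  lab <- segment_modules(ph$volume, mask)
  merged <- merge_small_labels(lab, 27L)
  expect_equal(sum(merged$data > 0L), sum(mask$data))
  expect_lte(length(merged$label_ids), length(lab$label_ids))
})

test_that("noiseless phantoms are recovered at or near the true count", {
  # well-separated configuration: exact recovery
  sp <- small_psd_spec(seed = 9, n_modules = 7L, module_median_nm = 60,
                       module_sigma_log = 0.15, n_trans_modules = 1L,
                       noise_sigma = 0, z_blur_sigma_nm = 0)
  ph <- generate_phantom(sp)
  mask <- binary_mask(ph$truth$labels$data > 0L, sp$voxel_size_nm)
  lab <- segment_modules(ph$volume, mask)
  expect_equal(length(lab$label_ids), nrow(ph$truth$manifest))
  # canonical geometry without noise: >= 90% of modules found (pairs below
  # the 4 nm smoothing scale may merge)
  spd <- default_psd_spec(seed = 2)
  spd$noise_sigma <- 0; spd$z_blur_sigma_nm <- 0
  phd <- generate_phantom(spd)
  maskd <- binary_mask(phd$truth$labels$data > 0L, spd$voxel_size_nm)
  labd <- segment_modules(phd$volume, maskd)
  expect_gte(length(labd$label_ids), ceiling(0.9 * nrow(phd$truth$manifest)))
  expect_lte(length(labd$label_ids), nrow(phd$truth$manifest))
})
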