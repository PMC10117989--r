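# Denoising by segmentation optimization: SNR definition, grid search,
# feasibility, idempotence.

test_that("compute_snr is main-component volume over the rest", {
  arr <- array(FALSE, dim = c(20, 20, 40))
  arr[2:11, 2:11, 2:11] <- TRUE                 # 1000 voxels
  arr[15:19, 15, 15] <- TRUE                    # 5
  arr[2:11, 15, 30] <- TRUE                     # 10
  m <- binary_mask(arr, 1)
  expect_equal(compute_snr(m), 1000 / 15, tolerance = 1e-12)
  # a single component has infinite SNR
  solo <- make_box_mask(c(8, 8, 8), 1, c(4, 4, 4))
  expect_identical(compute_snr(solo), Inf)
  expect_error(compute_snr(binary_mask(array(FALSE, dim = c(4, 4, 4)), 1)),
               "empty")
})

test_that("equal-size components give SNR 1 regardless of the tie winner", {
  arr <- array(FALSE, dim = c(10, 10, 20))
  arr[2:3, 2:3, 2:3] <- TRUE                    # 8 voxels
  arr[7:8, 7:8, 15:16] <- TRUE                  # 8 voxels
  m <- binary_mask(arr, 1)
  expect_equal(compute_snr(m), 1)
  # cross-check the component decomposition against a brute-force labeling
  bf <- bf_components(arr, 26L)
  expect_equal(sort(tabulate(bf[bf > 0])), c(8, 8))
  got <- label_components(m, 26L)
  expect_equal(sort(tabulate(got$data[got$data > 0]))[1:2], c(8, 8))
})

test_that("component labeling matches the brute-force oracle on random masks", {
  set.seed(21)
  for (conn in c(6L, 18L, 26L)) {
    arr <- array(runif(12^3) < 0.2, dim = c(12, 12, 12))
    got <- label_components(binary_mask(arr, 1), conn)$data
    bf <- bf_components(arr, conn)
    # same partition: component count and size multiset
    expect_equal(max(got), max(bf))
    expect_equal(sort(tabulate(got[got > 0])), sort(tabulate(bf[bf > 0])))
    # co-membership agrees on a sample of voxel pairs
    on <- which(arr)
    pick <- sample(on, min(40, length(on)))
    expect_equal(outer(got[pick], got[pick], "=="),
                 outer(bf[pick], bf[pick], "=="))
  }
})

test_that("removing small noise components never decreases the SNR", {
  set.seed(8)
  for (rep in 1:5) {
    arr <- array(FALSE, dim = c(24, 24, 24))
    arr[4:15, 4:15, 4:15] <- TRUE
    # sprinkle detached specks
    for (k in 1:15) {
      p <- sample(17:23, 3, replace = TRUE)
      arr[p[1], p[2], p[3]] <- TRUE
    }
    m <- binary_mask(arr, 1)
    snr0 <- compute_snr(m)
    lab <- label_components(m)
    sizes <- tabulate(lab$data[lab$data > 0])
    keep <- lab$data == 1 | lab$data %in% which(sizes >= 2)
    snr1 <- compute_snr(binary_mask(array(keep & arr, dim = dim(arr)), 1))
    expect_gte(snr1, snr0)
  }
})

test_that("the grid search picks the filter that removes all specks", {
  dims <- c(28, 24, 24)
  arr <- array(FALSE, dim = dims)
  arr[2:26, 2:21, 2:21] <- TRUE                  # 25x20x20 = 10,000 voxels
  # 50 isolated single-voxel specks on a 2-voxel lattice beside the blob
  speck_count <- 0
  for (z in seq(2, 26, by = 2)) for (y in seq(2, 20, by = 2)) {
    if (speck_count < 50) {
      arr[z, y, 23] <- TRUE
      speck_count <- speck_count + 1
    }
  }
  expect_equal(speck_count, 50)
  vol <- density_volume(array(as.numeric(arr), dim = dims), 1)
  voi <- binary_mask(array(TRUE, dim = dims), 1)
  res <- run_asom(vol, voi, asom_params(min_component_voxels_grid = c(1L, 50L)))
  expect_equal(res$chosen_min_component, 50L)
  expect_equal(res$components_removed, 50L)
  expect_identical(res$snr_after, Inf)
  expect_equal(sum(res$psd_mask$data), 10000)
})

test_that("a noiseless phantom is segmented exactly with infinite SNR", {
  sp <- small_psd_spec(seed = 1, noise_sigma = 0, z_blur_sigma_nm = 0,
                       gap_contrast = 0)                 # binary density
  ph <- generate_phantom(sp)
  voi <- rasterize_voi(phantom_voi_contours(ph$truth), dim(ph$volume$data),
                       sp$voxel_size_nm)
  res <- run_asom(ph$volume, voi)
  expect_identical(res$snr_after, Inf)
  expect_identical(unname(res$psd_mask$data),
                   unname(ph$truth$labels$data > 0L))
})

test_that("ASOM improves the SNR on noisy phantoms and respects the VOI", {
  for (s in 1:3) {
    sp <- small_psd_spec(seed = s)
    ph <- generate_phantom(sp)
    voi <- rasterize_voi(phantom_voi_contours(ph$truth), dim(ph$volume$data),
                         sp$voxel_size_nm)
    res <- run_asom(ph$volume, voi)
    expect_gte(res$snr_after, res$snr_before)
    expect_true(all(voi$mask$data[res$psd_mask$data]))   # mask within VOI
    # mask within the lowest-threshold mask
    lo <- quantile(ph$volume$data[voi$mask$data], 0.5, names = FALSE)
    expect_gte(res$chosen_threshold, lo)
  }
})

test_that("re-running ASOM on its own output mask returns the same mask", {
  sp <- small_psd_spec(seed = 2)
  ph <- generate_phantom(sp)
  voi <- rasterize_voi(phantom_voi_contours(ph$truth), dim(ph$volume$data),
                       sp$voxel_size_nm)
  res <- run_asom(ph$volume, voi)
  again <- run_asom(density_volume(array(as.numeric(res$psd_mask$data),
                                         dim = dim(res$psd_mask$data)),
                                   sp$voxel_size_nm),
                    voi)
  expect_identical(again$psd_mask$data, res$psd_mask$data)
})

test_that("degenerate inputs are rejected with explicit messages", {
  vol <- density_volume(array(1, dim = c(6, 6, 6)), 1)
  voi <- binary_mask(array(TRUE, dim = c(6, 6, 6)), 1)
  expect_error(run_asom(vol, voi), "constant")
  voi0 <- binary_mask(array(FALSE, dim = c(6, 6, 6)), 1)
  expect_error(run_asom(density_volume(array(rnorm(216), dim = c(6, 6, 6)), 1),
                        voi0), "overlap")
  expect_error(asom_params(threshold_quantiles = c(0.9, 0.5)), "increasing")
  expect_error(asom_params(min_main_fraction = 0), "min_main_fraction")
})
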