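# Principal-axis morphometry: surface extraction, extents, thickness,
# projected area, volume, scaling and rotation behavior, histograms.

test_that("surface voxels are the 6-connectivity boundary", {
  cube3 <- make_box_mask(c(5, 5, 5), 1, c(3, 3, 3), c(2, 2, 2))
  expect_equal(nrow(surface_voxels(cube3)), 26)      # all but the center
  single <- make_box_mask(c(3, 3, 3), 1, c(1, 1, 1), c(2, 2, 2))
  expect_equal(unname(surface_voxels(single)), matrix(c(2L, 2L, 2L), 1))
  cube10 <- make_box_mask(c(12, 12, 12), 1, c(10, 10, 10), c(2, 2, 2))
  expect_equal(nrow(surface_voxels(cube10)), 1000 - 512)
  # brute-force oracle on a random blob
  set.seed(3)
  blob <- make_sphere_mask(c(14, 14, 14), 1, 5)
  expect_equal(nrow(surface_voxels(blob)), bf_surface_count(blob$data))
  # objects touching the grid edge count the edge as surface
  edge <- make_box_mask(c(4, 4, 4), 1, c(4, 4, 4))
  expect_equal(nrow(surface_voxels(edge)), 64 - 8)
})

test_that("an axis-aligned box has closed-form extents and measurements", {
  m <- make_box_mask(c(8, 12, 24), 1, c(5, 10, 20), c(2, 2, 3))
  ax <- principal_axes(m)
  expect_equal(ax$extents_nm, c(20, 10, 5))
  expect_false(ax$degenerate)
  # axes orthonormal
  expect_equal(crossprod(ax$axes), diag(3), tolerance = 1e-9)
  psd <- measure_psd(m)
  expect_equal(psd$thickness_nm, 5)
  expect_equal(psd$area_nm2, 200)
  expect_equal(psd$volume_nm3, 1000)
})

test_that("a digitized sphere has equal extents near its diameter", {
  m <- make_sphere_mask(c(26, 26, 26), 1, 10)
  ax <- principal_axes(m)
  expect_true(all(abs(ax$extents_nm - 20) <= 1))
  psd <- measure_psd(m)
  expect_lt(abs(psd$area_nm2 - pi * 100) / (pi * 100), 0.05)
  expect_equal(psd$volume_nm3, sum(m$data))
})

test_that("extents are stable under rigid rotation within 1.5 voxels", {
  # rotate a 20 x 10 x 5 box by 45 degrees about z by digitizing the rotated
  # solid: voxel centers whose back-rotated coordinates fall inside the box
  dims <- c(9, 40, 40)
  th <- pi / 4
  ctr <- c(4.5, 20, 20)
  half <- c(2.5, 5, 10)
  arr <- array(FALSE, dim = dims)
  for (z in seq_len(dims[1])) for (y in seq_len(dims[2])) {
    pz <- z - 0.5 - ctr[1]; py <- y - 0.5 - ctr[2]
    xs <- seq_len(dims[3]) - 0.5 - ctr[3]
    u <- cos(th) * py + sin(th) * xs
    v <- -sin(th) * py + cos(th) * xs
    arr[z, y, ] <- abs(pz) <= half[1] & abs(u) <= half[2] & abs(v) <= half[3]
  }
  ax <- principal_axes(binary_mask(arr, 1))
  expect_true(all(abs(ax$extents_nm - c(20, 10, 5)) <= 1.5))
})

test_that("random ellipsoids under random rotations match analytic extents", {
  set.seed(17)
  for (rep in 1:6) {
    semi <- sort(runif(3, 4, 12), decreasing = TRUE)   # nm
    # random rotation from QR of a Gaussian matrix
    qr_ <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    dims <- c(34, 34, 34)
    ctr <- dims / 2
    w <- as.matrix(expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]),
                               x = seq_len(dims[3])))
    p <- sweep(w - 0.5, 2L, ctr) %*% R                 # body frame coords
    inside <- (p[, 1] / semi[1])^2 + (p[, 2] / semi[2])^2 +
      (p[, 3] / semi[3])^2 <= 1
    arr <- array(FALSE, dim = dims)
    arr[w[inside, , drop = FALSE]] <- TRUE
    ax <- principal_axes(binary_mask(arr, 1))
    expect_true(all(abs(ax$extents_nm - 2 * semi) <= 1.5))
  }
})

test_that("measurements scale exactly with the voxel size", {
  arr <- make_sphere_mask(c(20, 20, 20), 1, 7)$data
  m1 <- binary_mask(arr, 1)
  m2 <- binary_mask(arr, 2.5)
  a1 <- principal_axes(m1); a2 <- principal_axes(m2)
  expect_equal(a2$extents_nm, a1$extents_nm * 2.5)
  p1 <- measure_psd(m1); p2 <- measure_psd(m2)
  expect_equal(p2$thickness_nm, p1$thickness_nm * 2.5)
  expect_equal(p2$area_nm2, p1$area_nm2 * 2.5^2)
  expect_equal(p2$volume_nm3, p1$volume_nm3 * 2.5^3)
})

test_that("degenerate masks are flagged, not fatal", {
  sheet <- make_box_mask(c(1, 8, 8), 1, c(1, 8, 8))
  ax <- principal_axes(sheet)
  expect_true(ax$degenerate)
  expect_equal(ax$extents_nm[3], 1)   # one-voxel extent, not zero
  single <- make_box_mask(c(3, 3, 3), 0.7, c(1, 1, 1), c(2, 2, 2))
  expect_true(principal_axes(single)$degenerate)
})

test_that("module records carry per-label morphometrics and conserve volume", {
  arr <- array(0L, dim = c(10, 10, 20))
  arr[2:6, 2:6, 2:6] <- 1L
  arr[2:6, 2:6, 12:16] <- 2L
  lab <- label_volume(arr, 1)
  recs <- measure_modules(lab)
  expect_equal(recs$label_id, c(1L, 2L))
  expect_equal(recs$volume_nm3, c(125, 125))
  expect_equal(recs$size_nm, c(5, 5))
  expect_equal(recs$extent3_nm, c(5, 5))
  expect_false(any(recs$is_trans))
  # one-voxel label volume at voxel 0.7
  one <- label_volume(array(c(1L, rep(0L, 7)), dim = c(2, 2, 2)), 0.7)
  expect_equal(measure_modules(one)$volume_nm3, 0.7^3)

  sp <- small_psd_spec(seed = 2, noise_sigma = 0, z_blur_sigma_nm = 0)
  ph <- generate_phantom(sp)
  recs <- measure_modules(ph$truth$labels)
  expect_equal(sum(recs$volume_nm3),
               mask_volume_nm3(binary_mask(ph$truth$labels$data > 0L,
                                           sp$voxel_size_nm)))
  # extent ordering: size >= middle >= thickness-direction extent
  expect_true(all(recs$extent1_nm >= recs$extent2_nm))
  expect_true(all(recs$extent2_nm >= recs$extent3_nm))
  # measured sizes track nominal sizes (median absolute deviation <= 15%)
  dev <- abs(recs$size_nm - ph$truth$manifest$nominal_size_nm) /
    ph$truth$manifest$nominal_size_nm
  expect_lte(median(dev), 0.15)
})

test_that("size histograms bin from zero and report closed-interval fractions", {
  h <- size_histogram(c(45, 50, 85), 10)
  expect_equal(h$counts[5], 1L)                      # 45 in [40, 50)
  expect_equal(h$counts[6], 1L)                      # 50 in [50, 60)
  expect_equal(h$counts[9], 1L)                      # 85 in [80, 90)
  expect_equal(sum(h$counts), 3L)
  expect_equal(h$fraction_40_90, 1)
  h2 <- size_histogram(numeric(0), 10)
  expect_equal(sum(h2$counts), 0)
  expect_true(is.na(h2$fraction_40_90))
  h3 <- size_histogram(c(39.9, 40.0, 90.0, 90.1), 10)
  expect_equal(h3$fraction_40_90, 0.5)
  expect_equal(h3$fraction_10_170, 1)
  expect_error(size_histogram(c(1, 2), 0), "bin_width")
})
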