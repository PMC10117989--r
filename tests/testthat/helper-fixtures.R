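# Shared fixtures and independent brute-force oracles.

# small phantom for fast end-to-end tests (same voxel size and module scale
# as the canonical spec, smaller field of view)
small_psd_spec <- function(seed = 1L, ...) {
  args <- list(grid_shape = c(64L, 160L, 160L), voxel_size_nm = 2,
               disk_diameter_nm = 280, disk_thickness_nm = 110,
               n_modules = 12L, module_median_nm = 50,
               n_trans_modules = 2L, trans_radius_nm = 30,
               gap_contrast = 0.5, noise_sigma = 0.1, z_blur_sigma_nm = 2,
               seed = seed)
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(phantom_spec, args)
}

# digitized solid sphere mask: radius_nm around center (defaults to the grid
# center), voxel centers at (i - 0.5) * vox
make_sphere_mask <- function(dims, voxel_size_nm, radius_nm, center_nm = NULL) {
  if (is.null(center_nm)) center_nm <- dims * voxel_size_nm / 2
  zc <- (seq_len(dims[1]) - 0.5) * voxel_size_nm - center_nm[1]
  yc <- (seq_len(dims[2]) - 0.5) * voxel_size_nm - center_nm[2]
  xc <- (seq_len(dims[3]) - 0.5) * voxel_size_nm - center_nm[3]
  d2 <- outer(outer(zc^2, yc^2, "+"), xc^2, "+")
  binary_mask(d2 <= radius_nm^2, voxel_size_nm)
}

# axis-aligned solid box mask of nz x ny x nx voxels inside a grid
make_box_mask <- function(dims, voxel_size_nm, box, offset = c(1L, 1L, 1L)) {
  arr <- array(FALSE, dim = dims)
  arr[offset[1]:(offset[1] + box[1] - 1L),
      offset[2]:(offset[2] + box[2] - 1L),
      offset[3]:(offset[3] + box[3] - 1L)] <- TRUE
  binary_mask(arr, voxel_size_nm)
}

# brute-force connected-component labeling (tiny arrays only)
bf_components <- function(arr, connectivity = 26L) {
  d <- dim(arr)
  lab <- array(0L, dim = d)
  nb <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  nb <- nb[rowSums(abs(nb)) > 0 &
           rowSums(abs(nb)) <= c(`6` = 1, `18` = 2, `26` = 3)[as.character(connectivity)], ]
  nxt <- 0L
  for (i in which(arr)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      z <- (p - 1L) %% d[1] + 1L
      y <- ((p - 1L) %/% d[1]) %% d[2] + 1L
      x <- (p - 1L) %/% (d[1] * d[2]) + 1L
      for (k in seq_len(nrow(nb))) {
        zz <- z + nb$dz[k]; yy <- y + nb$dy[k]; xx <- x + nb$dx[k]
        if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3])
          next
        q <- zz + d[1] * (yy - 1L) + d[1] * d[2] * (xx - 1L)
        if (arr[q] && lab[q] == 0L) { lab[q] <- nxt; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# brute-force 6-neighbor surface extraction
bf_surface_count <- function(arr) {
  d <- dim(arr)
  n <- 0L
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (!arr[z, y, x]) next
    nb_out <- FALSE
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      zz <- z + s[1]; yy <- y + s[2]; xx <- x + s[3]
      if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3] ||
          !arr[zz, yy, xx]) { nb_out <- TRUE; break }
    }
    if (nb_out) n <- n + 1L
  }
  n
}

# exact two-sample KS p-value by full enumeration of group assignments
bf_ks_permutation_p <- function(a, b) {
  ks_d <- function(x, y) {
    s <- sort(unique(c(x, y)))
    max(abs(ecdf(x)(s) - ecdf(y)(s)))
  }
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  d_obs <- ks_d(a, b)
  d_perm <- apply(idx, 2L, function(ii) ks_d(pooled[ii], pooled[-ii]))
  mean(d_perm >= d_obs - 1e-12)
}

# two-module intensity phantom: density = max over two radial profiles
# (1 at center, 1 - gap at boundary), zero outside
two_sphere_density <- function(dims, voxel_size_nm, centers_nm, radius_nm,
                               gap = 0.5) {
  zc <- (seq_len(dims[1]) - 0.5) * voxel_size_nm
  yc <- (seq_len(dims[2]) - 0.5) * voxel_size_nm
  xc <- (seq_len(dims[3]) - 0.5) * voxel_size_nm
  f <- array(0, dim = dims)
  lab <- array(0L, dim = dims)
  bestf <- array(-Inf, dim = dims)
  for (m in seq_len(nrow(centers_nm))) {
    d2 <- outer(outer((zc - centers_nm[m, 1])^2, (yc - centers_nm[m, 2])^2, "+"),
                (xc - centers_nm[m, 3])^2, "+")
    dn <- sqrt(d2) / radius_nm
    fm <- 1 - gap * dn
    upd <- dn <= 1 & fm > bestf
    bestf[upd] <- fm[upd]
    f[upd] <- fm[upd]
    lab[upd] <- m
  }
  list(volume = density_volume(f, voxel_size_nm),
       mask = binary_mask(lab > 0L, voxel_size_nm),
       truth = lab)
}
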