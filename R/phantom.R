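# Synthetic phantoms: disk-shaped aggregates of globular modules with ground
# truth, emulating isolated PSDs in cryo-tomograms. A phantom is a union of
# spherical modules (plus vertical full-thickness cylinders for trans
# modules) packed inside an oblate disk envelope. Each module carries a
# radial density profile falling from 1 at its center to 1 - gap_contrast at
# its boundary; the volume density is the voxel-wise maximum over modules, so
# inter-module boundaries are density valleys that the watershed stage can
# adjudicate. Additive Gaussian noise and an anisotropic z-blur (a cheap
# surrogate for missing-wedge degradation) are applied after the ground
# truth is frozen.
#
# Spherical modules are arranged in two layers — an upper and a lower sheet
# of vertically paired spheres sharing one lateral footprint — echoing the
# layered organization of the PSD (a membrane-proximal core and a
# cytoplasmic pallium). The pairing guarantees that, per projected column,
# the top of the aggregate belongs to an upper-layer module and the bottom
# to a lower-layer one, so only the full-thickness cylinders genuinely
# connect both external surfaces.

#' Phantom specification
#'
#' @param grid_shape integer length-3 `(nz, ny, nx)`.
#' @param voxel_size_nm positive isotropic voxel size, nm.
#' @param disk_diameter_nm,disk_thickness_nm disk envelope dimensions, nm
#'   (thickness along z, must not exceed the diameter).
#' @param n_modules total module count (including trans modules).
#' @param module_median_nm,module_sigma_log lognormal size distribution of
#'   the spherical modules: `exp(rnorm(log(median), sigma_log))` diameters.
#' @param n_trans_modules number of modules spanning the full disk thickness
#'   (vertical cylinders); at most `n_modules`.
#' @param trans_radius_nm lateral radius of trans modules, nm.
#' @param gap_contrast density drop in `[0, 1]` from module center to module
#'   boundary.
#' @param noise_sigma additive Gaussian noise SD, in units of the foreground
#'   density level (1).
#' @param z_blur_sigma_nm anisotropic Gaussian blur applied along z only, nm.
#' @param seed integer RNG seed; identical spec and seed give bit-identical
#'   phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_size_nm,
                         disk_diameter_nm, disk_thickness_nm,
                         n_modules, module_median_nm = 50,
                         module_sigma_log = 0.45,
                         n_trans_modules = 0L, trans_radius_nm = 35,
                         gap_contrast = 0.5, noise_sigma = 0,
                         z_blur_sigma_nm = 0, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive integers")
  if (disk_thickness_nm > disk_diameter_nm)
    stop("disk_thickness_nm must not exceed disk_diameter_nm")
  if (n_trans_modules > n_modules)
    stop("n_trans_modules must not exceed n_modules")
  if (gap_contrast < 0 || gap_contrast > 1)
    stop("gap_contrast must be in [0, 1]")
  if (noise_sigma < 0 || z_blur_sigma_nm < 0)
    stop("noise_sigma and z_blur_sigma_nm must be >= 0")
  if (disk_diameter_nm > grid_shape[2] * voxel_size_nm ||
      disk_diameter_nm > grid_shape[3] * voxel_size_nm ||
      disk_thickness_nm > grid_shape[1] * voxel_size_nm)
    stop("disk envelope does not fit inside the grid")
  structure(list(grid_shape = grid_shape,
                 voxel_size_nm = as.numeric(voxel_size_nm),
                 disk_diameter_nm = as.numeric(disk_diameter_nm),
                 disk_thickness_nm = as.numeric(disk_thickness_nm),
                 n_modules = as.integer(n_modules),
                 module_median_nm = as.numeric(module_median_nm),
                 module_sigma_log = as.numeric(module_sigma_log),
                 n_trans_modules = as.integer(n_trans_modules),
                 trans_radius_nm = as.numeric(trans_radius_nm),
                 gap_contrast = as.numeric(gap_contrast),
                 noise_sigma = as.numeric(noise_sigma),
                 z_blur_sigma_nm = as.numeric(z_blur_sigma_nm),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Canonical PSD phantom specification
#'
#' The documented reference conditions for end-to-end validation: a 400 nm x
#' 130 nm disk of 30 modules with lognormal sizes of median 50 nm, 2 of them
#' spanning the full thickness, on a 96 x 224 x 224 grid of 2 nm voxels
#' (within the published 200-800 nm size and ~100-190 nm thickness ranges of
#' isolated PSDs, at a grid small enough for routine testing).
#'
#' @param seed integer RNG seed; only the seed field varies.
#' @return a [phantom_spec()].
#' @export
default_psd_spec <- function(seed = 1L) {
  phantom_spec(grid_shape = c(96L, 224L, 224L), voxel_size_nm = 2.0,
               disk_diameter_nm = 400, disk_thickness_nm = 130,
               n_modules = 30L, module_median_nm = 50,
               module_sigma_log = 0.45, n_trans_modules = 2L,
               trans_radius_nm = 35, gap_contrast = 0.5,
               noise_sigma = 0.1, z_blur_sigma_nm = 2, seed = seed)
}

#' Generate a synthetic PSD phantom with ground-truth labels
#'
#' Spherical modules are arranged as vertically stacked equal-radius pairs
#' (upper and lower layer, centers offset from the mid-plane by 0.875 of the
#' radius) whose lateral footprints are packed by rejection sampling (at most
#' `100 * n_modules` proposals): each new footprint must keep a normalized
#' lateral center distance of at least 0.80 to every placed one (no deep
#' overlap) and at most 0.95 to at least one (so the aggregate stays
#' connected). Trans modules are vertical cylinders spanning the full disk
#' thickness. The ground-truth label of a foreground voxel is the module with
#' the highest density profile there (ties to the lower module index). Noise
#' and z-blur are applied after the truth is frozen.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [density_volume()]) and `truth` (class
#'   `phantom_truth`: `labels`, a [label_volume()]; `manifest`, a data.frame
#'   with `label`, `center_z_nm`, `center_y_nm`, `center_x_nm`,
#'   `nominal_size_nm`, `is_trans`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  vox <- spec$voxel_size_nm
  dims <- spec$grid_shape
  extent_nm <- dims * vox
  center_nm <- extent_nm / 2            # (z, y, x)
  half_t <- spec$disk_thickness_nm / 2
  disk_r <- spec$disk_diameter_nm / 2
  n_reg <- spec$n_modules - spec$n_trans_modules

  # sample spherical-module diameters; resample out-of-range draws so that a
  # stacked pair (centers at mid +/- .PAIR_DZ_FACTOR * r) stays within the
  # disk thickness, leaving the cylinders as the full-thickness elements
  d_min <- max(10, 4 * vox)
  d_max <- max(d_min, spec$disk_thickness_nm / (1 + .PAIR_DZ_FACTOR))
  sample_diam <- function() {
    for (i in 1:100) {
      d <- rlnorm(1, meanlog = log(spec$module_median_nm),
                  sdlog = spec$module_sigma_log)
      if (d >= d_min && d <= d_max) return(d)
    }
    stop("could not sample a feasible module diameter; check the size ",
         "distribution against the disk thickness")
  }

  # lateral entities: vertically stacked pairs of equal-radius spheres, plus
  # full-thickness cylinders for trans modules (interleaved so they attach
  # near the cluster core), plus one singleton sphere when n_reg is odd
  n_pairs <- n_reg %/% 2L
  singleton <- n_reg %% 2L == 1L
  if (singleton && n_reg > 1L)
    warning("odd number of non-trans modules: one sphere is placed unpaired ",
            "at the mid-plane and will span the local aggregate thickness")
  n_entities <- n_pairs + as.integer(singleton) + spec$n_trans_modules
  ent_trans <- rep(FALSE, n_entities)
  if (spec$n_trans_modules > 0L) {
    pos <- unique(pmin(n_entities,
                       1L + round(seq(1, n_entities,
                                      length.out = spec$n_trans_modules + 2L))[
                                        2:(spec$n_trans_modules + 1L)]))
    k <- 1L
    while (length(pos) < spec$n_trans_modules) {      # collision fallback
      if (!(k %in% pos)) pos <- c(pos, k)
      k <- k + 1L
    }
    ent_trans[pos] <- TRUE
  }
  reg_kinds <- c(rep("pair", n_pairs), if (singleton) "single")

  entities <- list()
  proposals <- 0L
  max_proposals <- 100L * spec$n_modules
  reg_i <- 0L
  for (m in seq_len(n_entities)) {
    trans <- ent_trans[m]
    if (trans) {
      kind <- "cylinder"
      r <- spec$trans_radius_nm
    } else {
      reg_i <- reg_i + 1L
      kind <- reg_kinds[reg_i]
      r <- sample_diam() / 2
    }
    placed <- FALSE
    while (proposals < max_proposals) {
      proposals <- proposals + 1L
      if (length(entities) == 0L) {
        lat <- c(0, 0)
      } else {
        rho <- sqrt(runif(1)) * max(0, disk_r - r)
        th <- runif(1, 0, 2 * pi)
        lat <- rho * c(cos(th), sin(th))
      }
      cand <- list(lat = lat, radius = r, kind = kind)
      if (length(entities) == 0L) {
        entities[[m]] <- cand; placed <- TRUE; break
      }
      # lateral separation: deep enough overlap to stay connected, shallow
      # enough that density saddles remain for the watershed to find
      gaps <- vapply(entities, function(e)
        sqrt(sum((e$lat - lat)^2)) / (e$radius + r), numeric(1))
      if (all(gaps >= 0.80) && any(gaps <= 0.95)) {
        entities[[m]] <- cand; placed <- TRUE; break
      }
    }
    if (!placed) {
      stop("infeasible packing: placed ", length(entities), " of ",
           n_entities, " lateral entities within ", max_proposals,
           " proposals")
    }
  }

  # expand entities into modules (z, y, x centers in nm)
  modules <- list()
  for (e in entities) {
    cy <- center_nm[2] + e$lat[1]
    cx <- center_nm[3] + e$lat[2]
    if (e$kind == "cylinder") {
      modules[[length(modules) + 1L]] <-
        list(center = c(center_nm[1], cy, cx), radius = e$radius, trans = TRUE)
    } else if (e$kind == "pair") {
      dz <- .PAIR_DZ_FACTOR * e$radius
      modules[[length(modules) + 1L]] <-
        list(center = c(center_nm[1] + dz, cy, cx), radius = e$radius,
             trans = FALSE)
      modules[[length(modules) + 1L]] <-
        list(center = c(center_nm[1] - dz, cy, cx), radius = e$radius,
             trans = FALSE)
    } else {
      modules[[length(modules) + 1L]] <-
        list(center = c(center_nm[1], cy, cx), radius = e$radius,
             trans = FALSE)
    }
  }
  stopifnot(length(modules) == spec$n_modules)

  # rasterize: density = max over module profiles, truth = argmax
  density <- array(0, dim = dims)
  bestf <- array(-Inf, dim = dims)
  labels <- array(0L, dim = dims)
  zc <- (seq_len(dims[1]) - 0.5) * vox
  yc <- (seq_len(dims[2]) - 0.5) * vox
  xc <- (seq_len(dims[3]) - 0.5) * vox
  for (m in seq_along(modules)) {
    mod <- modules[[m]]
    r <- mod$radius
    if (mod$trans) {
      zi <- which(abs(zc - center_nm[1]) <= half_t)
    } else {
      zi <- which(abs(zc - mod$center[1]) <= r)
    }
    yi <- which(abs(yc - mod$center[2]) <= r)
    xi <- which(abs(xc - mod$center[3]) <= r)
    if (!length(zi) || !length(yi) || !length(xi)) next
    dy2 <- (yc[yi] - mod$center[2])^2
    dx2 <- (xc[xi] - mod$center[3])^2
    lat2 <- outer(dy2, dx2, "+")                       # |yi| x |xi|
    if (mod$trans) {
      dnorm_lat <- sqrt(lat2) / r
      inside2d <- dnorm_lat <= 1
      f2d <- 1 - spec$gap_contrast * dnorm_lat
      for (z in zi) {
        sl_f <- matrix(bestf[z, yi, xi], length(yi), length(xi))
        upd <- inside2d & (f2d > sl_f)
        if (any(upd)) {
          sl_d <- matrix(density[z, yi, xi], length(yi), length(xi))
          sl_l <- matrix(labels[z, yi, xi], length(yi), length(xi))
          sl_f[upd] <- f2d[upd]; sl_d[upd] <- f2d[upd]; sl_l[upd] <- m
          bestf[z, yi, xi] <- sl_f; density[z, yi, xi] <- sl_d
          labels[z, yi, xi] <- sl_l
        }
      }
    } else {
      for (z in zi) {
        dz2 <- (zc[z] - mod$center[1])^2
        dn <- sqrt(lat2 + dz2) / r
        inside <- dn <= 1
        if (!any(inside)) next
        f <- 1 - spec$gap_contrast * dn
        sl_f <- matrix(bestf[z, yi, xi], length(yi), length(xi))
        upd <- inside & (f > sl_f)
        if (any(upd)) {
          sl_d <- matrix(density[z, yi, xi], length(yi), length(xi))
          sl_l <- matrix(labels[z, yi, xi], length(yi), length(xi))
          sl_f[upd] <- f[upd]; sl_d[upd] <- f[upd]; sl_l[upd] <- m
          bestf[z, yi, xi] <- sl_f; density[z, yi, xi] <- sl_d
          labels[z, yi, xi] <- sl_l
        }
      }
    }
  }

  # drop modules that ended up with no voxel of their own, renumber 1..K
  present <- sort(unique(labels[labels > 0L]))
  if (length(present) < spec$n_modules)
    warning("achieved module count ", length(present), " of ",
            spec$n_modules, ": some modules were fully covered by others")
  remap <- integer(spec$n_modules)
  remap[present] <- seq_along(present)
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  manifest <- do.call(rbind, lapply(seq_along(present), function(k) {
    mod <- modules[[present[k]]]
    data.frame(label = k,
               center_z_nm = mod$center[1], center_y_nm = mod$center[2],
               center_x_nm = mod$center[3],
               nominal_size_nm = if (mod$trans)
                 max(spec$disk_thickness_nm, 2 * mod$radius) else
                   2 * mod$radius,
               is_trans = mod$trans)
  }))

  vol <- density
  if (spec$noise_sigma > 0)
    vol <- vol + array(rnorm(length(vol), 0, spec$noise_sigma), dim = dims)
  if (spec$z_blur_sigma_nm > 0) {
    vol <- .gauss_blur3(as.numeric(vol), dims,
                        c(spec$z_blur_sigma_nm / vox, 0, 0))
    dim(vol) <- dims
  }

  list(volume = density_volume(vol, vox),
       truth = structure(list(labels = label_volume(labels, vox),
                              manifest = manifest),
                         class = "phantom_truth"))
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %d modules (%d trans)\n",
              nrow(x$manifest), sum(x$manifest$is_trans)))
  invisible(x)
}

# convex outline of a 2D point cloud (continuous 0-based coords), expanded
# radially from its centroid by margin_vox; degenerate clouds fall back to a
# margin box
.outline_polygon <- function(pts, margin_vox) {
  hp <- NULL
  if (nrow(pts) >= 3L) {
    hp <- pts[grDevices::chull(pts), , drop = FALSE]
    if (nrow(hp) < 3L) hp <- NULL
  }
  if (is.null(hp)) {
    lo <- apply(pts, 2L, min) - margin_vox
    hi <- apply(pts, 2L, max) + margin_vox
    return(rbind(c(lo[1], lo[2]), c(lo[1], hi[2]),
                 c(hi[1], hi[2]), c(hi[1], lo[2])))
  }
  ctr <- colMeans(hp)
  dirs <- sweep(hp, 2L, ctr)
  nrm <- sqrt(rowSums(dirs^2))
  nrm[nrm == 0] <- 1
  hp + margin_vox * dirs / nrm
}

#' VOI contours enclosing a phantom's aggregate, slice by slice
#'
#' The synthetic analogue of the hand-drawn closed paths enclosing a PSD: on
#' every slice intersecting the structure, one closed outline per visible
#' lump (the convex hull of each ground-truth module's cross-section,
#' expanded by a small margin). The union of these outlines hugs the
#' structure the way an annotator traces it — slightly larger than the
#' structure, but following its concave silhouette rather than a loose
#' global hull.
#'
#' @param truth a `phantom_truth` (from [generate_phantom()]) or a
#'   [label_volume()]; a [binary_mask()] is also accepted (one outline per
#'   slice from its whole cross-section).
#' @param margin_nm radial margin beyond the structure outline, nm.
#' @return a [voi_contours()].
#' @export
phantom_voi_contours <- function(truth, margin_nm = 8) {
  lab <- if (inherits(truth, "phantom_truth")) truth$labels$data
         else if (inherits(truth, "label_volume")) truth$data
         else if (inherits(truth, "binary_mask")) {
           l <- truth$data; storage.mode(l) <- "integer"; l
         } else stop("truth must be a phantom_truth, label_volume or binary_mask")
  vox <- if (inherits(truth, "phantom_truth")) truth$labels$voxel_size_nm
         else truth$voxel_size_nm
  margin_vox <- margin_nm / vox
  entries <- list()
  for (z in seq_len(dim(lab)[1])) {
    sl <- lab[z, , ]
    if (!any(sl > 0L)) next
    for (id in unique(sl[sl > 0L])) {
      w <- which(sl == id, arr.ind = TRUE)
      pts <- cbind(w[, 1] - 0.5, w[, 2] - 0.5)  # continuous 0-based (row, col)
      entries[[length(entries) + 1L]] <-
        list(slice = z - 1L, vertices = .outline_polygon(pts, margin_vox))
    }
  }
  voi_contours(entries)
}

# vertical offset of pair centers from the mid-plane, in units of the pair
# radius: 0.875 matches the mean lateral packing separation, so intra-pair
# density valleys are as deep as lateral ones while each pair spans at most
# 1.875 r above and below the mid-plane (inside the disk half-thickness)
.PAIR_DZ_FACTOR <- 0.875
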