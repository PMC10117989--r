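# Principal-axis morphometry of PSDs and modules: the centroid and three
# orthogonal principal axes are computed from the covariance matrix of the
# coordinates forming the surface of the object; the shortest extent is the
# thickness, the longest is the module size, the projected area is the
# occupied-cell count along the thickness axis, and the volume is the voxel
# count times the cubed voxel size.

# logical array marking voxels of `arr_lab` (integer or logical) whose value
# differs from at least one of the 6 face neighbors (out-of-grid counts as
# different/outside). For a logical mask this is the object surface.
.face_boundary <- function(arr_lab) {
  d <- dim(arr_lab)
  out <- array(FALSE, dim = d)
  for (ax in 1:3) {
    n <- d[ax]
    if (n == 1L) { out <- out | (arr_lab != 0L); next }
    # compare arr[..., 1:(n-1), ...] with arr[..., 2:n, ...]
    a <- .slice_axis(arr_lab, ax, 1L, n - 1L)
    b <- .slice_axis(arr_lab, ax, 2L, n)
    diffm <- a != b
    out <- .or_axis(out, diffm, ax, 1L, n - 1L, arr_lab != 0L)
    out <- .or_axis(out, diffm, ax, 2L, n, arr_lab != 0L)
    # grid edges count as outside
    out <- .or_edge(out, arr_lab != 0L, ax)
  }
  out & (arr_lab != 0L)
}

.slice_axis <- function(arr, ax, from, to) {
  switch(ax,
         arr[from:to, , , drop = FALSE],
         arr[, from:to, , drop = FALSE],
         arr[, , from:to, drop = FALSE])
}

.or_axis <- function(out, diffm, ax, from, to, inmask) {
  switch(ax,
         { out[from:to, , ] <- out[from:to, , , drop = FALSE] | diffm; out },
         { out[, from:to, ] <- out[, from:to, , drop = FALSE] | diffm; out },
         { out[, , from:to] <- out[, , from:to, drop = FALSE] | diffm; out })
}

.or_edge <- function(out, inmask, ax) {
  d <- dim(out)
  n <- d[ax]
  switch(ax,
         { out[c(1L, n), , ] <- out[c(1L, n), , , drop = FALSE] |
             inmask[c(1L, n), , , drop = FALSE]; out },
         { out[, c(1L, n), ] <- out[, c(1L, n), , drop = FALSE] |
             inmask[, c(1L, n), , drop = FALSE]; out },
         { out[, , c(1L, n)] <- out[, , c(1L, n), drop = FALSE] |
             inmask[, , c(1L, n), drop = FALSE]; out })
}

#' Surface voxels of a binary mask
#'
#' Voxels of the mask with at least one of the 6 face neighbors outside the
#' mask; out-of-grid counts as outside. These are the "coordinates forming
#' the surface" used by the principal-axis computation.
#'
#' @param mask a non-empty [binary_mask()].
#' @return integer n x 3 matrix of 1-based (z, y, x) voxel indices.
#' @export
surface_voxels <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop("empty mask")
  lab <- mask$data
  storage.mode(lab) <- "integer"
  which_zyx(.face_boundary(lab))
}

#' Principal axes of a mask from its surface-coordinate covariance
#'
#' Eigen-decomposition of the covariance matrix of the surface-voxel center
#' coordinates (nm, centroid-subtracted). Axes are ordered by descending
#' extent, where the extent along an axis is (max - min projection of the
#' surface voxel centers) plus one voxel size, so a 1-voxel object has extent
#' equal to the voxel size rather than 0. Collinear or coplanar surfaces are
#' flagged degenerate instead of raising an error.
#'
#' @param mask a non-empty [binary_mask()].
#' @return an object of class `principal_axes`: `centroid_nm` (length-3,
#'   (z, y, x)), `axes` (3 x 3 orthonormal matrix, one axis per column,
#'   ordered by descending extent), `extents_nm` (descending), `degenerate`.
#' @export
principal_axes <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  surf <- surface_voxels(mask)
  coords <- voxel_centers_nm(surf, mask$voxel_size_nm)
  .principal_axes_of_points(coords, mask$voxel_size_nm)
}

.principal_axes_of_points <- function(coords, voxel_size_nm) {
  centroid <- colMeans(coords)
  centered <- sweep(coords, 2L, centroid)
  degenerate <- FALSE
  if (nrow(coords) < 4L) {
    degenerate <- TRUE
  }
  cv <- crossprod(centered) / max(1, nrow(coords) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[3] <= 1e-9 * max(eg$values[1], 1)) degenerate <- TRUE
  axes <- eg$vectors
  # deterministic sign: largest-magnitude entry of each axis positive
  for (k in 1:3) {
    i <- which.max(abs(axes[, k]))
    if (axes[i, k] < 0) axes[, k] <- -axes[, k]
  }
  proj <- centered %*% axes
  spread <- apply(proj, 2L, function(p) diff(range(p)))
  extents <- spread + voxel_size_nm
  ord <- order(-extents, -eg$values, seq_len(3))
  structure(list(centroid_nm = as.numeric(centroid),
                 axes = axes[, ord, drop = FALSE],
                 extents_nm = extents[ord],
                 eigenvalues = eg$values[ord],
                 degenerate = degenerate),
            class = "principal_axes")
}

#' @export
print.principal_axes <- function(x, ...) {
  cat(sprintf("principal_axes: extents %.4g x %.4g x %.4g nm%s\n",
              x$extents_nm[1], x$extents_nm[2], x$extents_nm[3],
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Whole-PSD morphometry
#'
#' Thickness is the smallest principal extent; the projected area is the
#' number of occupied cells times the squared voxel size after projecting
#' every mask voxel center onto the plane of the two non-thickness axes and
#' binning into a square grid of pitch `voxel_size_nm` anchored at the
#' centroid; the volume is the voxel count times the cubed voxel size.
#'
#' @param mask a non-empty [binary_mask()].
#' @return an object of class `psd_morphometry`: `axes` (a
#'   [principal_axes()] object), `thickness_nm`, `area_nm2`, `volume_nm3`.
#' @export
measure_psd <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop("empty mask")
  ax <- principal_axes(mask)
  vox <- mask$voxel_size_nm
  idx <- which_zyx(mask$data)
  coords <- voxel_centers_nm(idx, vox)
  centered <- sweep(coords, 2L, ax$centroid_nm)
  u <- centered %*% ax$axes[, 1]
  v <- centered %*% ax$axes[, 2]
  cells <- unique(cbind(floor(u / vox), floor(v / vox)))
  area <- nrow(cells) * vox^2
  volume <- nrow(coords) * vox^3
  thickness <- ax$extents_nm[3]
  if (!ax$degenerate && volume > area * thickness * 1.25)
    warning("volume exceeds area x thickness sanity bound for a disk-like shape")
  structure(list(axes = ax, thickness_nm = thickness, area_nm2 = area,
                 volume_nm3 = volume),
            class = "psd_morphometry")
}

#' @export
print.psd_morphometry <- function(x, ...) {
  cat(sprintf("psd_morphometry: thickness %.4g nm, area %.6g nm^2, volume %.6g nm^3\n",
              x$thickness_nm, x$area_nm2, x$volume_nm3))
  invisible(x)
}

#' Per-module morphometrics
#'
#' One record per label: volume (voxel count times cubed voxel size), the
#' three principal extents of the label's own surface-voxel cloud, the module
#' size (longest extent) and the surface centroid. `is_trans` is filled by
#' [find_trans_modules()] and is `FALSE` here.
#'
#' @param labels a [label_volume()] with at least one label.
#' @return a data.frame with columns `label_id`, `volume_nm3`, `size_nm`,
#'   `extent1_nm`, `extent2_nm`, `extent3_nm`, `centroid_z_nm`,
#'   `centroid_y_nm`, `centroid_x_nm`, `is_trans`, `degenerate`, sorted by
#'   label id.
#' @export
measure_modules <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  ids <- labels$label_ids
  if (length(ids) == 0L) stop("label volume has no labels")
  vox <- labels$voxel_size_nm
  # surface voxels of each label against everything else (other labels and
  # background), computed in one pass over the label array
  boundary <- .face_boundary(labels$data)
  counts <- tabulate(labels$data[labels$data > 0L], nbins = max(ids))
  rows <- lapply(ids, function(id) {
    surf_idx <- which_zyx(boundary & labels$data == id)
    coords <- voxel_centers_nm(surf_idx, vox)
    ax <- .principal_axes_of_points(coords, vox)
    data.frame(label_id = id,
               volume_nm3 = counts[id] * vox^3,
               size_nm = ax$extents_nm[1],
               extent1_nm = ax$extents_nm[1],
               extent2_nm = ax$extents_nm[2],
               extent3_nm = ax$extents_nm[3],
               centroid_z_nm = ax$centroid_nm[1],
               centroid_y_nm = ax$centroid_nm[2],
               centroid_x_nm = ax$centroid_nm[3],
               is_trans = FALSE,
               degenerate = ax$degenerate)
  })
  do.call(rbind, rows)
}

#' Module-size histogram
#'
#' Bins `[k*w, (k+1)*w)` from 0. Also reports the fraction of sizes within
#' the closed interval 40-90 nm (the reported PSD-fragment size range) and
#' within 10-170 nm.
#'
#' @param records a data.frame from [measure_modules()] (needs `size_nm`), or
#'   a numeric vector of sizes.
#' @param bin_width_nm positive bin width in nm.
#' @return list with `breaks_nm`, `counts`, `fraction_40_90`,
#'   `fraction_10_170`, `n`.
#' @export
size_histogram <- function(records, bin_width_nm = 10) {
  if (bin_width_nm <= 0) stop("bin_width_nm must be > 0")
  sizes <- if (is.data.frame(records)) records$size_nm else as.numeric(records)
  n <- length(sizes)
  if (n == 0L) {
    return(list(breaks_nm = c(0, bin_width_nm), counts = 0L,
                fraction_40_90 = NA_real_, fraction_10_170 = NA_real_, n = 0L))
  }
  kmax <- floor(max(sizes) / bin_width_nm) + 1L
  breaks <- seq(0, kmax * bin_width_nm, by = bin_width_nm)
  counts <- vapply(seq_len(kmax), function(k)
    sum(sizes >= breaks[k] & sizes < breaks[k + 1L]), integer(1))
  list(breaks_nm = breaks, counts = counts,
       fraction_40_90 = mean(sizes >= 40 & sizes <= 90),
       fraction_10_170 = mean(sizes >= 10 & sizes <= 170),
       n = n)
}
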