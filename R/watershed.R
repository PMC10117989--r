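# 3D marker-controlled watershed delineation of modules within the denoised
# PSD mask. Modules are patches of material differing in electron density, so
# the default floods the negated smoothed density (intensity watershed);
# a distance-transform variant is available for purely binary inputs.

#' Watershed parameter set
#'
#' @param smoothing_sigma_nm isotropic Gaussian pre-smoothing of the density,
#'   nm (default 4: the smallest granular substructures reported in isolated
#'   PSDs are 5-30 nm, and smoothing below half that scale preserves them).
#' @param h_depth h-maxima marker suppression depth as a fraction in `[0, 1]`
#'   of the smoothed-density range within the mask. After 4 nm smoothing the
#'   density valleys separating the smallest genuine modules (15-30 nm)
#'   retain only ~0.1 of the range, while the expected maximum of the
#'   smoothed voxel noise stays near 0.02 of it, so the default 0.05 sits in
#'   the middle of the usable window: small modules are kept, noise maxima
#'   are suppressed.
#' @param connectivity 6, 18 or 26 (default 26, matching the denoising stage).
#' @param method `"intensity"` (flood the negated smoothed density) or
#'   `"distance"` (flood the negated Euclidean distance transform of the
#'   mask; for binary inputs with no informative density).
#' @return an object of class `watershed_params`.
#' @export
watershed_params <- function(smoothing_sigma_nm = 4, h_depth = 0.05,
                             connectivity = 26L,
                             method = c("intensity", "distance")) {
  if (smoothing_sigma_nm < 0) stop("smoothing_sigma_nm must be >= 0")
  if (h_depth < 0 || h_depth > 1) stop("h_depth must be in [0, 1]")
  structure(list(smoothing_sigma_nm = as.numeric(smoothing_sigma_nm),
                 h_depth = as.numeric(h_depth),
                 connectivity = as.integer(match.arg(as.character(connectivity),
                                                     c("6", "18", "26"))),
                 method = match.arg(method)),
            class = "watershed_params")
}

#' Gaussian-smooth a density volume
#'
#' Separable Gaussian with reflecting boundaries; `sigma_nm` is converted to
#' voxels via the volume's voxel size.
#'
#' @param volume a [density_volume()].
#' @param sigma_nm non-negative isotropic standard deviation in nm.
#' @return a [density_volume()].
#' @export
smooth_density <- function(volume, sigma_nm) {
  stopifnot(inherits(volume, "density_volume"))
  if (sigma_nm < 0) stop("sigma_nm must be >= 0")
  if (sigma_nm == 0) return(volume)
  s <- sigma_nm / volume$voxel_size_nm
  out <- .gauss_blur3(as.numeric(volume$data), dim(volume$data),
                      rep(s, 3))
  dim(out) <- dim(volume$data)
  density_volume(out, volume$voxel_size_nm, volume$origin_nm)
}

# h-maxima markers of img within region: regional-maximum plateaus of the
# reconstruction of (img - h) under img. Returns an integer marker array
# (components numbered in first-seen linear-index order).
.h_maxima_markers <- function(img, region, dims, h, connectivity) {
  rec <- .grey_reconstruct(as.numeric(img) - h, as.numeric(img),
                           as.logical(region), dims, connectivity)
  .regional_maxima(rec, as.logical(region), dims, connectivity)
}

#' Partition a PSD mask into modules by 3D marker-controlled watershed
#'
#' The density is Gaussian-smoothed, markers are taken as the h-maxima of the
#' smoothed density restricted to the mask (suppression depth `h_depth` times
#' the within-mask smoothed-density range), and the negated smoothed density
#' is flooded from the markers, confined to the mask. Every mask voxel
#' receives exactly one label; labels are renumbered `1..K` by descending
#' voxel count (ties by smallest contained voxel index), so the partition is
#' deterministic.
#'
#' @param volume a [density_volume()].
#' @param psd_mask a non-empty [binary_mask()] of the same shape.
#' @param params a [watershed_params()].
#' @return a [label_volume()].
#' @export
segment_modules <- function(volume, psd_mask, params = watershed_params()) {
  stopifnot(inherits(volume, "density_volume"),
            inherits(psd_mask, "binary_mask"),
            inherits(params, "watershed_params"))
  if (!identical(dim(volume$data), dim(psd_mask$data)))
    stop("volume and mask shapes differ")
  if (!any(psd_mask$data)) stop("empty PSD mask")
  dims <- dim(volume$data)
  region <- as.logical(psd_mask$data)

  if (params$method == "distance") {
    relief <- sqrt(.edt_squared(region, dims))
  } else {
    sm <- smooth_density(volume, params$smoothing_sigma_nm)
    relief <- as.numeric(sm$data)
  }
  vals <- relief[region]
  rng <- diff(range(vals))
  if (rng == 0) {
    # flat relief: a single module covering the mask
    lab <- array(0L, dim = dims)
    lab[region] <- 1L
    return(label_volume(lab, psd_mask$voxel_size_nm))
  }
  h <- params$h_depth * rng
  markers <- .h_maxima_markers(relief, region, dims, h, params$connectivity)
  if (!any(markers > 0L)) {
    warning("no watershed markers found; returning a single-label partition")
    lab <- array(0L, dim = dims)
    lab[region] <- 1L
    return(label_volume(lab, psd_mask$voxel_size_nm))
  }
  lab <- .watershed_flood(-as.numeric(relief), markers, region, dims,
                          params$connectivity)
  dim(lab) <- dims
  out <- label_volume(.renumber_labels(lab), psd_mask$voxel_size_nm)
  stopifnot(sum(out$data > 0L) == sum(region))   # partition conservation
  out
}

#' Merge labels smaller than a voxel threshold into their largest neighbor
#'
#' Each label smaller than `min_voxels` is merged into the neighboring label
#' sharing the largest face-contact area (ties to the smaller label id),
#' iterating smallest-first until stable. The partition property is
#' preserved; isolated small labels with no neighbor are kept.
#'
#' @param labels a [label_volume()].
#' @param min_voxels positive integer; labels below this size are merged.
#' @return a [label_volume()].
#' @export
merge_small_labels <- function(labels, min_voxels) {
  stopifnot(inherits(labels, "label_volume"))
  min_voxels <- as.integer(min_voxels)
  if (min_voxels < 1L) stop("min_voxels must be >= 1")
  total <- sum(labels$data > 0L)
  if (min_voxels > total)
    stop("min_voxels exceeds the total mask volume (", total, " voxels)")
  if (min_voxels == 1L || length(labels$label_ids) <= 1L) return(labels)
  lab <- labels$data
  dims <- dim(lab)
  unmergeable <- integer(0)
  repeat {
    sizes <- tabulate(lab[lab > 0L])
    small <- setdiff(which(sizes > 0L & sizes < min_voxels), unmergeable)
    if (length(small) == 0L) break
    # merge the smallest offender first (deterministic, stable under ties)
    tgt <- small[order(sizes[small], small)][1]
    contact <- .label_contact(as.integer(lab), dims, as.integer(tgt))
    if (nrow(contact) == 0L) {                  # isolated: nothing to merge into
      unmergeable <- c(unmergeable, tgt)
      next
    }
    recipient <- contact[order(-contact[, 2], contact[, 1]), , drop = FALSE][1, 1]
    lab[lab == tgt] <- recipient
  }
  label_volume(.relabel_contiguous(lab), labels$voxel_size_nm)
}

# squeeze arbitrary positive labels to contiguous 1..K preserving the
# descending-size, smallest-first-voxel order
.relabel_contiguous <- function(lab) {
  .renumber_labels(lab)
}
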