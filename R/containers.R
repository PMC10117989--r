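#' Density volume container
#'
#' A 3D scalar grid with a physical voxel size. Arrays are indexed
#' `[z, y, x]` with `z` the tomographic slice axis; indices are 1-based in R,
#' and the physical center of voxel `(z, y, x)` is
#' `origin_nm + (index - 1 + 0.5) * voxel_size_nm` on each axis.
#'
#' @param data numeric 3D array, dim `(nz, ny, nx)`.
#' @param voxel_size_nm positive scalar, isotropic voxel edge length in nm.
#' @param origin_nm numeric length-3 physical origin (z, y, x), nm.
#' @return An object of class `density_volume` with fields `data`,
#'   `voxel_size_nm`, `origin_nm`.
#' @export
density_volume <- function(data, voxel_size_nm, origin_nm = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("expected 3D volume")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      !is.finite(voxel_size_nm) || voxel_size_nm <= 0)
    stop("voxel_size_nm must be a positive scalar")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  if (length(origin_nm) != 3L) stop("origin_nm must have length 3")
  structure(list(data = data, voxel_size_nm = as.numeric(voxel_size_nm),
                 origin_nm = as.numeric(origin_nm)),
            class = "density_volume")
}

#' Binary mask container
#'
#' @param data logical 3D array, dim `(nz, ny, nx)`.
#' @param voxel_size_nm positive scalar voxel edge length in nm.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, voxel_size_nm) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("expected 3D mask")
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask contains NA")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      voxel_size_nm <= 0)
    stop("voxel_size_nm must be a positive scalar")
  structure(list(data = data, voxel_size_nm = as.numeric(voxel_size_nm)),
            class = "binary_mask")
}

#' Label volume container
#'
#' An integer-labeled partition of a mask into modules; 0 is background and
#' labels must be the contiguous integers `1..K`.
#'
#' @param data integer 3D array, dim `(nz, ny, nx)`, values `>= 0`.
#' @param voxel_size_nm positive scalar voxel edge length in nm.
#' @return An object of class `label_volume` with fields `data`,
#'   `voxel_size_nm`, `label_ids`.
#' @export
label_volume <- function(data, voxel_size_nm) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("expected 3D label volume")
  storage.mode(data) <- "integer"
  if (anyNA(data) || any(data < 0L)) stop("labels must be non-negative integers")
  ids <- sort(unique(data[data > 0L]))
  if (length(ids) > 0L && !identical(as.integer(ids), seq_len(length(ids))))
    stop("labels must be contiguous positive integers 1..K")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      voxel_size_nm <= 0)
    stop("voxel_size_nm must be a positive scalar")
  structure(list(data = data, voxel_size_nm = as.numeric(voxel_size_nm),
                 label_ids = as.integer(ids)),
            class = "label_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  cat(sprintf("density_volume: %s voxels, voxel %.4g nm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = " x "), x$voxel_size_nm,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %s voxels, %d set, volume %.6g nm^3\n",
              paste(dim(x$data), collapse = " x "), sum(x$data),
              mask_volume_nm3(x)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label_volume: %s voxels, %d labels\n",
              paste(dim(x$data), collapse = " x "), length(x$label_ids)))
  invisible(x)
}

#' Physical volume of a mask
#'
#' Voxel count times the cubed voxel size, the voxel-counting volume used for
#' PSDs and modules throughout.
#'
#' @param mask a `binary_mask`.
#' @return volume in nm^3.
#' @export
mask_volume_nm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * mask$voxel_size_nm^3
}

# physical center coordinates (nm) of given 1-based voxel indices, as an
# n x 3 matrix in (z, y, x) order
voxel_centers_nm <- function(idx_zyx, voxel_size_nm, origin_nm = c(0, 0, 0)) {
  sweep((idx_zyx - 0.5) * voxel_size_nm, 2L, origin_nm, "+")
}

# 1-based (z, y, x) index matrix of TRUE voxels of a logical array
which_zyx <- function(arr) {
  w <- which(arr, arr.ind = TRUE)
  colnames(w) <- c("z", "y", "x")
  w
}
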