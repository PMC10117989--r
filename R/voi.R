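# Rasterization of per-slice closed contours into the 3D VOI mask that
# constrains segmentation. Interiority is decided on voxel centers with the
# even-odd rule; a center lying exactly on the contour counts as inside
# (hand-drawn VOIs are deliberately generous, so inclusive boundaries match
# annotator intent).

#' Even-odd point-in-polygon test on a set of points
#'
#' @param pts numeric n x 2 matrix of (row, col) points.
#' @param verts numeric m x 2 matrix of polygon vertices (closed implicitly).
#' @param boundary_inside logical; points exactly on an edge count as inside.
#' @return logical vector of length n.
#' @export
point_in_polygon <- function(pts, verts, boundary_inside = TRUE) {
  pts <- as.matrix(pts)
  verts <- as.matrix(verts)
  n <- nrow(pts)
  m <- nrow(verts)
  py <- pts[, 1]; px <- pts[, 2]
  inside <- rep(FALSE, n)
  on_edge <- rep(FALSE, n)
  eps <- 1e-9 * max(1, max(abs(verts)))
  j <- m
  for (i in seq_len(m)) {
    y1 <- verts[j, 1]; x1 <- verts[j, 2]
    y2 <- verts[i, 1]; x2 <- verts[i, 2]
    # boundary: |cross| small and point within segment bbox
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    if (seg_len2 > 0) {
      hit <- abs(cross) <= eps * sqrt(seg_len2) &
        px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
        py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
      on_edge <- on_edge | hit
    }
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    j <- i
  }
  if (boundary_inside) inside | on_edge else inside & !on_edge
}

#' Rasterize VOI contours into a 3D binary mask
#'
#' Per annotated slice, voxel centers inside the polygon by the even-odd rule
#' become TRUE (centers exactly on the contour count as inside); slices
#' without a contour entry stay all-FALSE. Several contours on one slice are
#' combined by union.
#'
#' @param contours a [voi_contours()]; slice indices 0-based, vertex
#'   coordinates in voxel units (voxel center of 0-based index i at i + 0.5).
#' @param shape integer length-3 grid shape `(nz, ny, nx)`.
#' @param voxel_size_nm positive scalar voxel size of the target volume.
#' @return an object of class `voi_mask`: list with `mask` (a
#'   [binary_mask()]) and `source` (provenance note).
#' @export
rasterize_voi <- function(contours, shape, voxel_size_nm) {
  stopifnot(inherits(contours, "voi_contours"))
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive integers")
  sl <- vapply(contours$entries, function(e) e$slice, integer(1))
  if (any(sl >= shape[1]))
    stop("contour slice index out of range: ", max(sl), " >= ", shape[1])
  arr <- array(FALSE, dim = shape)
  # voxel centers in continuous 0-based coords (row, col); only centers inside
  # the polygon's bounding box can be inside it
  cy <- seq_len(shape[2]) - 0.5
  cx <- seq_len(shape[3]) - 0.5
  for (e in contours$entries) {
    ry <- which(cy >= min(e$vertices[, 1]) - 1 & cy <= max(e$vertices[, 1]) + 1)
    rx <- which(cx >= min(e$vertices[, 2]) - 1 & cx <= max(e$vertices[, 2]) + 1)
    if (!length(ry) || !length(rx)) next
    pts <- cbind(rep(cy[ry], times = length(rx)),
                 rep(cx[rx], each = length(ry)))
    ins <- point_in_polygon(pts, e$vertices, boundary_inside = TRUE)
    z <- e$slice + 1L
    arr[z, ry, rx] <- arr[z, ry, rx] |
      matrix(ins, nrow = length(ry), ncol = length(rx))
  }
  structure(list(mask = binary_mask(arr, voxel_size_nm),
                 source = sprintf("rasterized from %d contours", length(contours$entries))),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("voi_mask (", x$source, ")\n", sep = "")
  print(x$mask)
  invisible(x)
}

#' Fill slice gaps in a contour set
#'
#' Annotators often skip slices; `copy-nearest` fills each interior gap with
#' the polygon of the nearer annotated neighbor (the lower slice index wins
#' ties). No contour morphing is performed: interpolated shapes would alter
#' measurements in an unspecified way.
#'
#' @param contours a [voi_contours()].
#' @param mode `"off"` (identity) or `"copy-nearest"`.
#' @return a [voi_contours()].
#' @export
interpolate_missing_slices <- function(contours, mode = c("off", "copy-nearest")) {
  stopifnot(inherits(contours, "voi_contours"))
  mode <- match.arg(mode)
  if (mode == "off" || length(contours$entries) < 2L) return(contours)
  sl <- vapply(contours$entries, function(e) e$slice, integer(1))
  ord <- order(sl)
  entries <- contours$entries[ord]
  sl <- sl[ord]
  out <- entries
  for (k in seq_len(length(sl) - 1L)) {
    lo <- sl[k]; hi <- sl[k + 1L]
    if (hi - lo <= 1L) next
    for (s in seq(lo + 1L, hi - 1L)) {
      nearer <- if ((s - lo) <= (hi - s)) k else k + 1L
      out[[length(out) + 1L]] <- list(slice = as.integer(s),
                                      vertices = entries[[nearer]]$vertices)
    }
  }
  sl_out <- vapply(out, function(e) e$slice, integer(1))
  voi_contours(out[order(sl_out)])
}
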