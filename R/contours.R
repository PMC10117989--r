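# Per-slice closed-contour files: JSON with a top-level list of
# {"slice": int (0-based), "vertices": [[row, col], ...]} in voxel units of
# the target volume. A vertex (r, c) lies in continuous voxel coordinates
# where the voxel with 0-based index (i, j) spans [i, i+1) x [j, j+1) and has
# its center at (i + 0.5, j + 0.5).

#' Volume-of-interest contour set
#'
#' @param entries list of entries, each a list with `slice` (0-based integer
#'   slice index) and `vertices` (numeric n x 2 matrix of (row, col) vertices,
#'   n >= 3, closed implicitly).
#' @return an object of class `voi_contours`.
#' @export
voi_contours <- function(entries) {
  if (!is.list(entries)) stop("entries must be a list")
  entries <- lapply(entries, function(e) {
    v <- e$vertices
    if (is.list(v)) v <- do.call(rbind, lapply(v, as.numeric))
    v <- as.matrix(v)
    if (ncol(v) != 2L) stop("vertices must be (row, col) pairs")
    if (nrow(v) < 3L) stop("contour needs at least 3 vertices")
    if (anyNA(v)) stop("contour contains NA vertices")
    if (.polygon_self_intersects(v)) stop("self-intersecting contour")
    s <- e$slice
    if (length(s) != 1L || is.na(s) || s < 0 || s != floor(s))
      stop("slice index must be a non-negative integer")
    list(slice = as.integer(s), vertices = unname(v))
  })
  structure(list(entries = entries), class = "voi_contours")
}

#' @export
print.voi_contours <- function(x, ...) {
  sl <- vapply(x$entries, function(e) e$slice, integer(1))
  cat(sprintf("voi_contours: %d contours on slices [%s]\n", length(x$entries),
              if (length(sl)) paste(range(sl), collapse = ", ") else ""))
  invisible(x)
}

# orientation of triplet (counterclockwise > 0)
.orient <- function(p, q, r) {
  (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
}

.on_segment <- function(p, q, r, eps = 1e-12) {
  # r collinear with p-q assumed; is r within the bounding box of p-q?
  r[1] <= max(p[1], q[1]) + eps && r[1] >= min(p[1], q[1]) - eps &&
    r[2] <= max(p[2], q[2]) + eps && r[2] >= min(p[2], q[2]) - eps
}

.segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- .orient(p3, p4, p1)
  d2 <- .orient(p3, p4, p2)
  d3 <- .orient(p1, p2, p3)
  d4 <- .orient(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  if (d1 == 0 && .on_segment(p3, p4, p1)) return(TRUE)
  if (d2 == 0 && .on_segment(p3, p4, p2)) return(TRUE)
  if (d3 == 0 && .on_segment(p1, p2, p3)) return(TRUE)
  if (d4 == 0 && .on_segment(p1, p2, p4)) return(TRUE)
  FALSE
}

# brute-force simplicity check over non-adjacent edge pairs
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      # skip adjacent edges (shared vertex)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (.segments_intersect(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Read VOI contours from a JSON file
#'
#' @param path JSON file with a list of `{"slice": int, "vertices": [[row,
#'   col], ...]}` objects; slice indices are 0-based, coordinates in voxel
#'   units of the target volume.
#' @return a [voi_contours()].
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  if (!is.list(js)) stop("contour file must contain a list of contours")
  voi_contours(js)
}

#' Write VOI contours to a JSON file
#'
#' @param contours a [voi_contours()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  stopifnot(inherits(contours, "voi_contours"))
  out <- lapply(contours$entries, function(e)
    list(slice = e$slice,
         vertices = lapply(seq_len(nrow(e$vertices)),
                           function(i) as.numeric(e$vertices[i, ]))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
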