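# MRC2014 volume I/O. The format is a fixed 1024-byte little-endian header
# followed by raw voxel data, columns (x) fastest, then rows (y), then
# sections (z). Internally arrays are (z, y, x), so data are permuted on the
# way in and out. Cell dimensions are stored in Angstrom per convention;
# voxel_size_nm = cella / m / 10.

.MRC_MODE_INT8 <- 0L
.MRC_MODE_INT16 <- 1L
.MRC_MODE_FLOAT32 <- 2L
.MRC_MODE_UINT16 <- 6L

.write_mrc <- function(data_zyx, voxel_size_nm, origin_nm, mode, path) {
  d <- dim(data_zyx)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  apx <- voxel_size_nm * 10                      # Angstrom per voxel
  wi(c(nx, ny, nz))                              # 1-3 NX NY NZ
  wi(mode)                                       # 4 MODE
  wi(c(0L, 0L, 0L))                              # 5-7 NSTART
  wi(c(nx, ny, nz))                              # 8-10 MX MY MZ
  wf(c(nx, ny, nz) * apx)                        # 11-13 CELLA (A)
  wf(c(90, 90, 90))                              # 14-16 CELLB
  wi(c(1L, 2L, 3L))                              # 17-19 MAPC MAPR MAPS
  rng <- range(data_zyx)
  wf(c(rng[1], rng[2], mean(data_zyx)))          # 20-22 DMIN DMAX DMEAN
  wi(1L)                                         # 23 ISPG (volume)
  wi(0L)                                         # 24 NSYMBT
  wi(0L); wi(0L)                                 # 25-26 EXTRA
  writeChar("MRCO", con, nchars = 4, eos = NULL) # 27 EXTTYP
  wi(20140L)                                     # 28 NVERSION
  wi(rep(0L, 21))                                # 29-49 EXTRA
  wf(rev(origin_nm) * 10)                        # 50-52 ORIGIN x,y,z (A)
  writeChar("MAP ", con, nchars = 4, eos = NULL) # 53 MAP
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # 54 MACHST (little-endian)
  wf(sd(as.numeric(data_zyx)))                   # 55 RMS
  wi(0L)                                         # 56 NLABL
  writeBin(raw(800), con)                        # 57-256 LABEL
  vec <- aperm(data_zyx, c(3L, 2L, 1L))          # x fastest
  if (mode == .MRC_MODE_FLOAT32) {
    writeBin(as.numeric(vec), con, size = 4L, endian = "little")
  } else if (mode == .MRC_MODE_INT16) {
    v <- as.integer(vec)
    if (any(v > 32767L) || any(v < -32768L))
      stop("values out of int16 range for MRC mode 1")
    writeBin(v, con, size = 2L, endian = "little")
  } else if (mode == .MRC_MODE_INT8) {
    writeBin(as.integer(vec), con, size = 1L, endian = "little")
  } else stop("unsupported MRC write mode ", mode)
  invisible(path)
}

.read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", n = k, size = 4L, endian = "little")
  rf <- function(k) readBin(con, "numeric", n = k, size = 4L, endian = "little")
  nxyz <- ri(3)
  mode <- ri(1)
  ri(3)                                          # nstart
  mxyz <- ri(3)
  cella <- rf(3)
  rf(3)                                          # cellb
  ri(3)                                          # mapc/mapr/maps
  rf(3)                                          # dmin/dmax/dmean
  ispg <- ri(1)
  nsymbt <- ri(1)
  seek(con, 49 * 4)
  origin_a <- rf(3)
  maptag <- readChar(con, 4, useBytes = TRUE)
  if (!identical(maptag, "MAP "))
    stop("not an MRC2014 file (missing MAP tag): ", path)
  seek(con, 1024 + nsymbt)
  nx <- nxyz[1]; ny <- nxyz[2]; nz <- nxyz[3]
  if (any(nxyz < 1L)) stop("invalid MRC dimensions")
  if (nz == 1L && ispg == 0L) stop("expected 3D volume, got a 2D MRC image")
  if (any(mxyz < 1L) || any(cella <= 0))
    stop("non-positive or absent pixel size in MRC header")
  apvox <- cella / mxyz                          # Angstrom per voxel, per axis
  if (diff(range(apvox)) > 1e-3 * mean(apvox))
    stop("anisotropic voxel size in MRC header (>0.1% spread): ",
         paste(signif(apvox, 6), collapse = ", "))
  voxel_size_nm <- mean(apvox) / 10
  n <- as.numeric(nx) * ny * nz
  vec <- switch(as.character(mode),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                  endian = "little"),
    "0" = readBin(con, "integer", n = n, size = 1L, signed = TRUE,
                  endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                  endian = "little"),
    stop("unsupported MRC mode ", mode))
  if (length(vec) != n) stop("truncated MRC data: ", path)
  arr <- aperm(array(vec, dim = c(nx, ny, nz)), c(3L, 2L, 1L))
  list(data = arr, voxel_size_nm = voxel_size_nm, mode = mode,
       origin_nm = rev(origin_a) / 10)
}

#' Read a density volume from an MRC2014 file
#'
#' The voxel size is taken from the cell dimensions (Angstrom, per the MRC
#' convention) and converted to nm; anisotropic headers are rejected beyond a
#' 0.1\% tolerance because all downstream morphometry assumes one voxel size.
#'
#' @param path path to an MRC2014 volume.
#' @return a [density_volume()].
#' @export
read_density <- function(path) {
  m <- .read_mrc(path)
  density_volume(m$data, m$voxel_size_nm, m$origin_nm)
}

#' Write a density volume to an MRC2014 file (32-bit float)
#'
#' @param volume a [density_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density <- function(volume, path) {
  stopifnot(inherits(volume, "density_volume"))
  .write_mrc(volume$data, volume$voxel_size_nm, volume$origin_nm,
             .MRC_MODE_FLOAT32, path)
  invisible(path)
}

#' Read a binary mask from an MRC2014 file
#'
#' @param path path to an integer-mode MRC file with values in \{0, 1\}.
#' @return a [binary_mask()].
#' @export
read_mask <- function(path) {
  m <- .read_mrc(path)
  if (!all(m$data %in% c(0, 1))) stop("mask file contains values other than 0/1")
  binary_mask(m$data > 0, m$voxel_size_nm)
}

#' Write a binary mask to an MRC2014 file (16-bit integer, 0/1)
#'
#' @param mask a [binary_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  arr <- mask$data
  storage.mode(arr) <- "integer"
  .write_mrc(arr, mask$voxel_size_nm, c(0, 0, 0), .MRC_MODE_INT16, path)
  invisible(path)
}

#' Read a label volume from an MRC2014 file
#'
#' @param path path to an integer-mode MRC label map.
#' @return a [label_volume()].
#' @export
read_labels <- function(path) {
  m <- .read_mrc(path)
  label_volume(m$data, m$voxel_size_nm)
}

#' Write a label volume to an MRC2014 file (16-bit integer)
#'
#' Labels must satisfy the `label_volume` invariant (contiguous `1..K`); more
#' than 32767 labels cannot be represented in the 16-bit mode and raise an
#' error rather than overflowing.
#'
#' @param labels a [label_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  if (length(labels$label_ids) > 32767L)
    stop("more than 32767 labels cannot be written in MRC int16 mode")
  .write_mrc(labels$data, labels$voxel_size_nm, c(0, 0, 0),
             .MRC_MODE_INT16, path)
  invisible(path)
}
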