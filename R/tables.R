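# Packaged reference tables: per-PSD morphometrics (area, thickness, volume)
# and per-module trans-PSD measurements (volume, size) for six control and
# two sonicated isolated PSDs, transcribed from the published quantification.
# Checksums guard against silent fixture corruption.

.TABLE1_MD5 <- "62056a37e81f4904779d6f20010ba96c"
.TABLE2_MD5 <- "3ac2c33f23f6843965ac7f51c4eed411"

.reference_table <- function(name, md5) {
  path <- system.file("extdata", name, package = "psdtomo")
  if (path == "" || !file.exists(path))
    stop("packaged reference table missing: ", name)
  got <- unname(tools::md5sum(path))
  if (!identical(got, md5))
    stop("reference table checksum mismatch for ", name,
         " (expected ", md5, ", got ", got, ")")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Reference per-PSD measurements (areas, thicknesses, volumes)
#'
#' @return data.frame with columns `psd_id`, `group`, `area_1e4nm2`,
#'   `thickness_nm`, `volume_1e4nm3` (areas in 10^4 nm^2, volumes in 10^4
#'   nm^3).
#' @export
psd_reference_table <- function() {
  .reference_table("table1.csv", .TABLE1_MD5)
}

#' Reference per-module trans-PSD measurements (volumes, sizes)
#'
#' @return data.frame with columns `psd_id`, `group`, `module_id`,
#'   `volume_1e4nm3`, `size_nm`.
#' @export
trans_reference_table <- function() {
  .reference_table("table2.csv", .TABLE2_MD5)
}

#' Write a module measurement table as CSV
#'
#' Floating-point columns are printed with 6 significant digits.
#'
#' @param df a data.frame (e.g. from [measure_modules()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurement_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
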