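# Trans-PSD modules: modules directly connected to both external surfaces of
# the PSD across its thickness. "Both external surfaces" is operationalized
# per projected cell: every PSD voxel center is projected onto the plane
# orthogonal to the thickness axis and binned into the morphometry area grid;
# within each occupied cell the voxel with the maximal thickness-axis
# coordinate belongs to the top sheet and the minimal one to the bottom sheet.
# This is robust to the curved, lumpy surfaces of real PSDs, unlike a
# geometric mid-plane split.

#' Top and bottom surface sheets of a PSD
#'
#' @param psd_mask a non-empty [binary_mask()].
#' @param axes a [principal_axes()] object for the PSD (thickness axis =
#'   third column); if missing it is computed from the mask.
#' @return list with `top` and `bottom`, each an integer n x 3 matrix of
#'   1-based (z, y, x) voxel indices. A cell containing a single voxel
#'   contributes that voxel to both sheets.
#' @export
classify_surface_voxels <- function(psd_mask, axes = NULL) {
  stopifnot(inherits(psd_mask, "binary_mask"))
  if (!any(psd_mask$data)) stop("empty mask")
  if (is.null(axes)) axes <- principal_axes(psd_mask)
  stopifnot(inherits(axes, "principal_axes"))
  # a flat sheet still has a well-defined thickness axis (its normal); the
  # axis is undefined only when the surface is collinear or a single point
  ev <- axes$eigenvalues
  if (is.null(ev) || sum(ev > 1e-9 * max(ev, 1)) < 2L)
    stop("degenerate principal axes: thickness axis undefined")
  vox <- psd_mask$voxel_size_nm
  idx <- which_zyx(psd_mask$data)
  coords <- voxel_centers_nm(idx, vox)
  centered <- sweep(coords, 2L, axes$centroid_nm)
  u <- floor((centered %*% axes$axes[, 1]) / vox)
  v <- floor((centered %*% axes$axes[, 2]) / vox)
  w <- centered %*% axes$axes[, 3]           # thickness-axis coordinate
  cell <- paste(u, v, sep = ",")
  ord <- order(cell, w, method = "radix")
  cell_o <- cell[ord]
  first <- !duplicated(cell_o)
  last <- !duplicated(cell_o, fromLast = TRUE)
  list(top = idx[ord[last], , drop = FALSE],
       bottom = idx[ord[first], , drop = FALSE])
}

#' Detect trans-PSD modules and summarize their volume contributions
#'
#' A module is trans when it owns at least `min_contact_voxels` voxels in the
#' top sheet and at least as many in the bottom sheet of the PSD surface (see
#' [classify_surface_voxels()]). The default of 1 contact voxel is the
#' literal reading of "directly connected"; raise it to suppress single-voxel
#' artifacts.
#'
#' @param labels a [label_volume()] partitioning the PSD mask.
#' @param psd a `psd_morphometry` from [measure_psd()] of the same mask.
#' @param min_contact_voxels positive integer contact threshold.
#' @return an object of class `trans_report`: `trans_label_ids`, `modules`
#'   (data.frame with `label_id`, `volume_nm3`, `size_nm`,
#'   `fraction_of_psd_volume` in percent, sorted by descending volume),
#'   `n_trans`, `total_trans_volume_percent`.
#' @export
find_trans_modules <- function(labels, psd, min_contact_voxels = 1L) {
  stopifnot(inherits(labels, "label_volume"), inherits(psd, "psd_morphometry"))
  min_contact_voxels <- as.integer(min_contact_voxels)
  if (min_contact_voxels < 1L) stop("min_contact_voxels must be >= 1")
  mask <- binary_mask(labels$data > 0L, labels$voxel_size_nm)
  if (abs(mask_volume_nm3(mask) - psd$volume_nm3) > 1e-6 * psd$volume_nm3)
    stop("labels do not partition the PSD mask used for the morphometry")
  sheets <- classify_surface_voxels(mask, psd$axes)
  lab_at <- function(idx) labels$data[idx]
  top_labels <- lab_at(sheets$top)
  bottom_labels <- lab_at(sheets$bottom)
  ids <- labels$label_ids
  top_n <- tabulate(top_labels, nbins = max(ids))
  bottom_n <- tabulate(bottom_labels, nbins = max(ids))
  trans_ids <- ids[top_n[ids] >= min_contact_voxels &
                   bottom_n[ids] >= min_contact_voxels]
  vox <- labels$voxel_size_nm
  counts <- tabulate(labels$data[labels$data > 0L], nbins = max(ids))
  if (length(trans_ids) > 0L) {
    recs <- measure_modules(.subset_labels(labels, trans_ids))
    # .subset_labels renumbers; map back to original ids by order
    vols <- counts[trans_ids] * vox^3
    sizes <- recs$size_nm[match(seq_along(trans_ids), recs$label_id)]
    df <- data.frame(label_id = trans_ids, volume_nm3 = vols, size_nm = sizes,
                     fraction_of_psd_volume = 100 * vols / psd$volume_nm3)
    df <- df[order(-df$volume_nm3, df$label_id), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(label_id = integer(0), volume_nm3 = numeric(0),
                     size_nm = numeric(0), fraction_of_psd_volume = numeric(0))
  }
  structure(list(trans_label_ids = df$label_id, modules = df,
                 n_trans = nrow(df),
                 total_trans_volume_percent = sum(df$fraction_of_psd_volume)),
            class = "trans_report")
}

# keep only the given labels (renumbered 1..k in the order supplied), zero out
# the rest; used to measure a subset without re-measuring the full map
.subset_labels <- function(labels, keep_ids) {
  lab <- labels$data
  out <- array(0L, dim = dim(lab))
  for (k in seq_along(keep_ids)) out[lab == keep_ids[k]] <- k
  label_volume(out, labels$voxel_size_nm)
}

#' @export
print.trans_report <- function(x, ...) {
  cat(sprintf("trans_report: %d trans modules, %.3g%% of PSD volume in total\n",
              x$n_trans, x$total_trans_volume_percent))
  invisible(x)
}

#' Summary of trans-module tables grouped by PSD
#'
#' Computes, per experimental group, the trans-module count, size and volume
#' ranges, the per-PSD total trans volume percentages and the range of
#' individual module percentages, from tabulated per-module and per-PSD
#' measurements. Percentages are reported both raw and rounded to 2
#' significant figures (the reporting convention of the reference tables).
#'
#' @param trans_table data.frame with columns `psd_id`, `group`, `module_id`,
#'   `volume_1e4nm3` (module volume in 10^4 nm^3 units), `size_nm`.
#' @param psd_table data.frame with columns `psd_id`, `group`,
#'   `volume_1e4nm3` (PSD volume in 10^4 nm^3 units).
#' @return named list of per-group summaries, each with `n_trans`,
#'   `size_range_nm`, `volume_range_nm3`, `per_psd_total_percent`,
#'   `total_percent_range`, `individual_percent_range` (all percent values to
#'   2 significant figures alongside unrounded `*_raw`).
#' @export
trans_summary_from_table <- function(trans_table, psd_table) {
  need_t <- c("psd_id", "group", "volume_1e4nm3", "size_nm")
  need_p <- c("psd_id", "group", "volume_1e4nm3")
  if (!all(need_t %in% names(trans_table)))
    stop("trans_table must have columns ", paste(need_t, collapse = ", "))
  if (!all(need_p %in% names(psd_table)))
    stop("psd_table must have columns ", paste(need_p, collapse = ", "))
  key_t <- paste(trans_table$group, trans_table$psd_id)
  key_p <- paste(psd_table$group, psd_table$psd_id)
  orphan <- setdiff(key_t, key_p)
  if (length(orphan) > 0L)
    stop("trans_table rows reference unknown PSDs: ",
         paste(orphan, collapse = "; "))
  psd_vol <- psd_table$volume_1e4nm3[match(key_t, key_p)]
  pct <- 100 * trans_table$volume_1e4nm3 / psd_vol
  out <- list()
  for (g in unique(psd_table$group)) {
    sel <- trans_table$group == g
    if (!any(sel)) {
      out[[g]] <- list(n_trans = 0L)
      next
    }
    tt <- trans_table[sel, , drop = FALSE]
    pp <- pct[sel]
    per_psd <- tapply(pp, tt$psd_id, sum)
    out[[g]] <- list(
      n_trans = nrow(tt),
      size_range_nm = signif(range(tt$size_nm), 2),
      size_range_nm_raw = range(tt$size_nm),
      volume_range_nm3 = signif(range(tt$volume_1e4nm3) * 1e4, 2),
      volume_range_nm3_raw = range(tt$volume_1e4nm3) * 1e4,
      per_psd_total_percent = signif(as.numeric(per_psd), 2),
      total_percent_range = signif(range(per_psd), 2),
      total_percent_range_raw = range(per_psd),
      individual_percent_range = signif(range(pp), 2),
      individual_percent_range_raw = range(pp))
  }
  out
}
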