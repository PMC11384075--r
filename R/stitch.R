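#' Calibrate the raw-unit to nanometre scale
#'
#' Given measured physical spacings (nm) paired with the corresponding
#' raw-unit spacings (e.g. distances between fiducial circles measured in
#' stained or electron-microscopy images versus read-name coordinates), the
#' scale is the least-squares ratio `k` minimising `sum((nm - k * raw)^2)`.
#'
#' @param nm Numeric vector of physical spacings in nm.
#' @param raw Numeric vector of the same spacings in raw units.
#' @return An object of class `scale_calibration` with `nm_per_unit` and the
#'   source pairs.
#' @examples
#' calibrate_scale(nm = 25000, raw = 728)
#' @export
calibrate_scale <- function(nm, raw) {
  stopifnot(length(nm) == length(raw), length(nm) >= 1L)
  if (any(raw == 0)) stop("zero raw spacing: scale undefined")
  k <- sum(nm * raw) / sum(raw^2)
  structure(list(nm_per_unit = k,
                 source = data.table::data.table(nm = nm, raw = raw)),
            class = "scale_calibration")
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("scale_calibration: %.4f nm per raw unit (%d spacing pairs)\n",
              x$nm_per_unit, nrow(x$source)))
  invisible(x)
}

#' Expected global fiducial-centroid position of a tile
#'
#' The chip is anchored at the top-left tile (swath 1, row 1): its fiducial
#' centroid defines the origin of the grid. Tiles advance by one tile
#' spacing per swath (x) and per row (y); even swaths (2, 4, 6) are offset
#' by one full tile along the configured axis.
#'
#' @param swath Swath number, 1-6.
#' @param row Tile row within the swath (1-based).
#' @param spacing Numeric `c(x, y)` tile spacing in raw units.
#' @param anchor Numeric `c(x, y)`: global raw-unit position of the anchor
#'   tile's centroid.
#' @param offset_axis Axis of the even-swath single-tile offset, "y" or "x".
#' @return Numeric `c(x, y)` expected centroid in global raw units.
#' @export
expected_centroid <- function(swath, row, spacing, anchor = c(0, 0),
                              offset_axis = "y") {
  if (!swath %in% 1:6) stop("swath must be between 1 and 6")
  stopifnot(row >= 1, offset_axis %in% c("x", "y"))
  shift <- as.numeric(swath %% 2L == 0L)
  if (offset_axis == "y")
    c(anchor[1] + (swath - 1) * spacing[1],
      anchor[2] + (row - 1 + shift) * spacing[2])
  else
    c(anchor[1] + (swath - 1 + shift) * spacing[1],
      anchor[2] + (row - 1) * spacing[2])
}

#' Per-tile offsets placing fiducial centroids on the expected grid
#'
#' For each tile with an observed (or interpolated) centroid, the offset is
#' `expected_centroid - observed_centroid`; adding it to a tile's local
#' coordinates moves them into the global raw-unit frame. The anchor
#' defaults to the observed centroid of the first tile (lowest swath, then
#' lowest row), so that tile's offset places it at the grid origin.
#'
#' @param centroids `data.table` with `tile_id`, `swath`, `row`, `cx`, `cy`
#'   (local raw units; `NA` centroids are excluded and reported).
#' @param spacing Numeric `c(x, y)` tile spacing in raw units.
#' @param anchor Global raw-unit centroid position of the top-left tile;
#'   default anchors the grid at that tile's observed centroid.
#' @param offset_axis See [expected_centroid()].
#' @return `data.table` with `tile_id`, `dx`, `dy`; excluded tiles carried
#'   in attribute `"excluded"`.
#' @export
compute_tile_offsets <- function(centroids, spacing, anchor = NULL,
                                 offset_axis = "y") {
  cts <- data.table::as.data.table(centroids)
  bad <- cts[is.na(cx) | is.na(cy)]
  if (nrow(bad))
    warning("tiles without centroid excluded from stitching: ",
            paste(bad$tile_id, collapse = ", "))
  cts <- cts[!is.na(cx) & !is.na(cy)]
  if (nrow(cts) == 0L) stop("no tiles with resolved centroids")
  data.table::setorder(cts, swath, row)
  if (is.null(anchor)) anchor <- c(cts$cx[1], cts$cy[1])
  exp_xy <- t(mapply(function(s, r) expected_centroid(s, r, spacing, anchor,
                                                      offset_axis),
                     cts$swath, cts$row))
  out <- data.table::data.table(tile_id = cts$tile_id,
                                dx = exp_xy[, 1] - cts$cx,
                                dy = exp_xy[, 2] - cts$cy)
  data.table::setattr(out, "excluded", bad$tile_id)
  out
}

#' Apply tile offsets and scale calibration to build a global index
#'
#' Each record's global position is `(local + offset) * nm_per_unit`.
#' Record counts are conserved; barcodes duplicated across the chip are
#' retained but counted in the `collisions` attribute.
#'
#' @param indexes Named list of `nova_tile_index` (from [index_fastq_dir()]).
#' @param offsets `data.table` from [compute_tile_offsets()].
#' @param calibration A [calibrate_scale()] result.
#' @return `data.table` (class `nova_global_index`) with columns `barcode`,
#'   `x_nm`, `y_nm`, `tile_id`; attributes `nm_per_unit`, `collisions`.
#' @export
apply_offsets <- function(indexes, offsets, calibration) {
  stopifnot(inherits(calibration, "scale_calibration"))
  k <- calibration$nm_per_unit
  off <- data.table::as.data.table(offsets)
  out <- vector("list", length(indexes))
  for (i in seq_along(indexes)) {
    idx <- indexes[[i]]
    if (nrow(idx$records) == 0L) next
    o <- off[tile_id == idx$tile_id]
    if (nrow(o) == 0L)
      stop("missing offset for tile ", idx$tile_id)
    out[[i]] <- data.table::data.table(barcode = idx$records$barcode,
                                       x_nm = (idx$records$x + o$dx) * k,
                                       y_nm = (idx$records$y + o$dy) * k,
                                       tile_id = idx$tile_id)
  }
  gi <- data.table::rbindlist(out)
  n_coll <- sum(duplicated(gi$barcode))
  if (n_coll > 0L)
    message(n_coll, " duplicate barcode records across tiles (retained, logged)")
  data.table::setattr(gi, "nm_per_unit", k)
  data.table::setattr(gi, "collisions", n_coll)
  data.table::setattr(gi, "class",
                      c("nova_global_index", class(gi)))
  gi
}

#' Stitch a set of tile indexes into one global frame
#'
#' Convenience orchestration: detect fiducials per tile, interpolate missing
#' centroids, compute offsets and apply them with the given calibration.
#'
#' @param indexes Named list of `nova_tile_index`.
#' @param calibration A [calibrate_scale()] result.
#' @param tile_spacing Numeric `c(x, y)` tile spacing in raw units.
#' @param tile_dims Numeric `c(width, height)` passed to the density imager.
#' @param bin_size Density-image bin size.
#' @param n_fiducials Expected fiducials per tile.
#' @param offset_axis See [expected_centroid()].
#' @param ... Passed to [detect_tile_fiducials()].
#' @return List with `global` (the `nova_global_index`), `centroids`,
#'   `offsets`, `fiducials` (per-tile detections).
#' @export
stitch_tiles <- function(indexes, calibration, tile_spacing, tile_dims,
                         bin_size = 25L, n_fiducials = 4L,
                         offset_axis = "y", ...) {
  fids <- lapply(indexes, detect_tile_fiducials, bin_size = bin_size,
                 width = tile_dims[1], height = tile_dims[2],
                 n_fiducials = n_fiducials, ...)
  cts <- data.table::rbindlist(lapply(fids, function(f) {
    parts <- split_tile_id(f$tile_id)
    data.table::data.table(tile_id = f$tile_id, swath = parts$swath,
                           row = parts$row, cx = f$centroid[1],
                           cy = f$centroid[2])
  }))
  cts <- interpolate_missing(cts)
  offsets <- compute_tile_offsets(cts, tile_spacing, offset_axis = offset_axis)
  global <- apply_offsets(indexes, offsets, calibration)
  list(global = global, centroids = cts, offsets = offsets, fiducials = fids)
}

#' Export a global index as tab-separated text
#'
#' @param global A `nova_global_index`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_global_index <- function(global, path) {
  hdr <- c("# novaST global index",
           sprintf("# nm_per_unit=%.10g", attr(global, "nm_per_unit")),
           sprintf("# collisions=%d", attr(global, "collisions")))
  writeLines(hdr, path)
  data.table::fwrite(data.table::as.data.table(global)[
    , .(barcode, x_nm, y_nm, tile_id)], path, sep = "\t",
    append = TRUE, col.names = TRUE)
  invisible(path)
}
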