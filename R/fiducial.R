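#' Build a barcode-density image for one tile
#'
#' Bins valid-barcode coordinates into `bin_size x bin_size` pixels
#' (coordinates are first cropped to a multiple of `bin_size`) and rescales
#' intensities to 0-255. Scaling is robust: counts are normalised by the
#' median nonzero pixel count and clipped at 255, so that typically occupied
#' pixels saturate and fiducial voids (zero counts) retain full contrast at
#' the fixed binarisation threshold downstream.
#'
#' The matrix is oriented image-style: `mat[i, j]` covers raw coordinates
#' `y` in `[(i-1), i) * bin_size` and `x` in `[(j-1), j) * bin_size`.
#'
#' @param index A `nova_tile_index`.
#' @param bin_size Raw units per pixel edge (default 25).
#' @param width,height Tile extent in raw units; inferred from the data when
#'   `NULL`. Supplying them keeps image dimensions identical across tiles.
#' @return An object of class `density_image`: `mat` (0-255), `counts`
#'   (raw per-pixel occupancy), `bin_size`, `origin` (raw units of pixel
#'   (1,1)'s corner) and `tile_id`.
#' @export
build_density_image <- function(index, bin_size = 25L, width = NULL,
                                height = NULL) {
  stopifnot(bin_size >= 1)
  rec <- index$records
  if (nrow(rec) == 0L) stop("empty index: cannot build a density image")
  ncol_px <- if (is.null(width)) (max(rec$x) %/% bin_size) + 1L
             else as.integer(width %/% bin_size)
  nrow_px <- if (is.null(height)) (max(rec$y) %/% bin_size) + 1L
             else as.integer(height %/% bin_size)
  jx <- rec$x %/% bin_size + 1L
  iy <- rec$y %/% bin_size + 1L
  keep <- jx >= 1L & jx <= ncol_px & iy >= 1L & iy <= nrow_px
  counts <- matrix(0L, nrow_px, ncol_px)
  tab <- data.table::data.table(i = iy[keep], j = jx[keep])[, .N, by = .(i, j)]
  counts[cbind(tab$i, tab$j)] <- tab$N
  ref <- stats::median(counts[counts > 0])
  mat <- pmin(counts / ref * 255, 255)
  structure(list(mat = mat, counts = counts, bin_size = as.integer(bin_size),
                 origin = c(0, 0), tile_id = index$tile_id),
            class = "density_image")
}

#' Preprocess a density image for circle detection
#'
#' Inverts the normalised image (voids become bright), removes isolated
#' salt pixels with a 3x3 median rank filter, and binarises at 128 to
#' produce a 0/255 image of the fiducial voids.
#'
#' @param img A `density_image` (or plain 0-255 matrix).
#' @param threshold Binarisation threshold (default 128).
#' @return Matrix of 0/255 values, same dimensions as the input.
#' @export
preprocess_image <- function(img, threshold = 128) {
  mat <- if (inherits(img, "density_image")) img$mat else img
  inv <- 255 - mat
  den <- EBImage::medianFilter(inv / 255, size = 1L) * 255
  ifelse(den >= threshold, 255, 0)
}

#' Detect circles in a binary image
#'
#' Gradient-voting circle transform: edge pixels of the binary image vote
#' along their local gradient direction (both senses, estimated on a
#' Gaussian-smoothed copy of the image to stabilise directions on ragged
#' stochastic boundaries) at every radius in each configured range. The
#' accumulator is summed over 5x5 pixel boxes; peaks exceeding
#' `vote_threshold * 2 * pi * min_radius` box votes and separated by at
#' least `min_dist_factor * min_radius` become circle candidates, whose
#' centres and radii are then refined by an algebraic least-squares circle
#' fit to the nearby edge pixels. The transform is run once per radius
#' range and candidates are labelled with the range's class.
#'
#' @param bw Binary matrix (0 / 255), image-oriented (`[y, x]`).
#' @param radius_ranges Named list of `c(min, max)` pixel radii; defaults to
#'   the outer 40-80 px and inner 15-30 px fiducial circle ranges.
#' @param vote_threshold Minimum box-summed accumulator votes for a
#'   candidate, in units of the minimum circle circumference
#'   `2*pi*rmin` (default 3; true circles score around 6-7 on simulated
#'   tiles while background clutter stays below 1.5).
#' @param min_dist_factor Minimum separation between accepted centres, in
#'   units of the range's minimum radius (default 2).
#' @param max_circles Cap on candidates per range.
#' @return `data.table` with columns `cx`, `cy` (0-based pixel coordinates
#'   of pixel centres), `r` (pixels), `votes`, `class`.
#' @export
detect_circles <- function(bw,
                           radius_ranges = list(outer = c(40, 80),
                                                inner = c(15, 30)),
                           vote_threshold = 3,
                           min_dist_factor = 2,
                           max_circles = 16L) {
  edges <- edge_pixels(bw)
  out <- list()
  for (cls in names(radius_ranges)) {
    rng <- radius_ranges[[cls]]
    cand <- hough_circle_range(edges, dim(bw), rng, vote_threshold,
                               min_dist_factor * rng[1], max_circles)
    if (nrow(cand)) cand[, class := cls]
    out[[cls]] <- cand
  }
  res <- data.table::rbindlist(out, fill = TRUE)
  if (!nrow(res))
    res <- data.table::data.table(cx = numeric(0), cy = numeric(0),
                                  r = numeric(0), votes = numeric(0),
                                  class = character(0))
  res[]
}

# edge pixels of a 0/255 binary image with unit gradient directions;
# 0-based pixel-centre coordinates (x = column - 1, y = row - 1).
# Gradient directions are taken from a Gaussian-smoothed (sigma = 2) copy
# of the image so that the ragged, occupancy-noise boundary does not
# scatter the Hough votes.
edge_pixels <- function(bw) {
  b <- bw > 0
  nr <- nrow(b); nc <- ncol(b)
  if (nr < 5L || nc < 5L)
    return(data.table::data.table(x = numeric(0), y = numeric(0),
                                  gx = numeric(0), gy = numeric(0)))
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- b
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nbr_any0 <- !pad[1:nr, 2:(nc + 1L)] | !pad[3:(nr + 2L), 2:(nc + 1L)] |
              !pad[2:(nr + 1L), 1:nc] | !pad[2:(nr + 1L), 3:(nc + 2L)]
  edge <- core & nbr_any0
  # Sobel gradient of the smoothed image
  sm <- as.matrix(EBImage::gblur(b * 1, sigma = 2))
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- sm
  gx <- (p[1:nr, 3:(nc + 2)] + 2 * p[2:(nr + 1), 3:(nc + 2)] + p[3:(nr + 2), 3:(nc + 2)]) -
        (p[1:nr, 1:nc]       + 2 * p[2:(nr + 1), 1:nc]       + p[3:(nr + 2), 1:nc])
  gy <- (p[3:(nr + 2), 1:nc] + 2 * p[3:(nr + 2), 2:(nc + 1)] + p[3:(nr + 2), 3:(nc + 2)]) -
        (p[1:nr, 1:nc]       + 2 * p[1:nr, 2:(nc + 1)]       + p[1:nr, 3:(nc + 2)])
  idx <- which(edge & (gx != 0 | gy != 0))
  iy <- (idx - 1L) %% nr + 1L
  jx <- (idx - 1L) %/% nr + 1L
  g <- sqrt(gx[idx]^2 + gy[idx]^2)
  data.table::data.table(x = jx - 1, y = iy - 1,
                         gx = gx[idx] / g, gy = gy[idx] / g)
}

# Hough voting + peak extraction + least-squares refinement for one range
hough_circle_range <- function(edges, img_dim, rng, vote_threshold,
                               min_dist, max_circles) {
  empty <- data.table::data.table(cx = numeric(0), cy = numeric(0),
                                  r = numeric(0), votes = numeric(0))
  if (nrow(edges) == 0L) return(empty)
  nr <- img_dim[1]; nc <- img_dim[2]
  acc <- matrix(0L, nr, nc)
  radii <- seq(rng[1], rng[2])
  for (r in radii) {
    for (sgn in c(-1, 1)) {
      cx <- round(edges$x + sgn * r * edges$gx) + 1
      cy <- round(edges$y + sgn * r * edges$gy) + 1
      ok <- cx >= 1 & cx <= nc & cy >= 1 & cy <= nr
      if (!any(ok)) next
      lin <- cy[ok] + (cx[ok] - 1) * nr
      tab <- tabulate(lin, nbins = nr * nc)
      acc <- acc + tab
    }
  }
  acc <- as.matrix(EBImage::filter2(acc, matrix(1, 5, 5), boundary = 0))
  min_votes <- vote_threshold * 2 * pi * rng[1]
  cand <- which(acc >= min_votes)
  if (!length(cand)) return(empty)
  cand <- cand[order(acc[cand], decreasing = TRUE)]
  py <- (cand - 1L) %% nr  # 0-based
  px <- (cand - 1L) %/% nr
  keep_x <- numeric(0); keep_y <- numeric(0); keep_v <- numeric(0)
  for (k in seq_along(cand)) {
    if (length(keep_x) >= max_circles) break
    if (length(keep_x) &&
        any((px[k] - keep_x)^2 + (py[k] - keep_y)^2 < min_dist^2)) next
    keep_x <- c(keep_x, px[k]); keep_y <- c(keep_y, py[k])
    keep_v <- c(keep_v, acc[cand[k]])
  }
  out <- vector("list", length(keep_x))
  for (k in seq_along(keep_x)) {
    fit <- refine_circle(edges, keep_x[k], keep_y[k], rng)
    out[[k]] <- data.table::data.table(cx = fit[1], cy = fit[2], r = fit[3],
                                       votes = keep_v[k])
  }
  res <- data.table::rbindlist(out)
  res <- res[r >= rng[1] - 1 & r <= rng[2] + 1]
  res
}

# algebraic (Kasa) least-squares circle fit to edge pixels near a candidate
# centre; concentric edge rings share the fitted centre by symmetry
refine_circle <- function(edges, cx0, cy0, rng) {
  d <- sqrt((edges$x - cx0)^2 + (edges$y - cy0)^2)
  sel <- d >= rng[1] - 1.5 & d <= rng[2] + 1.5
  if (sum(sel) < 6L) return(c(cx0, cy0, mean(rng)))
  x <- edges$x[sel]; y <- edges$y[sel]
  a <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(a, b), error = function(e) NULL)
  if (is.null(sol)) return(c(cx0, cy0, mean(rng)))
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(sol[3] + cx^2 + cy^2)
  if (sqrt((cx - cx0)^2 + (cy - cy0)^2) > 3)  # fit drifted off the peak
    return(c(cx0, cy0, stats::median(d[sel])))
  c(cx, cy, r)
}

#' Detect fiducials on one tile
#'
#' Runs the density-image, preprocessing and circle-detection steps and
#' assembles a per-tile fiducial report. A tile is `complete` when exactly
#' `n_fiducials` outer and `n_fiducials` inner circles are found (8 circles
#' in the default 4-fiducial layout); only then is the joint centroid of all
#' circle centres computed (in raw units). Per-class centroids are included
#' for QC.
#'
#' @param index A `nova_tile_index`.
#' @param bin_size Density-image bin size (raw units per pixel).
#' @param width,height Tile extent in raw units (see [build_density_image()]).
#' @param n_fiducials Expected fiducial marks per tile (default 4).
#' @param radius_ranges Passed to [detect_circles()].
#' @param ... Further arguments to [detect_circles()].
#' @return An object of class `tile_fiducials`: `tile_id`, `circles`,
#'   `complete`, `centroid` (raw units, `NA` when incomplete),
#'   `centroid_outer`, `centroid_inner`.
#' @export
detect_tile_fiducials <- function(index, bin_size = 25L, width = NULL,
                                  height = NULL, n_fiducials = 4L,
                                  radius_ranges = list(outer = c(40, 80),
                                                       inner = c(15, 30)),
                                  ...) {
  img <- build_density_image(index, bin_size, width, height)
  bw <- preprocess_image(img)
  circles <- detect_circles(bw, radius_ranges, ...)
  fiducials_from_circles(circles, index$tile_id, bin_size, img$origin,
                         n_fiducials)
}

fiducials_from_circles <- function(circles, tile_id, bin_size, origin,
                                   n_fiducials) {
  n_outer <- sum(circles$class == "outer")
  n_inner <- sum(circles$class == "inner")
  complete <- n_outer == n_fiducials && n_inner == n_fiducials
  px_to_raw <- function(p, off) (p + 0.5) * bin_size + off
  cls_centroid <- function(cls) {
    sub <- circles[class == cls]
    if (!nrow(sub)) return(c(NA_real_, NA_real_))
    c(px_to_raw(mean(sub$cx), origin[1]), px_to_raw(mean(sub$cy), origin[2]))
  }
  centroid <- if (complete)
    c(px_to_raw(mean(circles$cx), origin[1]),
      px_to_raw(mean(circles$cy), origin[2]))
  else c(NA_real_, NA_real_)
  structure(list(tile_id = tile_id, circles = circles,
                 complete = complete, centroid = centroid,
                 centroid_outer = cls_centroid("outer"),
                 centroid_inner = cls_centroid("inner"),
                 bin_size = bin_size),
            class = "tile_fiducials")
}

#' @export
print.tile_fiducials <- function(x, ...) {
  cat(sprintf("tile_fiducials: tile %s, %d circles, complete=%s, centroid=(%.1f, %.1f)\n",
              x$tile_id, nrow(x$circles), x$complete,
              x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Centroid of a complete fiducial set
#'
#' Arithmetic mean of all circle centres, converted from pixels to raw
#' units. Errors if the set is incomplete (incomplete tiles are handled by
#' [interpolate_missing()]).
#'
#' @param fiducials A `tile_fiducials`.
#' @return Numeric `c(x, y)` in raw units.
#' @export
tile_centroid <- function(fiducials) {
  if (!fiducials$complete)
    stop("fiducial set incomplete for tile ", fiducials$tile_id,
         "; centroid is missing (interpolate from neighbours)")
  fiducials$centroid
}

#' Interpolate missing tile centroids from grid neighbours
#'
#' Under the assumption of constant intra-tile fiducial placement, a missing
#' tile centroid (in local raw units) is estimated as the mean of the
#' available centroids of grid neighbours at distance 1 (same swath +/- one
#' row, same row +/- one swath). Tiles with no resolvable neighbour are
#' reported as unresolved.
#'
#' @param centroids `data.table` with columns `tile_id`, `swath`, `row`,
#'   `cx`, `cy` (`NA` where missing).
#' @return The table with missing centroids filled where possible and a
#'   logical `interpolated` column; unresolved tiles keep `NA`.
#' @export
interpolate_missing <- function(centroids) {
  out <- data.table::copy(centroids)
  out[, interpolated := FALSE]
  miss <- which(is.na(out$cx) | is.na(out$cy))
  for (i in miss) {
    nb <- out[!is.na(cx) & !is.na(cy) &
                abs(swath - out$swath[i]) + abs(row - out$row[i]) == 1L]
    if (nrow(nb) == 0L) next
    out$cx[i] <- mean(nb$cx)
    out$cy[i] <- mean(nb$cy)
    out$interpolated[i] <- TRUE
  }
  unresolved <- out[is.na(cx) | is.na(cy)]
  if (nrow(unresolved))
    warning("unresolved tile centroids (no neighbours): ",
            paste(unresolved$tile_id, collapse = ", "))
  out[]
}
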