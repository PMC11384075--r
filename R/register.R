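#' Fit a 2-D affine transform from landmark pairs
#'
#' Least-squares estimate of the full six-parameter affine map
#' `(x, y) -> A [x y 1]'` minimising the summed squared distances between
#' transformed source landmarks and their targets. Used to register stained
#' tissue images to the spatial coordinate frame from manually selected
#' fiducial landmarks.
#'
#' @param src Numeric n x 2 matrix of source points (e.g. image pixels).
#' @param dst Numeric n x 2 matrix of target points (e.g. global nm).
#' @return An object of class `affine_transform`: `A` (2 x 3 coefficient
#'   matrix), `residuals` (per-pair Euclidean distances), `rmse`.
#' @export
fit_affine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2L, ncol(dst) == 2L, nrow(src) == nrow(dst))
  if (nrow(src) < 3L)
    stop("degenerate configuration: at least 3 landmark pairs required")
  x <- cbind(src, 1)
  qx <- qr(x)
  if (qx$rank < 3L)
    stop("degenerate configuration: landmarks are collinear")
  coef <- qr.coef(qx, dst)           # 3 x 2
  a <- t(coef)                       # 2 x 3
  dimnames(a) <- NULL
  pred <- x %*% coef
  res <- sqrt(rowSums((pred - dst)^2))
  structure(list(A = a, residuals = res,
                 rmse = sqrt(mean(res^2))),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("affine_transform (2x3):\n")
  print(x$A)
  cat(sprintf("rmse over %d landmarks: %.4g\n", length(x$residuals), x$rmse))
  invisible(x)
}

#' Apply an affine transform to points
#'
#' @param transform An `affine_transform` (or plain 2 x 3 matrix).
#' @param points Numeric n x 2 matrix.
#' @return Numeric n x 2 matrix of transformed points.
#' @export
apply_affine <- function(transform, points) {
  a <- if (inherits(transform, "affine_transform")) transform$A
       else as.matrix(transform)
  stopifnot(identical(dim(a), c(2L, 3L)))
  points <- as.matrix(points)
  out <- cbind(points, 1) %*% t(a)
  colnames(out) <- c("x", "y")
  out
}

#' Read landmark pairs from a tab-separated file
#'
#' Expected columns: `src_x src_y dst_x dst_y` (header optional; `#`
#' comment lines ignored).
#'
#' @param path Landmark file.
#' @return List with matrices `src` and `dst`.
#' @export
read_landmarks <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  if (!all(c("src_x", "src_y", "dst_x", "dst_y") %in% names(dt))) {
    stopifnot(ncol(dt) >= 4L)
    data.table::setnames(dt, 1:4, c("src_x", "src_y", "dst_x", "dst_y"))
  }
  list(src = as.matrix(dt[, .(src_x, src_y)]),
       dst = as.matrix(dt[, .(dst_x, dst_y)]))
}

#' Write / read an affine transform as a small text sidecar
#'
#' Six whitespace-separated coefficients in row-major order.
#'
#' @param transform An `affine_transform`.
#' @param path Sidecar path.
#' @return For the writer, `path` invisibly; for the reader, an
#'   `affine_transform` (without residuals).
#' @export
write_affine <- function(transform, path) {
  writeLines(c("# novaST affine transform (2x3, row-major)",
               paste(format(t(transform$A), digits = 17), collapse = " ")),
             path)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  vals <- as.numeric(strsplit(trimws(lines[nzchar(lines)][1]), "\\s+")[[1]])
  stopifnot(length(vals) == 6L)
  structure(list(A = matrix(vals, 2L, 3L, byrow = TRUE),
                 residuals = numeric(0), rmse = NA_real_),
            class = "affine_transform")
}
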