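#' Default per-bin gene-count QC thresholds
#'
#' Minimum detected genes per bin at each bin level: 75 at bin50 (728-unit /
#' 25 um bins), 250 at bin100 (1456 / 50 um), 500 at bin200 (2912 / 100 um).
#'
#' @return Named numeric vector keyed bin50 / bin100 / bin200.
#' @export
qc_thresholds <- function() {
  c(bin50 = 75, bin100 = 250, bin200 = 500)
}

# canonical bin level label for a native bin size, or NA
bin_level <- function(bin_size_native) {
  unname(c(`728` = "bin50", `1456` = "bin100",
           `2912` = "bin200")[as.character(bin_size_native)])
}

#' Square-bin GEM counts
#'
#' Aggregates GEM records into square bins of `bin_size_native` native
#' coordinate units per edge, anchored at the chip origin: record (x, y)
#' falls in bin `(floor(x / s), floor(y / s))`. Total counts are conserved.
#'
#' @param gem `data.table` with geneID, x, y, MIDCount (native units).
#' @param bin_size_native Bin edge in native units (728, 1456, 2912 for
#'   25/50/100 um at the default scale; any positive size is accepted).
#' @param nm_per_unit Physical size of a native unit, used only to report
#'   the physical bin edge.
#' @return An object of class `nova_binned`: `counts` (sparse genes x bins
#'   matrix), `bins` (`data.table` bin, bx, by), `bin_size_native`,
#'   `bin_size_um`, `level`.
#' @export
bin_counts <- function(gem, bin_size_native, nm_per_unit = 25000 / 728) {
  if (!is.numeric(bin_size_native) || bin_size_native <= 0)
    stop("bin size must be positive")
  g <- data.table::as.data.table(gem)
  g[, `:=`(bx = x %/% as.integer(bin_size_native),
           by_ = y %/% as.integer(bin_size_native))]
  agg <- g[, .(count = sum(MIDCount)), by = .(geneID, bx, by_)]
  bins <- unique(agg[, .(bx, by_)])
  data.table::setorder(bins, bx, by_)
  bins[, bin := sprintf("%d_%d", bx, by_)]
  genes <- sort(unique(agg$geneID))
  mat <- Matrix::sparseMatrix(i = match(agg$geneID, genes),
                              j = match(sprintf("%d_%d", agg$bx, agg$by_),
                                        bins$bin),
                              x = agg$count,
                              dims = c(length(genes), nrow(bins)),
                              dimnames = list(genes, bins$bin))
  structure(list(counts = mat,
                 bins = bins[, .(bin, bx, by = by_)],
                 bin_size_native = bin_size_native,
                 bin_size_um = bin_size_native * nm_per_unit / 1000,
                 level = bin_level(bin_size_native)),
            class = "nova_binned")
}

#' @export
print.nova_binned <- function(x, ...) {
  cat(sprintf("nova_binned: %d genes x %d bins, bin edge %g units (%.1f um)%s\n",
              nrow(x$counts), ncol(x$counts), x$bin_size_native,
              x$bin_size_um,
              if (!is.na(x$level)) paste0(" [", x$level, "]") else ""))
  invisible(x)
}

#' Aggregate bins by an integer factor
#'
#' Re-bins an existing `nova_binned` by grouping `factor x factor` blocks of
#' bin indices; equivalent to binning the original GEM at
#' `factor * bin_size_native`.
#'
#' @param binned A `nova_binned`.
#' @param factor Positive integer aggregation factor.
#' @param nm_per_unit Passed through for the physical edge report.
#' @return A `nova_binned` at the coarser size.
#' @export
aggregate_bins <- function(binned, factor, nm_per_unit = 25000 / 728) {
  stopifnot(factor >= 1, factor == round(factor))
  tm <- methods::as(binned$counts, "TsparseMatrix")
  dt <- data.table::data.table(gene = rownames(binned$counts)[tm@i + 1L],
                               bx = binned$bins$bx[tm@j + 1L] %/% factor,
                               by_ = binned$bins$by[tm@j + 1L] %/% factor,
                               count = tm@x)
  gem <- dt[, .(MIDCount = sum(count)),
            by = .(geneID = gene, x = bx, y = by_)]
  out <- bin_counts(gem, 1L, nm_per_unit)
  out$bin_size_native <- binned$bin_size_native * factor
  out$bin_size_um <- out$bin_size_native * nm_per_unit / 1000
  out$level <- bin_level(out$bin_size_native)
  out
}

#' Remove bins with too few detected genes
#'
#' A bin is kept iff its number of detected (nonzero-count) genes is at
#' least the threshold for the bin level. Counts of surviving bins are
#' untouched.
#'
#' @param binned A `nova_binned`.
#' @param thresholds Named vector as [qc_thresholds()]; used when the bin
#'   level is one of bin50/bin100/bin200.
#' @param min_genes Explicit threshold overriding the level lookup;
#'   required for non-standard bin sizes.
#' @return The filtered `nova_binned`, with a `qc` element listing kept and
#'   removed bin counts.
#' @export
qc_filter <- function(binned, thresholds = qc_thresholds(),
                      min_genes = NULL) {
  if (is.null(min_genes)) {
    if (is.na(binned$level))
      stop("unknown bin level for size ", binned$bin_size_native,
           "; supply min_genes explicitly")
    min_genes <- thresholds[[binned$level]]
  }
  genes_per_bin <- Matrix::colSums(binned$counts > 0)
  keep <- genes_per_bin >= min_genes
  if (!any(keep))
    warning("all ", length(keep), " bins fall below ", min_genes,
            " detected genes")
  out <- binned
  out$counts <- binned$counts[, keep, drop = FALSE]
  out$bins <- binned$bins[keep]
  out$qc <- list(min_genes = min_genes, kept = sum(keep),
                 removed = sum(!keep),
                 removed_bins = binned$bins$bin[!keep])
  out
}

#' Normalise bins to a fixed total and log-transform
#'
#' Each bin's counts are scaled to a total of `target` (default 10000) and
#' natural-log transformed (`log1p`). Bins with zero total are left at zero
#' and counted.
#'
#' @param binned A `nova_binned`.
#' @param target Per-bin total after scaling.
#' @return The `nova_binned` with an extra sparse matrix `norm` and a
#'   `zero_bins` count.
#' @export
normalize_log <- function(binned, target = 10000) {
  totals <- Matrix::colSums(binned$counts)
  zero <- totals == 0
  scale <- ifelse(zero, 0, target / totals)
  norm <- binned$counts %*% Matrix::Diagonal(x = scale)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(binned$counts)
  out <- binned
  out$norm <- norm
  out$zero_bins <- sum(zero)
  out
}

#' Per-bin summary statistics
#'
#' Median detected genes and median total molecule count per bin, plus the
#' per-bin mitochondrial-count percentage (genes prefixed `mt-`/`MT-`),
#' which is reported but never used for filtering.
#'
#' @param binned A `nova_binned`.
#' @return List: `n_bins`, `median_genes`, `median_umis`, `per_bin`
#'   (`data.table` bin, genes, umis, pct_mito).
#' @export
summarize_bins <- function(binned) {
  if (ncol(binned$counts) == 0L)
    return(list(n_bins = 0L, median_genes = NA_real_,
                median_umis = NA_real_,
                per_bin = data.table::data.table()))
  genes <- Matrix::colSums(binned$counts > 0)
  umis <- Matrix::colSums(binned$counts)
  mito <- grepl("^mt-", rownames(binned$counts), ignore.case = TRUE)
  mito_counts <- if (any(mito))
    Matrix::colSums(binned$counts[mito, , drop = FALSE]) else 0
  per_bin <- data.table::data.table(bin = binned$bins$bin,
                                    genes = as.numeric(genes),
                                    umis = as.numeric(umis),
                                    pct_mito = ifelse(umis > 0,
                                                      100 * mito_counts / umis,
                                                      0))
  list(n_bins = ncol(binned$counts),
       median_genes = stats::median(per_bin$genes),
       median_umis = stats::median(per_bin$umis),
       per_bin = per_bin)
}

#' Export a binned matrix as Matrix Market triplets
#'
#' Writes `<prefix>.mtx` (genes x bins), `<prefix>_features.tsv`,
#' `<prefix>_bins.tsv` (bin key and bin-grid coordinates).
#'
#' @param binned A `nova_binned`.
#' @param prefix Output path prefix.
#' @return The `.mtx` path, invisibly.
#' @export
write_binned <- function(binned, prefix) {
  mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(binned$counts, mtx)
  writeLines(rownames(binned$counts), paste0(prefix, "_features.tsv"))
  data.table::fwrite(binned$bins, paste0(prefix, "_bins.tsv"), sep = "\t")
  invisible(mtx)
}
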