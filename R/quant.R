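#' Identify tissue-covered tiles from spatial barcode reads
#'
#' Extracts barcodes from the first `n_reads` R1 reads of the spatial
#' library and counts, per tile, how many distinct barcodes of that tile's
#' identification subset occur among them (exact 32-mer comparison). Tiles
#' with at least `min_hits` distinct hits are selected.
#'
#' @param r1 Path to the spatial library R1 FASTQ, or a character vector of
#'   R1 sequences.
#' @param subsets Named list (by tile id) of character vectors: each tile's
#'   subset barcodes, or a list of `nova_tile_index`.
#' @param n_reads Number of leading reads to use (default 1e6).
#' @param min_hits Minimum distinct subset barcodes matched (default 10).
#' @return Integer vector of selected tile ids; per-tile hit counts in
#'   attribute `"hits"`.
#' @export
identify_tiles <- function(r1, subsets, n_reads = 1000000L, min_hits = 10L) {
  seqs <- if (length(r1) == 1L && file.exists(r1))
    as.character(Biostrings::readDNAStringSet(r1, format = "fastq"))
  else as.character(r1)
  if (length(seqs) == 0L) stop("no spatial reads supplied for tile identification")
  seqs <- seqs[seq_len(min(n_reads, length(seqs)))]
  bc <- substr(seqs, 1L, 32L)
  hits <- vapply(subsets, function(s) {
    sub <- if (inherits(s, "nova_tile_index")) s$subset$barcode else s
    sum(sub %in% bc)
  }, numeric(1))
  sel <- as.integer(names(hits))[hits >= min_hits]
  if (!length(sel))
    stop("no tile reached ", min_hits, " subset hits; top counts: ",
         paste(utils::head(sort(hits, decreasing = TRUE), 5), collapse = ", "))
  structure(sel, hits = hits)
}

#' Build a 31-nt barcode whitelist from selected tiles
#'
#' Barcodes of the selected tiles are trimmed to 31 bases (enabling
#' single-mismatch error correction downstream). Barcodes that collide
#' after trimming are dropped symmetrically and counted.
#'
#' @param global A `nova_global_index` (barcode, x_nm, y_nm, tile_id).
#' @param tiles Integer tile ids covered by the tissue section.
#' @return An object of class `nova_whitelist`: `entries` (`data.table`
#'   barcode (31-nt), x_nm, y_nm, tile_id), `collisions` (count of dropped
#'   records), `tiles`.
#' @export
build_whitelist <- function(global, tiles) {
  if (!length(tiles)) stop("no tiles selected; whitelist would be empty")
  gi <- data.table::as.data.table(global)[tile_id %in% tiles]
  if (nrow(gi) == 0L) stop("selected tiles contribute no barcodes")
  gi[, barcode := substr(barcode, 1L, 31L)]
  dup <- gi$barcode %in% gi$barcode[duplicated(gi$barcode)]
  entries <- gi[!dup]
  if (nrow(entries) == 0L) stop("whitelist empty after collision removal")
  structure(list(entries = entries, collisions = sum(dup),
                 tiles = as.integer(tiles)),
            class = "nova_whitelist")
}

#' @export
print.nova_whitelist <- function(x, ...) {
  cat(sprintf("nova_whitelist: %d barcodes from %d tiles (%d trim-collision records dropped)\n",
              nrow(x$entries), length(x$tiles), x$collisions))
  invisible(x)
}

#' Match barcode reads against a whitelist with <= 1 mismatch
#'
#' Exact matches win. A read with no exact match is assigned to a whitelist
#' entry if exactly one entry lies at Hamming distance 1; zero or two or
#' more candidates leave the read unassigned (conservative, deterministic).
#'
#' @param queries Character vector of 31-nt cell/spatial barcodes.
#' @param whitelist A `nova_whitelist` or character vector of 31-nt entries.
#' @return Integer vector: index into the whitelist (NA when unassigned),
#'   with attribute `"reason"` (factor: exact / corrected / none /
#'   ambiguous).
#' @export
match_barcodes <- function(queries, whitelist) {
  wl <- if (inherits(whitelist, "nova_whitelist")) whitelist$entries$barcode
        else as.character(whitelist)
  if (!length(wl)) stop("empty whitelist")
  width <- nchar(wl[1])
  idx <- match(queries, wl)
  reason <- ifelse(is.na(idx), "none", "exact")
  todo <- which(is.na(idx) & nchar(queries) == width)
  if (length(todo)) {
    q <- queries[todo]
    hit_idx <- rep(NA_integer_, length(q))
    hit_n <- integer(length(q))
    for (p in seq_len(width)) {
      orig <- substr(q, p, p)
      for (b in c("A", "C", "G", "T")) {
        variant_of <- which(orig != b)
        if (!length(variant_of)) next
        v <- q[variant_of]
        substr(v, p, p) <- b
        m <- match(v, wl)
        found <- which(!is.na(m))
        if (!length(found)) next
        rows <- variant_of[found]
        hit_n[rows] <- hit_n[rows] + 1L
        first <- is.na(hit_idx[rows])
        hit_idx[rows[first]] <- m[found][first]
      }
    }
    assign <- hit_n == 1L
    idx[todo[assign]] <- hit_idx[assign]
    reason[todo[assign]] <- "corrected"
    reason[todo[hit_n >= 2L]] <- "ambiguous"
  }
  structure(idx, reason = factor(reason,
                                 levels = c("exact", "corrected",
                                            "ambiguous", "none")))
}

#' Match a single barcode (scalar convenience)
#'
#' @inheritParams match_barcodes
#' @param cb One barcode string.
#' @return Whitelist index or `NA`, with `"reason"` attribute.
#' @export
match_barcode <- function(cb, whitelist) {
  r <- match_barcodes(cb, whitelist)
  structure(r[1], reason = attr(r, "reason")[1])
}

# --- UMI deduplication ------------------------------------------------------

# encode 8-mers over ACGT as base-4 integers (0..65535)
encode_umi8 <- function(umis) {
  codes <- .BASE_CODE[as.integer(charToRaw(paste(substr(umis, 1L, 8L),
                                                 collapse = ""))) + 1L]
  if (anyNA(codes)) stop("UMIs contain non-ACGT bases")
  m <- matrix(codes, nrow = 8L)
  as.integer(colSums(m * 4L^(0:7)))
}

# connected components under Hamming-1 adjacency for coded 8-mers grouped by
# gid; returns data.table(gid, n_molecules)
umi_components <- function(gid, code) {
  dt <- unique(data.table::data.table(gid = gid, code = code))
  n <- nrow(dt)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- dt$gid * 65536 + dt$code
  pos <- seq_len(n)
  for (p in 0:7) {
    d <- (dt$code %/% 4L^p) %% 4L
    for (b in 0:3) {
      rows <- which(d != b)
      if (!length(rows)) next
      cand <- key[rows] + (b - d[rows]) * 4^p
      m <- match(cand, key)
      for (h in which(!is.na(m))) {
        ra <- find(rows[h]); rb <- find(m[h])
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  root <- vapply(pos, find, integer(1))
  dt[, comp := root]
  dt[, .(n_molecules = data.table::uniqueN(comp)), by = gid]
}

#' Count molecules from UMIs by single-mismatch merging
#'
#' UMIs (first 8 bases used) connected by Hamming-distance-1 edges are
#' merged into one molecule; the molecule count is the number of connected
#' components of that graph.
#'
#' @param umis Character vector of UMIs observed for one (barcode, gene)
#'   pair (>= 8 nt; bases beyond 8 ignored).
#' @return Integer molecule count.
#' @examples
#' dedup_umis(c("AAAAAAAA", "AAAAAAAT", "CCCCCCCC"))
#' @export
dedup_umis <- function(umis) {
  if (!length(umis)) return(0L)
  res <- umi_components(rep(1L, length(umis)), encode_umi8(umis))
  res$n_molecules[1]
}

#' Quantify a spatial library against a whitelist
#'
#' The internal quantification path: for every read pair, the first 31 nt
#' of R1 form the spatial barcode (matched with <= 1 mismatch against the
#' whitelist), the first 9 nt of R2 are the UMI (first 8 used for
#' deduplication) and the following bases identify the gene by lookup of
#' its synthetic transcript tag (unique single-mismatch tolerance, the same
#' conservative semantics as the barcode matcher). Molecules are counted
#' per (barcode, gene) by single-mismatch UMI merging.
#'
#' @param r1,r2 FASTQ paths (or equal-length character vectors of
#'   sequences).
#' @param whitelist A `nova_whitelist`.
#' @param gene_tags `data.table` with `gene_id` and `tag` columns.
#' @param umi_len UMI bases used for deduplication (default 8).
#' @param cb_len Barcode bases used (default 31).
#' @return List: `counts` (`data.table` barcode, gene_id, count),
#'   `stats` (named counts: total, assigned, unassigned_cb, ambiguous_cb,
#'   unassigned_gene).
#' @export
quantify <- function(r1, r2, whitelist, gene_tags, umi_len = 8L,
                     cb_len = 31L) {
  s1 <- if (length(r1) == 1L && file.exists(r1))
    as.character(Biostrings::readDNAStringSet(r1, format = "fastq"))
  else as.character(r1)
  s2 <- if (length(r2) == 1L && file.exists(r2))
    as.character(Biostrings::readDNAStringSet(r2, format = "fastq"))
  else as.character(r2)
  stopifnot(length(s1) == length(s2))
  tags <- data.table::as.data.table(gene_tags)
  tag_len <- nchar(tags$tag[1])

  cb <- substr(s1, 1L, cb_len)
  umi <- substr(s2, 1L, umi_len)
  payload <- substr(s2, 10L, 9L + tag_len)

  midx <- match_barcodes(cb, whitelist)
  reason <- attr(midx, "reason")
  gidx <- match_barcodes(payload, tags$tag)

  ok <- !is.na(midx) & !is.na(gidx)
  stats <- c(total = length(s1),
             assigned = sum(ok),
             unassigned_cb = sum(reason == "none"),
             ambiguous_cb = sum(reason == "ambiguous"),
             unassigned_gene = sum(!is.na(midx) & is.na(gidx)))

  if (!any(ok)) {
    counts <- data.table::data.table(barcode = character(0),
                                     gene_id = character(0),
                                     count = integer(0))
    return(list(counts = counts, stats = stats))
  }
  dt <- data.table::data.table(cb_idx = midx[ok], g_idx = gidx[ok],
                               code = encode_umi8(umi[ok]))
  dt[, gid := .GRP, by = .(cb_idx, g_idx)]
  groups <- unique(dt[, .(gid, cb_idx, g_idx)])
  mc <- umi_components(dt$gid, dt$code)
  groups <- merge(groups, mc, by = "gid")
  wl <- whitelist$entries
  counts <- data.table::data.table(barcode = wl$barcode[groups$cb_idx],
                                   gene_id = tags$gene_id[groups$g_idx],
                                   count = groups$n_molecules)
  list(counts = counts, stats = stats)
}

#' Import an externally produced sparse count matrix
#'
#' Reads a matrix-market triplet file with companion barcode and feature
#' lists (one entry per line, matching the matrix dimensions) and returns
#' per-(barcode, gene) counts, dropping and counting barcodes absent from
#' the supplied whitelist.
#'
#' @param mtx_path Matrix Market file (features x barcodes, as produced by
#'   common single-cell quantifiers).
#' @param barcodes_path,features_path One id per line.
#' @param whitelist Optional `nova_whitelist`; barcodes not present are
#'   excluded and counted.
#' @return List: `counts` (`data.table` barcode, gene_id, count),
#'   `dropped` (count of excluded barcode records).
#' @export
import_counts <- function(mtx_path, barcodes_path, features_path,
                          whitelist = NULL) {
  m <- Matrix::readMM(mtx_path)
  barcodes <- readLines(barcodes_path)
  features <- readLines(features_path)
  if (nrow(m) != length(features) || ncol(m) != length(barcodes))
    stop("matrix dimensions ", nrow(m), "x", ncol(m),
         " do not match feature/barcode lists (", length(features), ", ",
         length(barcodes), ")")
  tm <- methods::as(m, "TsparseMatrix")
  counts <- data.table::data.table(barcode = barcodes[tm@j + 1L],
                                   gene_id = features[tm@i + 1L],
                                   count = tm@x)
  counts <- counts[count > 0]
  dropped <- 0L
  if (!is.null(whitelist)) {
    keep <- counts$barcode %in% whitelist$entries$barcode
    dropped <- sum(!keep)
    counts <- counts[keep]
  }
  list(counts = counts, dropped = dropped)
}

#' Write counts and coordinates as a GEM file
#'
#' GEM is the tab-separated spatial count format (geneID, x, y, MIDCount)
#' of the Stereo-seq ecosystem. Coordinates are the barcode's global
#' position expressed in native grid units (`nm / nm_per_unit`, rounded);
#' records mapping to the same (gene, x, y) are summed.
#'
#' @param counts `data.table` with barcode, gene_id, count.
#' @param whitelist A `nova_whitelist` providing barcode coordinates.
#' @param calibration A [calibrate_scale()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gem <- function(counts, whitelist, calibration, path) {
  cts <- data.table::as.data.table(counts)
  wl <- whitelist$entries
  pos <- match(cts$barcode, wl$barcode)
  if (anyNA(pos))
    stop("barcodes without global coordinates: ",
         paste(utils::head(cts$barcode[is.na(pos)], 5), collapse = ", "))
  k <- calibration$nm_per_unit
  gem <- data.table::data.table(geneID = cts$gene_id,
                                x = as.integer(round(wl$x_nm[pos] / k)),
                                y = as.integer(round(wl$y_nm[pos] / k)),
                                MIDCount = as.integer(cts$count))
  gem <- gem[, .(MIDCount = sum(MIDCount)), by = .(geneID, x, y)]
  data.table::setorder(gem, geneID, x, y)
  writeLines(c("# novaST GEM",
               sprintf("# nm_per_unit=%.10g", k),
               sprintf("# generated=%s", format(Sys.time(), "%Y-%m-%d"))),
             path)
  data.table::fwrite(gem, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a GEM file
#'
#' @param path GEM file written by [write_gem()] (or any tab-separated
#'   geneID/x/y/MIDCount table with optional `#` header lines).
#' @return `data.table` with geneID, x, y, MIDCount.
#' @export
read_gem <- function(path) {
  gem <- data.table::fread(path, sep = "\t", skip = "geneID")
  stopifnot(all(c("geneID", "x", "y", "MIDCount") %in% names(gem)))
  gem
}
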