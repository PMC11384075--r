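#' Parse a sequencer read name
#'
#' Read names follow the standard colon-separated convention
#' `instrument:run:flowcell:lane:tile:x:y`, optionally followed by a
#' space-separated annotation. Fields 4-7 are returned as integers.
#'
#' @param name Read name (with or without leading `@`).
#' @return A list with integer elements `lane`, `tile`, `x`, `y`.
#' @examples
#' parse_read_name("@SIM:1:FC1:1:2101:15000:22000 1:N:0:ACGT")
#' @export
parse_read_name <- function(name) {
  head <- sub("\\s.*$", "", sub("^@", "", name))
  fields <- strsplit(head, ":", fixed = TRUE)[[1]]
  if (length(fields) < 7L)
    stop("malformed read name (need >= 7 colon-separated fields): ", name)
  vals <- suppressWarnings(as.integer(fields[4:7]))
  if (anyNA(vals))
    stop("malformed read name (non-integer lane/tile/x/y): ", name)
  list(lane = vals[1], tile = vals[2], x = vals[3], y = vals[4])
}

# vectorised read-name field extraction; returns data.table(lane,tile,x,y)
parse_read_names <- function(names) {
  head <- sub("\\s.*$", "", sub("^@", "", names))
  parts <- data.table::tstrsplit(head, ":", fixed = TRUE)
  if (length(parts) < 7L)
    stop("malformed read names: fewer than 7 colon-separated fields")
  out <- data.table::data.table(lane = as.integer(parts[[4]]),
                                tile = as.integer(parts[[5]]),
                                x = as.integer(parts[[6]]),
                                y = as.integer(parts[[7]]))
  if (anyNA(out))
    stop("malformed read names: non-integer lane/tile/x/y fields")
  out
}

#' Build a per-tile barcode index from FASTQ
#'
#' Reads one tile's spatial-barcode FASTQ, validates every 32-nt read
#' against the barcode design, and records the valid reads' barcodes and
#' local coordinates. The first `subset_size` valid reads are kept as the
#' tile-identification subset.
#'
#' @param fastq_path Path to the tile FASTQ (optionally gzipped).
#' @param pattern A [barcode_pattern()].
#' @param tile_id Expected tile id; taken from the first read name when `NULL`.
#' @param subset_size Number of valid reads reserved for tile identification
#'   (default 10000).
#' @return An object of class `nova_tile_index`: `tile_id`, `records`
#'   (`data.table` barcode/x/y), `subset` (same layout), and `stats`
#'   (total, valid, invalid counts).
#' @export
build_tile_index <- function(fastq_path, pattern = barcode_pattern(),
                             tile_id = NULL, subset_size = 10000L) {
  if (!file.exists(fastq_path)) stop("FASTQ not found: ", fastq_path)
  empty <- data.table::data.table(barcode = character(0),
                                  x = integer(0), y = integer(0))
  if (file.size(fastq_path) == 0L) {
    warning("empty FASTQ: ", fastq_path)
    return(new_tile_index(if (is.null(tile_id)) NA_integer_ else tile_id,
                          empty, empty, c(total = 0L, valid = 0L, invalid = 0L)))
  }
  reads <- Biostrings::readDNAStringSet(fastq_path, format = "fastq")
  seqs <- as.character(reads)
  info <- parse_read_names(names(reads))
  if (is.null(tile_id)) tile_id <- info$tile[1]
  ok <- validate_barcodes(seqs, pattern)
  records <- data.table::data.table(barcode = seqs[ok],
                                    x = info$x[ok], y = info$y[ok])
  subset <- records[seq_len(min(subset_size, nrow(records)))]
  new_tile_index(as.integer(tile_id), records, subset,
                 c(total = length(seqs), valid = sum(ok),
                   invalid = sum(!ok)))
}

new_tile_index <- function(tile_id, records, subset, stats) {
  structure(list(tile_id = tile_id, records = records,
                 subset = subset, stats = stats),
            class = "nova_tile_index")
}

#' @export
print.nova_tile_index <- function(x, ...) {
  cat(sprintf("nova_tile_index: tile %s, %d records (%d invalid reads dropped)\n",
              x$tile_id, nrow(x$records), x$stats[["invalid"]]))
  invisible(x)
}

# --- binary tile-index format ----------------------------------------------
# header: magic "NVST" (4 bytes), version u8, tile_id u32 LE, n_records u64 LE
# records: 16 bytes each: 2-bit packed barcode (8 bytes), x u32 LE, y u32 LE

.NVST_MAGIC <- charToRaw("NVST")
.NVST_VERSION <- 1L

#' Write a tile index to its binary on-disk format
#'
#' Fixed little-endian layout: a 17-byte header (magic `NVST`, version,
#' tile id, record count) followed by 16-byte records (2-bit packed 32-mer
#' barcode + two unsigned 32-bit coordinates). Round-trips losslessly with
#' [read_index()].
#'
#' @param index A `nova_tile_index` (or any object with `tile_id` and a
#'   `records` table of barcode/x/y).
#' @param path Output file path.
#' @param what Which record set to serialise: "records" or "subset".
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path, what = c("records", "subset")) {
  what <- match.arg(what)
  rec <- index[[what]]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.NVST_MAGIC, con)
  writeBin(as.raw(.NVST_VERSION), con)
  tid <- if (is.na(index$tile_id)) 0L else as.integer(index$tile_id)
  writeBin(tid, con, size = 4L, endian = "little")
  n <- nrow(rec)
  writeBin(as.integer(c(n %% 2^31, n %/% 2^31)), con, size = 4L,
           endian = "little")
  if (n > 0L) {
    packed <- matrix(pack_barcodes(rec$barcode), nrow = 8L)
    body <- raw(16L * n)
    dim(body) <- c(16L, n)
    body[1:8, ] <- packed
    xy <- writeBin(as.integer(rbind(rec$x, rec$y)), raw(),
                   size = 4L, endian = "little")
    dim(xy) <- c(8L, n)
    body[9:16, ] <- xy
    writeBin(as.vector(body), con)
  }
  invisible(path)
}

#' Read a binary tile index
#'
#' @param path File written by [write_index()].
#' @return A `nova_tile_index` (its `subset` is the first 10000 records and
#'   `stats` reflect only the stored records).
#' @export
read_index <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 17L) stop("index format error: file truncated: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, .NVST_MAGIC))
    stop("index format error: bad magic in ", path)
  version <- as.integer(readBin(con, "raw", 1L))
  if (version != .NVST_VERSION)
    stop("index format error: unsupported version ", version)
  tile_id <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  nparts <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  n <- nparts[1] + nparts[2] * 2^31
  if (sz != 17L + 16L * n)
    stop("index format error: expected ", 17 + 16 * n, " bytes, found ", sz)
  if (n == 0L) {
    rec <- data.table::data.table(barcode = character(0),
                                  x = integer(0), y = integer(0))
  } else {
    body <- readBin(con, "raw", 16L * n)
    dim(body) <- c(16L, n)
    barcode <- unpack_barcodes(as.vector(body[1:8, , drop = FALSE]))
    xy <- readBin(as.vector(body[9:16, , drop = FALSE]), "integer",
                  2L * n, size = 4L, endian = "little")
    rec <- data.table::data.table(barcode = barcode,
                                  x = xy[seq(1, 2 * n, 2)],
                                  y = xy[seq(2, 2 * n, 2)])
  }
  new_tile_index(tile_id, rec, rec[seq_len(min(10000L, nrow(rec)))],
                 c(total = nrow(rec), valid = nrow(rec), invalid = 0L))
}

#' Index every tile FASTQ in a directory
#'
#' Applies [build_tile_index()] to each `hdmi_tile_<id>.fastq[.gz]` file.
#'
#' @param fastq_dir Directory of per-tile FASTQ files.
#' @param pattern A [barcode_pattern()].
#' @param exclude_tiles Integer tile ids to skip (tiles noted as not
#'   sequenced).
#' @param subset_size Per-tile identification subset size.
#' @return Named list of `nova_tile_index`, keyed by tile id.
#' @export
index_fastq_dir <- function(fastq_dir, pattern = barcode_pattern(),
                            exclude_tiles = integer(0),
                            subset_size = 10000L) {
  files <- list.files(fastq_dir, pattern = "^hdmi_tile_\\d+\\.fastq(\\.gz)?$",
                      full.names = TRUE)
  if (!length(files)) stop("no tile FASTQ files found in ", fastq_dir)
  ids <- as.integer(sub("^hdmi_tile_(\\d+)\\.fastq(\\.gz)?$", "\\1",
                        basename(files)))
  keep <- !(ids %in% exclude_tiles)
  files <- files[keep]; ids <- ids[keep]
  out <- vector("list", length(files))
  names(out) <- as.character(ids)
  for (i in seq_along(files))
    out[[i]] <- build_tile_index(files[i], pattern, tile_id = ids[i],
                                 subset_size = subset_size)
  out[order(ids)]
}
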