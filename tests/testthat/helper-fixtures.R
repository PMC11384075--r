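# Shared fixtures built in code at test time.

# a compact chip: 2 swaths x 2 tile rows at the default tile geometry
small_sim_config <- function(seed = 7L, ...) {
  sim_config(n_swaths = 2L, tiles_per_swath = 2L, seed = seed, ...)
}

# write a FASTQ with given read names and sequences, return the path
fastq_fixture <- function(names, seqs, path = tempfile(fileext = ".fastq")) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names
  Biostrings::writeXStringSet(x, path, format = "fastq")
  path
}

# a valid barcode under the default template
valid_barcode <- function(degenerate = strrep("A", 20)) {
  paste0("CTCTTCCGATCT", degenerate)
}

# construct a nova_tile_index directly from records (bypasses FASTQ)
index_fixture <- function(barcode, x, y, tile_id = 1101L) {
  rec <- data.table::data.table(barcode = barcode,
                                x = as.integer(x), y = as.integer(y))
  structure(list(tile_id = tile_id, records = rec,
                 subset = rec[seq_len(min(10000L, nrow(rec)))],
                 stats = c(total = nrow(rec), valid = nrow(rec),
                           invalid = 0L)),
            class = "nova_tile_index")
}

# draw a binary image with fiducial voids (outer ring + inner disc) at the
# given centres (0-based pixel coordinates)
annulus_image <- function(nr, nc, centres, r_outer = 60, r_inner = 22,
                          ring_hw = 3) {
  bw <- matrix(0, nr, nc)
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), nc), nr, nc)
  for (k in seq_len(nrow(centres))) {
    d <- sqrt((xs - centres[k, 1])^2 + (ys - centres[k, 2])^2)
    bw[d <= r_inner | abs(d - r_outer) <= ring_hw] <- 255
  }
  bw
}

# simulated flow cell shared across tests in one file (cached per session)
.shared <- new.env()
shared_small_sim <- function() {
  if (is.null(.shared$sim)) {
    dir <- file.path(tempdir(), "novast-shared-sim")
    .shared$sim <- simulate_flowcell(small_sim_config(), dir)
  }
  .shared$sim
}
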