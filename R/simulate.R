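#' Simulated flow-cell configuration
#'
#' Describes a synthetic nano-patterned flow-cell surface: a grid of tiles
#' (swaths x tile rows), a hexagonal well lattice per tile, concentric-circle
#' fiducial voids, and the sequencing model for the spatial library.
#' All linear dimensions are in raw read-name coordinate units; one raw unit
#' corresponds to `nm_per_unit` nanometres (default 25000/728, so that a
#' 728-unit bin edge is 25 um).
#'
#' @param n_swaths Number of swaths (tile columns), 1-6.
#' @param tiles_per_swath Tile rows per swath.
#' @param tile_width,tile_height Tile dimensions in raw units.
#' @param well_pitch Centre-to-centre well spacing in raw units
#'   (default 18.2, i.e. 625 nm at the default scale).
#' @param unique_occupancy Probability that a well carries a unique usable
#'   barcode (default 0.80); the remainder are emitted as empty.
#' @param fiducials_per_tile Number of fiducial marks per tile (1, 2 or 4).
#' @param fiducial_outer_radius Radius of the outer fiducial ring, raw units.
#' @param fiducial_inner_radius Radius of the inner filled fiducial disc.
#' @param fiducial_ring_width Full width of the outer ring void, raw units.
#' @param barcode_pattern A [barcode_pattern()].
#' @param n_genes Number of synthetic genes; each gets a unique random tag.
#' @param gene_tag_length Length of the gene-identifying transcript tag (nt).
#' @param tissue_mask Rectangle `c(xmin, xmax, ymin, ymax)` in global raw
#'   units restricting which wells emit molecules; `NULL` = whole chip.
#' @param molecules_per_well Mean molecules captured per well in tissue
#'   (Poisson).
#' @param reads_per_molecule Mean sequenced reads per molecule (geometric,
#'   support >= 1).
#' @param error_rate Per-base substitution probability applied to the
#'   spatial library reads (R1 and R2).
#' @param hdmi_error_rate Per-base substitution probability applied to the
#'   spatial-barcode (array definition) reads; default 0, since the array
#'   sequencing pass is treated as the ground truth of the chip.
#' @param tile_jitter Maximum absolute per-tile read-frame offset (uniform
#'   integer in `[-tile_jitter, tile_jitter]`, raw units) modelling the
#'   sequencer's per-tile coordinate origin error.
#' @param nm_per_unit Physical size of one raw unit in nm.
#' @param swath_offset_axis Axis ("y" or "x") along which even swaths are
#'   shifted by one tile relative to odd swaths.
#' @param seed Integer seed; a fixed seed yields byte-identical outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_swaths = 6L,
                       tiles_per_swath = 6L,
                       tile_width = 5000,
                       tile_height = 5000,
                       well_pitch = 18.2,
                       unique_occupancy = 0.80,
                       fiducials_per_tile = 4L,
                       fiducial_outer_radius = 1100,
                       fiducial_inner_radius = 550,
                       fiducial_ring_width = 150,
                       barcode_pattern = novaST::barcode_pattern(),
                       n_genes = 600L,
                       gene_tag_length = 40L,
                       tissue_mask = NULL,
                       molecules_per_well = 1,
                       reads_per_molecule = 3,
                       error_rate = 0,
                       hdmi_error_rate = 0,
                       tile_jitter = 10,
                       nm_per_unit = 25000 / 728,
                       swath_offset_axis = "y",
                       seed = 1L) {
  stopifnot(n_swaths >= 1L, n_swaths <= 6L, tiles_per_swath >= 1L,
            tile_width > 0, tile_height > 0, well_pitch > 0,
            unique_occupancy >= 0, unique_occupancy <= 1,
            fiducials_per_tile %in% c(0L, 1L, 2L, 4L),
            fiducial_inner_radius < fiducial_outer_radius,
            fiducial_ring_width > 0,
            n_genes >= 1L, gene_tag_length >= 10L,
            molecules_per_well >= 0, reads_per_molecule >= 1,
            error_rate >= 0, error_rate < 1,
            hdmi_error_rate >= 0, hdmi_error_rate < 1, tile_jitter >= 0,
            nm_per_unit > 0, swath_offset_axis %in% c("x", "y"))
  if (fiducials_per_tile > 0L &&
      (2 * fiducial_outer_radius + fiducial_ring_width >
         min(tile_width, tile_height) / 2))
    stop("config error: fiducial larger than tile quadrant")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d swaths x %d tiles, tile %gx%g units, pitch %g, occupancy %.2f, seed %d\n",
              x$n_swaths, x$tiles_per_swath, x$tile_width, x$tile_height,
              x$well_pitch, x$unique_occupancy, x$seed))
  invisible(x)
}

#' Hexagonal lattice sites within a rectangle
#'
#' Row k (0-based) sits at `y = margin + k * pitch * sqrt(3)/2`; columns at
#' `x = margin + j * pitch`, shifted by `pitch/2` on odd rows. Sites with
#' both coordinates in `[margin, width - margin]` x `[margin, height -
#' margin]` (inclusive) are returned.
#'
#' @param width,height Rectangle dimensions.
#' @param pitch Lattice pitch.
#' @param margin Inset from every edge.
#' @return A `data.table` with real-valued columns `x`, `y`.
#' @export
hex_lattice <- function(width, height, pitch, margin = 0) {
  dy <- pitch * sqrt(3) / 2
  rows <- 0:floor((height - 2 * margin) / dy)
  out <- vector("list", length(rows))
  for (k in rows) {
    y <- margin + k * dy
    x0 <- margin + (k %% 2) * pitch / 2
    xs <- seq(x0, width - margin, by = pitch)
    if (length(xs)) out[[k + 1L]] <- data.table::data.table(x = xs, y = y)
  }
  data.table::rbindlist(out)
}

# tile_id as a 4-digit integer: surface, swath, 2-digit row
make_tile_id <- function(surface, swath, row) {
  as.integer(surface * 1000L + swath * 100L + row)
}

# decompose a 4-digit tile id
split_tile_id <- function(tile_id) {
  list(surface = tile_id %/% 1000L,
       swath = (tile_id %/% 100L) %% 10L,
       row = tile_id %% 100L)
}

# nominal global raw-unit origin of a tile (even swaths shifted one tile)
tile_origin <- function(swath, row, config) {
  shift <- as.numeric(swath %% 2L == 0L)
  if (config$swath_offset_axis == "y")
    c((swath - 1L) * config$tile_width,
      (row - 1L + shift) * config$tile_height)
  else
    c((swath - 1L + shift) * config$tile_width,
      (row - 1L) * config$tile_height)
}

# intra-tile fiducial centre positions (local raw units)
fiducial_centres <- function(config) {
  w <- config$tile_width; h <- config$tile_height
  frac <- switch(as.character(config$fiducials_per_tile),
    "0" = matrix(numeric(0), ncol = 2),
    "1" = matrix(c(0.5, 0.5), ncol = 2, byrow = TRUE),
    "2" = matrix(c(0.25, 0.5, 0.75, 0.5), ncol = 2, byrow = TRUE),
    "4" = matrix(c(0.25, 0.25, 0.75, 0.25, 0.25, 0.75, 0.75, 0.75),
                 ncol = 2, byrow = TRUE))
  data.table::data.table(fx = frac[, 1] * w, fy = frac[, 2] * h)
}

# TRUE for points inside any fiducial void (inner disc or outer ring)
in_fiducial_void <- function(x, y, centres, config) {
  void <- rep(FALSE, length(x))
  hw <- config$fiducial_ring_width / 2
  for (i in seq_len(nrow(centres))) {
    d <- sqrt((x - centres$fx[i])^2 + (y - centres$fy[i])^2)
    void <- void | d <= config$fiducial_inner_radius |
      abs(d - config$fiducial_outer_radius) <= hw
  }
  void
}

# apply per-base substitution errors to a character vector of reads
apply_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  len <- nchar(seqs[1])
  n <- length(seqs)
  total <- n * len
  n_err <- stats::rbinom(1L, total, error_rate)
  if (n_err == 0L) return(seqs)
  pos <- sample.int(total, n_err)
  ridx <- (pos - 1L) %/% len + 1L
  bpos <- (pos - 1L) %% len + 1L
  shift <- sample.int(3L, n_err, replace = TRUE)  # substitution offset 1..3
  affected <- unique(ridx)
  ord <- order(ridx)
  ridx <- ridx[ord]; bpos <- bpos[ord]; shift <- shift[ord]
  split_b <- split(bpos, ridx)
  split_s <- split(shift, ridx)
  chars <- strsplit(seqs[affected], "")
  for (i in seq_along(affected)) {
    v <- chars[[i]]
    p <- split_b[[i]]; s <- split_s[[i]]
    code <- .BASE_CODE[as.integer(charToRaw(paste(v[p], collapse = ""))) + 1L]
    v[p] <- .CODE_BASE[(code + s) %% 4L + 1L]
    chars[[i]] <- v
  }
  seqs[affected] <- vapply(chars, paste, character(1), collapse = "")
  seqs
}

# write a FASTQ file (constant quality "I") via Biostrings
write_fastq <- function(names, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Simulate a barcoded flow cell
#'
#' Lays a hexagonal well lattice over every tile, assigns unique
#' pattern-conformant barcodes to wells with probability `unique_occupancy`
#' (non-unique wells are emitted as empty), carves fiducial voids, applies a
#' per-tile read-frame jitter, and writes one spatial-barcode FASTQ per tile
#' (32-nt reads; tile/x/y encoded in read names). Ground truth for every
#' emitted well is returned and written as a TSV sidecar.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory; created if missing.
#' @return An object of class `nova_sim` with elements `config`, `fastq_dir`,
#'   `files` (per-tile FASTQ paths), `wells` (ground-truth `data.table`:
#'   tile_id, swath, row, x, y local read-frame coords, gx, gy global raw
#'   units, gx_nm, gy_nm, barcode), `tiles` (tile table with origins and
#'   jitter), `fiducials` (true centre positions per tile, local raw units),
#'   and `gene_tags` (gene_id, tag).
#' @export
simulate_flowcell <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  margin <- max(config$well_pitch, config$tile_jitter + 1)
  lattice <- hex_lattice(config$tile_width, config$tile_height,
                         config$well_pitch, margin = margin)
  lattice[, `:=`(px = as.integer(round(x)), py = as.integer(round(y)))]
  centres <- fiducial_centres(config)
  keep_lattice <- !in_fiducial_void(lattice$px, lattice$py, centres, config)
  lattice <- lattice[keep_lattice]

  tiles <- data.table::CJ(swath = seq_len(config$n_swaths),
                          row = seq_len(config$tiles_per_swath))
  tiles[, tile_id := make_tile_id(1L, swath, row)]
  org <- t(mapply(function(s, r) tile_origin(s, r, config),
                  tiles$swath, tiles$row))
  tiles[, `:=`(origin_x = org[, 1], origin_y = org[, 2])]
  jmax <- config$tile_jitter
  tiles[, `:=`(jitter_x = if (jmax > 0) sample(-jmax:jmax, .N, TRUE) else rep(0L, .N),
               jitter_y = if (jmax > 0) sample(-jmax:jmax, .N, TRUE) else rep(0L, .N))]

  wells_list <- vector("list", nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    occ <- stats::runif(nrow(lattice)) < config$unique_occupancy
    if (!any(occ)) {
      wells_list[[i]] <- data.table::data.table()
      next
    }
    w <- lattice[occ, .(px, py)]
    w[, `:=`(tile_id = tiles$tile_id[i], swath = tiles$swath[i],
             row = tiles$row[i],
             x = px + tiles$jitter_x[i],          # read-frame local coords
             y = py + tiles$jitter_y[i],
             gx = px + tiles$origin_x[i],          # true global raw units
             gy = py + tiles$origin_y[i])]
    wells_list[[i]] <- w
  }
  wells <- data.table::rbindlist(wells_list)
  if (nrow(wells)) {
    wells[, barcode := draw_unique_barcodes(.N, config$barcode_pattern)]
    wells[, `:=`(gx_nm = gx * config$nm_per_unit,
                 gy_nm = gy * config$nm_per_unit)]
  } else {
    wells <- data.table::data.table(
      px = integer(0), py = integer(0), tile_id = integer(0),
      swath = integer(0), row = integer(0), x = integer(0), y = integer(0),
      gx = numeric(0), gy = numeric(0), barcode = character(0),
      gx_nm = numeric(0), gy_nm = numeric(0))
  }

  gene_tags <- draw_gene_tags(config)

  files <- character(nrow(tiles))
  names(files) <- as.character(tiles$tile_id)
  for (i in seq_len(nrow(tiles))) {
    tid <- tiles$tile_id[i]
    tw <- wells[tile_id == tid]
    path <- file.path(out_dir, sprintf("hdmi_tile_%d.fastq", tid))
    if (nrow(tw)) {
      ord <- sample.int(nrow(tw))   # cluster output order is not spatial
      tw <- tw[ord]
      nm <- sprintf("SIM:1:FC1:1:%d:%d:%d 1:N:0:1", tid, tw$x, tw$y)
      seqs <- apply_substitutions(tw$barcode, config$hdmi_error_rate)
      write_fastq(nm, seqs, path)
    } else {
      file.create(path)
    }
    files[i] <- path
  }

  sim <- structure(list(config = config, fastq_dir = out_dir, files = files,
                        wells = wells, tiles = tiles,
                        fiducials = centres, gene_tags = gene_tags),
                   class = "nova_sim")
  write_sim_truth(sim, out_dir)
  sim
}

# unique barcodes at the trimmed 31-mer level (guarantees downstream
# identifiability; see methods vignette)
draw_unique_barcodes <- function(n, pattern) {
  bc <- sample_barcodes(n, pattern)
  repeat {
    dup <- duplicated(substr(bc, 1L, 31L))
    if (!any(dup)) break
    bc[dup] <- sample_barcodes(sum(dup), pattern)
  }
  bc
}

# unique random gene tags named gene_0001 ...
draw_gene_tags <- function(config) {
  n <- config$n_genes; len <- config$gene_tag_length
  repeat {
    tags <- apply_paste_columns(matrix(sample(c("A", "C", "G", "T"),
                                              n * len, replace = TRUE),
                                       nrow = len))
    if (!anyDuplicated(tags)) break
  }
  data.table::data.table(gene_id = sprintf("gene_%04d", seq_len(n)), tag = tags)
}

# truth sidecars: wells TSV, tiles TSV, gene tags TSV
write_sim_truth <- function(sim, out_dir) {
  wpath <- file.path(out_dir, "truth_wells.tsv")
  hdr <- c("# novaST simulator ground truth: one row per emitted well",
           "# columns: tile_id swath row x y gx gy gx_nm gy_nm barcode")
  writeLines(hdr, wpath)
  if (nrow(sim$wells))
    data.table::fwrite(sim$wells[, .(tile_id, swath, row, x, y, gx, gy,
                                     gx_nm, gy_nm, barcode)],
                       wpath, sep = "\t", append = TRUE, col.names = TRUE)
  data.table::fwrite(sim$tiles, file.path(out_dir, "truth_tiles.tsv"), sep = "\t")
  data.table::fwrite(sim$gene_tags, file.path(out_dir, "gene_tags.tsv"), sep = "\t")
  invisible(out_dir)
}

#' Simulate a spatial expression library
#'
#' Samples molecules from wells whose true global position lies inside the
#' configured tissue mask, assigns each molecule a gene and a UMI, duplicates
#' it into reads (geometric, mean `reads_per_molecule`), applies sequencing
#' errors, and writes a paired FASTQ (R1 = 34 nt barcode read, R2 = 91 nt:
#' 9-nt UMI + gene tag + poly-A filler).
#'
#' UMIs of molecules sharing a (barcode, gene) pair are kept at Hamming
#' distance >= 2 on their first 8 bases so that ground-truth molecule
#' identity is well defined under single-mismatch UMI merging.
#'
#' @param sim A `nova_sim` from [simulate_flowcell()].
#' @param out_dir Output directory for the FASTQ pair and truth sidecar.
#' @return An object of class `nova_spatial` with `r1`, `r2` (paths),
#'   `molecules` (truth `data.table`: molecule_id, barcode, gene_id, tile_id,
#'   gx, gy, gx_nm, gy_nm, umi, n_reads) and `reads` (read-level truth).
#' @export
simulate_spatial_reads <- function(sim, out_dir) {
  stopifnot(inherits(sim, "nova_sim"))
  config <- sim$config
  set.seed(config$seed + 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  mask <- config$tissue_mask
  wells <- sim$wells
  if (is.null(mask)) {
    tw <- wells
  } else {
    tw <- wells[gx >= mask[1] & gx <= mask[2] & gy >= mask[3] & gy <= mask[4]]
  }
  r1_path <- file.path(out_dir, "spatial_R1.fastq")
  r2_path <- file.path(out_dir, "spatial_R2.fastq")
  if (nrow(tw) == 0L) {
    warning("tissue mask covers no wells; writing empty spatial library")
    file.create(r1_path); file.create(r2_path)
    empty <- data.table::data.table()
    return(structure(list(r1 = r1_path, r2 = r2_path, molecules = empty,
                          reads = empty, sim = sim), class = "nova_spatial"))
  }

  nmol_per_well <- stats::rpois(nrow(tw), config$molecules_per_well)
  widx <- rep(seq_len(nrow(tw)), nmol_per_well)
  n_mol <- length(widx)
  if (n_mol == 0L) {
    warning("no molecules sampled from tissue wells")
    file.create(r1_path); file.create(r2_path)
    empty <- data.table::data.table()
    return(structure(list(r1 = r1_path, r2 = r2_path, molecules = empty,
                          reads = empty, sim = sim), class = "nova_spatial"))
  }
  mol <- tw[widx, .(barcode, tile_id, gx, gy, gx_nm, gy_nm)]
  mol[, molecule_id := seq_len(.N)]
  mol[, gene_id := sim$gene_tags$gene_id[sample.int(config$n_genes, .N, replace = TRUE)]]
  mol[, umi := draw_group_safe_umis(barcode, gene_id)]
  # reads per molecule: geometric with support >= 1, mean reads_per_molecule
  p <- 1 / config$reads_per_molecule
  mol[, n_reads := stats::rgeom(.N, p) + 1L]

  ridx <- rep(seq_len(n_mol), mol$n_reads)
  tagmap <- sim$gene_tags$tag[match(mol$gene_id, sim$gene_tags$gene_id)]
  filler <- strrep("A", 91L - 9L - config$gene_tag_length)
  r1 <- paste0(mol$barcode[ridx], "TT")
  r2 <- paste0(mol$umi[ridx], tagmap[ridx], filler)
  r1 <- apply_substitutions(r1, config$error_rate)
  r2 <- apply_substitutions(r2, config$error_rate)

  ord <- sample.int(length(r1))                  # shuffle read order
  ridx <- ridx[ord]; r1 <- r1[ord]; r2 <- r2[ord]
  rname <- sprintf("SPAT:1:LIB1:1:1:1:%d", seq_along(r1))
  write_fastq(paste(rname, "1:N:0:1"), r1, r1_path)
  write_fastq(paste(rname, "2:N:0:1"), r2, r2_path)

  reads <- data.table::data.table(read = rname, molecule_id = mol$molecule_id[ridx])
  mpath <- file.path(out_dir, "truth_molecules.tsv")
  writeLines(c("# novaST simulator ground truth: one row per molecule"), mpath)
  data.table::fwrite(mol, mpath, sep = "\t", append = TRUE, col.names = TRUE)

  structure(list(r1 = r1_path, r2 = r2_path, molecules = mol,
                 reads = reads, sim = sim), class = "nova_spatial")
}

# draw 9-nt UMIs such that within each (barcode, gene) group the first
# 8 bases are pairwise at Hamming distance >= 2
draw_group_safe_umis <- function(barcode, gene_id) {
  n <- length(barcode)
  umi <- apply_paste_columns(matrix(sample(c("A", "C", "G", "T"), n * 9L,
                                           replace = TRUE), nrow = 9L))
  grp <- paste(barcode, gene_id)
  repeat {
    bad <- umi_group_conflicts(umi, grp)
    if (!any(bad)) break
    umi[bad] <- apply_paste_columns(matrix(sample(c("A", "C", "G", "T"),
                                                  sum(bad) * 9L, replace = TRUE),
                                           nrow = 9L))
  }
  umi
}

# flag molecules whose 8-nt UMI prefix is within Hamming 1 of an earlier
# molecule in the same group
umi_group_conflicts <- function(umi, grp) {
  bad <- rep(FALSE, length(umi))
  dup_groups <- unique(grp[duplicated(grp)])
  if (!length(dup_groups)) return(bad)
  for (g in dup_groups) {
    idx <- which(grp == g)
    u <- substr(umi[idx], 1L, 8L)
    for (j in seq_along(idx)[-1]) {
      for (k in seq_len(j - 1L)) {
        if (hamming(u[j], u[k]) <= 1L) { bad[idx[j]] <- TRUE; break }
      }
    }
  }
  bad
}
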