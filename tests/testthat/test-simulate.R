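test_that("flow-cell simulation emits one read per occupied lattice site", {
  # full occupancy, no fiducials, no jitter: record count equals the
  # independently enumerated lattice-site count
  cfg <- sim_config(n_swaths = 1L, tiles_per_swath = 1L,
                    tile_width = 100, tile_height = 100, well_pitch = 10,
                    unique_occupancy = 1, fiducials_per_tile = 0L,
                    tile_jitter = 0, seed = 1L)
  sim <- simulate_flowcell(cfg, file.path(tempdir(), "sim-full"))
  margin <- max(cfg$well_pitch, cfg$tile_jitter + 1)
  expected <- bf_lattice_count(100, 100, 10, margin)
  expect_gt(expected, 0)
  expect_identical(nrow(sim$wells), expected)
  reads <- Biostrings::readDNAStringSet(sim$files[[1]], format = "fastq")
  expect_identical(length(reads), expected)
})

test_that("zero occupancy emits no records", {
  cfg <- sim_config(n_swaths = 1L, tiles_per_swath = 1L,
                    tile_width = 200, tile_height = 200, well_pitch = 10,
                    unique_occupancy = 0, fiducials_per_tile = 0L, seed = 1L)
  sim <- simulate_flowcell(cfg, file.path(tempdir(), "sim-empty"))
  expect_identical(nrow(sim$wells), 0L)
  expect_identical(file.size(sim$files[[1]]), 0)
})

test_that("occupied fraction matches the configured 80% within binomial error", {
  cfg <- sim_config(n_swaths = 1L, tiles_per_swath = 1L,
                    tile_width = 1200, tile_height = 1200, well_pitch = 12,
                    unique_occupancy = 0.8, fiducials_per_tile = 0L,
                    tile_jitter = 0, seed = 21L)
  sim <- simulate_flowcell(cfg, file.path(tempdir(), "sim-occ"))
  n_sites <- bf_lattice_count(1200, 1200, 12, 12)
  expect_gt(n_sites, 1e4)
  frac <- nrow(sim$wells) / n_sites
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / n_sites))
})

test_that("a fixed seed reproduces the simulation byte for byte", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  cfg <- sim_config(n_swaths = 1L, tiles_per_swath = 2L, seed = 99L,
                    tissue_mask = c(0, 5000, 0, 5000))
  s1 <- simulate_flowcell(cfg, d1)
  s2 <- simulate_flowcell(cfg, d2)
  for (f in basename(s1$files))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  r1 <- simulate_spatial_reads(s1, file.path(d1, "lib"))
  r2 <- simulate_spatial_reads(s2, file.path(d2, "lib"))
  expect_identical(unname(tools::md5sum(r1$r1)), unname(tools::md5sum(r2$r1)))
  expect_identical(unname(tools::md5sum(r1$r2)), unname(tools::md5sum(r2$r2)))
})

test_that("occupied wells carry collision-free barcodes", {
  sim <- shared_small_sim()
  expect_false(anyDuplicated(sim$wells$barcode) > 0)
  # unique even after the 31-base trim used downstream
  expect_false(anyDuplicated(substr(sim$wells$barcode, 1, 31)) > 0)
  expect_true(all(validate_barcodes(sim$wells$barcode)))
})

test_that("fiducial voids contain no wells", {
  sim <- shared_small_sim()
  cfg <- sim$config
  centres <- sim$fiducials
  for (i in seq_len(nrow(sim$tiles))) {
    t <- sim$tiles[i]
    w <- sim$wells[tile_id == t$tile_id]
    lx <- w$gx - t$origin_x    # physical local coordinates
    ly <- w$gy - t$origin_y
    for (k in seq_len(nrow(centres))) {
      d <- sqrt((lx - centres$fx[k])^2 + (ly - centres$fy[k])^2)
      expect_identical(sum(d <= cfg$fiducial_inner_radius), 0L)
      expect_identical(
        sum(abs(d - cfg$fiducial_outer_radius) <= cfg$fiducial_ring_width / 2),
        0L)
    }
  }
})

test_that("duplicate reads of one molecule share barcode and UMI", {
  cfg <- small_sim_config(seed = 13L, reads_per_molecule = 3)
  sim <- simulate_flowcell(cfg, file.path(tempdir(), "dup-fc"))
  sp <- simulate_spatial_reads(sim, file.path(tempdir(), "dup-lib"))
  r1 <- as.character(Biostrings::readDNAStringSet(sp$r1, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(sp$r2, format = "fastq"))
  expect_identical(length(r1), sum(sp$molecules$n_reads))
  expect_true(all(nchar(r1) == 34L))
  expect_true(all(nchar(r2) == 91L))
  # reads grouped by molecule id are identical at error rate 0
  dt <- data.table::data.table(mol = sp$reads$molecule_id, r1 = r1,
                               umi = substr(r2, 1, 9))
  per_mol <- dt[, .(n1 = data.table::uniqueN(r1),
                    nu = data.table::uniqueN(umi)), by = mol]
  expect_true(all(per_mol$n1 == 1L))
  expect_true(all(per_mol$nu == 1L))
})

test_that("tissue mask restricts reads to covered tiles", {
  # mask covering only swath 2 (x in [5000, 10000])
  cfg <- small_sim_config(seed = 17L, tissue_mask = c(5000, 10000, 0, 20000))
  sim <- simulate_flowcell(cfg, file.path(tempdir(), "mask-fc"))
  sp <- simulate_spatial_reads(sim, file.path(tempdir(), "mask-lib"))
  expect_setequal(unique(sp$molecules$tile_id), c(1201L, 1202L))
  # all read barcodes trace back to wells of those tiles
  src <- sim$wells[match(sp$molecules$barcode, barcode), tile_id]
  expect_true(all(src %in% c(1201L, 1202L)))
})

test_that("an empty tissue mask warns and writes empty output", {
  cfg <- small_sim_config(seed = 19L, tissue_mask = c(-100, -50, -100, -50))
  sim <- simulate_flowcell(cfg, file.path(tempdir(), "void-fc"))
  expect_warning(sp <- simulate_spatial_reads(sim, file.path(tempdir(), "void-lib")),
                 "no wells")
  expect_identical(nrow(sp$molecules), 0L)
  expect_identical(file.size(sp$r1), 0)
})

test_that("substitution count matches the binomial error model", {
  cfg <- sim_config(n_swaths = 1L, tiles_per_swath = 1L, seed = 23L,
                    error_rate = 0.01, reads_per_molecule = 1,
                    molecules_per_well = 0.12)
  sim <- simulate_flowcell(cfg, file.path(tempdir(), "err-fc"))
  sp <- simulate_spatial_reads(sim, file.path(tempdir(), "err-lib"))
  r1 <- as.character(Biostrings::readDNAStringSet(sp$r1, format = "fastq"))
  truth_r1 <- paste0(sp$molecules$barcode[match(sp$reads$molecule_id,
                                                sp$molecules$molecule_id)],
                     "TT")
  n_sub <- sum(vapply(seq_along(r1),
                      function(i) hamming(r1[i], truth_r1[i]), integer(1)))
  n_bases <- 34L * length(r1)
  expect_gt(n_bases, 1e5)
  p <- 0.01
  expect_lt(abs(n_sub - n_bases * p), 3 * sqrt(n_bases * p * (1 - p)))
})

test_that("oversized fiducials are rejected at configuration time", {
  expect_error(sim_config(tile_width = 1000, tile_height = 1000),
               "fiducial larger than tile")
})
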