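test_that("tissue tiles are identified from subset hits", {
  sim <- shared_small_sim()
  idx <- index_fastq_dir(sim$fastq_dir)
  subs <- lapply(idx, function(x) x$subset$barcode)
  # reads drawn only from two tiles
  w <- sim$wells[tile_id %in% c(1102L, 1201L)]
  set.seed(53)
  r1 <- paste0(sample(w$barcode, 20000, replace = TRUE), "TT")
  sel <- identify_tiles(r1, subs, min_hits = 10)
  expect_setequal(as.integer(sel), c(1102L, 1201L))
  expect_error(identify_tiles(character(0), subs), "no spatial reads")
  # random barcodes produce (essentially) no chance hits
  rnd <- sample_barcodes(5000)
  expect_error(identify_tiles(paste0(rnd, "TT"), subs, min_hits = 1),
               "no tile")
})

test_that("whitelist trims to 31 nt and drops trim collisions symmetrically", {
  mk <- function(suffix) paste0(valid_barcode(strrep("C", 19)), suffix)
  gi <- data.table::data.table(
    barcode = c(sample_barcodes(100), mk("A"), mk("G")),
    x_nm = 1, y_nm = 2, tile_id = rep(c(1101L, 1102L), 51))
  wl <- build_whitelist(gi, c(1101L, 1102L))
  expect_identical(nrow(wl$entries), 100L)
  expect_identical(wl$collisions, 2L)
  expect_true(all(nchar(wl$entries$barcode) == 31L))
  # containment: whitelist only draws from the selected tiles
  wl2 <- build_whitelist(gi, 1101L)
  expect_true(all(wl2$entries$barcode %in% substr(gi[tile_id == 1101L]$barcode,
                                                  1, 31)))
  expect_error(build_whitelist(gi, integer(0)), "no tiles")
})

test_that("barcode matching follows exact-then-unique-1MM semantics", {
  set.seed(59)
  wl <- unique(substr(sample_barcodes(500), 1, 31))
  # exact
  m <- match_barcode(wl[7], wl)
  expect_identical(as.integer(m), 7L)
  expect_identical(as.character(attr(m, "reason")), "exact")
  # unique distance-1 neighbour
  q <- wl[7]
  substr(q, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(q, 5, 5))[1]
  if (!q %in% wl) {
    m1 <- match_barcode(q, wl)
    expect_identical(as.integer(m1), bf_match(q, wl))
    expect_identical(as.character(attr(m1, "reason")), "corrected")
  }
  # two entries at distance 1 -> unassigned
  base <- substr(valid_barcode(strrep("C", 19)), 1, 31)
  v1 <- base; substr(v1, 31, 31) <- "A"
  v2 <- base; substr(v2, 31, 31) <- "G"
  amb <- match_barcode(base, c(wl, v1, v2))
  expect_true(is.na(amb))
  expect_identical(as.character(attr(amb, "reason")), "ambiguous")
})

test_that("vectorised matcher agrees with the brute-force Hamming scan", {
  set.seed(61)
  wl <- unique(substr(sample_barcodes(2000), 1, 31))
  # queries: exact copies, single mutants, double mutants, random
  mutate <- function(s, k) {
    for (pos in sample(31, k)) {
      substr(s, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(s, pos, pos)), 1)
    }
    s
  }
  q <- c(sample(wl, 300),
         vapply(sample(wl, 300), mutate, "", k = 1),
         vapply(sample(wl, 200), mutate, "", k = 2),
         substr(sample_barcodes(200), 1, 31))
  got <- match_barcodes(q, wl)
  want <- bf_match_bulk(q, wl)
  expect_identical(as.integer(got), as.integer(want))
})

test_that("UMI dedup counts Hamming-1 connected components", {
  expect_identical(dedup_umis(rep("AAAAAAAA", 5)), 1L)
  expect_identical(dedup_umis(c("AAAAAAAA", "AAAAAAAT")), 1L)
  expect_identical(dedup_umis(c("AAAAAAAA", "CCCCCCCC")), 2L)
  # chain: A-B at d1, B-C at d1, A-C at d2 still one component
  expect_identical(dedup_umis(c("AAAAAAAA", "AAAAAAAT", "AAAAAATT")), 1L)
  expect_identical(dedup_umis(character(0)), 0L)
})

test_that("UMI dedup agrees with an explicit connected-components oracle", {
  set.seed(67)
  for (trial in 1:300) {
    n <- sample(1:10, 1)
    # low-cardinality alphabet forces frequent near-collisions
    umis <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C"), 8, replace = TRUE), collapse = ""), "")
    expect_identical(dedup_umis(umis), bf_umi_components(umis),
                     info = paste(umis, collapse = ","))
  }
})

test_that("UMI dedup is permutation-invariant and nearly monotone", {
  set.seed(71)
  umis <- vapply(1:12, function(i)
    paste(sample(c("A", "C", "G"), 8, replace = TRUE), collapse = ""), "")
  base <- dedup_umis(umis)
  for (k in 1:5)
    expect_identical(dedup_umis(sample(umis)), base)
  for (k in 1:20) {
    extra <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                   collapse = "")
    expect_lte(dedup_umis(c(umis, extra)), base + 1L)
  }
})

test_that("internal quantification reproduces ground truth exactly at zero error", {
  sim <- shared_small_sim()
  dir <- file.path(tempdir(), "quant-lib")
  sp <- simulate_spatial_reads(sim, dir)
  idx <- index_fastq_dir(sim$fastq_dir)
  cal <- calibrate_scale(25000, 728)
  st <- stitch_tiles(idx, cal, tile_spacing = c(5000, 5000),
                     tile_dims = c(5000, 5000))
  sel <- identify_tiles(sp$r1, lapply(idx, function(x) x$subset$barcode))
  wl <- build_whitelist(st$global, sel)
  q <- quantify(sp$r1, sp$r2, wl, sim$gene_tags)
  expect_identical(sum(q$counts$count), nrow(sp$molecules))
  # conservation of reads across assignment categories
  expect_identical(q$stats[["assigned"]] + q$stats[["unassigned_cb"]] +
                     q$stats[["ambiguous_cb"]] + q$stats[["unassigned_gene"]],
                   q$stats[["total"]])
  # per-(barcode, gene) counts match the truth table
  truth <- sp$molecules[, .(n = .N),
                        by = .(barcode = substr(barcode, 1, 31), gene_id)]
  j <- merge(q$counts, truth, by = c("barcode", "gene_id"), all = TRUE)
  expect_false(anyNA(j$count))
  expect_false(anyNA(j$n))
  expect_identical(j$count, j$n)
})

test_that("reads with two barcode errors stay unassigned", {
  wl_bc <- unique(substr(sample_barcodes(50), 1, 31))
  wl <- structure(list(entries = data.table::data.table(
    barcode = wl_bc, x_nm = seq_along(wl_bc), y_nm = 1,
    tile_id = 1101L), collisions = 0L, tiles = 1101L),
    class = "nova_whitelist")
  tags <- data.table::data.table(gene_id = "gene_0001", tag = strrep("G", 40))
  q2 <- wl_bc[1]
  substr(q2, 1, 1) <- "G"; substr(q2, 2, 2) <- "A"  # two constant-block errors
  r1 <- paste0(q2, "TTT")
  r2 <- paste0("AAAAAAAAA", strrep("G", 40), strrep("A", 42))
  res <- quantify(r1, r2, wl, tags)
  expect_identical(nrow(res$counts), 0L)
  expect_identical(res$stats[["unassigned_cb"]], 1L)
})

test_that("external matrices import as per-barcode counts", {
  m <- Matrix::sparseMatrix(i = 1:3, j = 1:3, x = c(5, 2, 7), dims = c(3, 3))
  mtx <- tempfile(fileext = ".mtx"); Matrix::writeMM(m, mtx)
  bcs <- tempfile(); writeLines(c("B1", "B2", "B3"), bcs)
  fts <- tempfile(); writeLines(c("g1", "g2", "g3"), fts)
  imp <- import_counts(mtx, bcs, fts)
  expect_identical(nrow(imp$counts), 3L)
  expect_identical(sum(imp$counts$count), 14)
  # round trip: re-export the triplets and import again
  m2 <- Matrix::sparseMatrix(
    i = match(imp$counts$gene_id, c("g1", "g2", "g3")),
    j = match(imp$counts$barcode, c("B1", "B2", "B3")),
    x = imp$counts$count, dims = c(3, 3))
  mtx2 <- tempfile(fileext = ".mtx"); Matrix::writeMM(m2, mtx2)
  imp2 <- import_counts(mtx2, bcs, fts)
  expect_identical(data.table::setorder(imp2$counts, barcode),
                   data.table::setorder(imp$counts, barcode))
  # dimension mismatch
  writeLines(c("B1", "B2"), bcs)
  expect_error(import_counts(mtx, bcs, fts), "dimensions")
  # barcodes outside the whitelist are dropped and counted
  wl <- structure(list(entries = data.table::data.table(
    barcode = c("B1", "B3"), x_nm = 1:2, y_nm = 1:2, tile_id = 1L),
    collisions = 0L, tiles = 1L), class = "nova_whitelist")
  writeLines(c("B1", "B2", "B3"), bcs)
  imp3 <- import_counts(mtx, bcs, fts, wl)
  expect_identical(nrow(imp3$counts), 2L)
  expect_identical(imp3$dropped, 1L)
})

test_that("GEM files round-trip and conserve molecule totals", {
  wl <- structure(list(entries = data.table::data.table(
    barcode = c("b1", "b2"), x_nm = c(34.34, 6868), y_nm = c(34.34, 103.02),
    tile_id = 1101L), collisions = 0L, tiles = 1101L),
    class = "nova_whitelist")
  counts <- data.table::data.table(
    barcode = c("b1", "b1", "b2"),
    gene_id = c("gene_0001", "gene_0002", "gene_0001"),
    count = c(3L, 1L, 2L))
  cal <- calibrate_scale(25000, 728)
  path <- tempfile(fileext = ".gem")
  write_gem(counts, wl, cal, path)
  gem <- read_gem(path)
  expect_identical(nrow(gem), 3L)           # one line per (gene, x, y)
  expect_identical(sum(gem$MIDCount), sum(counts$count))
  expect_identical(sort(unique(gem$geneID)), c("gene_0001", "gene_0002"))
  # coordinates are native units: nm / nm_per_unit rounded
  expect_true(all(gem[geneID == "gene_0001" & MIDCount == 3]$x == 1))
  expect_true(all(gem[geneID == "gene_0001" & MIDCount == 2]$x == 200))
  # unknown barcode coordinates are an error
  bad <- data.table::data.table(barcode = "zz", gene_id = "g", count = 1L)
  expect_error(write_gem(bad, wl, cal, tempfile()), "without global")
})
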