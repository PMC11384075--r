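test_that("density image bins coordinates by floor division", {
  idx <- index_fixture(valid_barcode(), 50L, 74L)
  img <- build_density_image(idx, bin_size = 25)
  # x=50 -> column 3, y=74 -> row 3 (1-based)
  expect_identical(which(img$counts > 0), which(row(img$counts) == 3 &
                                                  col(img$counts) == 3))
  expect_identical(img$counts[3, 3], 1L)
  expect_equal(max(img$mat), 255)
})

test_that("uniform occupancy normalises to a flat 255 image", {
  # one record per pixel centre: every pixel counts exactly 1
  xy <- expand.grid(x = seq(12, 237, 25), y = seq(12, 237, 25))
  idx <- index_fixture(sample_barcodes(nrow(xy)), xy$x, xy$y)
  img <- build_density_image(idx, 25, width = 250, height = 250)
  expect_true(all(img$counts == 1L))
  expect_true(all(img$mat == 255))
  expect_error(build_density_image(index_fixture(character(0), integer(0),
                                                 integer(0))),
               "empty")
})

test_that("preprocessing inverts, denoises and binarises", {
  all_hi <- matrix(255, 50, 50)
  expect_true(all(preprocess_image(all_hi) == 0))
  all_lo <- matrix(0, 50, 50)
  expect_true(all(preprocess_image(all_lo) == 255))
  # isolated single-pixel voids are removed; a solid void block survives
  mat <- matrix(255, 60, 60)
  salt <- cbind(c(5, 15, 25, 45), c(7, 33, 50, 12))
  mat[salt] <- 0
  mat[30:40, 30:40] <- 0
  bw <- preprocess_image(mat)
  expect_true(all(bw[salt] == 0))
  expect_true(all(bw[32:38, 32:38] == 255))
})

test_that("circle detection is empty on a blank image", {
  expect_identical(nrow(detect_circles(matrix(0, 200, 200))), 0L)
})

test_that("a synthetic fiducial yields one outer and one inner circle near truth", {
  ctr <- matrix(c(100, 90), ncol = 2)
  bw <- annulus_image(200, 200, ctr, r_outer = 60, r_inner = 22)
  circles <- detect_circles(bw)
  expect_identical(sum(circles$class == "outer"), 1L)
  expect_identical(sum(circles$class == "inner"), 1L)
  for (cls in c("outer", "inner")) {
    cc <- circles[class == cls]
    expect_lt(abs(cc$cx - 100), 2)
    expect_lt(abs(cc$cy - 90), 2)
  }
  expect_lt(abs(circles[class == "outer"]$r - 60), 3)
  expect_lt(abs(circles[class == "inner"]$r - 22), 2)
})

test_that("four fiducials give eight circles and a complete tile", {
  ctrs <- cbind(c(50, 150, 50, 150), c(50, 50, 150, 150))
  bw <- annulus_image(200, 200, ctrs)
  circles <- detect_circles(bw)
  expect_identical(sum(circles$class == "outer"), 4L)
  expect_identical(sum(circles$class == "inner"), 4L)
  fid <- novaST:::fiducials_from_circles(circles, 1101L, 25L, c(0, 0), 4L)
  expect_true(fid$complete)
  # joint centroid of a symmetric layout is the pattern centre
  expect_equal(fid$centroid, (c(100, 100) + 0.5) * 25, tolerance = 1)
})

test_that("tile centroid averages all eight circle centres", {
  circles <- data.table::data.table(
    cx = c(90, 110, 90, 110, 95, 105, 95, 105),
    cy = c(90, 90, 110, 110, 95, 95, 105, 105),
    r = c(rep(60, 4), rep(22, 4)), votes = 1,
    class = rep(c("outer", "inner"), each = 4))
  fid <- novaST:::fiducials_from_circles(circles, 1101L, 25L, c(0, 0), 4L)
  expect_true(fid$complete)
  expect_equal(tile_centroid(fid), (c(100, 100) + 0.5) * 25)
  # concentric equal-size sets: per-class means agree with the joint mean
  expect_equal(fid$centroid_outer, fid$centroid)
  expect_equal(fid$centroid_inner, fid$centroid)
  # incomplete set: centroid is an error, handled by interpolation
  fid7 <- novaST:::fiducials_from_circles(circles[1:7], 1101L, 25L, c(0, 0), 4L)
  expect_false(fid7$complete)
  expect_error(tile_centroid(fid7), "incomplete")
})

test_that("missing centroids are interpolated from grid neighbours", {
  cts <- data.table::data.table(
    tile_id = c(1101L, 1102L, 1103L),
    swath = 1L, row = 1:3,
    cx = c(2500, NA, 2500), cy = c(2400, NA, 2400))
  out <- interpolate_missing(cts)
  expect_equal(out$cx[2], 2500)
  expect_equal(out$cy[2], 2400)
  expect_true(out$interpolated[2])
  # all present: no-op
  full <- data.table::data.table(tile_id = 1101:1102, swath = 1L, row = 1:2,
                                 cx = c(1, 2), cy = c(3, 4))
  out2 <- interpolate_missing(full)
  expect_identical(out2$cx, full$cx)
  expect_false(any(out2$interpolated))
  # isolated tile stays unresolved and is reported
  iso <- data.table::data.table(tile_id = c(1101L, 1301L), swath = c(1L, 3L),
                                row = 1L, cx = c(10, NA), cy = c(10, NA))
  expect_warning(out3 <- interpolate_missing(iso), "unresolved")
  expect_true(is.na(out3$cx[2]))
})

test_that("simulated tiles are recovered completely and accurately", {
  sim <- shared_small_sim()
  idx <- index_fastq_dir(sim$fastq_dir)
  for (tid in c("1101", "1202")) {
    fid <- detect_tile_fiducials(idx[[tid]], width = 5000, height = 5000)
    expect_true(fid$complete)
    expect_identical(nrow(fid$circles), 8L)
    t <- sim$tiles[tile_id == as.integer(tid)]
    truth <- c(2500 + t$jitter_x, 2500 + t$jitter_y)
    expect_lt(max(abs(fid$centroid - truth)), 2 * 25)
    # void pixels are darker than tissue pixels
    img <- build_density_image(idx[[tid]], 25, 5000, 5000)
    ctr <- sim$fiducials[1]
    px <- round((ctr$fx + t$jitter_x) / 25); py <- round((ctr$fy + t$jitter_y) / 25)
    inner <- img$counts[(py - 5):(py + 5), (px - 5):(px + 5)]
    expect_lt(median(inner), median(img$counts[img$counts >= 0]))
    expect_identical(sum(inner), 0L)
  }
})

test_that("detection is equivariant under record translation", {
  sim <- shared_small_sim()
  idx <- index_fastq_dir(sim$fastq_dir)[["1101"]]
  base <- detect_tile_fiducials(idx, width = 5000, height = 5000)
  delta <- c(100L, 75L)   # multiples of the 25-unit bin
  shifted <- index_fixture(idx$records$barcode,
                           idx$records$x + delta[1],
                           idx$records$y + delta[2])
  moved <- detect_tile_fiducials(shifted, width = 5000 + delta[1],
                                 height = 5000 + delta[2])
  expect_true(moved$complete)
  # border effects at the vacated margin may perturb the sub-pixel
  # refinement; equivariance holds at (sub-)pixel precision
  expect_lt(max(abs(moved$centroid - (base$centroid + delta))), 25)
})
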