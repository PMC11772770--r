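test_that("majority upscaling reproduces the 990 m worked examples", {
  # a 33x33 block entirely forest -> (forest, 1.0) at 990 m from 30 m input
  cov <- land_raster(matrix(1, 33, 33), cell_size = 30)
  up <- upscale_dominant_type(cov, window = 33)
  expect_equal(up$type$values[1, 1], 1)
  expect_equal(up$fraction$values[1, 1], 1.0)
  expect_equal(up$type$cell_size, 990)

  # 1089 cells: 545 cropland vs 544 grassland -> cropland, 545/1089
  vals <- c(rep(0, 545), rep(2, 544))
  cov2 <- land_raster(matrix(vals, 33, 33), cell_size = 30)
  up2 <- upscale_dominant_type(cov2, window = 33)
  expect_equal(up2$type$values[1, 1], 0)
  expect_equal(up2$fraction$values[1, 1], 545 / 1089)

  # all-nodata block -> nodata coarse cell
  m <- matrix(1, 4, 8); m[, 5:8] <- NA
  up3 <- upscale_dominant_type(land_raster(m, 30), window = 4)
  expect_equal(up3$type$values[1, 1], 1)
  expect_true(is.na(up3$type$values[1, 2]))
  expect_true(is.na(up3$fraction$values[1, 2]))

  expect_error(upscale_dominant_type(land_raster(matrix(1, 5, 5), 30), 33),
               "smaller than window")
})

test_that("block counting matches a naive per-block tally on random rasters", {
  set.seed(42)
  for (trial in 1:6) {
    nr <- sample(40:200, 1); nc <- sample(40:200, 1)
    w <- sample(c(3, 5, 7, 11), 1)
    m <- matrix(sample(c(0:9, NA), nr * nc, replace = TRUE,
                       prob = c(rep(0.095, 10), 0.05)), nr, nc)
    cov <- land_raster(m, cell_size = 30)
    up <- upscale_dominant_type(cov, window = w)
    exp_type <- matrix(NA_real_, nrow(up$type$values), ncol(up$type$values))
    exp_frac <- exp_type
    for (bi in seq_len(nrow(exp_type))) {
      for (bj in seq_len(ncol(exp_type))) {
        r0 <- (bi - 1) * w + 1; r1 <- min(nr, bi * w)
        c0 <- (bj - 1) * w + 1; c1 <- min(nc, bj * w)
        if ((r1 - r0 + 1) * (c1 - c0 + 1) < 0.5 * w * w) next
        o <- oracle_block_stats(m, r0, r1, c0, c1)
        exp_type[bi, bj] <- o$type
        exp_frac[bi, bj] <- o$fraction
      }
    }
    expect_identical(up$type$values, exp_type)
    expect_identical(up$fraction$values, exp_frac)
  }
})

test_that("modal ties break to the lowest class code", {
  m <- matrix(c(5, 5, 3, 3), 2, 2)
  up <- upscale_dominant_type(land_raster(m, 30), window = 2)
  expect_equal(up$type$values[1, 1], 3)
  expect_equal(up$fraction$values[1, 1], 0.5)
})

test_that("edge blocks are kept iff at least half the block is inside", {
  # 10 rows with window 4: trailing remainder of 2 rows = 50% -> kept
  m <- matrix(0, 10, 8)
  up <- upscale_dominant_type(land_raster(m, 30), window = 4)
  expect_equal(dim(up$type$values), c(3L, 2L))
  # remainder of 1 row = 25% -> dropped
  m2 <- matrix(0, 9, 8)
  up2 <- upscale_dominant_type(land_raster(m2, 30), window = 4)
  expect_equal(dim(up2$type$values), c(2L, 2L))
})

test_that("Jenks breaks separate three obvious clusters", {
  x <- c(1, 2, 3, 10, 11, 12, 20, 21, 22) / 100
  b <- jenks_breaks(x)
  expect_equal(b, c(0.03, 0.12))
  cls <- cut(x, c(-Inf, b, Inf))
  expect_equal(as.integer(table(cls)), c(3L, 3L, 3L))
})

test_that("Jenks equals the exhaustive optimum for n <= 25 (many random draws)", {
  set.seed(7)
  for (trial in 1:40) {
    n <- sample(3:25, 1)
    x <- round(runif(n), 3)
    if (length(unique(x)) < 3) next
    b <- jenks_breaks(x)
    o <- oracle_jenks3(x)
    expect_equal(jenks_partition_ssd(x, b), o$ssd, tolerance = 1e-12)
  }
})

test_that("Jenks recovers the gaps of three well-separated clusters", {
  set.seed(9)
  x <- c(runif(70, 0.00, 0.15), runif(70, 0.40, 0.55), runif(60, 0.80, 0.95))
  b <- jenks_breaks(x)
  expect_gte(b[1], 0.0); expect_lte(b[1], 0.40)
  expect_gte(b[2], 0.40); expect_lte(b[2], 0.80)
  o <- oracle_jenks3(sample(x, 25))  # spot-check optimality on a subsample
  expect_true(is.finite(o$ssd))
})

test_that("density breaks handle degenerate types and label per type", {
  fr <- tibble::tibble(
    type = c(rep(0, 9), rep(1, 4)),
    fraction = c(c(1, 2, 3, 10, 11, 12, 20, 21, 22) / 100, rep(0.7, 4))
  )
  expect_message(br <- compute_density_breaks(fr), "degenerate")
  expect_equal(br$b1[br$type == 0], 0.03)
  expect_equal(br$b2[br$type == 0], 0.12)
  expect_true(br$degenerate[br$type == 1])
  expect_true(is.na(br$b1[br$type == 1]))
})

test_that("density classification follows the type-major code layout", {
  # forest (type 1) at fraction 0.95 with breaks (0.5, 0.8) -> Forest_H = 5
  ty <- land_raster(matrix(1, 1, 3), 990)
  fr <- land_raster(matrix(c(0.95, 0.5, 0.65), 1, 3), 990)
  br <- tibble::tibble(type = 1, b1 = 0.5, b2 = 0.8, n = 3, degenerate = FALSE)
  ls <- classify_density(ty, fr, br)
  expect_equal(as.vector(ls$values), c(5, 3, 4))  # H, L (boundary at b1), M
  leg <- land_system_legend()
  expect_equal(leg$label[leg$value == 5], "Forest_H")
  expect_error(
    classify_density(land_raster(matrix(2, 1, 1), 990),
                     land_raster(matrix(0.5, 1, 1), 990), br),
    "type")
})

test_that("a full scene with all types and densities yields exactly 30 codes", {
  # 30 blocks, one per (type, density): type t with fractions that fall into
  # each of the three classes after global Jenks per type
  set.seed(5)
  w <- 10L
  blocks <- list()
  for (t in 0:9) {
    for (frac in c(0.34, 0.67, 1.0)) {
      blk <- matrix(sample(setdiff(0:9, t), w * w, replace = TRUE), w, w)
      k <- round(frac * w * w)
      blk[seq_len(k)] <- t
      blocks[[length(blocks) + 1L]] <- blk
    }
  }
  big <- do.call(rbind, lapply(0:9, function(t) {
    do.call(cbind, blocks[t * 3 + 1:3])
  }))
  cov <- land_raster(big, cell_size = 30)
  b <- build_land_system(cov, window = w)
  codes <- sort(unique(as.vector(b$ls$values)))
  expect_length(codes, 30L)
  expect_equal(codes, as.numeric(0:29))
  # merging densities recovers exactly the ten cover types
  merged <- merge_density(b$ls)
  expect_equal(sort(unique(as.vector(merged$values))), as.numeric(0:9))
})

test_that("land-system codes stay in budget and merging inverts typing", {
  set.seed(12)
  m <- matrix(sample(0:9, 60 * 60, replace = TRUE), 60, 60)
  cov <- land_raster(m, cell_size = 30)
  b <- build_land_system(cov, window = 5)
  v <- as.vector(b$ls$values)
  expect_true(all(v[!is.na(v)] %in% 0:29))
  # merge o classify gives the same cover type as the dominant-type grid
  expect_identical(merge_density(b$ls)$values, b$type$values)
})

test_that("merge_density maps Forest_L/M/H to forest and keeps nodata", {
  ls <- land_raster(matrix(c(3, 4, 5, NA), 2, 2), 990)
  out <- merge_density(ls)
  expect_equal(as.vector(out$values), c(1, 1, 1, NA))
  expect_error(merge_density(land_raster(matrix(31, 1, 1), 990)), "0..29")
})
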