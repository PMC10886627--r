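test_that("tile_grid partitions with stride = tile size and drops remainders", {
  expect_equal(nrow(tile_grid(1000, 1000, 250)), 16)
  expect_equal(nrow(tile_grid(600, 600, 250)), 4)
  g <- tile_grid(250, 250, 250)
  expect_equal(nrow(g), 1)
  expect_equal(unname(g[1, ]), c(0L, 0L))
  expect_equal(nrow(tile_grid(200, 200, 250)), 0)
  # non-square image
  expect_equal(nrow(tile_grid(500, 750, 250)), 2 * 3)
})

test_that("coverage matches containment and disjointness contracts", {
  aset <- annotation_set("c", list(
    annotation(rect_poly(0, 0, 100, 100), "stroma", "s1")))
  # tile fully inside the polygon
  cov <- coverage_by_class(c(10, 10), 50, aset, c(200, 200))
  expect_equal(unname(cov["stroma"]), 1.0)
  # tile disjoint from all polygons
  cov0 <- coverage_by_class(c(120, 120), 50, aset, c(200, 200))
  expect_equal(unname(cov0["stroma"]), 0)
  # rectangle covering the left 25 of 50 columns: coverage exactly 0.5
  half <- annotation_set("h", list(
    annotation(rect_poly(0, 0, 25, 200), "tumor", "t1")))
  ch <- coverage_by_class(c(0, 0), 50, half, c(200, 200))
  expect_equal(unname(ch["tumor"]), 0.5)
  expect_equal(unname(oracle_coverage(c(0, 0), 50, half, 200, 200)["tumor"]),
               0.5)
  expect_error(coverage_by_class(c(180, 0), 50, aset, c(200, 200)),
               "bounds")
})

test_that("the 99% labeling rule is exact at the pixel-counting boundary", {
  # polygon leaving exactly 625 of 62,500 pixel centers uncovered:
  # 2 full columns (500 px) plus 125 px of a third column
  at_threshold <- matrix(c(3.5, 0, 250, 0, 250, 250, 2.5, 250,
                           2.5, 125.5, 3.5, 125.5),
                         ncol = 2, byrow = TRUE)
  # one more pixel uncovered (626): shift the notch down one row
  below <- at_threshold
  below[5:6, 2] <- 126.5
  dims <- c(250, 250)
  for (case in list(list(p = at_threshold, kept = TRUE, n_out = 625),
                    list(p = below, kept = FALSE, n_out = 626))) {
    aset <- annotation_set("b", list(annotation(case$p, "tumor", "t")))
    # confirm the constructed uncovered count with the per-pixel oracle
    m <- oracle_class_mask(aset, "tumor", 250, 250)
    expect_equal(sum(!m), case$n_out)
    rec <- label_tile(c(0, 0), 250, aset, dims)
    if (case$kept) {
      expect_equal(rec$label, "tumor")
      expect_equal(rec$coverage, 1 - 625 / 62500)
    } else {
      expect_null(rec)
    }
  }
  # a 50/50 two-class tile is excluded (below threshold for both)
  mixed <- annotation_set("m", list(
    annotation(rect_poly(0, 0, 125, 250), "tumor", "a"),
    annotation(rect_poly(125, 0, 250, 250), "stroma", "b")))
  expect_null(label_tile(c(0, 0), 250, mixed, dims))
  # two overlapping classes both above threshold: contradictory, excluded
  overlap <- annotation_set("o", list(
    annotation(rect_poly(0, 0, 250, 250), "tumor", "a"),
    annotation(rect_poly(0, 0, 250, 250), "stroma", "b")))
  expect_null(label_tile(c(0, 0), 250, overlap, dims))
})

test_that("build_dataset matches the brute-force rasterization tiler", {
  # full coverage: one 500x500 image fully covered by a tumor polygon
  full <- annotation_set("f", list(
    annotation(rect_poly(-1, -1, 501, 501), "tumor", "t")))
  ds <- build_dataset(list(f = c(500, 500)), list(full), tile_size = 250)
  expect_equal(nrow(ds$tiles), 4)
  expect_true(all(ds$tiles$label == "tumor"))
  expect_equal(unname(ds$class_counts["tumor"]), 4L)

  # empty annotation set yields zero tiles
  ds0 <- build_dataset(list(e = c(500, 500)),
                       list(annotation_set("e")), 250)
  expect_equal(nrow(ds0$tiles), 0)

  # random synthetic specimens agree with the independent per-pixel tiler
  set.seed(19)
  spec <- desk_cohort_spec(n_images = 3, image_size = 192, seed = 77)
  for (i in 1:3) {
    sp <- generate_specimen(spec, i)
    h <- nrow(sp$image$ch2); w <- ncol(sp$image$ch2)
    got <- build_dataset(list(sp$image), list(sp$annotations), 64)$tiles
    want <- oracle_tile_dataset(sp$annotations, h, w, 64)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$x, want$x)
      expect_equal(got$y, want$y)
      expect_equal(got$label, want$label)
      expect_equal(got$coverage, want$coverage)
    }
  }
})

test_that("tiling is order-independent and monotone in the threshold", {
  set.seed(23)
  sp <- generate_specimen(desk_cohort_spec(n_images = 1, image_size = 192,
                                           seed = 9), 1)
  aset <- sp$annotations
  perm <- annotation_set(aset$image_id, rev(aset$annotations))
  d1 <- build_dataset(list(sp$image), list(aset), 64)
  d2 <- build_dataset(list(sp$image), list(perm), 64)
  o1 <- d1$tiles[order(d1$tiles$x, d1$tiles$y), ]
  o2 <- d2$tiles[order(d2$tiles$x, d2$tiles$y), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  # lowering the threshold never loses tiles
  n_99 <- nrow(build_dataset(list(sp$image), list(aset), 64, 0.99)$tiles)
  n_90 <- nrow(build_dataset(list(sp$image), list(aset), 64, 0.90)$tiles)
  n_50 <- nrow(build_dataset(list(sp$image), list(aset), 64, 0.50)$tiles)
  expect_true(n_99 <= n_90)
  expect_true(n_90 <= n_50)
})

test_that("extract_tile_pixels is an exact sub-grid copy", {
  set.seed(31)
  img <- make_random_srs("x", 128, 128)
  t3 <- build_three_channel(img)
  rec <- data.frame(image_id = "x", x = 64L, y = 0L, size = 64L,
                    label = "tumor", coverage = 1)
  tile <- extract_tile_pixels(t3, rec)
  expect_equal(dim(tile), c(64, 64, 3))
  # per-index oracle loop on a subsample of positions
  for (k in 1:20) {
    i <- sample(64, 1); j <- sample(64, 1)
    expect_identical(tile[i, j, 1], t3$plane1[i, j + 64])
    expect_identical(tile[i, j, 3], t3$plane3[i, j + 64])
  }
  # adjacent tiles use disjoint pixels: top-left block equals source
  rec0 <- rec; rec0$x <- 0L
  t0 <- extract_tile_pixels(t3, rec0)
  expect_identical(t0[, , 2], t3$plane2[1:64, 1:64])
  recbad <- rec; recbad$x <- 100L
  expect_error(extract_tile_pixels(t3, recbad), "bounds")
})
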