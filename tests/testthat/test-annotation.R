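test_that("the tissue vocabulary is closed and aliases resolve", {
  expect_equal(normalize_tissue_class("Tumor"), "tumor")
  expect_equal(normalize_tissue_class("Squamous epithelium"),
               "squamous_epithelium")
  expect_equal(normalize_tissue_class("AdiposeTissue"), "adipose")
  expect_equal(normalize_tissue_class("GLANDULAR TISSUE"), "glandular")
  expect_error(normalize_tissue_class("Nerve"), "Nerve")
  expect_true(is.na(normalize_tissue_class("Nerve", strict = FALSE)))
})

test_that("GeoJSON loading handles the QuPath dialect", {
  tri <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    geometry = list(type = "Polygon",
                    coordinates = list(list(c(0, 0), c(10, 0), c(5, 8),
                                            c(0, 0)))),
    properties = list(classification = list(name = "Tumor"))
  )))
  f <- tempfile(fileext = ".geojson")
  jsonlite::write_json(tri, f, auto_unbox = TRUE)
  aset <- load_annotations(f, image_id = "t1")
  expect_length(aset, 1)
  expect_equal(aset$annotations[[1]]$tissue_class, "tumor")

  # unknown class: error in strict mode, warning + skip in lenient mode
  tri$features[[1]]$properties$classification$name <- "Nerve"
  jsonlite::write_json(tri, f, auto_unbox = TRUE)
  expect_error(load_annotations(f), "Nerve")
  expect_warning(a2 <- load_annotations(f, strict = FALSE), "Nerve")
  expect_length(a2, 0)

  # multi-polygon with 2 parts becomes 2 annotations sharing the class
  mp <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    geometry = list(type = "MultiPolygon", coordinates = list(
      list(list(c(0, 0), c(4, 0), c(4, 4), c(0, 4), c(0, 0))),
      list(list(c(10, 10), c(14, 10), c(12, 14), c(10, 10)))
    )),
    properties = list(name = "Stroma")  # properties.name fallback
  )))
  jsonlite::write_json(mp, f, auto_unbox = TRUE)
  am <- load_annotations(f)
  expect_length(am, 2)
  expect_equal(vapply(am$annotations, function(a) a$tissue_class, ""),
               c("stroma", "stroma"))

  # non-polygon geometry and malformed JSON are format errors
  pt <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    geometry = list(type = "Point", coordinates = c(1, 2)),
    properties = list(classification = list(name = "Tumor"))
  )))
  jsonlite::write_json(pt, f, auto_unbox = TRUE)
  expect_error(load_annotations(f), "Point")
  writeLines("{not json", f)
  expect_error(load_annotations(f), "malformed|parse|lexical")
})

test_that("GeoJSON round trip preserves classes and areas", {
  set.seed(5)
  mk_poly <- function() {
    n <- sample(3:8, 1)
    th <- sort(runif(n, 0, 2 * pi))
    r <- runif(n, 5, 20)
    cbind(50 + r * cos(th), 50 + r * sin(th))
  }
  anns <- lapply(1:6, function(i) {
    annotation(mk_poly(), TISSUE_CLASSES[i], paste0("a", i))
  })
  aset <- annotation_set("rt", anns)
  f <- tempfile(fileext = ".geojson")
  write_annotations(aset, f)
  back <- load_annotations(f, image_id = "rt")
  expect_length(back, 6)
  for (i in 1:6) {
    expect_equal(back$annotations[[i]]$tissue_class,
                 aset$annotations[[i]]$tissue_class)
    expect_equal(annotation_area(back$annotations[[i]]),
                 annotation_area(aset$annotations[[i]]),
                 tolerance = 1e-6)
  }

  # polygon with a hole: re-read area equals outer minus hole (shoelace)
  outer <- rect_poly(0, 0, 10, 10)
  hole <- rect_poly(2, 2, 4, 4)
  hs <- annotation_set("h", list(annotation(list(outer, hole), "adipose",
                                            "h1")))
  write_annotations(hs, f)
  hb <- load_annotations(f, image_id = "h")
  expect_equal(annotation_area(hb$annotations[[1]]),
               oracle_shoelace(outer) - oracle_shoelace(hole),
               tolerance = 1e-9)

  # empty set round-trips as a valid FeatureCollection with no features
  write_annotations(annotation_set("e"), f)
  expect_length(load_annotations(f), 0)
})

test_that("annotation transfer is an identity on coordinates", {
  a <- annotation_set("srh_1", list(
    annotation(rect_poly(1, 2, 9, 8), "muscle", "m1")))
  b <- transfer_annotations(a, "srs_1", src_dim = c(10, 10),
                            target_dim = c(10, 10))
  expect_equal(b$image_id, "srs_1")
  expect_identical(b$annotations[[1]]$rings, a$annotations[[1]]$rings)
  # involution: transferring back reproduces the original
  c2 <- transfer_annotations(b, "srh_1")
  expect_identical(c2$annotations, a$annotations)
  expect_error(
    transfer_annotations(a, "x", src_dim = c(10, 10),
                         target_dim = c(20, 10)),
    "different size")
})

test_that("degenerate polygons are rejected", {
  expect_error(annotation(matrix(c(0, 0, 1, 1), 2, 2), "tumor", "x"),
               "3 vertices")
  expect_error(
    annotation(matrix(c(0, 0, 1, 1, 2, 2), 3, 2, byrow = TRUE), "tumor",
               "x"),
    "zero area")
})
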