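test_that("confusion_matrix tallies (true, predicted) pairs exactly", {
  # perfect predictions give a diagonal matrix
  y <- rep(TISSUE_CLASSES, times = c(3, 2, 1, 4, 2, 1))
  cm <- confusion_matrix(y, y)
  expect_equal(unname(diag(cm)), c(3, 2, 1, 4, 2, 1))
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  expect_error(confusion_matrix(character(0), character(0)), "empty")
  expect_error(confusion_matrix(c("tumor"), c("tumor", "stroma")),
               "length")
  expect_error(confusion_matrix("tumor", "nerve"), "unknown")

  # random 100-label fixture vs an exhaustive hand tally of all 36 cells
  set.seed(17)
  tr <- sample(TISSUE_CLASSES, 100, replace = TRUE)
  pr <- sample(TISSUE_CLASSES, 100, replace = TRUE)
  cm2 <- confusion_matrix(tr, pr)
  for (a in TISSUE_CLASSES) for (b in TISSUE_CLASSES) {
    expect_equal(cm2[a, b], sum(tr == a & pr == b))
  }
  expect_equal(sum(cm2), 100)
})

test_that("precision/recall follow the column/row-sum definitions", {
  y <- rep(TISSUE_CLASSES, times = c(5, 5, 5, 5, 5, 5))
  cm <- confusion_matrix(y, y)
  pr <- precision_recall(cm)
  expect_equal(unname(pr$precision), rep(1, 6))
  expect_equal(unname(pr$recall), rep(1, 6))

  # a class absent from truth and predictions: (0, 0) with a warning
  cm0 <- confusion_matrix(c("tumor", "stroma"), c("tumor", "stroma"))
  w <- testthat::capture_warnings(pr0 <- precision_recall(cm0))
  expect_length(w, 2)  # one for precision, one for recall
  expect_match(w, "zero denominator", all = TRUE)
  expect_equal(unname(pr0$precision["muscle"]), 0)
  expect_equal(unname(pr0$recall["muscle"]), 0)

  # cross-count fixture equals direct division
  cm3 <- matrix(0L, 6, 6, dimnames = list(TISSUE_CLASSES, TISSUE_CLASSES))
  cm3["squamous_epithelium", "squamous_epithelium"] <- 1281L
  cm3["squamous_epithelium", "tumor"] <- 112L
  cm3["tumor", "tumor"] <- 1053L
  cm3["tumor", "squamous_epithelium"] <- 85L
  pr3 <- suppressWarnings(precision_recall(cm3))
  expect_equal(unname(pr3$recall["squamous_epithelium"]), 1281 / 1393)
  expect_equal(unname(pr3$precision["tumor"]), 1053 / (1053 + 112))
  expect_equal(misclassification_fraction(cm3, "squamous_epithelium",
                                          "tumor"), 112 / 1393)
  expect_equal(round(100 * misclassification_fraction(
    cm3, "squamous_epithelium", "tumor")), 8)
})

test_that("f1_score is the harmonic mean with a zero guard", {
  expect_equal(round(f1_score(0.86, 0.90), 2), 0.88)
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0, 0.7), 0)
  expect_equal(f1_score(0, 0), 0)
  # always between min and max of (P, R); equals both when P == R
  set.seed(21)
  for (k in 1:25) {
    p <- runif(1); r <- runif(1)
    f <- f1_score(p, r)
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
  }
  expect_equal(f1_score(0.37, 0.37), 0.37)
})

test_that("balanced accuracy is the unweighted mean of recalls", {
  expect_equal(balanced_accuracy(rep(1, 6)), 1)
  expect_equal(balanced_accuracy(c(1, 0, 0, 0, 0, 0)), 1 / 6)
  expect_equal(round(balanced_accuracy(c(.91, .98, .90, .89, .82, .90)),
                     2), 0.90)
})

test_that("evaluation reports are internally consistent", {
  set.seed(25)
  tr <- sample(TISSUE_CLASSES, 200, replace = TRUE)
  pr <- ifelse(runif(200) < 0.7, tr,
               sample(TISSUE_CLASSES, 200, replace = TRUE))
  rep1 <- report_from_labels(tr, pr)
  # metrics recomputed from the emitted confusion matrix match exactly
  pr2 <- suppressWarnings(precision_recall(rep1$confusion))
  expect_identical(rep1$precision, pr2$precision)
  expect_identical(rep1$recall, pr2$recall)
  expect_identical(rep1$f1, f1_score(pr2$precision, pr2$recall))
  expect_identical(rep1$balanced_accuracy, mean(pr2$recall))
  expect_equal(unname(rep1$n_tiles), unname(rowSums(rep1$confusion)))

  # degenerate stub predictions: constant class
  repc <- report_from_labels(tr, rep("tumor", 200))
  expect_equal(unname(repc$recall["tumor"]), 1)
  expect_equal(unname(repc$recall["stroma"]), 0)
  expect_equal(repc$balanced_accuracy, 1 / 6)
})

test_that("render_report writes re-parseable rounded outputs", {
  set.seed(29)
  tr <- sample(TISSUE_CLASSES, 150, replace = TRUE)
  pr <- ifelse(runif(150) < 0.8, tr,
               sample(TISSUE_CLASSES, 150, replace = TRUE))
  rep1 <- report_from_labels(tr, pr)
  d <- tempfile(); dir.create(d)
  files <- render_report(rep1, d, prefix = "t")
  expect_true(all(file.exists(files)))
  met <- read.csv(file.path(d, "t_metrics.csv"))
  # display order and two-decimal rounding survive the round trip
  expect_equal(met$class[1], "stroma")
  expect_equal(met$class[6], "tumor")
  expect_equal(met$f1, unname(round(rep1$f1[met$class], 2)))
  cmr <- read.csv(file.path(d, "t_confusion.csv"), row.names = 1)
  expect_equal(unname(as.matrix(cmr)), unname(rep1$confusion))
  js <- jsonlite::read_json(file.path(d, "t.json"))
  expect_equal(js$balanced_accuracy, rep1$balanced_accuracy)
  png_dim <- dim(png::readPNG(file.path(d, "t_confusion.png")))
  expect_equal(png_dim[3], 3)
})
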