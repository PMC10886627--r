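# small helper: a tile_dataset with prescribed per-image class counts
mock_dataset <- function(count_mat) {
  rows <- list()
  for (i in seq_len(nrow(count_mat))) {
    for (j in seq_len(ncol(count_mat))) {
      n <- count_mat[i, j]
      if (n > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = rownames(count_mat)[i],
          x = seq_len(n) * 64L, y = 0L, size = 64L,
          label = TISSUE_CLASSES[j], coverage = 1)
      }
    }
  }
  tiles <- do.call(rbind, rows)
  cc <- table(factor(tiles$label, levels = TISSUE_CLASSES))
  structure(list(tiles = tiles,
                 class_counts = setNames(as.integer(cc), names(cc)),
                 manifest = data.frame(image_id = rownames(count_mat)),
                 tile_size = 64L, threshold = 0.99),
            class = "tile_dataset")
}

random_count_mat <- function(n_img, min_per_class = 1) {
  m <- matrix(rpois(n_img * 6, 3), n_img, 6,
              dimnames = list(sprintf("im%02d", seq_len(n_img)),
                              TISSUE_CLASSES))
  # guarantee cohort-level presence
  for (j in 1:6) if (sum(m[, j]) == 0) m[sample(n_img, 3), j] <- 1
  m
}

test_that("class_distribution equals hand-tallied frequencies", {
  cm <- matrix(0, 2, 6, dimnames = list(c("a", "b"), TISSUE_CLASSES))
  cm["a", "tumor"] <- 2; cm["a", "stroma"] <- 2
  ds <- mock_dataset(cm)
  expect_equal(class_distribution(ds, "a"), c(.5, .5, 0, 0, 0, 0))
  cm2 <- cm; cm2["b", "tumor"] <- 4
  expect_equal(class_distribution(mock_dataset(cm2), "b"),
               c(1, 0, 0, 0, 0, 0))
  # random fixture vs direct count ratio
  set.seed(12)
  m <- random_count_mat(5)
  ds3 <- mock_dataset(m)
  ids <- c("im01", "im03")
  want <- colSums(m[ids, ]) / sum(m[ids, ])
  expect_equal(class_distribution(ds3, ids), unname(want))
  expect_error(class_distribution(ds3, "nope"), "no tiles")
})

test_that("jensen_shannon_distance is the base-2 JS metric", {
  expect_equal(jensen_shannon_distance(c(.3, .7), c(.3, .7)), 0)
  expect_equal(jensen_shannon_distance(c(1, 0, 0), c(0, 1, 0)), 1)
  # hand-derived value for (.5,.5) vs (.25,.75): m = (.375,.625),
  # JS = (KL(p||m) + KL(q||m))/2 in bits, distance = sqrt(JS)
  p <- c(.5, .5); q <- c(.25, .75); m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  want <- sqrt((kl(p, m) + kl(q, m)) / 2)
  expect_equal(jensen_shannon_distance(p, q), want)
  expect_equal(round(want, 4), 0.2209)
  expect_error(jensen_shannon_distance(c(.5, .6), c(.5, .5)), "sum to 1")
})

test_that("jensen_shannon_distance satisfies metric axioms on random triples", {
  set.seed(99)
  for (k in 1:40) {
    p <- as.vector(rmultinom(1, 60, runif(6))) / 60
    q <- as.vector(rmultinom(1, 60, runif(6))) / 60
    r <- as.vector(rmultinom(1, 60, runif(6))) / 60
    dpq <- jensen_shannon_distance(p, q)
    dqp <- jensen_shannon_distance(q, p)
    expect_equal(dpq, dqp)
    expect_gte(dpq, 0)
    expect_lte(dpq, 1)
    expect_lte(jensen_shannon_distance(p, r),
               dpq + jensen_shannon_distance(q, r) + 1e-12)
    if (!identical(p, q)) expect_gt(dpq + (identical(p, q)), 0)
  }
})

test_that("iterative_split returns 64/16 image pools with all classes present", {
  set.seed(4)
  m <- random_count_mat(80)
  ds <- mock_dataset(m)
  sp <- iterative_split(ds, seed = 21)
  expect_equal(unname(sp$sizes["test"]), 16L)
  expect_equal(unname(sp$sizes["train"] + sp$sizes["val"]), 64L)
  expect_equal(unname(sp$sizes["val"]), 6L)  # round(0.1 * 64)
  ids <- c(sp$train_ids, sp$val_ids, sp$test_ids)
  expect_setequal(ids, rownames(m))
  expect_equal(anyDuplicated(ids), 0L)
  for (sub in list(sp$train_ids, sp$val_ids, sp$test_ids)) {
    expect_true(all(colSums(m[sub, , drop = FALSE]) > 0))
  }
  # determinism: same dataset + seed reproduces the identical split
  sp2 <- iterative_split(ds, seed = 21)
  expect_identical(sp[c("train_ids", "val_ids", "test_ids", "jsd")],
                   sp2[c("train_ids", "val_ids", "test_ids", "jsd")])
  # different seed gives a different (but equally sized) split
  sp3 <- iterative_split(ds, seed = 22)
  expect_equal(sp3$sizes, sp$sizes)
})

test_that("accepted-subset JSD trace is non-increasing at unforced acceptances", {
  set.seed(8)
  m <- random_count_mat(10)
  sp <- iterative_split(mock_dataset(m), seed = 13)
  for (tr in sp$trace) {
    j <- tr$jsd
    if (length(j) > 1) {
      drops <- diff(j)
      expect_true(all(drops[!tr$forced[-1]] < 0))
    }
  }
})

test_that("a cohort missing one class is an infeasibility error", {
  set.seed(2)
  m <- random_count_mat(20)
  m[, "muscle"] <- 0
  expect_error(iterative_split(mock_dataset(m)), "infeasible")
})

test_that("the stratified split beats naive random splitting on average", {
  set.seed(55)
  diffs <- replicate(20, {
    m <- random_count_mat(30)
    ds <- mock_dataset(m)
    s <- sample.int(1e6, 1)
    it <- iterative_split(ds, seed = s)
    nv <- naive_split(ds, seed = s)
    c(it$jsd[["train"]], nv$jsd[["train"]])
  })
  expect_lte(mean(diffs[1, ]), mean(diffs[2, ]))
})
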