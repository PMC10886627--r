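#' Tile-level class distribution of an image subset
#'
#' @param dataset a `tile_dataset`.
#' @param image_ids character vector of image ids (default: all images in
#'   the dataset).
#' @return Numeric vector of six relative frequencies in the canonical
#'   class order (sums to 1).
#' @export
class_distribution <- function(dataset, image_ids = NULL) {
  stopifnot(inherits(dataset, "tile_dataset"))
  tiles <- dataset$tiles
  if (!is.null(image_ids)) tiles <- tiles[tiles$image_id %in% image_ids, ]
  if (nrow(tiles) == 0) stop("no tiles among the given image ids")
  cc <- table(as_tissue_factor(tiles$label))
  as.numeric(cc) / sum(cc)
}

#' Jensen-Shannon distance between two class distributions
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms, a
#' bounded metric on probability vectors: symmetric, 0 iff the
#' distributions are equal, 1 for disjoint supports.  `0 * log(0)` terms
#' are treated as 0.
#'
#' @param p,q nonnegative numeric vectors of equal length summing to 1.
#' @param base logarithm base (default 2, giving range `[0, 1]`).
#' @return A number in `[0, 1]`.
#' @examples
#' jensen_shannon_distance(c(.5, .5), c(.25, .75))  # ~0.2209
#' @export
jensen_shannon_distance <- function(p, q, base = 2) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop("p and q must each sum to 1")
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i], base = base))
  }
  js <- (kl(p, m) + kl(q, m)) / 2
  sqrt(max(0, min(js, 1)))
}

# distribution of a set of per-image class-count rows; zero tiles -> NULL
.subset_dist <- function(count_mat, ids) {
  if (length(ids) == 0) return(NULL)
  tot <- colSums(count_mat[ids, , drop = FALSE])
  s <- sum(tot)
  if (s == 0) return(NULL)
  tot / s
}

#' Iterative Jensen-Shannon stratified image-level split
#'
#' Partitions the cohort's images into training, validation and test
#' subsets whose tile-level class distributions approximate the full
#' dataset's.  Subsets are filled one at a time (test, then validation;
#' training receives the remainder): images are drawn uniformly at random
#' from the unassigned pool, tentatively added, and kept only if the
#' subset's Jensen-Shannon distance to the full-dataset distribution
#' strictly decreases (the first image of a subset is always kept).  When
#' `stall_limit` consecutive draws have been rejected, the unassigned
#' image whose addition minimizes the distance is accepted instead, which
#' guarantees termination.  After filling, the boundary condition that
#' every class be present in every subset is checked; on failure the whole
#' procedure restarts from a derived seed, up to `max_restarts` times.
#'
#' @param dataset a `tile_dataset` covering the cohort.
#' @param train_frac fraction of images in the training pool
#'   (training + validation; default 0.8, i.e. 64 of 80 images).
#' @param val_frac_of_train fraction of the training pool allocated to
#'   validation (default 0.1; rounded to the nearest whole image).
#' @param seed integer seed controlling the draws.
#' @param stall_limit consecutive rejections before the best candidate is
#'   force-accepted (default 200).
#' @param max_restarts restarts allowed for the boundary condition
#'   (default 25).
#' @return An object of class `split_result`: `train_ids`, `val_ids`,
#'   `test_ids`, per-subset `distributions` and `jsd` (distance to the
#'   full-dataset distribution), the acceptance `trace` (per accepted
#'   image: subset JSD after addition and whether the acceptance was
#'   forced by stall handling), the realized `sizes`, `seed` and a config
#'   echo.
#' @export
iterative_split <- function(dataset, train_frac = 0.8,
                            val_frac_of_train = 0.1, seed = 1L,
                            stall_limit = 200L, max_restarts = 25L) {
  stopifnot(inherits(dataset, "tile_dataset"))
  tiles <- dataset$tiles
  ids <- unique(tiles$image_id)
  n <- length(ids)
  counts <- table(factor(tiles$image_id, levels = ids),
                  as_tissue_factor(tiles$label))
  counts <- matrix(as.integer(counts), nrow = n,
                   dimnames = list(ids, TISSUE_CLASSES))
  total_dist <- colSums(counts) / sum(counts)
  if (any(colSums(counts) == 0)) {
    stop("infeasible boundary condition: class(es) ",
         paste(TISSUE_CLASSES[colSums(counts) == 0], collapse = ", "),
         " absent from the cohort")
  }
  n_pool <- round(train_frac * n)
  n_test <- n - n_pool
  n_val <- round(val_frac_of_train * n_pool)
  n_train <- n_pool - n_val
  if (min(n_test, n_val, n_train) < 1) stop("subset sizes degenerate")

  fill_subset <- function(target, unassigned) {
    chosen <- character(0)
    cur_jsd <- Inf
    stalls <- 0L
    trace <- data.frame(jsd = numeric(0), forced = logical(0))
    while (length(chosen) < target) {
      cand <- if (length(unassigned) == 1) unassigned else
        sample(unassigned, 1)
      d <- .subset_dist(counts, c(chosen, cand))
      new_jsd <- if (is.null(d)) Inf else
        jensen_shannon_distance(d, total_dist)
      accept <- length(chosen) == 0 || new_jsd < cur_jsd
      forced <- FALSE
      if (!accept && stalls >= stall_limit) {
        forced <- TRUE
        # force-accept the candidate minimizing the post-addition JSD
        best <- vapply(unassigned, function(u) {
          du <- .subset_dist(counts, c(chosen, u))
          if (is.null(du)) Inf else jensen_shannon_distance(du, total_dist)
        }, 0)
        cand <- unassigned[which.min(best)]
        d <- .subset_dist(counts, c(chosen, cand))
        new_jsd <- min(best)
        accept <- TRUE
      }
      if (accept) {
        chosen <- c(chosen, cand)
        cur_jsd <- new_jsd
        unassigned <- setdiff(unassigned, cand)
        stalls <- 0L
        trace <- rbind(trace, data.frame(jsd = new_jsd, forced = forced))
      } else {
        stalls <- stalls + 1L
      }
    }
    list(chosen = chosen, unassigned = unassigned, trace = trace)
  }

  for (attempt in 0:max_restarts) {
    attempt_seed <- if (attempt == 0) as.integer(seed) else
      derive_seed(seed, "split-restart", attempt)
    res <- with_local_seed(attempt_seed, {
      s1 <- fill_subset(n_test, ids)
      s2 <- fill_subset(n_val, s1$unassigned)
      list(test = s1$chosen, val = s2$chosen, train = s2$unassigned,
           trace = list(test = s1$trace, val = s2$trace))
    })
    traces <- res$trace
    res$trace <- NULL
    ok <- all(vapply(res, function(sub) {
      d <- colSums(counts[sub, , drop = FALSE])
      all(d > 0)
    }, TRUE))
    if (ok) {
      dists <- lapply(res, function(sub) .subset_dist(counts, sub))
      jsds <- vapply(dists, jensen_shannon_distance, 0, q = total_dist)
      return(structure(
        list(train_ids = res$train, val_ids = res$val,
             test_ids = res$test,
             distributions = c(list(total = total_dist), dists),
             jsd = jsds, trace = traces,
             sizes = c(train = length(res$train), val = length(res$val),
                       test = length(res$test)),
             seed = as.integer(seed), attempt_seed = attempt_seed,
             config = list(train_frac = train_frac,
                           val_frac_of_train = val_frac_of_train,
                           stall_limit = stall_limit,
                           fill_order = c("test", "val", "train"))),
        class = "split_result"
      ))
    }
  }
  stop("infeasible boundary condition: could not place every class in ",
       "every subset within ", max_restarts, " restarts")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> train %d / val %d / test %d images\n",
              x$sizes["train"], x$sizes["val"], x$sizes["test"]))
  cat("JSD to total:",
      paste(sprintf("%s=%.4f", names(x$jsd), x$jsd), collapse = ", "),
      "\n")
  invisible(x)
}

#' Naive uniform-random image split (baseline for the stratified split)
#'
#' Draws subsets of the same sizes as [iterative_split()] but uniformly at
#' random, with no distribution matching.  Used to quantify the benefit of
#' the Jensen-Shannon procedure.
#'
#' @inheritParams iterative_split
#' @return A `split_result` (boundary condition not enforced; `jsd` may be
#'   `NA` for a subset with no tiles).
#' @export
naive_split <- function(dataset, train_frac = 0.8,
                        val_frac_of_train = 0.1, seed = 1L) {
  stopifnot(inherits(dataset, "tile_dataset"))
  tiles <- dataset$tiles
  ids <- unique(tiles$image_id)
  n <- length(ids)
  counts <- table(factor(tiles$image_id, levels = ids),
                  as_tissue_factor(tiles$label))
  counts <- matrix(as.integer(counts), nrow = n,
                   dimnames = list(ids, TISSUE_CLASSES))
  total_dist <- colSums(counts) / sum(counts)
  n_pool <- round(train_frac * n)
  n_test <- n - n_pool
  n_val <- round(val_frac_of_train * n_pool)
  res <- with_local_seed(seed, {
    test <- sample(ids, n_test)
    val <- sample(setdiff(ids, test), n_val)
    list(train = setdiff(ids, c(test, val)), val = val, test = test)
  })
  dists <- lapply(res, function(sub) .subset_dist(counts, sub))
  jsds <- vapply(dists, function(d) {
    if (is.null(d)) NA_real_ else jensen_shannon_distance(d, total_dist)
  }, 0)
  structure(
    list(train_ids = res$train, val_ids = res$val, test_ids = res$test,
         distributions = c(list(total = total_dist), dists), jsd = jsds,
         sizes = vapply(res, length, 0L), seed = as.integer(seed),
         config = list(train_frac = train_frac,
                       val_frac_of_train = val_frac_of_train,
                       method = "naive")),
    class = "split_result"
  )
}

#' Serialize a split result as JSON
#'
#' @param split a `split_result`.
#' @param path output path.
#' @export
write_split_json <- function(split, path) {
  stopifnot(inherits(split, "split_result"))
  obj <- list(
    train_ids = split$train_ids, val_ids = split$val_ids,
    test_ids = split$test_ids,
    distributions = lapply(split$distributions, function(d) {
      setNames(as.list(d), TISSUE_CLASSES)
    }),
    jsd = as.list(split$jsd), sizes = as.list(split$sizes),
    seed = split$seed, config = split$config
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
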