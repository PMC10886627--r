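#' Grid tile origins for an image
#'
#' Non-overlapping tiling: stride equals the tile size, anchored at pixel
#' (0, 0); tiles that would extend past the right or bottom edge are
#' dropped, so the grid is the largest complete partition prefix.
#'
#' @param image_height,image_width image dimensions in pixels.
#' @param tile_size tile edge length in pixels (default 250).
#' @return An m x 2 integer matrix of 0-based `(x, y)` tile origins (empty
#'   when the tile does not fit).
#' @export
tile_grid <- function(image_height, image_width, tile_size = 250) {
  stopifnot(image_height > 0, image_width > 0, tile_size > 0)
  nx <- image_width %/% tile_size
  ny <- image_height %/% tile_size
  if (nx == 0 || ny == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  g <- expand.grid(x = (seq_len(nx) - 1L) * tile_size,
                   y = (seq_len(ny) - 1L) * tile_size)
  as.matrix(g[order(g$y, g$x), , drop = FALSE])
}

#' Rasterize each class's polygon union onto the pixel-center grid
#'
#' Scanline even-odd rasterization: a pixel is covered when its center
#' lies inside the union of the class's polygons.  Pixel `(r, c)`
#' (1-based matrix indices) has center `(c - 0.5, r - 0.5)` in 0-based
#' pixel coordinates.
#'
#' @param aset an [annotation_set].
#' @param image_height,image_width image dimensions in pixels.
#' @return Named list of `image_height x image_width` logical matrices,
#'   one per class present in the set.
#' @export
class_pixel_masks <- function(aset, image_height, image_width) {
  stopifnot(inherits(aset, "annotation_set"))
  cls <- vapply(aset$annotations, function(a) a$tissue_class, "")
  masks <- list()
  for (cl in unique(cls)) {
    polys <- lapply(aset$annotations[cls == cl], function(a) a$rings)
    masks[[cl]] <- .rasterize_polygons(polys, as.integer(image_height),
                                       as.integer(image_width))
  }
  masks
}

#' Per-class coverage fraction of one tile
#'
#' For each tissue class, the fraction of the tile's pixels whose centers
#' lie inside the union of that class's polygons.  Fractions over classes
#' need not sum to 1 (unannotated pixels) and can sum to more than 1
#' (overlapping annotations of different classes).
#'
#' @param origin 0-based `(x, y)` tile corner.
#' @param tile_size tile edge length.
#' @param aset an [annotation_set] (or a precomputed mask list from the
#'   internal batch path).
#' @param image_dim `c(height, width)` of the source image.
#' @return Named numeric vector over the classes present in `aset`.
#' @export
coverage_by_class <- function(origin, tile_size, aset, image_dim) {
  masks <- if (inherits(aset, "annotation_set")) {
    class_pixel_masks(aset, image_dim[1], image_dim[2])
  } else {
    aset
  }
  if (origin[1] < 0 || origin[2] < 0 ||
      origin[1] + tile_size > image_dim[2] ||
      origin[2] + tile_size > image_dim[1]) {
    stop("tile at (", origin[1], ",", origin[2], ") exceeds image bounds")
  }
  rows <- (origin[2] + 1):(origin[2] + tile_size)
  cols <- (origin[1] + 1):(origin[1] + tile_size)
  vapply(masks, function(m) mean(m[rows, cols]), 0)
}

#' Label one tile under the coverage rule
#'
#' A tile is labeled with class `c` iff at least `threshold` (default 0.99)
#' of its pixel centers fall inside the union of class-`c` annotations.
#' A tile where no class reaches the threshold is excluded, as is the
#' (overlapping-annotation) corner case where two classes both reach it,
#' since that would give the learner contradictory label information.
#'
#' @inheritParams coverage_by_class
#' @param threshold labeling coverage threshold in `[0, 1]`.
#' @param image_id id recorded in the returned tile record.
#' @return A one-row data frame (`image_id`, `x`, `y`, `size`, `label`,
#'   `coverage`) for a retained tile, or `NULL` for an excluded one.
#' @export
label_tile <- function(origin, tile_size, aset, image_dim,
                       threshold = 0.99, image_id = NULL) {
  if (inherits(aset, "annotation_set") && is.null(image_id)) {
    image_id <- aset$image_id
  }
  cov <- coverage_by_class(origin, tile_size, aset, image_dim)
  hit <- which(cov >= threshold)
  if (length(hit) != 1) return(NULL)
  data.frame(image_id = image_id, x = as.integer(origin[1]),
             y = as.integer(origin[2]), size = as.integer(tile_size),
             label = names(cov)[hit], coverage = unname(cov[hit]),
             stringsAsFactors = FALSE)
}

#' Build the labeled tile dataset for a cohort
#'
#' Applies [tile_grid()] and the coverage rule to every image and
#' concatenates the retained tiles.  Deterministic given its inputs and
#' independent of annotation order.
#'
#' @param images list of [srs_image] objects (or a list of `c(height,
#'   width)` dimension vectors named by image id).
#' @param annots list of [annotation_set] objects, one per image, in the
#'   same order.
#' @param tile_size tile edge length (default 250).
#' @param threshold coverage threshold (default 0.99).
#' @return An object of class `tile_dataset`: `tiles` (data frame of tile
#'   records), `class_counts` (named integer vector over all six classes),
#'   and `manifest` (per-image retained-tile counts).
#' @export
build_dataset <- function(images, annots, tile_size = 250,
                          threshold = 0.99) {
  stopifnot(length(images) == length(annots))
  all_tiles <- list()
  manifest <- data.frame(image_id = character(0), n_tiles = integer(0))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (inherits(img, "srs_image")) {
      dm <- dim(img)
      iid <- img$image_id
    } else {
      dm <- img
      iid <- names(images)[i] %||% as.character(i)
    }
    aset <- annots[[i]]
    if (inherits(aset, "annotation_set") && nzchar(aset$image_id) &&
        inherits(images[[i]], "srs_image") && aset$image_id != iid) {
      stop("image/annotation id mismatch: '", iid, "' vs '",
           aset$image_id, "'")
    }
    origins <- tile_grid(dm[1], dm[2], tile_size)
    recs <- list()
    if (nrow(origins) > 0 && length(aset$annotations) > 0) {
      masks <- class_pixel_masks(aset, dm[1], dm[2])
      om <- matrix(as.integer(origins), ncol = 2)
      counts <- vapply(masks, function(m) {
        .tile_cover_counts(m, om, as.integer(tile_size))
      }, integer(nrow(origins)))
      counts <- matrix(counts, nrow = nrow(origins))
      cov <- counts / (tile_size * tile_size)
      for (t in seq_len(nrow(origins))) {
        hit <- which(cov[t, ] >= threshold)
        if (length(hit) == 1) {
          recs[[length(recs) + 1L]] <- data.frame(
            image_id = iid, x = origins[t, 1], y = origins[t, 2],
            size = as.integer(tile_size), label = names(masks)[hit],
            coverage = unname(cov[t, hit]), stringsAsFactors = FALSE
          )
        }
      }
    }
    n_kept <- length(recs)
    manifest <- rbind(manifest,
                      data.frame(image_id = iid, n_tiles = n_kept))
    all_tiles <- c(all_tiles, recs)
  }
  tiles <- if (length(all_tiles)) {
    do.call(rbind, all_tiles)
  } else {
    data.frame(image_id = character(0), x = integer(0), y = integer(0),
               size = integer(0), label = character(0),
               coverage = numeric(0))
  }
  if (anyDuplicated(tiles[, c("image_id", "x", "y")])) {
    stop("duplicate (image_id, origin) tile records")  # defensive
  }
  cc <- table(as_tissue_factor(tiles$label))
  structure(list(tiles = tiles,
                 class_counts = setNames(as.integer(cc), names(cc)),
                 manifest = manifest,
                 tile_size = tile_size, threshold = threshold),
            class = "tile_dataset")
}

#' @export
print.tile_dataset <- function(x, ...) {
  cat(sprintf("<tile_dataset> %d tiles from %d image(s), tile %d px\n",
              nrow(x$tiles), nrow(x$manifest), x$tile_size))
  print(x$class_counts)
  invisible(x)
}

#' Extract a tile's pixels from a three-channel or SRH image
#'
#' An exact sub-grid copy (no resampling) of the `size x size` block at the
#' record's origin.
#'
#' @param t a `three_channel_image` or `srh_image`.
#' @param rec one tile record row (from a `tile_dataset`'s `tiles`).
#' @return A `size x size x 3` numeric array.
#' @export
extract_tile_pixels <- function(t, rec) {
  size <- rec$size
  if (inherits(t, "three_channel_image")) {
    planes <- list(t$plane1, t$plane2, t$plane3)
    h <- nrow(t$plane1); w <- ncol(t$plane1)
  } else if (inherits(t, "srh_image")) {
    planes <- list(t$rgb[, , 1], t$rgb[, , 2], t$rgb[, , 3])
    h <- dim(t$rgb)[1]; w <- dim(t$rgb)[2]
  } else {
    stop("expected a three_channel_image or srh_image")
  }
  if (rec$x < 0 || rec$y < 0 || rec$x + size > w || rec$y + size > h) {
    stop("tile record out of image bounds")
  }
  rows <- (rec$y + 1):(rec$y + size)
  cols <- (rec$x + 1):(rec$x + size)
  out <- array(0, dim = c(size, size, 3))
  for (k in 1:3) out[, , k] <- planes[[k]][rows, cols]
  out
}
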