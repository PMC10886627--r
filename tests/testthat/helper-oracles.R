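# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package's scanline/clipping
# paths: point-in-polygon is evaluated per pixel center with the classical
# even-odd crossing test.

# even-odd mask of ONE polygon (outer ring + holes) over the pixel grid
oracle_mask_polygon <- function(rings, h, w) {
  px <- rep(seq_len(w) - 0.5, each = h)
  py <- rep(seq_len(h) - 0.5, times = w)
  cross <- integer(length(px))
  for (r in rings) {
    n <- nrow(r)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- r[i, 1]; y1 <- r[i, 2]; x2 <- r[j, 1]; y2 <- r[j, 2]
      spans <- (y1 > py) != (y2 > py)
      if (any(spans)) {
        xint <- x1 + (py[spans] - y1) * (x2 - x1) / (y2 - y1)
        idx <- which(spans)[px[spans] < xint]
        cross[idx] <- cross[idx] + 1L
      }
    }
  }
  matrix(cross %% 2L == 1L, h, w)
}

# union mask of all polygons of one class in an annotation set
oracle_class_mask <- function(aset, cls, h, w) {
  m <- matrix(FALSE, h, w)
  for (a in aset$annotations) {
    if (a$tissue_class == cls) {
      m <- m | oracle_mask_polygon(a$rings, h, w)
    }
  }
  m
}

# per-class coverage of one tile by per-pixel counting
oracle_coverage <- function(origin, size, aset, h, w) {
  cls <- unique(vapply(aset$annotations, function(a) a$tissue_class, ""))
  rows <- (origin[2] + 1):(origin[2] + size)
  cols <- (origin[1] + 1):(origin[1] + size)
  vapply(cls, function(cl) {
    mean(oracle_class_mask(aset, cl, h, w)[rows, cols])
  }, 0)
}

# full brute-force tiler: rasterizes every class, counts qualifying tiles
oracle_tile_dataset <- function(aset, h, w, tile_size, threshold = 0.99) {
  origins <- tile_grid(h, w, tile_size)
  cls <- unique(vapply(aset$annotations, function(a) a$tissue_class, ""))
  masks <- lapply(cls, oracle_class_mask, aset = aset, h = h, w = w)
  names(masks) <- cls
  out <- NULL
  for (t in seq_len(nrow(origins))) {
    rows <- (origins[t, 2] + 1):(origins[t, 2] + tile_size)
    cols <- (origins[t, 1] + 1):(origins[t, 1] + tile_size)
    cov <- vapply(masks, function(m) mean(m[rows, cols]), 0)
    hit <- which(cov >= threshold)
    if (length(hit) == 1) {
      out <- rbind(out, data.frame(x = origins[t, 1], y = origins[t, 2],
                                   label = names(masks)[hit],
                                   coverage = unname(cov[hit])))
    }
  }
  out
}

# shoelace area of one ring (closing vertex optional)
oracle_shoelace <- function(r) {
  n <- nrow(r)
  if (all(r[1, ] == r[n, ])) r <- r[-n, , drop = FALSE]
  x <- r[, 1]; y <- r[, 2]
  j <- c(seq_len(nrow(r))[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# scalar per-pixel recomputation of the SRH look-up table
oracle_srh_pixel <- function(ch2, ch3, lut) {
  vapply(1:3, function(k) {
    exp(-(lut$gain_h * ch3 * lut$hematoxylin_od[k] +
            lut$gain_e * ch2 * lut$eosin_od[k]))
  }, 0)
}

# convenience constructors
rect_poly <- function(x0, y0, x1, y1) {
  matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE)
}

make_random_srs <- function(id = "img", h = 32, w = 32) {
  q <- function(m) round(m * 65535) / 65535
  srs_image(id, q(matrix(runif(h * w), h, w)), q(matrix(runif(h * w), h, w)))
}
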