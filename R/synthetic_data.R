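# Synthetic SRS specimen generator.
#
# Emulates the statistical structure of a clinical SRS cohort: a set of
# specimen images, each partitioned into a few tissue regions with
# class-specific (CH2, CH3) intensity signatures, texture patterns and
# speckle noise, plus polygon annotations in the same GeoJSON dialect an
# annotation tool would export.  It makes no claim of photorealism; its
# purpose is to exercise every pipeline stage with controllable
# separability.

# Base class signatures on the [0, 1] intensity scale at separation 1.
# The biochemistry is encoded qualitatively: adipose is CH2-dominant
# (lipid), tumor/epithelium/gland are CH3-dominant (protein/DNA-rich),
# stroma and muscle are intermediate with distinct textures.
.base_signatures <- data.frame(
  tissue_class = TISSUE_CLASSES,
  mean_ch2 = c(0.20, 0.50, 0.90, 0.60, 0.30, 0.80),
  mean_ch3 = c(0.90, 0.50, 0.25, 0.70, 0.60, 0.85),
  texture = c("nuclei_dots", "fibrous", "vacuoles", "striations",
              "layered", "ring_glands"),
  texture_scale_px = c(8, 24, 14, 10, 28, 20),
  # texture weight on (ch2, ch3): dominant channel carries the pattern
  tex_w2 = c(0.3, 0.5, 1.0, 0.4, 0.3, 0.4),
  tex_w3 = c(1.0, 0.5, -0.4, 1.0, 1.0, 1.0),
  stringsAsFactors = FALSE
)

#' Per-class intensity/texture signatures
#'
#' @param separation margin scale: signatures are pulled toward (`1`) or
#'   pushed away from their common centroid; larger values make classes
#'   easier to separate.  Default 1.
#' @param noise_sd speckle noise standard deviation (default 0.06).
#' @param hard_mode move the squamous-epithelium signature next to the
#'   tumor signature, emulating the morphological tumor-vs-epithelium
#'   confusion that dominates real data.
#' @return Data frame with one row per tissue class.
#' @export
class_signatures <- function(separation = 1, noise_sd = 0.06,
                             hard_mode = FALSE) {
  sig <- .base_signatures
  c2 <- mean(sig$mean_ch2); c3 <- mean(sig$mean_ch3)
  sig$mean_ch2 <- pmin(pmax(c2 + separation * (sig$mean_ch2 - c2), 0.02),
                       0.98)
  sig$mean_ch3 <- pmin(pmax(c3 + separation * (sig$mean_ch3 - c3), 0.02),
                       0.98)
  if (hard_mode) {
    # emulate the dominant tumor-vs-epithelium confusion of real tissue:
    # carcinoma and normal squamous epithelium become near neighbors in
    # both intensity and texture (nuclear dot pattern at slightly
    # different scale)
    tu <- sig$tissue_class == "tumor"
    sq <- sig$tissue_class == "squamous_epithelium"
    sig$mean_ch2[sq] <- sig$mean_ch2[tu] + 0.02
    sig$mean_ch3[sq] <- sig$mean_ch3[tu] - 0.03
    sig$texture[sq] <- "nuclei_dots"
    sig$texture_scale_px[sq] <- sig$texture_scale_px[tu] + 3
    sig$tex_w2[sq] <- sig$tex_w2[tu]
    sig$tex_w3[sq] <- sig$tex_w3[tu]
  }
  sig$noise_sd <- noise_sd
  sig
}

#' Cohort generation specification
#'
#' Defaults describe the emulated study: 80 specimen images from 8
#' synthetic patients, 1000 x 1000 px, and a target tile-level class
#' mixture of 0.23 tumor, 0.23 stroma, 0.07 adipose, 0.03 muscle, 0.39
#' squamous epithelium and 0.05 glandular.  Each image is partitioned
#' into a few convex-ish polygonal regions (perturbed Voronoi cells) so
#' the tiling module's polygon-coverage path is genuinely exercised,
#' including partial-coverage exclusions at region borders.
#'
#' @param n_images number of specimen images (default 80).
#' @param image_size image edge length in pixels (square; default 1000).
#' @param mixture named target class mixture (must be positive and sum
#'   to 1).
#' @param n_regions_range inclusive range of regions per image.
#' @param separation,noise_sd,hard_mode passed to [class_signatures()].
#' @param image_offset_sd per-image random intensity offset (a crude
#'   inter-patient gain effect).
#' @param shrink,jitter_px region perturbation: cells are shrunk toward
#'   their centroid and vertices jittered, leaving thin unannotated seams.
#' @param n_patients synthetic patient count for the manifest.
#' @param seed master seed for the cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_images = 80, image_size = 1000,
                        mixture = c(tumor = 0.23, stroma = 0.23,
                                    adipose = 0.07, muscle = 0.03,
                                    squamous_epithelium = 0.39,
                                    glandular = 0.05),
                        n_regions_range = c(1, 6), separation = 1,
                        noise_sd = 0.06, hard_mode = FALSE,
                        image_offset_sd = 0.04, shrink = 0.985,
                        jitter_px = 1.5, n_patients = 8,
                        feasibility_tile_px = 250, seed = 1L) {
  mixture <- mixture[TISSUE_CLASSES]
  if (anyNA(mixture) || any(mixture <= 0)) {
    stop("mixture must assign a positive frequency to every class ",
         "(every class is required to be representable)")
  }
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture must sum to 1")
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size), mixture = mixture,
                 n_regions_range = as.integer(n_regions_range),
                 separation = separation, noise_sd = noise_sd,
                 hard_mode = hard_mode, image_offset_sd = image_offset_sd,
                 shrink = shrink, jitter_px = jitter_px,
                 n_patients = as.integer(n_patients),
                 feasibility_tile_px = as.integer(feasibility_tile_px),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Desk-profile cohort specification
#'
#' The CPU-scale variant used throughout the package's experiments: the
#' same 80-image cohort shape at reduced resolution, 384 px images tiled
#' at 64 px (a 6 x 6 complete-tile grid per image, comparable to the
#' 4 x 4 grid of 1000 px images at 250 px tiles), with at most 4 regions
#' per image so regions stay large enough to contribute interior tiles.
#' An 80-image cohort yields on the order of a thousand labeled tiles, so
#' the 3 percent muscle class still receives a workable number of tiles
#' spread over several images.
#'
#' @param ... overrides passed to [cohort_spec()].
#' @export
desk_cohort_spec <- function(...) {
  args <- list(...)
  defaults <- list(image_size = 384, n_regions_range = c(1, 4),
                   feasibility_tile_px = 64)
  do.call(cohort_spec, utils::modifyList(defaults, args))
}

# ---- geometry helpers ----------------------------------------------------

# Sutherland-Hodgman clip of a convex-ish polygon by half-plane ax+by<=c
.clip_halfplane <- function(poly, a, b, cc) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  out <- matrix(0, 0, 2)
  val <- a * poly[, 1] + b * poly[, 2] - cc
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- val[i] <= 0
    pj_in <- val[j] <= 0
    if (pi_in) out <- rbind(out, poly[i, ])
    if (xor(pi_in, pj_in)) {
      t <- val[i] / (val[i] - val[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Voronoi cells of `sites` within the [0,w] x [0,h] canvas
.voronoi_cells <- function(sites, w, h) {
  k <- nrow(sites)
  canvas <- matrix(c(0, 0, w, 0, w, h, 0, h), ncol = 2, byrow = TRUE)
  lapply(seq_len(k), function(i) {
    poly <- canvas
    for (j in seq_len(k)) {
      if (j == i) next
      d <- sites[j, ] - sites[i, ]
      m <- (sites[i, ] + sites[j, ]) / 2
      poly <- .clip_halfplane(poly, d[1], d[2], sum(d * m))
      if (nrow(poly) < 3) break
    }
    poly
  })
}

# ---- texture fields ------------------------------------------------------

# zero-mean-ish periodic fields over the full canvas; amp ~ 0.08
.texture_field <- function(texture, h, w, scale, amp = 0.08) {
  x <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  y <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  th <- runif(1, 0, pi)
  p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  switch(
    texture,
    striations = amp * sin(2 * pi * u / scale + p1),
    layered = amp * sin(2 * pi * v / (2 * scale) + p1) +
      0.4 * amp * sin(2 * pi * u / (6 * scale) + p2),
    fibrous = 0.6 * amp * (sin(2 * pi * u / scale + p1) +
                             sin(2 * pi * v / (1.7 * scale) + p2)),
    nuclei_dots = {
      g <- sin(2 * pi * x / scale + p1) * sin(2 * pi * y / scale + p2)
      amp * 1.5 * (g > 0.55) - amp * 0.3
    },
    vacuoles = {
      g <- sin(2 * pi * x / scale + p1) * sin(2 * pi * y / scale + p2)
      amp * 1.5 * (g > 0.35) - amp * 0.6
    },
    ring_glands = amp * sin(2 * pi * sqrt((x - w * runif(1))^2 +
                                            (y - h * runif(1))^2) / scale),
    stop("unknown texture: ", texture)
  )
}

# ---- specimen / cohort generation ---------------------------------------

# number of regions in image i, drawn from its own deterministic stream
# so that the cohort-wide region numbering is computable per image
.region_count <- function(spec, i) {
  with_local_seed(derive_seed(spec$seed, "region-count", i), {
    sample(seq(spec$n_regions_range[1], spec$n_regions_range[2]), 1)
  })
}

# classes of image i's regions: a golden-ratio low-discrepancy sequence
# over the cohort's global region stream, inverted through the mixture
# CDF.  Realized class counts track the target mixture far more tightly
# than iid draws, so small cohorts still honor the study's imbalance and
# rare classes are spread over many images (which keeps the split's
# every-class-per-subset boundary condition satisfiable).
.region_classes <- function(spec, i, k) {
  offset <- if (i > 1) {
    sum(vapply(seq_len(i - 1), function(j) .region_count(spec, j), 0L))
  } else {
    0L
  }
  u0 <- (derive_seed(spec$seed, "class-stream") %% 104729) / 104729
  phi <- (sqrt(5) - 1) / 2
  u <- (u0 + phi * (offset + seq_len(k))) %% 1
  brk <- cumsum(spec$mixture)
  TISSUE_CLASSES[findInterval(u, c(0, brk[-6]))]
}

#' Generate one synthetic specimen (image + annotations)
#'
#' Deterministic given `(spec$seed, image_index)`.  The canvas is
#' partitioned into perturbed Voronoi cells; each cell is assigned a
#' tissue class (low-discrepancy allocation over the cohort's region
#' stream, so realized class frequencies track the target mixture),
#' filled with its signature's base intensities, texture pattern and
#' Gaussian speckle (clipped into `[0, 1]` and quantized to the TIFF
#' grid), and emitted as one polygon annotation.  Regions of rare classes
#' (target frequency below 0.08) must contain at least two full tiles of
#' `feasibility_tile_px`; layouts are re-drawn until they do, so rare
#' classes survive tiling in enough images for a three-subset split.
#'
#' @param spec a [cohort_spec()].
#' @param image_index 1-based image index within the cohort.
#' @return List with `image` (an [srs_image]) and `annotations` (an
#'   [annotation_set]).
#' @export
generate_specimen <- function(spec, image_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  sig <- class_signatures(spec$separation, spec$noise_sd, spec$hard_mode)
  h <- spec$image_size; w <- spec$image_size
  image_id <- sprintf("synthetic_img%03d", image_index)
  k <- .region_count(spec, image_index)
  classes <- .region_classes(spec, image_index, k)
  rare <- TISSUE_CLASSES[spec$mixture < 0.08]
  with_local_seed(derive_seed(spec$seed, "specimen", image_index), {
    min_area <- (0.02 * h) * (0.02 * w)
    # full-coverage tile capability of a region polygon (feasibility check)
    n_capable_tiles <- function(poly) {
      ts <- spec$feasibility_tile_px
      org <- tile_grid(h, w, ts)
      if (nrow(org) == 0) return(0L)
      m <- .rasterize_polygons(list(list(poly)), h, w)
      cnt <- .tile_cover_counts(m, matrix(as.integer(org), ncol = 2),
                                as.integer(ts))
      sum(cnt >= 0.99 * ts * ts)
    }
    for (retry in 1:40) {
      sites <- cbind(runif(k, 0.1 * w, 0.9 * w), runif(k, 0.1 * h, 0.9 * h))
      cells <- if (k == 1) {
        list(matrix(c(0, 0, w, 0, w, h, 0, h), ncol = 2, byrow = TRUE))
      } else {
        .voronoi_cells(sites, w, h)
      }
      # shrink toward centroid + jitter, clamp to canvas
      cells <- lapply(cells, function(p) {
        if (nrow(p) < 3) return(p)
        ctr <- colMeans(p)
        p <- sweep(p, 2, ctr) * spec$shrink
        p <- sweep(p, 2, ctr, `+`)
        p <- p + matrix(runif(length(p), -spec$jitter_px, spec$jitter_px),
                        ncol = 2)
        p[, 1] <- pmin(pmax(p[, 1], 0), w)
        p[, 2] <- pmin(pmax(p[, 2], 0), h)
        p
      })
      areas <- vapply(cells, function(p) {
        if (nrow(p) < 3) 0 else abs(ring_area(p))
      }, 0)
      if (!all(areas >= min_area)) {
        if (retry == 40) stop("degenerate region layout after 40 retries")
        next
      }
      rare_idx <- which(classes %in% rare)
      if (length(rare_idx) == 0) break
      # rare-class regions must survive tiling; re-draw the layout until
      # each holds at least two full-coverage tiles (best effort)
      ok <- all(vapply(cells[rare_idx], n_capable_tiles, 0L) >= 2L)
      if (ok || retry == 40) break
    }
    # per-pixel means from region fills
    off2 <- rnorm(1, 0, spec$image_offset_sd)
    off3 <- rnorm(1, 0, spec$image_offset_sd)
    m2 <- matrix(0.02, h, w)
    m3 <- matrix(0.02, h, w)
    nsd <- matrix(0.3 * spec$noise_sd, h, w)
    anns <- list()
    for (i in seq_len(k)) {
      mask <- .rasterize_polygons(list(list(cells[[i]])), h, w)
      s <- sig[sig$tissue_class == classes[i], ]
      tex <- .texture_field(s$texture, h, w, s$texture_scale_px)
      m2[mask] <- s$mean_ch2 + s$tex_w2 * tex[mask]
      m3[mask] <- s$mean_ch3 + s$tex_w3 * tex[mask]
      nsd[mask] <- s$noise_sd
      anns[[i]] <- annotation(cells[[i]], classes[i],
                              sprintf("%s_a%03d", image_id, i))
    }
    ch2 <- quantize16(pmin(pmax(m2 + off2 + rnorm(h * w) * nsd, 0), 1))
    ch3 <- quantize16(pmin(pmax(m3 + off3 + rnorm(h * w) * nsd, 0), 1))
    list(image = srs_image(image_id, ch2, ch3),
         annotations = annotation_set(image_id, anns))
  })
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory; when given, each specimen is
#'   written as a 2-channel TIFF + JSON sidecar + GeoJSON annotation
#'   file, plus a cohort `manifest.csv`.
#' @return List with `images` (list of [srs_image]), `annots` (list of
#'   [annotation_set]) and `manifest` (data frame: image_id, patient_id,
#'   n_regions, classes).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  images <- vector("list", spec$n_images)
  annots <- vector("list", spec$n_images)
  manifest <- data.frame(image_id = character(spec$n_images),
                         patient_id = character(spec$n_images),
                         n_regions = integer(spec$n_images),
                         classes = character(spec$n_images),
                         stringsAsFactors = FALSE)
  for (i in seq_len(spec$n_images)) {
    sp <- generate_specimen(spec, i)
    images[[i]] <- sp$image
    annots[[i]] <- sp$annotations
    cls <- vapply(sp$annotations$annotations, function(a) a$tissue_class,
                  "")
    manifest$image_id[i] <- sp$image$image_id
    manifest$patient_id[i] <-
      sprintf("patient%02d", (i - 1) %% spec$n_patients + 1)
    manifest$n_regions[i] <- length(cls)
    manifest$classes[i] <- paste(sort(unique(cls)), collapse = ";")
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(spec$n_images)) {
      id <- images[[i]]$image_id
      write_srs_tiff(images[[i]], file.path(dir, paste0(id, ".tiff")))
      write_annotations(annots[[i]], file.path(dir, paste0(id, ".geojson")))
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(images = images, annots = annots, manifest = manifest)
}
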