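#' Construct a polygon annotation
#'
#' Coordinates are image pixel units: 0-based, origin at the top-left,
#' x rightward, y downward (the convention of image annotation tools such
#' as QuPath).  A polygon is an outer ring plus optional hole rings; rings
#' are n x 2 matrices of (x, y) vertices, closing vertex optional.
#'
#' @param rings list of n x 2 numeric matrices; first ring is the outer
#'   boundary, the rest are holes.
#' @param tissue_class canonical class id (one of [TISSUE_CLASSES]).
#' @param annotation_id character identifier.
#' @return Object of class `annotation`.
#' @export
annotation <- function(rings, tissue_class, annotation_id) {
  if (is.matrix(rings)) rings <- list(rings)
  stopifnot(is.list(rings), length(rings) >= 1)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    stopifnot(ncol(r) == 2)
    # drop an explicit closing vertex
    n <- nrow(r)
    if (n >= 2 && all(r[1, ] == r[n, ])) r <- r[-n, , drop = FALSE]
    r
  })
  if (nrow(rings[[1]]) < 3) stop("outer ring needs at least 3 vertices")
  if (abs(ring_area(rings[[1]])) == 0) stop("outer ring has zero area")
  tissue_class <- normalize_tissue_class(tissue_class)
  structure(list(rings = rings, tissue_class = tissue_class,
                 annotation_id = as.character(annotation_id)),
            class = "annotation")
}

# signed shoelace area of one ring (positive for counter-clockwise in
# standard axes; callers use abs())
ring_area <- function(r) {
  x <- r[, 1]; y <- r[, 2]
  j <- c(seq_len(nrow(r))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon area (outer ring minus holes)
#'
#' @param ann an [annotation].
#' @return Area in square pixels.
#' @export
annotation_area <- function(ann) {
  stopifnot(inherits(ann, "annotation"))
  a <- abs(ring_area(ann$rings[[1]]))
  if (length(ann$rings) > 1) {
    a <- a - sum(vapply(ann$rings[-1], function(r) abs(ring_area(r)), 0))
  }
  a
}

#' Construct an annotation set for one image
#'
#' @param image_id id of the annotated image.
#' @param annotations list of [annotation] objects (may be empty).
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(image_id, annotations = list()) {
  stopifnot(is.character(image_id), length(image_id) == 1)
  stopifnot(all(vapply(annotations, inherits, TRUE, "annotation")))
  structure(list(image_id = image_id, annotations = annotations),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cls <- vapply(x$annotations, function(a) a$tissue_class, "")
  cat(sprintf("<annotation_set '%s'> %d annotation(s)\n", x$image_id,
              length(x$annotations)))
  if (length(cls)) print(table(as_tissue_factor(cls)))
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$annotations)

# ---- GeoJSON (QuPath dialect) -------------------------------------------

.feature_class_name <- function(feat) {
  props <- feat$properties
  nm <- props$classification$name %||% props$name
  if (is.null(nm)) stop("feature has no classification name")
  nm
}

# GeoJSON polygon coordinates -> list of ring matrices
.coords_to_rings <- function(coords) {
  lapply(coords, function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    m
  })
}

#' Load annotations from a QuPath-dialect GeoJSON file
#'
#' Reads a GeoJSON FeatureCollection in which each feature carries a
#' Polygon or MultiPolygon geometry and a tissue-class name under
#' `properties.classification.name` (with `properties.name` accepted as a
#' fallback).  Each polygon part of a MultiPolygon becomes its own
#' [annotation].  Class names are matched case-insensitively through a
#' documented alias table (see [normalize_tissue_class()]).
#'
#' @param path GeoJSON file path.
#' @param image_id id to attach to the returned set (default: file stem).
#' @param image_bounds optional `c(height, width)`; vertex coordinates are
#'   clipped into these bounds when given.
#' @param strict if `TRUE` (default) an unknown class name is an error;
#'   otherwise the feature is skipped with a warning.
#' @return An [annotation_set].
#' @export
load_annotations <- function(path, image_id = NULL, image_bounds = NULL,
                             strict = TRUE) {
  gj <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop("malformed GeoJSON in ", path,
                                          ": ", conditionMessage(e)))
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection in ", path)
  }
  image_id <- image_id %||% sub("\\.geojson$", "", basename(path))
  anns <- list()
  for (feat in gj$features) {
    nm <- .feature_class_name(feat)
    cls <- normalize_tissue_class(nm, strict = strict)
    if (is.na(cls)) {
      warning("skipping annotation with unknown class '", nm, "'")
      next
    }
    geom <- feat$geometry
    aid <- feat$id %||% feat$properties$id %||%
      sprintf("%s_a%03d", image_id, length(anns) + 1L)
    parts <- switch(
      geom$type,
      Polygon = list(.coords_to_rings(geom$coordinates)),
      MultiPolygon = lapply(geom$coordinates, .coords_to_rings),
      stop("unsupported geometry type '", geom$type,
           "'; only Polygon and MultiPolygon are accepted")
    )
    for (k in seq_along(parts)) {
      rings <- parts[[k]]
      if (!is.null(image_bounds)) {
        rings <- lapply(rings, function(r) {
          r[, 1] <- pmin(pmax(r[, 1], 0), image_bounds[2])
          r[, 2] <- pmin(pmax(r[, 2], 0), image_bounds[1])
          r
        })
      }
      pid <- if (length(parts) > 1) paste0(aid, "_p", k) else aid
      anns[[length(anns) + 1L]] <- annotation(rings, cls, pid)
    }
  }
  annotation_set(image_id, anns)
}

#' Write an annotation set as QuPath-dialect GeoJSON
#'
#' Emits one Polygon feature per annotation with the class name under
#' `properties.classification.name`, so files written here are read back
#' by [load_annotations()] in strict mode (and are structured like QuPath
#' exports).
#'
#' @param aset an [annotation_set].
#' @param path output file path.
#' @export
write_annotations <- function(aset, path) {
  stopifnot(inherits(aset, "annotation_set"))
  feats <- lapply(aset$annotations, function(a) {
    coords <- lapply(a$rings, function(r) {
      r <- rbind(r, r[1, ])  # close the ring
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(
      type = "Feature",
      id = a$annotation_id,
      geometry = list(type = "Polygon", coordinates = coords),
      properties = list(
        classification = list(name = a$tissue_class),
        object_type = "annotation"
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Transfer annotations between co-registered images
#'
#' SRH renders are generated pixel-for-pixel from their SRS source, so
#' annotations drawn on one modality apply to the other unchanged; the
#' transfer is an identity map on coordinates, only the image id changes.
#'
#' @param src an [annotation_set].
#' @param target_image_id id of the co-registered target image.
#' @param src_dim,target_dim optional `c(height, width)` pairs; when both
#'   are given they must be identical.
#' @return An [annotation_set] for the target image.
#' @export
transfer_annotations <- function(src, target_image_id, src_dim = NULL,
                                 target_dim = NULL) {
  stopifnot(inherits(src, "annotation_set"))
  if (!is.null(src_dim) && !is.null(target_dim) &&
      !all(src_dim == target_dim)) {
    stop("cannot transfer annotations between images of different size (",
         paste(src_dim, collapse = "x"), " vs ",
         paste(target_dim, collapse = "x"), ")")
  }
  annotation_set(target_image_id, src$annotations)
}
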