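#' Confusion matrix over the six tissue classes
#'
#' Rows are true classes, columns predicted classes, both in the canonical
#' internal order ([TISSUE_CLASSES]).
#'
#' @param true_labels,pred_labels equal-length vectors of class names,
#'   factors or indices.
#' @return A 6 x 6 integer matrix with class dimnames.
#' @export
confusion_matrix <- function(true_labels, pred_labels) {
  if (length(true_labels) == 0) stop("empty label vectors")
  if (length(true_labels) != length(pred_labels)) {
    stop("label vectors differ in length (", length(true_labels), " vs ",
         length(pred_labels), ")")
  }
  to_f <- function(x) {
    if (is.numeric(x)) x <- TISSUE_CLASSES[x]
    f <- as_tissue_factor(as.character(x))
    if (anyNA(f)) {
      stop("unknown label(s): ",
           paste(unique(as.character(x)[is.na(f)]), collapse = ", "))
    }
    f
  }
  tb <- table(true = to_f(true_labels), predicted = to_f(pred_labels))
  matrix(as.integer(tb), nrow = length(TISSUE_CLASSES),
         dimnames = list(true = TISSUE_CLASSES,
                         predicted = TISSUE_CLASSES))
}

#' Per-class precision and recall from a confusion matrix
#'
#' Precision is the class's diagonal count over its column sum (true
#' positives over all positive predictions); recall is the diagonal count
#' over its row sum (true positives over all true members).  A zero
#' denominator yields 0 with a warning, so reports on degenerate test sets
#' never crash.
#'
#' @param cm a [confusion_matrix()].
#' @param class class name or index; `NULL` (default) returns all classes.
#' @return A list with numeric vectors `precision` and `recall`.
#' @export
precision_recall <- function(cm, class = NULL) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  safe_div <- function(num, den, what, cl) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warning(what, " undefined (zero denominator) for class(es) ",
              paste(cl[den == 0], collapse = ", "), "; reported as 0")
    }
    out
  }
  cls <- rownames(cm)
  prec <- safe_div(diag(cm), colSums(cm), "precision", cls)
  rec <- safe_div(diag(cm), rowSums(cm), "recall", cls)
  names(prec) <- names(rec) <- cls
  if (!is.null(class)) {
    prec <- prec[class]
    rec <- rec[class]
  }
  list(precision = prec, recall = rec)
}

#' F1 score (harmonic mean of precision and recall)
#'
#' `F1 = 2 P R / (P + R)`, defined as 0 when `P + R = 0`.
#'
#' @param precision,recall numbers (or vectors) in `[0, 1]`.
#' @return F1 value(s) in `[0, 1]`.
#' @examples
#' f1_score(0.86, 0.90)  # 0.88 to two decimals
#' @export
f1_score <- function(precision, recall) {
  s <- precision + recall
  ifelse(s > 0, 2 * precision * recall / s, 0)
}

#' Balanced accuracy: the unweighted mean of per-class recalls
#'
#' @param recalls numeric vector of per-class recall values in `[0, 1]`.
#' @return Their arithmetic mean.
#' @export
balanced_accuracy <- function(recalls) {
  stopifnot(all(recalls >= 0 & recalls <= 1))
  mean(recalls)
}

#' Misclassification fraction between a pair of classes
#'
#' `cm[a, b] / rowsum(a)`: the fraction of true class-`a` tiles predicted
#' as class `b`.
#'
#' @param cm a [confusion_matrix()].
#' @param true_class,pred_class class names or indices.
#' @return A fraction in `[0, 1]`.
#' @export
misclassification_fraction <- function(cm, true_class, pred_class) {
  rs <- sum(cm[true_class, ])
  if (rs == 0) return(0)
  cm[true_class, pred_class] / rs
}

#' Evaluate a trained model on a test tile set
#'
#' Composes [predict_tiles()], [confusion_matrix()] and the per-class
#' metrics into an evaluation report.  Deterministic given model and
#' tiles.
#'
#' @param model a trained `cnn_model`.
#' @param X test tile matrix ([tiles_to_matrix()] layout).
#' @param y true labels (names, factor or indices).
#' @return An `evaluation_report`: `confusion` (6 x 6 matrix), per-class
#'   `precision`, `recall`, `f1`, `n_tiles`, and `balanced_accuracy`.
#' @export
evaluate <- function(model, X, y) {
  if (nrow(X) == 0) stop("empty test set")
  pred <- predict_tiles(model, X)
  report_from_labels(y, pred$labels)
}

#' Build an evaluation report directly from label vectors
#'
#' @param true_labels,pred_labels vectors accepted by
#'   [confusion_matrix()].
#' @return An `evaluation_report` (see [evaluate()]).
#' @export
report_from_labels <- function(true_labels, pred_labels) {
  cm <- confusion_matrix(true_labels, pred_labels)
  pr <- suppressWarnings(precision_recall(cm))
  structure(
    list(confusion = cm, precision = pr$precision, recall = pr$recall,
         f1 = f1_score(pr$precision, pr$recall),
         n_tiles = rowSums(cm),
         balanced_accuracy = balanced_accuracy(pr$recall)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  df <- data.frame(precision = round(x$precision, 2),
                   recall = round(x$recall, 2), f1 = round(x$f1, 2),
                   n_tiles = x$n_tiles)
  print(df)
  cat(sprintf("balanced accuracy: %.2f\n", x$balanced_accuracy))
  invisible(x)
}

# display order used for rendered reports (most abundant benign classes
# first, tumor last), distinct from the internal enum order
.report_display_order <- c("stroma", "adipose", "squamous_epithelium",
                           "muscle", "glandular", "tumor")

#' Write an evaluation report to disk
#'
#' Emits a metrics CSV (two-decimal rounding, display order: stroma,
#' adipose, squamous epithelium, muscle, glandular, tumor), a
#' confusion-matrix CSV, a machine-readable full-precision JSON, and a
#' confusion-matrix heat-map PNG (dark-blue-to-dark-red diverging map,
#' drawn directly as pixels).  An optional tile overlay PNG draws
#' ground-truth vs predicted tile labels over an SRH render.
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"report"`).
#' @param overlay optional list with `srh` (an `srh_image`), `tiles` (tile
#'   records for that image) and `pred_labels`.
#' @return Invisibly, the vector of files written.
#' @export
render_report <- function(report, dir, prefix = "report",
                          overlay = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  ord <- .report_display_order
  metrics <- data.frame(
    class = ord,
    precision = round(report$precision[ord], 2),
    recall = round(report$recall[ord], 2),
    f1 = round(report$f1[ord], 2),
    n_tiles = report$n_tiles[ord]
  )
  f <- file.path(dir, paste0(prefix, "_metrics.csv"))
  write.csv(metrics, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, paste0(prefix, "_confusion.csv"))
  write.csv(as.data.frame(report$confusion), f)
  files <- c(files, f)
  f <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(
    list(precision = as.list(report$precision),
         recall = as.list(report$recall), f1 = as.list(report$f1),
         n_tiles = as.list(report$n_tiles),
         balanced_accuracy = report$balanced_accuracy,
         confusion = report$confusion),
    f, auto_unbox = TRUE, digits = NA
  )
  files <- c(files, f)
  f <- file.path(dir, paste0(prefix, "_confusion.png"))
  write_png(.confusion_heatmap(report$confusion), f)
  files <- c(files, f)
  if (!is.null(overlay)) {
    f <- file.path(dir, paste0(prefix, "_overlay.png"))
    write_png(.tile_overlay(overlay$srh, overlay$tiles,
                            overlay$pred_labels), f)
    files <- c(files, f)
  }
  invisible(files)
}

# diverging colormap heat map rendered directly as an RGB pixel array
# (cell_px pixels per matrix cell); avoids any graphics device
.confusion_heatmap <- function(cm, cell_px = 40) {
  k <- nrow(cm)
  v <- cm / max(cm, 1)
  lo <- c(0.03, 0.19, 0.42)   # dark blue
  mid <- c(0.97, 0.97, 0.96)  # near white
  hi <- c(0.55, 0.06, 0.15)   # dark red
  img <- array(0, dim = c(k * cell_px, k * cell_px, 3))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    t <- v[i, j]
    col <- if (t < 0.5) lo + (mid - lo) * (t / 0.5) else
      mid + (hi - mid) * ((t - 0.5) / 0.5)
    rows <- ((i - 1) * cell_px + 1):(i * cell_px)
    cols <- ((j - 1) * cell_px + 1):(j * cell_px)
    for (ch in 1:3) img[rows, cols, ch] <- col[ch]
  }
  img
}

# fixed display colors per class for tile overlays
.class_colors <- matrix(
  c(0.85, 0.10, 0.10,   # tumor - red
    0.95, 0.75, 0.20,   # stroma - amber
    0.55, 0.35, 0.75,   # adipose - purple
    0.80, 0.35, 0.10,   # muscle - brown
    0.15, 0.55, 0.85,   # squamous epithelium - blue
    0.15, 0.65, 0.35),  # glandular - green
  ncol = 3, byrow = TRUE, dimnames = list(TISSUE_CLASSES, NULL)
)

# draw tile label frames over an SRH render; left half of the top border
# shows the true class, the right half the predicted class
.tile_overlay <- function(srh, tiles, pred_labels, border = 3) {
  img <- srh$rgb
  for (t in seq_len(nrow(tiles))) {
    rec <- tiles[t, ]
    rows <- (rec$y + 1):(rec$y + rec$size)
    cols <- (rec$x + 1):(rec$x + rec$size)
    tcol <- .class_colors[as.character(rec$label), ]
    pcol <- .class_colors[as.character(pred_labels[t]), ]
    b <- seq_len(border)
    for (ch in 1:3) {
      img[rows[b], cols, ch] <- tcol[ch]                      # top: true
      img[rows[length(rows) + 1 - b], cols, ch] <- pcol[ch]   # bottom: pred
      img[rows, cols[b], ch] <- tcol[ch]
      img[rows, cols[length(cols) + 1 - b], ch] <- pcol[ch]
    }
  }
  img
}
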