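#' Classifier model configuration
#'
#' The default configuration mirrors the study design this pipeline
#' re-implements: a VGG19-style backbone taking `(250, 250, 3)` tiles,
#' a head of two fully connected layers (1000 and 100 neurons) with a
#' dropout layer (probability 0.5) between them, a 6-way softmax output,
#' and training for 100 epochs with batch size 100 at learning rate 1e-4
#' with random horizontal/vertical flip augmentation and class-weighted
#' cross-entropy.  The `small_cnn` backbone is a thin four-block conv/pool
#' stack for reduced tile sizes (e.g. 64 x 64), suitable for CPU-scale
#' runs; see [desk_profile_config()].
#'
#' @param tile_size input tile edge length (input is
#'   `(tile_size, tile_size, 3)`).
#' @param backbone `"vgg19_full"` (16 conv layers, widths 64-512) or
#'   `"small_cnn"` (4 conv/pool blocks, widths 8-32).
#' @param n_classes number of output classes (6).
#' @param learning_rate,batch_size,epochs Adam optimizer settings.
#' @param dropout dropout probability between the two head layers.
#' @param augment apply random flips during training.
#' @param seed weight-initialization / training seed.
#' @return A `model_config` list.
#' @export
model_config <- function(tile_size = 250,
                         backbone = c("vgg19_full", "small_cnn"),
                         n_classes = 6, learning_rate = 1e-4,
                         batch_size = 100, epochs = 100, dropout = 0.5,
                         augment = TRUE, seed = 1L) {
  backbone <- match.arg(backbone)
  stopifnot(tile_size > 0, learning_rate > 0, batch_size > 0, epochs >= 1,
            dropout >= 0, dropout < 1)
  structure(list(tile_size = as.integer(tile_size), backbone = backbone,
                 n_classes = as.integer(n_classes),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 augment = augment, seed = as.integer(seed)),
            class = "model_config")
}

#' CPU-scale desk-profile configuration
#'
#' The configuration used for the package's synthetic-cohort experiments:
#' 64 x 64 tiles, the `small_cnn` backbone, 18 epochs at learning rate
#' 1e-3 with batch size 32 (a few hundred training tiles need a smaller
#' batch than the full-size profile to get a useful number of optimizer
#' steps).  The full-size profile ([model_config()] defaults) is
#' available but compute-heavy.
#'
#' @param ... overrides passed on to [model_config()].
#' @export
desk_profile_config <- function(...) {
  args <- list(...)
  defaults <- list(tile_size = 64, backbone = "small_cnn",
                   learning_rate = 1e-3, epochs = 20, batch_size = 16)
  do.call(model_config, utils::modifyList(defaults, args))
}

# backbone layer lists -----------------------------------------------------

.backbone_layers <- function(backbone) {
  conv <- function(f) list(type = "conv", filters = f)
  pool <- list(type = "pool")
  if (backbone == "vgg19_full") {
    c(lapply(c(64, 64), conv), list(pool),
      lapply(c(128, 128), conv), list(pool),
      lapply(c(256, 256, 256, 256), conv), list(pool),
      lapply(c(512, 512, 512, 512), conv), list(pool),
      lapply(c(512, 512, 512, 512), conv), list(pool))
  } else {
    c(list(conv(8), pool, conv(16), pool, conv(32), pool, conv(32), pool))
  }
}

.model_arch <- function(cfg) {
  layers <- c(
    .backbone_layers(cfg$backbone),
    list(list(type = "dense", units = 1000L),
         list(type = "dropout", p = cfg$dropout),
         list(type = "dense", units = 100L),
         list(type = "output", units = cfg$n_classes))
  )
  list(input = c(cfg$tile_size, cfg$tile_size, 3L), layers = layers)
}

#' Build an untrained CNN
#'
#' Instantiates the backbone + head with randomly initialized weights
#' (He-normal, no pretraining) from the configuration's seed; the same
#' seed yields bit-identical initial parameters.
#'
#' @param cfg a [model_config()].
#' @return An object of class `cnn_model` (architecture, parameters,
#'   config echo).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  if (cfg$backbone == "small_cnn" && cfg$tile_size %% 16 != 0) {
    stop("small_cnn downsamples by 16; tile_size must be a multiple of 16")
  }
  if (cfg$tile_size < 32) {
    stop("input size incompatible with backbone downsampling")
  }
  arch <- .model_arch(cfg)
  params <- .cnn_init(arch, cfg$seed)
  structure(list(arch = arch, params = params, cfg = cfg, trained = FALSE),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model %s> input %dx%dx3, %strained\n",
              x$cfg$backbone, x$cfg$tile_size, x$cfg$tile_size,
              if (x$trained) "" else "un"))
  invisible(x)
}

#' Class weights from a class distribution
#'
#' Inverse-frequency weights `w_c = 1 / (K * p_c)` with `K` the number of
#' classes, normalized so that the expected weight under the training
#' distribution is 1 (`sum(p * w) = 1`), which keeps the weighted loss on
#' the same scale as the unweighted one.
#'
#' @param dist nonnegative class frequencies summing to 1; every class
#'   must be present (`p_c > 0`).
#' @return Numeric weight vector, named like `dist`.
#' @export
compute_class_weights <- function(dist) {
  if (any(dist <= 0)) {
    stop("class weight undefined for zero-frequency class(es): ",
         paste(which(dist <= 0), collapse = ", "))
  }
  if (abs(sum(dist) - 1) > 1e-9) stop("dist must sum to 1")
  1 / (length(dist) * dist)
}

#' Random flip augmentation of one tile
#'
#' Applies an independent 0.5-probability horizontal flip and vertical
#' flip.  The pixel-value multiset and the label are untouched.  Uses the
#' R RNG stream, so wrap in `set.seed()` for reproducibility.
#'
#' @param tile a `size x size x 3` array.
#' @return The (possibly flipped) tile.
#' @export
augment_tile <- function(tile) {
  if (runif(1) < 0.5) tile <- tile[, dim(tile)[2]:1, , drop = FALSE]
  if (runif(1) < 0.5) tile <- tile[dim(tile)[1]:1, , , drop = FALSE]
  tile
}

#' Flatten tiles into the model's input matrix
#'
#' Converts a list of `s x s x 3` arrays into the `n x (3 s^2)` matrix the
#' network consumes (channel-planar, row-major spatial layout).
#'
#' @param tiles list of tile arrays.
#' @return Numeric matrix with one row per tile.
#' @export
tiles_to_matrix <- function(tiles) {
  stopifnot(length(tiles) >= 1)
  d <- dim(tiles[[1]])
  X <- matrix(0, length(tiles), prod(d))
  for (i in seq_along(tiles)) {
    X[i, ] <- as.vector(aperm(tiles[[i]], c(2, 1, 3)))
  }
  X
}

#' Train the CNN with class-weighted cross-entropy
#'
#' Minimizes class-weighted cross-entropy with Adam; tiles are randomly
#' flipped each epoch when `cfg$augment` is on; dropout is active during
#' training only.  The final-epoch weights are returned (no early
#' stopping); per-epoch validation metrics are logged for audit.
#'
#' @param model an untrained [build_model()] output.
#' @param X,y training tiles ([tiles_to_matrix()] layout) and integer
#'   labels `1..K` (or a factor over [TISSUE_CLASSES]).
#' @param weights class weights from [compute_class_weights()] (default:
#'   uniform).
#' @param Xval,yval optional validation tiles/labels.
#' @return A trained `cnn_model` carrying `history` (per-epoch loss and
#'   accuracy).
#' @export
train <- function(model, X, y, weights = NULL, Xval = NULL, yval = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  cfg <- model$cfg
  y <- .as_label_index(y, cfg$n_classes)
  if (length(unique(y)) < cfg$n_classes) {
    stop("training set is missing ", cfg$n_classes - length(unique(y)),
         " class(es); every class must be present")
  }
  if (is.null(weights)) weights <- rep(1, cfg$n_classes)
  if (is.null(Xval)) {
    Xval <- matrix(0, 0, ncol(X))
    yval <- integer(0)
  } else {
    yval <- .as_label_index(yval, cfg$n_classes)
  }
  fit <- .cnn_train(model$arch, model$params, X, y - 1L, weights, Xval,
                    yval - 1L, cfg$epochs, cfg$batch_size,
                    cfg$learning_rate, derive_seed(cfg$seed, "train"),
                    cfg$augment)
  history <- as.data.frame(fit$history)
  names(history) <- c("epoch", "train_loss", "train_acc", "val_loss",
                      "val_acc")
  model$params <- fit$params
  model$history <- history
  model$trained <- TRUE
  model
}

.as_label_index <- function(y, n_classes) {
  if (is.factor(y)) y <- as.integer(y)
  if (is.character(y)) y <- as.integer(as_tissue_factor(y))
  y <- as.integer(y)
  if (anyNA(y) || any(y < 1) || any(y > n_classes)) {
    stop("labels must be class indices 1..", n_classes,
         " or names from the tissue vocabulary")
  }
  y
}

#' Predict class probabilities and labels for tiles
#'
#' Inference is deterministic (dropout off); the hard label is the argmax
#' with ties broken toward the lowest class index.
#'
#' @param model a trained `cnn_model`.
#' @param X tile matrix ([tiles_to_matrix()] layout).
#' @return List with `probs` (`n x K` matrix, rows sum to 1) and `labels`
#'   (factor over [TISSUE_CLASSES] when `K == 6`, else integer indices).
#' @export
predict_tiles <- function(model, X) {
  stopifnot(inherits(model, "cnn_model"))
  probs <- .cnn_forward(model$arch, model$params, X)
  idx <- max.col(probs, ties.method = "first")
  labels <- if (model$cfg$n_classes == length(TISSUE_CLASSES)) {
    factor(TISSUE_CLASSES[idx], levels = TISSUE_CLASSES)
  } else {
    idx
  }
  colnames(probs) <- if (model$cfg$n_classes == length(TISSUE_CLASSES)) {
    TISSUE_CLASSES
  } else {
    NULL
  }
  list(probs = probs, labels = labels)
}
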