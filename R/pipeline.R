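#' End-to-end pipeline configuration
#'
#' Bundles every stage parameter: cohort generation, modality, tiling,
#' splitting, model and rendering.  All stage randomness is derived
#' deterministically from the master `seed` (see [derive_seed()]), so any
#' stage can be re-run in isolation.  Defaults are the CPU-scale desk
#' profile; pass a full-size [cohort_spec()] / [model_config()] for the
#' 250-px VGG19 profile.
#'
#' @param modality `"srs"` (three-channel CH2/CH3/difference tensors) or
#'   `"srh"` (virtual-H&E RGB renders).  Both modalities share identical
#'   tiling and split, since annotations transfer one-to-one.
#' @param cohort a [cohort_spec()] (default [desk_cohort_spec()]).
#' @param tile_size,threshold tiling parameters.
#' @param train_frac,val_frac_of_train split fractions.
#' @param model a [model_config()] (default [desk_profile_config()]).
#' @param lut_params SRH look-up-table parameters.
#' @param normalize_strategy input scaling for the SRS tensor.
#' @param max_train_tiles optional cap on training tiles (subsampled
#'   deterministically) to bound CPU time; `Inf` disables.
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(modality = c("srs", "srh"), cohort = NULL,
                            tile_size = 64, threshold = 0.99,
                            train_frac = 0.8, val_frac_of_train = 0.1,
                            model = NULL, lut_params = srh_lut_params(),
                            normalize_strategy = "min_subtract_fixed_range",
                            max_train_tiles = Inf, seed = 1L) {
  modality <- match.arg(modality)
  cohort <- cohort %||% desk_cohort_spec(seed = derive_seed(seed, "cohort"))
  model <- model %||%
    desk_profile_config(tile_size = tile_size,
                        seed = derive_seed(seed, "model"))
  if (model$tile_size != tile_size) {
    stop("model tile_size (", model$tile_size,
         ") must equal the tiling tile_size (", tile_size, ")")
  }
  structure(list(modality = modality, cohort = cohort,
                 tile_size = as.integer(tile_size), threshold = threshold,
                 train_frac = train_frac,
                 val_frac_of_train = val_frac_of_train, model = model,
                 lut_params = lut_params,
                 normalize_strategy = normalize_strategy,
                 max_train_tiles = max_train_tiles,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  plain <- rapply(unclass(cfg), function(x) x, how = "list")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  # cohort_spec stores the mixture in canonical class order; YAML scalar
  # sequences drop vector names, so restore them positionally
  y$cohort$mixture <- setNames(unlist(y$cohort$mixture), TISSUE_CLASSES)
  y$cohort$n_regions_range <- unlist(y$cohort$n_regions_range)
  cohort <- do.call(cohort_spec, y$cohort)
  model <- do.call(model_config, y$model)
  pipeline_config(
    modality = y$modality, cohort = cohort, tile_size = y$tile_size,
    threshold = y$threshold, train_frac = y$train_frac,
    val_frac_of_train = y$val_frac_of_train, model = model,
    lut_params = y$lut_params,
    normalize_strategy = y$normalize_strategy,
    max_train_tiles = y$max_train_tiles %||% Inf, seed = y$seed
  )
}

# convert one specimen to the modality's pixel source
.convert_image <- function(img, cfg) {
  if (cfg$modality == "srs") {
    normalize_for_model(build_three_channel(img),
                        strategy = cfg$normalize_strategy)
  } else {
    render_srh(img, cfg$lut_params)
  }
}

# assemble the tile matrix + labels for a set of image ids
.assemble_tiles <- function(dataset, converted, ids) {
  recs <- dataset$tiles[dataset$tiles$image_id %in% ids, , drop = FALSE]
  if (nrow(recs) == 0) {
    return(list(X = matrix(0, 0, 0), y = integer(0), records = recs))
  }
  tiles <- lapply(seq_len(nrow(recs)), function(i) {
    extract_tile_pixels(converted[[recs$image_id[i]]], recs[i, ])
  })
  list(X = tiles_to_matrix(tiles),
       y = as.integer(as_tissue_factor(recs$label)), records = recs)
}

#' Run the full pipeline: generate, convert, tile, split, train, evaluate
#'
#' Executes every stage on one cohort and writes each stage's outputs
#' under `out_dir`: the resolved config (YAML), the cohort (TIFF +
#' GeoJSON + manifest, unless `materialize = FALSE`), the tile manifest
#' CSV, the split JSON, the training history CSV, and the evaluation
#' report (metrics CSV, confusion CSV/PNG, JSON, a sample tile-overlay
#' PNG) plus a structured run log.  Runs on the `srs` and `srh`
#' modalities from the same master seed share the identical tile manifest
#' and split and differ only in tile pixel content.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory.
#' @param materialize write the cohort's TIFF/GeoJSON files (default
#'   `TRUE`; the in-memory cohort is used either way).
#' @return List with `cohort`, `dataset`, `split`, `weights`, `model`
#'   (trained), `report` and `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir = tempfile("ramanhisto_run_"),
                         materialize = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run_log.txt")
  log_line <- function(stage, ...) {
    msg <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                   paste0(..., collapse = ""))
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           " (partial outputs in ", out_dir, ")", call. = FALSE)
    })
  }
  write_pipeline_config(cfg, file.path(out_dir, "config.yaml"))

  log_line("generate", "cohort of ", cfg$cohort$n_images, " images, seed ",
           cfg$cohort$seed)
  cohort <- run_stage("generate", {
    generate_cohort(cfg$cohort,
                    dir = if (materialize) file.path(out_dir, "cohort"))
  })

  log_line("convert", "modality ", cfg$modality)
  converted <- run_stage("convert", {
    out <- lapply(cohort$images, .convert_image, cfg = cfg)
    names(out) <- vapply(cohort$images, function(i) i$image_id, "")
    out
  })

  log_line("tile", "tile ", cfg$tile_size, " px, threshold ",
           cfg$threshold)
  dataset <- run_stage("tile", {
    build_dataset(cohort$images, cohort$annots, cfg$tile_size,
                  cfg$threshold)
  })
  write.csv(dataset$tiles, file.path(out_dir, "tile_manifest.csv"),
            row.names = FALSE)
  log_line("tile", nrow(dataset$tiles), " tiles; counts: ",
           paste(names(dataset$class_counts), dataset$class_counts,
                 sep = "=", collapse = " "))

  split <- run_stage("split", {
    iterative_split(dataset, cfg$train_frac, cfg$val_frac_of_train,
                    seed = derive_seed(cfg$seed, "split"))
  })
  write_split_json(split, file.path(out_dir, "split.json"))
  log_line("split", "train/val/test = ",
           paste(split$sizes, collapse = "/"), "; JSD = ",
           paste(sprintf("%.4f", split$jsd), collapse = "/"))

  sets <- run_stage("extract", {
    tr <- .assemble_tiles(dataset, converted, split$train_ids)
    if (is.finite(cfg$max_train_tiles) &&
        nrow(tr$X) > cfg$max_train_tiles) {
      keep <- with_local_seed(derive_seed(cfg$seed, "subsample"),
                              sample(nrow(tr$X), cfg$max_train_tiles))
      tr$X <- tr$X[keep, , drop = FALSE]
      tr$y <- tr$y[keep]
      tr$records <- tr$records[keep, , drop = FALSE]
    }
    list(train = tr,
         val = .assemble_tiles(dataset, converted, split$val_ids),
         test = .assemble_tiles(dataset, converted, split$test_ids))
  })

  weights <- compute_class_weights(
    class_distribution(dataset, split$train_ids))
  log_line("train", cfg$model$backbone, ", ", nrow(sets$train$X),
           " train tiles, ", cfg$model$epochs, " epochs")
  model <- run_stage("train", {
    m <- build_model(cfg$model)
    train(m, sets$train$X, sets$train$y, weights = weights,
          Xval = sets$val$X, yval = sets$val$y)
  })
  write.csv(model$history, file.path(out_dir, "training_history.csv"),
            row.names = FALSE)

  log_line("evaluate", nrow(sets$test$X), " test tiles")
  report <- run_stage("evaluate", {
    evaluate(model, sets$test$X, sets$test$y)
  })
  overlay <- run_stage("report", {
    oid <- sets$test$records$image_id[1]
    recs <- sets$test$records[sets$test$records$image_id == oid, ,
                              drop = FALSE]
    pred <- predict_tiles(model, .assemble_tiles(dataset, converted,
                                                 oid)$X)
    srh <- if (cfg$modality == "srh") converted[[oid]] else {
      render_srh(cohort$images[[which(names(converted) == oid)]],
                 cfg$lut_params)
    }
    list(srh = srh, tiles = recs, pred_labels = pred$labels)
  })
  render_report(report, out_dir, prefix = paste0("report_", cfg$modality),
                overlay = overlay)
  log_line("done", "balanced accuracy ",
           sprintf("%.3f", report$balanced_accuracy))
  list(cohort = cohort, dataset = dataset, split = split,
       weights = weights, model = model, report = report,
       sets = sets, out_dir = out_dir)
}
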