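SERIAL_FORMAT_VERSION <- "1.0"

#' Save a trained network to a directory
#'
#' Writes `meta.json` (format version, topology, feature mask, split,
#' metrics, seeds, descriptor names, scalers) and `weights.json` (layer
#' weight and bias arrays at full double precision).
#'
#' @param model A `trained_ann`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_ann <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format_version = SERIAL_FORMAT_VERSION,
    topology = list(n1 = model$topology$n1, n2 = model$topology$n2),
    nv = model$nv,
    feature_mask = model$feature_mask,
    descriptor_names = model$descriptor_names,
    split = list(tr = model$split$tr, va = model$split$va,
                 it = model$split$it),
    x_scaler = model$x_scaler,
    t_scaler = model$t_scaler,
    metrics = model$metrics,
    seed = model$seed,
    run_seed = model$run_seed,
    clip_predictions = model$clip_predictions,
    diagnostics = model$diagnostics[c("tr_mse", "va_mse", "best_epoch",
                                      "epochs_run")]
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  jsonlite::write_json(model$weights, file.path(dir, "weights.json"),
                       digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' Load a trained network saved by [save_ann()]
#'
#' @param dir Directory containing `meta.json` and `weights.json`.
#' @return A `trained_ann`.
#' @export
load_ann <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format_version, SERIAL_FORMAT_VERSION)) {
    stop("unsupported model format version: ", meta$format_version)
  }
  w <- jsonlite::read_json(file.path(dir, "weights.json"),
                           simplifyVector = TRUE)
  as_mat <- function(m) {
    if (is.null(dim(m))) matrix(m, nrow = if (length(m)) 1 else 0) else m
  }
  structure(list(
    topology = ann_topology(meta$topology$n1, meta$topology$n2),
    weights = list(W1 = as_mat(w$W1), b1 = as.numeric(w$b1),
                   W2 = if (length(w$W2)) as_mat(w$W2) else matrix(0, 0, 0),
                   b2 = as.numeric(w$b2),
                   W3 = as_mat(w$W3), b3 = as.numeric(w$b3)),
    split = subset_split(meta$split$tr, meta$split$va, meta$split$it),
    nv = meta$nv,
    feature_mask = as.logical(meta$feature_mask),
    descriptor_names = meta$descriptor_names,
    x_scaler = lapply(meta$x_scaler, as.numeric),
    t_scaler = lapply(meta$t_scaler, as.numeric),
    metrics = meta$metrics,
    seed = meta$seed,
    run_seed = meta$run_seed,
    clip_predictions = isTRUE(meta$clip_predictions),
    diagnostics = meta$diagnostics
  ), class = "trained_ann")
}

#' Save an optimization archive (one subdirectory per model)
#'
#' @param archive An `optimization_archive`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_archive <- function(archive, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(archive$models)) {
    save_ann(archive$models[[i]], file.path(dir, sprintf("model_%03d", i)))
  }
  jsonlite::write_json(
    list(format_version = SERIAL_FORMAT_VERSION,
         n_models = length(archive$models),
         fobj = archive$fobj, seeds = archive$seeds,
         config = unclass(archive$config),
         histories = archive$histories),
    file.path(dir, "archive.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Load an optimization archive saved by [save_archive()]
#'
#' @param dir Directory written by [save_archive()].
#' @return An `optimization_archive`.
#' @export
load_archive <- function(dir) {
  info <- jsonlite::read_json(file.path(dir, "archive.json"),
                              simplifyVector = TRUE)
  models <- lapply(seq_len(info$n_models), function(i) {
    load_ann(file.path(dir, sprintf("model_%03d", i)))
  })
  structure(list(models = models, fobj = as.numeric(info$fobj),
                 seeds = as.integer(info$seeds),
                 histories = info$histories,
                 config = info$config),
            class = "optimization_archive")
}
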