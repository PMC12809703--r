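#' Network topology
#'
#' Up to two hidden layers: `n1` neurons in the first (1-30) and `n2` in the
#' second (0-30), where `n2 = 0` denotes a single hidden layer.
#'
#' @param n1 First-hidden-layer neuron count.
#' @param n2 Second-hidden-layer neuron count (0 for a single hidden layer).
#' @return A list of class `ann_topology`.
#' @export
ann_topology <- function(n1, n2 = 0L) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (is.na(n1) || n1 < 1L || n1 > 30L) stop("n1 must be an integer in 1..30")
  if (is.na(n2) || n2 < 0L || n2 > 30L) stop("n2 must be an integer in 0..30")
  structure(list(n1 = n1, n2 = n2), class = "ann_topology")
}

#' Training configuration for a single network
#'
#' Networks are fitted by minimizing mean squared error on the training
#' subset with full-batch Adam; training halts once the validation-subset
#' error fails to improve for `patience` consecutive epochs, and the weights
#' from the best validation epoch are restored. The internal-test subset is
#' never touched during fitting. Given the seed, training is reproducible
#' bit for bit.
#'
#' @param max_epochs Maximum training epochs (default 500).
#' @param patience Epochs without validation improvement before stopping
#'   (default 20).
#' @param seed Integer seed for the weight initialization.
#' @param learning_rate Adam step size (default 0.02; small nets on small
#'   autoscaled data tolerate an aggressive step).
#' @param hidden_activation Hidden-layer nonlinearity; only `"tanh"` is
#'   implemented (bounded sigmoid family, linear output).
#' @param optimizer_tag Name of the gradient method; only `"adam"` is
#'   implemented.
#' @param clip_predictions Should user-facing descaled predictions be clipped
#'   to the practical EES range `[floor, rs_cap]`? Default TRUE; the
#'   objective computation always uses unclipped predictions.
#' @return A list of class `training_config`.
#' @export
training_config <- function(max_epochs = 500L, patience = 20L, seed = 1L,
                            learning_rate = 0.02,
                            hidden_activation = "tanh",
                            optimizer_tag = "adam",
                            clip_predictions = TRUE) {
  if (max_epochs < 1L) stop("max_epochs must be >= 1")
  if (patience < 1L) stop("patience must be >= 1")
  if (hidden_activation != "tanh") stop("only tanh hidden activation is implemented")
  if (optimizer_tag != "adam") stop("only the adam optimizer is implemented")
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 learning_rate = learning_rate,
                 hidden_activation = hidden_activation,
                 output_activation = "linear",
                 optimizer_tag = optimizer_tag,
                 clip_predictions = isTRUE(clip_predictions)),
            class = "training_config")
}

# Xavier-uniform layer initialization, drawn under the config seed
init_weights <- function(nv, topology, n_out = 9L, seed = 1L) {
  with_local_seed(seed, {
    xav <- function(fan_in, fan_out) {
      lim <- sqrt(6 / (fan_in + fan_out))
      matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
    }
    h_last <- if (topology$n2 > 0L) topology$n2 else topology$n1
    w <- list(W1 = xav(nv, topology$n1), b1 = rep(0, topology$n1))
    if (topology$n2 > 0L) {
      w$W2 <- xav(topology$n1, topology$n2)
      w$b2 <- rep(0, topology$n2)
    } else {
      w$W2 <- matrix(0, 0, 0)
      w$b2 <- numeric(0)
    }
    w$W3 <- xav(h_last, n_out)
    w$b3 <- rep(0, n_out)
    w
  })
}

#' Train a feed-forward network on autoscaled data
#'
#' @param x Autoscaled descriptor matrix already restricted to the selected
#'   descriptors (n_compounds x nv).
#' @param t Autoscaled target matrix (n_compounds x 9).
#' @param split A validated [subset_split()]; fitting uses only the training
#'   rows, early stopping only the validation rows.
#' @param topology An [ann_topology()].
#' @param cfg A [training_config()].
#' @return A list of class `trained_ann` holding the topology, weights,
#'   split, training diagnostics (`tr_mse`, `va_mse`, `best_epoch`,
#'   `epochs_run`) and `nv`. Feature mask, scalers, descriptor names and
#'   objective metrics are attached by [evaluate_candidate()].
#' @export
train_ann <- function(x, t, split, topology, cfg = training_config()) {
  x <- unclass(x); t <- unclass(t)
  if (!is.matrix(x) || ncol(x) < 1L) stop("x must be a matrix with nv >= 1 columns")
  if (nrow(x) != nrow(t)) stop("x and t must be row-aligned")
  if (length(split$tr) < 2L || length(split$va) < 1L) {
    stop("degenerate split: need >= 2 training and >= 1 validation rows")
  }
  w0 <- init_weights(ncol(x), topology, n_out = ncol(t), seed = cfg$seed)
  fit <- ann_train_cpp(x, t,
                       as.integer(split$tr) - 1L, as.integer(split$va) - 1L,
                       topology$n1, topology$n2,
                       w0$W1, w0$b1, w0$W2, w0$b2, w0$W3, w0$b3,
                       cfg$max_epochs, cfg$patience, cfg$learning_rate)
  structure(list(
    topology = topology,
    weights = list(W1 = fit$W1, b1 = as.numeric(fit$b1),
                   W2 = fit$W2, b2 = as.numeric(fit$b2),
                   W3 = fit$W3, b3 = as.numeric(fit$b3)),
    split = split,
    nv = ncol(x),
    feature_mask = NULL, descriptor_names = NULL,
    x_scaler = NULL, t_scaler = NULL,
    metrics = NULL,
    seed = cfg$seed,
    diagnostics = list(tr_mse = fit$tr_mse, va_mse = fit$va_mse,
                       best_epoch = fit$best_epoch,
                       epochs_run = fit$epochs_run,
                       va_history = fit$va_history),
    clip_predictions = cfg$clip_predictions
  ), class = "trained_ann")
}

# forward pass on an already-scaled, already-masked matrix
forward_ann <- function(weights, topology, x) {
  h <- tanh(sweep(x %*% weights$W1, 2, weights$b1, "+"))
  if (topology$n2 > 0L) {
    h <- tanh(sweep(h %*% weights$W2, 2, weights$b2, "+"))
  }
  sweep(h %*% weights$W3, 2, weights$b3, "+")
}

#' Predict EES profiles with a trained network
#'
#' Applies the stored descriptor scaler and feature mask, runs the forward
#' pass, and back-transforms the 9 outputs to original EES units using the
#' stored target scaler. Deterministic: identical inputs give identical
#' outputs.
#'
#' @param model A `trained_ann` with scalers and feature mask attached (as
#'   produced by [evaluate_candidate()] or loaded by [load_ann()]).
#' @param x_new Descriptor matrix in original units containing all descriptor
#'   columns the model was built from (the mask is applied internally).
#' @param clip Clip the descaled profile to the practical EES range? Defaults
#'   to the model's `clip_predictions` setting.
#' @param params [ees_params()] supplying the clipping range.
#' @return Matrix (n_compounds x 9) of EES values in original units.
#' @export
predict_ann <- function(model, x_new, clip = model$clip_predictions,
                        params = ees_params()) {
  if (is.null(model$x_scaler)) {
    stop("model has no stored scalers; use evaluate_candidate() or load_ann()")
  }
  x_new <- unclass(x_new)
  if (!is.null(model$descriptor_names)) {
    missing <- setdiff(model$descriptor_names, colnames(x_new))
    if (length(missing)) {
      stop("x_new is missing descriptor column(s): ",
           paste(missing, collapse = ", "))
    }
    x_new <- x_new[, model$descriptor_names, drop = FALSE]
  }
  xs <- apply_scaler(x_new, model$x_scaler)[, model$feature_mask, drop = FALSE]
  y <- descale(forward_ann(model$weights, model$topology, xs), model$t_scaler)
  if (isTRUE(clip)) y <- pmin(pmax(y, params$floor), params$rs_cap)
  colnames(y) <- paste0("mp", seq_len(ncol(y)))
  rownames(y) <- rownames(x_new)
  y
}
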