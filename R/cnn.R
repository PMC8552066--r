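# R-level interface to the compact convolutional driver-region classifier.

#' Build the custom CNN
#'
#' Three 3x3 same-padding convolutional blocks (default 32, 64, 64 filters,
#' ReLU, 2x2 max-pool each), flatten, dense 128 and 64 units with ReLU and
#' dropout between them, and a softmax head with one unit per class.
#' Weights are He-initialized from the seed; the model is usable for
#' prediction immediately.
#'
#' @param input_shape integer c(H, W, C); both spatial dims must be >= 8 so
#'   they survive the three 2x pooling stages
#' @param n_classes softmax head size (default 8: seven regions + none)
#' @param filters,dense_units,dropout architecture overrides
#' @param seed initialization seed
#' @return `driver_cnn` object
#' @export
build_custom_cnn <- function(input_shape, n_classes = 8L,
                             filters = c(32L, 64L, 64L),
                             dense_units = c(128L, 64L),
                             dropout = 0.6, seed = 1L) {
  if (length(input_shape) == 2L) input_shape <- c(input_shape, 1L)
  if (any(input_shape[1:2] < 8L))
    stop_af("input %s too small: spatial dims must be >= 8 to survive three 2x poolings",
            paste(input_shape, collapse = "x"))
  spec <- list(input_shape = as.integer(input_shape),
               filters = as.integer(filters),
               dense = as.integer(dense_units),
               n_classes = as.integer(n_classes),
               dropout = dropout)
  weights <- .cnn_init(spec, as.integer(seed))
  structure(list(spec = spec, weights = weights, history = NULL,
                 best_epoch = NULL, seed = as.integer(seed)),
            class = "driver_cnn")
}

#' @export
print.driver_cnn <- function(x, ...) {
  s <- x$spec
  cat(sprintf("driver_cnn: input %s, conv filters (%s), dense (%s), dropout %.2g, %d classes%s\n",
              paste(s$input_shape, collapse = "x"),
              paste(s$filters, collapse = ", "),
              paste(s$dense, collapse = ", "),
              s$dropout, s$n_classes,
              if (is.null(x$history)) " [untrained]"
              else sprintf(" [trained, best epoch %d]", x$best_epoch)))
  invisible(x)
}

#' Training configuration
#'
#' Defaults: Adam at learning rate 1e-3, batch 32, up to 1000 epochs with
#' early stopping (patience 50) and learning-rate reduction (factor 0.5,
#' patience 20), monitoring the training loss; the checkpointed best model
#' is returned, not the last.
#'
#' @param max_epochs,batch_size,lr,lr_factor,lr_patience,es_patience,monitor
#'   training controls; `monitor` is `"train_loss"` or `"val_loss"`
#' @param class_weights optional per-class weights (names "0".."7"); NULL =
#'   unweighted
#' @param seed shuffling/dropout seed
#' @param verbose print per-epoch progress
#' @return list of class `train_config`
#' @export
train_config <- function(max_epochs = 1000L, batch_size = 32L, lr = 1e-3,
                         lr_factor = 0.5, lr_patience = 20L,
                         es_patience = 50L, monitor = "train_loss",
                         class_weights = NULL, seed = 1L,
                         verbose = FALSE) {
  stopifnot(lr_factor > 0, lr_factor < 1, es_patience < max_epochs)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 es_patience = as.integer(es_patience), monitor = monitor,
                 class_weights = class_weights, seed = as.integer(seed),
                 verbose = isTRUE(verbose)), class = "train_config")
}

# (n, H, W, C) array -> D x n column-major matrix for the C++ kernels
.tensors_to_matrix <- function(x, spec) {
  d <- dim(x)
  if (length(d) != 4L || !all(d[2:4] == spec$input_shape))
    stop_af("tensor shape (%s) does not match model input (%s)",
            paste(d[-1], collapse = "x"),
            paste(spec$input_shape, collapse = "x"))
  m <- matrix(aperm(x, c(2, 3, 4, 1)), prod(d[2:4]), d[1])
  m
}

#' Train the CNN
#'
#' Class-weighted categorical cross-entropy with Adam; fully seeded and
#' single-threaded, so identical configs yield identical histories.
#'
#' @param model driver_cnn
#' @param x array (n, H, W, C) of training tensors
#' @param y integer labels 0..(n_classes-1)
#' @param x_val,y_val optional validation split (required when
#'   `monitor = "val_loss"`)
#' @param config train_config
#' @return the trained driver_cnn (checkpointed best weights, history,
#'   best_epoch)
#' @export
train_model <- function(model, x, y, x_val = NULL, y_val = NULL,
                        config = train_config()) {
  stopifnot(inherits(model, "driver_cnn"))
  if (length(unique(y)) < 2L)
    stop_af("training labels cover a single class; nothing to learn")
  if (any(y < 0 | y >= model$spec$n_classes))
    stop_af("labels must lie in 0..%d", model$spec$n_classes - 1L)
  X <- .tensors_to_matrix(x, model$spec)
  cw <- config$class_weights
  sw <- if (is.null(cw)) rep(1, length(y))
        else as.numeric(cw[as.character(y)])
  if (any(!is.finite(sw)))
    stop_af("class_weights missing entries for some observed labels")
  Xv <- if (!is.null(x_val)) .tensors_to_matrix(x_val, model$spec)
  res <- .cnn_train(model$spec, model$weights, X, as.integer(y), sw,
                    Xv, if (!is.null(y_val)) as.integer(y_val),
                    unclass(config))
  model$weights <- res$weights
  model$history <- as.data.frame(res$history)
  model$best_epoch <- res$best_epoch
  model$best_monitor <- res$best_monitor
  model$train_config <- config
  model
}

#' Predict driver-region probabilities
#'
#' Deterministic (dropout disabled).  Hard labels are the row-wise argmax.
#'
#' @param object driver_cnn
#' @param x array (n, H, W, C)
#' @param ... unused
#' @return list with `prob` (n x n_classes) and `labels` (integer 0-based)
#' @export
predict.driver_cnn <- function(object, x, ...) {
  if (is.null(dim(x)) || length(dim(x)) != 4L || dim(x)[1] == 0L)
    return(list(prob = matrix(numeric(0), 0, object$spec$n_classes),
                labels = integer(0)))
  X <- .tensors_to_matrix(x, object$spec)
  prob <- .cnn_predict(object$spec, object$weights, X)
  colnames(prob) <- as.character(seq_len(object$spec$n_classes) - 1L)
  list(prob = prob, labels = max.col(prob) - 1L)
}

#' Total weighted cross-entropy of a batch (sum reduction)
#'
#' Exposed for the class-weighting equivalence check: duplicating a sample
#' k times at weight 1 must equal one copy at weight k.
#' @param model driver_cnn
#' @param x array (n, H, W, C)
#' @param y integer labels
#' @param sample_weights numeric per-sample weights
#' @return scalar loss
#' @export
cnn_batch_loss <- function(model, x, y, sample_weights = rep(1, length(y))) {
  X <- .tensors_to_matrix(x, model$spec)
  .cnn_loss_sum(model$spec, model$weights, X, as.integer(y),
                as.numeric(sample_weights))
}

#' Save / load a trained model (weights + spec + history as RDS, sidecar
#' JSON with the spec and training summary)
#' @param model driver_cnn
#' @param path file path (.rds)
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- sub("\\.rds$", ".json", path)
  jsonlite::write_json(list(spec = model$spec,
                            best_epoch = model$best_epoch,
                            epochs_run = NROW(model$history)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "driver_cnn"))
  m
}
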