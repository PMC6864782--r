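#' Configuration for the bidirectional LSTM sequence classifier
#'
#' Defaults follow the training recipe used throughout the package:
#' per-sequence (stochastic) weight updates with momentum 0.9 and learning
#' rate 1e-4, initial weights drawn uniformly from \[-0.1, 0.1\], and
#' early stopping when the validation error stops improving.
#'
#' @param n_classes number of identities C (>= 2).
#' @param hidden_size memory cells per direction (default 64).
#' @param learning_rate SGD step size (default 1e-4).
#' @param momentum momentum coefficient (default 0.9).
#' @param init_range half-width of the uniform weight initialization
#'   (default 0.1, i.e. weights in \[-0.1, 0.1\]).
#' @param max_epochs training epoch cap (default 150).
#' @param patience epochs without validation improvement before stopping
#'   (default 10).
#' @param min_delta minimum validation-error improvement counted as
#'   progress (default 1e-4).
#' @param grad_clip elementwise gradient clip; 0 disables (default 1).
#' @param validation_fraction fraction of training sequences (stratified
#'   per class) held out for the early-stopping validation set (default
#'   1/8, i.e. one of eight training samples per identity).
#' @param standardize z-score features using training-set statistics
#'   before the network (default TRUE).
#' @param seed integer seed for initialization, the validation split and
#'   the per-epoch presentation order.
#' @return object of class `blstm_config`.
#' @export
blstm_config <- function(n_classes, hidden_size = 64L, learning_rate = 1e-4,
                         momentum = 0.9, init_range = 0.1,
                         max_epochs = 150L, patience = 10L, min_delta = 1e-4,
                         grad_clip = 1, validation_fraction = 1 / 8,
                         standardize = TRUE, seed = 1L) {
  if (n_classes < 2L) stop("configuration error: need n_classes >= 2",
                           call. = FALSE)
  if (learning_rate <= 0 || momentum < 0 || hidden_size < 1L) {
    stop("configuration error: rates must be positive", call. = FALSE)
  }
  structure(list(n_classes = as.integer(n_classes),
                 hidden_size = as.integer(hidden_size),
                 learning_rate = learning_rate, momentum = momentum,
                 init_range = init_range,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 grad_clip = grad_clip,
                 validation_fraction = validation_fraction,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "blstm_config")
}

# uniform init in [-r, r] for all weight blocks
init_blstm_weights <- function(D, H, C, r) {
  rmat <- function(nr, nc) matrix(runif(nr * nc, -r, r), nr, nc)
  list(Wf = rmat(4 * H, D), Uf = rmat(4 * H, H), bf = runif(4 * H, -r, r),
       Wb = rmat(4 * H, D), Ub = rmat(4 * H, H), bb = runif(4 * H, -r, r),
       V = rmat(C, 2 * H), co = runif(C, -r, r))
}

#' Train a bidirectional LSTM on labeled feature sequences
#'
#' Reads each sequence forward and backward through two independent LSTM
#' hidden layers joined by a shared softmax output layer, and minimizes
#' the per-timestep cross-entropy (summed over each sequence) by
#' stochastic gradient descent with momentum, updating after every
#' sequence with a freshly shuffled presentation order each epoch. A
#' stratified validation subset is split off internally; training stops
#' when its error has not improved for `patience` consecutive epochs, and
#' the weights from the best validation epoch are kept. The whole
#' procedure is deterministic given `config$seed`.
#'
#' @param sequences list of numeric matrices, one per sample, frames in
#'   rows (time) and features in columns; lengths may vary.
#' @param labels class labels (factor or character/integer), one per
#'   sequence; every class needs at least one sequence.
#' @param config a [blstm_config()]; `n_classes` must equal the number of
#'   distinct labels.
#' @return object of class `blstm` holding the learned weights, the
#'   config, the class levels, feature standardization parameters, and a
#'   per-epoch training history (`history$train_error`,
#'   `history$val_error`).
#' @export
blstm_train <- function(sequences, labels, config) {
  stopifnot(inherits(config, "blstm_config"))
  labels <- factor(labels)
  classes <- levels(labels)
  if (length(classes) != config$n_classes) {
    stop(sprintf("configuration error: %d classes in labels but n_classes = %d",
                 length(classes), config$n_classes), call. = FALSE)
  }
  if (length(sequences) != length(labels)) {
    stop("sequences and labels length mismatch", call. = FALSE)
  }
  counts <- table(labels)
  if (any(counts == 0)) {
    stop("configuration error: class without sequences: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  D <- ncol(sequences[[1]])
  if (any(vapply(sequences, ncol, 0L) != D)) {
    stop("shape error: all sequences must share feature width", call. = FALSE)
  }

  # feature standardization from the full training pool
  if (config$standardize) {
    pooled <- do.call(rbind, sequences)
    center <- colMeans(pooled)
    scale <- apply(pooled, 2, sd)
    scale[scale < 1e-12] <- 1
  } else {
    center <- rep(0, D); scale <- rep(1, D)
  }
  seqs <- lapply(sequences, function(m) {
    t((t(m) - center) / scale) # returns frames x features
  })

  y <- as.integer(labels) - 1L

  with_rng(sub_seed(config$seed, .STREAM[["train"]], 1L), {
    # stratified validation split: per class, hold out a fraction of the
    # sequences (at least one when the class has >= 2)
    val_idx <- integer(0)
    for (cl in seq_along(classes)) {
      idx <- which(y == cl - 1L)
      n_hold <- min(length(idx) - 1L,
                    max(if (length(idx) >= 2L) 1L else 0L,
                        floor(length(idx) * config$validation_fraction)))
      if (n_hold > 0L) val_idx <- c(val_idx, sample(idx, n_hold))
    }
    train_idx <- setdiff(seq_along(seqs), val_idx)

    w0 <- init_blstm_weights(D, config$hidden_size, config$n_classes,
                             config$init_range)
    n_train <- length(train_idx)
    orders <- t(vapply(seq_len(config$max_epochs),
                       function(e) sample(n_train),
                       integer(n_train))) - 1L # 0-based into train list

    Xtr <- lapply(seqs[train_idx], t) # D x T for the C++ side
    Xv <- lapply(seqs[val_idx], t)
    fit <- cpp_blstm_train(Xtr, y[train_idx], Xv, y[val_idx], w0,
                           config$learning_rate, config$momentum,
                           config$max_epochs, config$patience,
                           config$min_delta, config$grad_clip,
                           orders)
  })

  structure(list(weights = fit$weights, config = config, classes = classes,
                 center = center, scale = scale, input_size = D,
                 history = data.frame(epoch = seq_along(fit$train_error),
                                      train_error = fit$train_error,
                                      val_error = fit$val_error),
                 best_epoch = fit$best_epoch,
                 epochs_run = fit$epochs_run),
            class = "blstm")
}

#' @export
print.blstm <- function(x, ...) {
  cat(sprintf(paste0("<blstm> %d classes, %d cells/direction, input width %d\n",
                     "  trained %d epochs (best validation at epoch %d)\n"),
              length(x$classes), x$config$hidden_size, x$input_size,
              x$epochs_run, x$best_epoch))
  invisible(x)
}

#' Class posteriors for one feature sequence
#'
#' Runs the bidirectional forward pass, applies the softmax at every
#' timestep, and pools the per-timestep probability vectors by their
#' arithmetic mean (renormalized) into a single sequence-level posterior.
#'
#' @param model a trained [blstm_train()] model.
#' @param feature_sequence numeric matrix, frames x features; feature
#'   width must match training.
#' @param per_timestep if `TRUE`, also return the timestep-wise softmax
#'   matrix as attribute `"timesteps"`.
#' @return named numeric posterior vector over the model's classes,
#'   summing to 1.
#' @export
predict_posteriors <- function(model, feature_sequence, per_timestep = FALSE) {
  stopifnot(inherits(model, "blstm"))
  m <- as.matrix(feature_sequence)
  if (ncol(m) != model$input_size) {
    stop(sprintf("shape error: sequence width %d, model expects %d",
                 ncol(m), model$input_size), call. = FALSE)
  }
  xs <- t((t(m) - model$center) / model$scale)
  P <- cpp_blstm_posterior(model$weights, t(xs)) # T x C
  post <- colMeans(P)
  post <- post / sum(post)
  names(post) <- model$classes
  if (per_timestep) {
    colnames(P) <- model$classes
    attr(post, "timesteps") <- P
  }
  post
}

#' Predict classes or posteriors for a list of sequences
#'
#' @param object a `blstm` model.
#' @param newdata one feature matrix or a list of them.
#' @param type `"class"` for hard labels, `"posterior"` for the matrix of
#'   sequence-level posteriors (rows = sequences).
#' @param ... unused.
#' @return character vector of labels or a numeric posterior matrix.
#' @export
predict.blstm <- function(object, newdata, type = c("class", "posterior"),
                          ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) newdata <- list(newdata)
  P <- t(vapply(newdata, function(m) predict_posteriors(object, m),
                numeric(length(object$classes))))
  colnames(P) <- object$classes
  if (type == "posterior") return(P)
  object$classes[max.col(P, ties.method = "first")]
}
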