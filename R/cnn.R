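#' Network and training configuration
#'
#' Architecture and optimizer settings of the 1D dilated convolutional
#' classifier: four dilated convolution layers with ReLU activations, a
#' global max-pooling layer, one dense ReLU layer and a 3-way softmax output.
#' The global pool reduces any input length to one feature per channel, which
#' is what lets one trained model accept curves of different lengths.
#'
#' @param filters Output channels of the four convolution layers.
#' @param kernel_size Convolution kernel width (taps), default 9.
#' @param dilations Dilation rate of each layer, default `c(1, 2, 4, 8)`.
#' @param dense_units Width of the dense layer, default 64.
#' @param learning_rate Adaptive-moment (Adam) step size, default 1e-3.
#' @param epochs Training epochs, default 210.
#' @param batch_size Minibatch size, default 32.
#' @param target_len Length every curve is pooled/resampled to before entering
#'   the network, default 512. Must be at least the receptive field
#'   `1 + (kernel_size - 1) * sum(dilations)`.
#' @param n_classes Number of output classes, fixed at 3.
#' @return An object of class `"model_config"`.
#' @export
model_config <- function(filters = c(16L, 16L, 32L, 32L), kernel_size = 9L,
                         dilations = c(1L, 2L, 4L, 8L), dense_units = 64L,
                         learning_rate = 1e-3, epochs = 210L,
                         batch_size = 32L, target_len = 512L,
                         n_classes = 3L) {
  filters <- as.integer(filters); dilations <- as.integer(dilations)
  if (length(filters) != length(dilations))
    stop_invalid("filters and dilations must have the same length")
  if (any(filters < 1) || any(dilations < 1))
    stop_invalid("filters and dilations must be positive integers")
  if (as.integer(n_classes) != 3L)
    stop_invalid("the classifier is fixed at 3 oxidation classes")
  epochs <- as.integer(epochs)
  if (epochs < 1) stop_invalid("epochs must be >= 1")
  if (as.integer(target_len) < 16L) stop_invalid("target_len must be >= 16")
  rf <- 1L + (as.integer(kernel_size) - 1L) * sum(dilations)
  if (rf > as.integer(target_len))
    stop(errorCondition(
      sprintf("receptive field (%d) exceeds target_len (%d)", rf,
              as.integer(target_len)),
      class = c("oxirelax_config_error", "error", "condition")))
  structure(list(filters = filters, kernel_size = as.integer(kernel_size),
                 dilations = dilations, dense_units = as.integer(dense_units),
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = as.integer(batch_size),
                 target_len = as.integer(target_len), n_classes = 3L,
                 n_conv_layers = length(filters), receptive_field = rf),
            class = "model_config")
}

#' Normalize and resample a curve for the network
#'
#' Resamples a curve to `target_len` points and min-max scales the result to
#' exactly \[0, 1\]. Longer curves are mean-pooled over `target_len` nearly
#' equal contiguous blocks (block means of a decreasing sequence remain
#' decreasing, so curve shape is preserved); shorter curves are linearly
#' interpolated. A curve of the right length is only rescaled.
#'
#' @param x A `"relaxation_curve"` or numeric amplitude vector.
#' @param target_len Output length, >= 16.
#' @return Numeric vector of length `target_len` with min 0 and max 1.
#' @export
preprocess_curve <- function(x, target_len = 512L) {
  v <- if (is.data.frame(x)) x$amplitude else as.numeric(x)
  target_len <- as.integer(target_len)
  if (target_len < 16L) stop_invalid("target_len must be >= 16")
  if (any(!is.finite(v))) stop_invalid("curve contains non-finite values")
  n <- length(v)
  if (n > target_len) {
    bounds <- floor(seq(0, n, length.out = target_len + 1))
    v <- vapply(seq_len(target_len),
                function(i) mean(v[(bounds[i] + 1):bounds[i + 1]]),
                numeric(1))
  } else if (n < target_len) {
    v <- approx(seq_len(n), v, n = target_len)$y
  }
  rng <- range(v)
  if (rng[1] == rng[2])
    stop(errorCondition("constant curve cannot be min-max normalized",
                        class = c("oxirelax_degenerate_input", "error",
                                  "condition")))
  (v - rng[1]) / (rng[2] - rng[1])
}

# Stack heterogeneous inputs (matrix / list of curves / single curve /
# oxi_dataset) into an n x target_len matrix of preprocessed rows.
preprocess_input <- function(x, target_len) {
  if (inherits(x, "oxi_dataset")) x <- lapply(x$records, `[[`, "curve")
  if (inherits(x, "relaxation_curve")) x <- list(x)
  if (is.numeric(x) && is.null(dim(x))) x <- list(x)
  if (is.matrix(x)) x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
  t(vapply(x, preprocess_curve, numeric(target_len),
           target_len = target_len))
}

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

init_weights <- function(config) {
  k <- config$kernel_size
  cin <- 1L
  Wc <- list(); bc <- list()
  for (l in seq_along(config$filters)) {
    cout <- config$filters[l]
    Wc[[l]] <- he_init(k * cin, cout, k * cin)
    bc[[l]] <- matrix(0, 1, cout)
    cin <- cout
  }
  clast <- config$filters[length(config$filters)]
  list(Wc = Wc, bc = bc,
       W1 = he_init(clast, config$dense_units, clast),
       b1 = matrix(0, 1, config$dense_units),
       W2 = he_init(config$dense_units, config$n_classes,
                    config$dense_units),
       b2 = matrix(0, 1, config$n_classes))
}

param_count <- function(w) {
  sum(vapply(c(w$Wc, w$bc, list(w$W1, w$b1, w$W2, w$b2)), length, numeric(1)))
}

#' Stratified data split
#'
#' Splits sample indices into train/validation/test groups with per-class
#' proportions matching `fractions` (largest-remainder rounding per class).
#'
#' @param y Class labels.
#' @param fractions Named or positional fractions summing to 1; default
#'   70/15/15.
#' @param seed Optional integer seed.
#' @return List of integer index vectors `train`, `validation`, `test` (empty
#'   components dropped when their fraction is 0).
#' @export
stratified_split <- function(y, fractions = c(train = 0.70,
                                              validation = 0.15,
                                              test = 0.15),
                             seed = NULL) {
  if (abs(sum(fractions) - 1) > 1e-6)
    stop_invalid("split fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(fractions)))
    names(fractions) <- c("train", "validation", "test")[seq_along(fractions)]
  y <- as.factor(y)
  out <- lapply(fractions, function(f) integer(0))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    counts <- class_counts(length(idx), fractions)
    stopifnot(sum(counts) == length(idx))
    at <- 0L
    for (g in seq_along(fractions)) {
      if (counts[g] > 0)
        out[[g]] <- c(out[[g]], idx[(at + 1):(at + counts[g])])
      at <- at + counts[g]
    }
  }
  lapply(out, sort)
}

#' Fit the 1D dilated convolutional oxidation classifier
#'
#' Trains the network described by [model_config()] to map raw CPMG
#' relaxation curves to the three ordinal oxidation classes. Curves are first
#' passed through [preprocess_curve()] (min-max scaling to \[0, 1\] and
#' resampling to `config$target_len`). Optimization minimizes categorical
#' cross-entropy with the adaptive-moment (Adam) method for exactly
#' `config$epochs` epochs (no early stopping); per-epoch training and
#' validation accuracy and loss are recorded. Training is deterministic given
#' `seed` under single-threaded execution.
#'
#' @param x Curves: a numeric matrix (rows = curves), a list of
#'   `"relaxation_curve"`/numeric vectors (lengths may differ), or an
#'   `"oxi_dataset"` (in which case `y` defaults to its stored classes).
#' @param y Class labels in `"Good"`, `"Fair"`, `"Bad"`; at least two classes
#'   must be present.
#' @param config A [model_config()].
#' @param validation Either a fraction in \[0, 1) held out (stratified) for
#'   validation, or an integer vector of validation row indices, or `NULL`
#'   for none.
#' @param class_weights `NULL` (uniform), `"balanced"` (inverse frequency),
#'   or a numeric vector of 3 weights ordered as [oxidation_levels].
#' @param seed Integer seed controlling weight initialization, the validation
#'   split and minibatch shuffling.
#' @return An object of class `"oxinet"`: list with `config`, `weights`,
#'   `class_order`, `history` (data.frame: epoch, train_loss, train_acc,
#'   val_loss, val_acc), `n_train`, `n_validation`, `param_count`, `seed`.
#' @seealso [predict.oxinet()], [plot.oxinet()]
#' @export
oxinet <- function(x, y = NULL, config = model_config(), validation = 0.15,
                   class_weights = NULL, seed = 1L) {
  if (inherits(x, "oxi_dataset") && is.null(y)) y <- x$manifest$class
  if (is.null(y)) stop_invalid("y labels are required")
  y <- as_oxidation_factor(y)
  if (length(unique(y[!is.na(y)])) < 2)
    stop_invalid("training data must contain at least 2 classes")
  X <- preprocess_input(x, config$target_len)
  if (nrow(X) != length(y)) stop_invalid("x and y lengths differ")

  set.seed(seed)
  n <- nrow(X)
  if (is.null(validation) || (length(validation) == 1 && validation == 0)) {
    val_idx <- integer(0)
  } else if (length(validation) == 1 && validation > 0 && validation < 1) {
    val_idx <- stratified_split(y, c(train = 1 - validation,
                                     validation = validation))$validation
  } else {
    val_idx <- as.integer(validation)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  cw <- if (is.null(class_weights)) rep(1, 3)
        else if (identical(class_weights, "balanced")) {
          counts <- pmax(tabulate(y[tr_idx], 3), 1)
          length(tr_idx) / (3 * counts)
        } else as.numeric(class_weights)

  weights <- init_weights(config)
  order <- t(vapply(seq_len(config$epochs),
                    function(e) sample.int(length(tr_idx)),
                    integer(length(tr_idx))))
  if (config$epochs == 1L) order <- matrix(order, nrow = 1)

  fit <- .cnn_train(weights, unclass(config),
                    X[tr_idx, , drop = FALSE],
                    as.integer(y[tr_idx]) - 1L,
                    X[val_idx, , drop = FALSE],
                    as.integer(y[val_idx]) - 1L,
                    order, cw)
  history <- data.frame(epoch = seq_len(config$epochs),
                        train_loss = fit$history[, 1],
                        train_acc = fit$history[, 2],
                        val_loss = fit$history[, 3],
                        val_acc = fit$history[, 4])
  structure(list(config = config, weights = fit$weights,
                 class_order = oxidation_levels, history = history,
                 n_train = length(tr_idx), n_validation = length(val_idx),
                 param_count = param_count(fit$weights), seed = seed,
                 package_version = as.character(packageVersion("oxirelax"))),
            class = "oxinet")
}

# argmax with ties broken by class_order position (first maximum wins)
prob_to_class <- function(probs, class_order) {
  idx <- apply(probs, 1, which.max)
  factor(class_order[idx], levels = class_order, ordered = TRUE)
}

#' Predict oxidation class of relaxation curves
#'
#' Runs the forward pass of a trained [oxinet()] model. Curves of any length
#' are accepted: they are preprocessed to the model's `target_len` first.
#'
#' @param object A fitted `"oxinet"`.
#' @param newdata Curves in any form accepted by [oxinet()].
#' @param type `"class"` for the predicted labels, `"prob"` for the n x 3
#'   softmax probability matrix, `"both"` for a data.frame with `class` and
#'   `probability` (the winning softmax probability, in \[1/3, 1\]).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.oxinet <- function(object, newdata,
                           type = c("class", "prob", "both"), ...) {
  type <- match.arg(type)
  X <- preprocess_input(newdata, object$config$target_len)
  probs <- .cnn_forward(object$weights, unclass(object$config), X)
  colnames(probs) <- object$class_order
  cls <- prob_to_class(probs, object$class_order)
  switch(type,
         class = cls,
         prob = probs,
         both = data.frame(class = cls,
                           probability = probs[cbind(seq_len(nrow(probs)),
                                                     as.integer(cls))]))
}

#' @export
print.oxinet <- function(x, ...) {
  cfg <- x$config
  cat("1D dilated CNN oxidation classifier (oxinet)\n")
  cat(sprintf("  %d conv layers: filters (%s), kernel %d, dilations (%s)\n",
              cfg$n_conv_layers, paste(cfg$filters, collapse = ","),
              cfg$kernel_size, paste(cfg$dilations, collapse = ",")))
  cat(sprintf("  global max pool -> dense %d -> softmax %d; %d parameters\n",
              cfg$dense_units, cfg$n_classes, x$param_count))
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  trained %d epochs on %d curves (input length %d)\n",
              cfg$epochs, x$n_train, cfg$target_len))
  cat(sprintf("  final train acc %.3f / loss %.4f", h$train_acc,
              h$train_loss))
  if (x$n_validation > 0)
    cat(sprintf("; validation acc %.3f / loss %.4f", h$val_acc, h$val_loss))
  cat("\n")
  invisible(x)
}

#' @export
summary.oxinet <- function(object, ...) {
  print(object)
  cfg <- object$config
  cin <- 1L
  for (l in seq_along(cfg$filters)) {
    cat(sprintf("  conv%d: %d x %d channels, dilation %d, %d weights\n",
                l, cin, cfg$filters[l], cfg$dilations[l],
                length(object$weights$Wc[[l]]) +
                  length(object$weights$bc[[l]])))
    cin <- cfg$filters[l]
  }
  invisible(object)
}

#' Plot training history
#'
#' Accuracy and loss per epoch for the training and validation sets.
#'
#' @param x A fitted `"oxinet"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.oxinet <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "loss", ...)
  invisible(x)
}

#' Save / load a trained model artifact
#'
#' The artifact is a directory holding `config.json` (architecture, class
#' order, seed, package version), `weights.rds` and `history.csv`.
#'
#' @param model A fitted `"oxinet"`.
#' @param dir Artifact directory.
#' @return `save_oxinet` invisibly returns `dir`; `load_oxinet` returns the
#'   restored `"oxinet"`.
#' @export
save_oxinet <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(config = unclass(model$config),
               class_order = model$class_order,
               n_train = model$n_train, n_validation = model$n_validation,
               param_count = model$param_count, seed = model$seed,
               package_version = model$package_version)
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model$weights, file.path(dir, "weights.rds"))
  write.csv(model$history, file.path(dir, "history.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_oxinet
#' @export
load_oxinet <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "config.json"))
  cfg <- do.call(model_config,
                 meta$config[c("filters", "kernel_size", "dilations",
                               "dense_units", "learning_rate", "epochs",
                               "batch_size", "target_len")])
  weights <- readRDS(file.path(dir, "weights.rds"))
  history <- read.csv(file.path(dir, "history.csv"))
  structure(list(config = cfg, weights = weights,
                 class_order = meta$class_order, history = history,
                 n_train = meta$n_train, n_validation = meta$n_validation,
                 param_count = param_count(weights), seed = meta$seed,
                 package_version = meta$package_version),
            class = "oxinet")
}
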