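#' CSAE architecture and loss configuration
#'
#' Defines the convolutional supervised auto-encoder: `n_stages` encoder
#' stages (each two 3x3x3 convolutions, LeakyReLU, 3D channel dropout) with
#' factor-2 max pooling between consecutive stages, a mirrored decoder with
#' factor-2 nearest-neighbour upsampling, a single linear classification
#' layer on the flattened bottleneck, and the single mixing weight
#' `lambda_weight` of the combined loss
#' \deqn{L = (1-\lambda)\,\mathrm{MSE}(x, \hat x) + \lambda\, w_c\,
#'   \mathrm{CE}(y, \hat y).}
#'
#' @param target_extent network input extent; every component must be
#'   divisible by `2^(n_stages - 1)` and be at least 4.
#' @param n_stages number of encoder stages (default 5).
#' @param channels_per_stage strictly increasing channel widths, one per
#'   stage.
#' @param dropout_rate 3D (channel-wise) dropout probability.
#' @param leaky_slope negative slope of the LeakyReLU.
#' @param n_classes number of output classes.
#' @param lambda_weight \eqn{\lambda \in [0, 1]}: 0 gives a pure auto-encoder,
#'   1 a pure classifier.
#' @return object of class `csae_config`.
#' @examples
#' csae_config(c(24, 24, 16), n_stages = 3, channels_per_stage = c(8, 16, 32))
#' @export
csae_config <- function(target_extent,
                        n_stages = 5L,
                        channels_per_stage = c(8L, 16L, 32L, 64L, 128L),
                        dropout_rate = 0.1,
                        leaky_slope = 0.01,
                        n_classes = 3L,
                        lambda_weight = 0.9) {
  target_extent <- as.integer(round(target_extent))
  n_stages <- as.integer(n_stages)
  channels_per_stage <- as.integer(channels_per_stage)
  if (length(target_extent) != 3L || any(target_extent < 4L))
    stop("target_extent must be 3 components, each >= 4")
  if (length(channels_per_stage) != n_stages)
    stop("length(channels_per_stage) must equal n_stages")
  if (n_stages > 1 && any(diff(channels_per_stage) <= 0))
    stop("channels_per_stage must be strictly increasing")
  div <- 2^(n_stages - 1)
  if (any(target_extent %% div != 0))
    stop("each extent component must be divisible by 2^(n_stages - 1) = ", div,
         " (pad or choose another extent)")
  if (lambda_weight < 0 || lambda_weight > 1)
    stop("lambda_weight must lie in [0, 1]")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must lie in [0, 1)")
  structure(list(target_extent = target_extent,
                 n_stages = n_stages,
                 channels_per_stage = channels_per_stage,
                 dropout_rate = dropout_rate,
                 leaky_slope = leaky_slope,
                 n_classes = as.integer(n_classes),
                 lambda_weight = lambda_weight),
            class = "csae_config")
}

#' @export
print.csae_config <- function(x, ...) {
  cat(sprintf("<csae_config> %s input, %d stages (channels %s), %d classes, lambda %.2f\n",
              paste(x$target_extent, collapse = "x"), x$n_stages,
              paste(x$channels_per_stage, collapse = ","), x$n_classes,
              x$lambda_weight))
  invisible(x)
}

# canonical conv-layer table: encoder (2 per stage), decoder (2 per stage,
# stages n..2), output projection. Weight matrices are (27*cin) x cout with
# the spatial offset fastest within each input channel (dx, then dy, then dz).
csae_layer_table <- function(config) {
  ch <- config$channels_per_stage
  S <- config$n_stages
  rows <- list()
  for (s in seq_len(S)) {
    cin <- if (s == 1) 1L else ch[s - 1]
    rows[[length(rows) + 1]] <- data.frame(name = sprintf("enc%d_a", s), cin = cin, cout = ch[s])
    rows[[length(rows) + 1]] <- data.frame(name = sprintf("enc%d_b", s), cin = ch[s], cout = ch[s])
  }
  if (S > 1) for (s in S:2) {
    rows[[length(rows) + 1]] <- data.frame(name = sprintf("dec%d_a", s), cin = ch[s], cout = ch[s - 1])
    rows[[length(rows) + 1]] <- data.frame(name = sprintf("dec%d_b", s), cin = ch[s - 1], cout = ch[s - 1])
  }
  rows[[length(rows) + 1]] <- data.frame(name = "out", cin = ch[1], cout = 1L)
  do.call(rbind, rows)
}

csae_bottleneck_features <- function(config) {
  prod(config$target_extent %/% 2^(config$n_stages - 1)) *
    config$channels_per_stage[config$n_stages]
}

# He-normal initialization of all weights, deterministic given seed
init_csae_weights <- function(config, seed = 1) {
  with_local_seed(seed, {
    tab <- csae_layer_table(config)
    conv <- lapply(seq_len(nrow(tab)), function(i) {
      fan_in <- 27 * tab$cin[i]
      list(W = matrix(rnorm(fan_in * tab$cout[i], sd = sqrt(2 / fan_in)),
                      fan_in, tab$cout[i]),
           b = rep(0, tab$cout[i]))
    })
    names(conv) <- tab$name
    nf <- csae_bottleneck_features(config)
    list(conv = conv,
         head = list(W = matrix(rnorm(nf * config$n_classes, sd = sqrt(1 / nf)),
                                nf, config$n_classes),
                     b = rep(0, config$n_classes)))
  })
}

#' Number of trainable parameters of a CSAE
#'
#' @param config a [csae_config].
#' @return integer parameter count.
#' @export
csae_n_parameters <- function(config) {
  tab <- csae_layer_table(config)
  sum(27 * tab$cin * tab$cout + tab$cout) +
    csae_bottleneck_features(config) * config$n_classes + config$n_classes
}

as_input_matrix <- function(x, config) {
  V <- prod(config$target_extent)
  if (is.list(x) && !is.data.frame(x))
    x <- vapply(x, function(v) as.numeric(v), numeric(V))
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1)
  if (length(dim(x)) == 3L) x <- matrix(as.numeric(x), ncol = 1)
  if (nrow(x) != V)
    stop("input has ", nrow(x), " voxels per sample; config expects ", V)
  x
}

#' Fit a convolutional supervised auto-encoder
#'
#' Trains the CSAE on preprocessed input volumes with Adam, minimizing the
#' lambda-weighted sum of voxel-wise reconstruction MSE and class-weighted
#' categorical cross-entropy. Fully reproducible given `seed` (weight
#' initialization, shuffling and dropout all derive from it).
#'
#' @param x training inputs: a V x n matrix (one column per scan, voxels in
#'   (x, y, z) order), a list of 3D arrays, or a single array.
#' @param y class labels: factor (its levels fix the class order) or
#'   character/integer vector.
#' @param config a [csae_config]; its `target_extent` must match `x`.
#' @param epochs,batch_size,learning_rate Adam training settings.
#' @param class_weights per-class loss weights; default inverse-frequency
#'   weights from `y` via [class_weights].
#' @param validation optional `list(x =, y =)` held-out set evaluated each
#'   epoch for the history.
#' @param seed integer seed.
#' @param verbose print per-epoch loss.
#' @return object of class `csae`: list with `config`, `weights`, `classes`,
#'   `class_weights`, `history` (data frame with per-epoch reconstruction /
#'   classification / total losses on train and validation), and `settings`.
#' @seealso [predict.csae], [cross_validate], [guided_backprop]
#' @export
csae_fit <- function(x, y, config,
                     epochs = 30L, batch_size = 4L, learning_rate = 1e-3,
                     class_weights = NULL, validation = NULL,
                     seed = 1L, verbose = FALSE) {
  stopifnot(inherits(config, "csae_config"))
  x <- as_input_matrix(x, config)
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(y) != config$n_classes)
    stop("y has ", nlevels(y), " classes but config expects ", config$n_classes)
  if (length(y) != ncol(x)) stop("length(y) must equal the number of input columns")
  if (epochs < 1 || batch_size < 1) stop("epochs and batch_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (is.null(class_weights)) class_weights <- class_weights(y)
  if (length(class_weights) != config$n_classes || any(class_weights <= 0))
    stop("class_weights must be ", config$n_classes, " positive values")

  weights <- init_csae_weights(config, seed = stage_seed(seed, "init"))
  settings <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                   learning_rate = learning_rate,
                   lambda_weight = config$lambda_weight,
                   seed = as.integer(stage_seed(seed, "train")),
                   verbose = isTRUE(verbose))
  xv <- NULL; yv <- NULL
  if (!is.null(validation)) {
    xv <- as_input_matrix(validation$x, config)
    yv <- as.integer(factor(validation$y, levels = levels(y)))
    if (anyNA(yv)) stop("validation labels outside training levels")
  }
  fit <- cpp_csae_train(x, as.integer(y), xv, yv, weights,
                        unclass(config), settings, as.numeric(class_weights))
  history <- as.data.frame(fit$history)
  names(history) <- c("epoch", "train_reconstruction", "train_classification",
                      "train_total", "val_reconstruction", "val_classification",
                      "val_total")
  structure(list(config = config, weights = fit$weights,
                 classes = levels(y), class_weights = class_weights,
                 history = history, settings = settings,
                 n_train = ncol(x)),
            class = "csae")
}

#' Predict from a fitted CSAE
#'
#' @param object a fitted [csae_fit] model.
#' @param newdata inputs in any form accepted by [csae_fit] (already
#'   preprocessed with the same representation and, where applicable, the
#'   training fold's normalization statistics).
#' @param type `"prob"` (class-probability matrix, rows on the simplex),
#'   `"class"` (argmax labels), or `"all"` (probabilities, logits,
#'   reconstructions and per-sample reconstruction MSE).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.csae <- function(object, newdata, type = c("prob", "class", "all"), ...) {
  type <- match.arg(type)
  x <- as_input_matrix(newdata, object$config)
  out <- cpp_csae_forward(x, object$weights, unclass(object$config),
                          return_recon = (type == "all"))
  colnames(out$probs) <- object$classes
  if (type == "prob") return(out$probs)
  if (type == "class")
    return(factor(object$classes[max.col(out$probs)], levels = object$classes))
  colnames(out$logits) <- object$classes
  out
}

#' @export
print.csae <- function(x, ...) {
  cat(sprintf("Convolutional supervised auto-encoder (%d stages, lambda = %.2f)\n",
              x$config$n_stages, x$config$lambda_weight))
  cat(sprintf("  input %s, classes: %s\n",
              paste(x$config$target_extent, collapse = "x"),
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  %d parameters, trained %d epochs on %d scans\n",
              csae_n_parameters(x$config), nrow(x$history), x$n_train))
  ft <- x$history[nrow(x$history), ]
  cat(sprintf("  final train loss %.4f (recon %.4f, class %.4f)\n",
              ft$train_total, ft$train_reconstruction, ft$train_classification))
  invisible(x)
}

#' @export
summary.csae <- function(object, ...) {
  tab <- csae_layer_table(object$config)
  tab$parameters <- 27 * tab$cin * tab$cout + tab$cout
  out <- list(config = object$config, layers = tab,
              n_parameters = csae_n_parameters(object$config),
              classes = object$classes, class_weights = object$class_weights,
              history = object$history)
  class(out) <- "summary.csae"
  out
}

#' @export
print.summary.csae <- function(x, ...) {
  print(x$config)
  cat("convolution layers:\n")
  print(x$layers, row.names = FALSE)
  cat(sprintf("head + total parameters: %d\n", x$n_parameters))
  cat(sprintf("class weights: %s\n",
              paste(sprintf("%s=%.3f", x$classes, x$class_weights), collapse = ", ")))
  invisible(x)
}

#' @export
plot.csae <- function(x, which = c("total", "reconstruction", "classification"), ...) {
  which <- match.arg(which)
  h <- x$history
  tr <- h[[paste0("train_", which)]]
  va <- h[[paste0("val_", which)]]
  ylim <- range(c(tr, va), na.rm = TRUE)
  plot(h$epoch, tr, type = "l", xlab = "epoch", ylab = paste(which, "loss"),
       ylim = ylim, ...)
  if (any(is.finite(va))) {
    graphics::lines(h$epoch, va, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' @export
residuals.csae <- function(object, newdata, ...) {
  x <- as_input_matrix(newdata, object$config)
  out <- cpp_csae_forward(x, object$weights, unclass(object$config),
                          return_recon = TRUE)
  x - out$recon
}

#' Save or load a fitted CSAE checkpoint
#'
#' A checkpoint is a single file holding the weights with the configuration,
#' class labels and training history embedded, so a loaded model is
#' immediately usable with [predict.csae] and [guided_backprop].
#'
#' @param object a fitted [csae_fit] model.
#' @param path checkpoint file path (conventionally `.ckpt`).
#' @return `save_csae()` returns `path` invisibly; `load_csae()` the model.
#' @export
save_csae <- function(object, path) {
  stopifnot(inherits(object, "csae"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_csae
#' @export
load_csae <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "csae")) stop("'", path, "' is not a csae checkpoint")
  obj
}

#' The combined reconstruction/classification loss
#'
#' \deqn{L_{total} = (1-\lambda)\frac{1}{N}\sum_i (x_i - \hat x_i)^2 +
#'   \lambda\, w_c \left(-\log \hat y_c\right)}
#' where \eqn{c} is the true class. At \eqn{\lambda = 0} this is exactly the
#' reconstruction MSE; at \eqn{\lambda = 1} exactly the class-weighted
#' categorical cross-entropy. A predicted probability of exactly 0 at the
#' true class is clamped at 1e-12 (with a message).
#'
#' @param x,x_hat input and reconstruction (numeric, congruent).
#' @param y one-hot true-class vector.
#' @param y_prob predicted class probabilities (on the simplex).
#' @param lambda_weight \eqn{\lambda \in [0, 1]}.
#' @param class_weights positive per-class weights.
#' @return object of class `csae_loss`: list with `reconstruction_term`,
#'   `classification_term`, `total`.
#' @examples
#' combined_loss(c(0, 0), c(1, 0), y = c(1, 0, 0),
#'               y_prob = c(0.5, 0.25, 0.25), lambda_weight = 0.5)
#' @export
combined_loss <- function(x, x_hat, y, y_prob, lambda_weight,
                          class_weights = rep(1, length(y))) {
  if (length(x) != length(x_hat)) stop("x and x_hat are not congruent")
  if (lambda_weight < 0 || lambda_weight > 1) stop("lambda_weight must lie in [0, 1]")
  if (length(y) != length(y_prob) || length(y) != length(class_weights))
    stop("y, y_prob and class_weights must have equal length")
  if (any(y_prob < -1e-9) || abs(sum(y_prob) - 1) > 1e-6)
    stop("y_prob must lie on the probability simplex")
  if (!all(y %in% c(0, 1)) || sum(y) != 1) stop("y must be one-hot")
  if (any(class_weights <= 0)) stop("class_weights must be positive")
  cls <- which(y == 1)
  p <- y_prob[cls]
  if (p <= 0) {
    message("predicted probability 0 at the true class; clamped at 1e-12")
    p <- 1e-12
  }
  rec <- mean((x - x_hat)^2)
  ce <- -class_weights[cls] * log(p)
  structure(list(reconstruction_term = rec, classification_term = ce,
                 total = (1 - lambda_weight) * rec + lambda_weight * ce),
            class = "csae_loss")
}

#' @export
print.csae_loss <- function(x, ...) {
  cat(sprintf("total %.6g = (1-lambda) * %.6g [MSE] + lambda * %.6g [weighted CE]\n",
              x$total, x$reconstruction_term, x$classification_term))
  invisible(x)
}

#' Analytic gradient of [combined_loss]
#'
#' Gradient of the total loss with respect to the reconstruction `x_hat` and
#' the predicted probabilities `y_prob` (holding the simplex parameterization
#' fixed, i.e. the raw partial derivatives). Used for finite-difference
#' verification.
#'
#' @inheritParams combined_loss
#' @return list with `d_x_hat` and `d_y_prob`.
#' @export
combined_loss_grad <- function(x, x_hat, y, y_prob, lambda_weight,
                               class_weights = rep(1, length(y))) {
  cls <- which(y == 1)
  d_x_hat <- (1 - lambda_weight) * 2 * (x_hat - x) / length(x)
  d_y_prob <- rep(0, length(y_prob))
  d_y_prob[cls] <- -lambda_weight * class_weights[cls] / max(y_prob[cls], 1e-12)
  list(d_x_hat = d_x_hat, d_y_prob = d_y_prob)
}
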