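# Model zoo: 1D ResNet and Xception-style feature extractors, a BiLSTM
# sequence layer, a scaled-softmax head, and SGD-with-momentum training.
#
# "Layers" counts weighted layers on the extractor's main path: the initial
# convolution(s), both convolutions of each residual block (or the depthwise
# and pointwise halves of each separable convolution), and the final 1x1
# channel projection.  Shortcut projection convolutions are not counted.
# Every extractor reduces time by a total stride of 8, so the canonical
# 1056-sample window yields 132 feature steps.

#' Model configuration
#'
#' Hyperparameters for the classifiers.  The defaults are desk-scale: a
#' small extractor and short schedule that train in seconds on one CPU.  Use
#' [reference_model_config()] for the full-size reference architectures.
#'
#' @param family One of `"resnet"`, `"xception"`, `"lstm"`,
#'   `"resnet_bilstm"`, `"xception_bilstm"`.
#' @param layers Weighted-layer count of the convolutional extractor.
#' @param kernels Feature-map count (channel width) of the extractor trunk.
#' @param kernel_size Convolution kernel length.
#' @param bilstm_hidden Hidden units per LSTM direction.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum in `[0, 1)`.
#' @param weight_decay L2 regularisation coefficient, divided by the
#'   training-sample count in the update (biases are not decayed).
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param beta Softmax scale (> 0).
#' @param clip_norm Global gradient-norm ceiling per minibatch (`Inf` to
#'   disable); stabilises the recurrent backward pass.
#' @param seed Seed for weight initialisation and batch shuffling.
#' @return A list of class `model_config`.
#' @export
model_config <- function(family = c("resnet_bilstm", "xception_bilstm",
                                    "resnet", "xception", "lstm"),
                         layers = 8L, kernels = 12L, kernel_size = 7L,
                         bilstm_hidden = 32L, learning_rate = 0.02,
                         momentum = 0.9, weight_decay = 1e-4,
                         epochs = 12L, batch_size = 32L, beta = 1,
                         clip_norm = 5, seed = 1L) {
  family <- match.arg(family)
  stopifnot(layers >= 1, kernels >= 1, kernel_size >= 1, epochs >= 1,
            batch_size >= 1, learning_rate > 0, momentum >= 0, momentum < 1,
            weight_decay >= 0, beta > 0, clip_norm > 0)
  structure(list(family = family, layers = as.integer(layers),
                 kernels = as.integer(kernels),
                 kernel_size = as.integer(kernel_size),
                 bilstm_hidden = as.integer(bilstm_hidden),
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), beta = beta,
                 clip_norm = clip_norm, seed = as.integer(seed)),
            class = "model_config")
}

#' Reference (full-size) model configuration
#'
#' The 36-layer ResNet (15 feature maps) and 37-layer Xception (32-kernel
#' trunk, 64 output channels) reference extractors, with the long training
#' schedule (learning rate 0.001, 500 epochs).
#'
#' @param family `"resnet_bilstm"` or `"xception_bilstm"` (or the plain
#'   extractor families).
#' @param ... Overrides passed to [model_config()].
#' @export
reference_model_config <- function(family = "resnet_bilstm", ...) {
  args <- if (grepl("xception", family)) {
    list(family = family, layers = 37L, kernels = 32L, kernel_size = 36L)
  } else if (grepl("resnet", family)) {
    list(family = family, layers = 36L, kernels = 15L, kernel_size = 15L)
  } else {
    list(family = family)
  }
  do.call(model_config,
          utils::modifyList(c(args, learning_rate = 0.001, epochs = 500L),
                            list(...)))
}

.extractor_out_channels <- function(family) {
  if (grepl("xception", family)) 64L else 15L
}

# build the convolutional extractor layer list (no RNG discipline here;
# callers wrap construction in with_seed)
.build_extractor_layers <- function(family, layers, width, k, in_ch,
                                    out_channels) {
  lay <- list()
  if (family == "resnet") {
    if (layers < 4L) stop("resnet extractor needs at least 4 weighted layers")
    n_blocks <- (layers - 2L) %/% 2L
    extra <- (layers - 2L) %% 2L
    lay <- c(lay, list(new_layer_conv(in_ch, width, k, 2L, "same", "relu")))
    stride_done <- 2L
    for (bi in seq_len(n_blocks)) {
      s <- if (bi <= 2L && stride_done < 8L) 2L else 1L
      stride_done <- stride_done * s
      lay <- c(lay, list(new_layer_resblock(width, width, k, s)))
    }
    if (extra == 1L) {
      lay <- c(lay, list(new_layer_conv(width, width, k, 1L, "same", "relu")))
    }
    if (stride_done < 8L) {
      lay <- c(lay, list(new_layer_avgpool(8L %/% stride_done)))
    }
    lay <- c(lay, list(new_layer_conv(width, out_channels, 1L, 1L, "same",
                                      "linear")))
  } else {
    if (layers < 5L) {
      stop("xception extractor needs at least 5 weighted layers")
    }
    n_sep <- (layers - 3L) %/% 2L
    extra <- (layers - 3L) %% 2L
    entry_k <- min(k, 9L)
    lay <- c(lay, list(new_layer_conv(in_ch, width, entry_k, 2L, "same",
                                      "relu"),
                       new_layer_conv(width, width, entry_k, 1L, "same",
                                      "relu")))
    if (extra == 1L) {
      lay <- c(lay, list(new_layer_conv(width, width, entry_k, 1L, "same",
                                        "relu")))
    }
    stride_done <- 2L
    for (si in seq_len(n_sep)) {
      s <- if (si <= 2L && stride_done < 8L) 2L else 1L
      stride_done <- stride_done * s
      lay <- c(lay, list(new_layer_xsep(width, width, k, s)))
    }
    if (stride_done < 8L) {
      lay <- c(lay, list(new_layer_avgpool(8L %/% stride_done)))
    }
    lay <- c(lay, list(new_layer_conv(width, out_channels, 1L, 1L, "same",
                                      "linear")))
  }
  lay
}

#' Build a convolutional feature extractor
#'
#' Constructs the 1D extractor for a family and checks its shape contract:
#' on a `window_len`-sample input the extractor must emit
#' `out_channels x ceiling(window_len / 8)` feature maps — `(15, 132)` for
#' the reference ResNet and `(64, 132)` for the reference Xception on the
#' canonical 1056-sample window.
#'
#' @param family `"resnet"` or `"xception"`.
#' @param config A [model_config()] (its `layers`, `kernels`, `kernel_size`
#'   and `seed` fields are used).
#' @param in_channels Input channel count.
#' @param window_len Window length in samples used for the contract check.
#' @return A list of class `ppg_extractor` with elements `layers`,
#'   `out_channels` and `steps`.
#' @export
build_extractor <- function(family = c("resnet", "xception"),
                            config = model_config(), in_channels = 1L,
                            window_len = 1056L) {
  family <- match.arg(family)
  out_ch <- .extractor_out_channels(family)
  lay <- with_seed(config$seed,
    .build_extractor_layers(family, config$layers, config$kernels,
                            config$kernel_size, in_channels, out_ch))
  ext <- structure(list(layers = lay, out_channels = out_ch,
                        family = family, in_channels = in_channels),
                   class = "ppg_extractor")
  shape <- dim(extractor_forward(ext,
                                 array(0, c(in_channels, window_len, 1L))))
  expect_steps <- as.integer(ceiling(window_len / 8))
  if (shape[1] != out_ch || shape[2] != expect_steps) {
    stop("extractor shape contract violated: achieved (", shape[1], ", ",
         shape[2], "), expected (", out_ch, ", ", expect_steps, ")")
  }
  ext$steps <- expect_steps
  ext
}

#' Run an extractor forward
#'
#' @param extractor A [build_extractor()] object.
#' @param x Input array `(channels, time, batch)`.
#' @return Feature-map array `(out_channels, steps, batch)`.
#' @export
extractor_forward <- function(extractor, x) {
  for (l in extractor$layers) x <- layer_fwd(l, x)$y
  x
}

#' 1D convolution forward pass
#'
#' Cross-correlation of multi-channel inputs with a kernel bank, plus bias
#' and pointwise activation; `"valid"` padding by default.
#'
#' @param inputs Matrix `(in_channels, T)` or array
#'   `(in_channels, T, batch)`.
#' @param kernels Array `(in_channels, kernel_size, out_channels)`.
#' @param biases Numeric vector of length `out_channels`.
#' @param activation `"linear"`, `"relu"` or `"sigmoid"`.
#' @param stride Temporal stride.
#' @param pad `"valid"` (no padding) or `"same"`.
#' @return Feature maps, matrix `(out_channels, T_out)` for matrix input or
#'   the corresponding 3D array.
#' @export
conv1d_forward <- function(inputs, kernels, biases = NULL,
                           activation = c("linear", "relu", "sigmoid"),
                           stride = 1L, pad = c("valid", "same")) {
  activation <- match.arg(activation)
  pad <- match.arg(pad)
  was_mat <- is.matrix(inputs) || is.null(dim(inputs))
  if (is.null(dim(inputs))) inputs <- matrix(inputs, nrow = 1L)
  x <- if (was_mat) array(inputs, c(dim(inputs), 1L)) else inputs
  if (length(dim(kernels)) == 1L || is.null(dim(kernels))) {
    kernels <- array(kernels, c(1L, length(kernels), 1L))
  }
  if (is.null(biases)) biases <- numeric(dim(kernels)[3])
  if (dim(kernels)[2] > dim(x)[2]) {
    stop("kernel length ", dim(kernels)[2], " exceeds input length ",
         dim(x)[2])
  }
  if (dim(kernels)[1] != dim(x)[1]) {
    stop("kernel expects ", dim(kernels)[1], " input channels, got ",
         dim(x)[1])
  }
  pp <- .pad_amount(dim(x)[2], dim(kernels)[2], stride, pad)
  y <- conv1d_fwd_cpp(x, kernels, biases, as.integer(stride), pp[1], pp[2])
  y <- .act_fwd(y, activation)
  if (was_mat) y[, , 1L, drop = TRUE] else y
}

#' Initialise BiLSTM weights
#'
#' @param input_size Input feature dimension.
#' @param hidden Hidden units per direction.
#' @param seed Seed for the uniform fan-in initialisation.
#' @return A list with `forward` and `backward` weight sets (`wx`, `wh`,
#'   `b`; gate order input, forget, cell, output).
#' @export
init_bilstm_weights <- function(input_size, hidden, seed = 1L) {
  with_seed(seed, new_layer_bilstm(input_size, hidden)$params)
}

#' Bidirectional LSTM forward pass
#'
#' Concatenates a forward-time and a backward-time LSTM pass over a feature
#' sequence; output feature dimension is twice the hidden width.
#'
#' @param feature_sequence Matrix `(features, steps)` or array
#'   `(features, steps, batch)`.
#' @param weights A weight list from [init_bilstm_weights()].
#' @return Sequence embedding with `2 * hidden` channels and the same step
#'   count.
#' @export
bilstm_forward <- function(feature_sequence, weights) {
  was_mat <- is.matrix(feature_sequence)
  x <- if (was_mat) array(feature_sequence, c(dim(feature_sequence), 1L))
       else feature_sequence
  if (dim(x)[2] < 1L) stop("empty sequence")
  hidden <- ncol(weights$forward$wh)
  layer <- list(type = "bilstm", in_ch = dim(x)[1], hidden = hidden,
                params = weights)
  y <- layer_fwd(layer, x)$y
  if (was_mat) y[, , 1L, drop = TRUE] else y
}

#' Scaled softmax
#'
#' `softmax(z, beta)_i = exp(beta z_i) / sum_j exp(beta z_j)`, computed with
#' max-subtraction so large scores cannot overflow.  Columns of a matrix are
#' treated as independent score vectors.
#'
#' @param z Numeric vector or matrix of scores.
#' @param beta Positive scale; large values concentrate the distribution on
#'   the maximal score.
#' @return Probabilities of the same shape, each vector summing to 1.
#' @export
softmax <- function(z, beta = 1) {
  stopifnot(beta > 0)
  if (is.matrix(z)) {
    e <- exp(beta * sweep(z, 2L, apply(z, 2L, max)))
    sweep(e, 2L, colSums(e), "/")
  } else {
    e <- exp(beta * (z - max(z)))
    e / sum(e)
  }
}

#' One SGD-with-momentum parameter update
#'
#' Computes the update increment
#' `delta = -(lr * weight_decay / n_train) * value - (lr / batch_size) * grad
#' + momentum * prev_delta` (the decay term is dropped for biases) and
#' returns both the increment and the updated value.  `grad` is the
#' cost-function gradient summed over the minibatch.
#'
#' @param value Current parameter value (any numeric shape).
#' @param grad Gradient, same shape.
#' @param prev_delta Previous update increment, same shape.
#' @param lr Learning rate.
#' @param batch_size Minibatch size.
#' @param momentum Momentum coefficient.
#' @param weight_decay Regularisation coefficient.
#' @param n_train Training-sample count dividing the decay term.
#' @param bias If `TRUE`, no decay is applied.
#' @return List with `delta` and `value` (the updated parameter).
#' @export
sgd_step <- function(value, grad, prev_delta = 0, lr = 0.01, batch_size = 1L,
                     momentum = 0, weight_decay = 0, n_train = 1L,
                     bias = FALSE) {
  if (!identical(dim(value), dim(grad)) &&
      length(value) != length(grad)) {
    stop("shape mismatch between value (", paste(dim(value) %||%
         length(value), collapse = "x"), ") and grad (",
         paste(dim(grad) %||% length(grad), collapse = "x"), ")")
  }
  decay <- if (bias) 0 else (lr * weight_decay / n_train) * value
  delta <- -decay - (lr / batch_size) * grad + momentum * prev_delta
  list(delta = delta, value = value + delta)
}

# assemble the full layer list for a model family
.build_model_layers <- function(config, in_channels, window_len) {
  family <- config$family
  has_conv <- family %in% c("resnet", "xception", "resnet_bilstm",
                            "xception_bilstm")
  has_bilstm <- family %in% c("lstm", "resnet_bilstm", "xception_bilstm")
  lay <- list()
  feat <- in_channels
  if (has_conv) {
    base <- if (grepl("xception", family)) "xception" else "resnet"
    out_ch <- .extractor_out_channels(base)
    lay <- .build_extractor_layers(base, config$layers, config$kernels,
                                   config$kernel_size, in_channels, out_ch)
    feat <- out_ch
  } else {
    lay <- list(new_layer_avgpool(8L))
  }
  if (has_bilstm) {
    lay <- c(lay, list(new_layer_bilstm(feat, config$bilstm_hidden)))
    feat <- 2L * config$bilstm_hidden
  }
  lay <- c(lay, list(new_layer_meanpool_time(), new_layer_dense(feat, 2L)))
  lay
}

.model_forward <- function(model, x, keep_caches = FALSE) {
  caches <- if (keep_caches) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    r <- layer_fwd(model$layers[[i]], x)
    x <- r$y
    if (keep_caches) caches[[i]] <- r$cache
  }
  list(logits = x, caches = caches)
}

.model_backward <- function(model, caches, glogits) {
  grads <- vector("list", length(model$layers))
  g <- glogits
  for (i in rev(seq_along(model$layers))) {
    r <- layer_bwd(model$layers[[i]], caches[[i]], g)
    grads[[i]] <- r$grads
    g <- r$gx
  }
  grads
}

# per-window, per-channel standardisation
.standardize_windows <- function(samples_list) {
  lapply(samples_list, function(m) {
    mu <- rowMeans(m)
    sd <- sqrt(rowMeans((m - mu)^2))
    (m - mu) / pmax(sd, 1e-8)
  })
}

.windows_to_array <- function(samples_list) {
  ch <- nrow(samples_list[[1]])
  len <- ncol(samples_list[[1]])
  x <- array(0, c(ch, len, length(samples_list)))
  for (i in seq_along(samples_list)) x[, , i] <- samples_list[[i]]
  x
}

#' Train a fatigue classifier on labelled windows
#'
#' Minimises cross-entropy with the scaled-softmax head by stochastic
#' gradient descent with momentum (weight decay on weights only).  Windows
#' are standardised per window and channel before training.  Fully
#' deterministic given `config$seed`.
#'
#' @param windows Windows tibble from [segment()] / [segment_cohort()]:
#'   needs `samples` (list of channel-by-length matrices) and `label`.
#' @param config A [model_config()].
#' @return A `ppg_model` object with the trained layers, the config, and a
#'   per-epoch `history` tibble (`epoch`, `loss`, `rmse`).
#' @export
train_model <- function(windows, config = model_config()) {
  stopifnot(is.data.frame(windows), nrow(windows) >= 2)
  labels <- windows$label
  if (length(unique(labels)) < 2) {
    stop("training windows contain a single class: ", unique(labels))
  }
  xs <- .standardize_windows(windows$samples)
  x_all <- .windows_to_array(xs)
  n <- dim(x_all)[3]
  y <- rbind(as.numeric(labels == "fatigue"),
             as.numeric(labels != "fatigue"))
  model <- list(
    layers = with_seed(config$seed,
      .build_model_layers(config, dim(x_all)[1], dim(x_all)[2])),
    config = config,
    input_channels = dim(x_all)[1],
    window_len = dim(x_all)[2],
    classes = c("fatigue", "non_fatigue"))
  velocity <- lapply(model$layers, function(l) tree_zero(params_of(l)))
  history <- matrix(0, config$epochs, 2)
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(config$seed + 7919L * epoch, sample(n))
    ep_loss <- 0
    ep_sq <- 0
    n_batches <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- x_all[, , idx, drop = FALSE]
      yb <- y[, idx, drop = FALSE]
      fw <- .model_forward(model, xb, keep_caches = TRUE)
      p <- softmax(fw$logits, config$beta)
      ep_loss <- ep_loss + mean(-log(pmax(colSums(p * yb), 1e-12)))
      ep_sq <- ep_sq + mean((p[1, ] - yb[1, ])^2)
      n_batches <- n_batches + 1L
      glogits <- config$beta * (p - yb)
      grads <- .model_backward(model, fw$caches, glogits)
      if (is.finite(config$clip_norm)) {
        gnorm <- sqrt(sum(unlist(lapply(grads, function(g) {
          if (length(g)) sum(tree_flatten(g)^2) else 0
        })))) / length(idx)
        if (gnorm > config$clip_norm) {
          scale <- config$clip_norm / gnorm
          grads <- lapply(grads, function(g) {
            if (length(g)) rapply(g, function(v) v * scale, how = "replace")
            else g
          })
        }
      }
      for (i in seq_along(model$layers)) {
        if (length(grads[[i]]) == 0) next
        upd <- tree_update(
          params_of(model$layers[[i]]), grads[[i]], velocity[[i]],
          function(param, grad, state, is_bias) {
            r <- sgd_step(param, grad, state, lr = config$learning_rate,
                          batch_size = length(idx),
                          momentum = config$momentum,
                          weight_decay = config$weight_decay,
                          n_train = n, bias = is_bias)
            list(param = r$value, state = r$delta)
          })
        model$layers[[i]] <- set_params(model$layers[[i]], upd$param)
        velocity[[i]] <- upd$state
      }
    }
    history[epoch, ] <- c(ep_loss / n_batches, sqrt(ep_sq / n_batches))
  }
  model$history <- tibble::tibble(epoch = seq_len(config$epochs),
                                  loss = history[, 1], rmse = history[, 2])
  class(model) <- "ppg_model"
  model
}

#' Predict fatigue probabilities for windows
#'
#' @param object A trained `ppg_model`.
#' @param windows Windows tibble with a `samples` list-column matching the
#'   model's channel count and window length.
#' @param ... Unused.
#' @return The windows tibble (minus `samples`) with `p_fatigue`,
#'   `p_non_fatigue` and `.pred` columns.
#' @export
predict.ppg_model <- function(object, windows, ...) {
  xs <- .standardize_windows(windows$samples)
  bad <- vapply(xs, function(m) {
    nrow(m) != object$input_channels || ncol(m) != object$window_len
  }, logical(1))
  if (any(bad)) {
    stop("window shape mismatch: model expects ", object$input_channels,
         " x ", object$window_len)
  }
  x <- .windows_to_array(xs)
  logits <- .model_forward(list(layers = object$layers), x)$logits
  p <- softmax(logits, object$config$beta)
  out <- windows[, setdiff(names(windows), "samples"), drop = FALSE]
  out$p_fatigue <- p[1, ]
  out$p_non_fatigue <- p[2, ]
  out$.pred <- ifelse(p[1, ] >= 0.5, "fatigue", "non_fatigue")
  tibble::as_tibble(out)
}

#' @export
print.ppg_model <- function(x, ...) {
  cat("<ppg_model> ", x$config$family, ", ", length(x$layers), " layer groups, ",
      n_params_model(x), " parameters\n", sep = "")
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat("  trained ", nrow(x$history), " epochs; final loss ",
        signif(last$loss, 4), ", rmse ", signif(last$rmse, 4), "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn train_model Per-epoch training history as a tibble.
#' @param x A `ppg_model`.
#' @export
tidy.ppg_model <- function(x, ...) x$history

#' @describeIn train_model One-row model summary.
#' @export
glance.ppg_model <- function(x, ...) {
  tibble::tibble(family = x$config$family,
                 n_parameters = n_params_model(x),
                 epochs = x$config$epochs,
                 final_loss = x$history$loss[nrow(x$history)],
                 final_rmse = x$history$rmse[nrow(x$history)])
}

#' @describeIn train_model Training-curve plot (loss and RMSE per epoch).
#' @param object A `ppg_model`.
#' @export
autoplot.ppg_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("loss", "rmse"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training loss and RMSE") +
    ggplot2::theme_minimal()
}
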