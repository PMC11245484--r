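# Shared fixtures and independent oracles used across the test files.
# Everything is generated in code; no stored fixtures.

# brute-force nested-loop 1D convolution (cross-correlation), the oracle for
# the compiled conv kernel
naive_conv1d <- function(x, w, b = numeric(dim(w)[3])) {
  t_out <- ncol(x) - dim(w)[2] + 1L
  out <- matrix(0, dim(w)[3], t_out)
  for (o in seq_len(dim(w)[3])) {
    for (t in seq_len(t_out)) {
      acc <- b[o]
      for (i in seq_len(nrow(x))) {
        for (k in seq_len(dim(w)[2])) {
          acc <- acc + x[i, t + k - 1L] * w[i, k, o]
        }
      }
      out[o, t] <- acc
    }
  }
  out
}

# step-by-step scalar LSTM recurrence, the oracle for the compiled kernel;
# gate order i, f, g, o
naive_lstm <- function(x, wx, wh, b) {
  H <- ncol(wh)
  h <- matrix(0, H, ncol(x))
  hp <- numeric(H)
  cp <- numeric(H)
  sig <- function(v) 1 / (1 + exp(-v))
  for (t in seq_len(ncol(x))) {
    z <- as.numeric(wx %*% x[, t] + wh %*% hp + b)
    i <- sig(z[seq_len(H)])
    f <- sig(z[H + seq_len(H)])
    g <- tanh(z[2 * H + seq_len(H)])
    o <- sig(z[3 * H + seq_len(H)])
    cp <- f * cp + i * g
    hp <- o * tanh(cp)
    h[, t] <- hp
  }
  h
}

# threshold-sweep trapezoidal AUC, the oracle for the rank formulation
trapezoid_auc <- function(scores, truth) {
  pos <- truth == "fatigue"
  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(ths, function(t) mean(scores[pos] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(ths, function(t) mean(scores[!pos] >= t), numeric(1)), 1)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# small labelled window set with two distinct waveform shapes (separable)
toy_windows <- function(n_per_class = 16, len = 64, seed = 3) {
  ppgfatigue:::with_seed(seed, {
    mk <- function(f, n) {
      lapply(seq_len(n), function(i) {
        matrix(sin(2 * pi * f * seq_len(len) / len) + rnorm(len, 0, 0.2), 1)
      })
    }
    tibble::tibble(
      subject_id = "s1",
      window_index = seq_len(2 * n_per_class),
      channel = "ppg",
      label = rep(c("fatigue", "non_fatigue"), each = n_per_class),
      samples = c(mk(4, n_per_class), mk(9, n_per_class)))
  })
}

# tiny simulated cohort for fast end-to-end tests
tiny_cohort <- function(n_subjects = 4, duration_s = 60, seed = 11, ...) {
  simulate_cohort(n_subjects, synth_config(duration_s = duration_s,
                                           seed = seed), ...)
}

# rebuild a parameter tree from a flat numeric vector (gradient checking)
unflatten_like <- function(tree, values, pos = 1L) {
  if (is.list(tree)) {
    for (nm in names(tree)) {
      r <- unflatten_like(tree[[nm]], values, pos)
      tree[[nm]] <- r$tree
      pos <- r$pos
    }
    return(list(tree = tree, pos = pos))
  }
  k <- length(tree)
  new <- values[pos:(pos + k - 1L)]
  if (!is.null(dim(tree))) dim(new) <- dim(tree)
  list(tree = new, pos = pos + k)
}

# finite-difference gradient check of a full model on a 2-window batch;
# biases are jittered off zero so no ReLU pre-activation sits exactly on
# its kink
gradcheck_model <- function(config, len = 64L, n_checks = 6L, seed = 21) {
  layers <- ppgfatigue:::with_seed(config$seed,
    ppgfatigue:::.build_model_layers(config, 1L, len))
  model <- list(layers = layers)
  ppgfatigue:::with_seed(seed + 1L, {
    for (i in seq_along(model$layers)) {
      pt <- ppgfatigue:::params_of(model$layers[[i]])
      if (!length(pt)) next
      flat <- ppgfatigue:::tree_flatten(pt)
      flat <- flat + rnorm(length(flat), 0, 0.05)
      model$layers[[i]] <- ppgfatigue:::set_params(
        model$layers[[i]], unflatten_like(pt, flat)$tree)
    }
  })
  xb <- ppgfatigue:::with_seed(seed, array(rnorm(len * 2), c(1, len, 2)))
  y <- rbind(c(1, 0), c(0, 1))
  loss <- function(m) {
    p <- softmax(ppgfatigue:::.model_forward(m, xb)$logits, config$beta)
    mean(-log(colSums(p * y)))
  }
  fw <- ppgfatigue:::.model_forward(model, xb, keep_caches = TRUE)
  p <- softmax(fw$logits, config$beta)
  grads <- ppgfatigue:::.model_backward(model, fw$caches,
                                        config$beta * (p - y) / 2)
  worst <- 0
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (!length(g)) next
    pt <- ppgfatigue:::params_of(model$layers[[i]])
    flatg <- ppgfatigue:::tree_flatten(g)
    flat0 <- ppgfatigue:::tree_flatten(pt)
    idx <- ppgfatigue:::with_seed(seed + i,
                                  sample(length(flatg),
                                         min(n_checks, length(flatg))))
    for (j in idx) {
      f_at <- function(d) {
        flat <- flat0
        flat[j] <- flat[j] + d
        m2 <- model
        m2$layers[[i]] <- ppgfatigue:::set_params(
          m2$layers[[i]], unflatten_like(pt, flat)$tree)
        loss(m2)
      }
      eps <- 1e-6
      num <- (f_at(eps) - f_at(-eps)) / (2 * eps)
      rel <- abs(num - flatg[j]) / max(abs(num), abs(flatg[j]), 1e-4)
      worst <- max(worst, rel)
    }
  }
  worst
}
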