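# Internal layer framework: constructors, forward passes with caches, and
# hand-written backward passes.  Tensors are (channels, time, batch) arrays
# until global time-pooling, then (features, batch) matrices.

# He-style uniform for ReLU paths, Glorot-style for linear / gated ones;
# both are fan-scaled so activation variance is preserved through depth
.init_he <- function(dims, fan_in) {
  array(stats::runif(prod(dims), -1, 1) * sqrt(6 / fan_in), dim = dims)
}

.init_glorot <- function(dims, fan_in, fan_out) {
  array(stats::runif(prod(dims), -1, 1) * sqrt(6 / (fan_in + fan_out)),
        dim = dims)
}

.pad_amount <- function(T, k, stride, pad) {
  if (pad == "valid") return(c(0L, 0L))
  t_out <- ceiling(T / stride)
  total <- max(0L, (t_out - 1L) * stride + k - T)
  c(total %/% 2L, total - total %/% 2L)
}

.act_fwd <- function(z, activation) {
  switch(activation,
         linear = z,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)))
}

.act_bwd <- function(gy, z, activation) {
  switch(activation,
         linear = gy,
         relu = gy * (z > 0),
         sigmoid = { s <- 1 / (1 + exp(-z)); gy * s * (1 - s) })
}

new_layer_conv <- function(in_ch, out_ch, k, stride = 1L, pad = "same",
                           activation = "relu") {
  W <- if (activation == "relu") {
    .init_he(c(in_ch, k, out_ch), in_ch * k)
  } else {
    .init_glorot(c(in_ch, k, out_ch), in_ch * k, out_ch * k)
  }
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
       stride = as.integer(stride), pad = pad, activation = activation,
       params = list(W = W, b = numeric(out_ch)))
}

new_layer_dwconv <- function(ch, k, stride = 1L, pad = "same") {
  list(type = "dwconv", ch = ch, k = as.integer(k),
       stride = as.integer(stride), pad = pad,
       params = list(W = matrix(.init_he(c(k, ch), k), k, ch),
                     b = numeric(ch)))
}

new_layer_resblock <- function(in_ch, out_ch, k, stride = 1L) {
  sub <- list(
    conv1 = new_layer_conv(in_ch, out_ch, k, stride, "same", "relu"),
    conv2 = new_layer_conv(out_ch, out_ch, k, 1L, "same", "linear"))
  if (stride != 1L || in_ch != out_ch) {
    sub$proj <- new_layer_conv(in_ch, out_ch, 1L, stride, "same", "linear")
  }
  list(type = "resblock", sub = sub)
}

new_layer_xsep <- function(in_ch, out_ch, k, stride = 1L) {
  sub <- list(
    dw = new_layer_dwconv(in_ch, k, stride, "same"),
    pw = new_layer_conv(in_ch, out_ch, 1L, 1L, "same", "linear"))
  if (stride != 1L || in_ch != out_ch) {
    sub$proj <- new_layer_conv(in_ch, out_ch, 1L, stride, "same", "linear")
  }
  list(type = "xsep", sub = sub)
}

new_layer_avgpool <- function(stride) {
  list(type = "avgpool", stride = as.integer(stride), params = list())
}

new_layer_bilstm <- function(in_ch, hidden) {
  mk <- function() list(
    wx = matrix(.init_glorot(c(4 * hidden, in_ch), in_ch, hidden),
                4 * hidden, in_ch),
    wh = matrix(.init_glorot(c(4 * hidden, hidden), hidden, hidden),
                4 * hidden, hidden),
    b = numeric(4 * hidden))
  list(type = "bilstm", in_ch = in_ch, hidden = hidden,
       params = list(forward = mk(), backward = mk()))
}

new_layer_meanpool_time <- function() list(type = "meanpool_time", params = list())

new_layer_dense <- function(in_dim, out_dim) {
  list(type = "dense", in_dim = in_dim, out_dim = out_dim,
       params = list(W = matrix(.init_glorot(c(out_dim, in_dim), in_dim,
                                            out_dim), out_dim, in_dim),
                     b = numeric(out_dim)))
}

.rev_time <- function(x) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]

.rev_slices <- function(x) x[, , rev(seq_len(dim(x)[3])), drop = FALSE]

layer_fwd <- function(layer, x) {
  switch(layer$type,
    conv = {
      pp <- .pad_amount(dim(x)[2], layer$k, layer$stride, layer$pad)
      z <- conv1d_fwd_cpp(x, layer$params$W, layer$params$b, layer$stride,
                          pp[1], pp[2])
      list(y = .act_fwd(z, layer$activation), cache = list(x = x, z = z, pp = pp))
    },
    dwconv = {
      pp <- .pad_amount(dim(x)[2], layer$k, layer$stride, layer$pad)
      z <- dwconv1d_fwd_cpp(x, layer$params$W, layer$params$b, layer$stride,
                            pp[1], pp[2])
      list(y = z, cache = list(x = x, pp = pp))
    },
    resblock = {
      f1 <- layer_fwd(layer$sub$conv1, x)
      f2 <- layer_fwd(layer$sub$conv2, f1$y)
      if (!is.null(layer$sub$proj)) {
        fs <- layer_fwd(layer$sub$proj, x)
        sc <- fs$y
      } else {
        fs <- NULL
        sc <- x
      }
      z <- f2$y + sc
      list(y = pmax(z, 0),
           cache = list(f1 = f1, f2 = f2, fs = fs, z = z))
    },
    xsep = {
      f1 <- layer_fwd(layer$sub$dw, x)
      f2 <- layer_fwd(layer$sub$pw, f1$y)
      if (!is.null(layer$sub$proj)) {
        fs <- layer_fwd(layer$sub$proj, x)
        sc <- fs$y
      } else {
        fs <- NULL
        sc <- x
      }
      z <- f2$y + sc
      list(y = pmax(z, 0),
           cache = list(f1 = f1, f2 = f2, fs = fs, z = z))
    },
    avgpool = {
      s <- layer$stride
      t_out <- dim(x)[2] %/% s
      idx <- seq_len(t_out * s)
      xr <- x[, idx, , drop = FALSE]
      ch <- dim(x)[1]
      # mean over the length-s pooling axis without apply(): fold it into
      # the leading dimension and use colSums
      dim(xr) <- c(ch, s, t_out * dim(x)[3])
      y <- colSums(aperm(xr, c(2, 1, 3))) / s
      dim(y) <- c(ch, t_out, dim(x)[3])
      list(y = y, cache = list(in_dim = dim(x)))
    },
    bilstm = {
      if (dim(x)[2] < 1) stop("empty sequence")
      pf <- layer$params$forward
      pb <- layer$params$backward
      xp <- aperm(x, c(1, 3, 2))        # (features, batch, time)
      xpr <- .rev_slices(xp)
      rf <- lstm_fwd_cpp(xp, pf$wx, pf$wh, pf$b)
      rb <- lstm_fwd_cpp(xpr, pb$wx, pb$wh, pb$b)
      H <- layer$hidden
      y <- array(0, c(2 * H, dim(x)[2], dim(x)[3]))
      y[seq_len(H), , ] <- aperm(rf$h, c(1, 3, 2))
      y[H + seq_len(H), , ] <- aperm(.rev_slices(rb$h), c(1, 3, 2))
      list(y = y, cache = list(xp = xp, xpr = xpr, rf = rf, rb = rb))
    },
    meanpool_time = {
      y <- colSums(aperm(x, c(2, 1, 3))) / dim(x)[2]
      dim(y) <- c(dim(x)[1], dim(x)[3])
      list(y = y, cache = list(in_dim = dim(x)))
    },
    dense = {
      y <- layer$params$W %*% x + layer$params$b
      list(y = y, cache = list(x = x))
    },
    stop("unknown layer type: ", layer$type))
}

layer_bwd <- function(layer, cache, gy) {
  switch(layer$type,
    conv = {
      gz <- .act_bwd(gy, cache$z, layer$activation)
      r <- conv1d_bwd_cpp(cache$x, layer$params$W, gz, layer$stride,
                          cache$pp[1], cache$pp[2])
      list(gx = r$gx, grads = list(W = r$gw, b = as.numeric(r$gb)))
    },
    dwconv = {
      r <- dwconv1d_bwd_cpp(cache$x, layer$params$W, gy, layer$stride,
                            cache$pp[1], cache$pp[2])
      list(gx = r$gx, grads = list(W = r$gw, b = as.numeric(r$gb)))
    },
    resblock = , xsep = {
      gz <- gy * (cache$z > 0)
      first <- if (layer$type == "resblock") "conv1" else "dw"
      second <- if (layer$type == "resblock") "conv2" else "pw"
      b2 <- layer_bwd(layer$sub[[second]], cache$f2$cache, gz)
      b1 <- layer_bwd(layer$sub[[first]], cache$f1$cache, b2$gx)
      grads <- list()
      grads[[first]] <- b1$grads
      grads[[second]] <- b2$grads
      gx <- b1$gx
      if (!is.null(layer$sub$proj)) {
        bs <- layer_bwd(layer$sub$proj, cache$fs$cache, gz)
        grads$proj <- bs$grads
        gx <- gx + bs$gx
      } else {
        gx <- gx + gz
      }
      list(gx = gx, grads = list(sub = grads))
    },
    avgpool = {
      s <- layer$stride
      d <- cache$in_dim
      t_out <- dim(gy)[2]
      gx <- array(0, d)
      g <- gy / s
      for (j in seq_len(s)) {
        gx[, (seq_len(t_out) - 1L) * s + j, ] <- g
      }
      list(gx = gx, grads = list())
    },
    bilstm = {
      H <- layer$hidden
      pf <- layer$params$forward
      pb <- layer$params$backward
      ghf <- aperm(gy[seq_len(H), , , drop = FALSE], c(1, 3, 2))
      ghb <- .rev_slices(aperm(gy[H + seq_len(H), , , drop = FALSE],
                               c(1, 3, 2)))
      bf <- lstm_bwd_cpp(cache$xp, pf$wx, pf$wh, cache$rf$h, cache$rf$c,
                         cache$rf$gates, ghf)
      bb <- lstm_bwd_cpp(cache$xpr, pb$wx, pb$wh, cache$rb$h, cache$rb$c,
                         cache$rb$gates, ghb)
      list(gx = aperm(bf$gx + .rev_slices(bb$gx), c(1, 3, 2)),
           grads = list(forward = list(wx = bf$gwx, wh = bf$gwh,
                                       b = as.numeric(bf$gb)),
                        backward = list(wx = bb$gwx, wh = bb$gwh,
                                       b = as.numeric(bb$gb))))
    },
    meanpool_time = {
      d <- cache$in_dim
      gx <- array(0, d)
      for (t in seq_len(d[2])) gx[, t, ] <- gy / d[2]
      list(gx = gx, grads = list())
    },
    dense = {
      list(gx = t(layer$params$W) %*% gy,
           grads = list(W = gy %*% t(cache$x), b = rowSums(gy)))
    },
    stop("unknown layer type: ", layer$type))
}

# ---- parameter tree helpers (params and grads share the same nesting) ----

params_of <- function(layer) {
  if (!is.null(layer$sub)) {
    list(sub = lapply(layer$sub, function(l) l$params))
  } else {
    layer$params
  }
}

set_params <- function(layer, p) {
  if (!is.null(layer$sub)) {
    for (nm in names(layer$sub)) layer$sub[[nm]]$params <- p$sub[[nm]]
  } else {
    layer$params <- p
  }
  layer
}

# apply f(param, grad, state, is_bias) over parallel nested lists; returns
# list(param = ..., state = ...) trees
tree_update <- function(param, grad, state, f, name = "") {
  if (is.list(param)) {
    out_p <- param
    out_s <- state
    for (nm in names(param)) {
      r <- tree_update(param[[nm]], grad[[nm]], state[[nm]], f, nm)
      out_p[[nm]] <- r$param
      out_s[[nm]] <- r$state
    }
    list(param = out_p, state = out_s)
  } else {
    f(param, grad, state, identical(name, "b"))
  }
}

tree_zero <- function(param) {
  if (is.list(param)) lapply(param, tree_zero)
  else if (is.null(dim(param))) numeric(length(param))
  else array(0, dim = dim(param))
}

tree_add <- function(a, b) {
  if (is.list(a)) purrr::map2(a, b, tree_add) else a + b
}

tree_flatten <- function(p) {
  if (is.list(p)) unlist(lapply(p, tree_flatten), use.names = FALSE)
  else as.numeric(p)
}

n_params_model <- function(model) {
  sum(vapply(model$layers, function(l) length(tree_flatten(params_of(l))),
             numeric(1)))
}
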