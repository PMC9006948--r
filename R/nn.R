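# A compact CNN engine in base R.  Batches are (H, W, C, N) arrays;
# convolutions run as im2col gathers followed by one BLAS matrix
# multiplication, and the backward pass mirrors each forward step, so
# the whole network is trainable and differentiable end to end (the
# latter is what GradCAM needs).
#
# Weight layout for a convolution: W is (out_channels x k*k*in_channels)
# with the column index running over kernel row (fastest), kernel column,
# then input channel; the im2col index matrix is built in the same order.

# ---- im2col ---------------------------------------------------------------

# Index matrix (k*k*C x Ho*Wo) of padded linear positions for each output
# location, in column-major output order.
build_im2col <- function(H, W, C, k, stride = 1L, pad = 0L) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  oi <- rep(seq_len(Ho), Wo); oj <- rep(seq_len(Wo), each = Ho)
  bi <- (oi - 1L) * stride; bj <- (oj - 1L) * stride  # 0-based top-left
  idx <- matrix(0L, k * k * C, Ho * Wo)
  r <- 1L
  for (c in seq_len(C)) for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    idx[r, ] <- (bi + di + 1L) + (bj + dj) * Hp + (c - 1L) * Hp * Wp
    r <- r + 1L
  }
  list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
}

pad_batch <- function(x, pad, fill = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(fill, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

# ---- layer constructors ---------------------------------------------------

layer_conv <- function(name, in_ch, out_ch, k = 3L, stride = 1L,
                       pad = (k - 1L) %/% 2L, init_scale = NULL) {
  fan_in <- k * k * in_ch
  sc <- if (is.null(init_scale)) sqrt(2 / fan_in) else init_scale
  list(type = "conv", name = name, in_ch = in_ch, out_ch = out_ch,
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       W = matrix(stats::rnorm(out_ch * fan_in, 0, sc), out_ch),
       b = numeric(out_ch))
}

layer_bn <- function(name, ch, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", name = name, ch = ch, momentum = momentum, eps = eps,
       gamma = rep(1, ch), beta = numeric(ch),
       run_mean = numeric(ch), run_var = rep(1, ch))
}

layer_relu <- function(name) list(type = "relu", name = name)
layer_pool <- function(name, k = 2L, stride = k, pad = 0L)
  list(type = "pool", name = name, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
layer_gap <- function(name) list(type = "gap", name = name)
layer_dense <- function(name, in_f, out_f, init_scale = NULL) {
  sc <- if (is.null(init_scale)) sqrt(2 / in_f) else init_scale
  list(type = "dense", name = name, in_f = in_f, out_f = out_f,
       W = matrix(stats::rnorm(out_f * in_f, 0, sc), out_f),
       b = numeric(out_f))
}
layer_dropout <- function(name, p) list(type = "dropout", name = name, p = p)

layer_resblock <- function(name, in_ch, out_ch, stride = 1L) {
  down <- (stride != 1L || in_ch != out_ch)
  list(type = "resblock", name = name, down = down,
       conv1 = layer_conv(paste0(name, ".conv1"), in_ch, out_ch, 3L, stride),
       bn1 = layer_bn(paste0(name, ".bn1"), out_ch),
       conv2 = layer_conv(paste0(name, ".conv2"), out_ch, out_ch, 3L, 1L),
       bn2 = layer_bn(paste0(name, ".bn2"), out_ch),
       down_conv = if (down) layer_conv(paste0(name, ".down"), in_ch, out_ch,
                                        1L, stride, pad = 0L),
       down_bn = if (down) layer_bn(paste0(name, ".downbn"), out_ch))
}

# ---- single-layer forward / backward --------------------------------------

.bcast_ch <- function(vec, d) rep(rep(vec, each = d[1] * d[2]), times = d[4])

layer_forward <- function(layer, x, train = FALSE) {
  switch(layer$type,
    conv = {
      d <- dim(x)
      im <- build_im2col(d[1], d[2], d[3], layer$k, layer$stride, layer$pad)
      xp <- pad_batch(x, layer$pad)
      dim(xp) <- c(im$Hp * im$Wp * d[3], d[4])
      cols <- xp[as.vector(im$idx), , drop = FALSE]
      dim(cols) <- c(nrow(im$idx), ncol(im$idx) * d[4])
      y <- layer$W %*% cols + layer$b
      out <- aperm(array(y, c(layer$out_ch, im$Ho, im$Wo, d[4])), c(2, 3, 1, 4))
      list(out = out, cache = list(cols = cols, im = im, din = d))
    },
    bn = {
      d <- dim(x)
      n_eff <- d[1] * d[2] * d[4]
      if (train) {
        m <- apply(x, 3, mean)
        v <- apply(x, 3, stats::var) * (prod(d[-3]) - 1) / prod(d[-3])
      } else {
        m <- layer$run_mean; v <- layer$run_var
      }
      sd_ <- sqrt(v + layer$eps)
      xhat <- (x - .bcast_ch(m, d)) / .bcast_ch(sd_, d)
      y <- xhat * .bcast_ch(layer$gamma, d) + .bcast_ch(layer$beta, d)
      list(out = y, cache = list(xhat = xhat, sd = sd_, d = d, train = train,
                                 batch_mean = if (train) m, batch_var = if (train) v))
    },
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    pool = {
      d <- dim(x)
      im <- build_im2col(d[1], d[2], 1L, layer$k, layer$stride, layer$pad)
      xp <- pad_batch(x, layer$pad, fill = -Inf)
      dim(xp) <- c(im$Hp * im$Wp, d[3] * d[4])
      cols <- xp[as.vector(im$idx), , drop = FALSE]   # (k2*HoWo) x (C*N)
      dim(cols) <- c(nrow(im$idx), ncol(im$idx) * d[3] * d[4])
      amax <- max.col(t(cols), ties.method = "first")
      y <- cols[cbind(amax, seq_along(amax))]
      out <- array(y, c(im$Ho, im$Wo, d[3], d[4]))
      list(out = out, cache = list(amax = amax, im = im, din = d))
    },
    gap = {
      d <- dim(x)
      dim(x) <- c(d[1] * d[2], d[3] * d[4])
      y <- matrix(colMeans(x), d[3], d[4])
      list(out = y, cache = list(din = d))
    },
    dense = list(out = layer$W %*% x + layer$b, cache = list(x = x)),
    dropout = {
      if (!train || layer$p <= 0) list(out = x, cache = list(mask = NULL))
      else {
        mask <- array(stats::runif(length(x)) >= layer$p, dim(x)) / (1 - layer$p)
        list(out = x * mask, cache = list(mask = mask))
      }
    },
    resblock = {
      c1 <- layer_forward(layer$conv1, x, train)
      b1 <- layer_forward(layer$bn1, c1$out, train)
      r1 <- layer_forward(layer_relu("tmp"), b1$out, train)
      c2 <- layer_forward(layer$conv2, r1$out, train)
      b2 <- layer_forward(layer$bn2, c2$out, train)
      if (layer$down) {
        dc <- layer_forward(layer$down_conv, x, train)
        db <- layer_forward(layer$down_bn, dc$out, train)
        short <- db$out
      } else { dc <- db <- NULL; short <- x }
      s <- b2$out + short
      out <- pmax(s, 0)
      list(out = out, cache = list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2,
                                   dc = dc, db = db, mask = s > 0))
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      im <- cache$im; d <- cache$din
      dyp <- aperm(dy, c(3, 1, 2, 4))
      dim(dyp) <- c(layer$out_ch, im$Ho * im$Wo * d[4])
      db <- rowSums(dyp)
      dW <- tcrossprod(dyp, cache$cols)
      dcols <- crossprod(layer$W, dyp)
      dim(dcols) <- c(nrow(im$idx) * ncol(im$idx), d[4])
      rs <- rowsum(dcols, group = as.vector(im$idx))
      dxp <- matrix(0, im$Hp * im$Wp * d[3], d[4])
      dxp[as.integer(rownames(rs)), ] <- rs
      dim(dxp) <- c(im$Hp, im$Wp, d[3], d[4])
      dx <- dxp[layer$pad + seq_len(d[1]), layer$pad + seq_len(d[2]), , ,
                drop = FALSE]
      list(dx = dx, grads = list(W = dW, b = db))
    },
    bn = {
      d <- cache$d
      g <- layer$gamma
      dxhat <- dy * .bcast_ch(g, d)
      dgamma <- apply(dy * cache$xhat, 3, sum)
      dbeta <- apply(dy, 3, sum)
      if (cache$train) {
        n <- prod(d[-3])
        s1 <- apply(dxhat, 3, sum)
        s2 <- apply(dxhat * cache$xhat, 3, sum)
        dx <- (dxhat - .bcast_ch(s1 / n, d) -
                 cache$xhat * .bcast_ch(s2 / n, d)) / .bcast_ch(cache$sd, d)
      } else {
        dx <- dxhat / .bcast_ch(cache$sd, d)
      }
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dy * cache$mask, grads = NULL),
    pool = {
      im <- cache$im; d <- cache$din
      k2 <- layer$k^2
      ncols <- im$Ho * im$Wo * d[3] * d[4]
      dcols <- matrix(0, k2, ncols)
      dcols[cbind(cache$amax, seq_len(ncols))] <- as.vector(dy)
      dim(dcols) <- c(k2 * im$Ho * im$Wo, d[3] * d[4])
      rs <- rowsum(dcols, group = as.vector(im$idx))
      dxp <- matrix(0, im$Hp * im$Wp, d[3] * d[4])
      dxp[as.integer(rownames(rs)), ] <- rs
      dim(dxp) <- c(im$Hp, im$Wp, d[3], d[4])
      dx <- dxp[layer$pad + seq_len(d[1]), layer$pad + seq_len(d[2]), , ,
                drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    gap = {
      d <- cache$din
      dx <- array(rep(as.vector(dy) / (d[1] * d[2]), each = d[1] * d[2]), d)
      list(dx = dx, grads = NULL)
    },
    dense = list(dx = crossprod(layer$W, dy),
                 grads = list(W = tcrossprod(dy, cache$x), b = rowSums(dy))),
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = NULL)
      else list(dx = dy * cache$mask, grads = NULL)
    },
    resblock = {
      ds <- dy * cache$mask
      bb2 <- layer_backward(layer$bn2, cache$b2$cache, ds)
      bc2 <- layer_backward(layer$conv2, cache$c2$cache, bb2$dx)
      br1 <- layer_backward(layer_relu("tmp"), cache$r1$cache, bc2$dx)
      bb1 <- layer_backward(layer$bn1, cache$b1$cache, br1$dx)
      bc1 <- layer_backward(layer$conv1, cache$c1$cache, bb1$dx)
      if (layer$down) {
        bdb <- layer_backward(layer$down_bn, cache$db$cache, ds)
        bdc <- layer_backward(layer$down_conv, cache$dc$cache, bdb$dx)
        dx <- bc1$dx + bdc$dx
        grads <- list(conv1 = bc1$grads, bn1 = bb1$grads, conv2 = bc2$grads,
                      bn2 = bb2$grads, down_conv = bdc$grads, down_bn = bdb$grads)
      } else {
        dx <- bc1$dx + ds
        grads <- list(conv1 = bc1$grads, bn1 = bb1$grads, conv2 = bc2$grads,
                      bn2 = bb2$grads)
      }
      list(dx = dx, grads = grads)
    },
    stop("unknown layer type: ", layer$type))
}

# ---- network forward / backward -------------------------------------------

# Forward pass.  `x` is (H, W, C, N).  Returns logits (2 x N), per-layer
# caches (when want_cache) and the activations of any layers named in
# `collect`.
nn_forward <- function(net, x, train = FALSE, want_cache = FALSE,
                       collect = character(0)) {
  caches <- if (want_cache) vector("list", length(net$layers))
  collected <- list()
  for (i in seq_along(net$layers)) {
    lf <- layer_forward(net$layers[[i]], x, train)
    x <- lf$out
    if (want_cache) caches[[i]] <- lf$cache
    nm <- net$layers[[i]]$name
    if (nm %in% collect) collected[[nm]] <- x
  }
  list(logits = x, caches = caches, collected = collected)
}

# Backward pass from d(loss)/d(logits).  When `upto` names a layer, the
# backward pass stops there and returns the gradient with respect to that
# layer's *output*; otherwise gradients for every parameterized layer are
# accumulated.
nn_backward <- function(net, caches, dlogits, upto = NULL) {
  grads <- vector("list", length(net$layers))
  names(grads) <- vapply(net$layers, `[[`, "", "name")
  dy <- dlogits
  for (i in rev(seq_along(net$layers))) {
    nm <- net$layers[[i]]$name
    if (!is.null(upto) && nm == upto)
      return(list(d_out = dy, grads = grads))
    lb <- layer_backward(net$layers[[i]], caches[[i]], dy)
    grads[i] <- list(lb$grads)   # keep NULL slots without shrinking the list
    dy <- lb$dx
  }
  list(d_input = dy, grads = grads)
}

# Update running batch-norm statistics from the caches of a training-mode
# forward pass (returns the updated network).
nn_update_bn <- function(net, caches) {
  upd <- function(layer, cache) {
    if (layer$type == "bn" && isTRUE(cache$train)) {
      layer$run_mean <- (1 - layer$momentum) * layer$run_mean +
        layer$momentum * cache$batch_mean
      layer$run_var <- (1 - layer$momentum) * layer$run_var +
        layer$momentum * cache$batch_var
    } else if (layer$type == "resblock") {
      layer$bn1 <- upd(layer$bn1, cache$b1$cache)
      layer$bn2 <- upd(layer$bn2, cache$b2$cache)
      if (layer$down) layer$down_bn <- upd(layer$down_bn, cache$db$cache)
    }
    layer
  }
  for (i in seq_along(net$layers))
    net$layers[[i]] <- upd(net$layers[[i]], caches[[i]])
  net
}

# ---- parameter bookkeeping ------------------------------------------------

.param_fields <- c(conv = "W b", dense = "W b", bn = "gamma beta")

# Flatten all trainable parameters to a named list of arrays.
nn_params <- function(net) {
  out <- list()
  walk <- function(layer) {
    if (layer$type == "resblock") {
      for (f in c("conv1", "bn1", "conv2", "bn2",
                  if (layer$down) c("down_conv", "down_bn")))
        walk(layer[[f]])
    } else if (layer$type %in% names(.param_fields)) {
      for (f in strsplit(.param_fields[[layer$type]], " ")[[1]])
        out[[paste0(layer$name, ".", f)]] <<- layer[[f]]
    }
  }
  for (l in net$layers) walk(l)
  out
}

# Write a named parameter list back into the network.
nn_set_params <- function(net, params) {
  put <- function(layer) {
    if (layer$type == "resblock") {
      for (f in c("conv1", "bn1", "conv2", "bn2",
                  if (layer$down) c("down_conv", "down_bn")))
        layer[[f]] <- put(layer[[f]])
    } else if (layer$type %in% names(.param_fields)) {
      for (f in strsplit(.param_fields[[layer$type]], " ")[[1]]) {
        key <- paste0(layer$name, ".", f)
        if (!is.null(params[[key]])) layer[[f]] <- params[[key]]
      }
    }
    layer
  }
  for (i in seq_along(net$layers)) net$layers[[i]] <- put(net$layers[[i]])
  net
}

# Flatten the nested gradient structure returned by nn_backward to the
# same naming scheme as nn_params.
nn_flatten_grads <- function(net, grads) {
  out <- list()
  walk <- function(layer, g) {
    if (is.null(g)) return()
    if (layer$type == "resblock") {
      for (f in names(g)) walk(layer[[f]], g[[f]])
    } else {
      fields <- strsplit(.param_fields[[layer$type]], " ")[[1]]
      for (f in names(g)) {
        key <- paste0(layer$name, ".",
                      if (layer$type == "bn") f else f)
        out[[key]] <<- g[[f]]
      }
    }
  }
  for (i in seq_along(net$layers)) walk(net$layers[[i]], grads[[i]])
  out
}

# ---- optimizers -----------------------------------------------------------

# SGD with momentum 0.9, Adam and RMSProp with their usual defaults.
make_optimizer <- function(type = c("adam", "rmsprop", "sgd"), lr) {
  type <- match.arg(type)
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  step <- function(params, grads, lr_scale = 1) {
    lr <- lr * lr_scale
    state$t <- state$t + 1L
    for (key in names(grads)) {
      g <- grads[[key]]
      if (is.null(g)) next
      p <- params[[key]]
      if (type == "sgd") {
        v <- if (is.null(state[[key]])) 0 else state[[key]]
        v <- 0.9 * v + g
        state[[key]] <- v
        params[[key]] <- p - lr * v
      } else if (type == "rmsprop") {
        s <- if (is.null(state[[key]])) 0 else state[[key]]
        s <- 0.99 * s + 0.01 * g^2
        state[[key]] <- s
        params[[key]] <- p - lr * g / (sqrt(s) + 1e-8)
      } else {
        ms <- state[[key]]
        if (is.null(ms)) ms <- list(m = 0, v = 0)
        ms$m <- 0.9 * ms$m + 0.1 * g
        ms$v <- 0.999 * ms$v + 0.001 * g^2
        state[[key]] <- ms
        mhat <- ms$m / (1 - 0.9^state$t)
        vhat <- ms$v / (1 - 0.999^state$t)
        params[[key]] <- p - lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
    params
  }
  list(type = type, lr = lr, step = step)
}
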