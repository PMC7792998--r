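# Minimal CNN engine: composable layers (conv / leaky-ReLU / ReLU / batch
# norm / 2x2 max pool / 2x nearest upsample) with exact manual backprop and
# an Adam optimizer. Spatial kernels run in C++ (im2col + GEMM); pointwise
# and normalization layers are vectorized R. Layout: (H, W, C, N).

lyr_conv <- function(kh, kw, cin, cout, slope = 0.1) {
  fan_in <- kh * kw * cin
  sd <- sqrt(2 / (fan_in * (1 + slope^2)))  # He init adjusted for leaky ReLU
  list(type = "conv",
       W = array(rnorm(kh * kw * cin * cout, sd = sd), c(kh, kw, cin, cout)),
       b = numeric(cout))
}

lyr_lrelu <- function(slope) list(type = "lrelu", slope = slope)
lyr_relu <- function() list(type = "relu")
lyr_pool <- function() list(type = "pool")
lyr_up <- function() list(type = "up")

lyr_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c),
       momentum = momentum, eps = eps)
}

# Per-channel reductions on (H,W,C,N) arrays without transposition: reshape
# (free) to an (H*W) x (C*N) matrix whose column c + C*(n-1) holds channel c
# of sample n, reduce columns, then fold the C x N result over samples.
chan_mean <- function(m, C, N) rowMeans(matrix(colMeans(m), C, N))

# broadcast a per-channel vector across the (H*W) x (C*N) layout
chan_rep <- function(v, N) rep.int(v, N)

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv = {
      list(y = conv2d_fwd(x, layer$W, layer$b), cache = list(x = x), layer = layer)
    },
    lrelu = {
      neg <- x < 0
      y <- x
      y[neg] <- layer$slope * x[neg]
      list(y = y, cache = list(neg = neg), layer = layer)
    },
    relu = {
      neg <- x < 0
      y <- x
      y[neg] <- 0
      list(y = y, cache = list(neg = neg), layer = layer)
    },
    bn = {
      d <- dim(x)
      C <- d[3]; N <- d[4]
      dim(x) <- c(d[1] * d[2], C * N)
      if (training) {
        mu <- chan_mean(x, C, N)
        ctr <- x - matrix(chan_rep(mu, N), nrow(x), ncol(x), byrow = TRUE)
        va <- chan_mean(ctr^2, C, N)
        invstd <- 1 / sqrt(va + layer$eps)
        xhat <- ctr * matrix(chan_rep(invstd, N), nrow(x), ncol(x), byrow = TRUE)
        layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
        layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * va
        y <- xhat * matrix(chan_rep(layer$gamma, N), nrow(x), ncol(x), byrow = TRUE) +
          matrix(chan_rep(layer$beta, N), nrow(x), ncol(x), byrow = TRUE)
        dim(y) <- d
        list(y = y, cache = list(xhat = xhat, invstd = invstd, d = d),
             layer = layer)
      } else {
        scale <- layer$gamma / sqrt(layer$run_var + layer$eps)
        shift <- layer$beta - layer$run_mean * scale
        y <- x * matrix(chan_rep(scale, N), nrow(x), ncol(x), byrow = TRUE) +
          matrix(chan_rep(shift, N), nrow(x), ncol(x), byrow = TRUE)
        dim(y) <- d
        list(y = y, cache = NULL, layer = layer)
      }
    },
    pool = {
      r <- maxpool2_fwd(x)
      list(y = r$y, cache = list(argmax = r$argmax, xdim = dim(x)), layer = layer)
    },
    up = {
      list(y = upsample2_fwd(x), cache = NULL, layer = layer)
    },
    stop("unknown layer type ", layer$type)
  )
}

layer_backward <- function(layer, cache, gy) {
  switch(layer$type,
    conv = {
      r <- conv2d_bwd(cache$x, layer$W, gy)
      list(gx = r$gx, grads = list(W = r$gW, b = r$gb))
    },
    lrelu = {
      gx <- gy
      gx[cache$neg] <- layer$slope * gy[cache$neg]
      list(gx = gx, grads = NULL)
    },
    relu = {
      gx <- gy
      gx[cache$neg] <- 0
      list(gx = gx, grads = NULL)
    },
    bn = {
      d <- cache$d
      C <- d[3]; N <- d[4]
      dim(gy) <- dim(cache$xhat)
      npop <- d[1] * d[2] * N  # population per channel
      chan_sum <- function(m) rowSums(matrix(colSums(m), C, N))
      ggamma <- chan_sum(gy * cache$xhat)
      gbeta <- chan_sum(gy)
      bc <- function(v) matrix(chan_rep(v, N), nrow(gy), ncol(gy), byrow = TRUE)
      gxhat <- gy * bc(layer$gamma)
      # standard batch-norm backward, per channel over the (H,W,N) population
      gx <- (gxhat - bc(chan_sum(gxhat) / npop) -
               cache$xhat * bc(chan_sum(gxhat * cache$xhat) / npop)) *
        bc(cache$invstd)
      dim(gx) <- d
      list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
    },
    pool = {
      list(gx = maxpool2_bwd(gy, cache$argmax, as.integer(cache$xdim)), grads = NULL)
    },
    up = {
      list(gx = upsample2_bwd(gy), grads = NULL)
    }
  )
}

seg_forward <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, training)
    x <- r$y
    caches[i] <- list(r$cache)  # keep NULLs as placeholders
    layers[[i]] <- r$layer
  }
  list(y = x, caches = caches, layers = layers)
}

seg_backward <- function(layers, caches, gy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], gy)
    gy <- r$gx
    grads[i] <- list(r$grads)  # keep NULLs as placeholders
  }
  list(gx = gy, grads = grads)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(model) {
  st <- list(t = 0)
  for (seg in c("enc", "amp", "phase")) {
    st[[seg]] <- lapply(model[[seg]], function(l) {
      p <- intersect(names(l), c("W", "b", "gamma", "beta"))
      if (!length(p)) return(NULL)
      sapply(p, function(nm) list(m = l[[nm]] * 0, v = l[[nm]] * 0),
             simplify = FALSE)
    })
  }
  st
}

adam_update <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (seg in c("enc", "amp", "phase")) {
    for (i in seq_along(model[[seg]])) {
      g <- grads[[seg]][[i]]
      if (is.null(g)) next
      for (nm in names(g)) {
        s <- state[[seg]][[i]][[nm]]
        s$m <- beta1 * s$m + (1 - beta1) * g[[nm]]
        s$v <- beta2 * s$v + (1 - beta2) * g[[nm]]^2
        model[[seg]][[i]][[nm]] <- model[[seg]][[i]][[nm]] -
          lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
        state[[seg]][[i]][[nm]] <- s
      }
    }
  }
  list(model = model, state = state)
}

n_params_seg <- function(layers) {
  sum(vapply(layers, function(l) {
    p <- intersect(names(l), c("W", "b", "gamma", "beta"))
    sum(vapply(p, function(nm) length(l[[nm]]), 0L))
  }, 0))
}
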