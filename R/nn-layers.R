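# Minimal neural-network primitives on base-R rank-4 arrays (B, C, H, W),
# with hand-written backward passes. Convolution / pooling inner loops live
# in src/kernels.cpp; everything else is vectorized R.

tensor4 <- function(data, b, c, h, w) array(data, dim = c(b, c, h, w))

tdim <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4) stop("expected a rank-4 (B,C,H,W) array")
  d
}

# broadcast a per-channel vector over a (B,C,H,W) shape
ch_expand <- function(v, d) {
  aperm(array(v, dim = c(d[2], d[1], d[3], d[4])), c(2, 1, 3, 4))
}

# per-channel sums / means over batch and spatial axes
ch_sum <- function(x) {
  d <- tdim(x)
  m <- aperm(x, c(2, 1, 3, 4))
  dim(m) <- c(d[2], prod(d[-2]))
  rowSums(m)
}
ch_mean <- function(x) ch_sum(x) / (prod(tdim(x)[-2]))

is_layer <- function(x) is.list(x) && !is.null(x$kind)

## ---- constructors -------------------------------------------------------

nn_conv <- function(in_ch, out_ch, kernel, stride = 1L, pad = 0L,
                    groups = 1L, bias = TRUE) {
  if (in_ch %% groups != 0 || out_ch %% groups != 0) {
    stop("channel counts must be divisible by groups")
  }
  fan_in <- kernel * kernel * in_ch / groups
  w <- array(rnorm(out_ch * (in_ch / groups) * kernel * kernel,
                   sd = sqrt(2 / fan_in)),
             dim = c(out_ch, in_ch / groups, kernel, kernel))
  l <- list(kind = "conv", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
            stride = as.integer(stride), pad = as.integer(pad),
            groups = as.integer(groups),
            p = list(w = w))
  if (bias) l$p$b <- numeric(out_ch)
  l
}

nn_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  stats <- new.env(parent = emptyenv())
  stats$rm <- numeric(ch)
  stats$rv <- rep(1, ch)
  list(kind = "bn", ch = ch, eps = eps, momentum = momentum, stats = stats,
       p = list(gamma = rep(1, ch), beta = numeric(ch)))
}

nn_linear <- function(in_f, out_f) {
  list(kind = "linear", in_f = in_f, out_f = out_f,
       p = list(w = matrix(rnorm(in_f * out_f, sd = sqrt(2 / in_f)),
                           in_f, out_f),
                b = numeric(out_f)))
}

## ---- forward / backward -------------------------------------------------

conv_fw <- function(l, x) {
  d <- tdim(x)
  if (d[2] != l$in_ch) stop("conv: input has ", d[2], " channels, expected ",
                            l$in_ch)
  y <- cpp_conv2d_fw(x, d, l$p$w, dim(l$p$w),
                     if (is.null(l$p$b)) numeric(0) else l$p$b,
                     l$stride, l$pad, l$groups)
  list(y = y, cache = list(x = x))
}

conv_bw <- function(l, cache, gy) {
  r <- cpp_conv2d_bw(cache$x, tdim(cache$x), l$p$w, dim(l$p$w), gy,
                     !is.null(l$p$b), l$stride, l$pad, l$groups)
  g <- list(w = r$dw)
  if (!is.null(l$p$b)) g$b <- as.numeric(r$db)
  list(dx = r$dx, g = g)
}

# `train` modes: TRUE = batch statistics + running-stat update (training),
# "batch" = batch statistics without updating (inference on per-image
# statistics), FALSE = stored running statistics.
bn_fw <- function(l, x, train = TRUE) {
  d <- tdim(x)
  if (!identical(train, FALSE)) {
    mu <- ch_mean(x)
    xc <- x - ch_expand(mu, d)
    va <- ch_mean(xc * xc)
    if (isTRUE(train)) {
      l$stats$rm <- (1 - l$momentum) * l$stats$rm + l$momentum * mu
      l$stats$rv <- (1 - l$momentum) * l$stats$rv + l$momentum * va
    }
  } else {
    mu <- l$stats$rm
    va <- l$stats$rv
    xc <- x - ch_expand(mu, d)
  }
  inv_sd <- 1 / sqrt(va + l$eps)
  xhat <- xc * ch_expand(inv_sd, d)
  y <- xhat * ch_expand(l$p$gamma, d) + ch_expand(l$p$beta, d)
  list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, d = d))
}

bn_bw <- function(l, cache, gy) {
  d <- cache$d
  n <- prod(d[-2])
  dgamma <- ch_sum(gy * cache$xhat)
  dbeta <- ch_sum(gy)
  dxhat <- gy * ch_expand(l$p$gamma, d)
  s1 <- ch_sum(dxhat)
  s2 <- ch_sum(dxhat * cache$xhat)
  dx <- (dxhat - ch_expand(s1, d) / n -
           cache$xhat * ch_expand(s2, d) / n) * ch_expand(cache$inv_sd, d)
  list(dx = dx, g = list(gamma = dgamma, beta = dbeta))
}

relu_fw <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}
relu_bw <- function(cache, gy) gy * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

maxpool_fw <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- tdim(x)
  r <- cpp_maxpool_fw(x, d, k, stride, pad)
  list(y = r$y, cache = list(arg = r$arg, xlen = length(x), xdim = d))
}
maxpool_bw <- function(cache, gy) {
  dx <- cpp_maxpool_bw(cache$arg, gy, cache$xlen)
  dim(dx) <- cache$xdim
  dx
}

linear_fw <- function(l, x) {
  list(y = sweep(x %*% l$p$w, 2, l$p$b, "+"), cache = list(x = x))
}
linear_bw <- function(l, cache, gy) {
  list(dx = gy %*% t(l$p$w),
       g = list(w = t(cache$x) %*% gy, b = colSums(gy)))
}

## ---- losses -------------------------------------------------------------

# Softmax cross-entropy. logits: n x K, labels in 1..K. Mean over rows.
softmax_ce <- function(logits, labels) {
  n <- nrow(logits)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  gr <- p
  gr[idx] <- gr[idx] - 1
  list(loss = loss, grad = gr / n, prob = p)
}

# Smooth L1 (Huber with beta = 1), summed then normalized by `norm`.
smooth_l1 <- function(pred, target, norm = length(pred)) {
  d <- pred - target
  a <- abs(d)
  loss <- sum(ifelse(a < 1, 0.5 * d * d, a - 0.5)) / norm
  grad <- ifelse(a < 1, d, sign(d)) / norm
  list(loss = loss, grad = grad)
}

## ---- parameter-tree utilities ------------------------------------------

# Recursively add two gradient trees of identical structure (NULL = zero).
g_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  out <- a
  for (nm in union(names(a), names(b))) out[[nm]] <- g_add(a[[nm]], b[[nm]])
  out
}

adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- list()
  e$v <- list()
  e
}

# One Adam step over a model tree given a mirroring gradient tree.
# L2 weight decay is folded into the gradient (classic Adam + L2).
adam_step <- function(model, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  walk <- function(node, g, path) {
    if (is.null(g)) return(node)
    if (is_layer(node)) {
      for (nm in names(g)) {
        key <- paste(path, nm, sep = "/")
        p <- node$p[[nm]]
        gr <- g[[nm]] + weight_decay * p
        m <- st$m[[key]]; if (is.null(m)) m <- p * 0
        v <- st$v[[key]]; if (is.null(v)) v <- p * 0
        m <- beta1 * m + (1 - beta1) * gr
        v <- beta2 * v + (1 - beta2) * gr * gr
        st$m[[key]] <- m
        st$v[[key]] <- v
        node$p[[nm]] <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      }
      return(node)
    }
    for (nm in names(g)) {
      node[[nm]] <- walk(node[[nm]], g[[nm]], paste(path, nm, sep = "/"))
    }
    node
  }
  walk(model, grads, "")
}

# Census of learnable parameters in a model tree, grouped by layer kind.
param_census <- function(node) {
  if (is_layer(node)) {
    n <- sum(vapply(node$p, length, 1L))
    out <- c(conv = 0, norm = 0, linear = 0)
    key <- switch(node$kind, conv = "conv", bn = "norm", linear = "linear",
                  sam = "conv", "conv")
    out[key] <- n
    return(out)
  }
  if (!is.list(node)) return(c(conv = 0, norm = 0, linear = 0))
  Reduce(`+`, lapply(node, param_census), c(conv = 0, norm = 0, linear = 0))
}
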