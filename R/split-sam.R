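# Grouped spatial attention ("split" SAM): the channel dimension is split
# into G groups; each group is summarized by channel-wise max and average
# pooling, a shared 7x7 convolution turns the 2-channel summary into a
# single-channel logit map, and the sigmoid of that map gates the group.

#' Construct a split spatial-attention module
#'
#' One shared `kernel x kernel` convolution (2 -> 1 channels, bias, padding
#' preserving H x W) applied to the channel-pooled summary of each of
#' `groups` channel groups. Weights are Kaiming-initialized from the
#' caller's RNG stream.
#'
#' @param groups number of channel groups G (default 1)
#' @param kernel spatial size of the attention convolution (default 7)
#' @return an object usable with [apply_split_sam()] and [attention_map()]
#' @export
make_split_sam <- function(groups = 1L, kernel = 7L) {
  if (groups < 1) stop("groups must be >= 1")
  kernel <- as.integer(kernel)
  if (kernel %% 2 == 0) stop("attention kernel must be odd")
  fan_in <- 2 * kernel * kernel
  list(kind = "sam", groups = as.integer(groups), kernel = kernel,
       pad = (kernel - 1L) %/% 2L,
       p = list(w = array(rnorm(2 * kernel * kernel, sd = sqrt(2 / fan_in)),
                          dim = c(1, 2, kernel, kernel)),
                b = 0))
}

#' Split a feature map into channel groups
#'
#' @param x (B, C, H, W) array
#' @param g number of groups; C must be divisible by g
#' @return list of g arrays of shape (B, C/g, H, W) whose concatenation in
#'   order restores `x`
#' @export
split_channels <- function(x, g) {
  d <- tdim(x)
  if (d[2] %% g != 0) {
    stop("channel count ", d[2], " is not divisible by groups = ", g)
  }
  cg <- d[2] %/% g
  lapply(seq_len(g), function(i) {
    x[, ((i - 1) * cg + 1):(i * cg), , , drop = FALSE]
  })
}

concat_channels <- function(parts) {
  d <- tdim(parts[[1]])
  ctot <- sum(vapply(parts, function(p) dim(p)[2], 1L))
  out <- array(0, dim = c(d[1], ctot, d[3], d[4]))
  at <- 0L
  for (p in parts) {
    cp <- dim(p)[2]
    out[, (at + 1):(at + cp), , ] <- p
    at <- at + cp
  }
  out
}

#' Channel-wise max/average pooling
#'
#' Pools ACROSS the channel axis (spatial dimensions preserved), producing
#' the max map, the average map, and their channel concatenation.
#'
#' @param xg (B, Cg, H, W) array
#' @return list with `f_max`, `f_avg` (each B x 1 x H x W) and
#'   `concatenated` (B x 2 x H x W)
#' @export
channel_pool <- function(xg) {
  d <- tdim(xg)
  f_max <- xg[, 1, , , drop = FALSE]
  for (c in seq_len(d[2])[-1]) {
    f_max <- pmax(f_max, xg[, c, , , drop = FALSE])
  }
  dim(f_max) <- c(d[1], 1, d[3], d[4])
  f_avg <- xg[, 1, , , drop = FALSE]
  if (d[2] > 1) {
    for (c in seq_len(d[2])[-1]) f_avg <- f_avg + xg[, c, , , drop = FALSE]
  }
  f_avg <- f_avg / d[2]
  dim(f_avg) <- dim(f_max)
  structure(list(f_max = f_max, f_avg = f_avg,
                 concatenated = concat_channels(list(f_max, f_avg))),
            class = "pooled_pair")
}

#' Spatial attention map
#'
#' Applies the module's shared convolution to a 2-channel pooled summary
#' and squashes the result through the logistic sigmoid, yielding a
#' B x 1 x H x W map with values strictly inside (0, 1).
#'
#' @param fg a [channel_pool()] result or a (B, 2, H, W) array
#' @param sam a [make_split_sam()] module
#' @return (B, 1, H, W) attention map
#' @export
attention_map <- function(fg, sam) {
  if (inherits(fg, "pooled_pair")) fg <- fg$concatenated
  d <- tdim(fg)
  if (d[2] != 2) stop("pooled summary must have exactly 2 channels")
  wd <- dim(sam$p$w)
  if (!identical(wd, c(1L, 2L, sam$kernel, sam$kernel))) {
    stop("attention weights have shape (", paste(wd, collapse = ","),
         "), expected (1,2,", sam$kernel, ",", sam$kernel, ")")
  }
  a <- cpp_conv2d_fw(fg, d, sam$p$w, wd, sam$p$b, 1L, sam$pad, 1L)
  sigmoid(a)
}

bcast_map <- function(m, cg) m[, rep(1L, cg), , , drop = FALSE]

#' Apply split spatial attention
#'
#' Splits `x` into the module's channel groups, gates every group by its
#' own attention map (broadcast over the group's channels), and
#' re-concatenates the groups in their original order. Shape is preserved.
#'
#' @param x (B, C, H, W) array; C must be divisible by the module's groups
#' @param sam a [make_split_sam()] module
#' @return gated array, same shape as `x`
#' @export
apply_split_sam <- function(x, sam) {
  sam_fw(sam, x)$y
}

# forward with caches for training
sam_fw <- function(l, x) {
  parts <- split_channels(x, l$groups)
  maps <- vector("list", l$groups)
  caches <- vector("list", l$groups)
  out <- vector("list", l$groups)
  for (i in seq_along(parts)) {
    pooled <- channel_pool(parts[[i]])
    m <- attention_map(pooled, l)
    cg <- dim(parts[[i]])[2]
    out[[i]] <- parts[[i]] * bcast_map(m, cg)
    caches[[i]] <- list(xg = parts[[i]], pooled = pooled, m = m)
    maps[[i]] <- m
  }
  list(y = concat_channels(out), cache = list(groups = caches), maps = maps)
}

sam_bw <- function(l, cache, gy) {
  gparts <- split_channels(gy, l$groups)
  dxs <- vector("list", l$groups)
  dw <- l$p$w * 0
  db <- 0
  for (i in seq_along(gparts)) {
    cc <- cache$groups[[i]]
    xg <- cc$xg
    m <- cc$m
    d <- dim(xg)
    cg <- d[2]
    gyg <- gparts[[i]]
    # through the elementwise gate
    dxg <- gyg * bcast_map(m, cg)
    dm <- xg[, 1, , , drop = FALSE] * gyg[, 1, , , drop = FALSE]
    if (cg > 1) {
      for (c in 2:cg) {
        dm <- dm + xg[, c, , , drop = FALSE] * gyg[, c, , , drop = FALSE]
      }
    }
    dim(dm) <- dim(m)
    # through the sigmoid and the shared convolution
    da <- dm * m * (1 - m)
    r <- cpp_conv2d_bw(cc$pooled$concatenated, tdim(cc$pooled$concatenated),
                       l$p$w, dim(l$p$w), da, TRUE, 1L, l$pad, 1L)
    dw <- dw + r$dw
    db <- db + as.numeric(r$db)
    dfg <- r$dx
    dmax <- dfg[, 1, , , drop = FALSE]
    davg <- dfg[, 2, , , drop = FALSE]
    # average pooling spreads evenly; max pooling routes to the first
    # channel attaining the maximum
    dxg <- dxg + bcast_map(davg, cg) / cg
    remaining <- array(TRUE, dim(cc$pooled$f_max))
    for (c in seq_len(cg)) {
      hit <- (xg[, c, , , drop = FALSE] == cc$pooled$f_max) & remaining
      routed <- dmax * hit
      dim(routed) <- NULL
      dxg[, c, , ] <- dxg[, c, , ] + routed
      remaining <- remaining & !hit
    }
    dxs[[i]] <- dxg
  }
  list(dx = concat_channels(dxs), g = list(w = dw, b = db))
}
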