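# Model-complexity accounting (exact parameter census, multiply-accumulate
# counts from a shape-traced forward pass) and the edge-performance scaling
# model (pure arithmetic over measured frame rates and a structural
# complexity factor; no hardware timing is performed).

#' Parameter census of a model
#'
#' Walks the model tree and counts learnable parameters exactly, grouped by
#' layer family (convolutional — attention included —, normalization,
#' linear).
#'
#' @param model any model tree built by this package (bottleneck, backbone
#'   or detector)
#' @return list with `total_params`, `conv_params`, `norm_params`,
#'   `linear_params`
#' @export
count_params <- function(model) {
  cen <- param_census(model)
  list(total_params = sum(cen), conv_params = unname(cen["conv"]),
       norm_params = unname(cen["norm"]),
       linear_params = unname(cen["linear"]))
}

conv_macs <- function(l, h, w) {
  ho <- (h + 2 * l$pad - l$kernel) %/% l$stride + 1
  wo <- (w + 2 * l$pad - l$kernel) %/% l$stride + 1
  list(macs = l$kernel^2 * (l$in_ch / l$groups) * l$out_ch * ho * wo,
       h = ho, w = wo)
}

bottleneck_macs <- function(m, h, w) {
  total <- 0
  c1 <- conv_macs(m$conv1, h, w)
  total <- total + c1$macs
  c2 <- conv_macs(m$conv2, c1$h, c1$w)
  total <- total + c2$macs
  c3 <- conv_macs(m$conv3, c2$h, c2$w)
  total <- total + c3$macs
  if (m$meta$project) total <- total + conv_macs(m$down_conv, h, w)$macs
  if (!is.null(m$sam)) {
    k <- m$sam$kernel
    total <- total + m$sam$groups * k^2 * 2 * 1 * c3$h * c3$w
  }
  list(macs = total, h = c3$h, w = c3$w)
}

backbone_extractor_macs <- function(model, input_size) {
  st <- conv_macs(model$stem$conv, input_size, input_size)
  total <- st$macs
  h <- (st$h + 2 * 1 - 3) %/% 2 + 1  # 3x3/2 max pool, no MACs
  w <- (st$w + 2 * 1 - 3) %/% 2 + 1
  for (s in seq_len(model$meta$n_extract_stages)) {
    for (blk in model$stages[[paste0("s", s)]]) {
      bm <- bottleneck_macs(blk, h, w)
      total <- total + bm$macs
      h <- bm$h
      w <- bm$w
    }
  }
  list(macs = total, h = h, w = w)
}

#' Multiply-accumulate count of a forward pass
#'
#' Convolutions contribute `k^2 * (C_in/groups) * C_out * H_out * W_out`
#' MACs, linear layers `in * out`; pooling, normalization and activations
#' are not counted. For a detector the RoI head is counted once per
#' proposal (`proposals` of them), since per-image compute depends on the
#' proposal budget. FLOPs are reported as `2 * macs` and the convention is
#' recorded in the result.
#'
#' @param model a backbone or detector model
#' @param input_size square input side in pixels (default 600)
#' @param proposals RoI count for the head trunk (default 300)
#' @return a complexity report list (params, macs, flops, convention)
#' @export
count_macs <- function(model, input_size = 600L, proposals = 300L) {
  if (!is.null(model$rpn)) {
    bk <- model$backbone
    ex <- backbone_extractor_macs(bk, input_size)
    total <- ex$macs
    rc <- conv_macs(model$rpn$conv, ex$h, ex$w)
    total <- total + rc$macs +
      conv_macs(model$rpn$cls, rc$h, rc$w)$macs +
      conv_macs(model$rpn$box, rc$h, rc$w)$macs
    # head trunk per proposal at the RoI grid size
    p <- model$meta$roi_size
    head_one <- 0
    h <- p
    w <- p
    sn <- paste0("s", bk$meta$n_extract_stages + 1L)
    for (blk in bk$stages[[sn]]) {
      bm <- bottleneck_macs(blk, h, w)
      head_one <- head_one + bm$macs
      h <- bm$h
      w <- bm$w
    }
    head_one <- head_one + model$head$fc_cls$in_f * model$head$fc_cls$out_f +
      model$head$fc_box$in_f * model$head$fc_box$out_f
    total <- total + proposals * head_one
  } else {
    ex <- backbone_extractor_macs(model, input_size)
    total <- ex$macs
    sn <- paste0("s", model$meta$n_extract_stages + 1L)
    h <- ex$h
    w <- ex$w
    for (blk in model$stages[[sn]]) {
      bm <- bottleneck_macs(blk, h, w)
      total <- total + bm$macs
      h <- bm$h
      w <- bm$w
    }
  }
  rep <- count_params(model)
  rep$macs <- total
  rep$flops <- 2 * total
  rep$flops_convention <- "flops = 2 * macs"
  rep$input_size <- input_size
  rep$proposals <- if (!is.null(model$rpn)) proposals else NA_integer_
  rep
}

#' Edge-performance scaling arithmetic
#'
#' `speedup_factor()` is the ratio of the target-device frame rate to the
#' locally measured one; `structural_speedup()` divides it by the
#' structural complexity factor `r` (the fraction of compute the
#' lightweight model retains); `simulated_fps()` scales the local frame
#' rate by the combined factor.
#'
#' @param fps_device,fps_base frames per second on the target device and
#'   locally (both > 0)
#' @return dimensionless speed-up ratio
#' @export
speedup_factor <- function(fps_device, fps_base) {
  if (fps_base <= 0) stop("fps_base must be > 0")
  if (fps_device <= 0) stop("fps_device must be > 0")
  fps_device / fps_base
}

#' @rdname speedup_factor
#' @param speed_up1 base speed-up ratio
#' @param r structural complexity scaling factor in (0, 1]
#' @export
structural_speedup <- function(speed_up1, r) {
  if (r <= 0) stop("r must be > 0")
  speed_up1 / r
}

#' @rdname speedup_factor
#' @param speed_up2 structural speed-up ratio
#' @export
simulated_fps <- function(fps_base, speed_up2) {
  if (fps_base <= 0 || speed_up2 <= 0) stop("inputs must be > 0")
  fps_base * speed_up2
}

#' Full edge-performance estimate
#'
#' Combines the three scaling steps with the default constants: a locally
#' measured 0.08 frames/s, a reported 0.5 frames/s for the unmodified
#' detector on the target device, and a structural factor r = 0.35 for the
#' lightweight variant.
#'
#' @inheritParams speedup_factor
#' @inheritParams structural_speedup
#' @return list with `speed_up1`, `speed_up2`, `fps_simulated`, `t_base`
#' @export
edge_estimate <- function(fps_base = 0.08, fps_device = 0.5, r = 0.35) {
  s1 <- speedup_factor(fps_device, fps_base)
  s2 <- structural_speedup(s1, r)
  list(fps_base = fps_base, fps_device = fps_device, r = r,
       speed_up1 = s1, speed_up2 = s2,
       fps_simulated = simulated_fps(fps_base, s2),
       t_base = 1 / fps_base)
}
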