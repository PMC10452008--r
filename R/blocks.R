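# Building blocks of the encoder: ghost convolution blocks, switchable
# normalization, residual ghost (RGS) bottlenecks and the bottleneck
# transformer (BoT) with multi-head self-attention.  Modules are plain lists
# of tg parameters plus a `state` environment for non-learnable running
# statistics; `n_parameters()` and the optimizer discover parameters by
# walking the list structure.

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  tg_param(array(runif(prod(dims), -lim, lim), dim = dims))
}

#' Collect the learnable parameters of a module
#'
#' Recursively walks a module (nested lists) and returns every `tg_tensor`
#' with `requires_grad = TRUE`, named by its path.
#'
#' @param module a module list (or a single tensor).
#' @param prefix internal name prefix.
#' @return named list of parameter tensors.
#' @export
collect_params <- function(module, prefix = "") {
  if (is_node(module)) {
    if (module$req) {
      out <- list(module)
      names(out) <- prefix
      return(out)
    }
    return(list())
  }
  if (is.list(module)) {
    out <- list()
    nms <- names(module)
    for (i in seq_along(module)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, collect_params(module[[i]],
                                   paste0(prefix, if (nzchar(prefix)) "." else "", nm)))
    }
    return(out)
  }
  list()
}

#' Count learnable scalars in a module
#' @param module a module list.
#' @return integer number of learnable scalar weights.
#' @export
n_parameters <- function(module) {
  sum(vapply(collect_params(module), function(p) length(p$v), numeric(1)))
}

## ---- plain convolution ------------------------------------------------------

#' Plain convolution module
#'
#' A standard 2-d convolution layer, used for the stem, the decoder 1x1
#' convolutions, shortcut projections and as the reference when measuring the
#' parameter economy of ghost blocks.
#'
#' @param in_channels,out_channels channel counts.
#' @param kernel odd kernel size; "same" padding is used so only the stride
#'   changes resolution.
#' @param stride integer stride.
#' @param bias include a bias term?
#' @return a module list of class `gu_conv`.
#' @export
conv_layer <- function(in_channels, out_channels, kernel = 3L, stride = 1L,
                       bias = TRUE) {
  m <- list(
    type = "conv", in_channels = in_channels, out_channels = out_channels,
    kernel = kernel, stride = stride, pad = (kernel - 1L) %/% 2L,
    w = he_uniform(c(kernel, kernel, in_channels, out_channels),
                   kernel * kernel * in_channels),
    b = if (bias) tg_param(array(0, out_channels)) else NULL
  )
  class(m) <- c("gu_conv", "gu_module")
  m
}

#' Forward pass of a plain convolution module
#' @param m a [conv_layer()] module.
#' @param x input `tg_tensor` of dim (H, W, C, N).
#' @return convolved `tg_tensor`.
#' @export
conv_forward <- function(m, x) {
  tg_conv2d(x, m$w, m$b, stride = m$stride, pad = m$pad)
}

## ---- switchable normalization ----------------------------------------------

#' Switchable / batch normalization module
#'
#' Switchable normalization (SN) normalizes with a learned softmax mixture of
#' batch-wise (BN), instance-wise (IN) and layer-wise (LN) first and second
#' moments, with separate mixture weights for the mean and the variance, so a
#' layer can pick whichever statistic is reliable at the batch size it sees.
#' `type = "bn"` degenerates to plain batch normalization (the ablation
#' variant).  Running batch statistics are tracked with the given momentum and
#' replace the batch-wise component at inference time.
#'
#' @param channels number of channels normalized.
#' @param type `"sn"` or `"bn"`.
#' @param eps numerical stabilizer added to the mixed variance.
#' @param momentum running-statistics update rate.
#' @return a module list of class `gu_norm`.
#' @export
norm_layer <- function(channels, type = c("sn", "bn"), eps = 1e-5,
                       momentum = 0.1) {
  type <- match.arg(type)
  st <- new.env(parent = emptyenv())
  st$run_mean <- numeric(channels)
  st$run_var <- rep(1, channels)
  m <- list(
    type = "norm", norm_type = type, channels = channels, eps = eps,
    momentum = momentum,
    gamma = tg_param(array(1, channels)),
    beta = tg_param(array(0, channels)),
    state = st
  )
  if (type == "sn") {
    m$mean_logits <- tg_param(array(0, 3))  # order: BN, IN, LN
    m$var_logits <- tg_param(array(0, 3))
  }
  class(m) <- c("gu_norm", "gu_module")
  m
}

#' Forward pass of switchable (or batch) normalization
#'
#' @param x input `tg_tensor` of dim (H, W, C, N), batch N >= 1.
#' @param norm a [norm_layer()] module.
#' @param training if `TRUE`, batch-wise statistics come from the minibatch and
#'   running statistics are updated; otherwise the stored running statistics
#'   are used for the batch-wise component (IN and LN are always computed from
#'   the input).
#' @return normalized `tg_tensor`, `gamma * (x - mean)/sqrt(var + eps) + beta`.
#' @export
switchable_norm_forward <- function(x, norm, training = TRUE) {
  d <- dim(x$v)
  if (length(d) != 4L) stop("expected a (H, W, C, N) feature map")
  C <- d[3L]; N <- d[4L]
  if (N < 1L) stop("batch of size 0 is not a valid input")
  if (C != norm$channels) {
    stop("input has ", C, " channels but the normalizer expects ",
         norm$channels)
  }
  mu_in <- tg_mean_kd(x, c(1L, 2L))             # (1,1,C,N)
  m2_in <- tg_mean_kd(tg_square(x), c(1L, 2L))  # E[x^2] per (c, n)
  var_in <- tg_sub(m2_in, tg_square(mu_in))

  if (training) {
    mu_bn <- tg_mean_kd(mu_in, 4L)              # (1,1,C,1)
    var_bn <- tg_sub(tg_mean_kd(m2_in, 4L), tg_square(mu_bn))
    mom <- norm$momentum
    norm$state$run_mean <- (1 - mom) * norm$state$run_mean +
      mom * as.vector(mu_bn$v)
    norm$state$run_var <- (1 - mom) * norm$state$run_var +
      mom * as.vector(var_bn$v)
  } else {
    mu_bn <- tg_tensor(array(norm$state$run_mean, c(1L, 1L, C, 1L)))
    var_bn <- tg_tensor(array(norm$state$run_var, c(1L, 1L, C, 1L)))
  }

  if (norm$norm_type == "bn") {
    mu_mix <- tg_expand(mu_bn, c(1L, 1L, C, N))
    var_mix <- tg_expand(var_bn, c(1L, 1L, C, N))
  } else {
    mu_ln <- tg_mean_kd(mu_in, 3L)              # (1,1,1,N)
    var_ln <- tg_sub(tg_mean_kd(m2_in, 3L), tg_square(mu_ln))
    wm <- tg_softmax_rows(tg_reshape(norm$mean_logits, c(1L, 3L)))
    wv <- tg_softmax_rows(tg_reshape(norm$var_logits, c(1L, 3L)))
    pick <- function(w, k) tg_reshape(tg_slice(w, 2L, k), 1L)
    stat_dim <- c(1L, 1L, C, N)
    mu_mix <- tg_add(
      tg_add(tg_scale(tg_expand(mu_bn, stat_dim), pick(wm, 1L)),
             tg_scale(mu_in, pick(wm, 2L))),
      tg_scale(tg_expand(mu_ln, stat_dim), pick(wm, 3L)))
    var_mix <- tg_add(
      tg_add(tg_scale(tg_expand(var_bn, stat_dim), pick(wv, 1L)),
             tg_scale(var_in, pick(wv, 2L))),
      tg_scale(tg_expand(var_ln, stat_dim), pick(wv, 3L)))
  }

  xc <- tg_sub(x, tg_expand(mu_mix, d))
  den <- tg_expand(tg_sqrt(tg_add(var_mix, norm$eps)), d)
  xhat <- tg_div(xc, den)
  gam <- tg_expand(tg_reshape(norm$gamma, c(1L, 1L, C, 1L)), d)
  bet <- tg_expand(tg_reshape(norm$beta, c(1L, 1L, C, 1L)), d)
  tg_add(tg_mul(xhat, gam), bet)
}

## ---- ghost block ------------------------------------------------------------

#' Ghost convolution block
#'
#' Generates `ceiling(out_channels/ratio)` intrinsic feature maps with an
#' ordinary (by default 1x1 point-wise) convolution and expands them with a
#' cheap grouped convolution (one small filter bank per intrinsic map, 3x3 by
#' default); the output is the channel concatenation of intrinsic and cheap
#' maps.  This produces the same number of output maps as a plain convolution
#' at a fraction of the weight count.
#'
#' @param in_channels,out_channels channel counts.
#' @param ratio integer >= 2; fraction of intrinsic maps is
#'   `out_channels/ratio`.
#' @param primary_kernel odd kernel of the primary convolution (default 1).
#' @param cheap_kernel odd kernel of the cheap grouped convolution (default 3).
#' @param stride stride of the primary convolution.
#' @return module list of class `gu_ghost`.
#' @export
ghost_block <- function(in_channels, out_channels, ratio = 2L,
                        primary_kernel = 1L, cheap_kernel = 3L, stride = 1L) {
  stopifnot(ratio >= 2L, primary_kernel %% 2L == 1L, cheap_kernel %% 2L == 1L)
  intrinsic <- as.integer(ceiling(out_channels / ratio))
  cheap <- out_channels - intrinsic
  cheap_gen <- intrinsic * (ratio - 1L)  # generated, then trimmed to `cheap`
  m <- list(
    type = "ghost", in_channels = in_channels, out_channels = out_channels,
    ratio = ratio, intrinsic = intrinsic, cheap = cheap,
    cheap_gen = cheap_gen, primary_kernel = primary_kernel,
    cheap_kernel = cheap_kernel, stride = stride,
    w_primary = he_uniform(
      c(primary_kernel, primary_kernel, in_channels, intrinsic),
      primary_kernel^2 * in_channels),
    w_cheap = if (cheap > 0L) {
      he_uniform(c(cheap_kernel, cheap_kernel, 1L, cheap_gen), cheap_kernel^2)
    } else NULL
  )
  class(m) <- c("gu_ghost", "gu_module")
  m
}

#' Forward pass of a ghost block
#'
#' @param x input `tg_tensor` of dim (H, W, C, N).
#' @param gb a [ghost_block()] module.
#' @return `tg_tensor` with `gb$out_channels` channels; spatial dims divided
#'   by the block stride.
#' @export
ghost_block_forward <- function(x, gb) {
  C <- dim(x$v)[3L]
  if (C != gb$in_channels) {
    stop("input has ", C, " channels but the ghost block expects ",
         gb$in_channels)
  }
  prim <- tg_conv2d(x, gb$w_primary, stride = gb$stride,
                    pad = (gb$primary_kernel - 1L) %/% 2L)
  if (gb$cheap == 0L) return(prim)
  cheap <- tg_conv2d(prim, gb$w_cheap, stride = 1L,
                     pad = (gb$cheap_kernel - 1L) %/% 2L,
                     groups = gb$intrinsic)
  if (gb$cheap_gen > gb$cheap) {
    cheap <- tg_slice(cheap, 3L, seq_len(gb$cheap))
  }
  tg_concat(list(prim, cheap), 3L)
}

## ---- multi-head self-attention ----------------------------------------------

#' Multi-head self-attention over the spatial positions of a feature map
#'
#' All-to-all attention between the `H*W` spatial positions.  Queries, keys
#' and values are 1x1 convolution projections; content logits are
#' `q^T k / sqrt(head_dim)`.  When relative positions are enabled, per-head
#' height and width embeddings add a content-position term
#' `q^T (R_h + R_w) / sqrt(head_dim)` (the embeddings are sized to the
#' construction-time feature-map resolution, and inputs of any other size are
#' rejected rather than silently interpolated).  A final 1x1 convolution mixes
#' the concatenated heads.
#'
#' @param channels channel count (must be divisible by `heads`).
#' @param heads number of attention heads.
#' @param height,width spatial size the position embeddings are built for.
#' @param use_relative_positions enable the position term?
#' @return module list of class `gu_mhsa`.
#' @export
mhsa_block <- function(channels, heads = 4L, height, width,
                       use_relative_positions = TRUE) {
  if (channels %% heads != 0L) {
    stop("channels (", channels, ") not divisible by heads (", heads, ")")
  }
  dh <- channels %/% heads
  m <- list(
    type = "mhsa", channels = channels, heads = heads, head_dim = dh,
    height = height, width = width,
    use_relative_positions = use_relative_positions,
    wq = he_uniform(c(1L, 1L, channels, channels), channels),
    wk = he_uniform(c(1L, 1L, channels, channels), channels),
    wv = he_uniform(c(1L, 1L, channels, channels), channels),
    wo = he_uniform(c(1L, 1L, channels, channels), channels),
    rel_h = if (use_relative_positions) {
      tg_param(array(rnorm(dh * height * heads, sd = 1 / sqrt(dh)),
                     c(dh, height, heads)))
    } else NULL,
    rel_w = if (use_relative_positions) {
      tg_param(array(rnorm(dh * width * heads, sd = 1 / sqrt(dh)),
                     c(dh, width, heads)))
    } else NULL
  )
  class(m) <- c("gu_mhsa", "gu_module")
  m
}

#' Forward pass of multi-head self-attention
#'
#' @param x input `tg_tensor` of dim (H, W, C, N).
#' @param m an [mhsa_block()] module.
#' @param return_attention also return the attention weights?
#' @param logit_shift scalar added to every attention logit (softmax is
#'   invariant to it; exposed for property checks).
#' @param attn_override optional fixed (HW x HW) attention matrix substituted
#'   for the softmax output in every head (analysis aid, treated as constant).
#' @return the output `tg_tensor` (same dims as `x`), or, when
#'   `return_attention = TRUE`, a list with elements `out` and `attention`
#'   (array of dim `(heads, HW, HW, N)`, each row summing to 1).
#' @export
mhsa_forward <- function(x, m, return_attention = FALSE, logit_shift = 0,
                         attn_override = NULL) {
  d <- dim(x$v)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  if (C != m$channels) {
    stop("input has ", C, " channels but the attention block expects ",
         m$channels)
  }
  if (m$use_relative_positions && (H != m$height || W != m$width)) {
    stop("position embeddings were built for ", m$height, "x", m$width,
         " feature maps; got ", H, "x", W,
         " (inputs of other sizes are rejected, not interpolated)")
  }
  HW <- H * W
  dh <- m$head_dim
  scale <- 1 / sqrt(dh)
  q <- tg_conv2d(x, m$wq)
  k <- tg_conv2d(x, m$wk)
  v <- tg_conv2d(x, m$wv)
  tokens <- function(z, n) {
    # (H,W,C,1) -> (C, HW) token matrix; token order follows column-major (h, w)
    tg_reshape(tg_aperm(tg_slice(z, 4L, n), c(3L, 1L, 2L, 4L)), c(C, HW))
  }
  attn_arr <- if (return_attention) array(0, c(m$heads, HW, HW, N)) else NULL
  imgs <- vector("list", N)
  for (n in seq_len(N)) {
    qn <- tokens(q, n); kn <- tokens(k, n); vn <- tokens(v, n)
    head_outs <- vector("list", m$heads)
    for (h in seq_len(m$heads)) {
      rows <- ((h - 1L) * dh + 1L):(h * dh)
      qh <- tg_slice(qn, 1L, rows)
      kh <- tg_slice(kn, 1L, rows)
      vh <- tg_slice(vn, 1L, rows)
      logits <- tg_smul(tg_matmul(tg_t(qh), kh), scale)
      if (m$use_relative_positions) {
        rh <- tg_expand(tg_reshape(tg_slice(m$rel_h, 3L, h), c(dh, H, 1L)),
                        c(dh, H, W))
        rw <- tg_expand(tg_reshape(tg_slice(m$rel_w, 3L, h), c(dh, 1L, W)),
                        c(dh, H, W))
        r <- tg_reshape(tg_add(rh, rw), c(dh, HW))
        logits <- tg_add(logits, tg_smul(tg_matmul(tg_t(qh), r), scale))
      }
      if (logit_shift != 0) logits <- tg_add(logits, logit_shift)
      a <- if (is.null(attn_override)) {
        tg_softmax_rows(logits)
      } else {
        tg_tensor(attn_override)
      }
      if (return_attention) attn_arr[h, , , n] <- a$v
      head_outs[[h]] <- tg_matmul(vh, tg_t(a))  # (dh, HW)
    }
    cn <- tg_concat(head_outs, 1L)              # (C, HW)
    imgs[[n]] <- tg_reshape(tg_aperm(cn, c(2L, 1L)), c(H, W, C, 1L))
  }
  y <- if (N == 1L) imgs[[1L]] else tg_concat(imgs, 4L)
  out <- tg_conv2d(y, m$wo)
  if (return_attention) list(out = out, attention = attn_arr) else out
}

## ---- residual bottlenecks ---------------------------------------------------

# Dispatch between a ghost block and its plain-convolution stand-in (the
# ablation axis for the parameter-economy comparison).
gblock_forward <- function(x, m) {
  if (inherits(m, "gu_ghost")) ghost_block_forward(x, m) else conv_forward(m, x)
}

make_gblock <- function(in_channels, out_channels, kernel, stride, ratio,
                        use_ghost) {
  if (use_ghost) {
    ghost_block(in_channels, out_channels, ratio = ratio,
                primary_kernel = kernel, stride = stride)
  } else {
    conv_layer(in_channels, out_channels, kernel = kernel, stride = stride,
               bias = FALSE)
  }
}

make_bottleneck <- function(in_channels, out_channels, stride = 1L,
                            middle = c("ghost3", "mhsa"), ghost_ratio = 2L,
                            reduction = 4L, normalizer = "sn", heads = 4L,
                            attn_height = NULL, attn_width = NULL,
                            use_relative_positions = TRUE, use_ghost = TRUE) {
  middle <- match.arg(middle)
  stopifnot(stride %in% c(1L, 2L))
  mid <- max(out_channels %/% reduction, if (middle == "mhsa") heads else 1L)
  m <- list(
    type = if (middle == "mhsa") "bot_bottleneck" else "rgs_bottleneck",
    in_channels = in_channels, out_channels = out_channels, stride = stride,
    mid_channels = mid, middle = middle,
    g1 = make_gblock(in_channels, mid, 1L, 1L, ghost_ratio, use_ghost),
    n1 = norm_layer(mid, normalizer),
    mid_op = if (middle == "ghost3") {
      make_gblock(mid, mid, 3L, stride, ghost_ratio, use_ghost)
    } else {
      mhsa_block(mid, heads = heads, height = attn_height, width = attn_width,
                 use_relative_positions = use_relative_positions)
    },
    n2 = norm_layer(mid, normalizer),
    g3 = make_gblock(mid, out_channels, 1L, 1L, ghost_ratio, use_ghost),
    n3 = norm_layer(out_channels, normalizer),
    proj = if (stride != 1L || in_channels != out_channels) {
      conv_layer(in_channels, out_channels, kernel = 1L, stride = stride,
                 bias = FALSE)
    } else NULL,
    proj_n = if (stride != 1L || in_channels != out_channels) {
      norm_layer(out_channels, normalizer)
    } else NULL
  )
  class(m) <- c(m$type, "gu_module")
  m
}

#' Residual ghost bottleneck (RGS)
#'
#' A ResNet-style bottleneck whose three convolutions are ghost blocks, each
#' followed by switchable normalization: a 1x1 reduction, a 3x3 (optionally
#' strided) middle ghost block, and a 1x1 expansion, with a projection
#' shortcut whenever shape changes and ReLU after the residual sum.
#'
#' @param in_channels,out_channels channel counts.
#' @param stride 1 or 2 (applied in the middle ghost block).
#' @param ghost_ratio ghost ratio of all three ghost blocks.
#' @param reduction bottleneck width divisor (middle width =
#'   `out_channels/reduction`).
#' @param normalizer `"sn"` or `"bn"`.
#' @return module list of class `rgs_bottleneck`.
#' @export
rgs_bottleneck <- function(in_channels, out_channels, stride = 1L,
                           ghost_ratio = 2L, reduction = 4L,
                           normalizer = "sn") {
  make_bottleneck(in_channels, out_channels, stride, middle = "ghost3",
                  ghost_ratio = ghost_ratio, reduction = reduction,
                  normalizer = normalizer)
}

#' Bottleneck transformer block (BoT)
#'
#' Identical wiring to [rgs_bottleneck()] but the middle 3x3 ghost convolution
#' is replaced by multi-head self-attention; stride is fixed at 1 (stage-level
#' pooling does the downsampling).
#'
#' @inheritParams rgs_bottleneck
#' @param heads number of attention heads.
#' @param height,width feature-map resolution the attention stage will see.
#' @param use_relative_positions enable relative-position logits?
#' @return module list of class `bot_bottleneck`.
#' @export
bot_bottleneck <- function(in_channels, out_channels, heads = 4L,
                           height, width, ghost_ratio = 2L, reduction = 4L,
                           normalizer = "sn", use_relative_positions = TRUE) {
  make_bottleneck(in_channels, out_channels, stride = 1L, middle = "mhsa",
                  ghost_ratio = ghost_ratio, reduction = reduction,
                  normalizer = normalizer, heads = heads,
                  attn_height = height, attn_width = width,
                  use_relative_positions = use_relative_positions)
}

bottleneck_forward <- function(x, blk, training = TRUE, attn_override = NULL) {
  d <- dim(x$v)
  if (blk$stride > 1L && (d[1L] %% blk$stride != 0L ||
                          d[2L] %% blk$stride != 0L)) {
    stop("spatial dims ", d[1L], "x", d[2L], " not divisible by stride ",
         blk$stride, " (no implicit padding policy)")
  }
  h <- tg_relu(switchable_norm_forward(gblock_forward(x, blk$g1),
                                       blk$n1, training))
  mid <- if (blk$middle == "ghost3") {
    gblock_forward(h, blk$mid_op)
  } else {
    mhsa_forward(h, blk$mid_op, attn_override = attn_override)
  }
  h <- tg_relu(switchable_norm_forward(mid, blk$n2, training))
  h <- switchable_norm_forward(gblock_forward(h, blk$g3), blk$n3,
                               training)
  s <- if (is.null(blk$proj)) {
    x
  } else {
    switchable_norm_forward(conv_forward(blk$proj, x), blk$proj_n, training)
  }
  tg_relu(tg_add(h, s))
}

#' Forward pass of the residual ghost bottleneck
#'
#' @param x input `tg_tensor` of dim (H, W, C, N); spatial dims must be
#'   divisible by the block stride.
#' @param blk an [rgs_bottleneck()] module.
#' @param training normalization mode, see [switchable_norm_forward()].
#' @return `tg_tensor` with `blk$out_channels` channels at `dims/stride`
#'   resolution.
#' @export
rgs_bottleneck_forward <- function(x, blk, training = TRUE) {
  stopifnot(blk$middle == "ghost3")
  bottleneck_forward(x, blk, training)
}

#' Forward pass of the bottleneck transformer
#'
#' @inheritParams rgs_bottleneck_forward
#' @param blk a [bot_bottleneck()] module.
#' @param attn_override see [mhsa_forward()].
#' @return `tg_tensor` with `blk$out_channels` channels, spatial dims
#'   unchanged.
#' @export
bot_bottleneck_forward <- function(x, blk, training = TRUE,
                                   attn_override = NULL) {
  stopifnot(blk$middle == "mhsa")
  bottleneck_forward(x, blk, training, attn_override = attn_override)
}
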