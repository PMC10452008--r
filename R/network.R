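# The full segmentation network: a two-convolution stem, four downsampling
# stages (1, 2 and 3 stacked residual ghost bottlenecks, then a bottleneck
# transformer followed by 2x2 average pooling), and a four-unit decoder of
# transposed convolution -> ReLU -> skip concatenation -> 1x1 convolution ->
# ReLU, closed by a 1x1 classification head.  Each downsampling stage halves
# resolution, each decoder unit doubles it.

#' Network configuration
#'
#' @param in_channels input image channels (3 for RGB).
#' @param num_classes output classes (2: background / lesion).
#' @param stem_width channels of the two stem convolutions.
#' @param stage_widths 4-vector of encoder stage widths.
#' @param mhsa_heads attention heads in the bottleneck transformer; must divide
#'   `stage_widths[4] / reduction`.
#' @param ghost_ratio ghost ratio of all ghost blocks (>= 2).
#' @param reduction bottleneck width divisor.
#' @param normalizer `"sn"` (switchable) or `"bn"` (plain batch norm) inside
#'   the bottleneck blocks; the stem always uses batch normalization.
#' @param use_relative_positions enable relative-position attention logits.
#' @param use_ghost `FALSE` replaces every ghost block by a plain convolution
#'   of the same kernel (the parameter-economy reference).
#' @param input_size training patch side length; must be divisible by 16
#'   (four halvings).  The attention position embeddings are sized to
#'   `input_size / 8`.
#' @return a validated config list of class `ghost_unet_config`.
#' @export
ghost_unet_config <- function(in_channels = 3L, num_classes = 2L,
                              stem_width = 64L,
                              stage_widths = c(128L, 256L, 512L, 1024L),
                              mhsa_heads = 4L, ghost_ratio = 2L,
                              reduction = 4L, normalizer = c("sn", "bn"),
                              use_relative_positions = TRUE,
                              use_ghost = TRUE, input_size = 512L) {
  normalizer <- match.arg(normalizer)
  stopifnot(length(stage_widths) == 4L, ghost_ratio >= 2L, mhsa_heads >= 1L)
  if (input_size %% 16L != 0L) {
    stop("input_size must be divisible by 16 (four halvings); got ",
         input_size)
  }
  mid4 <- max(stage_widths[4L] %/% reduction, mhsa_heads)
  if (mid4 %% mhsa_heads != 0L) {
    stop("bottleneck-transformer width (", mid4,
         ") not divisible by mhsa_heads (", mhsa_heads, ")")
  }
  cfg <- list(
    in_channels = as.integer(in_channels),
    num_classes = as.integer(num_classes),
    stem_width = as.integer(stem_width),
    stage_widths = as.integer(stage_widths),
    rgs_depths = c(1L, 2L, 3L),
    mhsa_heads = as.integer(mhsa_heads),
    ghost_ratio = as.integer(ghost_ratio),
    reduction = as.integer(reduction),
    normalizer = normalizer,
    use_relative_positions = isTRUE(use_relative_positions),
    use_ghost = isTRUE(use_ghost),
    input_size = as.integer(input_size)
  )
  class(cfg) <- "ghost_unet_config"
  cfg
}

#' Reduced-width configuration for CPU-scale runs
#'
#' Same topology as the default network with stem width 8 and stage widths
#' 16/32/64/128, sized for 64x64 patches.
#'
#' @param input_size patch side length (divisible by 16).
#' @param ... overrides passed to [ghost_unet_config()].
#' @return a `ghost_unet_config`.
#' @export
cpu_small_config <- function(input_size = 64L, ...) {
  ghost_unet_config(stem_width = 8L, stage_widths = c(16L, 32L, 64L, 128L),
                    input_size = input_size, ...)
}

#' Build the segmentation network
#'
#' Constructs all modules with He-uniform convolution weights, unit scales,
#' zero shifts and zero (unbiased-mixture) switchable-normalization logits.
#'
#' @param cfg a [ghost_unet_config()].
#' @param seed optional integer; when given, initialization is drawn from a
#'   locally seeded RNG stream and the caller's RNG state is untouched.
#' @return a model list of class `ghost_unet`.
#' @export
ghost_unet <- function(cfg = ghost_unet_config(), seed = NULL) {
  if (!inherits(cfg, "ghost_unet_config")) stop("cfg must be a ghost_unet_config")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(as.integer(seed))
  }
  sw <- cfg$stage_widths
  stem <- cfg$stem_width
  nrm <- cfg$normalizer
  gr <- cfg$ghost_ratio
  red <- cfg$reduction
  ug <- cfg$use_ghost
  bot_res <- cfg$input_size %/% 8L
  stage_blocks <- function(in_ch, out_ch, depth, first_stride) {
    blocks <- vector("list", depth)
    for (i in seq_len(depth)) {
      blocks[[i]] <- make_bottleneck(
        if (i == 1L) in_ch else out_ch, out_ch,
        stride = if (i == 1L) first_stride else 1L,
        middle = "ghost3", ghost_ratio = gr, reduction = red,
        normalizer = nrm, use_ghost = ug)
    }
    blocks
  }
  model <- list(
    config = cfg,
    stem = list(
      conv1 = conv_layer(cfg$in_channels, stem, 3L, bias = FALSE),
      norm1 = norm_layer(stem, "bn"),
      conv2 = conv_layer(stem, stem, 3L, bias = FALSE),
      norm2 = norm_layer(stem, "bn")
    ),
    stage1 = stage_blocks(stem, sw[1L], cfg$rgs_depths[1L], 1L),
    stage2 = stage_blocks(sw[1L], sw[2L], cfg$rgs_depths[2L], 2L),
    stage3 = stage_blocks(sw[2L], sw[3L], cfg$rgs_depths[3L], 2L),
    stage4 = list(make_bottleneck(
      sw[3L], sw[4L], stride = 1L, middle = "mhsa", ghost_ratio = gr,
      reduction = red, normalizer = nrm, heads = cfg$mhsa_heads,
      attn_height = bot_res, attn_width = bot_res,
      use_relative_positions = cfg$use_relative_positions, use_ghost = ug)),
    decoder = {
      up_in <- c(sw[4L], sw[3L], sw[2L], sw[1L])
      up_out <- c(sw[3L], sw[2L], sw[1L], stem)
      skip_ch <- c(sw[3L], sw[2L], sw[1L], stem)
      units <- vector("list", 4L)
      for (i in 1:4) {
        units[[i]] <- list(
          tconv_w = he_uniform(c(2L, 2L, up_in[i], up_out[i]),
                               4L * up_in[i]),
          tconv_b = tg_param(array(0, up_out[i])),
          conv = conv_layer(up_out[i] + skip_ch[i], up_out[i], kernel = 1L)
        )
      }
      units
    },
    head = conv_layer(stem, cfg$num_classes, kernel = 1L)
  )
  class(model) <- "ghost_unet"
  model
}

#' @export
print.ghost_unet <- function(x, ...) {
  cfg <- x$config
  cat("<ghost_unet> stem", cfg$stem_width, "| stages",
      paste(cfg$stage_widths, collapse = "/"), "| heads", cfg$mhsa_heads,
      "| normalizer", cfg$normalizer, "| input", cfg$input_size, "\n")
  cat("  parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

check_encoder_input <- function(x, cfg) {
  d <- dim(x$v)
  if (length(d) != 4L) stop("expected a (H, W, C, N) feature map")
  if (d[1L] %% 16L != 0L || d[2L] %% 16L != 0L) {
    stop("input spatial dims ", d[1L], "x", d[2L],
         " must be divisible by 16 (four halvings)")
  }
  if (d[3L] != cfg$in_channels) {
    stop("input has ", d[3L], " channels, expected ", cfg$in_channels)
  }
}

#' Encoder forward pass
#'
#' Runs the stem and the four downsampling stages, capturing skip features at
#' full, 1/2, 1/4 and 1/8 resolution and the bottleneck at 1/16.
#'
#' @param x input `tg_tensor` of dim (H, W, C, N); H and W divisible by 16.
#' @param model a [ghost_unet()] model.
#' @param training normalization mode.
#' @return list with `skips` (4 feature maps, shallow to deep) and
#'   `bottleneck`.
#' @export
encoder_forward <- function(x, model, training = TRUE) {
  check_encoder_input(x, model$config)
  st <- model$stem
  h <- tg_relu(switchable_norm_forward(conv_forward(st$conv1, x), st$norm1,
                                       training))
  s1 <- tg_relu(switchable_norm_forward(conv_forward(st$conv2, h), st$norm2,
                                        training))
  h <- tg_maxpool2d(s1, k = 3L, stride = 2L, pad = 1L)
  for (blk in model$stage1) h <- bottleneck_forward(h, blk, training)
  s2 <- h
  for (blk in model$stage2) h <- bottleneck_forward(h, blk, training)
  s3 <- h
  for (blk in model$stage3) h <- bottleneck_forward(h, blk, training)
  s4 <- h
  h <- bottleneck_forward(s4, model$stage4[[1L]], training)
  b <- tg_avgpool2d(h)
  list(skips = list(s1, s2, s3, s4), bottleneck = b)
}

#' Decoder forward pass
#'
#' Four upsampling units, each: transposed convolution (x2) -> ReLU ->
#' concatenate the matching encoder skip -> 1x1 convolution -> ReLU.
#'
#' @param enc output of [encoder_forward()] from the same model.
#' @param model a [ghost_unet()] model.
#' @param training normalization mode (the decoder itself has no normalizers;
#'   kept for interface symmetry).
#' @return `tg_tensor` at the input resolution with `stem_width` channels.
#' @export
decoder_forward <- function(enc, model, training = TRUE) {
  u <- enc$bottleneck
  for (i in 1:4) {
    unit <- model$decoder[[i]]
    u <- tg_relu(tg_conv_transpose2d(u, unit$tconv_w, unit$tconv_b))
    skip <- enc$skips[[5L - i]]
    du <- dim(u$v); ds <- dim(skip$v)
    if (du[1L] != ds[1L] || du[2L] != ds[2L]) {
      stop("decoder unit ", i, ": upsampled resolution ", du[1L], "x", du[2L],
           " does not match skip resolution ", ds[1L], "x", ds[2L])
    }
    u <- tg_relu(conv_forward(unit$conv, tg_concat(list(u, skip), 3L)))
  }
  u
}

softmax_channels <- function(scores) {
  d <- dim(scores$v)
  mx <- apply(scores$v, c(1L, 2L, 4L), max)
  shift <- tg_tensor(expand_to(array(mx, dim = c(d[1L], d[2L], 1L, d[4L])), d))
  e <- tg_exp(tg_sub(scores, shift))
  tot <- tg_expand(tg_smul(tg_mean_kd(e, 3L), d[3L]), d)
  tg_div(e, tot)
}

#' Full network forward pass
#'
#' @param x input `tg_tensor` of dim (H, W, C, N), H and W divisible by 16.
#' @param model a [ghost_unet()] model.
#' @param training normalization mode (use `FALSE` for inference).
#' @param probabilities if `TRUE`, return per-pixel class probabilities
#'   (normalized exponential over the class channel) instead of raw scores.
#' @return `tg_tensor` of dim (H, W, num_classes, N).
#' @export
ghost_unet_forward <- function(x, model, training = FALSE,
                               probabilities = FALSE) {
  enc <- encoder_forward(x, model, training)
  scores <- conv_forward(model$head, decoder_forward(enc, model, training))
  if (probabilities) softmax_channels(scores) else scores
}

#' Per-pixel foreground probability for a batch of images
#'
#' Inference-mode convenience wrapper: runs the network without recording the
#' autodiff tape and returns the plain probability array of the foreground
#' (last) class.
#'
#' @param model a [ghost_unet()] model.
#' @param x numeric array (H, W, C, N) or (H, W, C).
#' @return numeric array (H, W, N) of foreground probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  tg_no_grad({
    p <- ghost_unet_forward(tg_tensor(x), model, training = FALSE,
                            probabilities = TRUE)
    fg <- aslice(p$v, 3L, model$config$num_classes)
    array(fg, dim = dim(x)[c(1L, 2L, 4L)])
  })
}

#' Count learnable parameters
#'
#' @param x a `ghost_unet` model or a `ghost_unet_config` (a model is then
#'   built just for counting; counts do not depend on initialization).
#' @return total learnable scalar count, with a per-module-group breakdown in
#'   attribute `"breakdown"`.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "ghost_unet_config")) x <- ghost_unet(x, seed = 0L)
  stopifnot(inherits(x, "ghost_unet"))
  groups <- c("stem", "stage1", "stage2", "stage3", "stage4", "decoder",
              "head")
  breakdown <- vapply(groups, function(g) n_parameters(x[[g]]), numeric(1))
  total <- sum(breakdown)
  attr(total, "breakdown") <- breakdown
  total
}

## ---- checkpoints -------------------------------------------------------------

collect_norm_states <- function(module, prefix = "") {
  out <- list()
  if (inherits(module, "gu_norm")) {
    out[[prefix]] <- list(run_mean = module$state$run_mean,
                          run_var = module$state$run_var)
    return(out)
  }
  if (is.list(module)) {
    nms <- names(module)
    for (i in seq_along(module)) {
      if (is_node(module[[i]]) || !is.list(module[[i]])) next
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, collect_norm_states(
        module[[i]], paste0(prefix, if (nzchar(prefix)) "." else "", nm)))
    }
  }
  out
}

#' Save / load model checkpoints
#'
#' A checkpoint stores the exact network configuration, every learnable
#' weight and all normalization running statistics, so that
#' `load_checkpoint(save_checkpoint(model, path))` reproduces forward outputs
#' bit-exactly and the configuration round-trips losslessly.
#'
#' @param model a [ghost_unet()] model.
#' @param path file path (RDS format).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ghost_unet"))
  params <- collect_params(model)
  obj <- list(
    format = "ghostunet-checkpoint-1",
    config = model$config,
    params = lapply(params, function(p) p$v),
    norm_states = collect_norm_states(model)
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "ghostunet-checkpoint-1")) {
    stop("not a ghostunet checkpoint: ", path)
  }
  model <- ghost_unet(obj$config, seed = 0L)
  params <- collect_params(model)
  if (!identical(names(params), names(obj$params))) {
    stop("checkpoint parameter names do not match the rebuilt model")
  }
  for (nm in names(params)) params[[nm]]$v <- obj$params[[nm]]
  states <- collect_norm_states(model)
  if (!identical(names(states), names(obj$norm_states))) {
    stop("checkpoint normalizer states do not match the rebuilt model")
  }
  assign_norm_states(model, obj$norm_states)
  model
}

assign_norm_states <- function(module, states, prefix = "") {
  if (inherits(module, "gu_norm")) {
    st <- states[[prefix]]
    module$state$run_mean <- st$run_mean
    module$state$run_var <- st$run_var
    return(invisible(NULL))
  }
  if (is.list(module)) {
    nms <- names(module)
    for (i in seq_along(module)) {
      if (is_node(module[[i]]) || !is.list(module[[i]])) next
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      assign_norm_states(module[[i]], states,
                         paste0(prefix, if (nzchar(prefix)) "." else "", nm))
    }
  }
  invisible(NULL)
}

# RNG bookkeeping: run `expr`-style seeded sections without disturbing the
# caller's RNG stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

with_local_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  code
}
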