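# Training, inference and evaluation entry points.  Defaults mirror the
# reference protocol for this architecture: dense crop, stride 512, patch
# 512x512x3, batch size 2, 4 attention heads, SGD with learning rate 1e-2,
# weight decay 1e-4, momentum 0.9, 500 epochs.  The cpu-small profile keeps
# all of those and overrides only the widths, the patch size and the epoch
# count so the full pipeline runs at desk scale.

#' Training configuration
#'
#' @param profile `"full"` (stem 64, stages 128/256/512/1024, patch 512,
#'   500 epochs) or `"cpu-small"` (stem 8, stages 16/32/64/128, patch 64,
#'   50 epochs); the optimizer settings are identical in both.
#' @param learning_rate,weight_decay,momentum SGD hyperparameters.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param patch_size training patch side length.
#' @param crop_stride dense-crop stride.
#' @param mhsa_heads attention heads.
#' @param ghost_ratio ghost ratio.
#' @param normalizer `"sn"` or `"bn"`.
#' @param loss `"cdl"` (class-wise dice) or `"dice"`.
#' @param positives_only train on lesion-bearing patches only (`FALSE`:
#'   negatives are used too, gated by the class-wise loss).
#' @param lr_schedule `"constant"` (default) or `"cosine"` decay to zero.
#' @param val_fraction fraction of training patches held out for model
#'   selection when no validation set is supplied.
#' @param seed master seed for initialization and batch shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(profile = c("full", "cpu-small"),
                         learning_rate = 1e-2, weight_decay = 1e-4,
                         momentum = 0.9, batch_size = 2L, epochs = NULL,
                         patch_size = NULL, crop_stride = 512L,
                         mhsa_heads = 4L, ghost_ratio = 2L,
                         normalizer = "sn", loss = c("cdl", "dice"),
                         positives_only = FALSE,
                         lr_schedule = c("constant", "cosine"),
                         val_fraction = 0.1, seed = 42L) {
  profile <- match.arg(profile)
  loss <- match.arg(loss)
  lr_schedule <- match.arg(lr_schedule)
  if (is.null(patch_size)) {
    patch_size <- if (profile == "cpu-small") 64L else 512L
  }
  if (is.null(epochs)) epochs <- if (profile == "cpu-small") 50L else 500L
  cfg <- list(optimizer = "sgd", profile = profile,
              learning_rate = learning_rate, weight_decay = weight_decay,
              momentum = momentum, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              patch_size = as.integer(patch_size),
              crop_stride = as.integer(crop_stride),
              mhsa_heads = as.integer(mhsa_heads),
              ghost_ratio = as.integer(ghost_ratio),
              normalizer = normalizer, loss = loss,
              positives_only = isTRUE(positives_only),
              lr_schedule = lr_schedule, val_fraction = val_fraction,
              seed = as.integer(seed))
  class(cfg) <- "train_config"
  cfg
}

network_config_for <- function(cfg) {
  if (cfg$profile == "cpu-small") {
    cpu_small_config(input_size = cfg$patch_size, mhsa_heads = cfg$mhsa_heads,
                     ghost_ratio = cfg$ghost_ratio,
                     normalizer = cfg$normalizer)
  } else {
    ghost_unet_config(input_size = cfg$patch_size,
                      mhsa_heads = cfg$mhsa_heads,
                      ghost_ratio = cfg$ghost_ratio,
                      normalizer = cfg$normalizer)
  }
}

## ---- SGD ----------------------------------------------------------------------

sgd_init <- function(params, lr, momentum, weight_decay) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr
  opt$momentum <- momentum
  opt$weight_decay <- weight_decay
  opt$velocity <- lapply(params, function(p) array(0, dim = dim(p$v)))
  opt
}

sgd_step <- function(opt, lr = opt$lr) {
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad + opt$weight_decay * p$v
    opt$velocity[[i]] <- opt$momentum * opt$velocity[[i]] + g
    p$v <- p$v - lr * opt$velocity[[i]]
  }
  tg_zero_grad(opt$params)
  invisible(opt)
}

## ---- training loop --------------------------------------------------------------

batch_tensor <- function(records) {
  arr <- acat(lapply(records, function(r) {
    array(r$image, dim = c(dim(r$image), 1L))
  }), 4L)
  tg_tensor(arr)
}

batch_loss <- function(model, records, loss_type, training = TRUE) {
  x <- batch_tensor(records)
  scores <- ghost_unet_forward(x, model, training = training)
  stopifnot(dim(scores$v)[3L] == 2L)
  p <- tg_sigmoid(tg_sub(tg_slice(scores, 3L, 2L), tg_slice(scores, 3L, 1L)))
  total <- NULL
  for (n in seq_along(records)) {
    pn <- tg_slice(p, 4L, n)
    r <- records[[n]]
    msk <- array(r$mask, dim = dim(pn$v))
    ln <- if (loss_type == "cdl") {
      class_wise_dice_loss_t(pn, msk, r$label)
    } else {
      dice_loss_t(pn, msk)
    }
    total <- if (is.null(total)) ln else tg_add(total, ln)
  }
  tg_smul(total, 1 / length(records))
}

#' Mean dice of a model over a set of records
#'
#' Inference-mode predictions binarized at `threshold`, scored against each
#' record's mask.  Following the package-wide aggregation convention (see
#' [evaluate_testset()]), the mean is taken over records with a non-empty
#' annotation: on an empty annotation the per-pair dice is all-or-nothing (one
#' stray pixel flips 1 to 0), which says nothing about segmentation quality.
#' When the set holds no positive record at all, the mean over all records
#' (empty-empty = 1 convention) is returned instead.
#'
#' @param model a [ghost_unet()] model.
#' @param records list of [patch_record()]s.
#' @param threshold binarization threshold.
#' @return mean dice coefficient.
#' @export
dataset_dsc <- function(model, records, threshold = 0.5) {
  vals <- vapply(records, function(r) {
    p <- predict_prob(model, r$image)[, , 1L]
    dsc(r$mask, (p > threshold) * 1L)
  }, numeric(1))
  pos <- vapply(records, function(r) r$label == 1L, logical(1))
  if (any(pos)) mean(vals[pos]) else mean(vals)
}

#' Mean predicted foreground fraction on lesion-free records
#'
#' The class-wise dice loss trains negative patches toward an all-zero mask;
#' this measures how close a model is to that target (0 = perfect).
#'
#' @inheritParams dataset_dsc
#' @return mean fraction of pixels predicted foreground over the negative
#'   records (`NaN` if there are none).
#' @export
negative_fp_fraction <- function(model, records, threshold = 0.5) {
  neg <- Filter(function(r) r$label == 0L, records)
  if (length(neg) == 0L) return(NaN)
  mean(vapply(neg, function(r) {
    p <- predict_prob(model, r$image)[, , 1L]
    mean(p > threshold)
  }, numeric(1)))
}

#' Train the segmentation network
#'
#' Seeded SGD training with the configured loss.  When a validation set is
#' available (given explicitly, or held out via `val_fraction`), the
#' checkpoint with the best validation dice is retained; otherwise the final
#' model is returned.
#'
#' @param cfg a [train_config()].
#' @param dataset list of [patch_record()]s whose patches match
#'   `cfg$patch_size`.
#' @param val_dataset optional validation records; `NULL` with
#'   `cfg$val_fraction > 0` holds out that fraction of `dataset` (no holdout
#'   when the dataset is too small to spare a record).
#' @param max_steps cap on optimizer steps (Inf: run all epochs).
#' @param checkpoint_path optional path; the retained model is saved there.
#' @param verbose print per-epoch progress.
#' @return list of class `gu_train_result` with `model`, `history`
#'   (data frame: epoch, loss, val_dsc), `steps`, `config`, `best_val_dsc`.
#' @export
train <- function(cfg, dataset, val_dataset = NULL, max_steps = Inf,
                  checkpoint_path = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(dataset) == 0L) stop("empty dataset")
  ps <- cfg$patch_size
  for (r in dataset) {
    if (!identical(dim(r$mask), c(ps, ps))) {
      stop("patch size ", paste(dim(r$mask), collapse = "x"),
           " does not match the configured patch size ", ps)
    }
  }
  if (cfg$positives_only) {
    dataset <- Filter(function(r) r$label == 1L, dataset)
    if (length(dataset) == 0L) stop("no positive patches to train on")
  }
  netcfg <- network_config_for(cfg)
  with_local_seed(cfg$seed, {
    if (is.null(val_dataset) && cfg$val_fraction > 0 &&
        length(dataset) >= 10L) {
      n_val <- max(1L, floor(cfg$val_fraction * length(dataset)))
      idx <- sample(length(dataset), n_val)
      val_dataset <- dataset[idx]
      dataset <- dataset[-idx]
    }
    model <- ghost_unet(netcfg)
    params <- collect_params(model)
    opt <- sgd_init(params, cfg$learning_rate, cfg$momentum,
                    cfg$weight_decay)
    n <- length(dataset)
    total_steps <- min(max_steps,
                       cfg$epochs * ceiling(n / cfg$batch_size))
    step <- 0L
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          val_dsc = numeric(0))
    best <- list(val = -Inf, params = NULL, states = NULL)
    for (ep in seq_len(cfg$epochs)) {
      if (step >= total_steps) break
      ord <- sample(n)
      ep_losses <- c()
      for (b in seq(1L, n, by = cfg$batch_size)) {
        if (step >= total_steps) break
        ids <- ord[b:min(b + cfg$batch_size - 1L, n)]
        lr <- if (cfg$lr_schedule == "cosine") {
          cfg$learning_rate * 0.5 * (1 + cos(pi * step / total_steps))
        } else cfg$learning_rate
        loss <- batch_loss(model, dataset[ids], cfg$loss, training = TRUE)
        tg_backward(loss)
        sgd_step(opt, lr)
        step <- step + 1L
        ep_losses <- c(ep_losses, as.numeric(loss$v))
      }
      val_dsc <- if (!is.null(val_dataset)) {
        dataset_dsc(model, val_dataset)
      } else NA_real_
      history <- rbind(history, data.frame(epoch = ep,
                                           loss = mean(ep_losses),
                                           val_dsc = val_dsc))
      if (!is.na(val_dsc) && val_dsc > best$val) {
        best <- list(val = val_dsc,
                     params = lapply(params, function(p) p$v),
                     states = collect_norm_states(model))
      }
      if (verbose) {
        message(sprintf("epoch %d  loss %.4f  val DSC %s", ep,
                        mean(ep_losses),
                        ifelse(is.na(val_dsc), "-", sprintf("%.4f", val_dsc))))
      }
    }
    if (!is.null(best$params)) {
      for (nm in names(params)) params[[nm]]$v <- best$params[[nm]]
      assign_norm_states(model, best$states)
    }
    if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
    out <- list(model = model, history = history, steps = step,
                config = cfg, network_config = netcfg,
                best_val_dsc = if (is.finite(best$val)) best$val else NA_real_)
    class(out) <- "gu_train_result"
    out
  })
}

#' @export
print.gu_train_result <- function(x, ...) {
  cat("<training run>", x$steps, "steps,", nrow(x$history), "epochs; final loss",
      sprintf("%.4f", tail(x$history$loss, 1)), "\n")
  invisible(x)
}

## ---- inference and evaluation ----------------------------------------------------

#' Predict binary masks for images
#'
#' Dense-crops each image to the model's patch size, runs inference,
#' binarizes foreground probabilities at `threshold` and (optionally)
#' stitches patch predictions back to full resolution with the logical-OR
#' rule.  Images already at patch size are predicted directly.
#'
#' @param model a [ghost_unet()] model (or a checkpoint path).
#' @param images a single (H, W, 3) array or a list of arrays / image file
#'   paths.
#' @param stride dense-crop stride (default: patch size, non-overlapping).
#' @param threshold probability binarization threshold.
#' @param stitch_full stitch patch predictions to image resolution? When
#'   `FALSE` a list of per-patch records is returned per image.
#' @return list of binary (H, W) masks (or per-patch lists).
#' @export
predict_masks <- function(model, images, stride = NULL, threshold = 0.5,
                          stitch_full = TRUE) {
  if (is.character(model)) model <- load_checkpoint(model)
  ps <- model$config$input_size
  if (is.null(stride)) stride <- ps
  if (!is.list(images)) images <- list(images)
  lapply(images, function(img) {
    if (is.character(img)) img <- read_image(img)
    d <- dim(img)
    if (d[1L] == ps && d[2L] == ps) {
      p <- predict_prob(model, img)[, , 1L]
      return((p > threshold) * 1L)
    }
    patches <- dense_crop(img, patch_size = ps, stride = stride)
    preds <- lapply(patches, function(pt) {
      p <- predict_prob(model, pt$image)[, , 1L]
      patch_record(pt$image, (p > threshold) * 1L, origin = pt$origin)
    })
    if (stitch_full) stitch(preds, d[1:2], rule = "or") else preds
  })
}

#' Evaluate a model on a test set
#'
#' Runs [predict_masks()] on each record and aggregates with
#' [evaluate_testset()].
#'
#' @param model a [ghost_unet()] model or checkpoint path.
#' @param testset list of [patch_record()]s.
#' @param threshold binarization threshold.
#' @param tau image-level positive-call threshold on the lesion fraction.
#' @return a `metrics_report`.
#' @export
evaluate_model <- function(model, testset, threshold = 0.5, tau = 1e-3) {
  if (is.character(model)) model <- load_checkpoint(model)
  preds <- predict_masks(model, lapply(testset, function(r) r$image),
                         threshold = threshold)
  evaluate_testset(preds, lapply(testset, function(r) r$mask),
                   vapply(testset, function(r) as.numeric(r$label),
                          numeric(1)),
                   tau = tau)
}
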