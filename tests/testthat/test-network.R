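# Full network: resolution ladder, live skip paths, parameter accounting,
# inference determinism and checkpoint round-trips (all at CPU-scale widths).

small_cfg <- function(size = 64L, ...) cpu_small_config(size, ...)

test_that("encoder produces the exact halving ladder and stage depths", {
  model <- ghost_unet(small_cfg(64L), seed = 61)
  expect_length(model$stage1, 1)
  expect_length(model$stage2, 2)
  expect_length(model$stage3, 3)
  expect_length(model$stage4, 1)
  expect_equal(model$stage4[[1]]$middle, "mhsa")

  for (N in c(1L, 2L)) {
    x <- tg_tensor(array(runif(64 * 64 * 3 * N), c(64, 64, 3, N)))
    enc <- tg_no_grad(encoder_forward(x, model, training = FALSE))
    dims <- lapply(enc$skips, function(s) dim(s$v))
    expect_equal(dims[[1]][1:2], c(64, 64))
    expect_equal(dims[[2]][1:2], c(32, 32))
    expect_equal(dims[[3]][1:2], c(16, 16))
    expect_equal(dims[[4]][1:2], c(8, 8))
    expect_equal(dim(enc$bottleneck$v), c(4, 4, 128, N))
    out <- tg_no_grad(ghost_unet_forward(x, model))
    expect_equal(dim(out$v), c(64, 64, 2, N))
  }
})

test_that("probability mode normalizes over classes at every pixel", {
  model <- ghost_unet(small_cfg(32L), seed = 62)
  x <- tg_tensor(array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
  p <- tg_no_grad(ghost_unet_forward(x, model, probabilities = TRUE))$v
  expect_lt(max(abs(apply(p, c(1, 2, 4), sum) - 1)), 1e-12)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("indivisible input sizes are rejected with the required divisor", {
  model <- ghost_unet(small_cfg(64L), seed = 63)
  x <- tg_tensor(array(0, c(48, 40, 3, 1)))  # 40 not divisible by 16
  expect_error(ghost_unet_forward(x, model), "divisible by 16")
  expect_error(ghost_unet_config(input_size = 100), "divisible by 16")
})

test_that("skips are live paths: zeroing one changes the output", {
  model <- ghost_unet(small_cfg(32L), seed = 64)
  x <- tg_tensor(array(runif(32 * 32 * 3), c(32, 32, 3, 1)))
  tg_no_grad({
    enc <- encoder_forward(x, model, training = FALSE)
    base <- decoder_forward(enc, model, training = FALSE)$v
    for (k in 1:4) {
      enc2 <- enc
      enc2$skips[[k]] <- tg_tensor(array(0, dim = dim(enc$skips[[k]]$v)))
      alt <- decoder_forward(enc2, model, training = FALSE)$v
      expect_gt(max(abs(alt - base)), 1e-8)
    }
  })
})

test_that("decoder rejects mismatched skip resolutions naming the stage", {
  model <- ghost_unet(small_cfg(32L), seed = 65)
  x <- tg_tensor(array(runif(32 * 32 * 3), c(32, 32, 3, 1)))
  enc <- tg_no_grad(encoder_forward(x, model, training = FALSE))
  enc$skips[[4]] <- tg_tensor(array(0, c(2, 2, 64, 1)))
  expect_error(tg_no_grad(decoder_forward(enc, model, training = FALSE)),
               "decoder unit 1")
})

test_that("parameter counts: ghost economy, width scaling, resolution invariance", {
  cfg_ghost <- small_cfg(64L)
  cfg_plain <- small_cfg(64L, use_ghost = FALSE)
  n_ghost <- count_parameters(cfg_ghost)
  n_plain <- count_parameters(cfg_plain)
  expect_lt(as.numeric(n_ghost), as.numeric(n_plain))

  # doubling widths ~quadruples the (conv-dominated) count
  cfg2 <- ghost_unet_config(stem_width = 16L,
                            stage_widths = c(32L, 64L, 128L, 256L),
                            input_size = 64L,
                            use_relative_positions = FALSE)
  cfg1 <- ghost_unet_config(stem_width = 8L,
                            stage_widths = c(16L, 32L, 64L, 128L),
                            input_size = 64L,
                            use_relative_positions = FALSE)
  ratio <- as.numeric(count_parameters(cfg2)) /
    as.numeric(count_parameters(cfg1))
  expect_gt(ratio, 3)
  expect_lt(ratio, 4.5)

  # counts do not depend on input resolution except the position tables
  n64 <- count_parameters(ghost_unet_config(
    stem_width = 8L, stage_widths = c(16L, 32L, 64L, 128L),
    input_size = 64L, use_relative_positions = FALSE))
  n32 <- count_parameters(ghost_unet_config(
    stem_width = 8L, stage_widths = c(16L, 32L, 64L, 128L),
    input_size = 32L, use_relative_positions = FALSE))
  expect_equal(as.numeric(n64), as.numeric(n32))
  with_rel <- count_parameters(small_cfg(64L))
  expect_gt(as.numeric(with_rel), as.numeric(n64))
})

test_that("inference is deterministic and finite at batch 1 under SN", {
  model <- ghost_unet(small_cfg(32L), seed = 66)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  p1 <- predict_prob(model, x)
  p2 <- predict_prob(model, x)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)))
  # training-mode forward at batch 1 is also finite
  y <- ghost_unet_forward(tg_tensor(x), model, training = TRUE)
  expect_true(all(is.finite(y$v)))
})

test_that("checkpoints round-trip config and forward outputs bit-exactly", {
  model <- ghost_unet(small_cfg(32L), seed = 67)
  # push the running stats away from initialization first
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  invisible(ghost_unet_forward(tg_tensor(x), model, training = TRUE))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  restored <- load_checkpoint(path)
  expect_identical(restored$config, model$config)
  expect_identical(predict_prob(restored, x), predict_prob(model, x))
})

test_that("a scalar loss reaches every module group with nonzero gradients", {
  set.seed(68)
  model <- ghost_unet(small_cfg(32L), seed = 68)
  x <- tg_tensor(array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
  y <- ghost_unet_forward(x, model, training = TRUE)
  tg_backward(tg_sum(tg_square(y)))
  for (group in c("stem", "stage1", "stage2", "stage3", "stage4", "decoder",
                  "head")) {
    ps <- collect_params(model[[group]])
    got <- vapply(ps, function(p) !is.null(p$grad) && any(p$grad != 0),
                  logical(1))
    expect_true(all(got), info = group)
  }
})
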