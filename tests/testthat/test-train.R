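# Training pipeline: configuration contract, seeded determinism, learning on
# a tiny task, prediction conventions and the CLI round trip.

test_that("default configuration carries the reference hyperparameters", {
  cfg <- train_config()
  expect_equal(cfg$optimizer, "sgd")
  expect_equal(cfg$learning_rate, 1e-2)
  expect_equal(cfg$weight_decay, 1e-4)
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$batch_size, 2L)
  expect_equal(cfg$epochs, 500L)
  expect_equal(cfg$patch_size, 512L)
  expect_equal(cfg$crop_stride, 512L)
  expect_equal(cfg$mhsa_heads, 4L)
  # cpu-small overrides only widths / patch size / epochs
  small <- train_config(profile = "cpu-small")
  expect_equal(small$patch_size, 64L)
  expect_lt(small$epochs, 500L)
  expect_equal(small$learning_rate, cfg$learning_rate)
  expect_equal(small$momentum, cfg$momentum)
  expect_equal(small$batch_size, cfg$batch_size)
  nc <- ghostunet:::network_config_for(small)
  expect_equal(nc$stem_width, 8L)
  expect_equal(nc$stage_widths, c(16L, 32L, 64L, 128L))
})

test_that("identical seed and config reproduce the first-epoch loss", {
  sp <- synth_params(size = 32, seed = 11)
  recs <- synthesize_dataset(sp, 4)
  cfg <- train_config(profile = "cpu-small", patch_size = 32L, seed = 7L,
                      val_fraction = 0)
  r1 <- train(cfg, recs, max_steps = 2)
  r2 <- train(cfg, recs, max_steps = 2)
  expect_identical(r1$history$loss[1], r2$history$loss[1])
  cfg2 <- train_config(profile = "cpu-small", patch_size = 32L, seed = 8L,
                       val_fraction = 0)
  r3 <- train(cfg2, recs, max_steps = 2)
  expect_false(identical(r1$history$loss[1], r3$history$loss[1]))
})

test_that("a short seeded run reduces the training loss on a tiny task", {
  sp <- synth_params(size = 32, seed = 12)
  recs <- synthesize_dataset(sp, 4)
  cfg <- train_config(profile = "cpu-small", patch_size = 32L, seed = 1L,
                      val_fraction = 0, epochs = 10L)
  res <- train(cfg, recs, max_steps = 20)
  expect_equal(res$steps, 20L)
  expect_lt(tail(res$history$loss, 1), res$history$loss[1])
  expect_true(all(diff(res$history$epoch) == 1))
})

test_that("dataset validation errors are informative", {
  cfg <- train_config(profile = "cpu-small", patch_size = 64L)
  expect_error(train(cfg, list()), "empty dataset")
  sp <- synth_params(size = 32, seed = 13)
  recs <- synthesize_dataset(sp, 2)
  expect_error(train(cfg, recs), "does not match the configured patch size")
  # positives-only mode with no positives
  sp0 <- synth_params(size = 64, lesion_prob = 0, seed = 13)
  neg <- synthesize_dataset(sp0, 2)
  cfg2 <- train_config(profile = "cpu-small", positives_only = TRUE)
  expect_error(train(cfg2, neg), "no positive patches")
})

test_that("training checkpoints round-trip through the filesystem", {
  sp <- synth_params(size = 32, seed = 14)
  recs <- synthesize_dataset(sp, 4)
  cfg <- train_config(profile = "cpu-small", patch_size = 32L, seed = 2L,
                      val_fraction = 0)
  ck <- tempfile(fileext = ".rds")
  res <- train(cfg, recs, max_steps = 3, checkpoint_path = ck)
  restored <- load_checkpoint(ck)
  x <- recs[[1]]$image
  expect_identical(predict_prob(restored, x), predict_prob(res$model, x))
})

test_that("prediction is order-invariant, binary, and stitches large images", {
  sp <- synth_params(size = 32, seed = 15)
  recs <- synthesize_dataset(sp, 3)
  cfg <- train_config(profile = "cpu-small", patch_size = 32L, seed = 3L,
                      val_fraction = 0)
  model <- train(cfg, recs, max_steps = 2)$model
  imgs <- lapply(recs, function(r) r$image)
  m_ab <- predict_masks(model, imgs[1:2])
  m_ba <- predict_masks(model, imgs[2:1])
  expect_identical(m_ab[[1]], m_ba[[2]])
  expect_true(all(unlist(m_ab) %in% c(0, 1)))
  # a larger image is dense-cropped and stitched back to full size
  big <- array(runif(64 * 96 * 3), c(64, 96, 3))
  mk <- predict_masks(model, big)[[1]]
  expect_equal(dim(mk), c(64, 96))
  # evaluation wires prediction into the metrics report
  rep_ <- evaluate_model(model, recs)
  expect_s3_class(rep_, "metrics_report")
  expect_true(rep_$pixel_pa >= 0 && rep_$pixel_pa <= 1)
})

test_that("the CLI runs synth -> train -> evaluate -> score end to end", {
  base <- tempfile("cli")
  suppressMessages(ghostunet_cli(
    c("synth", "--out", base, "--n-train", "4", "--n-val", "0",
      "--n-test", "2", "--size", "32", "--seed", "4")))
  expect_true(file.exists(file.path(base, "train", "manifest.tsv")))
  ck <- file.path(base, "model.rds")
  suppressMessages(ghostunet_cli(c(
    "train", "--data", file.path(base, "train"), "--out", ck,
    "--profile", "cpu-small", "--epochs", "1", "--seed", "5",
    "--max-steps", "2")))
  expect_true(file.exists(ck))
  json <- file.path(base, "report.json")
  suppressMessages(ghostunet_cli(c(
    "evaluate", "--checkpoint", ck, "--data", file.path(base, "test"),
    "--json", json)))
  rep_ <- jsonlite::read_json(json)
  expect_true(all(c("dsc", "auc", "pa", "ji", "rvd", "precision") %in%
                    names(rep_)))
  # predict + score on the test images
  pred_dir <- file.path(base, "pred")
  suppressMessages(ghostunet_cli(c(
    "predict", "--checkpoint", ck, "--images",
    file.path(base, "test", "images"), "--out", pred_dir)))
  expect_length(list.files(pred_dir, pattern = "png$"), 2)
  json2 <- file.path(base, "score.json")
  suppressMessages(ghostunet_cli(c(
    "score", "--pred", pred_dir, "--truth", file.path(base, "test", "masks"),
    "--json", json2)))
  expect_true(file.exists(json2))
})
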