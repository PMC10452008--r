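# Dense cropping and stitching, the synthetic generator, augmentation and the
# 0/255 mask I/O convention.

test_that("dense crop produces the edge-anchored grid", {
  img <- array(runif(1024 * 1024 * 3), c(1024, 1024, 3))
  ps <- dense_crop(img, patch_size = 512, stride = 512)
  expect_length(ps, 4)
  origins <- t(vapply(ps, function(p) p$origin, integer(2)))
  expect_equal(origins[order(origins[, 1], origins[, 2]), ],
               rbind(c(0, 0), c(0, 512), c(512, 0), c(512, 512)))

  # 3000x3000 (a typical tissue-slice size): 6x6 grid, last anchored at 2488
  img2 <- matrix(0, 3000, 3000)
  ps2 <- dense_crop(img2, patch_size = 512, stride = 512)
  expect_length(ps2, 36)
  rows <- sort(unique(vapply(ps2, function(p) p$origin[1], integer(1))))
  expect_equal(rows, c(0L, 512L, 1024L, 1536L, 2048L, 2488L))
  rm(img2, ps2)

  # patch equal to image size -> one patch at (0,0)
  ps3 <- dense_crop(array(0, c(64, 64, 3)), patch_size = 64, stride = 64)
  expect_length(ps3, 1)
  expect_equal(ps3[[1]]$origin, c(0L, 0L))
  expect_error(dense_crop(array(0, c(32, 32, 3)), patch_size = 64),
               "smaller than patch_size")
})

test_that("dense crop covers every pixel for any stride <= patch size", {
  set.seed(91)
  for (i in 1:5) {
    H <- sample(70:120, 1); W <- sample(70:120, 1)
    stride <- sample(16:48, 1)
    m <- random_mask(H, W, 0.3)
    ps <- dense_crop(array(0.5, c(H, W, 3)), mask = m, patch_size = 48,
                     stride = stride)
    cover <- matrix(0L, H, W)
    for (p in ps) {
      cover[(p$origin[1] + 1):(p$origin[1] + 48),
            (p$origin[2] + 1):(p$origin[2] + 48)] <- 1L
    }
    expect_true(all(cover == 1L))
  }
})

test_that("stitch inverts dense_crop and applies the OR rule", {
  set.seed(92)
  m <- random_mask(96, 80, 0.35)
  img <- array(0.5, c(96, 80, 3))
  # partition round-trip at stride = patch size
  ps <- dense_crop(img, mask = m, patch_size = 16, stride = 16)
  expect_identical(stitch(ps, c(96, 80)), m * 1)
  # overlapping crops of a constant mask reproduce it
  ones <- matrix(1L, 64, 64)
  pso <- dense_crop(array(0, c(64, 64, 3)), mask = ones, patch_size = 32,
                    stride = 16)
  expect_true(all(stitch(pso, c(64, 64)) == 1))
  # OR rule on a constructed 2-patch overlap
  pa <- patch_record(array(0, c(4, 4, 3)),
                     matrix(c(1, rep(0, 15)), 4, 4), origin = c(0, 0))
  pb <- patch_record(array(0, c(4, 4, 3)), matrix(0, 4, 4), origin = c(0, 2))
  out <- stitch(list(pa, pb), c(4, 6))
  expect_equal(out[1, 1], 1)       # positive in one overlapping patch
  expect_equal(sum(out), 1)
  # coverage gaps are named
  expect_error(stitch(list(pa), c(4, 6)), "coverage gap.*\\(0,4\\)")
  # mean rule averages overlaps
  pc <- patch_record(array(0, c(4, 4, 3)), matrix(1, 4, 4), origin = c(0, 0))
  pd <- patch_record(array(0, c(4, 4, 3)), matrix(0, 4, 4), origin = c(0, 0))
  expect_true(all(stitch(list(pc, pd), c(4, 4), rule = "mean") == 0.5))
})

test_that("the synthetic generator is seeded, label-consistent and unbiased", {
  sp <- synth_params(size = 32, seed = 5)
  r1 <- synthesize_sample(sp, 3)
  r2 <- synthesize_sample(sp, 3)
  expect_identical(r1, r2)                   # bit-identical in (seed, index)
  expect_false(identical(r1, synthesize_sample(sp, 4)))

  recs <- synthesize_dataset(sp, 60)
  for (r in recs) {
    expect_equal(r$label, as.integer(any(r$mask > 0)))
    expect_true(all(r$mask %in% c(0L, 1L)))
    expect_true(all(r$image >= 0 & r$image <= 1))
  }
  # positive fraction within binomial 99% bounds of 0.5 over 200 draws
  labs <- vapply(1:200, function(i) synthesize_sample(sp, i)$label,
                 integer(1))
  half_width <- qnorm(0.995) * sqrt(0.25 / 200)
  expect_gt(mean(labs), 0.5 - half_width)
  expect_lt(mean(labs), 0.5 + half_width)
  # lesion probability 0 -> all negative
  sp0 <- synth_params(size = 32, lesion_prob = 0, seed = 5)
  expect_true(all(vapply(1:20, function(i) synthesize_sample(sp0, i)$label,
                         integer(1)) == 0L))
})

test_that("augmentation preserves masks, labels and involutions", {
  sp <- synth_params(size = 32, lesion_prob = 1, seed = 6)
  r <- synthesize_sample(sp, 1)
  # identity draw leaves the record unchanged
  ident <- augment(r, ops = list(dihedral = 0, brightness = 0, contrast = 1))
  expect_identical(ident$image, r$image)
  expect_identical(ident$mask, r$mask)
  # double horizontal flip restores the original
  f <- augment(r, ops = list(dihedral = 4, brightness = 0, contrast = 1))
  ff <- augment(f, ops = list(dihedral = 4, brightness = 0, contrast = 1))
  expect_identical(ff$mask, r$mask)
  expect_identical(ff$image, r$image)
  # geometric ops preserve the foreground pixel count; jitter keeps labels
  for (seed in 1:6) {
    a <- augment(r, seed = seed)
    expect_equal(sum(a$mask), sum(r$mask))
    expect_equal(a$label, r$label)
    expect_true(all(a$mask %in% c(0L, 1L)))
    expect_identical(augment(r, seed = seed)$image, a$image)  # seeded draw
  }
})

test_that("mask I/O honours the 0/255 convention", {
  m <- random_mask(9, 7, 0.4)
  path <- tempfile(fileext = ".png")
  write_mask(m, path)
  expect_identical(read_mask(path), m * 1L)
  # a 255-valued pixel reads as foreground
  png::writePNG(matrix(c(1, 0, 0, 0), 2, 2), path)
  expect_equal(read_mask(path)[1, 1], 1L)
  # stray values fall under the >=128 rule with a warning
  png::writePNG(matrix(c(37, 200, 0, 255) / 255, 2, 2), path)
  expect_warning(m2 <- read_mask(path), ">=128 rule")
  expect_equal(as.vector(m2), c(0L, 1L, 0L, 1L))
  # multi-channel masks are rejected
  png::writePNG(array(0.5, c(2, 2, 3)), path)
  expect_error(read_mask(path), "single-channel")
  expect_error(write_mask(matrix(0.5, 2, 2), path), "binary")
})

test_that("dataset directories round-trip through the manifest", {
  sp <- synth_params(size = 32, seed = 9)
  dir <- tempfile("ds")
  recs <- synthesize_dataset(sp, 4, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- load_dataset(dir)
  expect_length(back, 4)
  for (i in 1:4) {
    expect_identical(back[[i]]$mask, recs[[i]]$mask * 1L)
    expect_equal(back[[i]]$label, recs[[i]]$label)
    expect_equal(back[[i]]$image, recs[[i]]$image, tolerance = 1e-9)
  }
})
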