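# Metrics vs independent brute-force oracles, algebraic identities between
# DSC and JI, AUC properties and the test-set aggregation conventions.

test_that("overlap metrics match set-arithmetic oracles on random pairs", {
  set.seed(81)
  for (i in 1:200) {
    a <- random_mask(7, 9, runif(1, 0.1, 0.7))
    p <- random_mask(7, 9, runif(1, 0.1, 0.7))
    o <- oracle_overlap(a, p)
    expect_equal(dsc(a, p), o$dsc, tolerance = 1e-12)
    expect_equal(jaccard(a, p), o$ji, tolerance = 1e-12)
    if (sum(a) > 0) {
      expect_equal(rvd(a, p), o$rvd, tolerance = 1e-12)
    }
    # identities: DSC = 2 JI / (1 + JI) and DSC >= JI
    expect_equal(dsc(a, p), 2 * jaccard(a, p) / (1 + jaccard(a, p)),
                 tolerance = 1e-12)
    expect_gte(dsc(a, p), jaccard(a, p))
  }
})

test_that("worked overlap example and conventions", {
  a <- matrix(0, 4, 4); a[1:4] <- 1          # |Y_A| = 4
  p <- matrix(0, 4, 4); p[3:8] <- 1          # |Y_P| = 6, |intersection| = 2
  p2 <- matrix(0, 4, 4); p2[c(1, 2, 3, 5, 6, 7)] <- 1  # intersection 3
  expect_equal(dsc(a, p2), 0.6)
  expect_equal(jaccard(a, p2), 3 / 7)
  expect_equal(rvd(a, p2), 0.5)
  expect_equal(rvd(a, matrix(0, 4, 4)), -1)   # empty prediction lower bound
  z <- matrix(0, 3, 3)
  expect_equal(dsc(z, z), 1)                  # empty-empty convention
  expect_equal(jaccard(z, z), 1)
  expect_warning(v <- rvd(z, z), "undefined")
  expect_true(is.na(v))
  expect_equal(dsc(a, 1 - a), 0)              # disjoint non-empty sets
  expect_error(dsc(a, matrix(0, 3, 3)), "shapes differ")
})

test_that("confusion counts, rates and pixel accuracy", {
  # TP=2, FP=1, TN=3, FN=2 at threshold 0.5
  scores <- c(0.9, 0.8, 0.2, 0.1, 0.7, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  cc <- confusion(scores, labels, 0.5)
  expect_equal(cc[c("tp", "fp", "tn", "fn")], list(tp = 2, fp = 1, tn = 3, fn = 2))
  expect_equal(cc$precision, 2 / 3)
  expect_equal(cc$tpr, 0.5)
  expect_equal(cc$fpr, 0.25)
  expect_equal(cc$pa, 5 / 8)
  # all correct
  cc2 <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0), 0.5)
  expect_equal(cc2$tpr, 1); expect_equal(cc2$fpr, 0)
  # threshold above all scores: no predicted positives, 0/0 -> 0
  cc3 <- confusion(scores, labels, 2)
  expect_equal(cc3$tp + cc3$fp, 0)
  expect_equal(cc3$precision, 0)
})

test_that("AUC equals exhaustive pair counting and is rank-invariant", {
  set.seed(82)
  for (i in 1:50) {
    labels <- c(rep(1, 4), rep(0, 4))
    scores <- round(runif(8), 1)  # rounding forces occasional ties
    expect_equal(auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(auc(exp(3 * scores) + 1, labels), auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_equal(auc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)  # perfect separation
  expect_equal(auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)  # all ties
  expect_error(auc(1:3, c(1, 1, 1)), "undefined")
})

test_that("test-set aggregation matches a per-metric oracle loop", {
  set.seed(83)
  n <- 20
  preds <- list(); anns <- list()
  for (i in 1:n) {
    anns[[i]] <- if (i <= 12) random_mask(8, 8, 0.4) else matrix(0, 8, 8)
    preds[[i]] <- random_mask(8, 8, 0.3)
  }
  labels <- vapply(anns, function(a) as.numeric(any(a > 0)), numeric(1))
  rep_ <- evaluate_testset(preds, anns, labels, tau = 1e-3)
  pos <- which(labels == 1)
  o_dsc <- mean(vapply(pos, function(i) oracle_overlap(anns[[i]], preds[[i]])$dsc,
                       numeric(1)))
  o_ji <- mean(vapply(pos, function(i) oracle_overlap(anns[[i]], preds[[i]])$ji,
                      numeric(1)))
  o_rvd <- mean(vapply(pos, function(i) oracle_overlap(anns[[i]], preds[[i]])$rvd,
                       numeric(1)))
  expect_equal(rep_$dsc, o_dsc, tolerance = 1e-12)
  expect_equal(rep_$ji, o_ji, tolerance = 1e-12)
  expect_equal(rep_$rvd, o_rvd, tolerance = 1e-12)
  fracs <- vapply(preds, mean, numeric(1))
  expect_equal(rep_$auc, oracle_auc(fracs, labels), tolerance = 1e-12)
  cc <- confusion(fracs, labels, 1e-3)
  expect_equal(rep_$pa, cc$pa)
  expect_equal(rep_$precision, cc$precision)
})

test_that("perfect predictions on a balanced pair give the trivial report", {
  a <- matrix(0, 6, 6); a[2:4, 2:4] <- 1
  z <- matrix(0, 6, 6)
  rep_ <- evaluate_testset(list(a, z), list(a, z))
  expect_equal(rep_$dsc, 1)
  expect_equal(rep_$pa, 1)
  expect_equal(rep_$auc, 1)
  expect_equal(rep_$rvd, 0)
  expect_error(evaluate_testset(list(a), list(a, z)), "misaligned")
})

test_that("reports serialize to JSON and TSV", {
  a <- matrix(0, 4, 4); a[1:2] <- 1
  rep_ <- evaluate_testset(list(a, matrix(0, 4, 4)),
                           list(a, matrix(0, 4, 4)))
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  write_metrics_report(rep_, jp, tp)
  j <- jsonlite::read_json(jp)
  expect_equal(j$dsc, 1)
  tab <- read.delim(tp)
  expect_true("dsc" %in% tab$metric)
})
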