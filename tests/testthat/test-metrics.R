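test_that("iou, dice and mae match their set definitions", {
  Tm <- matrix(0L, 3, 3); Tm[1, 1:2] <- 1L; Tm[2, 1:2] <- 1L  # 4 px
  Pm <- matrix(0L, 3, 3); Pm[1, 1:2] <- 1L; Pm[3, 3] <- 1L    # 2 hits + 1 FP
  P <- binary_mask(Pm); T <- binary_mask(Tm)
  expect_equal(iou(P, T), 2 / 5)
  expect_equal(dice(P, T), 4 / 7)
  expect_equal(mae(P, T), 3 / 9)

  expect_equal(iou(T, T), 1)
  expect_equal(dice(T, T), 1)
  expect_equal(mae(T, T), 0)

  disj <- binary_mask({ m <- matrix(0L, 3, 3); m[3, 1] <- 1L; m })
  expect_equal(iou(disj, T), 0)

  # empty-empty convention: perfect prediction of absence
  e <- binary_mask(matrix(0L, 4, 4))
  expect_equal(iou(e, e), 1)
  expect_equal(dice(e, e), 1)
  expect_equal(mae(e, e), 0)
})

test_that("Dice is the exact algebraic transform of IoU", {
  for (seed in 1:50) {
    P <- random_binary(32, 32, p = runif(1, 0.1, 0.9), seed = seed)
    T <- random_binary(32, 32, p = runif(1, 0.1, 0.9), seed = seed + 500)
    i <- iou(P, T); d <- dice(P, T)
    expect_lt(abs(d - 2 * i / (1 + i)), 1e-12)
    expect_true(i >= 0 && i <= d && d <= 1)
    expect_equal(mae(P, T), 1 - mean(unclass(P) == unclass(T)))
  }
})

test_that("all five metrics match their brute-force oracles", {
  for (seed in 1:15) {
    h <- sample(8:24, 1); w <- sample(8:24, 1)
    P <- random_binary(h, w, p = runif(1, 0.05, 0.8), seed = seed)
    T <- random_blobby(h, w, n = sample(1:3, 1), seed = seed + 40)
    expect_identical(iou(P, T), oracle_iou(P, T))
    expect_identical(dice(P, T), oracle_dice(P, T))
    expect_identical(mae(P, T), oracle_mae(P, T))
    expect_lt(abs(weighted_fmeasure(P, T) - oracle_wfm(P, T)), 1e-9)
    expect_lt(abs(emeasure(P, T) - oracle_emeasure(P, T)), 1e-9)
  }
})

test_that("weighted F-measure rewards errors near the object", {
  Tm <- matrix(0L, 32, 32); Tm[9:12, 9:12] <- 1L
  T <- binary_mask(Tm)
  expect_equal(weighted_fmeasure(T, T), 1)

  # far-apart disjoint prediction scores ~0 (interior blocks, so the
  # Gaussian support fits and no border effect inflates the score)
  Pfar <- matrix(0L, 32, 32); Pfar[25:28, 25:28] <- 1L
  expect_lt(weighted_fmeasure(binary_mask(Pfar), T), 0.05)

  # a boundary-adjacent false positive costs less than a distant one
  Pnear <- Tm; Pnear[9, 13] <- 1L
  Pdist <- Tm; Pdist[28, 28] <- 1L
  expect_gt(weighted_fmeasure(binary_mask(Pnear), T),
            weighted_fmeasure(binary_mask(Pdist), T))

  # empty ground truth conventions
  e <- binary_mask(matrix(0L, 8, 8))
  ne <- binary_mask({ m <- matrix(0L, 8, 8); m[2, 2] <- 1L; m })
  expect_equal(weighted_fmeasure(e, e), 1)
  expect_equal(weighted_fmeasure(ne, e), 0)
})

test_that("E-measure behaves per the enhanced-alignment formulation", {
  Tm <- matrix(0L, 4, 4); Tm[, 1:2] <- 1L
  T <- binary_mask(Tm)
  expect_equal(emeasure(T, T), 1)
  comp <- binary_mask(1L - Tm)
  expect_lte(emeasure(comp, T), 0.25)

  # degenerate ground truths
  e <- binary_mask(matrix(0L, 4, 4)); f <- binary_mask(matrix(1L, 4, 4))
  expect_equal(emeasure(e, e), 1)
  expect_equal(emeasure(f, e), 0)
  expect_equal(emeasure(f, f), 1)
  expect_equal(emeasure(e, f), 0)

  # the perfect prediction is the global maximum (exhaustive 3x3 scan)
  T3 <- binary_mask(matrix(c(1L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L), 3, 3))
  best <- emeasure(T3, T3)
  for (idx in 0:511) {
    P3 <- binary_mask(matrix(as.integer(intToBits(idx)[1:9]), 3, 3))
    expect_lte(emeasure(P3, T3), best + 1e-12)
  }
})

test_that("metrics are invariant under simultaneous flips and transposition", {
  P <- random_binary(14, 20, p = 0.3, seed = 21)
  T <- random_blobby(14, 20, n = 2, seed = 22)
  metrics <- function(P, T) {
    c(iou(P, T), dice(P, T), mae(P, T), emeasure(P, T))
  }
  ref <- metrics(P, T)
  wref <- weighted_fmeasure(P, T)
  tr <- function(m) binary_mask(t(unclass(m)))
  fl <- function(m) binary_mask(unclass(m)[nrow(m):1, ])
  expect_equal(metrics(tr(P), tr(T)), ref, tolerance = 1e-12)
  expect_equal(metrics(fl(P), fl(T)), ref, tolerance = 1e-12)
  # the weighted F-measure is invariant only up to nearest-pixel tie-breaks
  # (the error propagated to the ground truth depends on which equidistant
  # pixel the distance transform selects, and that choice is orientation
  # dependent); tolerance covers the tie effect
  expect_equal(weighted_fmeasure(tr(P), tr(T)), wref, tolerance = 0.05)
  expect_equal(weighted_fmeasure(fl(P), fl(T)), wref, tolerance = 0.05)
})

test_that("metrics validate shapes", {
  a <- random_binary(4, 4); b <- random_binary(4, 5)
  for (f in list(iou, dice, mae, weighted_fmeasure, emeasure)) {
    expect_error(f(a, b), "shapes differ")
  }
})

test_that("evaluate_pairs aggregates with error accounting", {
  T1 <- random_blobby(16, 16, n = 2, seed = 1)
  P_good <- T1
  P_half <- binary_mask({ m <- unclass(T1); m[1:8, ] <- 0L; m })
  bad <- random_binary(4, 4)
  rep <- evaluate_pairs(list(
    list(P = P_good, T = T1, image_id = "a"),
    list(P = P_half, T = T1, image_id = "b"),
    list(P = bad, T = T1, image_id = "broken")
  ))
  expect_identical(rep$n_images, 2L)
  expect_identical(rep$n_errors, 1L)
  expect_identical(rep$errors$image_id, "broken")
  expect_equal(rep$aggregate[["iou"]],
               mean(c(iou(P_good, T1), iou(P_half, T1))))
  # aggregates are exactly the column means of the per-image table
  expect_equal(unname(rep$aggregate),
               unname(colMeans(rep$per_image[-1])))

  # single perfect pair: perfect aggregates
  solo <- evaluate_pairs(list(list(P = T1, T = T1, image_id = "x")))
  expect_equal(unname(solo$aggregate),
               c(1, 1, 0, 1, 1))
  expect_error(evaluate_pairs(list()), "no pairs")
})

test_that("metric reports serialize to CSV with an aggregate footer", {
  T1 <- random_blobby(12, 12, n = 1, seed = 2)
  P1 <- random_binary(12, 12, p = 0.4, seed = 3)
  rep <- evaluate_pairs(list(list(P = P1, T = T1, image_id = "img1"),
                             list(P = T1, T = T1, image_id = "img2")))
  tmp <- withr::local_tempdir()
  csv <- file.path(tmp, "report.csv")
  write_metric_report(rep, csv, json_path = file.path(tmp, "report.json"))
  tab <- read.csv(csv)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$image_id[3], "aggregate")
  expect_equal(tab$iou[3], rep$aggregate[["iou"]])
  js <- jsonlite::fromJSON(file.path(tmp, "report.json"))
  expect_equal(js$aggregate$dice, rep$aggregate[["dice"]])
})
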