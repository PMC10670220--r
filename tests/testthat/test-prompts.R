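blob_of <- function(m) label_blobs(binary_mask(m))[[1]]

test_that("method A returns the bounding-box center", {
  sq <- matrix(0L, 5, 5); sq[1:3, 1:3] <- 1L
  cp <- method_a(blob_of(sq))
  expect_identical(c(cp$row, cp$col), c(1L, 1L))

  # single pixel: degenerate bbox
  px <- matrix(0L, 10, 10); px[8, 4] <- 1L
  cp <- method_a(blob_of(px))
  expect_identical(c(cp$row, cp$col), c(7L, 3L))

  # hollow ring spanning rows/cols 0-9: center (5,5) falls off-blob
  ring <- matrix(0L, 12, 12); ring[1:10, 1:10] <- 1L; ring[3:8, 3:8] <- 0L
  blob <- blob_of(ring)
  cp <- method_a(blob)
  expect_identical(c(cp$row, cp$col), c(5L, 5L))
  expect_false(any(blob$pixels[, "row"] == cp$row &
                     blob$pixels[, "col"] == cp$col))
})

test_that("method B snaps the centroid into the blob", {
  plus <- matrix(0L, 4, 4)
  plus[cbind(c(1, 2, 2, 2, 3), c(2, 1, 2, 3, 2))] <- 1L
  cp <- method_b(blob_of(plus))
  expect_identical(c(cp$row, cp$col), c(1L, 1L))

  px <- matrix(0L, 10, 10); px[8, 4] <- 1L
  cp <- method_b(blob_of(px))
  expect_identical(c(cp$row, cp$col), c(7L, 3L))

  # ring: centroid is hollow; checkpoint must be a blob pixel at minimal
  # distance from the true centroid (brute-force nearest scan)
  ring <- matrix(0L, 12, 12); ring[1:10, 1:10] <- 1L; ring[3:8, 3:8] <- 0L
  blob <- blob_of(ring)
  cp <- method_b(blob)
  expect_true(any(blob$pixels[, "row"] == cp$row &
                    blob$pixels[, "col"] == cp$col))
  d2 <- (blob$pixels[, "row"] - blob$centroid[["row"]])^2 +
    (blob$pixels[, "col"] - blob$centroid[["col"]])^2
  got <- (cp$row - blob$centroid[["row"]])^2 +
    (cp$col - blob$centroid[["col"]])^2
  expect_equal(got, min(d2))
})

test_that("method C draws a seeded uniform blob pixel", {
  px <- matrix(0L, 10, 10); px[8, 4] <- 1L
  cp <- method_c(blob_of(px), rng_seed = 99)
  expect_identical(c(cp$row, cp$col), c(7L, 3L))

  blob <- blob_of(unclass(random_blobby(20, 20, n = 1, seed = 5)))
  for (seed in 1:10) {
    cp <- method_c(blob, rng_seed = seed)
    expect_true(any(blob$pixels[, "row"] == cp$row &
                      blob$pixels[, "col"] == cp$col))
    expect_identical(method_c(blob, rng_seed = seed), cp)  # determinism
  }

  # uniformity on a 2-pixel blob: binomial 5-sigma band around 0.5
  two <- matrix(0L, 3, 3); two[1, 1] <- 1L; two[1, 2] <- 1L
  blob2 <- blob_of(two)
  n <- 10000L
  hits <- sum(vapply(seq_len(n), function(s) {
    method_c(blob2, rng_seed = s)$col == 0L
  }, logical(1)))
  expect_lt(abs(hits / n - 0.5), 5 * sqrt(0.25 / n))
})

test_that("method D lays the origin-anchored lattice over blobs", {
  rect <- binary_mask(matrix(1L, 100, 100))
  cp <- method_d(rect, prompt_config("D", b = 50))
  expect_identical(nrow(cp), 4L)
  expect_identical(cp$row, c(0L, 0L, 50L, 50L))
  expect_identical(cp$col, c(0L, 50L, 0L, 50L))

  # unit lattice covers every foreground pixel
  m <- random_binary(15, 15, p = 0.3, seed = 2)
  cp1 <- method_d(m, prompt_config("D", b = 1))
  expect_identical(nrow(cp1), sum(unclass(m)))
})

test_that("method D fallback rescues blobs the lattice misses", {
  m <- matrix(0L, 100, 100); m[8, 8] <- 1L  # pixel (7,7), off-lattice for b=50
  cp <- method_d(binary_mask(m), prompt_config("D", b = 50))
  expect_identical(nrow(cp), 1L)
  expect_identical(c(cp$row, cp$col), c(7L, 7L))
})

test_that("method D equals the exhaustive lattice-and-offset oracle", {
  for (seed in 1:10) {
    mask <- random_binary(40, 40, p = 0.2, seed = seed)
    for (b in c(2L, 5L, 7L)) {
      got <- method_d(mask, prompt_config("D", b = b))
      want <- oracle_method_d(mask, b)
      expect_identical(got[c("row", "col")],
                       want, label = sprintf("seed %d b %d", seed, b))
      # every blob contributes at least one checkpoint
      expect_setequal(unique(got$blob_id),
                      seq_along(label_blobs(mask)))
    }
  }
})

test_that("border mode keeps prompts off blob boundaries and rescues small blobs", {
  m <- matrix(0L, 50, 50)
  m[11:40, 11:40] <- 1L  # big blob survives erosion
  m[3:4, 3:4] <- 1L      # small blob vanishes under the 10x10 kernel
  mask <- binary_mask(m)
  cfg <- prompt_config("D", b = 5, border_mode = TRUE)
  cp <- method_d(mask, cfg)
  big <- cp[cp$row >= 10 & cp$col >= 10, ]
  expect_gt(nrow(big), 0L)
  for (i in seq_len(nrow(big))) {
    r <- big$row[i] + 1L; cc <- big$col[i] + 1L
    nb <- m[max(1, r - 1):min(50, r + 1), max(1, cc - 1):min(50, cc + 1)]
    expect_true(all(nb == 1L))  # >= 1 px from the un-eroded boundary
  }
  # rescued blob still prompts
  expect_true(any(cp$row <= 3 & cp$col <= 3))
  # without rescue the small blob is lost
  cfg2 <- prompt_config("D", b = 5, border_mode = TRUE,
                        rescue_on_empty_erosion = FALSE)
  cp2 <- method_d(mask, cfg2)
  expect_false(any(cp2$row <= 3 & cp2$col <= 3))
})

test_that("extract_prompts dispatches per method with one point per blob", {
  empty <- binary_mask(matrix(0L, 10, 10))
  for (meth in c("A", "B", "C", "D")) {
    ps <- extract_prompts(empty, prompt_config(meth, b = 3))
    expect_identical(nrow(ps$checkpoints), 0L)
  }
  m <- matrix(0L, 30, 30)
  m[2:5, 2:5] <- 1L; m[2:5, 20:23] <- 1L; m[20:23, 10:13] <- 1L
  mask <- binary_mask(m)
  for (meth in c("A", "B", "C")) {
    ps <- extract_prompts(mask, prompt_config(meth))
    expect_identical(nrow(ps$checkpoints), 3L)
    expect_setequal(ps$checkpoints$blob_id, 1:3)
    expect_true(all(ps$checkpoints$method == meth))
  }
  psd <- extract_prompts(mask, prompt_config("D", b = 50))
  expect_gte(nrow(psd$checkpoints), 3L)
})

test_that("prompt sets serialize deterministically and round-trip", {
  mask <- random_blobby(40, 40, n = 3, seed = 9)
  ps <- extract_prompts(mask, prompt_config("D", b = 6))
  tmp <- withr::local_tempdir()
  p1 <- file.path(tmp, "a.json"); p2 <- file.path(tmp, "b.json")
  write_prompts(ps, p1)
  write_prompts(extract_prompts(mask, prompt_config("D", b = 6)), p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical
  back <- read_prompts(p1)
  expect_identical(back$checkpoints, ps$checkpoints)
  expect_identical(back$config$method, "D")
  expect_identical(back$config$b, 6L)
})

test_that("prompt_config validates its arguments", {
  expect_error(prompt_config("D", b = 0), "b must be")
  expect_error(prompt_config("Z"), "arg")
})
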