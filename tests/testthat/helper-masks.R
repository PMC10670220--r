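# Random mask generators used across the suite. All seeded explicitly so
# failures are reproducible.

random_binary <- function(h, w, p = 0.4, seed = 1) {
  set.seed(seed)
  binary_mask(matrix(as.integer(runif(h * w) < p), h, w))
}

# random mask made of a few blobs rather than iid noise: closer to real
# segmentation masks and exercises multi-pixel components
random_blobby <- function(h, w, n = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, h, w)
  for (i in seq_len(n)) {
    r <- sample(2:max(2, min(h, w) %/% 6), 1)
    cr <- sample(seq_len(h), 1); cc <- sample(seq_len(w), 1)
    rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    m[(rows - cr)^2 + (cols - cc)^2 <= r^2] <- 1L
  }
  binary_mask(m)
}

random_scores <- function(h, w, seed = 1, polarity = "foreground_high") {
  set.seed(seed)
  score_mask(matrix(sample(0:255, h * w, replace = TRUE), h, w), polarity)
}

as_scores <- function(bin, polarity = "foreground_high") {
  score_mask(matrix(unclass(bin) * 255L, nrow(bin), ncol(bin)), polarity)
}

# strip class and polarity, keep dim: for comparing against plain matrices
bare <- function(m) matrix(as.integer(m), nrow(m), ncol(m))
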