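# Independent brute-force oracles. Each re-derives a quantity from first
# principles with a different algorithm than the package implementation:
# flood fill instead of label propagation, per-pixel scans instead of
# vectorized shifts, explicit set arithmetic instead of matrix logic.

# --- connected components: queue-based flood fill -------------------------
oracle_label <- function(mask) {
  m <- unclass(mask)
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (m[i, j] == 1L && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue) > 0L) {
        p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ni <- p[1] + di; nj <- p[2] + dj
          if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
              m[ni, nj] == 1L && lab[ni, nj] == 0L) {
            lab[ni, nj] <- cur
            queue[[length(queue) + 1L]] <- c(ni, nj)
          }
        }
      }
    }
  }
  lab
}

# --- erosion: literal "kernel fits" scan ----------------------------------
oracle_erode <- function(mask, kernel, anchor = NULL) {
  m <- unclass(mask)
  h <- nrow(m); w <- ncol(m)
  if (is.null(anchor)) {
    anchor <- c(ceiling(nrow(kernel) / 2) - 1L, ceiling(ncol(kernel) / 2) - 1L)
  }
  offs <- which(kernel, arr.ind = TRUE) - 1L
  out <- matrix(0L, h, w)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    fits <- TRUE
    for (k in seq_len(nrow(offs))) {
      ri <- i + offs[k, 1] - anchor[1]
      cj <- j + offs[k, 2] - anchor[2]
      if (ri < 1 || ri > h || cj < 1 || cj > w || m[ri, cj] != 1L) {
        fits <- FALSE; break
      }
    }
    if (fits) out[i, j] <- 1L
  }
  binary_mask(out)
}

# --- method D: residue arithmetic on flood-fill blob pixel sets -----------
# A lattice of period b shifted by (dy, dx) meets exactly the pixels with
# row %% b == dy and col %% b == dx.
oracle_method_d <- function(mask, b) {
  lab <- oracle_label(mask)
  out <- NULL
  for (id in seq_len(max(lab, 0L))) {
    idx <- which(lab == id)
    r0 <- (idx - 1L) %% nrow(lab); c0 <- (idx - 1L) %/% nrow(lab)
    hits <- r0 %% b == 0L & c0 %% b == 0L
    if (!any(hits)) {
      offsets <- list()
      if (b > 1L) {
        for (dx in 1:(b - 1L)) offsets[[length(offsets) + 1L]] <- c(0L, dx)
        for (dy in 1:(b - 1L)) for (dx in 0:(b - 1L)) {
          offsets[[length(offsets) + 1L]] <- c(dy, dx)
        }
      }
      for (off in offsets) {
        hits <- r0 %% b == off[1] & c0 %% b == off[2]
        if (any(hits)) break
      }
    }
    if (any(hits)) out <- rbind(out, cbind(r0[hits], c0[hits], id))
  }
  if (is.null(out)) return(data.frame(row = integer(), col = integer()))
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  data.frame(row = out[, 1], col = out[, 2])
}

# --- metrics ----------------------------------------------------------------
oracle_iou <- function(P, T) {
  p <- which(unclass(P) == 1L); t <- which(unclass(T) == 1L)
  u <- length(union(p, t))
  if (u == 0L) 1 else length(intersect(p, t)) / u
}

oracle_dice <- function(P, T) {
  p <- which(unclass(P) == 1L); t <- which(unclass(T) == 1L)
  if (length(p) + length(t) == 0L) 1 else
    2 * length(intersect(p, t)) / (length(p) + length(t))
}

oracle_mae <- function(P, T) {
  sum(unclass(P) != unclass(T)) / length(unclass(P))
}

# weighted F-measure: same formulation, per-pixel re-derivation.
# Ties in the nearest-ground-truth search go to the smallest column-major
# linear index (the stated convention of the metric).
oracle_wfm <- function(P, T) {
  gt <- unclass(T) == 1L
  pd <- unclass(P)
  h <- nrow(gt); w <- ncol(gt)
  if (!any(gt)) return(if (any(pd == 1L)) 0 else 1)
  eps <- .Machine$double.eps
  E <- abs(pd - unclass(T))
  fg_idx <- which(gt)
  fr <- (fg_idx - 1L) %% h; fc <- (fg_idx - 1L) %/% h
  Et <- E; D <- matrix(0, h, w)
  for (q in which(!gt)) {
    qr <- (q - 1L) %% h; qc <- (q - 1L) %/% h
    d2 <- (fr - qr)^2 + (fc - qc)^2
    k <- which.min(d2)  # fg_idx ascending => first minimum = smallest index
    D[q] <- sqrt(d2[k])
    Et[q] <- E[fg_idx[k]]
  }
  half <- 3L
  x <- seq(-half, half)
  K <- outer(exp(-x^2 / 50), exp(-x^2 / 50)); K <- K / sum(K)
  EA <- matrix(0, h, w)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    acc <- 0
    for (dj in -half:half) for (di in -half:half) {
      ri <- i + di; cj <- j + dj
      if (ri >= 1 && ri <= h && cj >= 1 && cj <= w) {
        acc <- acc + K[di + half + 1L, dj + half + 1L] * Et[ri, cj]
      }
    }
    EA[i, j] <- acc
  }
  MIN_E_EA <- E
  MIN_E_EA[gt & EA < E] <- EA[gt & EA < E]
  B <- ifelse(gt, 1, 2 - exp(log(0.5) / 5 * D))
  Ew <- MIN_E_EA * B
  TPw <- sum(gt) - sum(Ew[gt])
  FPw <- sum(Ew[!gt])
  R <- 1 - mean(Ew[gt])
  Pw <- TPw / (eps + TPw + FPw)
  max(0, min(1, 2 * R * Pw / (eps + R + Pw)))
}

# enhanced-alignment measure, explicit per-pixel loop
oracle_emeasure <- function(P, T) {
  p <- as.numeric(unclass(P)); t <- as.numeric(unclass(T))
  n <- length(t)
  if (sum(t) == 0) return(mean(1 - p))
  if (sum(t) == n) return(mean(p))
  mp <- sum(p) / n; mt <- sum(t) / n
  acc <- 0
  for (i in seq_len(n)) {
    gc <- t[i] - mt; pc <- p[i] - mp
    align <- 2 * gc * pc / (gc^2 + pc^2)
    acc <- acc + (align + 1)^2 / 4
  }
  acc / n
}

# fusion: per-pixel evaluation of the weighted-average formula
oracle_fuse <- function(seg, zs, wseg, wzs, threshold) {
  s <- unclass(if (mask_polarity(seg) == "foreground_low") invert(seg) else seg)
  z <- unclass(if (mask_polarity(zs) == "foreground_low") invert(zs) else zs)
  h <- nrow(s); w <- ncol(s)
  fs <- matrix(0L, h, w); fb <- matrix(0L, h, w)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    v <- (wseg * s[i, j] + wzs * z[i, j]) / (wseg + wzs)
    v <- sign(v) * floor(abs(v) + 0.5)
    fs[i, j] <- v
    fb[i, j] <- as.integer(v >= threshold)
  }
  list(score = fs, binary = fb)
}
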