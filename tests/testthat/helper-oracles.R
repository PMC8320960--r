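# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately use naive double-loop formulations, not the package's
# vectorised implementations.

# erosion oracle: pixel survives iff the full window (positioned by anchor)
# is inside the mask
oracle_erode <- function(mask, size, anchor = "center") {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (anchor == "center") {
    h <- (size - 1) %/% 2
    expand.grid(dr = -h:h, dc = -h:h)
  } else expand.grid(dr = 0:(size - 1), dc = 0:(size - 1))
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ok <- TRUE
    for (k in seq_len(nrow(offs))) {
      r <- i + offs$dr[k]; c <- j + offs$dc[k]
      if (r < 1 || r > nr || c < 1 || c > nc || !mask[r, c]) { ok <- FALSE; break }
    }
    out[i, j] <- ok
  }
  out
}

# direct double-loop convolution with symmetric (edge-reflect) padding
oracle_conv_sym <- function(x, kernel) {
  nr <- nrow(x); nc <- ncol(x)
  kh <- (nrow(kernel) - 1) %/% 2; kw <- (ncol(kernel) - 1) %/% 2
  reflect <- function(i, n) { if (i < 1) 1 - i else if (i > n) 2 * n + 1 - i else i }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in -kh:kh) for (b in -kw:kw) {
      acc <- acc + kernel[a + kh + 1, b + kw + 1] *
        x[reflect(i + a, nr), reflect(j + b, nc)]
    }
    out[i, j] <- acc
  }
  out
}

# top-m selection oracle by explicit sort of positive values
oracle_top_fraction <- function(diff, fraction) {
  v <- as.numeric(t(diff))
  pos <- which(v > 0)
  if (!length(pos)) return(matrix(FALSE, nrow(diff), ncol(diff)))
  m <- ceiling(fraction * length(pos))
  ord <- pos[order(v[pos], decreasing = TRUE)]
  sel <- ord[seq_len(m)]
  out <- matrix(FALSE, nrow(diff), ncol(diff))
  for (s in sel) out[(s - 1) %/% ncol(diff) + 1, (s - 1) %% ncol(diff) + 1] <- TRUE
  out
}

# GLCM contrast oracle: explicit pair counting over the four distance-1
# offsets, symmetric, normalised per offset, averaged
oracle_glcm_contrast <- function(q) {
  offsets <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  total <- 0
  for (off in offsets) {
    s <- 0; n <- 0
    for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
      r <- i + off[1]; c <- j + off[2]
      if (r >= 1 && r <= nrow(q) && c >= 1 && c <= ncol(q)) {
        s <- s + 2 * (q[i, j] - q[r, c])^2   # symmetric pair both ways
        n <- n + 2
      }
    }
    total <- total + s / n
  }
  total / length(offsets)
}

# AUC oracle: concordant-pair counting with half credit for ties
oracle_auc <- function(scores, pos) {
  ps <- scores[pos]; ns <- scores[!pos]
  tot <- 0
  for (a in ps) for (b in ns) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ps) * length(ns))
}

# exhaustive CFS subset search for small feature counts
oracle_exhaustive_cfs <- function(tables) {
  p <- length(tables$r_cf)
  best <- 0
  for (m in seq_len(2^p - 1)) {
    s <- which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
    mm <- cfs_merit(s, tables)
    if (mm > best + 1e-12) best <- mm
  }
  best
}

random_cor_tables <- function(p) {
  A <- matrix(stats::runif(p * p, -1, 1), p, p)
  R <- abs(stats::cov2cor(crossprod(A) + diag(p) * 0.5))
  structure(list(r_cf = stats::runif(p), r_ff = R,
                 names = paste0("f", seq_len(p))),
            class = "correlation_tables")
}

# flat-background patch with one centred disk blob
disk_patch <- function(n = 64, radius = 6, bg = 100, contrast = 80,
                       centre = c(n, n) / 2) {
  px <- matrix(bg, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if ((i - centre[1])^2 + (j - centre[2])^2 <= radius^2)
      px[i, j] <- bg + contrast
  }
  image_patch(px, 70, 12, "disk")
}

disk_mask <- function(n, radius, centre = c(n, n) / 2) {
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - centre[1])^2 + (j - centre[2])^2 <= radius^2) m[i, j] <- TRUE
  m
}

patch_from <- function(px, spacing = 70) {
  depth <- if (max(px) <= 255) 8L else if (max(px) <= 4095) 12L else 16L
  image_patch(px, spacing, depth, "t")
}
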