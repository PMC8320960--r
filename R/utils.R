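# Internal numeric helpers shared across the pipeline.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shift a matrix by (dr, dc), filling vacated cells
#'
#' Used by the shift-accumulate convolution and the morphological operators.
#' @keywords internal
shift_matrix <- function(x, dr, dc, fill = 0) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- x[src_r[ok_r], src_c[ok_c]]
  out
}

#' Pad a matrix by edge reflection (half-sample symmetric)
#' @keywords internal
pad_symmetric <- function(x, n) {
  if (n == 0L) return(x)
  nr <- nrow(x); nc <- ncol(x)
  if (n > nr || n > nc) stop("padding exceeds matrix size", call. = FALSE)
  ri <- c(rev(seq_len(n)), seq_len(nr), nr - seq_len(n) + 1L)
  ci <- c(rev(seq_len(n)), seq_len(nc), nc - seq_len(n) + 1L)
  x[ri, ci]
}

#' 2-D convolution with an odd-sized kernel and symmetric boundary handling
#'
#' Implemented by shift-accumulate: the output is the weighted sum of shifted
#' copies of the symmetrically padded input, which keeps the operation exact
#' and dependency-free for the small kernels used here.
#' @keywords internal
conv2_sym <- function(x, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  pad <- max((kr - 1L) %/% 2L, (kc - 1L) %/% 2L)
  xp <- pad_symmetric(x, pad)
  out <- matrix(0, nrow(xp), ncol(xp))
  cr <- (kr + 1L) %/% 2L
  cc <- (kc + 1L) %/% 2L
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- kernel[i, j]
      if (w != 0) out <- out + w * shift_matrix(xp, cr - i, cc - j)
    }
  }
  out[pad + seq_len(nrow(x)), pad + seq_len(ncol(x)), drop = FALSE]
}

#' Separable natural-cubic-spline surface through a coarse grid
#'
#' Interpolates values sampled at (`row_at`, `col_at`) onto the full pixel
#' grid `rows` x `cols`.  Linear extrapolation beyond the outermost samples
#' (the natural-spline boundary condition).
#' @keywords internal
spline_resize <- function(coarse, row_at, col_at, rows, cols) {
  stopifnot(nrow(coarse) == length(row_at), ncol(coarse) == length(col_at))
  interp1 <- function(at, v, out_at) {
    if (length(at) == 1L) return(rep(v, length(out_at)))
    if (length(at) == 2L) {  # spline needs >= 3 points; fall back to linear
      slope <- (v[2] - v[1]) / (at[2] - at[1])
      return(v[1] + (out_at - at[1]) * slope)
    }
    stats::splinefun(at, v, method = "natural")(out_at)
  }
  # interpolate along columns first, then along rows
  tmp <- t(apply(coarse, 1L, function(v) interp1(col_at, v, seq_len(cols))))
  if (length(col_at) == 1L) tmp <- matrix(tmp, nrow = nrow(coarse), ncol = cols)
  apply(tmp, 2L, function(v) interp1(row_at, v, seq_len(rows)))
}

#' Restore the RNG state on exit and evaluate with a local seed
#' @keywords internal
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-item seed from a master seed (counter scheme)
#'
#' Deterministic, collision-sparse and independent of how many items were
#' generated before, so datasets can be extended without reshuffling.
#' @keywords internal
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 10007 + as.numeric(index) * 7919) %% 2147483562) + 1L
}
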