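# MC candidate segmentation: from an (enhanced) patch to the binary MC
# probability image (Image C).
#
# Chain: estimate the local tissue background on a coarse subregion grid,
# subtract it, keep the brightest fraction of positive differences, clean
# up (single-pixel removal + 3x3 erosion) and, for low-contrast patches,
# relax the threshold (Image A).  In parallel, a 9x9 zero-sum
# contrast-enhancement kernel is applied and the brightest fraction of its
# response kept (Image B).  Image C is the pixelwise AND of A and B.

#' Estimate the local background surface of a patch
#'
#' The patch is tiled into `subregion_px` x `subregion_px` subregions (the
#' last row/column truncated at the image border), each summarised by its
#' median — robust against the bright calcifications the surface must not
#' absorb — and the coarse grid of medians is interpolated back to full
#' resolution with a separable natural cubic (bicubic) spline.
#'
#' @param patch An [image_patch()] or numeric matrix.
#' @param subregion_px Subregion side in pixels (default 30).
#' @return An object of class `background_model` with fields `surface`
#'   (matrix, same shape as the patch) and `subregion_px`.
#' @export
estimate_background <- function(patch, subregion_px = 30L) {
  x <- if (inherits(patch, "image_patch")) patch$pixels else as.matrix(patch)
  nr <- nrow(x); nc <- ncol(x)
  if (min(nr, nc) < subregion_px)
    stop("subregion_px larger than the image", call. = FALSE)
  r_breaks <- seq(1L, nr, by = subregion_px)
  c_breaks <- seq(1L, nc, by = subregion_px)
  r_id <- findInterval(seq_len(nr), r_breaks)
  c_id <- findInterval(seq_len(nc), c_breaks)
  coarse <- matrix(0, length(r_breaks), length(c_breaks))
  row_at <- numeric(length(r_breaks)); col_at <- numeric(length(c_breaks))
  for (i in seq_along(r_breaks)) row_at[i] <- mean(which(r_id == i))
  for (j in seq_along(c_breaks)) col_at[j] <- mean(which(c_id == j))
  for (i in seq_along(r_breaks)) {
    ri <- which(r_id == i)
    for (j in seq_along(c_breaks)) {
      coarse[i, j] <- stats::median(x[ri, which(c_id == j)])
    }
  }
  surface <- spline_resize(coarse, row_at, col_at, nr, nc)
  structure(list(surface = surface, subregion_px = as.integer(subregion_px)),
            class = "background_model")
}

#' Difference image: patch minus background surface
#'
#' @param patch An [image_patch()] or matrix.
#' @param background A `background_model` (or matrix).
#' @return Numeric matrix of signed differences with (initially unset)
#'   attribute `threshold_t`.
#' @export
difference_image <- function(patch, background) {
  x <- if (inherits(patch, "image_patch")) patch$pixels else as.matrix(patch)
  s <- if (inherits(background, "background_model")) background$surface else as.matrix(background)
  if (!all(dim(x) == dim(s))) stop("shape mismatch", call. = FALSE)
  d <- x - s
  attr(d, "threshold_t") <- NA_real_
  d
}

#' Select the brightest fraction of positive difference pixels
#'
#' Among strictly positive difference pixels, the `ceiling(fraction * n)`
#' largest are set true.  The smallest selected value is recorded as the
#' threshold (attribute `threshold_t` on the result and, by convention,
#' carried forward to the fallback step).  Ties at the cutoff are broken by
#' raster (row-major) order for determinism.
#'
#' @param diff Difference image matrix.
#' @param fraction Fraction in (0, 1] (default 0.05).
#' @return Logical mask with attribute `threshold_t` (NA when no positive
#'   pixel exists, in which case the mask is empty).
#' @export
select_top_fraction <- function(diff, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  v <- as.numeric(t(diff))           # raster (row-major) order
  pos <- which(v > 0)
  mask <- matrix(FALSE, nrow(diff), ncol(diff))
  if (length(pos) == 0L) {
    attr(mask, "threshold_t") <- NA_real_
    return(mask)
  }
  m <- ceiling(fraction * length(pos))
  sel <- pos[order(-v[pos])[seq_len(m)]]   # order() is stable: raster ties
  thr <- min(v[sel])
  idx_row <- (sel - 1L) %/% ncol(diff) + 1L
  idx_col <- (sel - 1L) %% ncol(diff) + 1L
  mask[cbind(idx_row, idx_col)] <- TRUE
  attr(mask, "threshold_t") <- thr
  mask
}

#' Binary erosion with an all-ones structuring element
#'
#' A pixel survives iff every pixel of the window positioned by `anchor`
#' lies inside the mask; out-of-bounds counts as background.
#'
#' @param mask Logical matrix.
#' @param size Window side length.
#' @param anchor `"center"` (odd sizes) or `"topleft"` (the convention used
#'   for the even 2x2 element of the cluster-rule stage).
#' @return Eroded logical mask.
#' @export
erode_mask <- function(mask, size = 3L, anchor = c("center", "topleft")) {
  anchor <- match.arg(anchor)
  offs <- if (anchor == "center") {
    stopifnot(size %% 2L == 1L)
    h <- (size - 1L) %/% 2L
    expand.grid(dr = -h:h, dc = -h:h)
  } else {
    expand.grid(dr = 0:(size - 1L), dc = 0:(size - 1L))
  }
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs))) {
    out <- out & shift_matrix(mask, -offs$dr[k], -offs$dc[k], fill = FALSE)
  }
  out
}

#' Remove isolated pixels and erode (cleanup of the thresholded mask)
#'
#' Isolated single pixels (8-connected components of size 1) are removed,
#' then a binary erosion with a 3x3 all-ones structuring element (centre
#' origin) is applied.  The output never contains a pixel absent from the
#' input.
#'
#' @param mask Logical mask (threshold attribute, if any, is preserved).
#' @return Cleaned logical mask.
#' @export
cleanup_mask <- function(mask) {
  thr <- attr(mask, "threshold_t")
  # a pixel is isolated iff none of its 8 neighbours is true
  nb <- matrix(0L, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- nb + shift_matrix(mask, dr, dc, fill = FALSE)
  }
  kept <- mask & nb > 0L
  out <- erode_mask(kept, 3L, "center")
  attr(out, "threshold_t") <- thr
  out
}

#' Low-contrast fallback producing Image A
#'
#' If the cleaned mask covers fewer than `min_fraction` of the patch
#' pixels, pixels of the difference image exceeding half the recorded
#' selection threshold are added; otherwise the mask is returned unchanged.
#'
#' @param mask Cleaned logical mask carrying attribute `threshold_t`.
#' @param diff Difference image the threshold was defined on.
#' @param min_fraction Coverage below which the fallback fires (default 0.10).
#' @return Image A as a logical mask.
#' @export
low_contrast_fallback <- function(mask, diff, min_fraction = 0.10) {
  thr <- attr(mask, "threshold_t")
  if (sum(mask) >= min_fraction * length(mask)) return(mask)
  if (is.null(thr) || is.na(thr)) {
    warning("selection threshold undefined; fallback skipped")
    return(mask)
  }
  out <- mask | (diff > thr / 2)
  attr(out, "threshold_t") <- thr
  out
}

#' 9x9 zero-sum contrast-enhancement filter
#'
#' Convolution with the 9x9 kernel whose centre is 80 and whose 80
#' off-centre entries are -1 (zero-sum high-pass), with symmetric boundary
#' handling.  Accepts a plain matrix, an [image_patch()] or a
#' `background_model`.
#'
#' @param x Input grid.
#' @return Filtered numeric matrix, same shape.
#' @export
highpass_filter <- function(x) {
  g <- if (inherits(x, "image_patch")) x$pixels
       else if (inherits(x, "background_model")) x$surface
       else as.matrix(x)
  if (min(dim(g)) < 9L) stop("input smaller than the 9x9 kernel", call. = FALSE)
  k <- matrix(-1, 9L, 9L); k[5L, 5L] <- 80
  conv2_sym(g, k)
}

#' Image B: brightest fraction of the filtered grid
#'
#' The `ceiling(fraction * N)` highest-valued pixels of the whole filtered
#' grid are set true (raster-order tie-break).
#'
#' @param filtered Filtered numeric matrix.
#' @param fraction Fraction in (0, 1] (default 0.05).
#' @return Logical mask.
#' @export
image_b <- function(filtered, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  v <- as.numeric(t(filtered))
  m <- ceiling(fraction * length(v))
  sel <- order(-v)[seq_len(m)]
  mask <- matrix(FALSE, nrow(filtered), ncol(filtered))
  mask[cbind((sel - 1L) %/% ncol(filtered) + 1L, (sel - 1L) %% ncol(filtered) + 1L)] <- TRUE
  mask
}

#' Pixelwise AND of two binary masks (Image C)
#'
#' @param a,b Logical masks of identical shape.
#' @return Logical mask.
#' @export
combine_masks <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  unname(a & b)
}

#' MC probability image of a patch (Images A, B and C)
#'
#' Runs the full candidate-segmentation chain.  The contrast-enhancement
#' kernel is applied to the patch itself — i.e. to its bicubic resampling
#' at native resolution — so that Image B retains calcification detail and
#' the conjunction with Image A is non-destructive (see the methods
#' vignette for the rationale).
#'
#' @param patch An [image_patch()] (typically the enhanced patch).
#' @param subregion_px Background subregion side (default 30).
#' @param fraction Top-fraction for Images A and B (default 0.05).
#' @param fallback_fraction Minimum Image-A coverage before the
#'   low-contrast fallback fires (default 0.10).
#' @return List with `image_a`, `image_b`, `image_c` (logical masks),
#'   `background` (`background_model`), `diff` and `threshold_t`.
#' @export
mc_probability_image <- function(patch, subregion_px = 30L, fraction = 0.05,
                                 fallback_fraction = 0.10) {
  bg <- estimate_background(patch, subregion_px)
  d <- difference_image(patch, bg)
  a0 <- select_top_fraction(d, fraction)
  a1 <- cleanup_mask(a0)
  a <- low_contrast_fallback(a1, d, fallback_fraction)
  b <- image_b(highpass_filter(patch), fraction)
  cc <- combine_masks(a, b)
  list(image_a = a, image_b = b, image_c = cc, background = bg, diff = d,
       threshold_t = attr(a0, "threshold_t"))
}
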