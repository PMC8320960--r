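# Dice-based evaluation of a segmentation against a radiologist reference
# outline: rasterise the outline, take the convex hull of segmented MCs
# inside it, and score the overlap.

#' Rasterise a closed polygon into a binary mask
#'
#' Pixel centres inside or on the polygon boundary are set true.
#'
#' @param vertices n x 2 matrix of `(row, col)` vertices (0-based).
#' @param shape `(rows, cols)` of the target mask.
#' @return Logical mask.
#' @export
fill_polygon <- function(vertices, shape) {
  uv <- unique(round(vertices, 8))
  if (nrow(uv) < 3L) stop("degenerate polygon (< 3 distinct vertices)", call. = FALSE)
  nr <- shape[1]; nc <- shape[2]
  px_row <- rep(seq_len(nr) - 1L, times = nc)
  px_col <- rep(seq_len(nc) - 1L, each = nr)
  inside <- pracma::inpolygon(px_col, px_row, vertices[, 2], vertices[, 1],
                              boundary = TRUE)
  matrix(inside, nr, nc)
}

#' Reference mask from a radiologist annotation outline
#'
#' @param outline n x 2 matrix of `(row, col)` vertices.
#' @param shape `(rows, cols)` of the patch.
#' @return Logical mask of the filled outline (boundary included).
#' @export
reference_mask <- function(outline, shape) {
  fill_polygon(outline, shape)
}

#' Convex hull of the segmented MCs inside a reference mask
#'
#' Blobs of `seg` whose centroid lies inside `ref` contribute all their
#' pixels; the filled convex hull of those pixels is returned (empty when
#' no blob qualifies; the pixels themselves when they span fewer than
#' three non-collinear points).
#'
#' @param seg Segmentation mask.
#' @param ref Reference mask of identical shape.
#' @return Logical mask of the filled hull.
#' @export
hull_mask <- function(seg, ref) {
  if (!all(dim(seg) == dim(ref))) stop("shape mismatch", call. = FALSE)
  bl <- label_blobs(seg)
  out <- matrix(FALSE, nrow(seg), ncol(seg))
  if (!length(bl$blobs)) return(out)
  keep <- vapply(bl$blobs, function(b) {
    r <- min(max(round(b$centroid["row"]) + 1, 1), nrow(ref))
    c <- min(max(round(b$centroid["col"]) + 1, 1), ncol(ref))
    ref[r, c]
  }, logical(1))
  if (!any(keep)) return(out)
  pts <- do.call(rbind, lapply(bl$blobs[keep], function(b) b$pixels))
  return(convex_hull_mask(pts, dim(seg)))
}

# Filled convex hull of 1-based pixel coordinates; handles degenerate
# (collinear / tiny) point sets by returning the points themselves.
convex_hull_mask <- function(pixels, shape) {
  out <- matrix(FALSE, shape[1], shape[2])
  pts <- unique(pixels[, c(1, 2), drop = FALSE])
  if (nrow(pts) < 3L) { out[pts] <- TRUE; return(out) }
  h <- grDevices::chull(pts[, 2], pts[, 1])   # (x, y) = (col, row)
  hv <- pts[h, , drop = FALSE]
  # collinear point sets make chull return a zero-area polygon
  area2 <- abs(sum(hv[, 2] * c(hv[-1, 1], hv[1, 1]) - c(hv[-1, 2], hv[1, 2]) * hv[, 1]))
  if (nrow(hv) < 3L || area2 < 1e-9) { out[pixels] <- TRUE; return(out) }
  fill_polygon(hv - 1L, shape)   # to 0-based vertices
}

#' Dice similarity between two binary masks
#'
#' `dice = 2 TP / (2 TP + FP + FN)`.  Two empty masks score 1 (perfect
#' agreement on absence).
#'
#' @param x,y Logical masks of identical shape (`x` is scored against the
#'   reference `y`).
#' @return An object of class `dice_report`: `dice`, `true_positive_px`,
#'   `false_positive_px`, `false_negative_px`.
#' @export
dice <- function(x, y) {
  if (!all(dim(x) == dim(y))) stop("shape mismatch", call. = FALSE)
  tp <- sum(x & y); fp <- sum(x & !y); fn <- sum(!x & y)
  d <- if (tp + fp + fn == 0L) 1 else 2 * tp / (2 * tp + fp + fn)
  structure(list(dice = d, true_positive_px = tp, false_positive_px = fp,
                 false_negative_px = fn),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("<dice_report> dice = %.4f (TP %d, FP %d, FN %d)\n",
              x$dice, x$true_positive_px, x$false_positive_px,
              x$false_negative_px))
  invisible(x)
}

#' Evaluate a segmentation against an annotation outline
#'
#' Builds the reference mask from the outline, the convex hull of the
#' segmented MCs inside it, and reports their Dice overlap.
#'
#' @param seg Segmentation mask.
#' @param outline n x 2 `(row, col)` vertex matrix.
#' @return A `dice_report` with the hull and reference masks attached as
#'   attributes `hull` and `reference`.
#' @export
evaluate_segmentation <- function(seg, outline) {
  ref <- reference_mask(outline, dim(seg))
  hull <- hull_mask(seg, ref)
  rep <- dice(hull, ref)
  attr(rep, "hull") <- hull
  attr(rep, "reference") <- ref
  rep
}
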