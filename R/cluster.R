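# Clinical cluster rules: from the MC probability image (Image C) to the
# final segmentation.  A clinically significant cluster has at least three
# MCs within a 1 cm^2 area; the patch is tiled into 1 cm^2 blocks (last
# row/column truncated at the border), blobs are assigned to blocks by
# centroid, and blocks holding fewer than `min_count` blobs are emptied.

#' Side of a 1 cm^2 block in pixels
#'
#' `round(10000 / spacing_um)`: 143 px at 70 um (digital mammograms),
#' 200 px at 50 um (digitized film).
#'
#' @param spacing_um Pixel spacing in micrometres (> 0).
#' @return Integer block side in pixels.
#' @export
block_side_px <- function(spacing_um) {
  if (!is.numeric(spacing_um) || spacing_um <= 0)
    stop("spacing_um must be positive", call. = FALSE)
  as.integer(round(10000 / spacing_um))
}

#' Pre-cleaning of Image C
#'
#' 8-connected components of one or two pixels are removed as artifacts,
#' then a binary erosion with a 2x2 all-ones element is applied.  The even
#' element has no centre; its origin is anchored at the top-left cell, so a
#' pixel survives iff the 2x2 window whose top-left corner sits on it is
#' entirely true.
#'
#' @param mask Logical mask.
#' @return Cleaned logical mask.
#' @export
pre_clean <- function(mask) {
  bl <- label_blobs(mask)
  small <- which(vapply(bl$blobs, function(b) b$pixel_count, numeric(1)) <= 2)
  if (length(small)) {
    mask <- bl$labels > 0L & !(matrix(bl$labels %in% small, nrow(mask), ncol(mask)))
  } else {
    mask <- bl$labels > 0L
  }
  erode_mask(mask, 2L, "topleft")
}

#' Label 8-connected components of a binary mask
#'
#' @param mask Logical matrix.
#' @return An object of class `blob_set`: `labels` (integer matrix, 0 =
#'   background) and `blobs`, a list of records with `label`,
#'   `pixel_count`, `centroid` (0-based `(row, col)`) and `pixels` (n x 2
#'   matrix of 1-based matrix indices).
#' @export
label_blobs <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  todo <- which(mask)
  nlab <- 0L
  offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  visited <- matrix(FALSE, nr, nc)
  blobs <- list()
  for (seed in todo) {
    if (visited[seed]) next
    nlab <- nlab + 1L
    frontier <- seed
    visited[seed] <- TRUE
    comp <- seed
    while (length(frontier)) {
      fr <- (frontier - 1L) %% nr + 1L
      fc <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        rr <- fr + offs[k, 1]; cc <- fc + offs[k, 2]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (!any(ok)) next
        idx <- (cc[ok] - 1L) * nr + rr[ok]
        idx <- idx[mask[idx] & !visited[idx]]
        if (length(idx)) {
          visited[idx] <- TRUE
          nxt <- c(nxt, idx)
        }
      }
      nxt <- unique(nxt)
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    labels[comp] <- nlab
    pr <- (comp - 1L) %% nr + 1L
    pc <- (comp - 1L) %/% nr + 1L
    blobs[[nlab]] <- list(label = nlab, pixel_count = length(comp),
                          centroid = c(row = mean(pr) - 1, col = mean(pc) - 1),
                          pixels = cbind(row = pr, col = pc))
  }
  structure(list(labels = labels, blobs = blobs), class = "blob_set")
}

#' @export
print.blob_set <- function(x, ...) {
  cat(sprintf("<blob_set> %d blobs, %d pixels\n", length(x$blobs),
              sum(x$labels > 0L)))
  invisible(x)
}

#' Tiling of an image into square blocks
#'
#' Blocks tile the image from the top-left; the last row/column of blocks
#' is truncated to the image bounds, so the union of the blocks is the
#' image and the blocks are disjoint.
#'
#' @param shape `(rows, cols)` of the image.
#' @param side Block side in pixels.
#' @return An object of class `block_grid` with fields `side`, `shape`,
#'   `n_row_blocks`, `n_col_blocks`.
#' @export
block_grid <- function(shape, side) {
  stopifnot(side >= 1L)
  structure(list(side = as.integer(side), shape = as.integer(shape),
                 n_row_blocks = ceiling(shape[1] / side),
                 n_col_blocks = ceiling(shape[2] / side)),
            class = "block_grid")
}

#' Apply the clinical cluster rule to a blob set
#'
#' Each blob is assigned to the block containing its centroid; in every
#' block holding fewer than `min_count` blobs, all of its blobs are
#' removed.  Surviving blobs are re-rendered into the output mask (the
#' blocks "stitched together").
#'
#' @param blobs A `blob_set`.
#' @param grid A `block_grid` covering the blob image.
#' @param min_count Minimum blobs per block (default 3).
#' @return Logical mask of the surviving blobs; attribute `kept_labels`
#'   lists the surviving blob labels.
#' @export
apply_cluster_rule <- function(blobs, grid, min_count = 3L) {
  stopifnot(inherits(blobs, "blob_set"), inherits(grid, "block_grid"))
  mask <- matrix(FALSE, grid$shape[1], grid$shape[2])
  if (!length(blobs$blobs)) {
    attr(mask, "kept_labels") <- integer(0)
    return(mask)
  }
  cent <- t(vapply(blobs$blobs, function(b) b$centroid, numeric(2)))
  br <- pmin(floor(cent[, 1] / grid$side) + 1L, grid$n_row_blocks)
  bc <- pmin(floor(cent[, 2] / grid$side) + 1L, grid$n_col_blocks)
  key <- paste(br, bc)
  counts <- table(key)
  keep <- which(counts[key] >= min_count)
  for (i in keep) mask[blobs$blobs[[i]]$pixels] <- TRUE
  attr(mask, "kept_labels") <- as.integer(keep)
  mask
}

#' Full MC-cluster segmentation of a patch
#'
#' Optionally enhances the patch, builds the MC probability image
#' (Image C), pre-cleans it, labels 8-connected blobs, applies the
#' clinical cluster rule on the 1 cm^2 block grid and returns the final
#' mask together with the surviving blob set.
#'
#' @param patch An [image_patch()].
#' @param enhance Logical: apply wavelet enhancement first (default FALSE;
#'   the pipeline driver runs both variants).
#' @param config A [pipeline_config()] providing the tunables.
#' @return List with `mask` (final segmentation), `blobs` (surviving
#'   `blob_set`), `image_c`, `prob` (the [mc_probability_image()] output)
#'   and `block_side`.
#' @export
segment_patch <- function(patch, enhance = FALSE, config = pipeline_config()) {
  if (enhance) {
    patch <- mcclassify::enhance(patch, weight = config$enhance_weight,
                                 levels = config$enhance_levels,
                                 ssi_ref = config$ssi_ref)
  }
  prob <- mc_probability_image(patch,
                               subregion_px = config$subregion_px,
                               fraction = config$top_fraction,
                               fallback_fraction = config$fallback_fraction)
  cleaned <- pre_clean(prob$image_c)
  bl <- label_blobs(cleaned)
  side <- config$block_side %||% block_side_px(patch$spacing_um)
  grid <- block_grid(dim(patch$pixels), side)
  final <- apply_cluster_rule(bl, grid, config$min_per_block)
  list(mask = final, blobs = label_blobs(final), image_c = prob$image_c,
       prob = prob, block_side = side)
}
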