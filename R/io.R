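# Reading, writing and cropping of image patches, masks, annotation
# outlines and feature tables.
#
# Conventions used throughout the package: 0-based (row, col) coordinates,
# origin at the top-left pixel, rows increasing downward, bounding boxes
# inclusive of both ends.  Patch pixels are stored as a numeric matrix in
# native intensity units (0 .. 2^bit_depth - 1).

#' Construct an image patch
#'
#' The unit of processing: a 2-D grayscale intensity grid with its pixel
#' spacing in micrometres and its bit depth.
#'
#' @param pixels Numeric matrix of non-negative intensities.
#' @param spacing_um Pixel spacing in micrometres (> 0); digital mammograms
#'   are typically 70, digitized films 50.
#' @param bit_depth Integer, one of 8, 12, 16.
#' @param id Free-text identifier.
#' @return An object of class `image_patch`.
#' @export
image_patch <- function(pixels, spacing_um, bit_depth = 12L, id = "patch") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("patch must have at least 2 rows and 2 columns", call. = FALSE)
  if (!spacing_um > 0) stop("spacing_um must be positive", call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 12L, 16L))
    stop("bit_depth must be 8, 12 or 16", call. = FALSE)
  if (any(pixels < 0) || any(pixels > 2^bit_depth - 1))
    stop("intensities outside [0, 2^bit_depth - 1]", call. = FALSE)
  structure(list(pixels = pixels, spacing_um = spacing_um,
                 bit_depth = bit_depth, id = id),
            class = "image_patch")
}

#' @export
print.image_patch <- function(x, ...) {
  cat(sprintf("<image_patch '%s'> %d x %d px, %g um/px, %d-bit, range [%g, %g]\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$spacing_um, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.image_patch <- function(x) dim(x$pixels)

infer_bit_depth <- function(maxval) {
  if (maxval <= 255) 8L else if (maxval <= 4095) 12L else 16L
}

# --- PGM ------------------------------------------------------------------

read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  tokens <- character(0)
  magic <- NULL
  # read header tokens (magic, width, height, maxval), skipping comments
  buf <- character(0)
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PGM header", call. = FALSE)
      if (ch == "#") { repeat { ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break } ; next }
      if (grepl("[[:space:]]", ch)) { if (nzchar(tok)) return(tok) else next }
      tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (w < 1L || h < 1L) stop("zero-sized PGM image", call. = FALSE)
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else {
    if (maxval < 256) {
      vals <- as.integer(readBin(con, "raw", n = w * h))
    } else {
      vals <- readBin(con, "integer", n = w * h, size = 2L, signed = FALSE,
                      endian = "big")
    }
  }
  if (length(vals) != w * h) stop("truncated PGM payload", call. = FALSE)
  list(pixels = matrix(vals, nrow = h, ncol = w, byrow = TRUE), maxval = maxval)
}

write_pgm <- function(pixels, path, maxval) {
  con <- file(path, "wb"); on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(pixels), nrow(pixels), maxval),
            con, eos = NULL)
  vals <- as.integer(round(t(pixels)))
  if (maxval < 256) {
    writeBin(as.raw(vals), con)
  } else {
    writeBin(vals, con, size = 2L, endian = "big")
  }
}

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L) stop("not a PNG file: ", path, call. = FALSE)
  as.integer(hdr[25])  # IHDR bit-depth byte
}

# --- patches --------------------------------------------------------------

#' Read a grayscale image patch from PNG, TIFF or PGM
#'
#' Intensities are preserved bit-exactly in native integer units.
#'
#' @param path File path; format chosen by extension (`.png`, `.tif`/`.tiff`,
#'   `.pgm`).
#' @param spacing_um Pixel spacing in micrometres to attach to the patch.
#' @param id Identifier; defaults to the file name without extension.
#' @return An [image_patch()].
#' @export
read_patch <- function(path, spacing_um, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  id <- id %||% tools::file_path_sans_ext(basename(path))
  if (ext == "pgm") {
    p <- read_pgm(path)
    return(image_patch(p$pixels, spacing_um, infer_bit_depth(p$maxval), id))
  }
  if (ext == "png") {
    depth <- png_bit_depth(path)
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) {
      if (dim(arr)[3] > 2L) stop("color image not supported: ", path, call. = FALSE)
      arr <- arr[, , 1L]  # gray + alpha: keep gray
    }
    px <- round(arr * (2^depth - 1))
    return(image_patch(px, spacing_um, if (depth <= 8) 8L else 16L, id))
  }
  if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(arr)) == 3L) {
      if (dim(arr)[3] > 2L) stop("color image not supported: ", path, call. = FALSE)
      arr <- arr[, , 1L]
    }
    bps <- attr(arr, "bits.per.sample") %||% infer_bit_depth(max(arr))
    return(image_patch(arr, spacing_um, infer_bit_depth(2^bps - 1), id))
  }
  stop("unsupported image format: ", ext, call. = FALSE)
}

#' Write an image patch to PNG, TIFF or PGM
#'
#' The round trip `read_patch(write_patch(x))` reproduces the pixel array
#' exactly.  PNG/TIFF write 8- or 16-bit containers (12-bit data is stored
#' in 16-bit samples); PGM writes the native maximum value.
#'
#' @param patch An [image_patch()].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_patch <- function(patch, path) {
  stopifnot(inherits(patch, "image_patch"))
  ext <- tolower(tools::file_ext(path))
  px <- round(patch$pixels)
  if (ext == "pgm") {
    write_pgm(px, path, maxval = 2^patch$bit_depth - 1)
  } else if (ext == "png") {
    if (patch$bit_depth != 8L)
      stop("PNG output is 8-bit only; use TIFF or PGM for deeper data",
           call. = FALSE)
    png::writePNG(px / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    depth <- if (patch$bit_depth == 8L) 8L else 16L
    tiff::writeTIFF(px / (2^depth - 1), path, bits.per.sample = depth)
  } else stop("unsupported image format: ", ext, call. = FALSE)
  invisible(path)
}

# --- masks ----------------------------------------------------------------

#' Read / write a binary mask as 8-bit PNG (0/255)
#' @param path PNG file path.
#' @return `read_mask()` returns a logical matrix; `write_mask()` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  arr >= 0.5
}

#' @rdname read_mask
#' @param mask Logical matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

# --- annotation outlines --------------------------------------------------

#' Read / write an annotation outline (closed polygon) as a 2-column CSV
#'
#' Vertices are `(row, col)` points in 0-based patch coordinates.
#'
#' @param path CSV file with columns `row,col`.
#' @return `read_outline()` returns an n x 2 numeric matrix with columns
#'   `row`, `col`.
#' @export
read_outline <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("row", "col") %in% names(d)))
    stop("outline CSV must have 'row' and 'col' columns", call. = FALSE)
  m <- cbind(row = d$row, col = d$col)
  if (nrow(m) < 3L) stop("outline needs at least 3 vertices", call. = FALSE)
  m
}

#' @rdname read_outline
#' @param outline n x 2 matrix of `(row, col)` vertices.
#' @export
write_outline <- function(outline, path) {
  utils::write.csv(data.frame(row = outline[, 1], col = outline[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

# --- ROI cropping ---------------------------------------------------------

#' Crop the annotation-centred region of interest
#'
#' Returns the axis-aligned bounding box of the outline expanded by
#' `margin_px` on every side, clipped to the patch bounds.
#'
#' @param patch An [image_patch()].
#' @param outline n x 2 matrix of `(row, col)` vertices (0-based).
#' @param margin_px Non-negative integer margin.
#' @return A cropped [image_patch()]; attribute `offset` records the 0-based
#'   `(row, col)` of its top-left pixel in the parent patch.
#' @export
crop_roi <- function(patch, outline, margin_px = 0L) {
  stopifnot(inherits(patch, "image_patch"), margin_px >= 0)
  nr <- nrow(patch$pixels); nc <- ncol(patch$pixels)
  r <- outline[, 1]; c <- outline[, 2]
  if (any(r < 0) || any(r > nr - 1) || any(c < 0) || any(c > nc - 1))
    stop("outline vertices outside patch bounds", call. = FALSE)
  r0 <- max(0L, floor(min(r)) - margin_px)
  r1 <- min(nr - 1L, ceiling(max(r)) + margin_px)
  c0 <- max(0L, floor(min(c)) - margin_px)
  c1 <- min(nc - 1L, ceiling(max(c)) + margin_px)
  out <- image_patch(patch$pixels[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L), drop = FALSE],
                     patch$spacing_um, patch$bit_depth, paste0(patch$id, "_roi"))
  attr(out, "offset") <- c(row = r0, col = c0)
  out
}

# --- feature tables -------------------------------------------------------

#' Read / write a feature table as CSV
#'
#' The table has an `id` column, a `label` column (`benign` / `malignant` /
#' `unknown`) and one numeric column per registry feature.
#'
#' @param path CSV path.
#' @return `read_feature_table()` returns a data frame.
#' @export
read_feature_table <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("id", "label") %in% names(d)))
    stop("feature table must have 'id' and 'label' columns", call. = FALSE)
  d$label <- factor(d$label, levels = c("benign", "malignant", "unknown"))
  d
}

#' @rdname read_feature_table
#' @param table Feature table data frame.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
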