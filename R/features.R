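# The 51-slot feature descriptor of a segmented patch.
#
# Features characterise either individual MCs (blob-level, aggregated over
# the cluster) or the cluster as a whole, and are grouped into three
# categories of 17: size, shape and texture.  The registry fixes the order
# and naming; clinically named quantities (summation of blob mean
# intensities, variance of the centroid distances, cluster convex-hull
# area, mean blob perimeter, cluster area, mean blob size) occupy explicit
# slots, and the remaining slots are standard aggregates of per-blob
# geometry and first-order / co-occurrence texture statistics.

#' The ordered 51-feature registry
#'
#' @return Data frame with columns `name`, `category`
#'   (`size`/`shape`/`texture`) and `description`; exactly 51 rows, 17 per
#'   category, unique names, fixed order.
#' @export
feature_registry <- function() {
  reg <- rbind(
    data.frame(category = "size", name = c(
      "blob_area_mean", "blob_area_sd", "blob_area_min", "blob_area_max",
      "cluster_area", "cluster_hull_area", "cluster_hull_perimeter",
      "blob_perimeter_mean", "blob_perimeter_sd", "blob_perimeter_max",
      "blob_count", "cluster_density", "blob_equiv_diameter_mean",
      "centroid_dist_mean", "centroid_dist_sd", "centroid_dist_var",
      "centroid_dist_max"),
      description = c(
        "mean area of individual MCs (px)", "sd of MC areas",
        "smallest MC area", "largest MC area",
        "total MC cluster area (sum of blob areas)",
        "area of the cluster convex hull (px)",
        "perimeter of the cluster convex hull (crack length)",
        "mean MC perimeter (crack length)", "sd of MC perimeters",
        "largest MC perimeter", "number of MCs in the cluster",
        "MC count per unit hull area",
        "mean equivalent circular diameter of MCs",
        "mean distance of MC centroids from the cluster centroid",
        "sd of centroid distances", "variance of centroid distances",
        "largest centroid distance")),
    data.frame(category = "shape", name = c(
      "blob_eccentricity_mean", "blob_eccentricity_sd", "blob_eccentricity_max",
      "blob_elongation_mean", "blob_elongation_max",
      "blob_circularity_mean", "blob_circularity_sd",
      "blob_solidity_mean", "blob_solidity_min",
      "blob_extent_mean", "blob_extent_sd",
      "cluster_eccentricity", "cluster_elongation", "cluster_compactness",
      "cluster_solidity", "cluster_aspect_ratio", "cluster_radial_spread"),
      description = c(
        "mean moment eccentricity of MCs", "sd of MC eccentricities",
        "largest MC eccentricity", "mean major/minor axis ratio of MCs",
        "largest MC elongation", "mean MC circularity 4*pi*A/P^2",
        "sd of MC circularities", "mean MC solidity (area / hull area)",
        "smallest MC solidity", "mean MC extent (area / bbox area)",
        "sd of MC extents", "moment eccentricity of the blob union",
        "major/minor axis ratio of the blob union",
        "hull compactness 4*pi*hull_area/hull_perimeter^2",
        "cluster area / hull area", "hull bounding-box aspect ratio",
        "sd/mean ratio of centroid distances")),
    data.frame(category = "texture", name = c(
      "intensity_mean", "intensity_sd", "intensity_skewness",
      "intensity_kurtosis", "intensity_entropy", "intensity_range",
      "glcm_contrast", "glcm_correlation", "glcm_energy",
      "glcm_homogeneity", "glcm_entropy",
      "blob_intensity_mean_sum", "blob_intensity_mean_sd",
      "blob_intensity_mean_min", "blob_intensity_mean_max",
      "blob_intensity_sd_mean", "background_contrast"),
      description = c(
        "mean intensity of segmented pixels", "sd of segmented intensities",
        "skewness of segmented intensities",
        "excess kurtosis of segmented intensities",
        "entropy of the 32-bin intensity histogram",
        "intensity range of segmented pixels",
        "co-occurrence contrast (mean over 4 offsets)",
        "co-occurrence correlation", "co-occurrence energy",
        "co-occurrence homogeneity", "co-occurrence entropy",
        "summation of the mean intensities of individual MCs",
        "sd of MC mean intensities", "smallest MC mean intensity",
        "largest MC mean intensity", "mean within-MC intensity sd",
        "mean MC intensity minus local background median"))
  )
  reg[, c("name", "category", "description")]
}

# moment-based axis lengths of a pixel set; returns c(lambda_major,
# lambda_minor) eigenvalues of the covariance (with the 1/12 pixel term
# keeping single rows/columns non-degenerate)
pixel_moments <- function(px) {
  r <- px[, 1]; c <- px[, 2]
  mu20 <- stats::var(r) * (length(r) - 1) / length(r) + 1 / 12
  mu02 <- stats::var(c) * (length(c) - 1) / length(c) + 1 / 12
  if (length(r) == 1L) { mu20 <- 1 / 12; mu02 <- 1 / 12 }
  mu11 <- if (length(r) == 1L) 0 else
    sum((r - mean(r)) * (c - mean(c))) / length(r)
  tr <- mu20 + mu02
  det_ <- sqrt(max((mu20 - mu02)^2 + 4 * mu11^2, 0))
  c(major = (tr + det_) / 2, minor = max((tr - det_) / 2, 1e-12))
}

shape_from_moments <- function(px) {
  lam <- pixel_moments(px)
  ecc <- sqrt(max(0, 1 - lam["minor"] / lam["major"]))
  elong <- sqrt(lam["major"] / lam["minor"])
  c(eccentricity = unname(ecc), elongation = unname(elong))
}

# crack-length perimeter: each pixel edge exposed to background counts 1
crack_perimeter <- function(mask) {
  p <- 0L
  for (off in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    p <- p + sum(mask & !shift_matrix(mask, off[1], off[2], fill = FALSE))
  }
  p
}

# hull area of a pixel set by shoelace over centre coordinates plus the
# boundary correction (Pick-style), capped below by the pixel count of a
# degenerate set
hull_area_points <- function(px) {
  pts <- unique(px)
  if (nrow(pts) < 3L) return(nrow(pts))
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hv <- pts[h, , drop = FALSE]
  if (nrow(hv) < 3L) return(nrow(pts))
  x <- hv[, 2]; y <- hv[, 1]
  a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  max(a + per / 2 + 1, nrow(pts))
}

#' Per-blob geometry and intensity properties
#'
#' For every blob: area, crack-length perimeter, moment eccentricity in
#' `[0, 1)`, elongation (major/minor axis ratio), circularity
#' `4*pi*A/P^2`, solidity (area / hull area), extent (area / bounding-box
#' area), mean and sd of intensity, and distance of the blob centroid to
#' the cluster centroid (the mean of blob centroids).  Degenerate
#' single-pixel geometry is imputed (eccentricity 0, elongation 1,
#' circularity 1, solidity 1).
#'
#' @param patch An [image_patch()].
#' @param blobs A `blob_set` with at least one blob.
#' @return Data frame, one row per blob.
#' @export
blob_properties <- function(patch, blobs) {
  stopifnot(inherits(blobs, "blob_set"))
  if (!length(blobs$blobs))
    stop("empty blob set: patch not segmentable", call. = FALSE)
  px <- patch$pixels
  cent <- t(vapply(blobs$blobs, function(b) b$centroid, numeric(2)))
  ccent <- colMeans(cent)
  rows <- lapply(blobs$blobs, function(b) {
    n <- b$pixel_count
    bb_r <- range(b$pixels[, 1]); bb_c <- range(b$pixels[, 2])
    sub <- matrix(FALSE, diff(bb_r) + 1L, diff(bb_c) + 1L)
    sub[cbind(b$pixels[, 1] - bb_r[1] + 1L, b$pixels[, 2] - bb_c[1] + 1L)] <- TRUE
    per <- crack_perimeter(sub)
    if (n == 1L) {
      ecc <- 0; elong <- 1; circ <- 1; sol <- 1
    } else {
      s <- shape_from_moments(b$pixels)
      ecc <- s["eccentricity"]; elong <- s["elongation"]
      # 4*pi*A/P^2 with the Euclidean perimeter estimated from the crack
      # length (P ~ crack * pi/4 for smooth convex shapes), so a disk
      # scores ~1
      circ <- 4 * pi * n / (per * pi / 4)^2
      sol <- min(n / hull_area_points(b$pixels), 1)
    }
    ints <- px[b$pixels]
    data.frame(label = b$label, area = n, perimeter = per,
               eccentricity = unname(ecc), elongation = unname(elong),
               circularity = unname(circ), solidity = unname(sol),
               extent = n / ((diff(bb_r) + 1) * (diff(bb_c) + 1)),
               mean_intensity = mean(ints),
               sd_intensity = if (n > 1L) stats::sd(ints) else 0,
               centroid_row = b$centroid["row"], centroid_col = b$centroid["col"],
               centroid_dist = sqrt(sum((b$centroid - ccent)^2)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cluster_centroid") <- ccent
  out
}

#' Cluster-level geometry of a blob set
#'
#' @param blobs A `blob_set` with at least one blob.
#' @param shape Image shape `(rows, cols)`; defaults to the label grid's.
#' @return List with cluster centroid, hull area/perimeter, total area,
#'   union eccentricity/elongation, blob count, density and centroid
#'   distance statistics.
#' @export
cluster_properties <- function(blobs, shape = dim(blobs$labels)) {
  stopifnot(inherits(blobs, "blob_set"))
  if (!length(blobs$blobs))
    stop("empty blob set: patch not segmentable", call. = FALSE)
  all_px <- do.call(rbind, lapply(blobs$blobs, function(b) b$pixels))
  cent <- t(vapply(blobs$blobs, function(b) b$centroid, numeric(2)))
  ccent <- colMeans(cent)
  d <- sqrt(rowSums((cent - matrix(ccent, nrow(cent), 2, byrow = TRUE))^2))
  hull <- convex_hull_mask(all_px, shape)
  hull_area <- sum(hull)
  hull_per <- crack_perimeter(hull)
  s <- if (nrow(all_px) > 1L) shape_from_moments(all_px) else
    c(eccentricity = 0, elongation = 1)
  bb_r <- diff(range(all_px[, 1])) + 1; bb_c <- diff(range(all_px[, 2])) + 1
  list(centroid = ccent,
       hull_area = hull_area, hull_perimeter = hull_per,
       cluster_area = sum(vapply(blobs$blobs, function(b) b$pixel_count, numeric(1))),
       eccentricity = unname(s["eccentricity"]),
       elongation = unname(s["elongation"]),
       compactness = if (hull_per > 0) 4 * pi * hull_area / hull_per^2 else 1,
       aspect_ratio = max(bb_r, bb_c) / min(bb_r, bb_c),
       blob_count = length(blobs$blobs),
       density = length(blobs$blobs) / hull_area,
       dist_mean = mean(d), dist_sd = stats::sd(d) %|NA|% 0,
       dist_var = stats::var(d) %|NA|% 0, dist_max = max(d))
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

# quantize a numeric matrix to n gray levels over its observed min-max
quantize_levels <- function(x, n = 32L) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(matrix(1L, nrow(x), ncol(x)))
  q <- floor((x - rng[1]) / (rng[2] - rng[1]) * n) + 1L
  q[q > n] <- n
  q
}

#' Gray-level co-occurrence features of a quantized grid
#'
#' Symmetric co-occurrence counts at distance 1 for offsets (0,1), (1,0),
#' (1,1), (1,-1), normalized per offset; contrast, correlation, energy,
#' homogeneity and entropy are averaged over the four offsets.
#'
#' @param q Integer matrix of gray levels in `1..n_levels`.
#' @param n_levels Number of gray levels (default 32).
#' @return Named numeric vector `contrast`, `correlation`, `energy`,
#'   `homogeneity`, `entropy`.
#' @export
glcm_features <- function(q, n_levels = 32L) {
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  acc <- c(contrast = 0, correlation = 0, energy = 0, homogeneity = 0,
           entropy = 0)
  lev <- seq_len(n_levels)
  for (off in offsets) {
    P <- glcm_counts(q, off, n_levels)
    P <- P + t(P)                       # symmetric pairs
    if (sum(P) == 0) next
    P <- P / sum(P)
    pi_ <- rowSums(P)
    mu <- sum(lev * pi_); sg <- sqrt(sum((lev - mu)^2 * pi_))
    ii <- matrix(lev, n_levels, n_levels)
    jj <- t(ii)
    corr <- if (sg > 0) sum((ii - mu) * (jj - mu) * P) / sg^2 else 1
    nz <- P > 0
    acc <- acc + c(contrast = sum((ii - jj)^2 * P),
                   correlation = corr,
                   energy = sum(P^2),
                   homogeneity = sum(P / (1 + abs(ii - jj))),
                   entropy = -sum(P[nz] * log(P[nz])))
  }
  acc / length(offsets)
}

# raw directed co-occurrence counts for one offset
glcm_counts <- function(q, off, n_levels) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- seq_len(nr - abs(off[1]))
  if (off[1] < 0) r1 <- r1 + abs(off[1])
  c1 <- seq_len(nc - abs(off[2]))
  if (off[2] < 0) c1 <- c1 + abs(off[2])
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  P <- matrix(0, n_levels, n_levels)
  tab <- table(factor(a, levels = seq_len(n_levels)),
               factor(b, levels = seq_len(n_levels)))
  P + unclass(tab)
}

#' Texture descriptor of the segmented region
#'
#' First-order statistics on masked pixels, co-occurrence features on the
#' cluster bounding box (32 gray levels over the observed range), and
#' per-blob intensity aggregates.
#'
#' @param patch An [image_patch()].
#' @param mask Non-empty segmentation mask.
#' @param n_levels Gray levels for quantization (default 32).
#' @return Named list of texture values.
#' @export
texture_features <- function(patch, mask, n_levels = 32L) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  px <- patch$pixels
  v <- px[mask]
  rng <- range(v)
  # 32-bin first-order entropy
  if (rng[2] > rng[1]) {
    h <- tabulate(pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * n_levels) + 1L,
                       n_levels), n_levels)
    p <- h[h > 0] / sum(h)
    ent <- -sum(p * log(p))
  } else ent <- 0
  idx <- which(mask, arr.ind = TRUE)
  bb_r <- range(idx[, 1]); bb_c <- range(idx[, 2])
  box <- px[bb_r[1]:bb_r[2], bb_c[1]:bb_c[2], drop = FALSE]
  g <- glcm_features(quantize_levels(box, n_levels), n_levels)
  bl <- label_blobs(mask)
  bmeans <- vapply(bl$blobs, function(b) mean(px[b$pixels]), numeric(1))
  bsds <- vapply(bl$blobs, function(b)
    if (b$pixel_count > 1L) stats::sd(px[b$pixels]) else 0, numeric(1))
  bg_px <- px[bb_r[1]:bb_r[2], bb_c[1]:bb_c[2], drop = FALSE][
    !mask[bb_r[1]:bb_r[2], bb_c[1]:bb_c[2], drop = FALSE]]
  bg_med <- if (length(bg_px)) stats::median(bg_px) else stats::median(px)
  list(intensity_mean = mean(v),
       intensity_sd = if (length(v) > 1L) stats::sd(v) else 0,
       intensity_skewness = if (length(v) > 2L && stats::sd(v) > 0)
         e1071::skewness(v) else 0,
       intensity_kurtosis = if (length(v) > 3L && stats::sd(v) > 0)
         e1071::kurtosis(v) else 0,
       intensity_entropy = ent,
       intensity_range = diff(rng),
       glcm_contrast = unname(g["contrast"]),
       glcm_correlation = unname(g["correlation"]),
       glcm_energy = unname(g["energy"]),
       glcm_homogeneity = unname(g["homogeneity"]),
       glcm_entropy = unname(g["entropy"]),
       blob_intensity_mean_sum = sum(bmeans),
       blob_intensity_mean_sd = if (length(bmeans) > 1L) stats::sd(bmeans) else 0,
       blob_intensity_mean_min = min(bmeans),
       blob_intensity_mean_max = max(bmeans),
       blob_intensity_sd_mean = mean(bsds),
       background_contrast = mean(bmeans) - bg_med)
}

#' Extract the ordered 51-feature vector of a segmented patch
#'
#' @param patch An [image_patch()].
#' @param seg Segmentation mask with at least one blob.
#' @param id Sample identifier (defaults to the patch id).
#' @param label Class label (`benign`, `malignant` or `unknown`).
#' @return Named numeric vector of length 51 in registry order, with
#'   attributes `id` and `label`.
#' @export
extract_features <- function(patch, seg, id = patch$id, label = "unknown") {
  bl <- label_blobs(seg)
  if (!length(bl$blobs))
    stop("empty segmentation: patch not segmentable", call. = FALSE)
  bp <- blob_properties(patch, bl)
  cp <- cluster_properties(bl, dim(seg))
  tx <- texture_features(patch, seg)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  vals <- c(
    # size
    blob_area_mean = mean(bp$area), blob_area_sd = sd0(bp$area),
    blob_area_min = min(bp$area), blob_area_max = max(bp$area),
    cluster_area = cp$cluster_area, cluster_hull_area = cp$hull_area,
    cluster_hull_perimeter = cp$hull_perimeter,
    blob_perimeter_mean = mean(bp$perimeter),
    blob_perimeter_sd = sd0(bp$perimeter),
    blob_perimeter_max = max(bp$perimeter),
    blob_count = cp$blob_count, cluster_density = cp$density,
    blob_equiv_diameter_mean = mean(2 * sqrt(bp$area / pi)),
    centroid_dist_mean = cp$dist_mean, centroid_dist_sd = cp$dist_sd,
    centroid_dist_var = cp$dist_var, centroid_dist_max = cp$dist_max,
    # shape
    blob_eccentricity_mean = mean(bp$eccentricity),
    blob_eccentricity_sd = sd0(bp$eccentricity),
    blob_eccentricity_max = max(bp$eccentricity),
    blob_elongation_mean = mean(bp$elongation),
    blob_elongation_max = max(bp$elongation),
    blob_circularity_mean = mean(bp$circularity),
    blob_circularity_sd = sd0(bp$circularity),
    blob_solidity_mean = mean(bp$solidity),
    blob_solidity_min = min(bp$solidity),
    blob_extent_mean = mean(bp$extent), blob_extent_sd = sd0(bp$extent),
    cluster_eccentricity = cp$eccentricity,
    cluster_elongation = cp$elongation,
    cluster_compactness = cp$compactness,
    cluster_solidity = min(cp$cluster_area / cp$hull_area, 1),
    cluster_aspect_ratio = cp$aspect_ratio,
    cluster_radial_spread = cp$dist_sd / (cp$dist_mean + 1e-12)
  )
  vals <- c(vals, unlist(tx))
  reg <- feature_registry()
  stopifnot(identical(names(vals), reg$name))
  structure(vals, id = id, label = label)
}

#' Build a feature table from patches and segmentations
#'
#' @param patches List of [image_patch()] objects.
#' @param segs List of segmentation masks (same length).
#' @param labels Character vector of class labels.
#' @param ids Identifiers (default: patch ids).
#' @return Feature table data frame (`id`, `label`, 51 feature columns).
#'   Unsegmentable patches (no blobs) are dropped; attribute
#'   `excluded_ids` records them.
#' @export
extract_feature_table <- function(patches, segs, labels,
                                  ids = vapply(patches, function(p) p$id, character(1))) {
  stopifnot(length(patches) == length(segs), length(patches) == length(labels))
  rows <- list(); excluded <- character(0)
  for (i in seq_along(patches)) {
    fv <- tryCatch(extract_features(patches[[i]], segs[[i]], ids[i], labels[i]),
                   error = function(e) NULL)
    if (is.null(fv)) { excluded <- c(excluded, ids[i]); next }
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(id = ids[i], label = labels[i]),
            as.data.frame(as.list(fv), check.names = FALSE))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stop("no segmentable patches", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded_ids") <- excluded
  out
}
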