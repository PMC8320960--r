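test_that("the registry has 51 uniquely named features, 17 per category", {
  reg <- feature_registry()
  expect_identical(nrow(reg), 51L)
  expect_identical(anyDuplicated(reg$name), 0L)
  expect_equal(unname(table(reg$category)[c("shape", "size", "texture")]),
               c(17L, 17L, 17L), ignore_attr = TRUE)
})

test_that("blob geometry behaves on disks, lines and single pixels", {
  n <- 64
  pm <- disk_mask(n, 10)
  patch <- disk_patch(n, 10)
  bp <- blob_properties(patch, label_blobs(pm))
  expect_lt(bp$eccentricity, 0.2)
  expect_gt(bp$circularity, 0.85); expect_lt(bp$circularity, 1.1)
  expect_equal(bp$area, sum(pm))

  line <- matrix(FALSE, 30, 30); line[15, 5:24] <- TRUE
  bl <- blob_properties(patch_from(matrix(100, 30, 30)), label_blobs(line))
  expect_gte(bl$elongation, 10)
  expect_gt(bl$eccentricity, 0.99)

  single <- matrix(FALSE, 10, 10); single[5, 5] <- TRUE
  bs <- blob_properties(patch_from(matrix(100, 10, 10)), label_blobs(single))
  expect_equal(bs$area, 1)
  expect_equal(bs$eccentricity, 0)
  expect_equal(bs$elongation, 1)
  expect_equal(bs$circularity, 1)
  expect_equal(bs$solidity, 1)

  expect_error(blob_properties(patch, label_blobs(matrix(FALSE, 5, 5))),
               "empty")
})

test_that("cluster geometry: hull area, concentric spread, distance scaling", {
  # single-pixel blobs at the 4 corners of a 100x100 square
  m <- matrix(FALSE, 120, 120)
  m[cbind(c(10, 10, 109, 109), c(10, 109, 10, 109))] <- TRUE
  cp <- cluster_properties(label_blobs(m), c(120, 120))
  shoelace <- 99 * 99   # polygon area over pixel centres
  expect_lt(abs(cp$hull_area - shoelace) / shoelace, 0.025)
  expect_identical(cp$blob_count, 4L)

  # concentric blobs -> near-zero distance spread
  conc <- matrix(FALSE, 40, 40)
  conc[10, 20:21] <- TRUE; conc[30, 20:21] <- TRUE
  conc[20:21, 10] <- TRUE; conc[20:21, 30] <- TRUE
  cpc <- cluster_properties(label_blobs(conc), c(40, 40))
  expect_lt(cpc$dist_sd / cpc$dist_mean, 0.15)

  # doubling every centroid's offset doubles the mean distance
  mk <- function(scale) {
    mm <- matrix(FALSE, 200, 200)
    offs <- scale * cbind(c(-20, 20, -20, 20), c(-20, -20, 20, 20))
    mm[cbind(100 + offs[, 1], 100 + offs[, 2])] <- TRUE
    cluster_properties(label_blobs(mm), c(200, 200))$dist_mean
  }
  expect_equal(mk(2), 2 * mk(1), tolerance = 1e-9)
})

test_that("texture limits and GLCM oracle agreement", {
  # constant region
  p <- patch_from(matrix(100, 20, 20))
  m <- matrix(TRUE, 20, 20)
  tx <- texture_features(p, m)
  expect_equal(tx$intensity_sd, 0)
  expect_equal(tx$glcm_energy, 1)
  expect_equal(tx$glcm_contrast, 0)

  # checkerboard and random grids vs the pair-counting oracle
  set.seed(61)
  cb <- matrix(ifelse((row(matrix(0, 12, 12)) + col(matrix(0, 12, 12))) %% 2 == 0,
                      10, 200), 12, 12)
  for (g in list(cb, matrix(sample(0:4000, 144), 12, 12))) {
    q <- mcclassify:::quantize_levels(g, 32L)
    feats <- glcm_features(q, 32L)
    expect_equal(unname(feats["contrast"]), oracle_glcm_contrast(q),
                 tolerance = 1e-10)
  }

  # scaling intensities by 2 leaves the quantized-level features unchanged
  px <- matrix(sample(0:2000, 400), 20, 20)
  t1 <- texture_features(patch_from(px), m)
  t2 <- texture_features(patch_from(2 * px), m)
  for (f in c("glcm_contrast", "glcm_correlation", "glcm_energy",
              "glcm_homogeneity", "glcm_entropy", "intensity_entropy"))
    expect_identical(t1[[f]], t2[[f]])

  expect_error(texture_features(p, matrix(FALSE, 20, 20)), "empty")
})

test_that("feature vectors are 51-long, translation-invariant, deterministic", {
  s <- generate_patch(phantom_spec(seed = 77))
  seg <- segment_patch(s$patch)$mask
  fv <- extract_features(s$patch, seg)
  expect_length(fv, 51)
  expect_identical(names(fv), feature_registry()$name)
  expect_true(all(is.finite(fv)))

  # bit-identical determinism
  fv2 <- extract_features(s$patch, seg)
  expect_identical(unclass(fv), unclass(fv2))

  # translation invariance of shape/size features
  px <- matrix(100, 80, 80); m0 <- matrix(FALSE, 80, 80)
  put <- function(px, m, dr, dc) {
    for (ctr in list(c(20, 20), c(20, 30), c(32, 24))) {
      r <- ctr[1] + dr; c <- ctr[2] + dc
      px[(r - 2):(r + 2), (c - 2):(c + 2)] <- 180
      m[(r - 2):(r + 2), (c - 2):(c + 2)] <- TRUE
    }
    list(px = px, m = m)
  }
  a <- put(px, m0, 0, 0); b <- put(px, m0, 25, 30)
  fa <- extract_features(patch_from(a$px), a$m)
  fb <- extract_features(patch_from(b$px), b$m)
  reg <- feature_registry()
  geo <- reg$name[reg$category %in% c("size", "shape")]
  expect_equal(fa[geo], fb[geo], tolerance = 1e-9)
})

test_that("area features scale quadratically with blob diameter", {
  mk <- function(r) {
    n <- 120
    m <- matrix(FALSE, n, n)
    for (ctr in list(c(30, 30), c(30, 80), c(80, 50))) {
      m <- m | disk_mask(n, r, ctr)
    }
    px <- matrix(100, n, n); px[m] <- 200
    extract_features(patch_from(px), m)
  }
  f1 <- mk(4); f2 <- mk(8)
  expect_equal(unname(f2["blob_area_mean"] / f1["blob_area_mean"]), 4,
               tolerance = 0.15)
})

test_that("unsegmentable patches are excluded from feature tables", {
  s1 <- generate_patch(phantom_spec(seed = 5))
  seg1 <- segment_patch(s1$patch)$mask
  empty <- matrix(FALSE, 160, 160)
  tab <- extract_feature_table(list(s1$patch, s1$patch), list(seg1, empty),
                               c("benign", "benign"), c("ok", "bad"))
  expect_identical(nrow(tab), 1L)
  expect_identical(attr(tab, "excluded_ids"), "bad")
  expect_identical(ncol(tab), 53L)
})
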