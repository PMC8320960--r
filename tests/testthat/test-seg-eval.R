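test_that("polygon rasterisation covers rectangles, triangles, full frame", {
  sq <- cbind(row = c(0, 0, 9, 9), col = c(0, 9, 9, 0))
  m <- reference_mask(sq, c(20, 20))
  expect_identical(sum(m), 100L)
  expect_true(all(m[1:10, 1:10]))

  tri <- cbind(row = c(0, 0, 9), col = c(0, 9, 0))
  a_raster <- sum(reference_mask(tri, c(20, 20)))
  a_shoelace <- 0.5 * abs(0 * 0 - 9 * 0 + 9 * 9 - 0 * 0 + 0 * 0 - 0 * 9)  # 40.5
  # boundary pixels are included, so the raster count sits between the
  # shoelace area and its Pick-style boundary-inclusive bound
  per <- 9 + 9 + 9 * sqrt(2)
  expect_gte(a_raster, a_shoelace)
  expect_lt(abs(a_raster - (a_shoelace + per / 2 + 1)), 10)

  border <- cbind(row = c(0, 0, 14, 14), col = c(0, 11, 11, 0))
  expect_true(all(reference_mask(border, c(15, 12))))

  expect_error(reference_mask(cbind(row = c(1, 1, 1), col = c(2, 2, 2)),
                              c(10, 10)), "degenerate")
})

test_that("hull mask covers exactly the hull of blobs inside the reference", {
  ref <- matrix(FALSE, 30, 30); ref[5:25, 5:25] <- TRUE

  seg0 <- matrix(FALSE, 30, 30); seg0[1, 1] <- TRUE; seg0[29, 29] <- TRUE
  expect_false(any(hull_mask(seg0, ref)))

  # three isolated pixels forming a triangle inside ref
  seg <- matrix(FALSE, 30, 30)
  seg[8, 8] <- TRUE; seg[8, 20] <- TRUE; seg[20, 8] <- TRUE
  h <- hull_mask(seg, ref)
  expect_true(all(h[seg]))
  # half-plane oracle: consistent edge-sign test around the triangle
  verts <- rbind(c(8, 8), c(8, 20), c(20, 8))
  inside_tri <- function(r, c) {
    s <- vapply(1:3, function(k) {
      a <- verts[k, ]; b <- verts[k %% 3 + 1, ]
      (b[1] - a[1]) * (c - a[2]) - (b[2] - a[2]) * (r - a[1])
    }, numeric(1))
    all(s >= 0) || all(s <= 0)
  }
  for (r in seq(6, 24, by = 3)) for (c in seq(6, 24, by = 3)) {
    if (inside_tri(r, c)) expect_true(h[r, c])
  }
  expect_gt(sum(h), 60)      # filled interior, not just the vertices
  expect_lt(sum(h), 100)     # but not the whole square

  # one blob fully inside -> hull superset of blob
  segb <- matrix(FALSE, 30, 30); segb[10:14, 10:14] <- TRUE
  expect_true(all(hull_mask(segb, ref)[segb]))
})

test_that("hull masks are convex up to 1 px rasterisation", {
  set.seed(51)
  seg <- matrix(FALSE, 40, 40)
  pts <- cbind(sample(5:35, 6), sample(5:35, 6))
  seg[pts] <- TRUE
  h <- hull_mask(seg, matrix(TRUE, 40, 40))
  idx <- which(h, arr.ind = TRUE)
  for (k in 1:50) {
    a <- idx[sample(nrow(idx), 1), ]; b <- idx[sample(nrow(idx), 1), ]
    for (t in seq(0, 1, length.out = 8)) {
      p <- round(a + t * (b - a))
      nbhd <- h[max(1, p[1] - 1):min(40, p[1] + 1),
                max(1, p[2] - 1):min(40, p[2] + 1)]
      expect_true(any(nbhd))   # segment point within 1 px of the hull
    }
  }
})

test_that("dice follows its closed form and symmetry", {
  a <- matrix(FALSE, 10, 10); a[1:5, ] <- TRUE
  expect_equal(dice(a, a)$dice, 1.0)
  b <- matrix(FALSE, 10, 10); b[6:10, ] <- TRUE
  expect_equal(dice(a, b)$dice, 0.0)

  x <- matrix(FALSE, 20, 20); x[1:5, 1:20] <- TRUE          # 100 px
  y <- matrix(FALSE, 20, 20); y[3:7, 1:20] <- TRUE          # 100 px, 60 shared
  r <- dice(x, y)
  expect_equal(r$dice, 2 * 60 / 200)
  expect_equal(r$true_positive_px, 60L)
  expect_equal(r$false_positive_px, 40L)

  set.seed(52)
  for (i in 1:10) {
    u <- matrix(runif(100) < 0.4, 10, 10)
    v <- matrix(runif(100) < 0.4, 10, 10)
    expect_equal(dice(u, v)$dice, dice(v, u)$dice)
    expect_gte(dice(u, v)$dice, 0); expect_lte(dice(u, v)$dice, 1)
  }
  expect_equal(dice(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3))$dice, 1.0)
  expect_error(dice(a, matrix(TRUE, 3, 3)), "mismatch")
})
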