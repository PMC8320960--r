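test_that("constant images have zero detail coefficients", {
  p <- image_patch(matrix(137, 64, 64), 70, 12)
  d <- decompose(p, 3L)
  for (l in 1:3) {
    expect_lt(max(abs(d$detail[[l]]$H)), 1e-9)
    expect_lt(max(abs(d$detail[[l]]$V)), 1e-9)
    expect_lt(max(abs(d$detail[[l]]$D)), 1e-9)
  }
})

test_that("decompose/reconstruct round trip is exact within 1e-8", {
  set.seed(21)
  for (dims in list(c(64, 64), c(65, 97), c(40, 56), c(33, 33))) {
    x <- matrix(stats::runif(prod(dims), 0, 4095), dims[1], dims[2])
    d <- decompose(x, 3L)
    expect_lt(max(abs(reconstruct(d) - x)) / max(abs(x)), 1e-8)
  }
  expect_error(decompose(matrix(0, 16, 16), 3L), "too small")
})

test_that("a vertical step edge concentrates energy in the vertical sub-band", {
  x <- matrix(0, 64, 64); x[, 33:64] <- 100
  d <- decompose(x, 1L)
  eV <- sum(d$detail[[1]]$V^2)
  eH <- sum(d$detail[[1]]$H^2)
  eD <- sum(d$detail[[1]]$D^2)
  expect_gt(eV, 10 * (eH + eD + 1e-12))
})

test_that("log_energy matches the sum-of-squares definition", {
  expect_equal(log_energy(matrix(0, 4, 4)), log(1e-12))
  expect_equal(log_energy(2), log(1e-12 + 4))
  set.seed(22)
  g <- matrix(rnorm(64), 8, 8)
  acc <- 0
  for (i in 1:8) for (j in 1:8) acc <- acc + g[i, j]^2   # brute-force oracle
  expect_equal(log_energy(g), log(1e-12 + acc))
})

test_that("SSI is the weighted sum of TLEs and orders sharpness correctly", {
  expect_equal(ssi(c(0, 0, 0)), 0)
  expect_equal(ssi(c(10, 20, 30), weight = 0.10), 6.0)
  # sharp textured image vs its smoothed version
  set.seed(25)
  n <- 64
  cb <- matrix(ifelse((row(matrix(0, n, n)) %/% 4 + col(matrix(0, n, n)) %/% 4)
                      %% 2 == 0, 200, 50), n, n) + matrix(rnorm(n * n, sd = 15), n, n)
  blur <- mcclassify:::conv2_sym(cb, matrix(1 / 25, 5, 5))
  s_sharp <- sharpness_profile(decompose(cb, 3L))$ssi
  s_blur <- sharpness_profile(decompose(blur, 3L))$ssi
  expect_gt(s_sharp, s_blur)
})

test_that("sharpness profile totals are consistent", {
  set.seed(23)
  p <- image_patch(matrix(runif(64 * 64, 0, 4000), 64, 64), 70, 12)
  pr <- sharpness_profile(decompose(p, 3L))
  expect_equal(pr$tle, rowSums(pr$log_energies))
  expect_equal(pr$ssi, sum(0.10 * pr$tle))
  expect_true(is.finite(pr$ssi))
})

test_that("enhancement with weight 0 is the identity", {
  set.seed(24)
  p <- image_patch(matrix(runif(64 * 64, 100, 3000), 64, 64), 70, 12)
  e <- enhance(p, weight = 0, ssi_ref = 1000)
  expect_lt(max(abs(e$pixels - p$pixels)) / max(p$pixels), 1e-6)
})

test_that("enhancement increases blob contrast and respects the ceiling", {
  p <- disk_patch(64, radius = 5, bg = 500, contrast = 60)
  m <- disk_mask(64, 5)
  ref <- sharpness_profile(decompose(p, 3L))$ssi + 50  # blurrier than reference
  e <- enhance(p, weight = 0.10, ssi_ref = ref)
  contrast0 <- mean(p$pixels[m]) - mean(p$pixels[!m])
  contrast1 <- mean(e$pixels[m]) - mean(e$pixels[!m])
  expect_gt(contrast1, contrast0)

  # near-saturated input never exceeds the bit-depth ceiling
  sat <- disk_patch(64, radius = 5, bg = 3900, contrast = 190)
  es <- enhance(sat, weight = 0.5, ssi_ref = ref)
  expect_lte(max(es$pixels), 4095)
  expect_gte(min(es$pixels), 0)
})

test_that("blob contrast is monotone non-decreasing in the weight", {
  p <- disk_patch(64, radius = 5, bg = 500, contrast = 60)
  m <- disk_mask(64, 5)
  ref <- sharpness_profile(decompose(p, 3L))$ssi + 50
  contrasts <- vapply(c(0, 0.2, 0.4, 0.8), function(w) {
    e <- enhance(p, weight = w, ssi_ref = ref)
    mean(e$pixels[m]) - mean(e$pixels[!m])
  }, numeric(1))
  expect_true(all(diff(contrasts) >= -1e-9))
  expect_error(enhance(p, weight = 0.9), "0.8")
})
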