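# Synthetic mammographic phantoms: smooth low-frequency breast-tissue
# background plus small bright blobs whose morphology and spatial
# arrangement differ between the benign and malignant classes, with
# pixel-level ground truth.  Every stage of the pipeline is testable on
# these patches without any clinical image database.

#' Specification of a synthetic phantom patch
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: 160 x 160 px at 70 um (so one full clinical 1 cm^2 block covers
#' the cluster), a 12-bit intensity scale, a smooth background field with
#' correlation length half the patch, additive white noise of sd 5, and a
#' cluster of bright blobs.  Benign clusters are round, uniformly sized
#' and dispersed; malignant clusters (reached by `effect = 1` in
#' [generate_dataset()]) are more numerous, pleomorphic, size-varied and
#' tightly / linearly arranged.
#'
#' @param shape Patch `(rows, cols)`.
#' @param spacing_um Pixel spacing (um).
#' @param bit_depth Bit depth (8, 12, 16).
#' @param base Background base level (native units).
#' @param lf_amplitude Amplitude (sd) of the low-frequency tissue field.
#' @param lf_corr_px Correlation length of the field in pixels.
#' @param noise_sd White-noise sd (the sigma that blob contrast is
#'   measured against).
#' @param n_blobs Integer range `c(min, max)` of blob count.
#' @param diameter_px Range of blob diameters in pixels.
#' @param contrast Range of blob peak contrasts (native units).
#' @param irregularity Boundary irregularity in `[0, 1]` (0 = smooth
#'   ellipse).
#' @param dispersion_px Cluster dispersion radius in pixels.
#' @param geometry Cluster arrangement: `"scattered"`, `"linear"` or
#'   `"branching"`.
#' @param label Class label attached to the sample.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(160L, 160L), spacing_um = 70,
                         bit_depth = 12L, base = 500, lf_amplitude = 60,
                         lf_corr_px = 80, noise_sd = 5,
                         n_blobs = c(6L, 10L), diameter_px = c(4, 9),
                         contrast = c(25, 60), irregularity = 0.15,
                         dispersion_px = 45, geometry = "scattered",
                         label = "benign", seed = 1L) {
  stopifnot(all(n_blobs >= 0), all(diameter_px >= 1), all(contrast > 0),
            irregularity >= 0, irregularity <= 1,
            geometry %in% c("scattered", "linear", "branching"))
  structure(list(shape = as.integer(shape), spacing_um = spacing_um,
                 bit_depth = as.integer(bit_depth), base = base,
                 lf_amplitude = lf_amplitude, lf_corr_px = lf_corr_px,
                 noise_sd = noise_sd, n_blobs = as.integer(n_blobs),
                 diameter_px = diameter_px, contrast = contrast,
                 irregularity = irregularity, dispersion_px = dispersion_px,
                 geometry = geometry, label = label, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Class-conditional spec for the malignant end of the morphology axes
#'
#' More and smaller-to-larger (size-varied) blobs, irregular boundaries,
#' tight linear arrangement — the axes that make cluster area, blob size,
#' density and centroid-distance spread the true class signal carriers.
#'
#' @param seed Seed.
#' @param effect Interpolation in `[0, 1]` between the benign spec (0) and
#'   the fully malignant spec (1).
#' @param ... Overrides passed to [phantom_spec()].
#' @return A `phantom_spec` with `label = "malignant"`.
#' @export
malignant_spec <- function(seed = 1L, effect = 1, ...) {
  b <- phantom_spec(seed = seed)
  m <- list(n_blobs = c(13L, 19L), diameter_px = c(3, 13),
            contrast = c(25, 60), irregularity = 0.6, dispersion_px = 25)
  lerp <- function(a, z) a + effect * (z - a)
  spec <- phantom_spec(
    n_blobs = as.integer(round(lerp(b$n_blobs, m$n_blobs))),
    diameter_px = lerp(b$diameter_px, m$diameter_px),
    contrast = lerp(b$contrast, m$contrast),
    irregularity = lerp(b$irregularity, m$irregularity),
    dispersion_px = lerp(b$dispersion_px, m$dispersion_px),
    geometry = if (effect > 0) "linear" else "scattered",
    label = "malignant", seed = seed, ...)
  spec
}

# radial profile of one (possibly irregular) blob: returns a function of
# polar angle giving the local radius, for semi-axes a >= b and harmonic
# perturbations scaled by the irregularity
blob_radius_fun <- function(a, b, theta0, irr, phases) {
  function(theta) {
    t_ <- theta - theta0
    r_ell <- a * b / sqrt((b * cos(t_))^2 + (a * sin(t_))^2)
    bump <- 0.5 * sin(2 * theta + phases[1]) +
            0.3 * sin(3 * theta + phases[2]) +
            0.2 * sin(5 * theta + phases[3])
    pmax(r_ell * (1 + 0.5 * irr * bump), 0.5)
  }
}

#' Generate one synthetic phantom sample
#'
#' Background = base + smoothed Gaussian field + white noise; blobs are
#' anti-aliased ellipses deformed by the irregularity parameter, placed by
#' the cluster geometry, added on top and clipped to the bit-depth range.
#' Intensities are rounded to integers, as in acquired mammograms.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_sample`: `patch`
#'   ([image_patch()]), `truth_mask` (logical), `outline` (dilated convex
#'   hull of the planted blobs, as an n x 2 vertex matrix), `label`,
#'   `blob_truth` (per-blob records with centre, diameter, contrast) and
#'   `spec`.
#' @export
generate_patch <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  with_local_seed(spec$seed, {
    # smooth low-frequency field: coarse white noise, bicubic upsampled
    step <- max(4L, as.integer(spec$lf_corr_px %/% 2L))
    row_at <- seq(-step, nr + step, by = step)
    col_at <- seq(-step, nc + step, by = step)
    coarse <- matrix(stats::rnorm(length(row_at) * length(col_at)),
                     length(row_at), length(col_at))
    field <- spline_resize(coarse, row_at, col_at, nr, nc)
    field <- field / max(stats::sd(field), 1e-9) * spec$lf_amplitude
    bg <- spec$base + field +
      matrix(stats::rnorm(nr * nc, sd = spec$noise_sd), nr, nc)

    n_b <- if (spec$n_blobs[1] == spec$n_blobs[2]) spec$n_blobs[1] else
      sample(spec$n_blobs[1]:spec$n_blobs[2], 1L)
    centre <- c(nr, nc) / 2
    pos <- matrix(0, 0, 2)
    if (n_b > 0L) {
      R <- spec$dispersion_px
      if (spec$geometry == "scattered") {
        rr <- R * sqrt(stats::runif(n_b)); th <- stats::runif(n_b, 0, 2 * pi)
        pos <- cbind(centre[1] + rr * sin(th), centre[2] + rr * cos(th))
      } else if (spec$geometry == "linear") {
        phi <- stats::runif(1, 0, pi)
        t_ <- stats::runif(n_b, -R, R)
        jit <- stats::rnorm(n_b, sd = R / 6)
        pos <- cbind(centre[1] + t_ * sin(phi) + jit * cos(phi),
                     centre[2] + t_ * cos(phi) - jit * sin(phi))
      } else {  # branching: two arms sharing the cluster centre
        phi <- stats::runif(1, 0, pi)
        arm <- sample(c(0, pi / 4), n_b, replace = TRUE)
        t_ <- stats::runif(n_b, 0, R)
        jit <- stats::rnorm(n_b, sd = R / 8)
        ang <- phi + arm
        pos <- cbind(centre[1] + t_ * sin(ang) + jit * cos(ang),
                     centre[2] + t_ * cos(ang) - jit * sin(ang))
      }
      # keep blobs inside the patch with a margin; resample misplaced ones
      mrg <- max(spec$diameter_px) / 2 + 2
      for (i in seq_len(n_b)) {
        tries <- 0L
        while ((pos[i, 1] < mrg || pos[i, 1] > nr - mrg ||
                pos[i, 2] < mrg || pos[i, 2] > nc - mrg)) {
          tries <- tries + 1L
          if (tries > 50L) stop("cannot place blob inside patch", call. = FALSE)
          rr <- R * sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
          pos[i, ] <- centre + rr * c(sin(th), cos(th))
        }
      }
    }

    truth <- matrix(FALSE, nr, nc)
    img <- bg
    blob_truth <- list()
    if (n_b > 0L) for (i in seq_len(n_b)) {
      dmax <- stats::runif(1, spec$diameter_px[1], spec$diameter_px[2])
      aspect <- stats::runif(1, max(0.45, 1 - spec$irregularity), 1)
      a <- dmax / 2; b_ <- a * aspect
      con <- stats::runif(1, spec$contrast[1], spec$contrast[2])
      rfun <- blob_radius_fun(a, b_, stats::runif(1, 0, pi),
                              spec$irregularity, stats::runif(3, 0, 2 * pi))
      half <- ceiling(a * 1.9) + 2L
      rs <- max(1L, floor(pos[i, 1] - half)):min(nr, ceiling(pos[i, 1] + half))
      cs <- max(1L, floor(pos[i, 2] - half)):min(nc, ceiling(pos[i, 2] + half))
      dr <- outer(rs - pos[i, 1], rep(1, length(cs)))
      dc <- outer(rep(1, length(rs)), cs - pos[i, 2])
      dist <- sqrt(dr^2 + dc^2)
      rloc <- matrix(rfun(atan2(dc, dr)), length(rs), length(cs))
      cover <- pmin(pmax(rloc - dist + 0.5, 0), 1)   # 1-px anti-aliased edge
      img[rs, cs] <- img[rs, cs] + con * cover
      inblob <- cover >= 0.5
      truth[rs, cs] <- truth[rs, cs] | inblob
      blob_truth[[i]] <- list(centre = pos[i, ], diameter = dmax,
                              contrast = con, area_px = sum(inblob))
    }
    img <- round(pmin(pmax(img, 0), 2^spec$bit_depth - 1))
    patch <- image_patch(img, spec$spacing_um, spec$bit_depth,
                         id = sprintf("phantom_%s_%d", spec$label, spec$seed))
    outline <- if (any(truth)) {
      px <- which(truth, arr.ind = TRUE)
      h <- grDevices::chull(px[, 2], px[, 1])
      hv <- px[h, , drop = FALSE]
      ctr <- colMeans(px)
      # dilate the hull outward by 5 px from the hull centroid
      d <- sweep(hv, 2, ctr)
      nn <- sqrt(rowSums(d^2)); nn[nn == 0] <- 1
      hv <- sweep(hv + 5 * d / nn, 2, c(1, 1))   # to 0-based
      hv[, 1] <- pmin(pmax(hv[, 1], 0), nr - 1)
      hv[, 2] <- pmin(pmax(hv[, 2], 0), nc - 1)
      unname(hv)
    } else NULL
    structure(list(patch = patch, truth_mask = truth, outline = outline,
                   label = spec$label, blob_truth = blob_truth, spec = spec),
              class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s, %d blobs, %d truth px\n", x$label,
              length(x$blob_truth), sum(x$truth_mask)))
  invisible(x)
}

#' Generate a labelled synthetic dataset
#'
#' Benign samples follow the default benign [phantom_spec()]; malignant
#' samples follow [malignant_spec()] interpolated by `effect` (0 gives
#' distributions identical to the benign class, 1 the maximally distinct
#' defaults).  Per-sample seeds are derived from the master seed by a
#' counter scheme, so the dataset is reproducible and extensible.
#'
#' @param n_benign,n_malignant Sample counts.
#' @param effect Class separation in `[0, 1]`.
#' @param seed Master seed.
#' @param ... Shared overrides passed to both class specs (e.g. `shape`).
#' @return List of `phantom_sample` objects, benign first.
#' @export
generate_dataset <- function(n_benign, n_malignant, effect = 1, seed = 1L, ...) {
  out <- vector("list", n_benign + n_malignant)
  for (i in seq_len(n_benign)) {
    sp <- phantom_spec(seed = derive_seed(seed, i), ...)
    out[[i]] <- generate_patch(sp)
    out[[i]]$patch$id <- sprintf("benign_%03d", i)
  }
  for (j in seq_len(n_malignant)) {
    sp <- malignant_spec(seed = derive_seed(seed, n_benign + j), effect = effect, ...)
    out[[n_benign + j]] <- generate_patch(sp)
    out[[n_benign + j]]$patch$id <- sprintf("malignant_%03d", j)
  }
  out
}
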