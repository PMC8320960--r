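# Structured configuration and the end-to-end pipeline driver:
# enhance -> segment -> cluster rules -> features (unenhanced + enhanced
# variants) -> alpha/beta feature selection -> ensemble & stacked
# classification with cross-validated reporting.

#' Pipeline configuration
#'
#' All tunables of the pipeline with defaults equal to the method's
#' printed parameterization: 30-px background subregions, 5% top
#' fractions, 10% fallback coverage, 3x3 and 2x2 erosions (fixed in code),
#' at least 3 MCs per 1 cm^2 block, enhancement weight 0.10 at 3 levels.
#'
#' @param subregion_px Background subregion side (px).
#' @param top_fraction Fraction for Images A and B.
#' @param fallback_fraction Image-A coverage below which the low-contrast
#'   fallback fires.
#' @param min_per_block Minimum MCs per block.
#' @param block_side Block side override in px; `NULL` derives the
#'   clinical 1 cm^2 side from the pixel spacing (the non-clinical
#'   100-px-block variant is `block_side = 100`).
#' @param enhance_weight Wavelet enhancement weight in (0, 0.8].
#' @param enhance_levels Decomposition levels.
#' @param ssi_ref Reference SSI (`NULL` = default synthetic reference).
#' @param crop_margin_px ROI crop margin around annotations.
#' @param meta Stacking meta-learner, `"nb"` or `"ada"`.
#' @param scheme Cross-validation scheme, `"10fold"` or `"loocv"`.
#' @param seeds Seed values of the repeated CV runs.
#' @param select `"cfs"` (per-training-fold alpha/beta intersection) or
#'   `"none"`.
#' @param seed Master seed of the run.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(subregion_px = 30L, top_fraction = 0.05,
                            fallback_fraction = 0.10, min_per_block = 3L,
                            block_side = NULL, enhance_weight = 0.10,
                            enhance_levels = 3L, ssi_ref = NULL,
                            crop_margin_px = 10L,
                            meta = "nb", scheme = "10fold", seeds = 1:10,
                            select = "cfs", seed = 1L) {
  structure(list(subregion_px = as.integer(subregion_px),
                 top_fraction = top_fraction,
                 fallback_fraction = fallback_fraction,
                 min_per_block = as.integer(min_per_block),
                 block_side = if (is.null(block_side)) NULL else as.integer(block_side),
                 enhance_weight = enhance_weight,
                 enhance_levels = as.integer(enhance_levels),
                 ssi_ref = ssi_ref,
                 crop_margin_px = as.integer(crop_margin_px),
                 meta = meta, scheme = scheme, seeds = as.integer(seeds),
                 select = select, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The round trip through the file is lossless.
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# stable short hash of the configuration (FNV-1a over its serialised text)
config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(unclass(config), digits.d = 15)),
               collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(txt)) h <- ((h + b) * 16777619) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full MC-cluster classification pipeline
#'
#' For every labelled sample the patch is segmented twice — from the
#' unenhanced and the wavelet-enhanced patch — and the 51-feature vector
#' extracted from each variant (tables alpha and beta).  Samples with no
#' surviving blob in either variant are excluded and counted.  Feature
#' selection (CFS + best-first intersection of alpha and beta) is
#' reported on the full tables and refitted inside every training fold of
#' the cross-validated ensemble-vote and stacked-generalization
#' classifiers.
#'
#' @param samples List of `phantom_sample` objects, or a list of lists
#'   with fields `patch` (an [image_patch()]) and `label`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for artifacts (masks, feature
#'   tables, selection and report JSON).
#' @return An object of class `pipeline_report`.
#' @export
run_pipeline <- function(samples, config = pipeline_config(), out_dir = NULL) {
  if (length(samples) < 10L)
    stop("at least 10 labelled samples required for cross-validation",
         call. = FALSE)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  patches <- lapply(samples, `[[`, "patch")
  labels <- vapply(samples, function(s) s$label, character(1))
  ids <- vapply(patches, function(p) p$id, character(1))

  seg_u <- vector("list", length(samples))
  seg_e <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    seg_u[[i]] <- segment_patch(patches[[i]], enhance = FALSE, config)$mask
    seg_e[[i]] <- segment_patch(patches[[i]], enhance = TRUE, config)$mask
    if (!is.null(out_dir)) {
      write_mask(seg_u[[i]], file.path(out_dir, paste0(ids[i], "_seg.png")))
      write_mask(seg_e[[i]], file.path(out_dir, paste0(ids[i], "_seg_enh.png")))
    }
  }
  ok <- vapply(seq_along(samples), function(i)
    any(seg_u[[i]]) && any(seg_e[[i]]), logical(1))
  excluded <- ids[!ok]
  if (sum(ok) < 10L)
    stop("fewer than 10 segmentable samples", call. = FALSE)

  tab_a <- extract_feature_table(patches[ok], seg_u[ok], labels[ok], ids[ok])
  tab_b <- extract_feature_table(patches[ok], seg_e[ok], labels[ok], ids[ok])
  selection <- intersect_protocol(tab_a, tab_b)

  sel_mode <- if (identical(config$select, "cfs")) "cfs" else "none"
  stacked <- cross_validate(tab_b, model = "stack", scheme = config$scheme,
                            seeds = config$seeds, meta = config$meta,
                            select = sel_mode, table_beta = tab_a)
  ensemble <- cross_validate(tab_b, model = "ensemble", scheme = config$scheme,
                             seeds = config$seeds,
                             select = sel_mode, table_beta = tab_a)

  report <- structure(list(
    config = config, config_hash = config_hash(config), seed = config$seed,
    n_samples = length(samples), n_used = sum(ok),
    excluded_ids = excluded,
    selection = list(alpha = selection$alpha$subset,
                     beta = selection$beta$subset,
                     common = selection$subset),
    stacked = stacked, ensemble = ensemble),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    write_feature_table(tab_a, file.path(out_dir, "features_unenhanced.csv"))
    write_feature_table(tab_b, file.path(out_dir, "features_enhanced.csv"))
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(feature_registry(), file.path(out_dir, "feature_registry.csv"),
                     row.names = FALSE)
  }
  report
}

# plain-list view of a pipeline report (for JSON serialisation)
report_to_list <- function(report) {
  list(config = unclass(report$config), config_hash = report$config_hash,
       seed = report$seed, n_samples = report$n_samples,
       n_used = report$n_used, excluded_ids = report$excluded_ids,
       selection = report$selection,
       stacked = unclass(report$stacked)[c("accuracy_mean", "accuracy_sd",
                                           "auc_mean", "auc_sd", "accuracy", "auc")],
       ensemble = unclass(report$ensemble)[c("accuracy_mean", "accuracy_sd",
                                             "auc_mean", "auc_sd", "accuracy", "auc")])
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d samples (%d used, %d excluded), config %s\n",
              x$n_samples, x$n_used, length(x$excluded_ids), x$config_hash))
  cat("  selected features:", paste(x$selection$common, collapse = ", "), "\n")
  cat("  stacked:  "); print(x$stacked)
  cat("  ensemble: "); print(x$ensemble)
  invisible(x)
}
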