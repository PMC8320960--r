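# Correlation-based feature selection (CFS) with best-first subset search,
# the alpha/beta intersection protocol, and fold-stability reporting.
#
# Subset merit rewards features correlated with the class and penalises
# mutually redundant features:
#   Merit(S) = k * mean(r_cf) / sqrt(k + k (k-1) mean(r_ff))
# with k = |S|.  Correlations are absolute point-biserial (feature vs
# binary class) and Pearson (feature-feature) — a continuous-data
# simplification of the discretised symmetric-uncertainty variant, kept
# swappable behind the correlation-table interface.

#' Correlation tables for CFS
#'
#' @param x Numeric matrix / data frame of features (samples x features).
#' @param y Binary class factor or vector.
#' @return An object of class `correlation_tables`: `r_cf` (named vector
#'   of absolute feature-class correlations), `r_ff` (absolute
#'   feature-feature correlation matrix, unit diagonal) and `names`.
#' @export
correlation_tables <- function(x, y) {
  x <- as.matrix(x)
  yb <- as.numeric(factor(y)) - 1
  if (length(unique(yb)) != 2L) stop("class must be binary", call. = FALSE)
  r_cf <- abs(suppressWarnings(stats::cor(x, yb)))[, 1]
  r_cf[is.na(r_cf)] <- 0   # zero-variance features carry no signal
  r_ff <- abs(suppressWarnings(stats::cor(x)))
  r_ff[is.na(r_ff)] <- 0
  diag(r_ff) <- 1
  structure(list(r_cf = r_cf, r_ff = r_ff,
                 names = colnames(x) %||% paste0("f", seq_len(ncol(x)))),
            class = "correlation_tables")
}

#' CFS merit of a feature subset
#'
#' @param subset Integer indices (or names) of the subset; the empty
#'   subset has merit 0.
#' @param tables A `correlation_tables`.
#' @return Scalar merit (non-negative).
#' @export
cfs_merit <- function(subset, tables) {
  stopifnot(inherits(tables, "correlation_tables"))
  if (is.character(subset)) subset <- match(subset, tables$names)
  k <- length(subset)
  if (k == 0L) return(0)
  rcf <- mean(tables$r_cf[subset])
  if (k == 1L) return(rcf)
  rff_sub <- tables$r_ff[subset, subset]
  rff <- mean(rff_sub[upper.tri(rff_sub)])
  denom <- sqrt(k + k * (k - 1) * rff)
  if (denom <= 0) return(0)
  k * rcf / denom
}

#' Best-first search over feature subsets
#'
#' Bidirectional greedy hill-climbing with backtracking: starting from the
#' empty set, the open list is expanded at its best-merit node by all
#' single-feature additions and deletions; the search stops after
#' `stale_limit` consecutive expansions that fail to improve the best
#' merit found.  Deterministic: ties are broken by feature order.
#'
#' @param tables A `correlation_tables`.
#' @param stale_limit Consecutive non-improving expansions tolerated
#'   (default 5).
#' @return An object of class `selection_result`: `subset` (feature names,
#'   registry order), `indices`, `merit`.
#' @export
best_first <- function(tables, stale_limit = 5L) {
  stopifnot(inherits(tables, "correlation_tables"))
  p <- length(tables$r_cf)
  key_of <- function(s) paste0("s", paste(s, collapse = ","))
  visited <- new.env(parent = emptyenv())
  open_keys <- character(0); open_merit <- numeric(0); open_sets <- list()
  push <- function(s) {
    k <- key_of(s)
    if (!is.null(visited[[k]])) return(invisible(NULL))
    visited[[k]] <- TRUE
    open_keys <<- c(open_keys, k)
    open_merit <<- c(open_merit, cfs_merit(s, tables))
    open_sets[[length(open_sets) + 1L]] <<- s
    invisible(NULL)
  }
  push(integer(0))
  best_set <- integer(0); best_merit <- 0
  stale <- 0L
  while (length(open_keys) > 0L && stale <= stale_limit) {
    i <- which.max(open_merit)   # first max: deterministic tie-break
    s <- open_sets[[i]]; m <- open_merit[i]
    open_keys <- open_keys[-i]; open_merit <- open_merit[-i]
    open_sets[[i]] <- NULL
    if (m > best_merit + 1e-12) {
      best_merit <- m; best_set <- s; stale <- 0L
    } else stale <- stale + 1L
    for (f in seq_len(p)) {
      child <- if (f %in% s) sort(setdiff(s, f)) else sort(c(s, f))
      push(child)
    }
  }
  structure(list(subset = tables$names[best_set], indices = best_set,
                 merit = best_merit),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features, merit %.4f: %s\n",
              length(x$indices), x$merit, paste(x$subset, collapse = ", ")))
  invisible(x)
}

# split a feature table into X (numeric matrix) and y (factor)
table_xy <- function(table) {
  feat <- setdiff(names(table), c("id", "label"))
  list(x = as.matrix(table[, feat, drop = FALSE]),
       y = droplevels(factor(table$label)))
}

#' CFS + best-first selection on a feature table
#'
#' @param table Feature table (`id`, `label`, feature columns).
#' @param stale_limit Best-first stale limit.
#' @return A `selection_result`.
#' @export
select_features <- function(table, stale_limit = 5L) {
  xy <- table_xy(table)
  best_first(correlation_tables(xy$x, xy$y), stale_limit)
}

#' Intersection protocol over unenhanced / enhanced feature tables
#'
#' Runs CFS + best-first on the table extracted from unenhanced patches
#' (group alpha) and on the table from enhanced patches (group beta) and
#' returns their common features.  An empty intersection falls back to
#' alpha with a warning.
#'
#' @param table_unenhanced,table_enhanced Feature tables sharing the
#'   registry.
#' @return A `selection_result` with the intersection subset and fields
#'   `alpha`, `beta` holding the per-table selections.
#' @export
intersect_protocol <- function(table_unenhanced, table_enhanced) {
  a <- select_features(table_unenhanced)
  b <- select_features(table_enhanced)
  common <- intersect(a$subset, b$subset)
  if (!length(common)) {
    warning("empty alpha/beta intersection; falling back to alpha")
    common <- a$subset
  }
  xy <- table_xy(table_unenhanced)
  idx <- match(common, colnames(xy$x))
  structure(list(subset = common, indices = idx,
                 merit = cfs_merit(idx, correlation_tables(xy$x, xy$y)),
                 alpha = a, beta = b),
            class = "selection_result")
}

#' Fold-stability of the feature selection
#'
#' Runs selection on the training portion of each stratified fold and
#' reports the per-fold subsets, the consensus (features selected in more
#' than half the folds) and the mean pairwise Jaccard similarity.
#'
#' @param table Feature table.
#' @param n_folds Number of stratified folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return List with `fold_subsets`, `consensus`, `jaccard`.
#' @export
stability_check <- function(table, n_folds = 10L, seed = 1L) {
  xy <- table_xy(table)
  if (min(base::table(xy$y)) < n_folds)
    stop("a class has fewer members than folds", call. = FALSE)
  folds <- make_folds(xy$y, n_folds, seed)
  subsets <- lapply(seq_len(n_folds), function(k) {
    tr <- folds != k
    best_first(correlation_tables(xy$x[tr, , drop = FALSE], xy$y[tr]))$subset
  })
  all_feat <- unique(unlist(subsets))
  votes <- vapply(all_feat, function(f)
    sum(vapply(subsets, function(s) f %in% s, logical(1))), numeric(1))
  consensus <- all_feat[votes > n_folds / 2]
  jac <- if (n_folds > 1L) {
    pairs <- utils::combn(n_folds, 2)
    mean(apply(pairs, 2, function(pp) {
      a <- subsets[[pp[1]]]; b <- subsets[[pp[2]]]
      u <- union(a, b)
      if (!length(u)) 1 else length(intersect(a, b)) / length(u)
    }))
  } else 1
  list(fold_subsets = subsets, consensus = consensus, jaccard = jac)
}
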