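# Benign/malignant classification: nine base learners, majority-vote
# ensemble, stacked generalization with a naive Bayes (or AdaBoost)
# meta-classifier, stratified cross-validation over seed runs, and
# rank-based ROC AUC.

CLASS_LEVELS <- c("benign", "malignant")

#' Names and printed hyperparameters of the nine base learners
#'
#' kNN with k = 5; an MLP with (n_features + n_classes)/2 hidden units; a
#' pruned classification tree; a 100-tree random forest; naive Bayes; and
#' SVMs with RBF, sigmoid, linear and polynomial kernels.  All other
#' hyperparameters are library defaults.
#'
#' @return Character vector of the nine learner names.
#' @export
base_learner_names <- function() {
  c("knn", "mlp", "tree", "rf", "nb",
    "svm_rbf", "svm_sigmoid", "svm_linear", "svm_poly")
}

# z-score parameters fitted on training data (guarding zero variance)
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sg <- apply(x, 2, stats::sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  list(mu = mu, sg = sg)
}
apply_scaler <- function(sc, x) sweep(sweep(x, 2, sc$mu), 2, sc$sg, "/")

# Fit one base learner.  x: numeric matrix; y: factor with CLASS_LEVELS.
fit_base <- function(name, x, y) {
  y <- factor(y, levels = CLASS_LEVELS)
  switch(name,
    knn = {
      sc <- fit_scaler(x)
      list(kind = "knn", sc = sc, x = apply_scaler(sc, x), y = y)
    },
    mlp = {
      sc <- fit_scaler(x)
      size <- max(1L, round((ncol(x) + 2L) / 2))
      fit <- nnet::nnet(apply_scaler(sc, x), stats::model.matrix(~ y - 1)[, 2],
                        size = size, trace = FALSE, maxit = 200,
                        MaxNWts = 10000, entropy = TRUE)
      list(kind = "mlp", sc = sc, fit = fit)
    },
    tree = {
      d <- data.frame(x, .y = y, check.names = FALSE)
      list(kind = "tree", fit = rpart::rpart(.y ~ ., data = d, method = "class"))
    },
    rf = list(kind = "rf",
              fit = randomForest::randomForest(x, y, ntree = 100L)),
    nb = list(kind = "nb", fit = e1071::naiveBayes(x, y)),
    svm_rbf = list(kind = "svm",
                   fit = e1071::svm(x, y, kernel = "radial")),
    svm_sigmoid = list(kind = "svm",
                       fit = e1071::svm(x, y, kernel = "sigmoid")),
    svm_linear = list(kind = "svm",
                      fit = e1071::svm(x, y, kernel = "linear")),
    svm_poly = list(kind = "svm",
                    fit = e1071::svm(x, y, kernel = "polynomial")),
    stop("unknown learner: ", name, call. = FALSE))
}

# Predict classes (factor) and a malignancy score for one base learner.
predict_base <- function(model, x) {
  out <- switch(model$kind,
    knn = {
      xs <- apply_scaler(model$sc, x)
      cl <- class::knn(model$x, xs, model$y, k = 5L, prob = TRUE)
      pr <- attr(cl, "prob")
      score <- ifelse(cl == "malignant", pr, 1 - pr)
      list(class = cl, score = score)
    },
    mlp = {
      p <- as.numeric(stats::predict(model$fit, apply_scaler(model$sc, x)))
      list(class = factor(ifelse(p > 0.5, "malignant", "benign"),
                          levels = CLASS_LEVELS), score = p)
    },
    tree = {
      d <- data.frame(x, check.names = FALSE)
      p <- stats::predict(model$fit, d, type = "prob")[, "malignant"]
      list(class = factor(ifelse(p > 0.5, "malignant", "benign"),
                          levels = CLASS_LEVELS), score = p)
    },
    rf = {
      p <- stats::predict(model$fit, x, type = "prob")[, "malignant"]
      list(class = factor(ifelse(p > 0.5, "malignant", "benign"),
                          levels = CLASS_LEVELS), score = p)
    },
    nb = {
      p <- stats::predict(model$fit, x, type = "raw")[, "malignant"]
      list(class = factor(ifelse(p > 0.5, "malignant", "benign"),
                          levels = CLASS_LEVELS), score = p)
    },
    svm = {
      cl <- stats::predict(model$fit, x, decision.values = TRUE)
      dv <- attr(cl, "decision.values")[, 1]
      # decision values are signed toward the first training level
      flip <- if (grepl("^malignant", colnames(attr(cl, "decision.values"))[1])) 1 else -1
      list(class = factor(as.character(cl), levels = CLASS_LEVELS),
           score = flip * dv)
    },
    stop("unknown model kind"))
  out$class <- factor(as.character(out$class), levels = CLASS_LEVELS)
  out
}

#' Majority-vote malignancy estimate from nine base votes
#'
#' The malignancy fraction is the number of malignant votes over the total
#' (9); the final label is malignant iff the fraction exceeds 0.5 (a tie
#' is impossible with an odd vote count).  Eight malignant votes out of
#' nine give 8/9, reported clinically as 89% malignancy.
#'
#' @param votes Vector of 9 votes: logical, 0/1, or the class labels.
#' @return List with `fraction` in `[0, 1]` and `label`.
#' @export
ensemble_vote <- function(votes) {
  if (length(votes) != 9L) stop("exactly 9 votes required", call. = FALSE)
  v <- if (is.character(votes) || is.factor(votes))
    as.character(votes) == "malignant" else as.logical(votes)
  if (any(is.na(v))) stop("invalid votes", call. = FALSE)
  frac <- mean(v)
  list(fraction = frac,
       label = if (frac > 0.5) "malignant" else "benign")
}

#' Fit the nine base learners
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Class factor (`benign` / `malignant`), both classes present.
#' @return Named list of fitted base models.
#' @export
fit_base_learners <- function(x, y) {
  y <- factor(y, levels = CLASS_LEVELS)
  if (nlevels(droplevels(y)) < 2L)
    stop("single-class training data", call. = FALSE)
  models <- lapply(base_learner_names(), fit_base, x = x, y = y)
  names(models) <- base_learner_names()
  models
}

# 9-column vote matrix (factor levels as character) for given data
base_votes <- function(models, x) {
  v <- vapply(models, function(m) as.character(predict_base(m, x)$class),
              character(nrow(x)))
  matrix(v, nrow = nrow(x), ncol = length(models),
         dimnames = list(NULL, names(models)))
}

#' Fit a stacked-generalization classifier
#'
#' The nine base learners are the level-0 models.  Meta-features are their
#' out-of-fold predictions from an internal stratified 5-fold split of the
#' training data (so the meta-learner never sees a base prediction made on
#' a sample that base model was trained on).  The meta-classifier is naive
#' Bayes (default, votes treated as nominal) or a small AdaBoost.M1 over
#' decision stumps.
#'
#' @param x Training feature matrix.
#' @param y Training class factor.
#' @param meta `"nb"` or `"ada"`.
#' @param inner_folds Internal folds for meta-feature generation (default 5).
#' @param seed Seed for the internal split.
#' @return An object of class `stacked_model`.
#' @export
stack_fit <- function(x, y, meta = c("nb", "ada"), inner_folds = 5L, seed = 1L) {
  meta <- match.arg(meta)
  y <- factor(y, levels = CLASS_LEVELS)
  if (min(base::table(y)) < 2L) stop("need at least 2 samples per class", call. = FALSE)
  inner_folds <- min(inner_folds, min(base::table(y)))
  folds <- make_folds(y, inner_folds, seed)
  meta_x <- matrix(NA_character_, nrow(x), 9L,
                   dimnames = list(NULL, base_learner_names()))
  for (k in seq_len(inner_folds)) {
    tr <- folds != k
    mods <- fit_base_learners(x[tr, , drop = FALSE], y[tr])
    meta_x[!tr, ] <- base_votes(mods, x[!tr, , drop = FALSE])
  }
  meta_df <- as.data.frame(lapply(as.data.frame(meta_x),
                                  factor, levels = CLASS_LEVELS))
  meta_fit <- if (meta == "nb") {
    e1071::naiveBayes(meta_df, y, laplace = 1)
  } else {
    adaboost_fit(ifelse(meta_x == "malignant", 1, 0), y)
  }
  structure(list(base = fit_base_learners(x, y), meta = meta_fit,
                 meta_kind = meta, meta_features = meta_x),
            class = "stacked_model")
}

#' Predict with a stacked classifier
#'
#' @param object A `stacked_model`.
#' @param x Feature matrix.
#' @param ... Unused.
#' @return List with `class` (factor) and `score` (malignancy
#'   probability from the meta-learner).
#' @export
predict.stacked_model <- function(object, x, ...) {
  votes <- base_votes(object$base, x)
  if (object$meta_kind == "nb") {
    vd <- as.data.frame(lapply(as.data.frame(votes),
                               factor, levels = CLASS_LEVELS))
    p <- stats::predict(object$meta, vd, type = "raw")[, "malignant"]
  } else {
    p <- adaboost_predict(object$meta, ifelse(votes == "malignant", 1, 0))
  }
  list(class = factor(ifelse(p > 0.5, "malignant", "benign"),
                      levels = CLASS_LEVELS),
       score = p)
}

# --- AdaBoost.M1 over decision stumps (meta-learner option) ---------------

adaboost_fit <- function(x, y, rounds = 30L) {
  y01 <- ifelse(y == "malignant", 1, -1)
  n <- nrow(x); w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  d <- data.frame(x, check.names = FALSE)
  for (t in seq_len(rounds)) {
    fit <- rpart::rpart(factor(y01) ~ ., data = d, weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- ifelse(stats::predict(fit, d, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != y01))
    if (err <= 1e-10) { stumps <- c(stumps, list(fit)); alphas <- c(alphas, 10); break }
    if (err >= 0.5) break
    a <- 0.5 * log((1 - err) / err)
    stumps <- c(stumps, list(fit)); alphas <- c(alphas, a)
    w <- w * exp(-a * y01 * pred)
    w <- w / sum(w)
  }
  if (!length(stumps)) {  # nothing better than chance: constant majority
    maj <- if (mean(y01) >= 0) 1 else -1
    return(list(stumps = list(), alphas = numeric(0), majority = maj))
  }
  list(stumps = stumps, alphas = alphas, majority = NULL)
}

adaboost_predict <- function(model, x) {
  d <- data.frame(x, check.names = FALSE)
  if (!length(model$stumps))
    return(rep(if (model$majority > 0) 1 else 0, nrow(d)))
  margin <- rep(0, nrow(d))
  for (t in seq_along(model$stumps)) {
    pred <- ifelse(stats::predict(model$stumps[[t]], d, type = "class") == "1", 1, -1)
    margin <- margin + model$alphas[t] * pred
  }
  1 / (1 + exp(-2 * margin))   # logistic link on the boosting margin
}

# --- cross-validation ------------------------------------------------------

#' Stratified fold assignment
#'
#' Each class's members are shuffled and dealt round-robin into `k` folds,
#' so every fold holds roughly the class proportions of the whole sample
#' and every observation appears in exactly one fold.
#'
#' @param y Class factor.
#' @param k Number of folds.
#' @param seed Seed for the shuffle.
#' @return Integer fold id per observation.
#' @export
make_folds <- function(y, k, seed = 1L) {
  folds <- integer(length(y))
  with_local_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Rank-based area under the ROC curve
#'
#' Equals the trapezoidal area under the TPR-FPR curve over all score
#' thresholds and the normalised rank-sum statistic: the fraction of
#' (positive, negative) score pairs ranked concordantly, with half credit
#' for ties.
#'
#' @param scores Continuous malignancy scores.
#' @param labels Class labels (`malignant` is the positive class) or
#'   logicals.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.character(labels) || is.factor(labels))
    as.character(labels) == "malignant" else as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated evaluation of a classifier
#'
#' Stratified 10-fold cross-validation repeated over seed runs (seed 1 for
#' the first run, incremented by 1 each run), or a single deterministic
#' leave-one-out run.  Each observation is tested exactly once per run;
#' accuracy (%) and AUC are reported as mean and sd over the runs.  When
#' `select = "cfs"` the CFS + best-first selection is refitted on every
#' training fold (with the alpha/beta intersection when `table_beta` is
#' supplied), so no test information leaks into the feature choice.
#'
#' @param table Feature table (`id`, `label`, feature columns).
#' @param model `"stack"`, `"ensemble"` or one of the nine base learner
#'   names.
#' @param scheme `"10fold"` or `"loocv"`.
#' @param seeds Seed values for the repeated runs (default `1:10`).
#' @param meta Meta-learner for `"stack"`.
#' @param select `"none"` or `"cfs"`.
#' @param table_beta Optional second table (enhanced variant) for the
#'   per-fold intersection protocol.
#' @return An object of class `eval_report`.
#' @export
cross_validate <- function(table, model = "stack",
                           scheme = c("10fold", "loocv"), seeds = 1:10,
                           meta = "nb", select = c("none", "cfs"),
                           table_beta = NULL) {
  scheme <- match.arg(scheme)
  select <- match.arg(select)
  xy <- table_xy(table)
  y <- factor(as.character(xy$y), levels = CLASS_LEVELS)
  n <- length(y)
  if (nlevels(droplevels(y)) < 2L) stop("both classes required", call. = FALSE)
  if (scheme == "loocv") seeds <- seeds[1]
  n_folds <- if (scheme == "loocv") n else {
    k <- 10L
    if (min(base::table(y)) < k) {
      warning("a class has fewer members than folds; reducing fold count")
      k <- max(2L, min(base::table(y)))
    }
    k
  }
  acc <- auc <- numeric(length(seeds))
  for (si in seq_along(seeds)) {
    seed <- seeds[si]
    folds <- if (scheme == "loocv") seq_len(n) else make_folds(y, n_folds, seed)
    pred <- factor(rep(NA_character_, n), levels = CLASS_LEVELS)
    score <- numeric(n)
    for (k in seq_len(n_folds)) {
      tr <- folds != k
      feat_idx <- seq_len(ncol(xy$x))
      if (select == "cfs") {
        sel_a <- select_features(table[tr, , drop = FALSE])
        sel <- if (!is.null(table_beta)) {
          sb <- select_features(table_beta[tr, , drop = FALSE])
          common <- intersect(sel_a$subset, sb$subset)
          if (length(common)) common else sel_a$subset
        } else sel_a$subset
        if (length(sel)) feat_idx <- match(sel, colnames(xy$x))
      }
      xtr <- xy$x[tr, feat_idx, drop = FALSE]
      xte <- xy$x[!tr, feat_idx, drop = FALSE]
      with_local_seed(derive_seed(seed, k), {
        if (model == "stack") {
          fit <- stack_fit(xtr, y[tr], meta = meta, seed = derive_seed(seed, k))
          pr <- predict(fit, xte)
          pred[!tr] <- pr$class
          score[!tr] <- pr$score
        } else if (model == "ensemble") {
          mods <- fit_base_learners(xtr, y[tr])
          votes <- base_votes(mods, xte)
          fr <- apply(votes, 1L, function(v) ensemble_vote(v)$fraction)
          pred[!tr] <- factor(ifelse(fr > 0.5, "malignant", "benign"),
                              levels = CLASS_LEVELS)
          score[!tr] <- fr
        } else {
          m <- fit_base(model, xtr, y[tr])
          pr <- predict_base(m, xte)
          pred[!tr] <- pr$class
          score[!tr] <- pr$score
        }
      })
    }
    acc[si] <- 100 * mean(pred == y)
    auc[si] <- roc_auc(score, y)
  }
  structure(list(scheme = scheme, model = model, n_samples = n,
                 seeds = seeds,
                 accuracy = acc, auc = auc,
                 accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc) %|NA|% 0,
                 auc_mean = mean(auc), auc_sd = stats::sd(auc) %|NA|% 0),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s / %s on %d samples (%d run%s)\n",
              x$model, x$scheme, x$n_samples, length(x$seeds),
              if (length(x$seeds) > 1) "s" else ""))
  cat(sprintf("  accuracy %.2f +/- %.2f %%   AUC %.3f +/- %.3f\n",
              x$accuracy_mean, x$accuracy_sd, x$auc_mean, x$auc_sd))
  invisible(x)
}
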