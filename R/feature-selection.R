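# Feature selection: training-cohort standardization, Spearman redundancy
# filtering, and recursive feature elimination with cross-validated linear
# SVMs (RFECV).
#
# The SVM fits use a precomputed linear Gram matrix that is downdated as
# features are eliminated (K <- K - X_dropped X_dropped^T), which makes the
# elimination path over 2048 deep features tractable without changing the
# classifier: a soft-margin C-SVC with C = 1 solved by the compiled SMO
# routine in src/smo.cpp (validated against e1071's libsvm interface in the
# test suite).

#' Selection configuration
#'
#' @param spearman_cutoff absolute Spearman correlation above which a
#'   feature pair is redundant (default 0.85).
#' @param svm_C SVM regularization parameter (default 1).
#' @param cv_folds stratified cross-validation folds (default 10).
#' @param min_features minimum number of features retained (default 3).
#' @param rfe_step features dropped per elimination round while more than
#'   `rfe_step_until` remain; elimination proceeds one-by-one below that.
#'   Set `rfe_step = 1` for a pure single-step path.
#' @param rfe_step_until feature count at which elimination switches to
#'   single steps.
#' @param seed RNG seed for the fold assignment.
#' @return an `lg_selection_config`.
#' @export
selection_config <- function(spearman_cutoff = 0.85, svm_C = 1,
                             cv_folds = 10L, min_features = 3L,
                             rfe_step = 64L, rfe_step_until = 256L,
                             seed = 1L) {
  stopifnot(spearman_cutoff > 0, spearman_cutoff < 1, cv_folds >= 2,
            min_features >= 1, rfe_step >= 1, svm_C > 0)
  structure(list(spearman_cutoff = spearman_cutoff, svm_C = svm_C,
                 cv_folds = as.integer(cv_folds),
                 min_features = as.integer(min_features),
                 rfe_step = as.integer(rfe_step),
                 rfe_step_until = as.integer(rfe_step_until),
                 scoring = "accuracy", seed = as.integer(seed)),
            class = "lg_selection_config")
}

#' Fit / apply a per-column standardizer
#'
#' `fit_standardizer` learns column means and standard deviations on the
#' training matrix; `apply_standardizer` reuses those training statistics
#' on any cohort (never re-fitting, so cohort shift is preserved rather
#' than erased). Zero-variance columns get scale 1 with a warning.
#'
#' @param X numeric matrix (rows = patients).
#' @return `fit_standardizer`: an `lg_scaler`; `apply_standardizer`: the
#'   standardized matrix.
#' @export
fit_standardizer <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 2)
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  if (any(zero <- scale == 0)) {
    warning(sprintf("%d zero-variance column(s); scale set to 1", sum(zero)))
    scale[zero] <- 1
  }
  structure(list(center = center, scale = scale), class = "lg_scaler")
}

#' @rdname fit_standardizer
#' @param scaler an `lg_scaler` fitted on the training cohort.
#' @export
apply_standardizer <- function(scaler, X) {
  stopifnot(inherits(scaler, "lg_scaler"), ncol(X) == length(scaler$center))
  sweep(sweep(X, 2L, scaler$center), 2L, scaler$scale, `/`)
}

#' Spearman redundancy filter
#'
#' Computes the pairwise Spearman rank correlation matrix and removes one
#' member of every pair whose absolute correlation exceeds the cutoff.
#' Columns are visited in order; a column is kept iff its absolute rank
#' correlation with every previously kept column is at most the cutoff, so
#' the later-indexed member of a redundant pair is always the one dropped —
#' a deterministic, order-stable rule. Rank correlation makes the filter
#' invariant to monotone transformations of the columns.
#'
#' @param X numeric matrix with at least 3 rows.
#' @param cutoff redundancy threshold on `|rho|` (default 0.85).
#' @return integer vector of kept column indices.
#' @export
spearman_filter <- function(X, cutoff = 0.85) {
  stopifnot(is.matrix(X), nrow(X) >= 3)
  R <- apply(X, 2L, rank)
  rho <- suppressWarnings(stats::cor(R))
  rho[is.na(rho)] <- 0 # constant columns correlate with nothing
  p <- ncol(X)
  kept <- logical(p)
  kept[1L] <- TRUE
  for (j in seq_len(p)[-1L])
    kept[j] <- all(abs(rho[which(kept), j]) <= cutoff)
  which(kept)
}

# Stratified fold assignment, seeded.
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      ix <- sample(which(y == cls))
      fold[ix] <- rep_len(seq_len(k), length(ix))
    }
    fold
  })
}

# Fit a linear C-SVC from its precomputed Gram matrix. Labels enter as
# 0/1 and are mapped to -1/+1; `coef` holds alpha_i * y_i for every row.
# `warm` takes the alpha vector of a previous (nearby) fit, which cuts the
# solver iterations sharply along the elimination path.
svm_kernel_fit <- function(K, y01, C, warm = NULL) {
  yy <- ifelse(y01 == 1L, 1L, -1L)
  fit <- smo_svc(K, yy, C, warm_start = warm)
  if (!fit$converged)
    warning("SVM solver reached its iteration cap before convergence")
  fit$alpha <- fit$coef * yy
  fit
}

# Decision values for held-out rows: f = K[test, train] coef + b.
svm_kernel_decision <- function(fit, K_test_train) {
  drop(K_test_train %*% fit$coef) + fit$b
}

svm_kernel_cv_accuracy <- function(K, y01, fold, C) {
  accs <- vapply(sort(unique(fold)), function(f) {
    tr <- which(fold != f); te <- which(fold == f)
    m <- svm_kernel_fit(K[tr, tr, drop = FALSE], y01[tr], C)
    pred <- svm_kernel_decision(m, K[te, tr, drop = FALSE]) >= 0
    mean(pred == (y01[te] == 1L))
  }, numeric(1))
  mean(accs)
}

#' Recursive feature elimination with cross-validation
#'
#' Recursively removes the features with the smallest squared linear-SVM
#' weights, scoring each candidate feature count by stratified k-fold
#' cross-validated accuracy, and returns the feature set at the
#' accuracy-optimal count (ties resolved toward fewer features), never
#' below `min_features`. With `n_features` given, elimination runs straight
#' to that count and only the final set is cross-validated — the mode used
#' to reproduce a fixed selected-feature count.
#'
#' @param X standardized (and Spearman-filtered) feature matrix.
#' @param y binary labels.
#' @param cfg a [selection_config()].
#' @param n_features optional fixed number of features to retain
#'   (overrides the cross-validation optimum).
#' @return list with `selected` (column indices of `X`, ascending),
#'   `cv_curve` (data frame `n_features`, `accuracy`) and `ranking_path`.
#' @export
rfecv_select <- function(X, y, cfg = selection_config(), n_features = NULL) {
  y <- as.integer(y)
  assert_binary_labels(y)
  if (nrow(X) < cfg$cv_folds)
    stop("fewer rows than cross-validation folds", call. = FALSE)
  fold <- stratified_folds(y, cfg$cv_folds, cfg$seed)
  floor_n <- max(cfg$min_features,
                 if (is.null(n_features)) cfg$min_features
                 else min(n_features, ncol(X)))
  score_all <- is.null(n_features)
  cols <- seq_len(ncol(X))
  K <- tcrossprod(X)
  curve <- list()
  sets <- list()
  warm <- NULL
  repeat {
    cnt <- length(cols)
    if (score_all) {
      acc <- svm_kernel_cv_accuracy(K, y, fold, cfg$svm_C)
      curve[[length(curve) + 1L]] <- c(n_features = cnt, accuracy = acc)
      sets[[length(sets) + 1L]] <- cols
    }
    if (cnt <= floor_n) break
    m <- svm_kernel_fit(K, y, cfg$svm_C, warm = warm)
    warm <- m$alpha
    w <- crossprod(X[, cols, drop = FALSE], m$coef)
    step_now <- if (cnt > cfg$rfe_step_until)
      min(cfg$rfe_step, cnt - cfg$rfe_step_until) else 1L
    step_now <- min(step_now, cnt - floor_n)
    drop_local <- order(w^2)[seq_len(step_now)]
    dropped <- cols[drop_local]
    K <- K - tcrossprod(X[, dropped, drop = FALSE])
    cols <- cols[-drop_local]
  }
  if (score_all) {
    cv_curve <- as.data.frame(do.call(rbind, curve))
    best <- order(-cv_curve$accuracy, cv_curve$n_features)[1L]
    selected <- sort(sets[[best]])
  } else {
    acc <- svm_kernel_cv_accuracy(K, y, fold, cfg$svm_C)
    cv_curve <- data.frame(n_features = length(cols), accuracy = acc)
    selected <- sort(cols)
  }
  list(selected = selected, cv_curve = cv_curve,
       ranking_path = NULL)
}

#' Full training-cohort feature selection
#'
#' Standardize, Spearman-filter, then RFECV, all fitted on the training
#' cohort only. The frozen result can be applied to any cohort without
#' touching its labels.
#'
#' @param X training feature matrix.
#' @param y training labels.
#' @param cfg a [selection_config()].
#' @param n_features optional fixed selected-feature count (`NULL` = the
#'   cross-validation optimum).
#' @return an `lg_selection`: `scaler`, `kept_after_spearman` (original
#'   column indices), `selected` (original column indices), `cv_curve`,
#'   `config`, `n_input`.
#' @export
select_features <- function(X, y, cfg = selection_config(),
                            n_features = NULL) {
  scaler <- fit_standardizer(X)
  Xs <- apply_standardizer(scaler, X)
  kept <- spearman_filter(Xs, cfg$spearman_cutoff)
  rfe <- rfecv_select(Xs[, kept, drop = FALSE], y, cfg, n_features)
  structure(list(scaler = scaler, kept_after_spearman = kept,
                 selected = kept[rfe$selected], cv_curve = rfe$cv_curve,
                 config = cfg, n_input = ncol(X)),
            class = "lg_selection")
}

#' Apply a frozen selection to a cohort
#'
#' Standardizes with the training scaler and subsets the selected columns.
#' No statistic is re-fitted; validation labels are never consulted.
#'
#' @param selection an `lg_selection` from [select_features()].
#' @param X feature matrix of any cohort (same column layout as training).
#' @return n x |selected| standardized matrix.
#' @export
apply_selection <- function(selection, X) {
  stopifnot(inherits(selection, "lg_selection"))
  if (ncol(X) != selection$n_input)
    stop("cohort feature width differs from the training cohort", call. = FALSE)
  apply_standardizer(selection$scaler, X)[, selection$selected, drop = FALSE]
}

#' Serialize / restore a selection result as JSON
#'
#' Stores scaler statistics, kept and selected column indices and the CV
#' curve, so validation cohorts can be transformed in a separate process.
#'
#' @param selection an `lg_selection`.
#' @param path JSON file path.
#' @export
write_selection_json <- function(selection, path) {
  jsonlite::write_json(list(
    center = selection$scaler$center, scale = selection$scaler$scale,
    kept_after_spearman = selection$kept_after_spearman,
    selected = selection$selected, cv_curve = selection$cv_curve,
    n_input = selection$n_input), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_selection_json
#' @export
read_selection_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(scaler = structure(list(center = j$center, scale = j$scale),
                                    class = "lg_scaler"),
                 kept_after_spearman = as.integer(j$kept_after_spearman),
                 selected = as.integer(j$selected),
                 cv_curve = as.data.frame(j$cv_curve), config = NULL,
                 n_input = as.integer(j$n_input)),
            class = "lg_selection")
}
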