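# Standardization, Spearman redundancy filtering, and RFECV with the
# compiled linear-SVM engine (validated here against libsvm via e1071).

test_that("standardizer centers and scales on training statistics only", {
  set.seed(1)
  X <- matrix(rnorm(200 * 5, mean = 3, sd = 2), 200, 5)
  sc <- fit_standardizer(X)
  Xs <- apply_standardizer(sc, X)
  expect_true(all(abs(colMeans(Xs)) < 1e-10))
  expect_equal(unname(apply(Xs, 2, sd)), rep(1, 5))
  # shifted validation matrix keeps its shift (no re-fitting)
  Xv <- X + 1.5
  Xvs <- apply_standardizer(sc, Xv)
  expect_equal(colMeans(Xvs) - colMeans(Xs), 1.5 / sc$scale)
})

test_that("zero-variance columns get unit scale with a warning", {
  X <- cbind(rnorm(50), rep(2, 50))
  expect_warning(sc <- fit_standardizer(X), "zero-variance")
  Xs <- apply_standardizer(sc, X)
  expect_true(all(Xs[, 2] == 0)) # unchanged values minus their mean
})

test_that("spearman filter drops the later member of each redundant pair", {
  set.seed(2)
  x <- rnorm(100)
  X <- cbind(a = x, b = rnorm(100), dup = x, mono = exp(2 * x))
  kept <- spearman_filter(X, 0.85)
  # the duplicate and the strictly monotone transform (|rho| = 1) both go
  expect_equal(kept, c(1L, 2L))
})

test_that("independent noise columns survive the filter at n = 621", {
  set.seed(3)
  X <- matrix(rnorm(621 * 40), 621, 40)
  expect_equal(spearman_filter(X, 0.85), 1:40)
})

test_that("the filter is invariant to monotone transformations", {
  set.seed(4)
  X <- matrix(rnorm(80 * 6), 80, 6)
  X[, 4] <- X[, 1] + 0.1 * rnorm(80) # planted redundancy
  f <- function(M) spearman_filter(M, 0.85)
  M2 <- X
  M2[, 1] <- qlogis(plogis(M2[, 1]))      # identity, numerically
  M2[, 4] <- M2[, 4]^3                    # monotone
  M2[, 2] <- exp(M2[, 2])                 # monotone
  expect_equal(f(X), f(M2))
})

test_that("the compiled SVM solver agrees with libsvm", {
  set.seed(5)
  for (rep in 1:3) {
    n <- 90; d <- 15
    X <- matrix(rnorm(n * d), n, d)
    y <- rbinom(n, 1, 0.45)
    X[, 1:3] <- X[, 1:3] + y
    fit <- lymphgraph:::svm_kernel_fit(tcrossprod(X), y, 1)
    w_ours <- drop(crossprod(X, fit$coef))
    m <- e1071::svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE)
    w_ref <- drop(crossprod(X[m$index, , drop = FALSE], m$coefs))
    # libsvm's +1 class depends on label order; align by sign
    s <- sign(sum(w_ours * w_ref))
    expect_gt(cor(s * w_ours, w_ref), 0.999)
    expect_lt(max(abs(s * w_ours - w_ref)), 0.05)
    expect_lt(abs(s * fit$b - (-m$rho)), 0.05)
    # decision values agree on the training points
    f_ours <- drop(tcrossprod(X) %*% fit$coef) + fit$b
    f_ref <- drop(attr(predict(m, X, decision.values = TRUE),
                       "decision.values"))
    expect_gt(abs(cor(f_ours, f_ref)), 0.999)
  }
})

test_that("rfecv keeps at least min_features and returns a cv curve", {
  set.seed(6)
  X <- matrix(rnorm(60 * 10), 60, 10) # pure noise
  y <- rep(c(0L, 1L), 30)
  res <- rfecv_select(X, y, selection_config(cv_folds = 5, seed = 1))
  expect_gte(length(res$selected), 3)
  expect_gt(nrow(res$cv_curve), 0)
  # majority-class floor: CV accuracy of noise hovers near 0.5 here
  expect_lt(max(res$cv_curve$accuracy), 0.8)
  # three inputs, min three features: nothing eliminated
  res3 <- rfecv_select(X[, 1:3], y, selection_config(cv_folds = 5, seed = 1))
  expect_equal(res3$selected, 1:3)
})

test_that("rfecv recovers planted informative columns", {
  hits <- vapply(1:5, function(s) {
    co <- generate_feature_cohort(cohort_spec(
      150, 0.4, n_features = 30, n_informative = 5, n_redundant = 0,
      class_separation = 2, seed = s))
    Xs <- apply_standardizer(fit_standardizer(co$features), co$features)
    res <- rfecv_select(Xs, co$labels,
                        selection_config(cv_folds = 5, rfe_step = 4,
                                         rfe_step_until = 15, seed = s))
    sum(co$truth$informative %in% res$selected)
  }, numeric(1))
  expect_gte(median(hits), 4)
})

test_that("selection is reproducible and validation-label free", {
  co <- tiny_cohorts(seed = 3)
  cfg <- selection_config(cv_folds = 5, rfe_step = 16, rfe_step_until = 24,
                          seed = 11)
  s1 <- select_features(co$train$features, co$train$labels, cfg, 8)
  s2 <- select_features(co$train$features, co$train$labels, cfg, 8)
  expect_identical(s1$selected, s2$selected)
  expect_true(all(s1$selected %in% s1$kept_after_spearman))
  expect_equal(length(s1$selected), 8)
  # applying the frozen result never reads labels: scrambling them changes
  # nothing
  v <- co$val1
  a <- apply_selection(s1, v$features)
  v$labels <- rev(v$labels)
  b <- apply_selection(s1, v$features)
  expect_identical(a, b)
})

test_that("rfecv rejects degenerate inputs", {
  X <- matrix(rnorm(40), 8, 5)
  expect_error(rfecv_select(X, rep(c(0L, 1L), 4),
                            selection_config(cv_folds = 10)), "folds")
  expect_error(rfecv_select(X, rep(0L, 8), selection_config(cv_folds = 2)),
               "both classes")
})

test_that("selection round-trips through JSON", {
  co <- tiny_cohorts(seed = 4)
  sel <- select_features(co$train$features, co$train$labels,
                         selection_config(cv_folds = 5, seed = 2), 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_json(sel, path)
  back <- read_selection_json(path)
  expect_equal(back$selected, sel$selected)
  expect_equal(back$scaler$center, sel$scaler$center, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply_selection(back, co$val1$features),
               apply_selection(sel, co$val1$features), tolerance = 1e-12)
})
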