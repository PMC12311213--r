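# Diagnostic evaluation: thresholded confusion metrics with bootstrap
# confidence intervals, ROC/AUC, the paired DeLong test, decision-curve
# analysis, inter-model Pearson agreement and repeated-measures ANOVA.

#' Confusion counts at a probability cutoff
#'
#' A patient is called positive iff `prob >= cutoff`.
#'
#' @param prob predicted positive-class probabilities in \[0,1\].
#' @param labels binary truth (1 = metastasis-positive).
#' @param cutoff probability cutoff (default 0.5).
#' @return list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_at_cutoff <- function(prob, labels, cutoff = 0.5) {
  if (length(prob) != length(labels))
    stop("prob and labels must have the same length", call. = FALSE)
  pos <- prob >= cutoff
  list(TP = sum(pos & labels == 1L), FP = sum(pos & labels == 0L),
       TN = sum(!pos & labels == 0L), FN = sum(!pos & labels == 1L))
}

#' Diagnostic metrics from confusion counts
#'
#' accuracy = (TP + TN) / (TP + FP + TN + FN), sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP), PPV = TP / (TP + FP) and
#' NPV = TN / (TN + FN). A metric with an empty denominator is `NA`.
#'
#' The `npv` argument exists for auditing: `"as_printed"` reproduces a
#' variant formula, FN / (FN + TN), that circulates in print but is not a
#' predictive value (it is 1 minus the NPV); the default is the standard
#' definition.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` (see
#'   [confusion_at_cutoff()]).
#' @param npv `"standard"` or `"as_printed"`.
#' @return named list of point estimates.
#' @export
diagnostic_metrics <- function(counts, npv = c("standard", "as_printed")) {
  npv <- match.arg(npv)
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  with(counts, list(
    accuracy = safe_div(TP + TN, TP + FP + TN + FN),
    sensitivity = safe_div(TP, TP + FN),
    specificity = safe_div(TN, TN + FP),
    ppv = safe_div(TP, TP + FP),
    npv = if (npv == "standard") safe_div(TN, TN + FN)
          else safe_div(FN, FN + TN)))
}

metric_value <- function(metric, prob, labels, cutoff) {
  if (is.function(metric)) return(metric(prob, labels))
  if (metric == "auc") {
    if (length(unique(labels)) < 2L) return(NA_real_)
    return(roc_auc(prob, labels)$auc)
  }
  diagnostic_metrics(confusion_at_cutoff(prob, labels, cutoff))[[metric]]
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples cases with replacement within each label class (preserving
#' the class counts), recomputes the metric, and reports the percentile
#' interval. Resamples on which the metric is undefined are skipped; the
#' number skipped is attached as attribute `n_degenerate`.
#'
#' @param prob predicted probabilities.
#' @param labels binary truth.
#' @param metric one of `"accuracy"`, `"sensitivity"`, `"specificity"`,
#'   `"ppv"`, `"npv"`, `"auc"`, or a function `(prob, labels) -> number`.
#' @param n_boot number of bootstrap resamples (>= 100; default 2000).
#' @param seed RNG seed.
#' @param cutoff probability cutoff for thresholded metrics.
#' @param conf confidence level (default 0.95).
#' @return numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(prob, labels, metric = "sensitivity",
                         n_boot = 2000L, seed = 1L, cutoff = 0.5,
                         conf = 0.95) {
  stopifnot(n_boot >= 100)
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(if (length(pos)) sample(pos, replace = TRUE),
               if (length(neg)) sample(neg, replace = TRUE))
      metric_value(metric, prob[idx], labels[idx], cutoff)
    }, numeric(1))
  })
  n_deg <- sum(is.na(vals))
  q <- stats::quantile(vals, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       na.rm = TRUE, names = FALSE, type = 7)
  structure(c(lo = q[1], hi = q[2]), n_degenerate = n_deg)
}

#' ROC curve and AUC
#'
#' The AUC is the tie-corrected Mann-Whitney statistic,
#' `P(score+ > score-) + 0.5 P(score+ = score-)`, computed from mid-ranks.
#' The curve enumerates every distinct score as a cutoff.
#'
#' @param prob scores (higher = more metastasis-like).
#' @param labels binary truth; both classes required.
#' @return list with `curve` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(prob, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  m <- sum(labels == 1L)
  n <- sum(labels == 0L)
  r <- rank(prob) # mid-ranks handle ties
  auc <- (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n)
  thr <- c(Inf, sort(unique(prob), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(prob >= t & labels == 0L) / n,
                 numeric(1)),
    tpr = vapply(thr, function(t) sum(prob >= t & labels == 1L) / m,
                 numeric(1)))
  list(curve = curve, auc = auc)
}

# Structural components of the AUC: V10 (one value per positive case) and
# V01 (one per negative case), with psi = 1, 1/2, 0 for wins, ties, losses.
delong_components <- function(prob, labels) {
  x <- prob[labels == 1L]
  y <- prob[labels == 0L]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance of a single AUC
#'
#' `var(V10)/m + var(V01)/n` from the per-case structural components.
#'
#' @param prob scores.
#' @param labels binary truth.
#' @return the estimated variance of the empirical AUC.
#' @export
delong_variance <- function(prob, labels) {
  cmp <- delong_components(prob, labels)
  stats::var(cmp$v10) / length(cmp$v10) + stats::var(cmp$v01) / length(cmp$v01)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of two models scored on the same cases. The
#' covariance of the two AUCs is estimated from the covariances of the
#' per-case structural components; the AUC difference divided by its
#' standard error is referred to the normal distribution (two-sided).
#'
#' @param prob_a,prob_b paired scores from the two models.
#' @param labels shared binary truth.
#' @return list with `auc_a`, `auc_b`, `z`, `p` and `var_diff`.
#' @export
delong_test <- function(prob_a, prob_b, labels) {
  stopifnot(length(prob_a) == length(labels),
            length(prob_b) == length(labels))
  ca <- delong_components(prob_a, labels)
  cb <- delong_components(prob_b, labels)
  m <- length(ca$v10); n <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (var_diff <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else z <- d / sqrt(var_diff)
  list(auc_a = ca$auc, auc_b = cb$auc, z = z,
       p = if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z)),
       var_diff = var_diff)
}

#' Decision curve analysis
#'
#' Net benefit of acting on the model at threshold probability `p_t`:
#' `NB(p_t) = TP/n - (FP/n) * p_t / (1 - p_t)`, with patients called
#' positive iff `prob >= p_t`. The treat-all reference is
#' `pi - (1 - pi) * p_t / (1 - p_t)` with `pi` the prevalence; treat-none
#' is 0 everywhere.
#'
#' @param prob predicted probabilities.
#' @param labels binary truth.
#' @param pt_grid threshold probabilities in (0,1); default 0.01 to 0.99 by
#'   0.01.
#' @return data frame `p_t`, `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(prob, labels, pt_grid = seq(0.01, 0.99, 0.01)) {
  stopifnot(all(pt_grid > 0 & pt_grid < 1))
  n <- length(labels)
  pi_hat <- mean(labels == 1L)
  rows <- lapply(pt_grid, function(pt) {
    cc <- confusion_at_cutoff(prob, labels, pt)
    data.frame(p_t = pt,
               net_benefit = cc$TP / n - (cc$FP / n) * pt / (1 - pt),
               treat_all = pi_hat - (1 - pi_hat) * pt / (1 - pt),
               treat_none = 0)
  })
  do.call(rbind, rows)
}

#' Pairwise Pearson agreement between model outputs
#'
#' @param prob_by_model named list (or matrix columns) of paired
#'   probability vectors, one per model.
#' @return symmetric correlation matrix with unit diagonal; pairs
#'   involving a constant output are `NA`.
#' @export
agreement_matrix <- function(prob_by_model) {
  M <- if (is.matrix(prob_by_model)) prob_by_model
       else do.call(cbind, prob_by_model)
  r <- suppressWarnings(stats::cor(M))
  diag(r) <- 1
  r
}

#' Repeated-measures ANOVA across model outputs
#'
#' Cases are subjects, models the within-subject factor:
#' `df_num = k - 1`, `df_den = (k - 1)(n - 1)`, and
#' `F = MS_model / MS_error` after removing the between-subject sum of
#' squares. `method = "one_way"` instead ignores the pairing and runs a
#' classic one-way ANOVA across models.
#'
#' @param prob_by_model named list or n x k matrix of paired model outputs.
#' @param method `"repeated"` (default) or `"one_way"`.
#' @return list with `F`, `df_num`, `df_den`, `p`.
#' @export
rm_anova <- function(prob_by_model, method = c("repeated", "one_way")) {
  method <- match.arg(method)
  M <- if (is.matrix(prob_by_model)) prob_by_model
       else do.call(cbind, prob_by_model)
  n <- nrow(M); k <- ncol(M)
  stopifnot(k >= 2, n >= 3)
  if (method == "one_way") {
    ow <- stats::oneway.test(value ~ model, data.frame(
      value = as.vector(M), model = factor(rep(seq_len(k), each = n))),
      var.equal = TRUE)
    return(list(F = unname(ow$statistic), df_num = unname(ow$parameter[1]),
                df_den = unname(ow$parameter[2]), p = ow$p.value))
  }
  grand <- mean(M)
  ss_model <- n * sum((colMeans(M) - grand)^2)
  ss_subj <- k * sum((rowMeans(M) - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_err <- ss_tot - ss_model - ss_subj
  df_num <- k - 1
  df_den <- (k - 1) * (n - 1)
  Fval <- if (ss_err <= 0) 0 else (ss_model / df_num) / (ss_err / df_den)
  if (ss_model == 0) Fval <- 0
  list(F = Fval, df_num = df_num, df_den = df_den,
       p = stats::pf(Fval, df_num, df_den, lower.tail = FALSE))
}

#' Cohort-level diagnostic report
#'
#' Point estimates and bootstrap confidence intervals for accuracy,
#' sensitivity, specificity, PPV, NPV (at one probability cutoff) and AUC.
#'
#' @param prob predicted probabilities.
#' @param labels binary truth.
#' @param cutoff probability cutoff (default 0.5).
#' @param n_boot bootstrap resamples for the intervals.
#' @param seed RNG seed.
#' @return an `lg_report`: data frame with columns `metric`, `estimate`,
#'   `ci_low`, `ci_high`, plus attributes `cutoff` and `counts`.
#' @export
diagnostic_report <- function(prob, labels, cutoff = 0.5, n_boot = 2000L,
                              seed = 1L) {
  counts <- confusion_at_cutoff(prob, labels, cutoff)
  est <- diagnostic_metrics(counts)
  est$auc <- roc_auc(prob, labels)$auc
  rows <- lapply(names(est), function(mt) {
    ci <- bootstrap_ci(prob, labels, mt, n_boot = n_boot,
                       seed = stage_seed(seed, paste0("ci-", mt)),
                       cutoff = cutoff)
    data.frame(metric = mt, estimate = est[[mt]], ci_low = ci[1],
               ci_high = ci[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, cutoff = cutoff, counts = counts, class = c("lg_report",
                                                             "data.frame"))
}
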