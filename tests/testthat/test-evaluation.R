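# Diagnostic metrics, ROC/AUC, DeLong, decision curves, agreement and
# repeated-measures ANOVA.

test_that("confusion counts follow the inclusive cutoff", {
  prob <- c(.9, .2, .6, .4); labels <- c(1L, 0L, 1L, 0L)
  cc <- confusion_at_cutoff(prob, labels, 0.5)
  expect_equal(cc, list(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  cc0 <- confusion_at_cutoff(prob, labels, 0)
  expect_equal(cc0$TN + cc0$FN, 0L)
  cc1 <- confusion_at_cutoff(prob, labels, 1 + 1e-9)
  expect_equal(cc1$TP + cc1$FP, 0L)
  expect_error(confusion_at_cutoff(prob, labels[-1], 0.5), "length")
})

test_that("diagnostic metrics evaluate the printed formulas", {
  m <- diagnostic_metrics(list(TP = 3, FP = 1, TN = 4, FN = 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 2 / 3)
  perfect <- diagnostic_metrics(list(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_true(all(unlist(perfect) == 1))
  expect_true(is.na(diagnostic_metrics(list(TP = 0, FP = 2, TN = 3,
                                            FN = 0))$sensitivity))
  # audit mode: the non-standard printed variant is 1 - NPV
  ap <- diagnostic_metrics(list(TP = 3, FP = 1, TN = 4, FN = 2),
                           npv = "as_printed")
  expect_equal(ap$npv, 1 / 3)
})

test_that("AUC equals exhaustive pair counting, with tie correction", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0L, 0L, 1L, 1L))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0L, 0L, 1L, 1L))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 6), rep(c(0L, 1L), 3))$auc, 0.5)
  # exact pair-counting oracle on random instances
  set.seed(13)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    prob <- round(runif(n), 2) # ties likely
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    pos <- prob[labels == 1]; neg <- prob[labels == 0]
    wins <- 0
    for (a in pos) for (b in neg) wins <- wins + (a > b) + 0.5 * (a == b)
    expect_equal(roc_auc(prob, labels)$auc,
                 wins / (length(pos) * length(neg)))
  }
  expect_error(roc_auc(runif(5), rep(1L, 5)), "both classes")
})

test_that("the ROC curve starts at (0,0) and ends at (1,1)", {
  set.seed(14)
  r <- roc_auc(runif(40), rbinom(40, 1, 0.5))
  expect_equal(unlist(r$curve[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("AUC and DeLong variance agree with pROC", {
  set.seed(15)
  n <- 80
  labels <- rbinom(n, 1, 0.4)
  labels[1:2] <- c(0L, 1L)
  prob <- plogis(labels + rnorm(n))
  r <- suppressMessages(pROC::roc(labels, prob, quiet = TRUE))
  expect_equal(roc_auc(prob, labels)$auc, as.numeric(pROC::auc(r)))
  expect_equal(delong_variance(prob, labels), as.numeric(pROC::var(r)),
               tolerance = 1e-10)
})

test_that("the paired DeLong test matches pROC and is antisymmetric", {
  set.seed(16)
  n <- 100
  labels <- rbinom(n, 1, 0.4); labels[1:2] <- c(0L, 1L)
  base <- labels + rnorm(n)
  pa <- plogis(base + rnorm(n, sd = 0.5))
  pb <- plogis(base + rnorm(n, sd = 0.8))
  ours <- delong_test(pa, pb, labels)
  ref <- suppressMessages(pROC::roc.test(
    pROC::roc(labels, pa, quiet = TRUE), pROC::roc(labels, pb, quiet = TRUE),
    method = "delong"))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  expect_equal(abs(ours$z), abs(as.numeric(ref$statistic)), tolerance = 1e-9)
  swapped <- delong_test(pb, pa, labels)
  expect_equal(swapped$z, -ours$z)
  expect_equal(swapped$p, ours$p)
  ident <- delong_test(pa, pa, labels)
  expect_equal(ident$z, 0)
  expect_equal(ident$p, 1)
})

test_that("bootstrap intervals are seeded, bracket the estimate and collapse when exact", {
  labels <- rep(c(0L, 1L), 25)
  perfect <- as.numeric(labels)
  ci <- bootstrap_ci(perfect, labels, "sensitivity", n_boot = 200, seed = 1)
  expect_equal(as.numeric(ci), c(1, 1))
  set.seed(17)
  prob <- plogis(labels + rnorm(50))
  ci1 <- bootstrap_ci(prob, labels, "auc", n_boot = 300, seed = 5)
  ci2 <- bootstrap_ci(prob, labels, "auc", n_boot = 300, seed = 5)
  expect_identical(ci1, ci2)
  est <- roc_auc(prob, labels)$auc
  expect_lte(ci1[1], est)
  expect_gte(ci1[2], est)
  expect_error(bootstrap_ci(prob, labels, "auc", n_boot = 50), "100")
})

test_that("decision curves evaluate the net-benefit formula", {
  # n = 10, 4 true positives and 2 false positives called at p_t = 0.2
  prob <- c(.9, .8, .7, .6, .1, .3, .25, .15, .12, .05)
  labels <- c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L)
  dc <- decision_curve(prob, labels, pt_grid = 0.2)
  expect_equal(dc$net_benefit, 0.4 - 0.2 * 0.25)
  expect_equal(dc$treat_none, 0)
  expect_equal(dc$treat_all, 0.5 - 0.5 * 0.25)
  # treat-all reference at prevalence 0.4
  labels2 <- c(rep(1L, 4), rep(0L, 6))
  dc2 <- decision_curve(runif(10), labels2, pt_grid = 0.2)
  expect_equal(dc2$treat_all, 0.4 - 0.6 * 0.25)
  # the model's net benefit can never exceed the prevalence
  set.seed(18)
  p <- runif(60); l <- rbinom(60, 1, 0.35)
  dcg <- decision_curve(p, l)
  expect_true(all(dcg$net_benefit <= mean(l) + 1e-12))
  expect_true(all(diff(dcg$p_t) > 0))
})

test_that("agreement matrices have unit diagonal and flag constant models", {
  set.seed(19)
  M <- cbind(a = runif(30), b = runif(30))
  M <- cbind(M, c = M[, "a"] * 0.5 + 0.5)
  r <- agreement_matrix(M)
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(r["a", "c"], 1)
  expect_equal(r, t(r))
  Mc <- cbind(M, d = rep(0.4, 30))
  rc <- agreement_matrix(Mc)
  expect_true(is.na(rc["a", "d"]))
})

test_that("repeated-measures ANOVA reproduces textbook degrees of freedom", {
  set.seed(20)
  n <- 112; k <- 4
  M <- matrix(runif(n * k), n, k) + outer(rnorm(n), rep(1, k))
  res <- rm_anova(M)
  expect_equal(res$df_num, 3)
  expect_equal(res$df_den, 333)
  # oracle: stats::aov with an explicit within-subject error stratum
  df <- data.frame(y = as.vector(M), subj = factor(rep(seq_len(n), k)),
                   model = factor(rep(seq_len(k), each = n)))
  a <- summary(stats::aov(y ~ model + Error(subj / model), df))
  tab <- a[["Error: subj:model"]][[1]]
  expect_equal(res$F, tab["model", "F value"], tolerance = 1e-10)
  expect_equal(res$p, tab["model", "Pr(>F)"], tolerance = 1e-10)
  # identical models: F = 0
  ident <- rm_anova(cbind(M[, 1], M[, 1], M[, 1]))
  expect_equal(ident$F, 0)
  # one-way variant uses the between-groups layout
  ow <- rm_anova(M, method = "one_way")
  expect_equal(ow$df_num, 3)
  expect_equal(ow$df_den, 4 * 112 - 4)
})

test_that("diagnostic reports bracket every estimate with its interval", {
  set.seed(21)
  labels <- rbinom(100, 1, 0.4); labels[1:2] <- c(0L, 1L)
  prob <- plogis(labels * 1.5 + rnorm(100))
  rep <- diagnostic_report(prob, labels, n_boot = 200, seed = 3)
  expect_setequal(rep$metric, c("accuracy", "sensitivity", "specificity",
                                "ppv", "npv", "auc"))
  expect_true(all(rep$ci_low <= rep$estimate + 1e-12))
  expect_true(all(rep$ci_high >= rep$estimate - 1e-12))
  expect_true(all(rep$estimate >= 0 & rep$estimate <= 1))
})
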