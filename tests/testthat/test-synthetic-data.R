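# The generative model behind the synthetic cohorts: class-conditional
# Gaussians with a closed-form Bayes AUC, planted rank-correlated
# redundancy, and Bernoulli labels.

test_that("identical spec and seed reproduce a cohort bit for bit", {
  spec <- cohort_spec(50, 0.4, n_features = 30, n_informative = 3,
                      n_redundant = 4, seed = 7)
  a <- generate_feature_cohort(spec)
  b <- generate_feature_cohort(spec)
  expect_identical(a$features, b$features)
  expect_identical(a$labels, b$labels)
  expect_identical(a$ids, b$ids)
})

test_that("truth bookkeeping is consistent and in range", {
  co <- generate_feature_cohort(cohort_spec(40, 0.4, n_features = 25,
                                            n_informative = 4,
                                            n_redundant = 6, seed = 2))
  tr <- co$truth
  expect_length(intersect(tr$informative, tr$redundant), 0)
  expect_true(all(c(tr$informative, tr$redundant) %in% seq_len(25)))
  expect_true(all(tr$partners %in% tr$informative))
  # copies sit downstream of their sources so the order-stable filter rule
  # removes the copy
  expect_true(all(tr$redundant > max(tr$informative)))
  expect_equal(nrow(co$features), length(co$ids))
  expect_equal(nrow(co$features), length(co$labels))
})

test_that("zero class separation gives a Bayes AUC of one half", {
  co <- generate_feature_cohort(cohort_spec(30, 0.5, n_features = 10,
                                            n_informative = 2,
                                            n_redundant = 0,
                                            class_separation = 0, seed = 1))
  expect_equal(co$truth$bayes_auc, 0.5)
})

test_that("empirical AUC of the oracle discriminant matches the closed form", {
  # Bayes rule for equal-covariance Gaussians: the sum of informative
  # columns. Monte-Carlo at n = 5000 against Phi(2 / sqrt(2)) = 0.9214.
  co <- generate_feature_cohort(cohort_spec(5000, 0.4, n_features = 12,
                                            n_informative = 4,
                                            n_redundant = 0,
                                            class_separation = 2, seed = 42))
  score <- rowSums(co$features[, co$truth$informative, drop = FALSE])
  emp <- roc_auc(score, co$labels)$auc
  expect_equal(emp, pnorm(2 / sqrt(2)), tolerance = 0.02)
  expect_equal(co$truth$bayes_auc, 0.9213504, tolerance = 1e-6)
})

test_that("planted redundancy is detectable by the Spearman filter", {
  co <- generate_feature_cohort(cohort_spec(621, 0.35, n_features = 100,
                                            n_informative = 10,
                                            n_redundant = 20,
                                            redundancy_rho = 0.95, seed = 5))
  rho <- vapply(seq_along(co$truth$redundant), function(k)
    abs(cor(co$features[, co$truth$redundant[k]],
            co$features[, co$truth$partners[k]], method = "spearman")),
    numeric(1))
  expect_gte(mean(rho > 0.85), 0.9)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(50, 0), "prevalence")
  expect_error(cohort_spec(50, 1.2), "prevalence")
  expect_error(cohort_spec(50, 0.4, n_features = 5, n_informative = 4,
                           n_redundant = 4), "exceed")
  expect_error(cohort_spec(50, 0.4, n_informative = 0, n_redundant = 0,
                           class_separation = 1), "informative")
  expect_error(cohort_spec(50, 0.4, n_redundant = 2, redundancy_rho = 0.5),
               "redundancy_rho")
  expect_error(cohort_spec(50, NaN), "finite")
})

test_that("toy images carry a valid tight bounding box", {
  imgs <- generate_toy_images(5, prevalence = 0.4, seed = 3)
  for (im in imgs) {
    expect_true(all(im$pixels >= 0 & im$pixels <= 1))
    bb <- im$bbox
    expect_true(bb["x_min"] >= 0 && bb["y_min"] >= 0)
    expect_true(bb["x_max"] <= ncol(im$pixels))
    expect_true(bb["y_max"] <= nrow(im$pixels))
    expect_gte((bb["x_max"] - bb["x_min"]) * (bb["y_max"] - bb["y_min"]), 4)
  }
})

test_that("toy image generation is deterministic and label-calibrated", {
  a <- generate_toy_images(3, 0.4, seed = 11)
  b <- generate_toy_images(3, 0.4, seed = 11)
  expect_identical(lapply(a, `[[`, "pixels"), lapply(b, `[[`, "pixels"))
  imgs <- generate_toy_images(200, 0.4, seed = 12)
  labs <- vapply(imgs, `[[`, 0L, "label")
  half <- qnorm(0.995) * sqrt(0.4 * 0.6 / 200) # binomial 99% interval
  expect_true(abs(mean(labs) - 0.4) <= half)
})

test_that("study cohorts reproduce the three-hospital geometry", {
  st <- make_study_cohorts(seed = 0)
  expect_equal(nrow(st$train$features), 621)
  expect_equal(nrow(st$val1$features), 112)
  expect_equal(nrow(st$val2$features), 87)
  expect_length(intersect(st$train$ids, c(st$val1$ids, st$val2$ids)), 0)
  expect_length(intersect(st$val1$ids, st$val2$ids), 0)
  # one generative model: planted columns shared across cohorts
  expect_identical(st$train$truth$informative, st$val1$truth$informative)
  expect_identical(st$train$truth$redundant, st$val2$truth$redundant)
})
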