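# Two-layer GCN: forward semantics against an independent dense oracle,
# analytic gradients against finite differences, permutation equivariance,
# and the training protocol.

test_that("forward pass matches the independent dense oracle", {
  for (s in 1:5) {
    inst <- random_instance(6, 4, s)
    got <- gcn_forward(normalize_adjacency(inst$A), inst$X, inst$params)
    want <- dense_gcn_oracle(inst$A, inst$X, inst$params)
    expect_lt(max(abs(got$Z - want$Z)), 1e-8)
    expect_lt(max(abs(got$H1 - want$H1)), 1e-8)
    expect_lt(max(abs(got$H2 - want$H2)), 1e-8)
    expect_equal(rowSums(got$Z), rep(1, 6), tolerance = 1e-9)
  }
})

test_that("equal output-layer columns give probability one half everywhere", {
  inst <- random_instance(8, 3, 2)
  inst$params$W_fc <- cbind(inst$params$W_fc[, 1], inst$params$W_fc[, 1])
  Z <- gcn_forward(normalize_adjacency(inst$A), inst$X, inst$params)$Z
  expect_equal(Z, matrix(0.5, 8, 2), tolerance = 1e-12)
})

test_that("with identity propagation the model is a row-wise network", {
  inst <- random_instance(7, 4, 3)
  P <- diag(7)
  Z <- gcn_forward(P, inst$X, inst$params)$Z
  # perturbing one node's features leaves all other predictions untouched
  X2 <- inst$X
  X2[3, ] <- X2[3, ] + 5
  Z2 <- gcn_forward(P, X2, inst$params)$Z
  expect_equal(Z[-3, ], Z2[-3, ], tolerance = 1e-12)
  expect_gt(max(abs(Z[3, ] - Z2[3, ])), 1e-6)
})

test_that("predictions are permutation-equivariant", {
  inst <- random_instance(9, 4, 4)
  P <- as.matrix(normalize_adjacency(inst$A))
  Z <- gcn_forward(P, inst$X, inst$params)$Z
  pi <- sample(9)
  Zp <- gcn_forward(P[pi, pi], inst$X[pi, , drop = FALSE], inst$params)$Z
  expect_equal(Zp, Z[pi, ], tolerance = 1e-12)
})

test_that("one-hot encoding round-trips and rejects bad labels", {
  expect_equal(one_hot(1L, 2), matrix(c(0, 1), 1))
  expect_equal(one_hot(0L, 2), matrix(c(1, 0), 1))
  y <- sample(0:1, 25, replace = TRUE)
  Y <- one_hot(y, 2)
  expect_equal(rowSums(Y), rep(1, 25))
  expect_equal(max.col(Y) - 1L, y)
  expect_error(one_hot(2L, 2), "range")
})

test_that("analytic gradients match central finite differences", {
  inst <- random_instance(5, 3, 6)
  P <- as.matrix(normalize_adjacency(inst$A))
  y <- c(0L, 1L, 1L, 0L, 1L)
  Y <- one_hot(y, 2)
  batch <- 1:5
  A1x <- P %*% inst$X
  got <- lymphgraph:::gcn_step_grads(P, A1x, Y, batch, inst$params, 0)
  loss_at <- function(par) {
    H1 <- pmax(A1x %*% par$W0, 0)
    H2 <- pmax(P %*% H1 %*% par$W1, 0)
    Z <- lymphgraph:::row_softmax(H2 %*% par$W_fc)
    -mean(log(rowSums(Z[batch, ] * Y[batch, ]) + 1e-12))
  }
  h <- 1e-5
  for (nm in c("W0", "W1", "W_fc")) {
    W <- inst$params[[nm]]
    idx <- cbind(sample(nrow(W), 4, replace = TRUE),
                 sample(ncol(W), 4, replace = TRUE))
    for (r in seq_len(nrow(idx))) {
      pp <- inst$params; pp[[nm]][idx[r, 1], idx[r, 2]] <- W[idx[r, 1], idx[r, 2]] + h
      pm <- inst$params; pm[[nm]][idx[r, 1], idx[r, 2]] <- W[idx[r, 1], idx[r, 2]] - h
      fd <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      an <- got$grads[[nm]][idx[r, 1], idx[r, 2]]
      denom <- max(abs(fd), abs(an), 1e-8)
      expect_lt(abs(fd - an) / denom, 1e-4)
    }
  }
})

test_that("training is seeded, bounded and refuses degenerate labels", {
  tg <- tiny_graph(seed = 5, threshold = 0.4)
  cfg <- gcn_config(max_epochs = 15, seed = 8, learning_rate = 0.01)
  f1 <- gcn_train(tg$graph, tg$labels, cfg)
  f2 <- gcn_train(tg$graph, tg$labels, cfg)
  expect_identical(f1$history, f2$history)
  expect_lte(nrow(f1$history), 15)
  f0 <- gcn_train(tg$graph, tg$labels, gcn_config(max_epochs = 0, seed = 8))
  expect_equal(nrow(f0$history), 0)
  expect_equal(f0$params$W0, gcn_init(ncol(tg$graph$X),
                                      gcn_config(max_epochs = 0, seed = 8))$W0)
  expect_error(gcn_train(tg$graph, rep(1L, tg$graph$n_nodes), cfg),
               "both classes")
  expect_error(gcn_train(tg$graph, tg$labels[-1], cfg), "disagree")
})

test_that("compiled and reference training engines coincide", {
  # full batch, no dropout: the loop is deterministic given the seed
  tg <- tiny_graph(seed = 6, threshold = 0.4)
  cfg <- gcn_config(max_epochs = 12, batch_size = Inf, dropout_rate = 0,
                    learning_rate = 0.01, seed = 3)
  fr <- gcn_train(tg$graph, tg$labels, cfg, engine = "r")
  fc <- gcn_train(tg$graph, tg$labels, cfg, engine = "cpp")
  expect_equal(fr$params$W0, fc$params$W0, tolerance = 1e-10)
  expect_equal(fr$params$W_fc, fc$params$W_fc, tolerance = 1e-10)
  expect_equal(fr$history$train_loss, fc$history$train_loss,
               tolerance = 1e-10)
  expect_equal(fr$best_epoch, fc$best_epoch)
})

test_that("prediction is deterministic, bounded and label-free", {
  tg <- tiny_graph(seed = 7, threshold = 0.4)
  fit <- gcn_train(tg$graph, tg$labels,
                   gcn_config(max_epochs = 20, seed = 2,
                              learning_rate = 0.01))
  p1 <- gcn_predict(tg$graph, fit)
  p2 <- gcn_predict(tg$graph, fit)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_named(p1, tg$graph$ids)
})

test_that("trained parameters round-trip through a JSON checkpoint", {
  tg <- tiny_graph(seed = 9, threshold = 0.4)
  fit <- gcn_train(tg$graph, tg$labels,
                   gcn_config(max_epochs = 10, seed = 1,
                              learning_rate = 0.01))
  path <- withr::local_tempfile(fileext = ".json")
  write_gcn_checkpoint(fit, path)
  back <- read_gcn_checkpoint(path)
  expect_equal(back$W0, fit$params$W0, tolerance = 1e-12)
  expect_equal(gcn_predict(tg$graph, back), gcn_predict(tg$graph, fit),
               tolerance = 1e-12)
})

test_that("a null-signal cohort yields chance-level discrimination", {
  co <- generate_feature_cohort(cohort_spec(150, 0.4, n_features = 15,
                                            n_informative = 2,
                                            n_redundant = 0,
                                            class_separation = 0, seed = 31))
  X <- apply_standardizer(fit_standardizer(co$features), co$features)
  g <- assemble_graph(node_table(co$ids, X, co$labels), 0.5)
  fit <- gcn_train(g, co$labels, gcn_config(max_epochs = 40, seed = 4,
                                            learning_rate = 0.01))
  # fresh draw from the same null model
  co2 <- generate_feature_cohort(cohort_spec(150, 0.4, n_features = 15,
                                             n_informative = 2,
                                             n_redundant = 0,
                                             class_separation = 0,
                                             seed = 32))
  X2 <- apply_standardizer(fit_standardizer(co$features), co2$features)
  g2 <- assemble_graph(node_table(co2$ids, X2, co2$labels), 0.5)
  auc <- roc_auc(gcn_predict(g2, fit), co2$labels)$auc
  expect_lt(abs(auc - 0.5), 0.15) # Monte-Carlo noise band at n = 150
})
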