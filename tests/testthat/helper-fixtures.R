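# Small programmatic fixtures shared across test files.

# A compact three-cohort study drawn from one generative model: fast enough
# for end-to-end tests, large enough for the statistics to be stable.
tiny_cohorts <- function(seed = 1L, n_train = 120L, n_val1 = 50L,
                         n_val2 = 40L, n_features = 80L, n_informative = 6L,
                         n_redundant = 8L, class_separation = 2) {
  mk <- function(n, prev, tag, prefix)
    generate_feature_cohort(cohort_spec(
      n, prev, n_features = n_features, n_informative = n_informative,
      n_redundant = n_redundant, class_separation = class_separation,
      seed = stage_seed(seed, tag), id_prefix = prefix))
  list(train = mk(n_train, 0.35, "tr", "TR"),
       val1 = mk(n_val1, 0.40, "v1", "V1"),
       val2 = mk(n_val2, 0.40, "v2", "V2"))
}

# Independent dense re-implementation of the two-layer propagation rule
# and softmax head, written with explicit loops. This is the oracle the
# package's forward pass is checked against; it must never share code with
# the implementation.
dense_gcn_oracle <- function(A, X, params) {
  n <- nrow(A)
  At <- A + diag(n)
  D <- rowSums(At)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    P[i, j] <- At[i, j] / sqrt(D[i] * D[j])
  act <- function(M) ifelse(M > 0, M, 0)
  H1 <- act(P %*% X %*% params$W0)
  H2 <- act(P %*% H1 %*% params$W1)
  S <- H2 %*% params$W_fc
  Z <- matrix(0, n, ncol(S))
  for (i in seq_len(n)) {
    e <- exp(S[i, ] - max(S[i, ]))
    Z[i, ] <- e / sum(e)
  }
  list(Z = Z, H1 = H1, H2 = H2)
}

# A random graph + features + initialized parameters.
random_instance <- function(n, d, seed, p_edge = 0.4) {
  set.seed(seed)
  A <- matrix(rbinom(n * n, 1, p_edge), n, n)
  A <- 1 * ((A + t(A)) > 0)
  diag(A) <- 0
  X <- matrix(rnorm(n * d), n, d)
  cfg <- gcn_config(hidden1 = 7, hidden2 = 5, seed = seed)
  list(A = A, X = X, params = gcn_init(d, cfg))
}

# A small ready-made graph on selected features.
tiny_graph <- function(seed = 1L, threshold = 0.6, n = 60L) {
  co <- generate_feature_cohort(cohort_spec(
    n, 0.4, n_features = 20L, n_informative = 4L, n_redundant = 0L,
    class_separation = 2, seed = seed))
  X <- apply_standardizer(fit_standardizer(co$features), co$features)
  list(graph = assemble_graph(node_table(co$ids, X, co$labels), threshold),
       labels = co$labels)
}
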