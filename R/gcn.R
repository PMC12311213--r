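# Two-layer graph convolutional network for transductive node
# classification, written from scratch with explicit forward and backward
# passes.
#
# Propagation rule per layer:  H^(l+1) = ReLU(P H^(l) W^(l))  with
# P = D_tilde^(-1/2) (A + I) D_tilde^(-1/2) the symmetrically normalized
# self-looped adjacency, H^(0) = X the selected features. The second
# hidden state passes through dropout and a dense softmax head:
# Z = softmax(H^(2) W_fc). Training minimizes cross-entropy on labeled
# training nodes with Adam; every patient in the cohort participates in
# propagation, but loss and gradients only touch training labels.

# -- shared numerics ---------------------------------------------------------

row_softmax <- function(S) {
  S <- S - S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S)
  E / rowSums(E)
}

dropout_mask <- function(nr, nc, rate) {
  keep <- 1 - rate
  matrix((runif(nr * nc) < keep) / keep, nr, nc)
}

adam_state <- function(par) {
  zeros <- lapply(par, function(p) p * 0)
  list(par = par, m = zeros, v = zeros, t = 0L)
}

adam_step <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    state$par[[nm]] <- state$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

# -- configuration and parameters --------------------------------------------

#' GCN configuration
#'
#' Defaults follow the training protocol of the pipeline: Adam with
#' learning rate 1e-4 and batch size 32, up to 500 epochs, early stopping
#' with patience on a held-out loss. Because training is transductive on a
#' single graph, a "batch" is a subset of labeled training nodes over which
#' the cross-entropy is computed for one full-graph gradient step; one
#' epoch sweeps all training nodes in shuffled batches. Early stopping
#' monitors the loss on an internal stratified mask of training nodes
#' (`early_stop_fraction`), never the external validation cohorts, to keep
#' model selection leakage-free.
#'
#' @param hidden1,hidden2 widths of the two graph convolution layers.
#' @param dropout_rate dropout applied to the second hidden state during
#'   training.
#' @param learning_rate Adam learning rate.
#' @param batch_size labeled nodes per gradient step; `Inf` for full-batch.
#' @param max_epochs maximum training epochs.
#' @param patience epochs without monitored-loss improvement before
#'   stopping.
#' @param early_stop_fraction fraction of training nodes held out (per
#'   class) as the early-stopping monitor; 0 disables the mask and early
#'   stopping.
#' @param seed RNG seed covering initialization, batching and dropout.
#' @param n_classes number of output classes.
#' @return an `lg_gcn_config`.
#' @export
gcn_config <- function(hidden1 = 64L, hidden2 = 32L, dropout_rate = 0.5,
                       learning_rate = 1e-4, batch_size = 32L,
                       max_epochs = 500L, patience = 50L,
                       early_stop_fraction = 0.15, seed = 1L,
                       n_classes = 2L) {
  stopifnot(hidden1 >= 1, hidden2 >= 1, dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, max_epochs >= 0, patience >= 1,
            early_stop_fraction >= 0, early_stop_fraction < 0.5)
  structure(list(hidden1 = as.integer(hidden1), hidden2 = as.integer(hidden2),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 batch_size = batch_size, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 early_stop_fraction = early_stop_fraction,
                 seed = as.integer(seed), n_classes = as.integer(n_classes)),
            class = "lg_gcn_config")
}

glorot <- function(nin, nout) {
  limit <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -limit, limit), nin, nout)
}

#' Initialize GCN parameters
#'
#' Glorot-uniform weights `W0` (d x hidden1), `W1` (hidden1 x hidden2) and
#' `W_fc` (hidden2 x n_classes), seeded through the config.
#'
#' @param d input feature width.
#' @param cfg a [gcn_config()].
#' @return an `lg_gcn_params` list.
#' @export
gcn_init <- function(d, cfg = gcn_config()) {
  with_seed(cfg$seed, {
    structure(list(W0 = glorot(d, cfg$hidden1),
                   W1 = glorot(cfg$hidden1, cfg$hidden2),
                   W_fc = glorot(cfg$hidden2, cfg$n_classes)),
              class = "lg_gcn_params")
  })
}

#' One-hot encode integer labels
#'
#' @param labels integer labels in `0:(n_classes - 1)`.
#' @param n_classes number of classes.
#' @return an n x n_classes 0/1 matrix whose rows sum to 1.
#' @export
one_hot <- function(labels, n_classes = 2L) {
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= n_classes))
    stop("labels out of range for one-hot encoding", call. = FALSE)
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

# -- forward / backward ------------------------------------------------------

#' GCN forward pass
#'
#' Computes `H1 = ReLU(P X W0)`, `H2 = ReLU(P H1 W1)` and
#' `Z = softmax(H2d W_fc)` where `H2d` is `H2` after (inverted) dropout
#' when `dropout_rate > 0`. Every row of `Z` sums to 1.
#'
#' @param p_hat normalized propagation matrix (dense or `Matrix` sparse).
#' @param X n x d feature matrix.
#' @param params an `lg_gcn_params`.
#' @param dropout_rate dropout probability on the second hidden state
#'   (0 = evaluation mode).
#' @param seed RNG seed for the dropout mask (required when
#'   `dropout_rate > 0`).
#' @return list with `Z` (n x n_classes probabilities), `H1`, `H2`.
#' @export
gcn_forward <- function(p_hat, X, params, dropout_rate = 0, seed = NULL) {
  n <- nrow(X)
  if (nrow(p_hat) != n || ncol(p_hat) != n)
    stop("p_hat must be n x n with n = nrow(X)", call. = FALSE)
  if (nrow(params$W0) != ncol(X))
    stop("W0 does not match feature width", call. = FALSE)
  A1 <- as.matrix(p_hat %*% X)
  H1 <- relu(A1 %*% params$W0)
  H2 <- relu(as.matrix(p_hat %*% H1) %*% params$W1)
  H2d <- H2
  if (dropout_rate > 0) {
    if (is.null(seed)) stop("dropout requires a seed", call. = FALSE)
    M <- with_seed(seed, dropout_mask(nrow(H2), ncol(H2), dropout_rate))
    H2d <- H2 * M
  }
  Z <- row_softmax(H2d %*% params$W_fc)
  list(Z = Z, H1 = H1, H2 = H2)
}

# One training step: forward with dropout, cross-entropy on `batch` rows,
# analytic gradients. A1x = P %*% X is precomputed. Consumes RNG for the
# dropout mask.
gcn_step_grads <- function(P, A1x, Y, batch, par, dropout_rate) {
  H1 <- relu(A1x %*% par$W0)
  A2 <- as.matrix(P %*% H1)
  H2 <- relu(A2 %*% par$W1)
  if (dropout_rate > 0) {
    M <- dropout_mask(nrow(H2), ncol(H2), dropout_rate)
    H2d <- H2 * M
  } else {
    M <- NULL
    H2d <- H2
  }
  Z <- row_softmax(H2d %*% par$W_fc)
  nb <- length(batch)
  dS <- matrix(0, nrow(Z), ncol(Z))
  dS[batch, ] <- (Z[batch, , drop = FALSE] - Y[batch, , drop = FALSE]) / nb
  dWfc <- crossprod(H2d, dS)
  dH2 <- dS %*% t(par$W_fc)
  if (!is.null(M)) dH2 <- dH2 * M
  dZ2 <- dH2 * (H2 > 0)
  dW1 <- crossprod(A2, dZ2)
  dH1 <- as.matrix(P %*% (dZ2 %*% t(par$W1)))
  dZ1 <- dH1 * (H1 > 0)
  dW0 <- crossprod(A1x, dZ1)
  loss <- -mean(log(rowSums(Z[batch, , drop = FALSE] *
                              Y[batch, , drop = FALSE]) + 1e-12))
  list(grads = list(W0 = dW0, W1 = dW1, W_fc = dWfc), loss = loss)
}

cross_entropy <- function(Z, Y, idx) {
  -mean(log(rowSums(Z[idx, , drop = FALSE] * Y[idx, , drop = FALSE]) + 1e-12))
}

#' Train the GCN on a cohort graph
#'
#' Full-graph forward passes with Adam updates on shuffled batches of
#' labeled training nodes (cross-entropy loss). A stratified fraction of
#' training nodes is masked out as the early-stopping monitor; training
#' stops when the mask loss has not improved for `patience` epochs, and the
#' parameters from the best-mask-loss epoch are returned. With
#' `early_stop_fraction = 0` all nodes are trained on and the final-epoch
#' parameters are returned.
#'
#' @param graph an `lg_graph` from [assemble_graph()].
#' @param labels binary node labels (1 = metastasis-positive); both classes
#'   required.
#' @param cfg a [gcn_config()].
#' @param engine `"cpp"` (compiled loop, default) or `"r"` (reference
#'   implementation in plain R; same algorithm, used for equivalence
#'   testing).
#' @return an `lg_gcn_fit`: `params`, `history` (per-epoch train/mask loss
#'   and accuracy), `epoch_stopped`, `best_epoch`, `mask_idx`, `config`.
#' @export
gcn_train <- function(graph, labels, cfg = gcn_config(),
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  labels <- as.integer(labels)
  if (graph$n_nodes != length(labels))
    stop("graph and labels disagree on the number of patients", call. = FALSE)
  assert_binary_labels(labels)
  P <- graph$p_hat
  X <- graph$X
  Y <- one_hot(labels, cfg$n_classes)
  n <- nrow(X)
  empty_history <- data.frame(epoch = integer(), train_loss = numeric(),
                              train_acc = numeric(), mask_loss = numeric(),
                              mask_acc = numeric())
  with_seed(cfg$seed, {
    # parameters first so initialization matches gcn_init() under the same
    # seed; the early-stop mask draws afterwards from the same stream
    par <- list(W0 = glorot(ncol(X), cfg$hidden1),
                W1 = glorot(cfg$hidden1, cfg$hidden2),
                W_fc = glorot(cfg$hidden2, cfg$n_classes))
    if (cfg$early_stop_fraction > 0) {
      mask_idx <- sort(unlist(lapply(split(seq_len(n), labels), function(ix)
        sample(ix, max(1L, round(cfg$early_stop_fraction * length(ix)))))))
    } else mask_idx <- integer(0)
    train_idx <- setdiff(seq_len(n), mask_idx)
    opt <- adam_state(par)
    A1x <- as.matrix(P %*% X)
    dimnames(A1x) <- NULL
    bs <- if (is.finite(cfg$batch_size)) as.integer(cfg$batch_size)
          else length(train_idx)
    if (engine == "cpp" && cfg$max_epochs > 0L) {
      Psp <- methods::as(methods::as(P, "dMatrix"), "CsparseMatrix")
      res <- gcn_train_loop(Psp, A1x, Y, as.integer(labels),
                            as.integer(train_idx), as.integer(mask_idx),
                            par$W0, par$W1, par$W_fc, cfg$learning_rate,
                            bs, cfg$max_epochs, cfg$patience,
                            cfg$dropout_rate)
      history <- data.frame(epoch = seq_along(res$train_loss),
                            train_loss = res$train_loss,
                            train_acc = res$train_acc,
                            mask_loss = res$mask_loss,
                            mask_acc = res$mask_acc)
      return(structure(list(
        params = structure(list(W0 = res$W0, W1 = res$W1, W_fc = res$W_fc),
                           class = "lg_gcn_params"),
        history = history, epoch_stopped = res$epoch_stopped,
        best_epoch = res$best_epoch, mask_idx = mask_idx, config = cfg),
        class = "lg_gcn_fit"))
    }
    best <- list(loss = Inf, par = par, epoch = 0L)
    wait <- 0L
    history <- empty_history
    epoch <- 0L
    while (epoch < cfg$max_epochs) {
      epoch <- epoch + 1L
      ord <- sample(train_idx)
      for (start in seq.int(1L, length(ord), by = bs)) {
        batch <- ord[start:min(start + bs - 1L, length(ord))]
        sg <- gcn_step_grads(P, A1x, Y, batch, opt$par, cfg$dropout_rate)
        opt <- adam_step(opt, sg$grads, cfg$learning_rate)
      }
      H1 <- relu(A1x %*% opt$par$W0)
      Z <- row_softmax(relu(as.matrix(P %*% H1) %*% opt$par$W1) %*%
                         opt$par$W_fc)
      pred <- max.col(Z) - 1L
      monitor_idx <- if (length(mask_idx)) mask_idx else train_idx
      monitor_loss <- cross_entropy(Z, Y, monitor_idx)
      history <- rbind(history, data.frame(
        epoch = epoch,
        train_loss = cross_entropy(Z, Y, train_idx),
        train_acc = mean(pred[train_idx] == labels[train_idx]),
        mask_loss = if (length(mask_idx)) cross_entropy(Z, Y, mask_idx) else NA_real_,
        mask_acc = if (length(mask_idx))
          mean(pred[mask_idx] == labels[mask_idx]) else NA_real_))
      if (monitor_loss < best$loss - 1e-6) {
        best <- list(loss = monitor_loss, par = opt$par, epoch = epoch)
        wait <- 0L
      } else if (length(mask_idx)) {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    final_par <- if (length(mask_idx) && cfg$max_epochs > 0L) best$par
                 else opt$par
    structure(list(params = structure(final_par, class = "lg_gcn_params"),
                   history = history, epoch_stopped = epoch,
                   best_epoch = if (length(mask_idx)) best$epoch else epoch,
                   mask_idx = mask_idx, config = cfg),
              class = "lg_gcn_fit")
  })
}

#' Write / read a GCN parameter checkpoint as JSON
#'
#' Stores the three weight matrices with their shapes plus the training
#' configuration, so a trained model can be reloaded in a separate
#' process.
#'
#' @param fit an `lg_gcn_fit` (or bare `lg_gcn_params`).
#' @param path JSON file path.
#' @export
write_gcn_checkpoint <- function(fit, path) {
  params <- if (inherits(fit, "lg_gcn_fit")) fit$params else fit
  cfg <- if (inherits(fit, "lg_gcn_fit")) unclass(fit$config) else NULL
  jsonlite::write_json(list(
    shapes = lapply(params, dim),
    W0 = params$W0, W1 = params$W1, W_fc = params$W_fc, config = cfg),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gcn_checkpoint
#' @export
read_gcn_checkpoint <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(W0 = j$W0, W1 = j$W1, W_fc = j$W_fc),
            class = "lg_gcn_params")
}

#' Predict positive-class probabilities on a cohort graph
#'
#' Deterministic evaluation-mode forward pass; returns the
#' metastasis-positive probability (second softmax column) for every node.
#'
#' @param graph an `lg_graph`.
#' @param params trained `lg_gcn_params` (or an `lg_gcn_fit`).
#' @return numeric vector of length `graph$n_nodes`, named by patient id.
#' @export
gcn_predict <- function(graph, params) {
  if (inherits(params, "lg_gcn_fit")) params <- params$params
  Z <- gcn_forward(graph$p_hat, graph$X, params)$Z
  stats::setNames(Z[, 2L], graph$ids)
}
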