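# Deep-feature extraction behind a pluggable backbone contract.
#
# A backbone is a deterministic map from preprocessed images to fixed-width
# feature vectors. The reference backbone is a 50-layer residual network
# (bottleneck blocks 3-4-6-3) with the classification head removed, whose
# globally pooled final activation has width 2048. Tests never require
# pretrained weights: a randomly initialized reference backbone settles the
# dimensionality contract, and a tiny single-convolution backbone carries
# the end-to-end tests.

#' Construct a backbone contract
#'
#' @param name backbone name.
#' @param feature_dim width of the extracted feature vector.
#' @param apply function mapping a list of grayscale matrices to an
#'   n x feature_dim matrix; must be deterministic.
#' @param params optional parameter object carried for reproducibility.
#' @return an `lg_backbone`.
#' @export
backbone <- function(name, feature_dim, apply, params = NULL) {
  stopifnot(is.character(name), feature_dim >= 1, is.function(apply))
  structure(list(name = name, feature_dim = as.integer(feature_dim),
                 apply = apply, params = params), class = "lg_backbone")
}

# -- minimal conv-net numerics -----------------------------------------------

# 2-D convolution of an (h, w, c_in) array with (kh, kw, c_in, c_out)
# weights, implemented as one BLAS matmul per kernel offset.
conv2d <- function(x, W, stride = 1L, pad = 0L) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  h <- dim(x)[1]; w <- dim(x)[2]
  if (pad > 0L) {
    xp <- array(0, c(h + 2L * pad, w + 2L * pad, cin))
    xp[pad + seq_len(h), pad + seq_len(w), ] <- x
  } else xp <- x
  h_out <- (dim(xp)[1] - kh) %/% stride + 1L
  w_out <- (dim(xp)[2] - kw) %/% stride + 1L
  ri <- seq.int(1L, by = stride, length.out = h_out)
  ci <- seq.int(1L, by = stride, length.out = w_out)
  out <- matrix(0, h_out * w_out, cout)
  for (di in seq_len(kh)) for (dj in seq_len(kw)) {
    patch <- xp[ri + di - 1L, ci + dj - 1L, , drop = FALSE]
    dim(patch) <- c(h_out * w_out, cin)
    out <- out + patch %*% matrix(W[di, dj, , ], cin, cout)
  }
  array(out, c(h_out, w_out, cout))
}

maxpool2d <- function(x, k = 3L, stride = 2L, pad = 1L) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  xp <- array(-Inf, c(h + 2L * pad, w + 2L * pad, cin))
  xp[pad + seq_len(h), pad + seq_len(w), ] <- x
  h_out <- (dim(xp)[1] - k) %/% stride + 1L
  w_out <- (dim(xp)[2] - k) %/% stride + 1L
  ri <- seq.int(1L, by = stride, length.out = h_out)
  ci <- seq.int(1L, by = stride, length.out = w_out)
  out <- array(-Inf, c(h_out, w_out, cin))
  for (di in seq_len(k)) for (dj in seq_len(k))
    out <- pmax(out, xp[ri + di - 1L, ci + dj - 1L, , drop = FALSE])
  out
}

# Batch normalization in evaluation mode (fixed statistics).
batchnorm_eval <- function(x, bn) {
  scale <- bn$gamma / sqrt(bn$var + 1e-5)
  shift <- bn$beta - bn$mean * scale
  sweep(sweep(x, 3L, scale, `*`), 3L, shift, `+`)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

he_conv <- function(kh, kw, cin, cout)
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))

bn_identity <- function(c) list(gamma = rep(1, c), beta = rep(0, c),
                                mean = rep(0, c), var = rep(1, c))

# -- 50-layer residual reference backbone ------------------------------------

resnet50_params <- function(seed) {
  with_seed(seed, {
    widths <- c(64L, 128L, 256L, 512L)
    blocks <- c(3L, 4L, 6L, 3L)
    p <- list(conv1 = he_conv(7L, 7L, 3L, 64L), bn1 = bn_identity(64L),
              stages = vector("list", 4L))
    cin <- 64L
    for (s in seq_len(4L)) {
      w <- widths[s]; cout <- 4L * w
      stage <- vector("list", blocks[s])
      for (b in seq_len(blocks[s])) {
        stride <- if (b == 1L && s > 1L) 2L else 1L
        blk <- list(
          conv_a = he_conv(1L, 1L, cin, w), bn_a = bn_identity(w),
          conv_b = he_conv(3L, 3L, w, w), bn_b = bn_identity(w),
          conv_c = he_conv(1L, 1L, w, cout), bn_c = bn_identity(cout),
          stride = stride)
        if (b == 1L) {
          blk$down <- he_conv(1L, 1L, cin, cout)
          blk$bn_down <- bn_identity(cout)
        }
        stage[[b]] <- blk
        cin <- cout
      }
      p$stages[[s]] <- stage
    }
    p
  })
}

bottleneck_forward <- function(x, blk) {
  y <- relu(batchnorm_eval(conv2d(x, blk$conv_a), blk$bn_a))
  y <- relu(batchnorm_eval(conv2d(y, blk$conv_b, stride = blk$stride,
                                  pad = 1L), blk$bn_b))
  y <- batchnorm_eval(conv2d(y, blk$conv_c), blk$bn_c)
  sc <- if (!is.null(blk$down))
    batchnorm_eval(conv2d(x, blk$down, stride = blk$stride), blk$bn_down)
  else x
  relu(y + sc)
}

resnet50_forward <- function(image, params) {
  x <- array(rep(image, 3L), c(dim(image), 3L)) # replicate gray to 3 channels
  x <- relu(batchnorm_eval(conv2d(x, params$conv1, stride = 2L, pad = 3L),
                           params$bn1))
  x <- maxpool2d(x)
  for (stage in params$stages) for (blk in stage)
    x <- bottleneck_forward(x, blk)
  apply(x, 3L, mean) # global average pooling, width 2048
}

#' Reference 50-layer residual backbone
#'
#' Standard bottleneck architecture (3-4-6-3 blocks) with the fully
#' connected classification layer and softmax removed; the globally pooled
#' activation of the last convolutional stage is the 2048-wide deep-feature
#' vector. Weights are randomly initialized (He) from `seed`; pretrained
#' weights, when available, can be supplied as a drop-in `params` object of
#' the same structure. Batch normalization runs in evaluation mode, so
#' feature extraction is a pure function of (weights, image).
#'
#' @param seed RNG seed for weight initialization.
#' @param params optional pre-built parameter list (overrides `seed`).
#' @return an `lg_backbone` with `feature_dim = 2048`.
#' @export
resnet50_backbone <- function(seed = 1L, params = NULL) {
  if (is.null(params)) params <- resnet50_params(seed)
  backbone("resnet50", 2048L,
           apply = function(images) {
             t(vapply(images, resnet50_forward, numeric(2048L),
                      params = params))
           },
           params = params)
}

#' Tiny convolutional backbone for fast tests
#'
#' One 7x7 convolution (stride 4) with `feature_dim` He-initialized
#' filters, ReLU, and global average pooling. Cheap, deterministic, and
#' sensitive enough to lesion size/shape for end-to-end tests on toy
#' images.
#'
#' @param seed RNG seed for the filters.
#' @param feature_dim number of filters (= feature width).
#' @return an `lg_backbone`.
#' @export
tiny_cnn_backbone <- function(seed = 1L, feature_dim = 16L) {
  W <- with_seed(seed, he_conv(7L, 7L, 1L, feature_dim))
  backbone("tiny_cnn", feature_dim,
           apply = function(images) {
             t(vapply(images, function(im) {
               a <- relu(conv2d(array(im, c(dim(im), 1L)), W, stride = 4L))
               apply(a, 3L, mean)
             }, numeric(feature_dim)))
           },
           params = list(W = W))
}

#' Extract deep features from preprocessed images
#'
#' @param images a list of grayscale matrices (all the same size), or a
#'   single matrix.
#' @param backbone an `lg_backbone`.
#' @return an n x `feature_dim` matrix, rows in input order, columns named
#'   `fNNNN`.
#' @export
extract_features <- function(images, backbone) {
  stopifnot(inherits(backbone, "lg_backbone"))
  if (is.matrix(images)) images <- list(images)
  dims <- vapply(images, dim, integer(2L))
  if (ncol(dims) > 1L && any(dims != dims[, 1L]))
    stop("all images must share the same dimensions", call. = FALSE)
  F <- backbone$apply(images)
  if (!is.matrix(F) || ncol(F) != backbone$feature_dim)
    stop("backbone output width does not match its declared feature_dim",
         call. = FALSE)
  if (any(!is.finite(F))) stop("non-finite features extracted", call. = FALSE)
  colnames(F) <- sprintf("f%04d", seq_len(ncol(F)) - 1L)
  F
}

#' Fine-tuning configuration
#'
#' Training protocol for the temporary binary classification head:
#' cross-entropy loss, Adam, learning rate 1e-4, batch size 32, 200 epochs.
#'
#' @param learning_rate,batch_size,epochs,seed training hyperparameters.
#' @return an `lg_finetune_config`.
#' @export
fine_tune_config <- function(learning_rate = 1e-4, batch_size = 32L,
                             epochs = 200L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "lg_finetune_config")
}

#' Fit a temporary binary head on a backbone's features
#'
#' Attaches a softmax classification head to the backbone's feature output,
#' trains it with Adam on cross-entropy, then removes it, returning the
#' backbone with the trained head and its history stored as attributes
#' (`head`, `head_history`). The backbone's feature map itself is left
#' untouched, so extracted features are identical before and after.
#'
#' @param backbone an `lg_backbone`.
#' @param images list of preprocessed grayscale matrices.
#' @param labels binary labels (1 = metastasis-positive), both classes
#'   required.
#' @param cfg a [fine_tune_config()].
#' @return the backbone, with `head` and `head_history` attributes.
#' @export
fine_tune <- function(backbone, images, labels, cfg = fine_tune_config()) {
  labels <- as.integer(labels)
  assert_binary_labels(labels)
  F <- extract_features(images, backbone)
  # the head trains on standardized features: raw pooled activations have
  # arbitrary scale, which stalls first-order optimization
  scaler <- suppressWarnings(fit_standardizer(F))
  F <- apply_standardizer(scaler, F)
  n <- nrow(F); d <- ncol(F)
  Y <- one_hot(labels, 2L)
  with_seed(cfg$seed, {
    W <- matrix(rnorm(d * 2L, sd = 1 / sqrt(d)), d, 2L)
    b <- c(0, 0)
    opt <- adam_state(list(W = W, b = b))
    history <- NULL
    if (cfg$epochs > 0L) {
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample.int(n)
        for (start in seq.int(1L, n, by = cfg$batch_size)) {
          idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
          P <- row_softmax(F[idx, , drop = FALSE] %*% opt$par$W +
                             matrix(opt$par$b, length(idx), 2L, byrow = TRUE))
          G <- (P - Y[idx, , drop = FALSE]) / length(idx)
          grads <- list(W = crossprod(F[idx, , drop = FALSE], G),
                        b = colSums(G))
          opt <- adam_step(opt, grads, cfg$learning_rate)
        }
        P <- row_softmax(F %*% opt$par$W +
                           matrix(opt$par$b, n, 2L, byrow = TRUE))
        history <- rbind(history, data.frame(
          epoch = ep, loss = -mean(log(rowSums(P * Y) + 1e-12)),
          accuracy = mean((P[, 2L] >= 0.5) == (labels == 1L))))
      }
    }
    attr(backbone, "head") <- c(opt$par, list(scaler = scaler))
    attr(backbone, "head_history") <- history
    backbone
  })
}
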