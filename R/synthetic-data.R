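# Synthetic stand-in for the three private hospital cohorts.
#
# The real study data (B-mode breast ultrasound with confirmed axillary
# node status) are not deposited, so the pipeline is exercised on cohorts
# drawn from a generative model with a known answer: class-conditional
# equal-covariance Gaussians in a small informative subspace, planted
# rank-correlated redundant columns to exercise the Spearman filter, and
# pure-noise nuisance columns. The equal-covariance Gaussian family is
# chosen because its Bayes-optimal AUC has the closed form
# Phi(Delta / sqrt(2)), where Delta is the Mahalanobis distance between
# class means, which gives every downstream accuracy claim an analytic
# reference point.

#' Specification of a synthetic patient cohort
#'
#' @param n_patients number of patients (rows).
#' @param prevalence expected fraction of metastasis-positive labels, in (0,1).
#' @param n_features total feature count; the deep-feature stand-in defaults
#'   to the 2048 activations of a 50-layer residual backbone.
#' @param n_informative number of label-carrying Gaussian columns.
#' @param n_redundant number of planted redundant columns, each a noisy
#'   monotone copy of an informative partner column.
#' @param redundancy_rho target absolute Spearman correlation of a redundant
#'   column with its partner; must exceed 0.85 so the redundancy filter can
#'   remove the planted pairs.
#' @param class_separation Mahalanobis distance between the class means in
#'   the informative subspace. The Bayes-optimal AUC of the generative model
#'   is `pnorm(class_separation / sqrt(2))`.
#' @param seed integer RNG seed.
#' @param id_prefix prefix for patient identifiers.
#' @param mean_shift optional per-column mean offset applied to every
#'   feature, a knob for emulating mild cohort shift (default 0).
#' @return an object of class `lg_cohort_spec`.
#' @export
cohort_spec <- function(n_patients, prevalence, n_features = 2048L,
                        n_informative = 10L, n_redundant = 20L,
                        redundancy_rho = 0.95, class_separation = 2,
                        seed = 1L, id_prefix = "P", mean_shift = 0) {
  for (nm in c("n_patients", "prevalence", "n_features", "n_informative",
               "n_redundant", "redundancy_rho", "class_separation", "seed",
               "mean_shift"))
    assert_scalar_number(get(nm), nm)
  if (n_patients < 1 || n_features < 1 || n_informative < 0 || n_redundant < 0)
    stop("cohort dimensions must be positive", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1)
    stop("`prevalence` must lie strictly in (0, 1)", call. = FALSE)
  if (prevalence * n_patients < 1)
    stop("`prevalence * n_patients` must be at least 1", call. = FALSE)
  if (n_informative + n_redundant > n_features)
    stop("n_informative + n_redundant must not exceed n_features", call. = FALSE)
  if (class_separation < 0)
    stop("`class_separation` must be non-negative", call. = FALSE)
  if (n_informative == 0 && class_separation > 0)
    stop("class_separation > 0 requires at least one informative column",
         call. = FALSE)
  if (n_redundant > 0 && n_informative == 0)
    stop("redundant columns need informative partner columns", call. = FALSE)
  if (n_redundant > 0 && (redundancy_rho <= 0.85 || redundancy_rho > 1))
    stop("`redundancy_rho` must lie in (0.85, 1] so planted pairs are removable",
         call. = FALSE)
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 redundancy_rho = redundancy_rho,
                 class_separation = class_separation, seed = as.integer(seed),
                 id_prefix = id_prefix, mean_shift = mean_shift),
            class = "lg_cohort_spec")
}

# Deterministic scatter of planted columns across the feature vector.
# Depends only on the dimensions, never on the cohort seed, so cohorts of
# different sizes drawn from the same generative model share their truth
# columns and training-fit selectors transfer to the validation cohorts.
planted_layout <- function(n_features, n_informative, n_redundant) {
  with_seed(stage_seed(0L, sprintf("layout-%d-%d-%d", n_features,
                                   n_informative, n_redundant)), {
    # copies are planted downstream (larger indices) of their sources, the
    # way a derived feature follows what it derives from; the order-stable
    # drop-the-later-column rule of the Spearman filter then removes the
    # copy, never the source
    idx <- sort(sample.int(n_features, n_informative + n_redundant))
    list(informative = idx[seq_len(n_informative)],
         redundant = idx[n_informative + seq_len(n_redundant)])
  })
}

#' Generate one synthetic feature cohort
#'
#' Labels are Bernoulli(prevalence). Informative columns are unit-variance
#' Gaussians whose class means differ by `class_separation / sqrt(n_informative)`
#' each, so the joint Mahalanobis separation equals `class_separation`.
#' Redundant columns are signed linear copies of an informative partner plus
#' Gaussian noise; the noise scale is calibrated through the bivariate-normal
#' identity `rho_pearson = 2 sin(pi * rho_spearman / 6)` so the planted pairs
#' reach the target Spearman correlation in expectation. Remaining columns
#' are pure noise.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `lg_cohort` with fields `ids`, `features`
#'   (n x p matrix with `fNNNN` column names), `labels` (integer 0/1, 1 =
#'   metastasis-positive) and `truth` (planted column indices, partner map
#'   and the closed-form Bayes AUC).
#' @export
generate_feature_cohort <- function(spec) {
  stopifnot(inherits(spec, "lg_cohort_spec"))
  n <- spec$n_patients
  p <- spec$n_features
  layout <- planted_layout(p, spec$n_informative, spec$n_redundant)
  with_seed(spec$seed, {
    labels <- rbinom(n, 1L, spec$prevalence)
    X <- matrix(rnorm(n * p), n, p)
    if (spec$n_informative > 0 && spec$class_separation > 0) {
      delta <- spec$class_separation / sqrt(spec$n_informative)
      X[, layout$informative] <- X[, layout$informative] +
        outer(labels, rep(delta, spec$n_informative))
    }
    partners <- integer(0)
    if (spec$n_redundant > 0) {
      partners <- layout$informative[1L + (seq_len(spec$n_redundant) - 1L) %%
                                       spec$n_informative]
      rho_p <- min(1, 2 * sin(pi * spec$redundancy_rho / 6))
      noise_sd <- sqrt(max(0, 1 / rho_p^2 - 1))
      signs <- rep_len(c(1, -1), spec$n_redundant)
      X[, layout$redundant] <- sweep(X[, partners, drop = FALSE], 2L, signs,
                                     `*`) +
        noise_sd * matrix(rnorm(n * spec$n_redundant), n)
    }
    if (spec$mean_shift != 0) X <- X + spec$mean_shift
    colnames(X) <- sprintf("f%04d", seq_len(p) - 1L)
    structure(list(
      ids = sprintf("%s%04d", spec$id_prefix, seq_len(n)),
      features = X,
      labels = as.integer(labels),
      truth = list(informative = layout$informative,
                   redundant = layout$redundant, partners = partners,
                   bayes_auc = pnorm(spec$class_separation / sqrt(2))),
      spec = spec), class = "lg_cohort")
  })
}

#' @export
print.lg_cohort <- function(x, ...) {
  cat(sprintf("<lg_cohort> %d patients x %d features, %d metastasis-positive (%.1f%%)\n",
              nrow(x$features), ncol(x$features), sum(x$labels),
              100 * mean(x$labels)))
  cat(sprintf("  planted: %d informative, %d redundant; Bayes AUC %.3f\n",
              length(x$truth$informative), length(x$truth$redundant),
              x$truth$bayes_auc))
  invisible(x)
}

#' Generate toy lesion images
#'
#' Each image is a speckle-noise background carrying one hypoechoic
#' elliptical "lesion". Metastasis-positive lesions are drawn larger and
#' with irregular margins, so shape statistics carry the label signal and a
#' downstream feature extractor has something to find. Bounding boxes are
#' tight around the lesion, 0-based and half-open.
#'
#' @param n number of images.
#' @param prevalence expected fraction of positive labels.
#' @param seed RNG seed; identical arguments reproduce the images bit for bit.
#' @param size image side length in pixels.
#' @return a list of `lg_toy_image` objects, each with fields `pixels`
#'   (size x size matrix in \[0,1\]), `bbox` (x_min, y_min, x_max, y_max)
#'   and `label`.
#' @export
generate_toy_images <- function(n, prevalence = 0.4, seed = 1L, size = 96L) {
  stopifnot(n >= 1, size >= 32, prevalence > 0, prevalence < 1)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      label <- rbinom(1L, 1L, prevalence)
      px <- matrix(pmin(1, pmax(0, 0.38 + 0.09 * rnorm(size * size))),
                   size, size)
      # positives: larger semi-axes and wobblier margins; lesion size
      # scales with the image so small test images stay feasible
      sc <- size / 96
      ax <- sc * (if (label == 1L) runif(1, 12, 20) else runif(1, 7, 12))
      by <- sc * (if (label == 1L) runif(1, 12, 20) else runif(1, 7, 12))
      wobble_amp <- if (label == 1L) 0.22 else 0.05
      ph <- runif(3, 0, 2 * pi)
      cx <- runif(1, ax * 1.4, size - ax * 1.4)
      cy <- runif(1, by * 1.4, size - by * 1.4)
      xs <- matrix(seq_len(size), size, size, byrow = TRUE) # column = x
      ys <- matrix(seq_len(size), size, size)               # row = y
      u <- (xs - cx) / ax
      v <- (ys - cy) / by
      r <- sqrt(u^2 + v^2)
      th <- atan2(v, u)
      edge <- 1 + wobble_amp * (sin(2 * th + ph[1]) + 0.6 * sin(3 * th + ph[2]) +
                                  0.4 * sin(5 * th + ph[3])) / 2
      inside <- r <= edge
      px[inside] <- pmin(1, pmax(0, 0.13 + 0.05 * rnorm(sum(inside))))
      cols <- range(which(apply(inside, 2, any)))
      rows <- range(which(apply(inside, 1, any)))
      bbox <- c(x_min = cols[1] - 1L, y_min = rows[1] - 1L,
                x_max = cols[2], y_max = rows[2])
      structure(list(pixels = px, bbox = bbox, label = label),
                class = "lg_toy_image")
    })
  })
}

#' Generate the three study cohorts
#'
#' Draws a training cohort and two external validation cohorts with the
#' study's sizes (621 / 112 / 87) and metastasis prevalences
#' (0.346 / 0.402 / 0.402), all from the same generative model so that
#' selectors fitted on the training cohort transfer.
#'
#' @param seed global seed; per-cohort seeds are derived with [stage_seed()].
#' @param class_separation Mahalanobis separation of the informative
#'   subspace (default 2, Bayes AUC about 0.921).
#' @param n_features,n_informative,n_redundant,redundancy_rho generative
#'   model dimensions shared by the three cohorts.
#' @return a list with elements `train`, `val1`, `val2`, each an `lg_cohort`.
#' @export
make_study_cohorts <- function(seed = 1L, class_separation = 2,
                               n_features = 2048L, n_informative = 10L,
                               n_redundant = 20L, redundancy_rho = 0.95) {
  sizes <- c(train = 621L, val1 = 112L, val2 = 87L)
  prev <- c(train = 0.346, val1 = 0.402, val2 = 0.402)
  prefix <- c(train = "TR", val1 = "V1", val2 = "V2")
  out <- lapply(names(sizes), function(k) {
    generate_feature_cohort(cohort_spec(
      n_patients = sizes[[k]], prevalence = prev[[k]],
      n_features = n_features, n_informative = n_informative,
      n_redundant = n_redundant, redundancy_rho = redundancy_rho,
      class_separation = class_separation,
      seed = stage_seed(seed, paste0("cohort-", k)), id_prefix = prefix[[k]]))
  })
  names(out) <- names(sizes)
  out
}
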