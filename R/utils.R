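# Internal helpers shared across modules.

#' Derive a stage-specific seed from a global seed
#'
#' A single experiment seed fans out to per-stage seeds so that individual
#' pipeline stages can be re-run in isolation and still reproduce the full
#' run. The stage name is hashed with a small polynomial rolling hash and
#' folded into the global seed modulo 2^31 - 1, keeping the result a valid
#' 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param stage character scalar naming the stage (e.g. "simulate", "train").
#' @return an integer seed in [0, 2^31 - 2].
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage),
            length(stage) == 1L)
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  as.integer((abs(seed) + h) %% m)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

assert_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}

assert_binary_labels <- function(labels) {
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary (0 = node-negative, 1 = metastasis-positive)",
         call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  invisible(labels)
}
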