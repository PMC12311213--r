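# Interchange formats: per-patient feature CSV, bounding-box CSV, PNG
# images, edge-list TSV and Matrix Market adjacency.

#' Write / read a cohort feature table as CSV
#'
#' Columns are `id`, the `fNNNN` feature columns, and `label`. The reader
#' validates unique ids, finite features and binary labels.
#'
#' @param cohort an `lg_cohort` (or any list with `ids`, `features`, `labels`).
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns an `lg_cohort` (without generative `truth`).
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- data.frame(id = cohort$ids, cohort$features,
                   label = cohort$labels, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df)[1], "id") || !identical(names(df)[ncol(df)], "label"))
    stop("malformed feature CSV: expected columns id, f..., label", call. = FALSE)
  dup <- df$id[duplicated(df$id)]
  if (length(dup))
    stop(sprintf("duplicate patient id: %s", dup[1]), call. = FALSE)
  X <- as.matrix(df[, setdiff(names(df), c("id", "label")), drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X)))
    stop("non-finite feature values in feature CSV", call. = FALSE)
  labels <- as.integer(df$label)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  structure(list(ids = as.character(df$id), features = X, labels = labels,
                 truth = NULL, spec = NULL), class = "lg_cohort")
}

#' Write / read toy images as PNG plus a bounding-box CSV
#'
#' The CSV has columns `id, x_min, y_min, x_max, y_max, label` with 0-based
#' half-open pixel coordinates; each image is stored as `<id>.png`.
#'
#' @param images list of `lg_toy_image`.
#' @param dir output directory (created if needed).
#' @return invisibly, the bbox CSV path.
#' @export
write_toy_images <- function(images, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("IMG%04d", seq_along(images))
  for (i in seq_along(images))
    png::writePNG(images[[i]]$pixels, file.path(dir, paste0(ids[i], ".png")))
  bb <- do.call(rbind, lapply(images, function(im) im$bbox))
  df <- data.frame(id = ids, bb, label = vapply(images, `[[`, 0L, "label"))
  path <- file.path(dir, "bboxes.csv")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_toy_images
#' @param bbox_csv path to the bounding-box CSV written by [write_toy_images()].
#' @export
read_toy_images <- function(bbox_csv) {
  df <- utils::read.csv(bbox_csv)
  dir <- dirname(bbox_csv)
  lapply(seq_len(nrow(df)), function(i) {
    px <- png::readPNG(file.path(dir, paste0(df$id[i], ".png")))
    if (length(dim(px)) == 3L) px <- to_grayscale(px)
    structure(list(pixels = px,
                   bbox = c(x_min = df$x_min[i], y_min = df$y_min[i],
                            x_max = df$x_max[i], y_max = df$y_max[i]),
                   label = as.integer(df$label[i])), class = "lg_toy_image")
  })
}

#' Write / read a graph edge list as TSV
#'
#' Columns `source_id`, `target_id`, `similarity`.
#'
#' @param graph an `lg_graph` from [assemble_graph()].
#' @param path file path.
#' @export
write_edge_tsv <- function(graph, path) {
  e <- graph$edges
  df <- data.frame(source_id = graph$ids[e$i], target_id = graph$ids[e$j],
                   similarity = e$similarity)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_tsv
#' @export
read_edge_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "numeric"))
}

#' Write / read a binary adjacency matrix in Matrix Market format
#'
#' @param A adjacency matrix (dense or sparse, symmetric 0/1).
#' @param path file path (conventionally `.mtx`).
#' @export
write_adjacency_mtx <- function(A, path) {
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                                          "dMatrix"), "generalMatrix"), path)
  invisible(path)
}

#' @rdname write_adjacency_mtx
#' @export
read_adjacency_mtx <- function(path) {
  # pattern-format files read as logical; normalize to numeric 0/1
  m <- Matrix::readMM(path)
  methods::as(methods::as(m, "dMatrix"), "CsparseMatrix")
}
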