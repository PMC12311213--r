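# Patient graphs: nodes are patients of one cohort, edges connect pairs
# whose selected-feature vectors have cosine similarity at or above a
# threshold. Each cohort gets its own graph; edges never cross cohorts.

#' Cosine similarity between the rows of a matrix
#'
#' `S[i, j] = <x_i, x_j> / (||x_i|| ||x_j||)`; symmetric with unit
#' diagonal. Rows with zero norm are rejected because their direction is
#' undefined.
#'
#' @param X n x d matrix (rows = patients).
#' @param ids optional row identifiers used in error messages.
#' @return an n x n similarity matrix.
#' @export
cosine_similarity_matrix <- function(X, ids = rownames(X)) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) {
    bad <- which(nrm == 0)[1]
    lab <- if (!is.null(ids)) ids[bad] else as.character(bad)
    stop(sprintf("row %s has zero norm; cosine similarity undefined", lab),
         call. = FALSE)
  }
  S <- tcrossprod(X / nrm)
  S <- pmin(pmax(S, -1), 1)
  diag(S) <- 1
  S
}

#' Threshold a similarity matrix into an edge list
#'
#' An edge (i, j), i < j, is created iff `S[i, j] >= threshold`
#' (inclusive). Self-pairs are never edges; self-loops enter only through
#' `A + I` during normalization.
#'
#' @param S symmetric similarity matrix.
#' @param threshold similarity cutoff in \[-1, 1\] (values above 1 give an
#'   empty edge set).
#' @return data frame with columns `i`, `j` (1-based, `i < j`) and
#'   `similarity`.
#' @export
build_edges <- function(S, threshold) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), threshold >= -1)
  up <- which(upper.tri(S) & S >= threshold, arr.ind = TRUE)
  data.frame(i = up[, 1L], j = up[, 2L],
             similarity = S[up])
}

#' Symmetrically normalized self-looped adjacency
#'
#' Computes `P = D_tilde^(-1/2) (A + I) D_tilde^(-1/2)` where `D_tilde` is
#' the diagonal degree matrix of `A + I`. Self-loops guarantee every row
#' has degree at least 1, so the normalization is always defined; an
#' isolated node's row is the corresponding standard basis vector. The
#' result is symmetric with spectral radius 1.
#'
#' @param A symmetric 0/1 adjacency matrix with zero diagonal (dense or
#'   sparse).
#' @return a sparse symmetric `Matrix`.
#' @export
normalize_adjacency <- function(A) {
  A <- Matrix::Matrix(A, sparse = TRUE)
  if (!Matrix::isSymmetric(A)) stop("adjacency must be symmetric", call. = FALSE)
  a_tilde <- A + Matrix::Diagonal(nrow(A))
  dmh <- 1 / sqrt(Matrix::rowSums(a_tilde))
  Matrix::Diagonal(x = dmh) %*% a_tilde %*% Matrix::Diagonal(x = dmh)
}

#' Assemble a cohort patient graph
#'
#' From a node table (ids, selected features, labels) and a similarity
#' threshold, builds the edge list, adjacency `A`, self-looped `A + I`,
#' degree vector and the normalized propagation matrix used by the GCN.
#'
#' @param node_table list with `ids`, `X` (n x d selected-feature matrix)
#'   and `labels`; see [node_table()].
#' @param threshold cosine similarity cutoff.
#' @param S optional precomputed similarity matrix (saves recomputation
#'   when several thresholds are applied to one cohort).
#' @return an `lg_graph`: `ids`, `X`, `labels`, `n_nodes`, `edges`, `S`,
#'   `A` (sparse), `a_tilde`, `d_tilde` (degree vector of `A + I`),
#'   `p_hat`, `threshold`.
#' @export
assemble_graph <- function(node_table, threshold, S = NULL) {
  stopifnot(is.list(node_table), !is.null(node_table$X))
  X <- node_table$X
  n <- nrow(X)
  if (is.null(S)) S <- cosine_similarity_matrix(X, node_table$ids)
  edges <- build_edges(S, threshold)
  A <- Matrix::sparseMatrix(i = c(edges$i, edges$j), j = c(edges$j, edges$i),
                            x = 1, dims = c(n, n))
  a_tilde <- A + Matrix::Diagonal(n)
  structure(list(ids = node_table$ids, X = X, labels = node_table$labels,
                 n_nodes = n, edges = edges, S = S, A = A,
                 a_tilde = a_tilde, d_tilde = Matrix::rowSums(a_tilde),
                 p_hat = normalize_adjacency(A), threshold = threshold),
            class = "lg_graph")
}

#' Build a node table
#'
#' The per-cohort object behind the graph: d selected features plus a
#' unique id and the target class per patient (d + 2 columns when written
#' out; 22 selected features give the study's 24-column geometry).
#'
#' @param ids unique patient identifiers.
#' @param X n x d feature matrix (standardized, selected features).
#' @param labels binary labels.
#' @return a list with class `lg_node_table`.
#' @export
node_table <- function(ids, X, labels) {
  stopifnot(length(ids) == nrow(X), length(labels) == nrow(X))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate patient id: %s", ids[duplicated(ids)][1]),
         call. = FALSE)
  structure(list(ids = as.character(ids), X = X,
                 labels = as.integer(labels)), class = "lg_node_table")
}

#' Summarize a patient graph
#'
#' @param graph an `lg_graph`.
#' @return list with `n_nodes`, `n_edges`, `n_components`, `density` and
#'   `threshold`.
#' @export
graph_summary <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(graph$n_nodes)))
  list(n_nodes = graph$n_nodes, n_edges = nrow(graph$edges),
       n_components = igraph::count_components(g),
       density = if (graph$n_nodes > 1)
         nrow(graph$edges) / choose(graph$n_nodes, 2) else 0,
       threshold = graph$threshold)
}

#' Export connected components and edge list
#'
#' Writes the edge list as TSV (`source_id`, `target_id`, `similarity`)
#' and a per-component node listing (components of size >= 2 first, then
#' isolated nodes), the minimal analogue of plotting only the connected
#' components.
#'
#' @param graph an `lg_graph`.
#' @param path directory to write into (created if needed).
#' @return invisibly, the paths written.
#' @export
export_components <- function(graph, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  edge_path <- file.path(path, "edges.tsv")
  write_edge_tsv(graph, edge_path)
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(graph$n_nodes)))
  comp <- igraph::components(g)
  comp_df <- data.frame(component = comp$membership,
                        id = graph$ids,
                        label = graph$labels)
  comp_df <- comp_df[order(comp$csize[comp$membership], decreasing = TRUE), ]
  comp_path <- file.path(path, "components.tsv")
  utils::write.table(comp_df, comp_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(edges = edge_path, components = comp_path))
}
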