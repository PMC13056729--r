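#' Spatial adjacency by distance threshold
#'
#' Two spots are adjacent iff their Euclidean distance is at most `r`
#' (self-pairs excluded). For Visium-scale pixel coordinates 550 covers a spot
#' and its six immediate hexagonal neighbours; Slide-seqV2-like coordinates
#' use 50.
#'
#' @param coords n x 2 numeric matrix of spot coordinates.
#' @param r positive radius, in the same units as `coords`.
#' @return A sparse symmetric binary `dgCMatrix` with zero diagonal.
#' @export
build_spatial_graph <- function(coords, r) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stopf("coords contains non-finite values")
  if (r <= 0) stopf("radius r must be positive")
  n <- nrow(coords)
  if (n == 1) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(1, 1)))
  }
  D <- as.matrix(stats::dist(coords))
  adj <- (D <= r)
  diag(adj) <- FALSE
  methods::as(Matrix::Matrix(adj * 1, sparse = TRUE), "generalMatrix")
}

#' Feature graph by cosine k-nearest neighbours
#'
#' Directed kNN under cosine similarity of expression rows (self excluded,
#' similarity ties broken towards the lower spot index), then symmetrised by
#' union, so every spot keeps at least `k` feature neighbours.
#'
#' @param X n x d numeric matrix (preprocessed expression).
#' @param k neighbours per spot, `1 <= k < n`.
#' @return A sparse symmetric binary `dgCMatrix` with zero diagonal.
#' @export
build_feature_graph <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k >= n) stopf("k must satisfy 1 <= k < n (got k = %d, n = %d)", k, n)
  nrm <- sqrt(rowSums(X * X))
  if (any(nrm == 0)) {
    stopf("all-zero expression row(s): spot index %s (cosine similarity undefined)",
          paste(which(nrm == 0), collapse = ", "))
  }
  S <- tcrossprod(X / nrm)
  diag(S) <- -Inf
  # top-k per row, descending similarity, ties to lower index
  nbr <- t(apply(S, 1, function(s) order(-s, seq_along(s))[seq_len(k)]))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(nbr)),
                            x = 1, dims = c(n, n))
  A <- (A + Matrix::t(A)) > 0           # union symmetrisation
  methods::as(Matrix::Matrix(A * 1, sparse = TRUE), "generalMatrix")
}

#' Symmetric normalisation with self-loops
#'
#' Returns `D^-1/2 (A + I) D^-1/2`, the propagation operator of the graph
#' convolutions; `D` is the degree matrix of `A + I`. Isolated nodes map to a
#' self-weight of 1.
#'
#' @param A square sparse symmetric binary matrix with zero diagonal.
#' @return Sparse symmetric `dgCMatrix` with spectral radius <= 1.
#' @export
normalize_adjacency <- function(A) {
  A <- methods::as(A, "CsparseMatrix")
  if (nrow(A) != ncol(A)) stopf("A must be square")
  if (!Matrix::isSymmetric(A)) stopf("A must be symmetric")
  if (any(Matrix::diag(A) != 0)) stopf("A must have a zero diagonal")
  At <- A + Matrix::Diagonal(nrow(A))
  dis <- 1 / sqrt(Matrix::rowSums(At))
  methods::as(Matrix::Diagonal(x = dis) %*% At %*% Matrix::Diagonal(x = dis),
              "generalMatrix")
}

#' Build both graphs and their normalised forms
#'
#' @param ds a preprocessed [spot_dataset()].
#' @param r spatial radius (see [build_spatial_graph()]).
#' @param k feature-graph neighbours (default 15).
#' @return A list of class `dual_graph` with `A_s`, `A_f`, `A_s_norm`,
#'   `A_f_norm`, and the config.
#' @export
build_dual_graph <- function(ds, r, k = 15) {
  A_s <- build_spatial_graph(ds$coords, r)
  A_f <- build_feature_graph(ds$expr, k)
  structure(list(A_s = A_s, A_f = A_f,
                 A_s_norm = normalize_adjacency(A_s),
                 A_f_norm = normalize_adjacency(A_f),
                 r = r, k = k),
            class = "dual_graph")
}

#' @export
print.dual_graph <- function(x, ...) {
  cat(sprintf("dual_graph: n = %d spots; spatial edges = %d (r = %g); feature edges = %d (k = %d)\n",
              nrow(x$A_s), sum(x$A_s) / 2, x$r, sum(x$A_f) / 2, x$k))
  invisible(x)
}

#' Export a graph as an edge-list TSV
#'
#' Writes one row per undirected edge (`i`, `j`, `weight`), 1-based indices,
#' `i < j`.
#'
#' @param A sparse symmetric matrix.
#' @param path output file.
#' @export
write_edge_list <- function(A, path) {
  T3 <- Matrix::summary(methods::as(A, "TsparseMatrix"))
  T3 <- T3[T3$i < T3$j, , drop = FALSE]
  utils::write.table(data.frame(i = T3$i, j = T3$j, weight = T3$x),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
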