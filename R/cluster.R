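# Domain calling on learned embeddings and agreement scoring.

kmeanspp_init <- function(H, K) {
  n <- nrow(H)
  centers <- matrix(0, K, ncol(H))
  centers[1, ] <- H[sample.int(n, 1), ]
  d2 <- rowSums((H - matrix(centers[1, ], n, ncol(H), byrow = TRUE))^2)
  for (kk in seq_len(K - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[kk + 1, ] <- H[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums((H - matrix(centers[kk + 1, ], n, ncol(H), byrow = TRUE))^2))
  }
  centers
}

lloyd <- function(H, centers, max_iter = 100) {
  n <- nrow(H); K <- nrow(centers)
  hsq <- rowSums(H * H)
  lab <- integer(n)
  for (it in seq_len(max_iter)) {
    D <- outer(hsq, rowSums(centers * centers), "+") - 2 * H %*% t(centers)
    new_lab <- max.col(-D, ties.method = "first")
    # empty clusters: re-seed from the point farthest from its centre
    for (kk in which(tabulate(new_lab, K) == 0)) {
      far <- which.max(D[cbind(seq_len(n), new_lab)])
      centers[kk, ] <- H[far, ]
      new_lab[far] <- kk
      D[, kk] <- rowSums((H - matrix(centers[kk, ], n, ncol(H), byrow = TRUE))^2)
    }
    if (it > 1 && all(new_lab == lab)) break
    lab <- new_lab
    centers <- rowsum(H, lab) / as.vector(tabulate(lab, K))
  }
  wcss <- sum((H - centers[lab, , drop = FALSE])^2)
  list(labels = lab, centers = centers, wcss = wcss)
}

#' Call spatial domains by K-means on embeddings
#'
#' K-means with k-means++ initialisation; `restarts` independent seeded runs,
#' keeping the run with the lowest within-cluster sum of squares. Empty
#' clusters are re-seeded from the farthest point.
#'
#' @param H n x h embedding matrix.
#' @param K number of domains (`K <= n`).
#' @param seed integer seed.
#' @param restarts independent runs (default 10).
#' @return list of class `domain_assignment` with 0-based `labels`, `K`,
#'   `centroids` and `wcss`.
#' @export
cluster_domains <- function(H, K, seed = 0L, restarts = 10) {
  H <- as.matrix(H)
  if (K > nrow(H)) stopf("K (%d) exceeds number of spots (%d)", K, nrow(H))
  best <- NULL
  withr_seed(as.integer(seed), {
    for (r in seq_len(restarts)) {
      fit <- lloyd(H, kmeanspp_init(H, K))
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
  })
  structure(list(labels = best$labels - 1L, K = as.integer(K),
                 centroids = best$centers, wcss = best$wcss),
            class = "domain_assignment")
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two labelings, corrected for chance under
#' the permutation model; 1 = identical partitions, ~0 = random agreement.
#'
#' @param labels_a,labels_b vectors of equal length.
#' @return scalar in \[-1, 1\].
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stopf("label vectors differ in length (%d vs %d)",
          length(labels_a), length(labels_b))
  }
  if (!length(labels_a)) stopf("empty labelings")
  tab <- table(labels_a, labels_b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  tot <- ch2(length(labels_a))
  expected <- sum_a * sum_b / tot
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (mx - expected)
}

#' Majority-vote spatial smoothing of domain labels
#'
#' One pass: a spot whose label disagrees with more than half of its spatial
#' neighbours adopts the neighbourhood majority. Disabled by default so the
#' headline output is the raw K-means assignment.
#'
#' @param labels integer vector.
#' @param A_s sparse spatial adjacency.
#' @param enabled apply the smoothing (default `FALSE` returns the input).
#' @return integer vector of the same length.
#' @export
refine_spatial <- function(labels, A_s, enabled = FALSE) {
  if (!enabled) return(labels)
  out <- labels
  T3 <- Matrix::summary(methods::as(A_s, "TsparseMatrix"))
  nbrs <- split(T3$j, T3$i)
  for (i in as.integer(names(nbrs))) {
    nb <- labels[nbrs[[as.character(i)]]]
    tt <- table(nb)
    top <- names(tt)[which.max(tt)]
    if (tt[top] > length(nb) / 2 && top != as.character(labels[i])) {
      out[i] <- as.integer(top)
    }
  }
  out
}
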