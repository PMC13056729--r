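# Spatial-aware Deep Graph Infomax: degree-weighted readout, bilinear
# discriminator with a spatial bias, adaptive hard-negative mining, and the
# contrastive objective.

#' Degree-weighted global readout
#'
#' Pools node embeddings into one global summary using spatial centrality
#' weights `w_i = 1 + deg_s(i)` (the +1 keeps isolated spots contributing),
#' then squashes the weighted mean through a sigmoid so the summary stays
#' bounded for the bilinear discriminator. Set `squash = FALSE` for the plain
#' weighted mean.
#'
#' @param H n x h embedding matrix.
#' @param A_s sparse spatial adjacency.
#' @param squash apply the sigmoid (default `TRUE`).
#' @return list with `s` (length-h summary) and `w` (length-n weights).
#' @export
spatial_readout <- function(H, A_s, squash = TRUE) {
  w <- 1 + Matrix::rowSums(A_s)
  s_raw <- colSums(H * w) / sum(w)
  list(s = if (squash) sigmoid(s_raw) else s_raw, s_raw = s_raw, w = w)
}

#' Discriminator score for one (node, summary) pair
#'
#' `sigmoid(h' W_spatial s + bias)`, where the spatial bias of spot i is a
#' learnable scalar times its normalised spatial degree.
#'
#' @param h_i length-h node embedding.
#' @param s length-h global summary.
#' @param bias_i scalar spatial bias term.
#' @param W_spatial h x h bilinear weight matrix.
#' @return probability in (0, 1).
#' @export
discriminate <- function(h_i, s, bias_i, W_spatial) {
  sigmoid(sum(h_i * (W_spatial %*% s)) + bias_i)
}

# Per-spot spatial bias vector: b0 * deg / max_deg (0 when the graph is edgeless)
spatial_bias_vec <- function(A_s, b0) {
  deg <- Matrix::rowSums(A_s)
  mx <- max(deg)
  if (mx == 0) rep(0, length(deg)) else b0 * deg / mx
}

#' Adaptive hard-negative selection
#'
#' For each spot i, excludes itself and its spatial and feature neighbours,
#' then picks the remaining spot with maximal cosine similarity of embeddings
#' (ties to the lower index). Spots whose candidate set is empty fall back to
#' a seeded uniform random spot (never i itself).
#'
#' @param H n x h embedding matrix.
#' @param A_s,A_f sparse binary adjacencies.
#' @param rng_seed integer seed controlling only the random fallback.
#' @return integer vector `neg_index` of length n.
#' @export
select_hard_negatives <- function(H, A_s, A_f, rng_seed = 0L) {
  n <- nrow(H)
  if (n < 2) stopf("hard-negative selection needs at least 2 spots")
  S <- row_cosine_similarity(H)
  excl <- methods::as((A_s + A_f) > 0, "TsparseMatrix")
  S[cbind(excl@i + 1L, excl@j + 1L)] <- -Inf
  diag(S) <- -Inf
  neg <- max.col(S, ties.method = "first")
  empty <- !is.finite(S[cbind(seq_len(n), neg)])
  if (any(empty)) {
    idx <- which(empty)
    rnd <- withr_seed(rng_seed, {
      vapply(idx, function(i) sample.int(n - 1L, 1L), integer(1))
    })
    rnd <- rnd + (rnd >= idx)   # skip i itself
    neg[idx] <- rnd
  }
  neg
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Contrastive (DGI) objective
#'
#' Mean binary cross-entropy of the discriminator over the n positive
#' (node, summary) pairs and the n mined negatives, plus an optional spatial
#' smoothness penalty `lambda_spatial * sum_(i,j in E_s) ||h_i - h_j||^2`
#' (each undirected edge once). Log arguments are clamped at 1e-12.
#'
#' @param H n x h embeddings (positive samples).
#' @param neg_index mined negatives from [select_hard_negatives()].
#' @param s global summary vector.
#' @param bias length-n spatial bias vector.
#' @param W_spatial bilinear discriminator weights.
#' @param A_s sparse spatial adjacency (for the penalty term).
#' @param lambda_spatial penalty weight (default 0; the same smoothness
#'   penalty is normally carried by the spatial regulariser).
#' @return scalar loss (>= 0 when `lambda_spatial >= 0`).
#' @export
dgi_loss <- function(H, neg_index, s, bias, W_spatial, A_s, lambda_spatial = 0) {
  n <- nrow(H)
  Ws <- as.vector(W_spatial %*% s)
  u_pos <- as.vector(H %*% Ws) + bias
  u_neg <- as.vector(H[neg_index, , drop = FALSE] %*% Ws) + bias[neg_index]
  p_pos <- pmax(sigmoid(u_pos), 1e-12)
  q_neg <- pmax(1 - sigmoid(u_neg), 1e-12)
  loss <- -mean(log(p_pos) + log(q_neg))
  if (lambda_spatial != 0) {
    loss <- loss + lambda_spatial * edge_sq_dist_sum(H, A_s)
  }
  loss
}

# sum over undirected edges of ||h_i - h_j||^2 via the graph Laplacian
edge_sq_dist_sum <- function(H, A) {
  deg <- Matrix::rowSums(A)
  LH <- deg * H - as.matrix(A %*% H)
  sum(H * LH)
}

#' Contrastive projection head
#'
#' One-hidden-layer MLP (h -> h, ReLU, -> h) applied to the attention-weighted
#' sum of the view embeddings; its output is the embedding used by the
#' readout, discriminator and negative mining.
#'
#' @param H_mix n x h attention-weighted sum (`a_s H_s + a_f H_f + a_c H_c`).
#' @param params parameter list (uses `W_m1`, `b_m1`, `W_m2`, `b_m2`).
#' @return list with `H_con` (n x h projection) and the hidden cache.
#' @export
contrast_projection <- function(H_mix, params) {
  Z1 <- sweep(H_mix %*% params$W_m1, 2, params$b_m1, "+")
  H1 <- relu(Z1)
  H_con <- sweep(H1 %*% params$W_m2, 2, params$b_m2, "+")
  list(H_con = H_con, Z1 = Z1, H1 = H1)
}
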