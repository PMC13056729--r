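# Multi-view GCN encoder: view-specific spatial/feature convolutions, a
# parameter-shared co-convolution over both graphs, and attention fusion of
# the three resulting embeddings.

#' Initialise all learnable weights
#'
#' Glorot-uniform initialisation, controlled by the current RNG state. Layer
#' dimensions chain input d -> hidden_dims[1] -> hidden_dims[2]; the attention
#' head, fusion layer, projection MLP, discriminator and ZINB heads all live
#' on the final embedding dimension.
#'
#' @param d input dimension (number of genes of `expr`).
#' @param hidden_dims integer pair, default `c(128, 64)`.
#' @return Named list of parameter arrays (an `encoder_state`).
#' @export
init_params <- function(d, hidden_dims = c(128, 64)) {
  h1 <- hidden_dims[1]; h2 <- hidden_dims[2]
  p <- list(
    W_s1 = glorot_matrix(d, h1), W_s2 = glorot_matrix(h1, h2),
    W_f1 = glorot_matrix(d, h1), W_f2 = glorot_matrix(h1, h2),
    W_c1 = glorot_matrix(d, h1), W_c2 = glorot_matrix(h1, h2),
    W_att = glorot_matrix(h2, h2), b_att = numeric(h2),
    w_co  = glorot_matrix(h2, 1)[, 1],
    F_fuse = glorot_matrix(h2, h2),
    W_m1 = glorot_matrix(h2, h2), b_m1 = numeric(h2),
    W_m2 = glorot_matrix(h2, h2), b_m2 = numeric(h2),
    W_disc = glorot_matrix(h2, h2), b0_disc = 0,
    W_pi = glorot_matrix(h2, d), b_pi = numeric(d),
    W_mu = glorot_matrix(h2, d), b_mu = numeric(d),
    W_th = glorot_matrix(h2, d), b_th = numeric(d),
    W_mse = glorot_matrix(h2, d), b_mse = numeric(d)
  )
  attr(p, "dims") <- c(d = d, h1 = h1, h2 = h2)
  p
}

#' One graph convolution layer
#'
#' Computes `A_norm %*% H_in %*% W_layer`, optionally followed by ReLU.
#'
#' @param H_in n x p input activations.
#' @param A_norm normalised adjacency from [normalize_adjacency()].
#' @param W_layer p x q weight matrix.
#' @param activate apply ReLU (default `TRUE`).
#' @return n x q matrix.
#' @export
gcn_layer <- function(H_in, A_norm, W_layer, activate = TRUE) {
  if (ncol(H_in) != nrow(W_layer)) {
    stopf("gcn_layer dimension mismatch: H_in has %d columns, W_layer %d rows",
          ncol(H_in), nrow(W_layer))
  }
  Z <- as.matrix(A_norm %*% (H_in %*% W_layer))
  if (activate) relu(Z) else Z
}

# One two-layer branch with inverted dropout after layer 1 (train mode only).
# Returns activations plus the pre-activations / mask needed for backprop.
gcn_branch <- function(X, A_norm, W1, W2, dropout, train) {
  AX <- as.matrix(A_norm %*% X)
  Z1 <- AX %*% W1
  H1 <- relu(Z1)
  mask <- NULL
  H1d <- H1
  if (train && dropout > 0) {
    mask <- matrix(stats::runif(length(H1)) >= dropout, nrow(H1), ncol(H1)) / (1 - dropout)
    H1d <- H1 * mask
  }
  AH <- as.matrix(A_norm %*% H1d)
  Z2 <- AH %*% W2
  H2 <- relu(Z2)
  list(H = H2, Z2 = Z2, AH = AH, H1d = H1d, Z1 = Z1, AX = AX, mask = mask)
}

# Backprop through one branch; returns gradients for W1, W2 and (optionally) X.
gcn_branch_backward <- function(br, dH, A_norm, W1, W2, dropout, train) {
  dZ2 <- dH * (br$Z2 > 0)
  gW2 <- crossprod(br$AH, dZ2)
  dH1d <- as.matrix(A_norm %*% (dZ2 %*% t(W2)))   # A symmetric
  dH1 <- if (train && dropout > 0) dH1d * br$mask else dH1d
  dZ1 <- dH1 * (br$Z1 > 0)
  gW1 <- crossprod(br$AX, dZ1)
  list(gW1 = gW1, gW2 = gW2, dZ1 = dZ1)
}

#' Attention fusion of the three view embeddings
#'
#' Each view embedding row is scored by a shared attention head,
#' `score_v(i) = w_co . tanh(W_att h_v(i) + b_att)`; the three scores per spot
#' pass through a softmax giving convex weights `(a_s, a_f, a_c)`, and the
#' fused embedding is the bias-free linear map `F_fuse` of the weighted sum.
#'
#' @param H_s,H_f,H_c n x h view embeddings.
#' @param params parameter list from [init_params()] (uses `W_att`, `b_att`,
#'   `w_co`, `F_fuse`).
#' @return list with `a_s`, `a_f`, `a_c` (n-vectors summing to 1 per spot),
#'   `H_mix` (pre-fusion weighted sum) and `H` (fused embedding).
#' @export
attention_fuse <- function(H_s, H_f, H_c, params) {
  stopifnot(all(dim(H_s) == dim(H_f)), all(dim(H_s) == dim(H_c)))
  score1 <- function(H) {
    T_ <- tanh(sweep(H %*% params$W_att, 2, params$b_att, "+"))
    list(T = T_, s = as.vector(T_ %*% params$w_co))
  }
  vs <- score1(H_s); vf <- score1(H_f); vc <- score1(H_c)
  S <- cbind(vs$s, vf$s, vc$s)
  S <- S - apply(S, 1, max)
  E <- exp(S)
  A <- E / rowSums(E)
  H_mix <- A[, 1] * H_s + A[, 2] * H_f + A[, 3] * H_c
  H <- H_mix %*% params$F_fuse
  list(a_s = A[, 1], a_f = A[, 2], a_c = A[, 3], H_mix = H_mix, H = H,
       cache = list(Ts = vs$T, Tf = vf$T, Tc = vc$T, A = A))
}

#' Cross-view consistency loss
#'
#' L2-row-normalises both co-embeddings and returns the squared Frobenius
#' norm of the difference of their Gram (spot-similarity) matrices. Computed
#' through the trace identity
#' `||G_s - G_f||_F^2 = ||Hs'Hs||_F^2 - 2 ||Hf'Hs||_F^2 + ||Hf'Hf||_F^2`,
#' which avoids forming the n x n Gram matrices.
#'
#' @param H_sc,H_fc n x h co-embeddings from the spatial and feature paths.
#' @return non-negative scalar.
#' @export
consistency_loss <- function(H_sc, H_fc) {
  stopifnot(all(dim(H_sc) == dim(H_fc)))
  Hs <- row_l2_normalize(H_sc)
  Hf <- row_l2_normalize(H_fc)
  Gss <- crossprod(Hs); Gff <- crossprod(Hf); Gfs <- crossprod(Hf, Hs)
  sum(Gss * Gss) - 2 * sum(Gfs * Gfs) + sum(Gff * Gff)
}

# Gradient of consistency_loss wrt the raw (un-normalised) inputs.
consistency_loss_grad <- function(H_sc, H_fc, eps = 1e-12) {
  nrm_s <- pmax(sqrt(rowSums(H_sc^2)), eps)
  nrm_f <- pmax(sqrt(rowSums(H_fc^2)), eps)
  Hs <- H_sc / nrm_s
  Hf <- H_fc / nrm_f
  # dL/dHs_hat = 4 (Hs (Hs'Hs) - Hf (Hf'Hs)); symmetric for Hf with sign flip
  Gss <- crossprod(Hs); Gfs <- crossprod(Hf, Hs); Gff <- crossprod(Hf)
  dHs_hat <- 4 * (Hs %*% Gss - Hf %*% Gfs)
  dHf_hat <- 4 * (Hf %*% Gff - Hs %*% t(Gfs))
  # backprop through row normalisation: dh = (g - h_hat (h_hat . g)) / ||h||;
  # rows with (near-)zero norm take a zero subgradient
  proj <- function(Hhat, G, nrm) {
    out <- (G - Hhat * rowSums(Hhat * G)) / nrm
    out[nrm <= 1e-8, ] <- 0
    out
  }
  list(dH_sc = proj(Hs, dHs_hat, nrm_s), dH_fc = proj(Hf, dHf_hat, nrm_f))
}

#' Full encoder forward pass
#'
#' Runs the three branches (spatial with `W_s*`, feature with `W_f*`, and the
#' co-convolution with the shared `W_c*` over both graphs), averages the two
#' co-embeddings, and fuses the three views by attention.
#'
#' @param X n x d preprocessed expression.
#' @param G a [build_dual_graph()] object.
#' @param params parameter list from [init_params()].
#' @param mode `"train"` (dropout active) or `"eval"`.
#' @param dropout dropout rate after layer 1 of each branch (default 0.1).
#' @return list with `H_s`, `H_f`, `H_sc`, `H_fc`, `H_c`, attention weights,
#'   `H_mix`, fused `H`, and internal caches for backprop.
#' @export
encode <- function(X, G, params, mode = c("eval", "train"), dropout = 0.1) {
  mode <- match.arg(mode)
  train <- mode == "train"
  dims <- attr(params, "dims")
  if (ncol(X) != nrow(params$W_s1)) {
    stopf("X has %d columns but encoder expects %d", ncol(X), nrow(params$W_s1))
  }
  br_s <- gcn_branch(X, G$A_s_norm, params$W_s1, params$W_s2, dropout, train)
  br_f <- gcn_branch(X, G$A_f_norm, params$W_f1, params$W_f2, dropout, train)
  br_sc <- gcn_branch(X, G$A_s_norm, params$W_c1, params$W_c2, dropout, train)
  br_fc <- gcn_branch(X, G$A_f_norm, params$W_c1, params$W_c2, dropout, train)
  H_c <- (br_sc$H + br_fc$H) / 2
  att <- attention_fuse(br_s$H, br_f$H, H_c, params)
  list(H_s = br_s$H, H_f = br_f$H, H_sc = br_sc$H, H_fc = br_fc$H, H_c = H_c,
       a_s = att$a_s, a_f = att$a_f, a_c = att$a_c,
       H_mix = att$H_mix, H = att$H,
       cache = list(br_s = br_s, br_f = br_f, br_sc = br_sc, br_fc = br_fc,
                    att = att$cache, train = train, dropout = dropout))
}
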