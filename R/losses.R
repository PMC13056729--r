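# Spatial regularisation and total-loss assembly.

#' Loss weights
#'
#' Weights of the four jointly optimised objectives (reconstruction,
#' cross-view consistency, spatial regularisation, contrastive), the
#' negative-pair balance inside the spatial regulariser, and the optional
#' smoothness penalty inside the contrastive objective. Defaults are the
#' published operating point: alpha 10.0, beta 0.1, gamma 0.1, delta 0.15.
#'
#' @param alpha ZINB reconstruction weight.
#' @param beta consistency weight.
#' @param gamma spatial regularisation weight.
#' @param delta contrastive (DGI) weight.
#' @param lambda_reg repulsion balance inside the spatial regulariser.
#' @param lambda_spatial smoothness penalty inside the DGI loss (default 0:
#'   the same penalty already enters through gamma).
#' @param w_mse weight of the mean-squared reconstruction used only by the
#'   `zinb = FALSE` ablation.
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 10.0, beta = 0.1, gamma = 0.1, delta = 0.15,
                         lambda_reg = 0.1, lambda_spatial = 0, w_mse = 0) {
  w <- list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
            lambda_reg = lambda_reg, lambda_spatial = lambda_spatial,
            w_mse = w_mse)
  if (any(unlist(w) < 0)) stopf("loss weights must be non-negative")
  structure(w, class = "loss_weights")
}

#' Spatial regularisation loss
#'
#' Attraction over spatial-neighbour pairs minus `lambda_reg` times repulsion
#' over sampled non-neighbour pairs:
#' `sum_(i,j in E_s) ||h_i - h_j||^2 / 2 - lambda_reg *
#'  sum_(i,k in E_neg) ||h_i - h_k||^2 / 2`.
#'
#' @param H n x h embeddings.
#' @param E_spatial 2-column integer matrix of positive (neighbour) pairs.
#' @param E_neg 2-column integer matrix of sampled non-neighbour pairs.
#' @param lambda_reg repulsion weight.
#' @return scalar.
#' @export
spatial_reg_loss <- function(H, E_spatial, E_neg, lambda_reg) {
  check_pairs <- function(E, nm) {
    if (length(E) && any(E[, 1] == E[, 2])) stopf("%s contains self-pairs", nm)
  }
  check_pairs(E_spatial, "E_spatial"); check_pairs(E_neg, "E_neg")
  if (length(E_spatial) && length(E_neg)) {
    key <- function(E) paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
    if (any(key(E_neg) %in% key(E_spatial))) {
      stopf("E_neg overlaps E_spatial: edge sets must be disjoint")
    }
  }
  half_sq <- function(E) {
    if (!length(E)) return(0)
    D <- H[E[, 1], , drop = FALSE] - H[E[, 2], , drop = FALSE]
    sum(D * D) / 2
  }
  half_sq(E_spatial) - lambda_reg * half_sq(E_neg)
}

# Gradient of spatial_reg_loss wrt H (pairs with multiplicity supported).
spatial_reg_grad <- function(H, E_spatial, E_neg, lambda_reg) {
  g <- matrix(0, nrow(H), ncol(H))
  add_pairs <- function(g, E, w) {
    if (!length(E)) return(g)
    D <- H[E[, 1], , drop = FALSE] - H[E[, 2], , drop = FALSE]
    gi <- rowsum(w * D, E[, 1])
    gj <- rowsum(-w * D, E[, 2])
    g[as.integer(rownames(gi)), ] <- g[as.integer(rownames(gi)), ] + gi
    g[as.integer(rownames(gj)), ] <- g[as.integer(rownames(gj)), ] + gj
    g
  }
  g <- add_pairs(g, E_spatial, 1)
  add_pairs(g, E_neg, -lambda_reg)
}

#' Total training loss
#'
#' Exact weighted sum
#' `alpha l_zinb + beta l_con + gamma l_reg + delta l_dgi (+ w_mse l_mse)`.
#' Aborts naming the offending term if any component is non-finite.
#'
#' @param components named list/vector with `l_zinb`, `l_con`, `l_reg`,
#'   `l_dgi` (optionally `l_mse`).
#' @param weights a [loss_weights()].
#' @return scalar total loss.
#' @export
total_loss <- function(components, weights) {
  comp <- as.list(components)
  for (nm in c("l_zinb", "l_con", "l_reg", "l_dgi")) {
    if (is.null(comp[[nm]])) stopf("missing loss component '%s'", nm)
    if (!is.finite(comp[[nm]])) stopf("non-finite loss component '%s'", nm)
  }
  l_mse <- comp$l_mse %||% 0
  if (!is.finite(l_mse)) stopf("non-finite loss component 'l_mse'")
  weights$alpha * comp$l_zinb + weights$beta * comp$l_con +
    weights$gamma * comp$l_reg + weights$delta * comp$l_dgi +
    weights$w_mse * l_mse
}
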