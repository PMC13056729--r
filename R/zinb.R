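# Zero-inflated negative binomial decoder: three single-layer heads mapping
# the fused embedding to per-spot-per-gene dropout probability, NB mean and
# NB dispersion, and the corresponding negative log-likelihood on raw counts.

MU_LO <- 1e-5; MU_HI <- 1e6
TH_LO <- 1e-4; TH_HI <- 1e4

#' Decode embeddings to ZINB parameters
#'
#' `pi = sigmoid(H W_pi + b_pi)`, `mu = clamp(exp(H W_mu + b_mu), 1e-5, 1e6)`,
#' `theta = clamp(softplus(H W_th + b_th), 1e-4, 1e4)`; each head is a single
#' linear layer from the embedding to the gene panel.
#'
#' @param H n x h fused embedding.
#' @param params parameter list (uses `W_pi`, `b_pi`, `W_mu`, `b_mu`, `W_th`,
#'   `b_th`).
#' @return list of class `zinb_params` with matrices `pi`, `mu`, `theta` and
#'   pre-activation caches.
#' @export
zinb_heads <- function(H, params) {
  Zpi <- sweep(H %*% params$W_pi, 2, params$b_pi, "+")
  Zmu <- sweep(H %*% params$W_mu, 2, params$b_mu, "+")
  Zth <- sweep(H %*% params$W_th, 2, params$b_th, "+")
  pi_ <- sigmoid(Zpi)
  pi_ <- pmin(pmax(pi_, 1e-10), 1 - 1e-10)
  mu <- pmin(pmax(exp(pmin(Zmu, log(MU_HI) + 1)), MU_LO), MU_HI)
  th <- pmin(pmax(softplus(Zth), TH_LO), TH_HI)
  structure(list(pi = pi_, mu = mu, theta = th,
                 cache = list(Zmu = Zmu, Zth = Zth)),
            class = "zinb_params")
}

#' ZINB negative log-likelihood
#'
#' `P(x) = pi * 1[x = 0] + (1 - pi) * NB(x; mu, theta)` with the
#' mean-dispersion NB pmf
#' `NB(x) = Gamma(x + theta) / (Gamma(theta) x!) (theta/(theta+mu))^theta (mu/(theta+mu))^x`.
#' Evaluated in log space (log-gamma, log-sum-exp at x = 0); probabilities are
#' floored at 1e-12 inside the log. Returns the total over all entries (the
#' literal double sum).
#'
#' @param x non-negative integer matrix (raw counts).
#' @param params a [zinb_heads()] result, or any list with `pi`, `mu`,
#'   `theta` matrices/scalars conformable with `x`.
#' @return scalar NLL (>= 0).
#' @export
zinb_nll <- function(x, params) {
  x <- as.matrix(x)
  if (any(x < 0) || any(x != round(x))) stopf("x must contain non-negative integers")
  zinb_nll_core(x, params)$nll
}

# Combined NLL + gradients wrt the three pre-activations; fused compiled
# kernel (one pass, log pmf evaluated once). Entries where the log was
# floored, or where a clamp saturated, get a zero subgradient.
zinb_nll_core <- function(x, zp, want_grads = FALSE) {
  dm <- dim(x)
  expand <- function(v) {
    v <- as.matrix(v)
    if (length(v) == 1 && prod(dm) > 1) v <- matrix(v[1], dm[1], dm[2])
    storage.mode(v) <- "double"
    v
  }
  storage.mode(x) <- "double"
  Zth <- if (want_grads) expand(zp$cache$Zth) else matrix(0, dm[1], dm[2])
  .zinb_core_cpp(x, expand(zp$pi), expand(zp$mu), expand(zp$theta), Zth,
                 want_grads)
}

#' Denoised expression from the decoder
#'
#' Returns the fitted NB mean `mu` as the enhanced expression matrix
#' (`mode = "mean"`), or the zero-inflation-adjusted expectation
#' `(1 - pi) * mu` (`mode = "expected"`).
#'
#' @param params a [zinb_heads()] result.
#' @param mode `"mean"` (default) or `"expected"`.
#' @return n x d numeric matrix.
#' @export
impute_expression <- function(params, mode = c("mean", "expected")) {
  mode <- match.arg(mode)
  if (mode == "mean") params$mu else (1 - params$pi) * params$mu
}
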