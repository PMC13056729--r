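# Small numerical helpers shared by the encoder, contrastive module and trainer.

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow for large |x|
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' @noRd
glorot_matrix <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# L2-normalise rows; guard zero rows with eps so 0-rows stay 0 instead of NaN.
row_l2_normalize <- function(H, eps = 1e-12) {
  nrm <- sqrt(rowSums(H * H))
  H / pmax(nrm, eps)
}

row_cosine_similarity <- function(H) {
  Hn <- row_l2_normalize(H)
  tcrossprod(Hn)
}

# Derive a 32-bit sub-seed from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483647)
}

## ---- Adam optimizer over a named list of arrays ----------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam step with decoupled-from-nothing classic L2 weight decay added to the
# gradient (matches torch.optim.Adam's `weight_decay` semantics). Gradients may
# be clipped to a global norm first.
adam_step <- function(params, grads, state, lr = 1e-3, weight_decay = 1e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8, clip_norm = 5.0) {
  if (!is.null(clip_norm) && is.finite(clip_norm)) {
    total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
    if (total > clip_norm) {
      sc <- clip_norm / (total + 1e-12)
      grads <- lapply(grads, function(g) g * sc)
    }
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
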