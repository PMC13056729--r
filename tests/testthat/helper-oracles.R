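# Independent brute-force oracles used across tests. These deliberately use
# the most direct O(n^2) / scalar formulations, not the package's code paths.

bf_spatial_graph <- function(coords, r) {
  n <- nrow(coords)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sqrt(sum((coords[i, ] - coords[j, ])^2)) <= r) A[i, j] <- 1
  }
  A
}

bf_feature_graph <- function(X, k) {
  n <- nrow(X)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    S[i, j] <- sum(X[i, ] * X[j, ]) / (sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2)))
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- S[i, ]; s[i] <- -Inf
    nb <- order(-s, seq_len(n))[seq_len(k)]
    A[i, nb] <- 1
  }
  pmax(A, t(A))
}

bf_normalized_adjacency <- function(A) {
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  diag(1 / sqrt(d)) %*% At %*% diag(1 / sqrt(d))
}

bf_hard_negatives <- function(H, As, Af, rng_seed = 0L) {
  n <- nrow(H)
  As <- as.matrix(As); Af <- as.matrix(Af)
  out <- integer(n)
  for (i in seq_len(n)) {
    excl <- unique(c(i, which(As[i, ] > 0), which(Af[i, ] > 0)))
    cand <- setdiff(seq_len(n), excl)
    if (length(cand) == 0) { out[i] <- NA_integer_; next }
    sims <- vapply(cand, function(k2) {
      sum(H[i, ] * H[k2, ]) / (sqrt(sum(H[i, ]^2)) * sqrt(sum(H[k2, ]^2)))
    }, numeric(1))
    out[i] <- cand[order(-sims, cand)[1]]
  }
  out
}

# scalar ZINB pmf, direct formula (no logs)
bf_zinb_pmf <- function(x, pi_, mu, theta) {
  nb <- gamma(x + theta) / (gamma(theta) * factorial(x)) *
    (theta / (theta + mu))^theta * (mu / (theta + mu))^x
  pi_ * (x == 0) + (1 - pi_) * nb
}

# ARI by exhaustive enumeration of all pairs (Rand + closed-form chance term)
bf_ari_pairs <- function(a, b) {
  n <- length(a)
  s_ab <- 0; s_a <- 0; s_b <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ta <- a[i] == a[j]; tb <- b[i] == b[j]
    s_ab <- s_ab + (ta && tb); s_a <- s_a + ta; s_b <- s_b + tb
  }
  tot <- n * (n - 1) / 2
  exp_ <- s_a * s_b / tot
  mx <- (s_a + s_b) / 2
  if (mx == exp_) return(1)
  (s_ab - exp_) / (mx - exp_)
}

# small deterministic parameter set for encoder-level tests
tiny_params <- function(d, h1 = 6, h2 = 4, seed = 42) {
  set.seed(seed)
  init_params(d, c(h1, h2))
}

tiny_dataset <- function(n = 30, d = 12, K = 3, seed = 7, pi_sim = 0.2) {
  generate_dataset(sim_config(n_spots = n, layout = "hex", K_true = K,
                              n_genes = d, markers_per_domain = max(1, d %/% (2 * K)),
                              theta_sim = 2, pi_sim = pi_sim, seed = seed))
}
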