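empty_graph <- function(n) {
  Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(n, n))
}

path_graph <- function(n) {
  Matrix::sparseMatrix(i = c(1:(n - 1), 2:n), j = c(2:n, 1:(n - 1)), x = 1,
                       dims = c(n, n))
}

test_that("readout reduces to known weighted means", {
  set.seed(2)
  H <- matrix(rnorm(5 * 4), 5, 4)
  # edgeless: uniform weights -> column mean
  ro <- spatial_readout(H, empty_graph(5))
  expect_equal(ro$w, rep(1, 5))
  expect_equal(ro$s, sigmoid(colMeans(H)))
  # single spot
  ro1 <- spatial_readout(H[1, , drop = FALSE], empty_graph(1))
  expect_equal(ro1$s, sigmoid(H[1, ]))
  # 5-spot path graph: centrality weights 2,3,3,3,2
  ro2 <- spatial_readout(H, path_graph(5))
  w <- c(2, 3, 3, 3, 2)
  expect_equal(ro2$w, w)
  expect_equal(ro2$s, sigmoid(colSums(H * w) / sum(w)))
  # squash can be disabled
  expect_equal(spatial_readout(H, path_graph(5), squash = FALSE)$s,
               colSums(H * w) / sum(w))
})

test_that("discriminator reduces to scalar arithmetic and stays in (0,1)", {
  expect_equal(discriminate(rep(0, 4), rnorm(4), 0, diag(4)), 0.5)
  h <- c(0.3, -1); s <- c(0.5, 0.25)
  expect_equal(discriminate(h, s, 0.2, diag(2)), sigmoid(sum(h * s) + 0.2))
  set.seed(3)
  for (i in 1:10) {
    v <- discriminate(rnorm(4), rnorm(4), rnorm(1), matrix(rnorm(16), 4, 4))
    expect_true(v > 0 && v < 1)
  }
})

test_that("hard negatives honour the exclusion set", {
  # node 1 adjacent to node 2 only: candidate set is {3}
  As <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(3, 3))
  H <- matrix(rnorm(12), 3, 4)
  neg <- select_hard_negatives(H, As, empty_graph(3), rng_seed = 1)
  expect_equal(neg[1], 3L)
})

test_that("fully connected graphs force the seeded random fallback", {
  n <- 6
  A <- Matrix::Matrix(1, n, n, sparse = TRUE); diag(A) <- 0
  A <- methods::as(A, "generalMatrix")
  H <- matrix(rnorm(n * 3), n, 3)
  neg1 <- select_hard_negatives(H, A, empty_graph(n), rng_seed = 5)
  neg2 <- select_hard_negatives(H, A, empty_graph(n), rng_seed = 5)
  expect_identical(neg1, neg2)            # seed-controlled
  expect_true(all(neg1 != seq_len(n)))    # never the anchor itself
})

test_that("hard-negative mining equals the exhaustive oracle", {
  set.seed(31)
  n <- 30
  H <- matrix(rnorm(n * 6), n, 6)
  co <- cbind(runif(n, 0, 400), runif(n, 0, 400))
  As <- build_spatial_graph(co, 120)
  Af <- build_feature_graph(H, 4)
  neg <- select_hard_negatives(H, As, Af, rng_seed = 0)
  oracle <- bf_hard_negatives(H, As, Af)
  nonempty <- !is.na(oracle)
  expect_equal(neg[nonempty], oracle[nonempty])
  # hardness: the mined negative is at least as similar as any candidate
  S <- tcrossprod(H / sqrt(rowSums(H^2)))
  for (i in which(nonempty)) {
    excl <- unique(c(i, which(as.matrix(As)[i, ] > 0), which(as.matrix(Af)[i, ] > 0)))
    cand <- setdiff(seq_len(n), excl)
    expect_true(all(S[i, neg[i]] >= S[i, cand] - 1e-12))
  }
  expect_error(select_hard_negatives(H[1, , drop = FALSE], empty_graph(1),
                                     empty_graph(1)), "at least 2")
})

test_that("an uninformative discriminator scores the canonical two-log-two loss", {
  n <- 8
  H <- matrix(rnorm(n * 4), n, 4)
  # W = 0 and zero bias force D = 0.5 everywhere
  val <- dgi_loss(H, rep(1L, n), s = rnorm(4), bias = rep(0, n),
                  W_spatial = matrix(0, 4, 4), A_s = empty_graph(n),
                  lambda_spatial = 0)
  expect_equal(val, 2 * log(2), tolerance = 1e-12)
})

test_that("identical embeddings zero the smoothness penalty", {
  n <- 5
  H <- matrix(1, n, 3)
  A <- path_graph(n)
  s <- c(0.2, -0.1, 0.4)
  expect_equal(dgi_loss(H, rep(1L, n), s, rep(0, n), diag(3), A, 0),
               dgi_loss(H, rep(1L, n), s, rep(0, n), diag(3), A, 10))
})

test_that("the contrastive objective matches a term-by-term scalar oracle", {
  set.seed(17)
  n <- 4; h <- 3
  H <- matrix(rnorm(n * h), n, h)
  neg <- c(3L, 4L, 1L, 2L)
  s <- runif(h); bias <- rnorm(n) * 0.1
  W <- matrix(rnorm(h * h), h, h)
  A <- path_graph(n)
  lam <- 0.05
  pos_terms <- vapply(1:n, function(i) log(sigmoid(sum(H[i, ] * (W %*% s)) + bias[i])), numeric(1))
  neg_terms <- vapply(1:n, function(i) log(1 - sigmoid(sum(H[neg[i], ] * (W %*% s)) + bias[neg[i]])), numeric(1))
  pen <- sum(vapply(1:(n - 1), function(i) sum((H[i, ] - H[i + 1, ])^2), numeric(1)))
  oracle <- -mean(pos_terms + neg_terms) + lam * pen
  expect_equal(dgi_loss(H, neg, s, bias, W, A, lam), oracle, tolerance = 1e-10)
  expect_gte(dgi_loss(H, neg, s, bias, W, A, 0), 0)
})

test_that("projection head reduces to dense two-layer arithmetic", {
  p <- tiny_params(3, h2 = 4)
  # identity-initialised MLP passes non-negative input through
  p$W_m1 <- diag(4); p$b_m1[] <- 0; p$W_m2 <- diag(4); p$b_m2[] <- 0
  Hp <- matrix(abs(rnorm(20)), 5, 4)
  expect_equal(contrast_projection(Hp, p)$H_con, Hp)
  # zero input lands on the output bias
  p$b_m2 <- rnorm(4)
  expect_equal(contrast_projection(matrix(0, 2, 4), p)$H_con,
               matrix(p$b_m2, 2, 4, byrow = TRUE))
  # random instance vs direct arithmetic
  set.seed(40)
  p2 <- tiny_params(3, h2 = 4, seed = 4)
  Hm <- matrix(rnorm(24), 6, 4)
  oracle <- pmax(sweep(Hm %*% p2$W_m1, 2, p2$b_m1, "+"), 0) %*% p2$W_m2
  oracle <- sweep(oracle, 2, p2$b_m2, "+")
  expect_equal(contrast_projection(Hm, p2)$H_con, oracle, tolerance = 1e-12)
})

test_that("a trained discriminator separates positives from mined negatives", {
  ds <- generate_dataset(sim_config(n_spots = 150, K_true = 3, n_genes = 40,
                                    markers_per_domain = 6, fold_change = 5,
                                    seed = 9))
  dsp <- preprocess(ds, n_hvg = 40)
  G <- build_dual_graph(dsp, r = 150, k = 8)
  fit <- train(dsp, G, train_config(seed = 1, max_epochs = 40, patience = 39))
  ev <- encode(dsp$expr, fit$G, fit$params, mode = "eval")
  pr <- contrast_projection(ev$H_mix, fit$params)
  ro <- spatial_readout(pr$H_con, G$A_s)
  bias <- spatialDG:::spatial_bias_vec(G$A_s, fit$params$b0_disc)
  neg <- select_hard_negatives(pr$H_con, G$A_s, G$A_f, rng_seed = 0)
  Ws <- as.vector(fit$params$W_disc %*% ro$s)
  d_pos <- spatialDG:::sigmoid(as.vector(pr$H_con %*% Ws) + bias)
  d_neg <- spatialDG:::sigmoid(as.vector(pr$H_con[neg, ] %*% Ws) + bias[neg])
  expect_gt(mean(d_pos), mean(d_neg))
})
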