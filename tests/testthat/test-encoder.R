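test_that("graph convolution reduces to its dense three-matrix product", {
  # identity propagation
  H <- matrix(abs(rnorm(12)), 4, 3)
  I4 <- normalize_adjacency(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                 x = numeric(0), dims = c(4, 4)))
  expect_equal(gcn_layer(H, I4, diag(3)), H)
  # zero weights annihilate
  expect_equal(gcn_layer(H, I4, matrix(0, 3, 2)), matrix(0, 4, 2))
  # random instance vs dense arithmetic
  set.seed(14)
  A <- matrix(rbinom(100, 1, 0.3), 10, 10); A <- pmax(A, t(A)); diag(A) <- 0
  An <- normalize_adjacency(Matrix::Matrix(A, sparse = TRUE))
  Hin <- matrix(rnorm(10 * 6), 10, 6)
  W <- matrix(rnorm(6 * 4), 6, 4)
  expect_equal(gcn_layer(Hin, An, W),
               pmax(bf_normalized_adjacency(A) %*% Hin %*% W, 0), tolerance = 1e-12)
  expect_error(gcn_layer(Hin, An, matrix(0, 5, 4)), "dimension mismatch")
})

test_that("identical graphs with tied weights collapse the views", {
  ds <- tiny_dataset(n = 20, d = 8)
  dsp <- preprocess(ds, n_hvg = 8)
  G <- build_dual_graph(dsp, r = 150, k = 4)
  G$A_f <- G$A_s; G$A_f_norm <- G$A_s_norm
  p <- tiny_params(8)
  p$W_f1 <- p$W_s1; p$W_f2 <- p$W_s2
  e <- encode(dsp$expr, G, p, mode = "eval")
  expect_equal(e$H_s, e$H_f)
  expect_equal(e$H_sc, e$H_fc)
  expect_equal(e$H_sc, e$H_c)
})

test_that("zero input propagates to zero embeddings and uniform attention", {
  ds <- tiny_dataset(n = 15, d = 6)
  dsp <- preprocess(ds, n_hvg = 6)
  G <- build_dual_graph(dsp, r = 150, k = 3)
  p <- tiny_params(6)
  e <- encode(dsp$expr * 0, G, p, mode = "eval")
  expect_equal(e$H_s, matrix(0, 15, 4))
  expect_equal(e$H_c, matrix(0, 15, 4))
  expect_equal(e$a_s, rep(1 / 3, 15))
  expect_equal(e$a_f, rep(1 / 3, 15))
  expect_equal(e$a_c, rep(1 / 3, 15))
})

test_that("co-embedding is exactly the mean of its two paths and weights stay on the simplex", {
  ds <- tiny_dataset(n = 25, d = 10)
  dsp <- preprocess(ds, n_hvg = 10)
  G <- build_dual_graph(dsp, r = 150, k = 5)
  p <- tiny_params(10)
  e <- encode(dsp$expr, G, p, mode = "eval")
  expect_equal(e$H_c, (e$H_sc + e$H_fc) / 2)
  expect_equal(e$a_s + e$a_f + e$a_c, rep(1, 25), tolerance = 1e-12)
  expect_true(all(e$a_s >= 0 & e$a_f >= 0 & e$a_c >= 0))
})

test_that("encoding in eval mode is deterministic; dropout perturbs training mode", {
  ds <- tiny_dataset(n = 20, d = 8)
  dsp <- preprocess(ds, n_hvg = 8)
  G <- build_dual_graph(dsp, r = 150, k = 4)
  p <- tiny_params(8)
  e1 <- encode(dsp$expr, G, p, mode = "eval")
  e2 <- encode(dsp$expr, G, p, mode = "eval")
  expect_identical(e1$H, e2$H)
  set.seed(1); t1 <- encode(dsp$expr, G, p, mode = "train", dropout = 0.5)
  set.seed(2); t2 <- encode(dsp$expr, G, p, mode = "train", dropout = 0.5)
  expect_false(identical(t1$H, t2$H))
})

test_that("shared co-convolution weights couple both paths; view weights stay isolated", {
  ds <- tiny_dataset(n = 20, d = 8)
  dsp <- preprocess(ds, n_hvg = 8)
  G <- build_dual_graph(dsp, r = 150, k = 4)
  p <- tiny_params(8)
  base <- encode(dsp$expr, G, p, mode = "eval")
  p2 <- p; p2$W_c1 <- p2$W_c1 + 0.1
  pert <- encode(dsp$expr, G, p2, mode = "eval")
  expect_false(isTRUE(all.equal(base$H_sc, pert$H_sc)))
  expect_false(isTRUE(all.equal(base$H_fc, pert$H_fc)))
  expect_equal(base$H_s, pert$H_s)
  p3 <- p; p3$W_s1 <- p3$W_s1 + 0.1
  pert3 <- encode(dsp$expr, G, p3, mode = "eval")
  expect_equal(base$H_f, pert3$H_f)
  expect_false(isTRUE(all.equal(base$H_s, pert3$H_s)))
})

test_that("consistency loss vanishes for identical inputs and is symmetric", {
  set.seed(6)
  H <- matrix(rnorm(18), 6, 3)
  expect_equal(consistency_loss(H, H), 0)
  H2 <- matrix(rnorm(18), 6, 3)
  expect_equal(consistency_loss(H, H2), consistency_loss(H2, H))
})

test_that("consistency loss equals the dense Gram-difference oracle", {
  A <- rbind(c(1, 0), c(1, 1), c(0, 2))
  B <- rbind(c(2, 1), c(0, 1), c(1, 1))
  nrmA <- A / sqrt(rowSums(A^2)); nrmB <- B / sqrt(rowSums(B^2))
  oracle <- sum((nrmA %*% t(nrmA) - nrmB %*% t(nrmB))^2)
  expect_equal(consistency_loss(A, B), oracle, tolerance = 1e-12)
  # larger random instance
  set.seed(33)
  A <- matrix(rnorm(40), 10, 4); B <- matrix(rnorm(40), 10, 4)
  nrmA <- A / sqrt(rowSums(A^2)); nrmB <- B / sqrt(rowSums(B^2))
  oracle <- sum((nrmA %*% t(nrmA) - nrmB %*% t(nrmB))^2)
  expect_equal(consistency_loss(A, B), oracle, tolerance = 1e-10)
})

test_that("consistency loss ignores per-row positive rescaling", {
  set.seed(7)
  A <- matrix(rnorm(24), 8, 3); B <- matrix(rnorm(24), 8, 3)
  v <- consistency_loss(A, B)
  expect_equal(consistency_loss(A * runif(8, 0.1, 5), B * runif(8, 0.1, 5)), v,
               tolerance = 1e-10)
})

test_that("attention fusion weighs equal views uniformly and matches hand arithmetic", {
  p <- tiny_params(4, h2 = 2)
  set.seed(10)
  H <- matrix(rnorm(6), 3, 2)
  out <- attention_fuse(H, H, H, p)
  expect_equal(out$a_s, rep(1 / 3, 3))
  expect_equal(out$H, H %*% p$F_fuse)
  # 2-spot hand instance, scalar arithmetic of the scoring head
  p$W_att <- rbind(c(0.3, -0.2), c(0.1, 0.5))
  p$b_att <- c(0.05, -0.1)
  p$w_co <- c(1.2, -0.7)
  Hs <- rbind(c(0.5, 1), c(-1, 0.2)); Hf <- Hs * 2; Hc <- Hs - 0.3
  sc <- function(H) {
    vapply(1:2, function(i) sum(p$w_co * tanh(H[i, ] %*% p$W_att + p$b_att)), numeric(1))
  }
  S <- cbind(sc(Hs), sc(Hf), sc(Hc))
  Aexp <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  out2 <- attention_fuse(Hs, Hf, Hc, p)
  expect_equal(cbind(out2$a_s, out2$a_f, out2$a_c), Aexp, tolerance = 1e-12)
  Hmix <- Aexp[, 1] * Hs + Aexp[, 2] * Hf + Aexp[, 3] * Hc
  expect_equal(out2$H, Hmix %*% p$F_fuse, tolerance = 1e-12)
})

test_that("a seeded small forward pass reproduces its frozen summary", {
  ds <- tiny_dataset(n = 20, d = 8, seed = 123)
  dsp <- preprocess(ds, n_hvg = 8)
  G <- build_dual_graph(dsp, r = 150, k = 4)
  p <- tiny_params(8, seed = 99)
  e <- encode(dsp$expr, G, p, mode = "eval")
  # frozen after auditing the run against the per-op oracles above
  expect_equal(dim(e$H), c(20L, 4L))
  expect_equal(sum(abs(e$H)), 10.9730654925, tolerance = 1e-8)
  expect_equal(e$H[1, ],
               c(-0.0567797583, 0.0952418186, -0.0737031651, 0.0019980461),
               tolerance = 1e-7)
})
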