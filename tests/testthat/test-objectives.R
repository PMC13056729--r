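test_that("spatial regularisation matches scalar pair arithmetic", {
  H <- rbind(c(0, 0), c(1, 0), c(0, 1))
  E_pos <- rbind(c(1L, 2L), c(1L, 3L))
  E_neg <- rbind(c(2L, 3L))
  # ||h1-h2||^2 = 1, ||h1-h3||^2 = 1, ||h2-h3||^2 = 2
  expect_equal(spatial_reg_loss(H, E_pos, E_neg, lambda_reg = 0.5),
               (1 + 1) / 2 - 0.5 * (2 / 2))
  # identical embeddings: zero
  expect_equal(spatial_reg_loss(matrix(1, 3, 2), E_pos, E_neg, 0.5), 0)
  # pure attraction is non-negative
  expect_gte(spatial_reg_loss(H, E_pos, matrix(0L, 0, 2), 0), 0)
})

test_that("spatial regularisation rejects malformed edge sets", {
  H <- matrix(rnorm(6), 3, 2)
  expect_error(spatial_reg_loss(H, rbind(c(1L, 1L)), matrix(0L, 0, 2), 0.1),
               "self-pairs")
  expect_error(spatial_reg_loss(H, rbind(c(1L, 2L)), rbind(c(2L, 1L)), 0.1),
               "disjoint")
})

test_that("total loss is the exact weighted sum of its components", {
  w <- loss_weights()  # alpha 10, beta .1, gamma .1, delta .15
  expect_equal(total_loss(list(l_zinb = 1, l_con = 1, l_reg = 1, l_dgi = 1), w), 10.35)
  expect_equal(total_loss(list(l_zinb = 0, l_con = 0, l_reg = 0, l_dgi = 0), w), 0)
  set.seed(5)
  for (i in 1:5) {
    comp <- as.list(setNames(rnorm(4), c("l_zinb", "l_con", "l_reg", "l_dgi")))
    expect_equal(total_loss(comp, w),
                 10 * comp$l_zinb + 0.1 * comp$l_con + 0.1 * comp$l_reg + 0.15 * comp$l_dgi)
  }
  expect_error(total_loss(list(l_zinb = NaN, l_con = 0, l_reg = 0, l_dgi = 0), w),
               "l_zinb")
  expect_error(loss_weights(alpha = -1), "non-negative")
})

test_that("analytic gradients of the full objective match finite differences", {
  ds <- tiny_dataset(n = 24, d = 10, seed = 5)
  dsp <- preprocess(ds, n_hvg = 10)
  G <- build_dual_graph(dsp, r = 150, k = 4)
  cfg <- train_config(seed = 3, hidden_dims = c(6, 4), dropout = 0,
                      max_epochs = 5, patience = 4)
  # every term active, including the optional penalty and the MSE head
  w <- loss_weights(lambda_spatial = 0.01, w_mse = 0.5)
  p <- tiny_params(10, h1 = 6, h2 = 4, seed = 8)
  E_sp <- spatialDG:::spatial_edge_pairs(G$A_s)
  set.seed(2)
  E_neg <- spatialDG:::sample_negative_pairs(G$A_s, nrow(E_sp))
  neg <- select_hard_negatives(
    contrast_projection(encode(dsp$expr, G, p, "eval")$H_mix, p)$H_con,
    G$A_s, G$A_f, rng_seed = 4)
  fw <- spatialDG:::sdg_forward(dsp, G, p, w, cfg, neg_index = neg,
                                E_sp = E_sp, E_neg = E_neg, mode = "train",
                                want_grads = TRUE)
  loss_at <- function(pp) {
    spatialDG:::sdg_forward(dsp, G, pp, w, cfg, neg_index = neg,
                            E_sp = E_sp, E_neg = E_neg, mode = "train")$l_total
  }
  eps <- 1e-6
  set.seed(99)
  for (nm in names(p)) {
    for (ii in unique(sample.int(length(p[[nm]]), min(4, length(p[[nm]]))))) {
      p1 <- p; p1[[nm]][ii] <- p1[[nm]][ii] + eps
      p2 <- p; p2[[nm]][ii] <- p2[[nm]][ii] - eps
      fd <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      an <- fw$grads[[nm]][ii]
      expect_equal(an, fd, tolerance = 5e-4,
                   label = sprintf("grad %s[%d]", nm, ii))
    }
  }
})

test_that("training history has one row per epoch and is seed-reproducible", {
  ds <- tiny_dataset(n = 40, d = 12, seed = 2)
  dsp <- preprocess(ds, n_hvg = 12)
  G <- build_dual_graph(dsp, r = 150, k = 5)
  cfg1 <- train_config(seed = 7, hidden_dims = c(8, 5), max_epochs = 1, patience = 0)
  expect_error(train_config(max_epochs = 5, patience = 10), "patience")
  f1 <- train(dsp, G, cfg1)
  expect_equal(nrow(f1$history), 1)
  cfg <- train_config(seed = 7, hidden_dims = c(8, 5), max_epochs = 8, patience = 7)
  fa <- train(dsp, G, cfg)
  fb <- train(dsp, G, cfg)
  expect_equal(fa$history$l_total, fb$history$l_total, tolerance = 1e-6)
  expect_equal(fa$params$W_s1, fb$params$W_s1, tolerance = 1e-8)
})

test_that("the logged components satisfy the weighted-sum identity at every epoch", {
  ds <- tiny_dataset(n = 40, d = 12, seed = 9)
  dsp <- preprocess(ds, n_hvg = 12)
  G <- build_dual_graph(dsp, r = 150, k = 5)
  w <- loss_weights()
  fit <- train(dsp, G, train_config(seed = 1, hidden_dims = c(8, 5),
                                    max_epochs = 10, patience = 9), w)
  h <- fit$history
  recon <- w$alpha * h$l_zinb + w$beta * h$l_con + w$gamma * h$l_reg + w$delta * h$l_dgi
  expect_equal(h$l_total, recon, tolerance = 1e-6)
})

test_that("zeroing one objective leaves the others unchanged at the first epoch", {
  ds <- tiny_dataset(n = 40, d = 12, seed = 4)
  dsp <- preprocess(ds, n_hvg = 12)
  G <- build_dual_graph(dsp, r = 150, k = 5)
  cfg <- train_config(seed = 5, hidden_dims = c(8, 5), max_epochs = 1, patience = 0)
  full <- train(dsp, G, cfg, loss_weights())$history
  nocon <- train(dsp, G, cfg, loss_weights(), ablate(consistency = FALSE))$history
  expect_equal(nocon$l_zinb[1], full$l_zinb[1], tolerance = 1e-10)
  expect_equal(nocon$l_reg[1], full$l_reg[1], tolerance = 1e-10)
  expect_equal(nocon$l_dgi[1], full$l_dgi[1], tolerance = 1e-10)
  expect_equal(nocon$l_con[1], 0)
})

test_that("early stopping cannot fire before the patience window", {
  ds <- tiny_dataset(n = 30, d = 10, seed = 11)
  dsp <- preprocess(ds, n_hvg = 10)
  G <- build_dual_graph(dsp, r = 150, k = 4)
  # min_delta = 1 declares every epoch an improvement failure after the first
  fit <- train(dsp, G, train_config(seed = 2, hidden_dims = c(6, 4),
                                    max_epochs = 30, patience = 5, min_delta = 1))
  expect_gte(nrow(fit$history), 5)
  expect_lt(nrow(fit$history), 30)
})

test_that("ablation switches reshape the objective as declared", {
  ds <- tiny_dataset(n = 40, d = 12, seed = 6)
  dsp <- preprocess(ds, n_hvg = 12)
  G <- build_dual_graph(dsp, r = 150, k = 5)
  cfg <- train_config(seed = 3, hidden_dims = c(8, 5), max_epochs = 3, patience = 2)
  # all-on flags leave the default trainer untouched
  expect_equal(train(dsp, G, cfg, ablation = ablate())$history$l_total,
               train(dsp, G, cfg)$history$l_total, tolerance = 1e-10)
  # dgi off: contrastive component identically zero
  nodgi <- train(dsp, G, cfg, ablation = ablate(dgi = FALSE))
  expect_true(all(nodgi$history$l_dgi == 0))
  # zinb off: reconstruction switches to the MSE head and is monitored
  nozinb <- train(dsp, G, cfg, ablation = ablate(zinb = FALSE))
  expect_true(all(nozinb$history$l_zinb == 0))
  expect_true(all(nozinb$history$l_mse > 0))
  expect_equal(nozinb$monitored, "l_mse")
  # everything off is rejected
  expect_error(train(dsp, G, cfg, weights = loss_weights(0, 0, 0, 0),
                     ablation = ablate(dgi = FALSE)),
               "no active loss term")
})
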