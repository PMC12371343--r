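test_that("a GraphSAGE layer matches hand evaluation of the recurrence", {
  # 2 nodes, 1 undirected edge, scalar features (1, 3), W1 = W2 = 1:
  # out = (ReLU(1 + 3), ReLU(3 + 1)) = (4, 4)
  net <- gene_network(c("a", "b"), rbind(c("a", "b")))
  out <- sage_layer(matrix(c(1, 3), 2, 1), net, matrix(1), matrix(1))
  expect_equal(unname(out), matrix(c(4, 4), 2, 1))
  # W2 = 0 nulls the aggregator
  out0 <- sage_layer(matrix(c(1, 3), 2, 1), net, matrix(2), matrix(0))
  expect_equal(unname(out0), matrix(c(2, 6), 2, 1))
  # isolated node with identity W1 and nonnegative features passes through
  net3 <- gene_network(c("a", "b", "c"), rbind(c("a", "b")))
  H <- matrix(c(1, 2, 5, 0.5, 1, 2), 3, 2)
  out3 <- sage_layer(H, net3, diag(2), diag(2))
  expect_equal(unname(out3[3, ]), unname(H[3, ]))
  expect_error(sage_layer(H, net3, diag(3), diag(2)), "dimension")
})

test_that("encode and decode match a straight-line hand computation", {
  net <- three_node_net()
  X <- matrix(c(0.2, 1.0, 0.4,
                0.8, 0.1, 0.6), 3, 2)
  w <- hand_weights(input_dim = 2, hidden_dim = 2)
  cfg <- gae_config(hidden_dim = 2)
  Z <- gae_encode(X, net, w, cfg, training_mode = FALSE)
  S <- gae_decode(Z, w$W3)
  # independent per-node recomputation (no package linear algebra reuse)
  nb <- list(a = 2, b = c(1, 3), c = 2)
  relu <- function(v) ifelse(v > 0, v, 0)
  H1 <- matrix(0, 3, 2)
  for (i in 1:3) {
    agg <- colMeans(X[nb[[i]], , drop = FALSE])
    H1[i, ] <- relu(as.numeric(w$W1_1 %*% X[i, ] + w$W2_1 %*% agg))
  }
  Z2 <- matrix(0, 3, 2)
  for (i in 1:3) {
    agg <- colMeans(H1[nb[[i]], , drop = FALSE])
    Z2[i, ] <- relu(as.numeric(w$W1_2 %*% H1[i, ] + w$W2_2 %*% agg))
  }
  expect_lt(max(abs(Z - Z2)), 1e-6)
  S2 <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    S2[i, j] <- 1 / (1 + exp(-sum(Z2[i, ] * as.numeric(w$W3 %*% Z2[j, ]))))
  }
  expect_lt(max(abs(S - S2)), 1e-6)
})

test_that("decoder identities hold", {
  # zero embeddings give scores of exactly 0.5
  S <- gae_decode(matrix(0, 4, 3), diag(3))
  expect_true(all(S == 0.5))
  # hidden_dim 1, z = (1, 2), W3 = ln 3: score(1, 2) = sigmoid(2 ln 3) = 0.9
  S2 <- gae_decode(matrix(c(1, 2), 2, 1), matrix(log(3)))
  expect_equal(S2[1, 2], 0.9)
  # symmetric W3 implies a symmetric score matrix
  set.seed(1)
  Z <- matrix(runif(12), 4, 3)
  W3 <- crossprod(matrix(runif(9), 3, 3))
  expect_equal(gae_decode(Z, W3), t(gae_decode(Z, W3)))
  # scores always in (0, 1)
  expect_true(all(S2 > 0 & S2 < 1))
})

test_that("BCE loss matches hand values and is nonnegative", {
  net <- gene_network(c("a", "b"), rbind(c("a", "b")))
  S <- matrix(0.5, 2, 2, dimnames = list(net$genes, net$genes))
  task <- training_task(net, positives = rbind(c("a", "b")),
                        negatives = NULL)
  expect_equal(bce_loss(S, task), log(2))
  S2 <- matrix(c(0, 0.8, 0.2, 0), 2, 2, byrow = TRUE,
               dimnames = list(net$genes, net$genes))
  task2 <- training_task(net, positives = rbind(c("a", "b")),
                         negatives = rbind(c("b", "a")))
  expect_equal(bce_loss(S2, task2), -mean(c(log(0.8), log(0.8))),
               tolerance = 1e-9)
  # perfect scores: loss bounded by the 1e-7 clamp, effectively 0
  S3 <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE,
               dimnames = list(net$genes, net$genes))
  expect_lt(bce_loss(S3, task2), 1e-6)
  expect_error(training_task(net, positives = rbind(c("a", "b")),
                             negatives = rbind(c("a", "b"))), "overlap")
})

test_that("dropout-free training mode equals evaluation mode", {
  net <- three_node_net()
  X <- matrix(runif(6), 3, 2)
  set.seed(5)
  w <- gae_weights(2, 4)
  cfg <- gae_config(hidden_dim = 4, edge_dropout = 0, feature_dropout = 0)
  expect_equal(gae_encode(X, net, w, cfg, training_mode = TRUE),
               gae_encode(X, net, w, cfg, training_mode = FALSE))
  # all-zero weights collapse the embedding to zero
  w0 <- lapply(w, function(m) m * 0)
  class(w0) <- "gae_weights"
  expect_true(all(gae_encode(X, net, w0, cfg) == 0))
  # embeddings are nonnegative (final ReLU)
  expect_true(all(gae_encode(X, net, w, cfg) >= 0))
})

test_that("training is reproducible and epochs = 0 returns init scores", {
  pb <- planted_two_block()
  task <- training_task(pb$net, positives = pb$net$edges,
                        negatives = candidate_pairs(pb$net))
  cfg <- gae_config(hidden_dim = 16, epochs = 50, seed = 3)
  f1 <- gae_train(pb$net, pb$X, task, cfg)
  f2 <- gae_train(pb$net, pb$X, task, cfg)
  expect_identical(f1$final_loss, f2$final_loss)
  expect_identical(f1$scores, f2$scores)
  cfg0 <- gae_config(hidden_dim = 16, epochs = 0, seed = 3)
  f0 <- gae_train(pb$net, pb$X, task, cfg0)
  expect_true(is.na(f0$final_loss))
  set.seed(3)
  w_init <- gae_weights(ncol(pb$X), 16)
  expect_equal(f0$weights$W1_1, w_init$W1_1)
})

test_that("leave-one-out training recovers a held-out within-block edge", {
  pb <- planted_two_block()
  cand <- candidate_pairs(pb$net)
  # hold out one within-block edge by removing it from the graph first
  dmg <- remove_edge(pb$net, "g1", "g2")
  cand2 <- candidate_pairs(dmg)
  ci <- which(cand2[, 1] == "g1" & cand2[, 2] == "g2")
  task <- training_task(dmg, positives = dmg$edges,
                        negatives = cand2[-ci, , drop = FALSE],
                        held_out = cand2[ci, ])
  fit <- gae_train(dmg, pb$X, task,
                   gae_config(hidden_dim = 32, epochs = 1000, seed = 2))
  held_score <- fit$scores["g1", "g2"]
  cross <- cand2[pb$block[match(cand2[, 1], pb$net$genes)] !=
                   pb$block[match(cand2[, 2], pb$net$genes)], ,
                 drop = FALSE]
  cross_scores <- fit$scores[cbind(match(cross[, 1], pb$net$genes),
                                   match(cross[, 2], pb$net$genes))]
  expect_gt(held_score, stats::median(cross_scores))
})

test_that("improve_graph additions shrink as the threshold rises", {
  pb <- planted_two_block(n_per_block = 3, n_features = 12)
  dmg <- remove_edge(pb$net, "g1", "g2")
  imp <- improve_graph(dmg, pb$X,
                       gae_config(hidden_dim = 8, epochs = 120, seed = 4,
                                  threshold = 0.9))
  expect_equal(nrow(imp$scores), dmg$m^2 - nrow(dmg$edges))
  added <- function(t) with(imp$scores, paste(source, target)[score >= t])
  expect_true(all(added(0.95) %in% added(0.9)))
  expect_true(all(added(0.9) %in% added(0.5)))
  # returned network = input edges plus accepted candidates
  expect_equal(nrow(imp$network$edges),
               nrow(dmg$edges) + sum(imp$scores$added))
})

test_that("split-mode training validates its fractions", {
  pb <- planted_split_instance()
  expect_error(split_train(pb$net, pb$X, gae_config(), val_frac = 0.5,
                           test_frac = 0.5), "val_frac")
})
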