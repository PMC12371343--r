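# shared fixtures built in code

# two groups of 4 nodes, dense within groups; features carry a
# group-indicator pattern plus small noise -- a planted instance where
# link prediction is learnable
planted_two_block <- function(n_per_block = 4, n_features = 40,
                              noise = 0.1, seed = 42) {
  set.seed(seed)
  m <- 2 * n_per_block
  genes <- paste0("g", seq_len(m))
  block <- rep(1:2, each = n_per_block)
  edges <- NULL
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j && block[i] == block[j]) edges <- rbind(edges, genes[c(i, j)])
    }
  }
  net <- gene_network(genes, edges)
  X <- matrix(stats::rnorm(m * n_features, sd = noise), m, n_features)
  X[block == 1, seq_len(n_features / 2)] <-
    X[block == 1, seq_len(n_features / 2)] + 1
  X[block == 2, -seq_len(n_features / 2)] <-
    X[block == 2, -seq_len(n_features / 2)] + 1
  X <- pmax(X, 0)
  rownames(X) <- genes
  list(net = net, X = X, block = block)
}

# a larger planted two-block instance with ~60 within-block edges for
# split-mode training (blocks of 6: 2 * 6 * 5 = 60 directed edges)
planted_split_instance <- function(seed = 42) {
  planted_two_block(n_per_block = 6, n_features = 40, noise = 0.1,
                    seed = seed)
}

# tiny deterministic 3-node network for forward-pass oracles
three_node_net <- function() {
  gene_network(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
}

# hand-set small GAE weights for the forward-pass oracle
hand_weights <- function(input_dim, hidden_dim = 2) {
  W <- function(nr, nc, v) matrix(v, nr, nc, byrow = TRUE)
  structure(list(
    W1_1 = W(hidden_dim, input_dim, seq_len(hidden_dim * input_dim) / 10),
    W2_1 = W(hidden_dim, input_dim, rep(c(0.2, -0.1), length.out = hidden_dim * input_dim)),
    W1_2 = W(hidden_dim, hidden_dim, c(0.5, -0.3, 0.1, 0.4)),
    W2_2 = W(hidden_dim, hidden_dim, c(-0.2, 0.6, 0.3, -0.1)),
    W3   = W(hidden_dim, hidden_dim, c(1.0, -0.5, 0.25, 0.75))
  ), class = "gae_weights")
}
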