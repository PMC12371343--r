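#' Graph-autoencoder configuration
#'
#' Defaults follow the hyperparameter choices used throughout the
#' benchmark protocol: hidden dimension 200, learning rate 1e-4, 1000
#' epochs, edge dropout 0.2, feature dropout 0.3, inclusion threshold
#' 0.9.
#'
#' @param hidden_dim embedding width of both GraphSAGE layers.
#' @param learning_rate Adam step size.
#' @param epochs number of training epochs (full-graph gradient steps).
#' @param edge_dropout probability of dropping each undirected edge from
#'   the aggregation, resampled every epoch.
#' @param feature_dropout probability of zeroing each first-layer output
#'   unit (inverted dropout), resampled every epoch.
#' @param threshold decoder score at or above which a candidate edge is
#'   added by [improve_graph()].
#' @param seed RNG seed for weight initialisation and dropout.
#' @param normalize_features if `TRUE`, node features are log1p-transformed
#'   and standardised before encoding; default uses raw expression.
#' @return a list of class `gae_config`.
#' @export
gae_config <- function(hidden_dim = 200, learning_rate = 1e-4,
                       epochs = 1000, edge_dropout = 0.2,
                       feature_dropout = 0.3, threshold = 0.9, seed = 1L,
                       normalize_features = FALSE) {
  stopifnot(hidden_dim >= 1, learning_rate > 0, epochs >= 0,
            edge_dropout >= 0, edge_dropout < 1,
            feature_dropout >= 0, feature_dropout < 1,
            threshold > 0, threshold < 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 edge_dropout = edge_dropout,
                 feature_dropout = feature_dropout, threshold = threshold,
                 seed = as.integer(seed),
                 normalize_features = normalize_features),
            class = "gae_config")
}

# undirected edge list (0-based, deduplicated, self-loops excluded):
# message passing treats every directed edge as undirected
undirected_edges <- function(net) {
  if (nrow(net$edges) == 0) return(matrix(integer(0), ncol = 2))
  i <- match(net$edges[, 1], net$genes)
  j <- match(net$edges[, 2], net$genes)
  keep <- i != j
  a <- pmin(i[keep], j[keep]); b <- pmax(i[keep], j[keep])
  u <- unique(cbind(a, b))
  matrix(as.integer(u - 1L), ncol = 2)
}

# full (no-dropout) mean-aggregation operator; N(i) excludes i itself
aggregation_matrix <- function(net) {
  M <- matrix(0, net$m, net$m)
  ue <- undirected_edges(net) + 1L
  if (nrow(ue)) {
    for (r in seq_len(nrow(ue))) {
      M[ue[r, 1], ue[r, 2]] <- M[ue[r, 1], ue[r, 2]] + 1
      M[ue[r, 2], ue[r, 1]] <- M[ue[r, 2], ue[r, 1]] + 1
    }
    d <- rowSums(M)
    M[d > 0, ] <- M[d > 0, , drop = FALSE] / d[d > 0]
  }
  M
}

#' Initialise GAE weights (Glorot-uniform)
#'
#' Draws from the current RNG state; call `set.seed()` first for
#' reproducible initialisation.
#'
#' @param input_dim feature dimension (number of cells).
#' @param hidden_dim embedding width.
#' @return a list of class `gae_weights` with `W1_1`, `W2_1` (hidden x
#'   input), `W1_2`, `W2_2`, `W3` (hidden x hidden).
#' @export
gae_weights <- function(input_dim, hidden_dim) {
  glorot <- function(nout, nin) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nout * nin, -lim, lim), nout, nin)
  }
  structure(list(W1_1 = glorot(hidden_dim, input_dim),
                 W2_1 = glorot(hidden_dim, input_dim),
                 W1_2 = glorot(hidden_dim, hidden_dim),
                 W2_2 = glorot(hidden_dim, hidden_dim),
                 W3 = glorot(hidden_dim, hidden_dim)),
            class = "gae_weights")
}

#' One GraphSAGE layer
#'
#' `out_i = ReLU(W1 H_i + W2 mean_{j in N(i)} H_j)` with N(i) the nodes
#' adjacent to i when every edge is treated as undirected (i itself
#' excluded); an empty neighbourhood contributes a zero aggregate.
#'
#' @param H nodes x features matrix (one row per gene).
#' @param net a [gene_network()].
#' @param W1,W2 output_dim x input_dim transform matrices.
#' @return nodes x output_dim matrix.
#' @export
sage_layer <- function(H, net, W1, W2) {
  H <- as.matrix(H)
  if (nrow(H) != net$m) stop("feature row count does not match gene count")
  if (ncol(W1) != ncol(H) || ncol(W2) != ncol(H) || nrow(W1) != nrow(W2)) {
    stop("weight dimensions inconsistent with features")
  }
  M <- aggregation_matrix(net)
  pmax(H %*% t(W1) + (M %*% H) %*% t(W2), 0)
}

prepare_features <- function(X, net, config) {
  if (inherits(X, "expression_dataset")) X <- X$values
  X <- as.matrix(X)
  if (nrow(X) != net$m) stop("feature row count does not match gene count")
  if (isTRUE(config$normalize_features)) {
    X <- log1p(X)
    X <- (X - rowMeans(X)) / pmax(apply(X, 1, stats::sd), 1e-8)
  }
  X
}

#' Encode node features to latent embeddings
#'
#' Two GraphSAGE layers. In training mode each undirected edge is
#' dropped with probability `edge_dropout` and first-layer outputs are
#' zeroed elementwise with probability `feature_dropout` (inverted
#' dropout); in evaluation mode no dropout is applied.
#'
#' @param X genes x cells feature matrix or [expression_dataset()].
#' @param net a [gene_network()].
#' @param weights a [gae_weights()].
#' @param config a [gae_config()].
#' @param training_mode apply dropout (draws from the current RNG).
#' @return m x hidden_dim embedding matrix Z (nonnegative).
#' @export
gae_encode <- function(X, net, weights, config = gae_config(),
                       training_mode = FALSE) {
  X <- prepare_features(X, net, config)
  M <- aggregation_matrix(net)
  if (training_mode && config$edge_dropout > 0) {
    ue <- undirected_edges(net) + 1L
    keep <- stats::runif(nrow(ue)) >= config$edge_dropout
    M <- matrix(0, net$m, net$m)
    for (r in which(keep)) {
      M[ue[r, 1], ue[r, 2]] <- M[ue[r, 1], ue[r, 2]] + 1
      M[ue[r, 2], ue[r, 1]] <- M[ue[r, 2], ue[r, 1]] + 1
    }
    d <- rowSums(M)
    M[d > 0, ] <- M[d > 0, , drop = FALSE] / d[d > 0]
  }
  H1 <- pmax(X %*% t(weights$W1_1) + (M %*% X) %*% t(weights$W2_1), 0)
  if (training_mode && config$feature_dropout > 0) {
    p <- config$feature_dropout
    mask <- matrix(stats::runif(length(H1)) >= p, nrow(H1), ncol(H1))
    H1 <- H1 * mask / (1 - p)
  }
  Z <- pmax(H1 %*% t(weights$W1_2) + (M %*% H1) %*% t(weights$W2_2), 0)
  rownames(Z) <- net$genes
  Z
}

#' Decode embeddings into an edge-score matrix
#'
#' `score(i, j) = sigmoid(z_i' W3 z_j)`; the matrix is not symmetric in
#' general (directed edges) and all entries lie in (0, 1).
#'
#' @param Z m x hidden_dim embedding matrix.
#' @param W3 hidden_dim x hidden_dim bilinear form.
#' @return m x m score matrix over ordered gene pairs (self-pairs
#'   included).
#' @export
gae_decode <- function(Z, W3) {
  Z <- as.matrix(Z)
  if (ncol(Z) != nrow(W3)) stop("embedding width does not match W3")
  S <- 1 / (1 + exp(-(Z %*% W3 %*% t(Z))))
  dimnames(S) <- list(rownames(Z), rownames(Z))
  S
}

#' Labelled pair set for GAE training
#'
#' @param net a [gene_network()] (defines index space).
#' @param positives two-column matrix of gene-name pairs with label 1
#'   (defaults to the network's edges).
#' @param negatives two-column matrix of gene-name pairs with label 0.
#' @param held_out optional single pair excluded from both sets
#'   (leave-one-out candidate).
#' @return a list of class `training_task` with 1-based index matrices
#'   `pos`, `neg` and `held_out`.
#' @export
training_task <- function(net, positives = net$edges, negatives,
                          held_out = NULL) {
  to_idx <- function(p) {
    if (is.null(p) || NROW(p) == 0) return(matrix(integer(0), ncol = 2))
    p <- matrix(as.character(as.matrix(p)), ncol = 2)
    idx <- cbind(match(p[, 1], net$genes), match(p[, 2], net$genes))
    if (anyNA(idx)) stop("pair endpoint not in gene list")
    idx
  }
  pos <- to_idx(positives); neg <- to_idx(negatives)
  keyp <- paste(pos[, 1], pos[, 2]); keyn <- paste(neg[, 1], neg[, 2])
  if (length(intersect(keyp, keyn))) stop("positives and negatives overlap")
  ho <- NULL
  if (!is.null(held_out)) {
    ho <- to_idx(matrix(held_out, ncol = 2))
    if (paste(ho[1], ho[2]) %in% c(keyp, keyn)) {
      stop("held-out pair must be excluded from the labelled sets")
    }
  }
  structure(list(pos = pos, neg = neg, held_out = ho), class = "training_task")
}

#' Binary cross-entropy loss over a labelled pair set
#'
#' Mean over the task's pairs of
#' `-(A_ij log s_ij + (1 - A_ij) log(1 - s_ij))`, with scores clamped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param scores m x m score matrix (from [gae_decode()]).
#' @param task a [training_task()].
#' @return nonnegative scalar loss.
#' @export
bce_loss <- function(scores, task) {
  n <- nrow(task$pos) + nrow(task$neg)
  if (n == 0) stop("empty training pair set")
  s <- pmin(pmax(c(scores[task$pos], scores[task$neg]), 1e-7), 1 - 1e-7)
  y <- c(rep(1, nrow(task$pos)), rep(0, nrow(task$neg)))
  -mean(y * log(s) + (1 - y) * log(1 - s))
}

#' Train the GAE on a labelled pair set
#'
#' Runs `epochs` Adam steps on the BCE loss with per-epoch edge and
#' feature dropout, then returns the final weights together with an
#' evaluation-mode (dropout-free) score matrix. Fixed `config$seed`
#' makes the result reproducible.
#'
#' @param net a [gene_network()].
#' @param X genes x cells features or [expression_dataset()].
#' @param task a [training_task()].
#' @param config a [gae_config()].
#' @return a list with `weights` ([gae_weights()]), `scores` (m x m
#'   evaluation-mode matrix) and `final_loss`.
#' @export
gae_train <- function(net, X, task, config = gae_config()) {
  X <- prepare_features(X, net, config)
  set.seed(config$seed)
  w <- gae_weights(ncol(X), config$hidden_dim)
  final_loss <- NA_real_
  if (config$epochs > 0) {
    pairs <- rbind(task$pos, task$neg) - 1L
    labels <- c(rep(1, nrow(task$pos)), rep(0, nrow(task$neg)))
    fit <- gae_train_cpp(X, undirected_edges(net), pairs, labels,
                         unclass(w), config$learning_rate, config$epochs,
                         config$edge_dropout, config$feature_dropout)
    w <- structure(fit[c("W1_1", "W2_1", "W1_2", "W2_2", "W3")],
                   class = "gae_weights")
    final_loss <- fit$final_loss
  }
  Z <- gae_encode(X, net, w, config, training_mode = FALSE)
  scores <- gae_decode(Z, w$W3)
  list(weights = w, scores = scores, final_loss = final_loss)
}

#' Ordered candidate pairs of a network
#'
#' All ordered gene pairs (self-pairs included) absent from the edge
#' set: the candidates scored by [improve_graph()].
#'
#' @param net a [gene_network()].
#' @return two-column character matrix of (source, target) pairs.
#' @export
candidate_pairs <- function(net) {
  A <- adjacency(net)
  idx <- which(A == 0, arr.ind = TRUE)
  # column-major order of which() is deterministic
  cbind(net$genes[idx[, 1]], net$genes[idx[, 2]])
}

#' Improve a network by leave-one-out candidate scoring
#'
#' For every ordered gene pair absent from the input edge set (self-pairs
#' included), a fresh GAE is trained with positives = the input edges and
#' negatives = all other non-edge pairs, the candidate itself held out of
#' both label sets; the trained model's evaluation-mode score for the
#' candidate is recorded. Candidates scoring at or above
#' `config$threshold` are added to the returned network. One training run
#' per candidate: m^2 - |E| runs in total.
#'
#' @param net a [gene_network()] (the damaged/prior-knowledge graph).
#' @param X genes x cells features or [expression_dataset()].
#' @param config a [gae_config()].
#' @param progress print one line per candidate.
#' @return a list with `network` (input edges plus accepted candidates),
#'   `scores` (data.frame `source,target,score,added`), and `threshold`.
#' @export
improve_graph <- function(net, X, config = gae_config(), progress = FALSE) {
  cand <- candidate_pairs(net)
  if (nrow(cand) == 0) stop("no candidate pairs: the graph is complete")
  score <- numeric(nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    others <- cand[-ci, , drop = FALSE]
    task <- training_task(net, positives = net$edges, negatives = others,
                          held_out = cand[ci, ])
    cfg <- config
    cfg$seed <- as.integer((config$seed + 7919 * ci) %% .Machine$integer.max)
    fit <- gae_train(net, X, task, cfg)
    score[ci] <- fit$scores[cand[ci, 1], cand[ci, 2]]
    if (progress) {
      message(sprintf("candidate %s -> %s: score %.3f", cand[ci, 1],
                      cand[ci, 2], score[ci]))
    }
  }
  added <- score >= config$threshold
  improved <- add_edges(net, cand[added, , drop = FALSE])
  list(network = improved,
       scores = data.frame(source = cand[, 1], target = cand[, 2],
                           score = score, added = added,
                           stringsAsFactors = FALSE),
       threshold = config$threshold)
}

#' Split-based training for edge-rich networks
#'
#' The standard GAE protocol for larger graphs: per run, disjoint
#' validation and test edge sets are withheld along with equal-size
#' sampled non-edge negatives; the model is trained on the remaining
#' edges (with 1:1 sampled training negatives) and the AUROC of test
#' edges against test negatives is reported.
#'
#' @param net a [gene_network()].
#' @param X genes x cells features or [expression_dataset()].
#' @param config a [gae_config()].
#' @param val_frac,test_frac fractions of edges withheld for validation
#'   and test (`val_frac + test_frac < 1`).
#' @param n_runs number of independent runs.
#' @return numeric vector of per-run test AUROCs.
#' @export
split_train <- function(net, X, config = gae_config(), val_frac = 0.05,
                        test_frac = 0.1, n_runs = 10) {
  if (val_frac + test_frac >= 1) stop("val_frac + test_frac must be < 1")
  ne <- nrow(net$edges)
  n_test <- floor(test_frac * ne)
  n_val <- floor(val_frac * ne)
  if (n_test < 2) stop("too few edges for a test split")
  nonedges <- candidate_pairs(net)
  auroc <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(as.integer((config$seed + 104729 * r) %% .Machine$integer.max))
    perm <- sample.int(ne)
    test_e <- net$edges[perm[seq_len(n_test)], , drop = FALSE]
    val_e <- net$edges[perm[n_test + seq_len(n_val)], , drop = FALSE]
    train_e <- net$edges[perm[-seq_len(n_test + n_val)], , drop = FALSE]
    nperm <- sample.int(nrow(nonedges))
    n_train_neg <- min(nrow(train_e), nrow(nonedges) - n_test - n_val)
    test_n <- nonedges[nperm[seq_len(n_test)], , drop = FALSE]
    train_n <- nonedges[nperm[n_test + n_val + seq_len(n_train_neg)], ,
                        drop = FALSE]
    train_net <- gene_network(net$genes, train_e)
    task <- training_task(train_net, positives = train_e,
                          negatives = train_n)
    cfg <- config
    cfg$seed <- as.integer((config$seed + 15485863 * r) %% .Machine$integer.max)
    fit <- gae_train(train_net, X, task, cfg)
    s_pos <- fit$scores[cbind(match(test_e[, 1], net$genes),
                              match(test_e[, 2], net$genes))]
    s_neg <- fit$scores[cbind(match(test_n[, 1], net$genes),
                              match(test_n[, 2], net$genes))]
    auroc[r] <- roc_auroc(c(s_pos, s_neg),
                          c(rep(1, length(s_pos)),
                            rep(0, length(s_neg))))$auroc
  }
  auroc
}
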