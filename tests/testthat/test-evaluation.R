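# independent oracle: Mann-Whitney probability by pair enumeration
mw_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

test_that("sweep-based AUROC equals pair-enumeration Mann-Whitney", {
  expect_equal(roc_auroc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auroc, 1)
  expect_equal(roc_auroc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))$auroc, 0.5)
  expect_equal(roc_auroc(c(0.9, 0.7, 0.3, 0.1), c(1, 0, 1, 0))$auroc, 3 / 4)
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    scores <- round(runif(n), 2)  # duplicates force tie handling
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auroc(scores, labels)$auroc, mw_auroc(scores, labels))
  }
  expect_error(roc_auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

make_exp <- function(removed, keys, scores, threshold = 0.9) {
  parts <- strsplit(keys, "->", fixed = TRUE)
  removal_experiment(strsplit(removed, "->", fixed = TRUE)[[1]],
                     data.frame(source = vapply(parts, `[[`, "", 1),
                                target = vapply(parts, `[[`, "", 2),
                                score = scores),
                     threshold)
}

test_that("removed-edge rank and weight follow the rank formula", {
  # m = 3, |E_I| = 4 -> 5 candidates; removed edge scores 3rd of 5
  net <- gene_network(c("a", "b", "c"),
                      rbind(c("a", "b"), c("b", "c"), c("c", "a"),
                            c("a", "a")))
  cand <- candidatize <- expand.grid(src = net$genes, tgt = net$genes,
                                     stringsAsFactors = FALSE)
  keys <- paste0(cand$src, "->", cand$tgt)
  inedge <- keys %in% paste0(net$edges[, 1], "->", net$edges[, 2])
  cand <- cand[!inedge, ]
  dmg <- net
  scores <- c(0.9, 0.8, 0.5, 0.3, 0.1)
  # put the removed edge at rank 3
  exp <- removal_experiment(c(cand$src[3], cand$tgt[3]),
                            data.frame(source = cand$src,
                                       target = cand$tgt, score = scores))
  rr <- removed_edge_rank(exp, dmg)
  expect_equal(rr$rank, 3)
  expect_equal(rr$edge_weight, (5 - 3) / 5)
  # best case: weight (n-1)/n; worst case: weight 0
  exp1 <- removal_experiment(c(cand$src[1], cand$tgt[1]),
                             data.frame(source = cand$src,
                                        target = cand$tgt, score = scores))
  expect_equal(removed_edge_rank(exp1, dmg)$edge_weight, 4 / 5)
  exp5 <- removal_experiment(c(cand$src[5], cand$tgt[5]),
                             data.frame(source = cand$src,
                                        target = cand$tgt, score = scores))
  expect_equal(removed_edge_rank(exp5, dmg)$edge_weight, 0)
})

test_that("spurious fraction pools additions over experiments", {
  e1 <- make_exp("a->b", c("a->b", paste0("x", 1:9, "->y")),
                 c(0.95, rep(0.95, 3), rep(0.1, 6)))
  e2 <- make_exp("c->d", c("c->d", paste0("x", 1:9, "->y")),
                 c(0.95, rep(0.1, 9)))
  expect_equal(spurious_fraction(list(e1, e2)), 3 / 18)
  # no additions -> 0; all additions -> 1
  e0 <- make_exp("a->b", c("a->b", "u->v"), c(0.1, 0.2))
  expect_equal(spurious_fraction(list(e0)), 0)
  eall <- make_exp("a->b", c("a->b", "u->v"), c(0.95, 0.99))
  expect_equal(spurious_fraction(list(eall)), 1)
})

test_that("mean-score flagging uses a strict cutoff and skips true edges", {
  true_net <- gene_network(c("a", "b", "u", "v"), rbind(c("a", "b")))
  e1 <- make_exp("a->b", c("a->b", "u->v", "v->u"), c(0.95, 0.4, 0.5))
  e2 <- make_exp("a->b", c("a->b", "u->v", "v->u"), c(0.9, 0.7, 0.5))
  ms <- mean_score_spurious(list(e1, e2), true_net)
  uv <- ms[ms$source == "u" & ms$target == "v", ]
  expect_equal(uv$mean_score, 0.55)
  expect_true(uv$flagged)
  # exactly at the cutoff is not flagged
  vu <- ms[ms$source == "v" & ms$target == "u", ]
  expect_false(vu$flagged)
  # true edges never appear
  expect_false(any(ms$source == "a" & ms$target == "b"))
})

test_that("ensemble summary counts classification labels", {
  mk <- function(lab) structure(list(classification = lab),
                                class = "fit_result")
  s <- ensemble_summary(list(mk("damaged_like"), mk("damaged_like"),
                             mk("mechanism_recovered")))
  expect_equal(sum(s), 3)
  expect_equal(unname(s["damaged_like"]), 2L)
  expect_equal(unname(s["mechanism_recovered"]), 1L)
  expect_equal(unname(s["decoupled"]), 0L)
  expect_error(ensemble_summary(list(mk("weird"))), "classification")
})
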