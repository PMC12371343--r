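#' ROC curve and AUROC of candidate edge scores
#'
#' Builds the ROC curve by sweeping the decision threshold over the
#' unique scores; the area under the curve (trapezoidal) equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, with ties counted one half.
#'
#' @param scores numeric vector of candidate scores.
#' @param labels binary vector (1 = true edge, 0 = non-edge).
#' @return a list with `curve` (data.frame `threshold,fpr,tpr`) and
#'   `auroc`.
#' @export
roc_auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, 1)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0, 1)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  auroc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                    utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auroc = auroc)
}

#' One edge-removal (leave-one-out improvement) experiment
#'
#' @param removed_edge character pair `(source, target)` removed from
#'   the true graph.
#' @param candidate_scores data.frame `source,target,score` over all
#'   candidates of the damaged graph (as returned in
#'   `improve_graph()$scores`).
#' @param threshold inclusion threshold defining `added_edges`.
#' @return a list of class `removal_experiment`.
#' @export
removal_experiment <- function(removed_edge, candidate_scores,
                               threshold = 0.9) {
  key <- paste0(candidate_scores$source, "->", candidate_scores$target)
  rk <- paste0(removed_edge[1], "->", removed_edge[2])
  if (!rk %in% key) stop("removed edge is not among the candidates")
  stopifnot(all(candidate_scores$score >= 0),
            all(candidate_scores$score <= 1))
  structure(list(removed_edge = as.character(removed_edge),
                 candidate_scores = candidate_scores,
                 added_edges = key[candidate_scores$score >= threshold],
                 threshold = threshold),
            class = "removal_experiment")
}

#' Rank of the removed edge among all candidates, and its edge weight
#'
#' The removed edge's 1-based descending rank R (mean rank on ties)
#' among the `m^2 - |E_I|` candidates of the damaged graph gives the
#' edge weight `(m^2 - |E_I| - R) / (m^2 - |E_I|)`:
#' large when the edge is easily recovered, 0 when it scores last.
#'
#' @param exp a [removal_experiment()].
#' @param net_damaged the damaged [gene_network()] used as GAE input.
#' @return a list with `rank` and `edge_weight`.
#' @export
removed_edge_rank <- function(exp, net_damaged) {
  cs <- exp$candidate_scores
  n_cand <- net_damaged$m^2 - nrow(net_damaged$edges)
  if (nrow(cs) != n_cand) {
    stop("candidates must cover all m^2 - |E_I| non-edges of the damaged graph")
  }
  key <- paste0(cs$source, "->", cs$target)
  rk <- paste0(exp$removed_edge[1], "->", exp$removed_edge[2])
  i <- match(rk, key)
  if (is.na(i)) stop("removed edge missing from candidates")
  R <- rank(-cs$score, ties.method = "average")[i]
  list(rank = R, edge_weight = (n_cand - R) / n_cand)
}

#' Pooled spurious-edge fraction over removal experiments
#'
#' Total number of added edges other than the removed edge, divided by
#' the total number of candidate edges other than the removed edge.
#'
#' @param experiments nonempty list of [removal_experiment()].
#' @return proportion in `[0, 1]`.
#' @export
spurious_fraction <- function(experiments) {
  stopifnot(length(experiments) >= 1)
  added <- 0; possible <- 0
  for (e in experiments) {
    rk <- paste0(e$removed_edge[1], "->", e$removed_edge[2])
    added <- added + length(setdiff(e$added_edges, rk))
    possible <- possible + nrow(e$candidate_scores) - 1
  }
  added / possible
}

#' Frequently recovered non-true edges (mean-score criterion)
#'
#' For every candidate pair absent from the true network, the mean of
#' its score over all experiments in which it was a candidate is taken;
#' pairs with mean score strictly greater than `cutoff` are flagged.
#'
#' @param experiments list of [removal_experiment()] covering each true
#'   edge's removal.
#' @param true_net the true [gene_network()].
#' @param cutoff mean-score cutoff (default 0.5, strict inequality).
#' @return data.frame `source,target,mean_score,flagged`.
#' @export
mean_score_spurious <- function(experiments, true_net, cutoff = 0.5) {
  all_sc <- do.call(rbind, lapply(experiments, `[[`, "candidate_scores"))
  key <- paste0(all_sc$source, "->", all_sc$target)
  true_keys <- paste0(true_net$edges[, 1], "->", true_net$edges[, 2])
  keep <- !key %in% true_keys
  ms <- tapply(all_sc$score[keep], key[keep], mean)
  parts <- strsplit(names(ms), "->", fixed = TRUE)
  data.frame(source = vapply(parts, `[[`, "", 1),
             target = vapply(parts, `[[`, "", 2),
             mean_score = as.numeric(ms),
             flagged = as.numeric(ms) > cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

FIT_CLASSES <- c("damaged_like", "mechanism_recovered", "no_bistability",
                 "decoupled")

#' Histogram of classification labels over an ensemble of fits
#'
#' @param results nonempty list of `fit_result` objects (classified).
#' @return named integer vector over the four outcome labels; counts
#'   sum to `length(results)`.
#' @export
ensemble_summary <- function(results) {
  stopifnot(length(results) >= 1)
  labs <- vapply(results, `[[`, "", "classification")
  if (anyNA(labs) || !all(labs %in% FIT_CLASSES)) {
    stop("all fits must carry a classification label")
  }
  table(factor(labs, levels = FIT_CLASSES))
}

#' Write a removal-experiment report as CSV
#'
#' One row per candidate: `source,target,score,rank,added,in_true_graph`.
#'
#' @param exp a [removal_experiment()].
#' @param true_net the true [gene_network()].
#' @param path output file path.
#' @return invisibly, the report data.frame.
#' @export
write_experiment_report <- function(exp, true_net, path) {
  cs <- exp$candidate_scores
  key <- paste0(cs$source, "->", cs$target)
  true_keys <- paste0(true_net$edges[, 1], "->", true_net$edges[, 2])
  df <- data.frame(cs,
                   rank = rank(-cs$score, ties.method = "average"),
                   added = key %in% exp$added_edges,
                   in_true_graph = key %in% true_keys |
                     key == paste0(exp$removed_edge[1], "->",
                                   exp$removed_edge[2]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
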