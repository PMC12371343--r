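#' Per-branch binned time series
#'
#' @param branch_id branch label.
#' @param times strictly increasing bin-centre sequence.
#' @param values genes x bins matrix.
#' @param n_cells_per_bin cell count per retained bin.
#' @param gene_names gene identifiers for the rows of `values`.
#' @return a list of class `binned_series`.
#' @export
binned_series <- function(branch_id, times, values, n_cells_per_bin,
                          gene_names = rownames(values)) {
  values <- as.matrix(values)
  stopifnot(length(times) == ncol(values), all(diff(times) > 0),
            all(is.finite(values)),
            length(n_cells_per_bin) == length(times))
  if (!is.null(gene_names)) rownames(values) <- gene_names
  structure(list(branch_id = as.character(branch_id),
                 times = as.numeric(times), values = values,
                 n_cells_per_bin = as.integer(n_cells_per_bin),
                 gene_names = rownames(values)),
            class = "binned_series")
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf("<binned_series> branch %s: %d genes x %d bins, t in [%.3g, %.3g]\n",
              x$branch_id, nrow(x$values), length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Bin cells into pseudotime windows, per branch
#'
#' Cells are partitioned by branch label, then assigned to half-open
#' bins `[k * width, (k + 1) * width)`; per bin and gene the aggregator
#' over member cells is taken, with bin centre `(k + 0.5) * width`.
#' Empty bins are dropped.
#'
#' @param data an [expression_dataset()].
#' @param width bin width on the dataset's native time scale.
#' @param aggregator `"mean"` (default) or `"median"`.
#' @return a list of [binned_series()], one per branch label (sorted).
#' @export
bin_pseudotime <- function(data, width = 0.1, aggregator = c("mean", "median")) {
  aggregator <- match.arg(aggregator)
  stopifnot(width > 0)
  if (ncol(data$values) == 0) stop("dataset has no cells")
  aggfun <- if (aggregator == "mean") rowMeans else {
    function(M) apply(M, 1, stats::median)
  }
  out <- list()
  for (b in sort(unique(data$branch))) {
    sel <- data$branch == b
    k <- floor(data$times[sel] / width)
    vals <- data$values[, sel, drop = FALSE]
    ks <- sort(unique(k))
    V <- sapply(ks, function(kk) aggfun(vals[, k == kk, drop = FALSE]))
    V <- matrix(V, nrow = nrow(data$values),
                dimnames = list(data$gene_names, NULL))
    out[[b]] <- binned_series(b, (ks + 0.5) * width, V,
                              as.integer(table(factor(k, levels = ks))),
                              data$gene_names)
  }
  if (sum(vapply(out, function(s) length(s$times), 1L)) == 0) {
    stop("all bins empty")
  }
  out
}

#' Normalise the time axis of binned series
#'
#' Divides bin centres by `t_max` so model time runs on \[0, 1\] and the
#' fitted timescale tau is comparable across datasets.
#'
#' @param series_list list of [binned_series()].
#' @param t_max time value mapped to 1 (default: global maximum bin
#'   centre across the list).
#' @return list of [binned_series()] with rescaled times.
#' @export
normalize_time <- function(series_list,
                           t_max = max(unlist(lapply(series_list, `[[`, "times")))) {
  stopifnot(t_max > 0)
  lapply(series_list, function(s) {
    binned_series(s$branch_id, s$times / t_max, s$values,
                  s$n_cells_per_bin, s$gene_names)
  })
}

#' Jointly scale expression values of several series to \[lo, hi\]
#'
#' One affine map `x' = lo + (hi - lo) * (x - gmin) / (gmax - gmin)` is
#' applied to every series, with `gmin`/`gmax` the minimum and maximum
#' over ALL series jointly, so between-branch expression differences are
#' preserved. Times are untouched.
#'
#' @param series_list list of [binned_series()].
#' @param lo,hi target interval bounds (default 0.1 and 0.9).
#' @return list of [binned_series()] with values in \[lo, hi\].
#' @export
scale_joint <- function(series_list, lo = 0.1, hi = 0.9) {
  stopifnot(length(series_list) >= 1, lo < hi)
  gmin <- min(vapply(series_list, function(s) min(s$values), 1))
  gmax <- max(vapply(series_list, function(s) max(s$values), 1))
  if (gmax <= gmin) stop("constant data: global max equals global min")
  lapply(series_list, function(s) {
    binned_series(s$branch_id, s$times,
                  lo + (hi - lo) * (s$values - gmin) / (gmax - gmin),
                  s$n_cells_per_bin, s$gene_names)
  })
}

#' Write a binned series as CSV (time, one column per gene)
#'
#' @param series a [binned_series()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_binned_series <- function(series, path) {
  df <- data.frame(time = series$times, t(series$values),
                   n_cells = series$n_cells_per_bin, check.names = FALSE)
  utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binned series written by [write_binned_series()]
#'
#' @param path CSV file path.
#' @param branch_id branch label to attach.
#' @return a [binned_series()].
#' @export
read_binned_series <- function(path, branch_id = "b1") {
  df <- utils::read.csv(path, check.names = FALSE)
  nc <- df$n_cells
  genes <- setdiff(colnames(df), c("time", "n_cells"))
  binned_series(branch_id, df$time, t(as.matrix(df[, genes, drop = FALSE])),
                if (is.null(nc)) rep(1L, nrow(df)) else nc, genes)
}
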