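#' Directed, optionally signed gene-regulatory network
#'
#' A `gene_network` stores an ordered gene list, a set of directed edges
#' (self-loops permitted), and an optional regulatory sign per edge
#' (+1 activation, -1 inhibition). The adjacency view `A` has
#' `A[i, j] = 1` iff gene `i` regulates gene `j`.
#'
#' @param genes character vector of gene identifiers (order is preserved;
#'   it defines row/column order of the adjacency matrix).
#' @param edges two-column character matrix or data frame of
#'   (source, target) pairs; may be empty.
#' @param signs optional numeric vector of +1/-1 aligned with the rows of
#'   `edges`. Defaults to +1 for every edge.
#' @return An object of class `gene_network` with elements `genes`,
#'   `edges` (two-column character matrix), `signs` (named numeric vector,
#'   names `"src->tgt"`), and `m` (gene count).
#' @examples
#' net <- gene_network(c("g1", "g2"), rbind(c("g1", "g2")))
#' adjacency(net)
#' @export
gene_network <- function(genes, edges = NULL, signs = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns (source, target)")
    storage.mode(edges) <- "character"
  }
  if (is.null(signs)) signs <- rep(1, nrow(edges))
  if (length(signs) != nrow(edges)) stop("signs must align with edges")
  if (!all(signs %in% c(-1, 1))) stop("signs must be +1 or -1")
  bad <- setdiff(c(edges), genes)
  if (length(bad) > 0) {
    stop("edge endpoint(s) not in gene list: ", paste(bad, collapse = ", "))
  }
  key <- if (nrow(edges) == 0) character(0) else {
    paste0(edges[, 1], "->", edges[, 2])
  }
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    first <- match(key, key)
    if (any(signs != signs[first])) {
      stop("conflicting signs for duplicated edge(s)")
    }
    edges <- edges[keep, , drop = FALSE]
    signs <- signs[keep]
    key <- key[keep]
  }
  names(signs) <- key
  structure(
    list(genes = genes, edges = edges, signs = signs, m = length(genes)),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "<gene_network> %d genes, %d edges (%d inhibitory)\n",
    x$m, nrow(x$edges), sum(x$signs < 0)
  ))
  invisible(x)
}

#' @export
format.gene_network <- function(x, ...) {
  sprintf("<gene_network: %d genes, %d edges>", x$m, nrow(x$edges))
}

edge_keys <- function(net) {
  if (nrow(net$edges) == 0) character(0)
  else paste0(net$edges[, 1], "->", net$edges[, 2])
}

#' Test whether a directed edge is present
#'
#' @param net a [gene_network()].
#' @param source,target gene identifiers.
#' @return logical scalar.
#' @export
has_edge <- function(net, source, target) {
  paste0(source, "->", target) %in% edge_keys(net)
}

#' Adjacency-matrix view of a network
#'
#' @param net a [gene_network()].
#' @param signed if `TRUE`, entries carry the edge sign (+1/-1) instead
#'   of 1.
#' @return an `m x m` numeric matrix with gene names on both dimensions;
#'   `A[i, j] != 0` iff gene i regulates gene j.
#' @export
adjacency <- function(net, signed = FALSE) {
  A <- matrix(0, net$m, net$m, dimnames = list(net$genes, net$genes))
  if (nrow(net$edges) > 0) {
    idx <- cbind(
      match(net$edges[, 1], net$genes),
      match(net$edges[, 2], net$genes)
    )
    A[idx] <- if (signed) net$signs else 1
  }
  A
}

#' Read a network from edge-list text
#'
#' Accepts BEELINE-style edge lists: one `source<delim>target[<delim>sign]`
#' per line, with an optional `Gene1,Gene2[,Sign]`-style header. Sign
#' tokens may be `+`, `-`, `1`, `-1` (default `+`). Duplicate edge lines
#' collapse to a single edge. Gene order is order of first appearance.
#'
#' @param text_source a file path, a connection, or a character vector of
#'   lines (a single string may contain embedded newlines).
#' @param delimiter field separator, default `","`.
#' @return a [gene_network()].
#' @export
read_edge_list <- function(text_source, delimiter = ",") {
  lines <- if (is.character(text_source) && length(text_source) == 1 &&
               !grepl("\n", text_source) && file.exists(text_source)) {
    readLines(text_source, warn = FALSE)
  } else if (inherits(text_source, "connection")) {
    readLines(text_source, warn = FALSE)
  } else {
    unlist(strsplit(as.character(text_source), "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  # optional header: first line whose first two fields look like column labels
  if (length(lines) > 0) {
    f <- strsplit(lines[1], delimiter, fixed = TRUE)[[1]]
    if (length(f) >= 2 && grepl("^gene", tolower(trimws(f[1]))) ) {
      lines <- lines[-1]
    }
  }
  src <- tgt <- character(length(lines))
  sgn <- numeric(length(lines))
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[i], delimiter, fixed = TRUE)[[1]])
    if (length(f) < 2 || !nzchar(f[1]) || !nzchar(f[2])) {
      stop(sprintf("malformed edge-list line %d: '%s'", i, lines[i]))
    }
    s <- if (length(f) >= 3 && nzchar(f[3])) f[3] else "+"
    sv <- switch(s, "+" = 1, "1" = 1, "+1" = 1, "-" = -1, "-1" = -1,
                 stop(sprintf("unknown sign token '%s' on line %d", s, i)))
    src[i] <- f[1]; tgt[i] <- f[2]; sgn[i] <- sv
  }
  genes <- unique(c(rbind(src, tgt)))
  gene_network(genes, cbind(src, tgt), sgn)
}

#' Write a network as an edge-list CSV
#'
#' Deterministic output: edges in stored order, columns
#' `Gene1,Gene2,Sign`. Round-trips through [read_edge_list()].
#'
#' @param net a [gene_network()].
#' @param path output file path; if `NULL`, the lines are returned
#'   invisibly instead of written.
#' @param delimiter field separator, default `","`.
#' @return invisibly, the character vector of lines written.
#' @export
write_edge_list <- function(net, path = NULL, delimiter = ",") {
  header <- paste(c("Gene1", "Gene2", "Sign"), collapse = delimiter)
  body <- if (nrow(net$edges) == 0) character(0) else {
    paste(net$edges[, 1], net$edges[, 2],
          ifelse(net$signs > 0, "+", "-"), sep = delimiter)
  }
  lines <- c(header, body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a network from a dense adjacency CSV
#'
#' Expects an `m x m` 0/1 (optionally signed -1/0/1) matrix with gene
#' names as header row and first column.
#'
#' @param path CSV file path.
#' @return a [gene_network()].
#' @export
read_adjacency <- function(path) {
  A <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  genes <- rownames(A)
  idx <- which(A != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(gene_network(genes))
  gene_network(genes, cbind(genes[idx[, 1]], genes[idx[, 2]]),
               sign(A[idx]))
}

#' Write a network as a dense adjacency CSV
#'
#' @param net a [gene_network()].
#' @param path output file path.
#' @param signed write signed entries (-1/0/1) rather than 0/1.
#' @return invisibly, the adjacency matrix written.
#' @export
write_adjacency <- function(net, path, signed = FALSE) {
  A <- adjacency(net, signed = signed)
  utils::write.csv(A, path, quote = FALSE)
  invisible(A)
}

#' Remove one directed edge (the "damage" operation)
#'
#' Returns a copy of the network with the named edge removed; the input
#' network, its gene list and all other edges are untouched.
#'
#' @param net a [gene_network()].
#' @param source,target gene identifiers of the edge to remove.
#' @return a [gene_network()] with one fewer edge.
#' @export
remove_edge <- function(net, source, target) {
  key <- paste0(source, "->", target)
  i <- match(key, edge_keys(net))
  if (is.na(i)) {
    stop(sprintf("edge (%s -> %s) is not present in the network",
                 source, target))
  }
  gene_network(net$genes, net$edges[-i, , drop = FALSE], unname(net$signs[-i]))
}

#' Add directed edges
#'
#' @param net a [gene_network()].
#' @param edges two-column matrix of (source, target) pairs to add;
#'   already-present edges are ignored.
#' @param signs optional signs for the new edges (default +1).
#' @return a [gene_network()].
#' @export
add_edges <- function(net, edges, signs = NULL) {
  edges <- matrix(as.character(as.matrix(edges)), ncol = 2)
  if (nrow(edges) == 0) return(net)
  if (is.null(signs)) signs <- rep(1, nrow(edges))
  new <- !(paste0(edges[, 1], "->", edges[, 2]) %in% edge_keys(net))
  gene_network(net$genes,
               rbind(net$edges, edges[new, , drop = FALSE]),
               c(unname(net$signs), signs[new]))
}

BENCHMARK_NAMES <- c("bifurcating", "bifurcating-converging", "trifurcating",
                     "cycle", "linear", "long-linear")

#' Packaged benchmark network topologies
#'
#' Returns one of six small signed benchmark GRNs shipped with the
#' package: `bifurcating`, `bifurcating-converging`, `trifurcating`,
#' `cycle`, `linear`, `long-linear`. The bifurcating topology has an
#' upstream activation chain g1 -> g2 -> g3 feeding both arms of a
#' mutually inhibitory (and self-activating) g4/g5 toggle switch, whose
#' state selects one of two branches.
#'
#' @param name topology name (see above).
#' @return a [gene_network()].
#' @export
benchmark_network <- function(name) {
  if (!name %in% BENCHMARK_NAMES) {
    stop("unknown benchmark network '", name, "'; valid names: ",
         paste(BENCHMARK_NAMES, collapse = ", "))
  }
  path <- system.file("extdata", "networks", paste0(name, ".csv"),
                      package = "grnode", mustWork = TRUE)
  read_edge_list(path)
}

in_degrees <- function(net) {
  d <- stats::setNames(rep(0L, net$m), net$genes)
  if (nrow(net$edges)) {
    t <- table(factor(net$edges[, 2], levels = net$genes))
    d[] <- as.integer(t)
  }
  d
}

out_degrees <- function(net) {
  d <- stats::setNames(rep(0L, net$m), net$genes)
  if (nrow(net$edges)) {
    t <- table(factor(net$edges[, 1], levels = net$genes))
    d[] <- as.integer(t)
  }
  d
}
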