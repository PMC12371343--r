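#' Simulation configuration for the stochastic expression generator
#'
#' Parameters of the Euler-Maruyama simulation of Hill-kinetics gene
#' expression with multiplicative noise. Defaults reproduce the study
#' conditions used throughout: 3000 cells, one observation time sampled
#' uniformly on \[0, t_max\] per cell, maximum time 8.
#'
#' @param n_cells number of simulated cells (independent trajectories).
#' @param t_max maximum simulation time; observation times are sampled
#'   uniformly on \[0, t_max\].
#' @param dt Euler-Maruyama step size.
#' @param noise_scale amplitude of the multiplicative noise term
#'   `noise_scale * x * dW`.
#' @param hill_exponent Hill coefficient of the regulation kinetics.
#' @param hill_threshold concentration at half-maximal regulation.
#' @param degradation first-order degradation rate (per gene, scalar
#'   recycled).
#' @param basal basal (leak) production rate per gene (scalar recycled).
#' @param seed RNG seed used by [simulate_cells()].
#' @param knockdown_gene optional gene whose degradation is multiplied
#'   by `knockdown_factor`.
#' @param knockdown_factor degradation multiplier (>= 1) for the
#'   knocked-down gene; 1 means no knockdown.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 3000, t_max = 8, dt = 0.01,
                       noise_scale = 0.05, hill_exponent = 3,
                       hill_threshold = 0.3, degradation = 1, basal = 0,
                       seed = 1L, knockdown_gene = NULL,
                       knockdown_factor = 1) {
  stopifnot(n_cells >= 1, t_max > 0, dt > 0, noise_scale >= 0,
            hill_exponent >= 1, hill_threshold > 0, all(degradation > 0),
            all(basal >= 0), knockdown_factor >= 1)
  structure(list(
    n_cells = as.integer(n_cells), t_max = t_max, dt = dt,
    noise_scale = noise_scale, hill_exponent = hill_exponent,
    hill_threshold = hill_threshold, degradation = degradation,
    basal = basal, seed = as.integer(seed),
    knockdown_gene = knockdown_gene, knockdown_factor = knockdown_factor
  ), class = "sim_config")
}

#' Genes x cells expression dataset
#'
#' @param values nonnegative genes x cells matrix.
#' @param times per-cell observation time.
#' @param branch per-cell branch label (character).
#' @param gene_names gene identifiers aligned with the rows of `values`.
#' @return a list of class `expression_dataset`.
#' @export
expression_dataset <- function(values, times, branch = NULL,
                               gene_names = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(nrow(values)))
  if (is.null(branch)) branch <- rep("b1", ncol(values))
  stopifnot(ncol(values) == length(times), length(times) == length(branch),
            nrow(values) == length(gene_names), all(is.finite(values)),
            all(values >= 0))
  rownames(values) <- gene_names
  structure(list(values = values, times = as.numeric(times),
                 branch = as.character(branch), gene_names = gene_names),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d cells, t in [%.3g, %.3g], branches: %s\n",
              nrow(x$values), ncol(x$values), min(x$times), max(x$times),
              paste(names(table(x$branch)), table(x$branch),
                    sep = ":", collapse = " ")))
  invisible(x)
}

# regulator index lists per target gene, from the signed adjacency
regulator_sets <- function(net) {
  As <- adjacency(net, signed = TRUE)
  lapply(seq_len(net$m), function(i) {
    list(act = which(As[, i] > 0), rep = which(As[, i] < 0))
  })
}

#' Hill-kinetics production rate of the simulator
#'
#' For each gene i the production rate is
#' `basal_i + S_act / (1 + S_act + S_rep)` where
#' `S_act = sum over activators a of (x_a / k)^n` and
#' `S_rep = sum over repressors r of (x_r / k)^n`, with `k` the Hill
#' threshold and `n` the Hill exponent. A gene with no regulators
#' produces at its basal rate only.
#'
#' @param state nonnegative per-gene concentration vector, or a genes x
#'   cells matrix to evaluate many cells at once.
#' @param net a [gene_network()].
#' @param config a [sim_config()].
#' @return rates with the shape of `state`.
#' @export
production_rate <- function(state, net, config) {
  if (any(state < 0)) stop("negative state entry in production_rate")
  vec <- is.null(dim(state))
  X <- if (vec) matrix(state, ncol = 1) else state
  if (nrow(X) != net$m) stop("state dimension does not match gene count")
  regs <- regulator_sets(net)
  rate <- production_rate_core(X, regs, config)
  if (vec) drop(rate) else rate
}

production_rate_core <- function(X, regs, config) {
  xh <- (X / config$hill_threshold)^config$hill_exponent
  m <- nrow(X)
  basal <- rep_len(config$basal, m)
  rate <- matrix(0, m, ncol(X))
  for (i in seq_len(m)) {
    a <- regs[[i]]$act; r <- regs[[i]]$rep
    sa <- if (length(a)) .colSums(xh[a, , drop = FALSE], length(a), ncol(X)) else 0
    sr <- if (length(r)) .colSums(xh[r, , drop = FALSE], length(r), ncol(X)) else 0
    rate[i, ] <- basal[i] + sa / (1 + sa + sr)
  }
  rate
}

# initial state: basal steady state, root gene(s) set high.
initial_state <- function(net, config) {
  deg <- rep_len(config$degradation, net$m)
  x0 <- rep_len(config$basal, net$m) / deg
  indeg <- in_degrees(remove_self_loops(net))
  roots <- which(indeg == 0)
  if (length(roots) == 0) roots <- 1L
  x0[roots] <- 1
  x0
}

remove_self_loops <- function(net) {
  keep <- net$edges[, 1] != net$edges[, 2]
  gene_network(net$genes, net$edges[keep, , drop = FALSE],
               unname(net$signs[keep]))
}

# Euler-Maruyama engine shared by simulate_cells / knockdown_reference.
# Steps n trajectories jointly; invokes `record(step_index, X)` after
# every step (step_index 0 is the initial state).
em_run <- function(net, config, n, record, kd_gene = NULL, kd_factor = 1) {
  m <- net$m
  regs <- regulator_sets(net)
  deg <- rep_len(config$degradation, m)
  if (!is.null(kd_gene)) {
    gi <- match(kd_gene, net$genes)
    if (is.na(gi)) stop("knockdown gene '", kd_gene, "' not in network")
    deg[gi] <- deg[gi] * kd_factor
  }
  n_steps <- ceiling(config$t_max / config$dt)
  X <- matrix(initial_state(net, config), m, n)
  clipped <- 0L
  record(0L, X)
  sdt <- sqrt(config$dt)
  for (k in seq_len(n_steps)) {
    rate <- production_rate_core(X, regs, config)
    drift <- (rate - deg * X) * config$dt
    if (config$noise_scale > 0) {
      X <- X + drift + config$noise_scale * X * sdt *
        matrix(stats::rnorm(m * n), m, n)
    } else {
      X <- X + drift
    }
    neg <- X < 0
    if (any(neg)) { clipped <- clipped + sum(neg); X[neg] <- 0 }
    if (!all(is.finite(X))) {
      stop("non-finite state during integration; decrease dt (dt = ",
           config$dt, ")")
    }
    record(k, X)
  }
  list(state = X, clipped = clipped, n_steps = n_steps)
}

# deterministic relaxation to an attractor; returns m x n terminal states
relax_deterministic <- function(net, config, X, time = NULL) {
  if (is.null(time)) time <- 2 * config$t_max
  regs <- regulator_sets(net)
  deg <- rep_len(config$degradation, net$m)
  n_steps <- ceiling(time / config$dt)
  for (k in seq_len(n_steps)) {
    rate <- production_rate_core(X, regs, config)
    X <- pmax(X + (rate - deg * X) * config$dt, 0)
  }
  X
}

# branch label per cell: signature of the nearest deterministic attractor
# reached from the trajectory's terminal state.
branch_labels <- function(net, config, terminal) {
  A <- relax_deterministic(net, config, terminal)
  sig <- apply(round(A, 1), 2, paste, collapse = ",")
  lev <- sort(unique(sig))
  labels <- paste0("b", match(sig, lev))
  labels
}

#' Simulate a cell-sampled stochastic expression dataset
#'
#' Runs `n_cells` independent Euler-Maruyama trajectories of
#' `dx_i = (production_i - degradation_i * x_i) dt + noise_scale * x_i dW`
#' from a common initial state (root gene high), samples one observation
#' time per cell uniformly on \[0, t_max\], and records the cell's state
#' at that time. Branch labels are assigned from the deterministic
#' attractor nearest to each trajectory's terminal state. Identical
#' config (including seed) gives a bit-identical dataset.
#'
#' @param net a [gene_network()].
#' @param config a [sim_config()]; its `knockdown_gene`/
#'   `knockdown_factor` fields are honoured.
#' @return an [expression_dataset()]; attribute `n_clipped` counts
#'   negative excursions clipped to 0.
#' @export
simulate_cells <- function(net, config = sim_config()) {
  if (net$m == 0) stop("network has no genes")
  set.seed(config$seed)
  n <- config$n_cells
  ts <- stats::runif(n, 0, config$t_max)
  # record each cell at the step whose time first reaches its sampled time
  rec_step <- pmin(ceiling(ts / config$dt), ceiling(config$t_max / config$dt))
  obs <- matrix(0, net$m, n)
  record <- function(k, X) {
    sel <- which(rec_step == k)
    if (length(sel)) obs[, sel] <<- X[, sel]
  }
  run <- em_run(net, config, n, record,
                kd_gene = config$knockdown_gene,
                kd_factor = config$knockdown_factor)
  labels <- branch_labels(net, config, run$state)
  ds <- expression_dataset(obs, ts, labels, net$genes)
  attr(ds, "n_clipped") <- run$clipped
  ds
}

#' Mean knockdown and baseline trajectories on a fixed time grid
#'
#' Averages `n_traj` stochastic trajectories with the chosen gene's
#' degradation rate multiplied by `factor`, next to a baseline
#' (factor 1) average computed from the same RNG seed and grid.
#'
#' @param net a [gene_network()].
#' @param config a [sim_config()].
#' @param gene gene to knock down.
#' @param factor degradation multiplier (the study uses 2, 5 and 8).
#' @param n_traj number of averaged trajectories (>= 100 recommended).
#' @param grid_dt spacing of the recording grid.
#' @return a list of class `knockdown_reference` with `time`,
#'   `baseline` and `knockdown` (genes x grid matrices), `gene`,
#'   `factor`.
#' @export
knockdown_reference <- function(net, config = sim_config(), gene,
                                factor = 5, n_traj = 100, grid_dt = 0.1) {
  if (factor < 1) stop("knockdown factor must be >= 1")
  if (!gene %in% net$genes) stop("gene '", gene, "' not in network")
  record_grid <- function(kd_factor) {
    set.seed(config$seed)
    steps <- round(seq(0, config$t_max, by = grid_dt) / config$dt)
    acc <- matrix(0, net$m, length(steps))
    record <- function(k, X) {
      j <- which(steps == k)
      if (length(j)) acc[, j] <<- rowMeans(X)
    }
    em_run(net, config, n_traj, record, kd_gene = gene,
           kd_factor = kd_factor)
    acc
  }
  base <- record_grid(1)
  kd <- record_grid(factor)
  structure(list(time = seq(0, config$t_max, by = grid_dt),
                 baseline = base, knockdown = kd, gene = gene,
                 factor = factor, gene_names = net$genes),
            class = "knockdown_reference")
}

#' Write an expression dataset as CSV files
#'
#' Writes `values` as a genes x cells CSV and a sidecar CSV with columns
#' `cell_id,time,branch`.
#'
#' @param data an [expression_dataset()].
#' @param path base path; writes `<path>.csv` and `<path>_cells.csv`.
#' @return invisibly, the two file paths.
#' @export
write_expression <- function(data, path) {
  vf <- paste0(path, ".csv"); cf <- paste0(path, "_cells.csv")
  vals <- data$values
  colnames(vals) <- paste0("cell", seq_len(ncol(vals)))
  utils::write.csv(vals, vf, quote = FALSE)
  utils::write.csv(data.frame(cell_id = colnames(vals), time = data$times,
                              branch = data$branch),
                   cf, quote = FALSE, row.names = FALSE)
  invisible(c(vf, cf))
}

#' Read an expression dataset written by [write_expression()]
#'
#' @param path base path used at write time.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(path) {
  vals <- as.matrix(utils::read.csv(paste0(path, ".csv"), row.names = 1,
                                    check.names = FALSE))
  meta <- utils::read.csv(paste0(path, "_cells.csv"))
  expression_dataset(vals, meta$time, meta$branch, rownames(vals))
}
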