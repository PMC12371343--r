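#' Parameters of the Hill-function ODE model
#'
#' The model is `tau * dx/dt = -x + H(x, W_in, u)` with
#' `H_i = (u_i + S_i^+) / (1 + u_i + S_i^+ + S_i^-)`, where
#' `S_i^+ = sum over activating inputs j of W_in[j, i] * x_j^3` and
#' `S_i^- = sum over inhibiting inputs j of -W_in[j, i] * x_j^3`.
#' `W_in[j, i]` is the (signed) influence of gene j on gene i and must
#' be zero wherever the supporting network has no edge j -> i
#' (graph compatibility).
#'
#' @param W_in m x m signed weight matrix.
#' @param u per-gene basal drive, `u >= 0`.
#' @param tau global timescale, `tau > 0`.
#' @param x0_per_branch named list of per-branch initial state vectors
#'   in `[0, 1]^m`.
#' @param gene_names gene identifiers (defaults to `W_in` dimnames).
#' @param net optional [gene_network()]; if given, graph compatibility
#'   of `W_in` is enforced.
#' @return a list of class `hill_params`.
#' @export
hill_params <- function(W_in, u, tau, x0_per_branch,
                        gene_names = rownames(W_in), net = NULL) {
  W_in <- as.matrix(W_in)
  m <- nrow(W_in)
  stopifnot(ncol(W_in) == m, length(u) == m, all(u >= 0), tau > 0)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(m))
  dimnames(W_in) <- list(gene_names, gene_names)
  if (!is.list(x0_per_branch)) x0_per_branch <- list(b1 = x0_per_branch)
  if (is.null(names(x0_per_branch))) {
    names(x0_per_branch) <- paste0("b", seq_along(x0_per_branch))
  }
  for (x0 in x0_per_branch) {
    stopifnot(length(x0) == m, all(x0 >= 0), all(x0 <= 1))
  }
  if (!is.null(net)) {
    if (any(W_in[adjacency(net)[gene_names, gene_names] == 0] != 0)) {
      stop("W_in has nonzero entries off the network's edge set")
    }
  }
  structure(list(W_in = W_in, u = as.numeric(u), tau = tau,
                 x0_per_branch = x0_per_branch, gene_names = gene_names),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("<hill_params> %d genes, %d nonzero weights, tau = %.4g, %d branch IC(s)\n",
              length(x$gene_names), sum(x$W_in != 0), x$tau,
              length(x$x0_per_branch)))
  invisible(x)
}

#' Fitting configuration for the Hill-ODE model
#'
#' @param lambda_p L1 penalty weight on `(W_in, u, tau)` (default 0.001).
#' @param lambda_ic initial-condition penalty weight (default 10).
#' @param w_bound symmetric bound on edge weights (`W` in
#'   `[-w_bound, w_bound]`).
#' @param u_max upper bound on basal drives.
#' @param tau_bounds bounds on the timescale.
#' @param population_multiplier DE population size = multiplier x
#'   decision-vector dimension.
#' @param max_generations generation budget of the jDE run.
#' @param stall_generations early stop after this many generations
#'   without improvement of the best loss.
#' @param seed RNG seed.
#' @param ode_rtol,ode_atol integration tolerances.
#' @param max_steps step budget per trajectory; exhaustion scores the
#'   member with `penalty` instead of aborting the run.
#' @param penalty loss assigned to members whose integration fails.
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(lambda_p = 0.001, lambda_ic = 10, w_bound = 5,
                       u_max = 5, tau_bounds = c(0.01, 10),
                       population_multiplier = 15, max_generations = 300,
                       stall_generations = 50, seed = 1L,
                       ode_rtol = 1e-6, ode_atol = 1e-8,
                       max_steps = 20000, penalty = 1e10) {
  stopifnot(lambda_p >= 0, lambda_ic >= 0, w_bound > 0, u_max > 0,
            length(tau_bounds) == 2, tau_bounds[1] > 0,
            tau_bounds[2] > tau_bounds[1], population_multiplier >= 4,
            max_generations >= 0)
  structure(list(lambda_p = lambda_p, lambda_ic = lambda_ic,
                 w_bound = w_bound, u_max = u_max, tau_bounds = tau_bounds,
                 population_multiplier = population_multiplier,
                 max_generations = as.integer(max_generations),
                 stall_generations = as.integer(stall_generations),
                 seed = as.integer(seed), ode_rtol = ode_rtol,
                 ode_atol = ode_atol, max_steps = as.integer(max_steps),
                 penalty = penalty),
            class = "fit_config")
}

#' In-silico knockdown specification
#'
#' Knocking down gene i replaces its equation by
#' `tau * dx_i/dt = -(k + 1) x_i + H_i`.
#'
#' @param gene gene to knock down.
#' @param k extra-degradation multiplier, `k >= 0` (default 2).
#' @return a list of class `knockdown_spec`.
#' @export
knockdown_spec <- function(gene, k = 2) {
  stopifnot(k >= 0)
  structure(list(gene = gene, k = k), class = "knockdown_spec")
}

#' Time derivative of the Hill-ODE model
#'
#' @param x state vector (finite).
#' @param params a [hill_params()].
#' @return `dx/dt = (-x + H(x)) / tau`.
#' @export
hill_rhs <- function(x, params) {
  stopifnot(all(is.finite(x)))
  if (params$tau <= 0) stop("tau must be > 0")
  drop(hill_rhs_cpp(x, params$W_in, params$u, params$tau,
                    rep(1, length(x))))
}

#' Simulate the Hill-ODE model on a time grid
#'
#' Adaptive Dormand-Prince RK45 integration; the state is confined to
#' the model's invariant region `[0, 1]^m` (at `x_i = 0` the derivative
#' is nonnegative, at `x_i = 1` negative; boundary overshoot from finite
#' steps is clamped). `x0` is the state at `t_grid[1]`.
#'
#' @param params a [hill_params()].
#' @param x0 initial state in `[0, 1]^m` (default: the first branch's
#'   stored initial state).
#' @param t_grid increasing time grid.
#' @param config a [fit_config()] (tolerances).
#' @return genes x times trajectory matrix.
#' @export
hill_simulate <- function(params, x0 = params$x0_per_branch[[1]], t_grid,
                          config = fit_config()) {
  stopifnot(all(diff(t_grid) > 0), all(x0 >= 0), all(x0 <= 1))
  out <- hill_simulate_cpp(params$W_in, params$u, params$tau, x0, t_grid,
                           -1L, 0, config$ode_rtol, config$ode_atol,
                           config$max_steps)
  dimnames(out) <- list(params$gene_names, NULL)
  out
}

#' Simulate the model under an in-silico knockdown
#'
#' Identical to [hill_simulate()] except that the knocked-down gene's
#' degradation coefficient is `k + 1` instead of 1.
#'
#' @param params a [hill_params()].
#' @param spec a [knockdown_spec()].
#' @param x0 initial state.
#' @param t_grid increasing time grid.
#' @param config a [fit_config()].
#' @return genes x times trajectory matrix.
#' @export
knockdown_simulate <- function(params, spec, x0 = params$x0_per_branch[[1]],
                               t_grid, config = fit_config()) {
  gi <- match(spec$gene, params$gene_names)
  if (is.na(gi)) stop("knockdown gene '", spec$gene, "' not in model")
  out <- hill_simulate_cpp(params$W_in, params$u, params$tau, x0, t_grid,
                           gi - 1L, spec$k, config$ode_rtol,
                           config$ode_atol, config$max_steps)
  dimnames(out) <- list(params$gene_names, NULL)
  out
}

# decision-vector layout shared by hill_fit / hill_total_loss
theta_layout <- function(net, branches) {
  E <- nrow(net$edges)
  m <- net$m
  list(E = E, m = m, B = length(branches), branches = branches,
       esrc = match(net$edges[, 1], net$genes) - 1L,
       etgt = match(net$edges[, 2], net$genes) - 1L,
       dim = E + m + 1 + length(branches) * m)
}

params_to_theta <- function(params, net, layout) {
  w <- params$W_in[cbind(layout$esrc + 1L, layout$etgt + 1L)]
  x0 <- unlist(params$x0_per_branch[layout$branches], use.names = FALSE)
  c(w, params$u, params$tau, x0)
}

theta_to_params <- function(theta, net, layout) {
  W <- matrix(0, layout$m, layout$m,
              dimnames = list(net$genes, net$genes))
  if (layout$E > 0) {
    W[cbind(layout$esrc + 1L, layout$etgt + 1L)] <- theta[seq_len(layout$E)]
  }
  u <- theta[layout$E + seq_len(layout$m)]
  tau <- theta[layout$E + layout$m + 1]
  x0 <- lapply(seq_len(layout$B), function(b) {
    theta[layout$E + layout$m + 1 + (b - 1) * layout$m + seq_len(layout$m)]
  })
  names(x0) <- layout$branches
  hill_params(W, pmax(u, 0), tau, x0, net$genes)
}

series_payload <- function(series_list) {
  list(times = lapply(series_list, `[[`, "times"),
       values = lapply(series_list, function(s) unname(s$values)))
}

#' Composite fitting loss of the Hill-ODE model
#'
#' `L_total = L_model + lambda_p * L_p + lambda_ic * L_IC` with
#' `L_model` the summed squared trajectory error over all branches,
#' `L_p` the L1 norm of `(W_in edge weights, u, tau)` (initial states
#' excluded), and `L_IC` the summed per-branch max-norm distance between
#' the model initial state and the first data point.
#'
#' @param params a [hill_params()] whose branch names cover the series.
#' @param series_list list of [binned_series()].
#' @param config a [fit_config()].
#' @param net optional [gene_network()] defining which `W_in` entries
#'   count as free parameters (defaults to the nonzero pattern).
#' @return named numeric vector `L_model`, `L_p`, `L_IC`, `L_total`.
#' @export
hill_total_loss <- function(params, series_list, config = fit_config(),
                            net = NULL) {
  branches <- vapply(series_list, `[[`, "", "branch_id")
  missing <- setdiff(branches, names(params$x0_per_branch))
  if (length(missing)) {
    stop("no initial state for branch(es): ", paste(missing, collapse = ", "))
  }
  if (is.null(net)) {
    idx <- which(params$W_in != 0, arr.ind = TRUE)
    net <- gene_network(params$gene_names,
                        cbind(params$gene_names[idx[, 1]],
                              params$gene_names[idx[, 2]]))
  }
  layout <- theta_layout(net, branches)
  theta <- params_to_theta(params, net, layout)
  pay <- series_payload(series_list)
  comp <- hill_loss_population_cpp(matrix(theta, ncol = 1), layout$esrc,
                                   layout$etgt, layout$m, pay$times,
                                   pay$values, config$lambda_p,
                                   config$lambda_ic, config$ode_rtol,
                                   config$ode_atol, config$max_steps,
                                   config$penalty)
  stats::setNames(comp[, 1], c("L_model", "L_p", "L_IC", "L_total"))
}

#' Fit the Hill-ODE model with self-adaptive differential evolution
#'
#' The decision vector holds one signed weight per network edge, the
#' basal drives `u`, the timescale `tau`, and one initial state per
#' branch. jDE (self-adaptive DE/rand/1/bin: per-member F and CR,
#' regenerated with probability 0.1 each generation and inherited on
#' success) minimises [hill_total_loss()]. Edge-weight signs are left
#' free even when the input network is signed, so the fit itself decides
#' whether an interaction is activating or inhibiting.
#'
#' @param net a [gene_network()] the fitted `W_in` must be compatible
#'   with.
#' @param series_list nonempty list of [binned_series()] (one per
#'   branch).
#' @param config a [fit_config()].
#' @param focus optional focus description passed to [classify_fit()];
#'   if `NULL` the result is left unclassified.
#' @return a list of class `fit_result`: `params`, `loss_components`
#'   (`L_model`, `L_p`, `L_IC`, `L_total`), `generations_run`,
#'   `classification`, `seed`, `trace` (best loss per generation).
#' @export
hill_fit <- function(net, series_list, config = fit_config(), focus = NULL) {
  if (net$m == 0) stop("network has no genes")
  if (length(series_list) == 0) stop("empty series list")
  branches <- vapply(series_list, `[[`, "", "branch_id")
  layout <- theta_layout(net, branches)
  lower <- c(rep(-config$w_bound, layout$E), rep(0, layout$m),
             config$tau_bounds[1], rep(0, layout$B * layout$m))
  upper <- c(rep(config$w_bound, layout$E), rep(config$u_max, layout$m),
             config$tau_bounds[2], rep(1, layout$B * layout$m))
  d <- layout$dim
  NP <- max(4 * d, config$population_multiplier * d)
  pay <- series_payload(series_list)
  evalpop <- function(Theta) {
    hill_loss_population_cpp(Theta, layout$esrc, layout$etgt, layout$m,
                             pay$times, pay$values, config$lambda_p,
                             config$lambda_ic, config$ode_rtol,
                             config$ode_atol, config$max_steps,
                             config$penalty)
  }
  set.seed(config$seed)
  pop <- matrix(stats::runif(d * NP, lower, upper), d, NP)
  comp <- evalpop(pop)
  f <- comp[4, ]
  if (!any(is.finite(f))) stop("population collapse: no finite loss")
  Fv <- rep(0.5, NP); CRv <- rep(0.9, NP)
  best <- min(f)
  stall <- 0L
  trace <- numeric(0)
  gen <- 0L
  while (gen < config$max_generations && stall < config$stall_generations) {
    gen <- gen + 1L
    # jDE control-parameter self-adaptation (tau1 = tau2 = 0.1)
    Ft <- ifelse(stats::runif(NP) < 0.1, 0.1 + 0.9 * stats::runif(NP), Fv)
    CRt <- ifelse(stats::runif(NP) < 0.1, stats::runif(NP), CRv)
    r <- vapply(seq_len(NP), function(i) {
      # three mutually distinct members, none equal to i
      ri <- sample.int(NP - 1L, 3)
      ri + (ri >= i)
    }, integer(3))
    # DE/rand/1 mutation + binomial crossover
    V <- pop[, r[1, ]] + rep(Ft, each = d) * (pop[, r[2, ]] - pop[, r[3, ]])
    V <- pmin(pmax(V, lower), upper)
    cross <- matrix(stats::runif(d * NP), d, NP) <
      matrix(CRt, d, NP, byrow = TRUE)
    jrand <- cbind(sample.int(d, NP, replace = TRUE), seq_len(NP))
    cross[jrand] <- TRUE
    Trial <- ifelse(cross, V, pop)
    tcomp <- evalpop(Trial)
    tf <- tcomp[4, ]
    win <- tf <= f
    pop[, win] <- Trial[, win]
    comp[, win] <- tcomp[, win]
    f[win] <- tf[win]
    Fv[win] <- Ft[win]; CRv[win] <- CRt[win]
    newbest <- min(f)
    if (newbest < best - 1e-12) { best <- newbest; stall <- 0L }
    else stall <- stall + 1L
    trace <- c(trace, best)
  }
  if (!any(is.finite(f))) stop("population collapse: no finite loss")
  bi <- which.min(f)
  params <- theta_to_params(pop[, bi], net, layout)
  result <- structure(list(
    params = params,
    loss_components = stats::setNames(comp[, bi],
                                      c("L_model", "L_p", "L_IC", "L_total")),
    generations_run = gen, classification = NA_character_,
    seed = config$seed, trace = trace
  ), class = "fit_result")
  if (!is.null(focus)) {
    result$classification <- classify_fit(result, net, focus, config)
  }
  result
}

#' @export
print.fit_result <- function(x, ...) {
  lc <- x$loss_components
  cat(sprintf("<fit_result> L_total = %.4g (model %.4g, L1 %.4g, IC %.4g), %d generations%s\n",
              lc["L_total"], lc["L_model"], lc["L_p"], lc["L_IC"],
              x$generations_run,
              if (is.na(x$classification)) ""
              else paste0(", class: ", x$classification)))
  invisible(x)
}

#' Focus description for fit classification
#'
#' Names the upstream source gene and the two toggle arms whose balance
#' the classification inspects: `target` is the arm whose incoming edge
#' was removed/restored, `other` the competing arm.
#'
#' @param source upstream gene (e.g. `"g3"`).
#' @param target restored-arm gene (e.g. `"g5"`).
#' @param other competing-arm gene (e.g. `"g4"`).
#' @param k knockdown strength used in the classification simulation.
#' @return a list of class `fit_focus`.
#' @export
fit_focus <- function(source, target, other, k = 2) {
  structure(list(source = source, target = target, other = other, k = k),
            class = "fit_focus")
}

late_time_mean <- function(traj, frac = 0.2) {
  T <- ncol(traj)
  sel <- seq.int(max(1L, T - ceiling(frac * T) + 1L), T)
  rowMeans(traj[, sel, drop = FALSE])
}

#' Classify the mechanism recovered by a fit
#'
#' Labels a [hill_fit()] result on a branching instance:
#' * `no_bistability` - simulations from the branch initial states end
#'   within 0.1 (max-norm) of each other;
#' * `mechanism_recovered` - the restored edge (source -> target)
#'   carries more weight than the competing arm (source -> other) AND an
#'   in-silico knockdown of the source (strength `k`) lowers the
#'   late-time target expression relative to baseline;
#' * `decoupled` - both arms receive negligible weight from the source
#'   (< 5% of the largest fitted weight); the data are explained by
#'   basal drives instead;
#' * `damaged_like` - otherwise (the competing arm dominates, as fits on
#'   the damaged graph must do).
#'
#' @param result a `fit_result` with at least two branch initial states.
#' @param net the supporting [gene_network()].
#' @param focus a [fit_focus()].
#' @param config a [fit_config()] (integration settings).
#' @return one of `"no_bistability"`, `"mechanism_recovered"`,
#'   `"decoupled"`, `"damaged_like"`.
#' @export
classify_fit <- function(result, net, focus, config = fit_config()) {
  params <- result$params
  gn <- params$gene_names
  for (g in c(focus$source, focus$target, focus$other)) {
    if (!g %in% gn) stop("focus gene '", g, "' not in model")
  }
  if (length(params$x0_per_branch) < 2) {
    stop("classification needs at least two branch initial states")
  }
  grid <- seq(0, 1, length.out = 101)
  ends <- sapply(params$x0_per_branch, function(x0) {
    hill_simulate(params, x0, grid, config)[, length(grid)]
  })
  sep <- max(apply(ends, 1, function(r) diff(range(r))))
  if (sep < 0.1) return("no_bistability")
  w_t <- abs(params$W_in[focus$source, focus$target])
  w_o <- abs(params$W_in[focus$source, focus$other])
  if (w_t > w_o) {
    # verify the knockdown direction by simulation, in the branch where
    # the target gene is highest at late time
    late <- sapply(params$x0_per_branch, function(x0) {
      late_time_mean(hill_simulate(params, x0, grid, config))[focus$target]
    })
    x0 <- params$x0_per_branch[[which.max(late)]]
    base <- late_time_mean(hill_simulate(params, x0, grid, config))
    kd <- late_time_mean(knockdown_simulate(params,
                                            knockdown_spec(focus$source,
                                                           focus$k),
                                            x0, grid, config))
    if (kd[focus$target] < base[focus$target]) return("mechanism_recovered")
  }
  wmax <- max(abs(params$W_in))
  if (wmax > 0 && w_t < 0.05 * wmax && w_o < 0.05 * wmax) {
    return("decoupled")
  }
  "damaged_like"
}

#' Serialise a fit result as JSON
#'
#' @param result a `fit_result`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fit_json <- function(result, path) {
  obj <- list(genes = result$params$gene_names,
              W_in = result$params$W_in, u = result$params$u,
              tau = result$params$tau,
              x0_per_branch = result$params$x0_per_branch,
              loss_components = as.list(result$loss_components),
              generations_run = result$generations_run,
              classification = result$classification, seed = result$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fit result written by [write_fit_json()]
#'
#' @param path JSON file path.
#' @return a `fit_result` (without optimisation trace).
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- matrix(unlist(obj$W_in), length(obj$genes), length(obj$genes),
              byrow = FALSE, dimnames = list(obj$genes, obj$genes))
  params <- hill_params(W, obj$u, obj$tau,
                        lapply(obj$x0_per_branch, as.numeric), obj$genes)
  structure(list(params = params,
                 loss_components = unlist(obj$loss_components),
                 generations_run = obj$generations_run,
                 classification = obj$classification %||% NA_character_,
                 seed = obj$seed, trace = numeric(0)),
            class = "fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
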