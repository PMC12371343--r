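#' Configuration of a full benchmark experiment
#'
#' Bundles the stage configurations of the benchmark protocol:
#' simulate cells on the true network, damage it by removing one edge,
#' improve it with the GAE, bin/scale the trajectories, fit an ensemble
#' of Hill-ODE models, and compare in-silico knockdowns against
#' simulated references.
#'
#' @param network_name one of the packaged benchmark topologies, or a
#'   [gene_network()] object.
#' @param removal edge to remove as `c(source, target)`, or `"each"` to
#'   run one removal experiment per true edge.
#' @param gae a [gae_config()].
#' @param sim a [sim_config()].
#' @param fit a [fit_config()].
#' @param n_fit_repeats ensemble size (default 25; 0 skips fitting).
#' @param knockdown a [knockdown_spec()] or `NULL`.
#' @param focus a [fit_focus()] for classification, or `NULL`.
#' @param output_dir directory for stage artifacts.
#' @param seed master seed; per-stage seeds are derived by fixed
#'   offsets.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(network_name = "bifurcating",
                              removal = c("g3", "g5"),
                              gae = gae_config(), sim = sim_config(),
                              fit = fit_config(), n_fit_repeats = 25,
                              knockdown = knockdown_spec("g3", 2),
                              focus = fit_focus("g3", "g5", "g4"),
                              output_dir = tempfile("grnode_exp"),
                              seed = 1L) {
  structure(list(network_name = network_name, removal = removal,
                 gae = gae, sim = sim, fit = fit,
                 n_fit_repeats = as.integer(n_fit_repeats),
                 knockdown = knockdown, focus = focus,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

# per-stage seeds derived from one master seed by fixed offsets
stage_seed <- function(master, stage) {
  offs <- c(simulate = 11L, gae = 211L, fit = 3011L, knockdown = 40009L)
  as.integer((as.numeric(master) * 97 + offs[[stage]]) %% .Machine$integer.max)
}

#' Run the full benchmark protocol
#'
#' Stage chain: simulate -> damage -> improve -> bin/scale -> fit
#' ensemble -> knockdown comparison -> metrics. Every artifact is
#' written under `config$output_dir` and referenced from a manifest
#' JSON; identical configs and seeds reproduce identical manifests.
#'
#' @param config an [experiment_config()].
#' @return the manifest, invisibly; also written as `manifest.json`.
#' @export
run_experiment <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  manifest <- list(seed = config$seed, stages = list())
  net <- if (inherits(config$network_name, "gene_network")) {
    config$network_name
  } else benchmark_network(config$network_name)
  write_edge_list(net, out("true_network.csv"))

  # --- simulate ---
  sim_cfg <- config$sim
  sim_cfg$seed <- stage_seed(config$seed, "simulate")
  data <- simulate_cells(net, sim_cfg)
  write_expression(data, out("expression"))
  manifest$stages$simulate <- list(seed = sim_cfg$seed,
                                   n_cells = sim_cfg$n_cells,
                                   files = c("expression.csv",
                                             "expression_cells.csv"))

  # --- damage + improve ---
  removals <- if (identical(config$removal, "each")) {
    lapply(seq_len(nrow(net$edges)), function(i) net$edges[i, ])
  } else list(as.character(config$removal))
  experiments <- list()
  improved <- NULL
  for (ri in seq_along(removals)) {
    rem <- removals[[ri]]
    damaged <- remove_edge(net, rem[1], rem[2])
    gcfg <- config$gae
    gcfg$seed <- stage_seed(config$seed, "gae") + ri
    imp <- improve_graph(damaged, data, gcfg)
    experiments[[ri]] <- removal_experiment(rem, imp$scores,
                                            gcfg$threshold)
    if (ri == 1) {
      improved <- imp$network
      write_edge_list(damaged, out("damaged_network.csv"))
      write_edge_list(improved, out("improved_network.csv"))
      utils::write.csv(imp$scores, out("candidate_scores.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  }
  manifest$stages$improve <- list(
    seed = stage_seed(config$seed, "gae"),
    n_removals = length(removals),
    spurious_fraction = spurious_fraction(experiments),
    files = c("damaged_network.csv", "improved_network.csv",
              "candidate_scores.csv"))

  # --- bin + scale ---
  series <- scale_joint(normalize_time(bin_pseudotime(data, width = 0.1),
                                       t_max = config$sim$t_max))
  for (s in series) {
    write_binned_series(s, out(paste0("series_", s$branch_id, ".csv")))
  }
  manifest$stages$prep <- list(branches = vapply(series, `[[`, "",
                                                 "branch_id"))

  # --- fit ensemble ---
  fits <- list()
  if (config$n_fit_repeats > 0) {
    for (k in seq_len(config$n_fit_repeats)) {
      fcfg <- config$fit
      fcfg$seed <- stage_seed(config$seed, "fit") + k
      fits[[k]] <- hill_fit(improved, series, fcfg, focus = config$focus)
      write_fit_json(fits[[k]], out(sprintf("fit_%02d.json", k)))
    }
    manifest$stages$fit <- list(
      seed = stage_seed(config$seed, "fit"),
      n_repeats = config$n_fit_repeats,
      losses = vapply(fits, function(f) f$loss_components[["L_total"]], 1))
    if (!is.null(config$focus)) {
      manifest$stages$fit$ensemble <- as.list(ensemble_summary(fits))
    }
  }

  # --- knockdown comparison ---
  if (!is.null(config$knockdown) && length(fits) > 0) {
    kd_cfg <- config$sim
    kd_cfg$seed <- stage_seed(config$seed, "knockdown")
    ref <- knockdown_reference(net, kd_cfg, config$knockdown$gene,
                               factor = 5)
    cmp <- lapply(fits, compare_knockdown, reference = ref,
                  gene = config$knockdown$gene,
                  focus_gene = config$focus$target, k = config$knockdown$k)
    manifest$stages$knockdown <- list(
      seed = kd_cfg$seed, gene = config$knockdown$gene,
      agreement = vapply(cmp, `[[`, TRUE, "agreement"))
  }

  manifest$stages$metrics <- list(
    spurious_fraction = spurious_fraction(experiments))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, network = net, improved = improved,
                 experiments = experiments, series = series, fits = fits))
}

#' Compare a fitted model's knockdown prediction with a simulated
#' reference
#'
#' Computes the late-time change (knockdown minus baseline, mean over
#' the last 20% of the grid) of every gene under the fitted model's
#' in-silico knockdown and under the stochastic simulator's reference;
#' agreement holds when the focal gene's change has the same sign in
#' both.
#'
#' @param fit a `fit_result`.
#' @param reference a [knockdown_reference()] (the 5x variant in the
#'   benchmark protocol).
#' @param gene the knocked-down gene.
#' @param focus_gene gene whose response is compared (default: the
#'   reference's most-affected downstream gene).
#' @param k model knockdown strength (default 2).
#' @param config a [fit_config()] for the model simulation.
#' @return a list with `agreement`, `model_effect`, `reference_effect`
#'   (named per-gene late-time changes).
#' @export
compare_knockdown <- function(fit, reference, gene, focus_gene = NULL,
                              k = 2, config = fit_config()) {
  params <- fit$params
  if (!gene %in% params$gene_names || !gene %in% reference$gene_names) {
    stop("gene '", gene, "' absent from fit or reference")
  }
  ref_eff <- late_time_mean(reference$knockdown) -
    late_time_mean(reference$baseline)
  names(ref_eff) <- reference$gene_names
  if (is.null(focus_gene)) {
    cand <- setdiff(reference$gene_names, gene)
    focus_gene <- cand[which.max(abs(ref_eff[cand]))]
  }
  grid <- seq(0, 1, length.out = 101)
  # evaluate in the branch with the highest late-time focal expression
  late <- vapply(params$x0_per_branch, function(x0) {
    late_time_mean(hill_simulate(params, x0, grid, config))[focus_gene]
  }, 1)
  x0 <- params$x0_per_branch[[which.max(late)]]
  base <- late_time_mean(hill_simulate(params, x0, grid, config))
  kd <- late_time_mean(knockdown_simulate(params, knockdown_spec(gene, k),
                                          x0, grid, config))
  model_eff <- kd - base
  names(model_eff) <- params$gene_names
  list(agreement = sign(model_eff[[focus_gene]]) ==
         sign(ref_eff[[focus_gene]]),
       focus_gene = focus_gene, model_effect = model_eff,
       reference_effect = ref_eff)
}
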