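# Model evaluation: structural distance, the prior/noise-ratio experiment
# harness, the random-prior significance test, and Boolean cell-fate
# prediction.

.edge_keys <- function(x) {
  if (inherits(x, "logic_model")) x <- model_edges(x)
  if (inherits(x, "prior_network")) x <- x$edges
  unique(edge_key(x$source, x$target))
}

#' Structural distance between two networks
#'
#' The number of directed-edge additions plus deletions needed to convert
#' the learned network into the true one; edge signs and gate structure
#' are ignored.
#'
#' @param learned,truth a [logic_model()], [prior_network()] or edge data
#'   frame (`source`, `target`).
#' @return non-negative integer.
#' @export
structural_distance <- function(learned, truth) {
  a <- .edge_keys(learned)
  b <- .edge_keys(truth)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Experiment grid for the prior/noise-ratio study
#'
#' @param prior_ratios fractions of true edges supplied as prior.
#' @param noise_ratios false-edge fractions relative to the prior size.
#' @param n_repeats repeats per grid cell (default 20).
#' @param seed base seed; every (cell, repeat) derives its own sub-seed.
#' @return list of class `experiment_grid`.
#' @export
experiment_grid <- function(prior_ratios, noise_ratios = 0,
                            n_repeats = 20L, seed = 1L) {
  if (any(prior_ratios < 0 | prior_ratios > 1))
    stop("prior ratios must lie in [0, 1]")
  if (any(noise_ratios < 0)) stop("noise ratios must be non-negative")
  structure(list(prior_ratios = prior_ratios, noise_ratios = noise_ratios,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "experiment_grid")
}

#' Prior/noise-ratio structure-recovery experiment
#'
#' For every grid cell and repeat: sample a perturbed prior from the truth
#' ([perturb_prior()]), fit the model to the data, and record the
#' structural distance of the learned network to the truth.
#'
#' @param truth ground-truth [logic_model()].
#' @param dataset the `perturbation_dataset` used for fitting.
#' @param grid an [experiment_grid()].
#' @param obj_cfg,ga_cfg,sim_cfg configuration passed to [fit()].
#' @param d_max indegree cap stored in the sampled priors.
#' @param space optional [search_space()] template; the prior of each
#'   repeat replaces confidences but the universe is rebuilt per repeat.
#' @return data frame with columns `prior_ratio`, `noise_ratio`, `repeat_id`,
#'   `sd` (structural distance), `fitness`.
#' @export
run_prior_ratio_experiment <- function(truth, dataset, grid,
                                       obj_cfg = objective_config(),
                                       ga_cfg = ga_config(),
                                       sim_cfg = simulation_config(),
                                       d_max = 2L) {
  cells <- expand.grid(prior_ratio = grid$prior_ratios,
                       noise_ratio = grid$noise_ratios,
                       repeat_id = seq_len(grid$n_repeats))
  out <- cells
  out$sd <- NA_integer_
  out$fitness <- NA_real_
  for (r in seq_len(nrow(cells))) {
    sub_seed <- grid$seed + 7919L * (r - 1L)
    prior <- perturb_prior(truth, cells$prior_ratio[r], cells$noise_ratio[r],
                           seed = sub_seed, d_max = d_max)
    ga <- ga_cfg
    ga$seed <- sub_seed
    res <- fit(dataset, prior, obj_cfg, ga, sim_cfg)
    out$sd[r] <- structural_distance(res$model, truth)
    out$fitness[r] <- res$best_fitness
  }
  out
}

# One random network satisfying the null-model rules: same node and edge
# counts as the prior, every node incident to >= 1 edge, stimulated nodes
# with no incoming but >= 1 outgoing edge, confidences permuted from the
# original scores.
.random_null_network <- function(prior, max_tries = 10000L) {
  nodes <- prior$nodes
  stim <- nodes[prior$roles == "stimulated"]
  n_edges <- nrow(prior$edges)
  pool <- expand.grid(source = nodes, target = nodes, stringsAsFactors = FALSE)
  pool <- pool[pool$source != pool$target & !(pool$target %in% stim), ]
  if (n_edges < 1) stop("prior has no edges to permute")
  for (try in seq_len(max_tries)) {
    pick <- pool[sample.int(nrow(pool), n_edges), , drop = FALSE]
    incident <- unique(c(pick$source, pick$target))
    if (!all(nodes %in% incident)) next
    if (!all(stim %in% pick$source)) next
    pick$sign <- sample(c(1L, -1L), n_edges, replace = TRUE)
    pick$confidence <- sample(prior$edges$confidence)
    return(prior_network(pick, roles = prior$roles, d_max = prior$d_max))
  }
  stop("could not satisfy the random-network constraints in ", max_tries,
       " tries (too few edges?)")
}

#' Random-prior significance test of a learned model
#'
#' Generates `n_random` random prior networks with the same node and edge
#' counts as the true prior (every node incident to at least one edge,
#' stimulated nodes source-only, confidences permuted from the original
#' scores), refits the model under each, and compares the best data loss
#' under the true prior against the null distribution.
#'
#' @param prior the true [prior_network()].
#' @param dataset the `perturbation_dataset`.
#' @param obj_cfg,ga_cfg,sim_cfg configuration passed to [fit()].
#' @param n_random number of random priors (default 500).
#' @param seed random seed.
#' @return list with `z_score` (`(mean_random - loss_true) / sd_random`),
#'   `empirical_p` (fraction of random losses <= the true loss),
#'   `loss_true` and the vector `random_losses`.
#' @export
random_prior_null <- function(prior, dataset, obj_cfg = objective_config(),
                              ga_cfg = ga_config(),
                              sim_cfg = simulation_config(),
                              n_random = 500L, seed = 1L) {
  if (!any(prior$roles == "stimulated"))
    stop("prior must have at least one stimulated node")
  true_fit <- fit(dataset, prior, obj_cfg, ga_cfg, sim_cfg)
  loss_true <- true_fit$objective$loss
  losses <- numeric(n_random)
  for (r in seq_len(n_random)) {
    rnet <- withr::with_seed(seed + 104729L * r, .random_null_network(prior))
    ga <- ga_cfg
    ga$seed <- seed + 104729L * r + 1L
    losses[r] <- fit(dataset, rnet, obj_cfg, ga, sim_cfg)$objective$loss
  }
  list(z_score = (mean(losses) - loss_true) / sd(losses),
       empirical_p = mean(losses <= loss_true),
       loss_true = loss_true, random_losses = losses)
}

#' Attach cell-fate nodes to a learned model
#'
#' Fate nodes (absent from the model) are wired from upstream signaling
#' nodes with OR gates: each incoming fate edge forms its own clause.
#'
#' @param model a [logic_model()].
#' @param fate_edges data frame `source`, `target` (fate node), `sign`.
#' @return an extended [logic_model()] whose fate nodes are
#'   `undesignated`.
#' @keywords internal
.attach_fates <- function(model, fate_edges) {
  fates <- unique(fate_edges$target)
  if (any(fates %in% model$nodes))
    stop("fate nodes must be absent from the model")
  if (!all(fate_edges$source %in% model$nodes))
    stop("fate edge sources must be model nodes")
  nodes <- c(model$nodes, fates)
  m <- length(nodes)
  B <- R <- C <- matrix(0L, m, m, dimnames = list(nodes, nodes))
  B[model$nodes, model$nodes] <- model$B
  R[,] <- 1L
  R[model$nodes, model$nodes] <- model$R
  C[,] <- 1L
  C[model$nodes, model$nodes] <- model$C
  sgn <- .normalize_sign(fate_edges$sign)
  for (k in seq_len(nrow(fate_edges))) {
    B[fate_edges$source[k], fate_edges$target[k]] <- 1L
    R[fate_edges$source[k], fate_edges$target[k]] <- if (sgn[k] == 1L) 1L else 0L
  }
  for (f in fates) {
    par <- which(B[, f] == 1L)
    C[par, f] <- seq_along(par) # OR of inputs
  }
  logic_model(nodes, B, R, C, hill = model$hill, roles = model$roles)
}

#' Boolean cell-fate prediction from binarized phosphoproteomic states
#'
#' For each experimental time point: measured nodes start from the
#' binarized data, every other node from an independent Bernoulli(0.5)
#' draw; the extended network (model plus OR-wired fate nodes) is run as a
#' synchronous Boolean network to its attractor, and a fate is counted
#' true if it is true at the fixed point — or, for cyclic attractors under
#' the default `"majority"` rule, true in at least half of the cycle's
#' states (`"fixed_only"` counts cyclic attractors as false). Fractions
#' are taken over `n_runs` repetitions.
#'
#' @param model a [logic_model()] (without fate nodes).
#' @param fate_edges data frame `source`, `target`, `sign` wiring fate
#'   nodes from signaling nodes; every fate node needs at least one edge.
#' @param phospho binary matrix, rows = time points, named columns =
#'   measured nodes present in the model.
#' @param n_runs Boolean simulations per time point (default 10000).
#' @param seed random seed.
#' @param cycle_rule `"majority"` or `"fixed_only"`.
#' @param max_steps attractor-search step cap.
#' @return matrix of fate-true fractions, rows = time points, columns =
#'   fate nodes.
#' @export
predict_cell_fates <- function(model, fate_edges, phospho, n_runs = 10000L,
                               seed = 1L,
                               cycle_rule = c("majority", "fixed_only"),
                               max_steps = 10000L) {
  cycle_rule <- match.arg(cycle_rule)
  fate_edges <- as.data.frame(fate_edges, stringsAsFactors = FALSE)
  fates <- unique(fate_edges$target)
  ext <- .attach_fates(model, fate_edges)
  measured <- colnames(phospho)
  if (is.null(measured) || !all(measured %in% model$nodes))
    stop("phospho columns must name model nodes")
  if (!all(phospho %in% c(0, 1)))
    stop("phospho must be binarized (see binarize())")
  free <- setdiff(ext$nodes, measured)
  meas_pos <- match(measured, ext$nodes)
  free_pos <- match(free, ext$nodes)
  fate_pos <- match(fates, ext$nodes)
  clamp <- rep(NA_real_, length(ext$nodes))
  out <- matrix(0, nrow(phospho), length(fates),
                dimnames = list(rownames(phospho), fates))
  withr::with_seed(seed, {
    for (t in seq_len(nrow(phospho))) {
      counts <- numeric(length(fates))
      for (run in seq_len(n_runs)) {
        init <- integer(length(ext$nodes))
        init[meas_pos] <- as.integer(phospho[t, ])
        init[free_pos] <- rbinom(length(free_pos), 1L, 0.5)
        att <- .bool_attractor_cpp(ext$B, ext$R, ext$C, init, clamp,
                                   as.integer(max_steps))
        states <- att$states
        if (att$fixed_point) {
          counts <- counts + states[1, fate_pos]
        } else if (cycle_rule == "majority") {
          counts <- counts + (colMeans(states[, fate_pos, drop = FALSE]) >= 0.5)
        }
      }
      out[t, ] <- counts / n_runs
    }
  })
  out
}

#' Correlate predicted and observed cell-fate trajectories
#'
#' Optionally drops predicted time points (e.g. to account for the delay
#' between signaling changes and observable fate changes) before computing
#' the per-fate Pearson correlation.
#'
#' @param predicted fate-fraction matrix from [predict_cell_fates()].
#' @param observed matrix of observed fate fractions with matching fate
#'   columns.
#' @param drop_points indices of predicted rows to exclude.
#' @return named vector of Pearson correlations, one per fate.
#' @export
fate_correlation <- function(predicted, observed, drop_points = integer()) {
  if (length(drop_points))
    predicted <- predicted[-drop_points, , drop = FALSE]
  observed <- as.matrix(observed)
  if (nrow(predicted) != nrow(observed))
    stop("series lengths differ after alignment: ", nrow(predicted),
         " vs ", nrow(observed))
  fates <- colnames(predicted)
  setNames(vapply(fates, function(f) cor(predicted[, f], observed[, f]),
                  numeric(1)), fates)
}
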