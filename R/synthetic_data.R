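# Generators for benchmarking: ground-truth logic networks, Boolean
# trajectories, subsampled time series, steady-state perturbation panels,
# and priors mixed with noise edges.

#' Specification of a random ground-truth network
#'
#' @param n_nodes node count.
#' @param n_edges edge count (>= n_nodes - 1 so the network is connected).
#' @param n_feedback_loops number of back edges closing a cycle.
#' @param n_and_gates number of nodes whose first two regulators are
#'   joined into one AND clause.
#' @param inhibition_fraction expected fraction of inhibitory edges.
#' @param n_stimulated number of input (stimulated) nodes.
#' @param seed random seed.
#' @return list of class `truth_network_spec`.
#' @export
truth_network_spec <- function(n_nodes, n_edges, n_feedback_loops = 1L,
                               n_and_gates = 0L, inhibition_fraction = 0.2,
                               n_stimulated = 2L, seed = 1L) {
  if (n_edges < n_nodes - 1) stop("need n_edges >= n_nodes - 1 for connectivity")
  if (n_edges < 1) stop("need at least one edge")
  if (n_stimulated < 1 || n_stimulated >= n_nodes)
    stop("n_stimulated must be in 1..(n_nodes - 1)")
  if (n_feedback_loops + n_nodes - n_stimulated > n_edges)
    stop("too many feedback loops for the edge budget")
  structure(list(n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
                 n_feedback_loops = as.integer(n_feedback_loops),
                 n_and_gates = as.integer(n_and_gates),
                 inhibition_fraction = inhibition_fraction,
                 n_stimulated = as.integer(n_stimulated),
                 seed = as.integer(seed)),
            class = "truth_network_spec")
}

.node_names <- function(n) {
  # letters without "i" (reserved to avoid confusion with inhibition flags)
  pool <- setdiff(letters, "i")
  if (n <= length(pool)) return(pool[seq_len(n)])
  paste0("n", seq_len(n))
}

#' Generate a random ground-truth signaling network
#'
#' Builds a weakly connected signed directed graph: stimulated nodes come
#' first in a random topological order, every other node receives one
#' spanning edge from an earlier node, extra forward edges are added up to
#' the budget, and the requested number of back edges (each targeting an
#' ancestor of its source, so each closes a feedback loop) complete the
#' graph. Edge signs are inhibitory with the requested probability; AND
#' gates merge the first two regulators of randomly chosen multi-input
#' nodes. Deterministic per spec and seed.
#'
#' @param spec a [truth_network_spec()].
#' @return a [logic_model()] whose roles mark the inputs `stimulated` and
#'   all remaining nodes `measured`.
#' @export
make_truth_network <- function(spec) {
  stopifnot(inherits(spec, "truth_network_spec"))
  withr::with_seed(spec$seed, {
    for (attempt in 1:100) {
      net <- .try_truth_network(spec)
      if (!is.null(net)) return(net)
    }
    stop("could not generate a connected network for this spec")
  })
}

# One generation attempt; NULL when the sampled topology is disconnected.
.try_truth_network <- function(spec) {
    n <- spec$n_nodes
    nodes <- .node_names(n)
    stim <- seq_len(spec$n_stimulated)
    n_back <- spec$n_feedback_loops
    n_forward <- spec$n_edges - n_back
    # spanning forward edges: node k > n_stimulated gets a parent among 1..k-1
    parent <- rep(NA_integer_, n)
    edges <- data.frame(from = integer(), to = integer())
    nonstim <- setdiff(seq_len(n), stim)
    for (q in seq_along(nonstim)) {
      k <- nonstim[q]
      # the first inputs each seed one cascade so no stimulated node is
      # left without outgoing signal; later nodes extend the intracellular
      # cascades (keeping feedback-loop targets reachable downstream)
      p <- if (q <= length(stim)) stim[q]
           else {
             up <- nonstim[seq_len(q - 1L)]
             if (length(up) == 1L) up else sample(up, 1)
           }
      parent[k] <- p
      edges <- rbind(edges, data.frame(from = p, to = k))
    }
    # extra forward edges among non-existing pairs (earlier -> later, not
    # into stimulated nodes)
    all_fwd <- expand.grid(from = seq_len(n), to = seq_len(n))
    all_fwd <- all_fwd[all_fwd$from < all_fwd$to & !(all_fwd$to %in% stim), ]
    have <- paste(edges$from, edges$to)
    pool <- all_fwd[!(paste(all_fwd$from, all_fwd$to) %in% have), ]
    need <- n_forward - nrow(edges)
    if (need < 0) stop("spec infeasible: fewer forward edges than spanning tree")
    if (need > nrow(pool)) stop("spec infeasible: not enough forward pairs")
    if (need > 0)
      edges <- rbind(edges, pool[sample.int(nrow(pool), need), ])
    # back edges: source -> one of its spanning-tree ancestors (not stimulated)
    ancestors <- function(k) {
      out <- integer()
      while (!is.na(parent[k])) { out <- c(out, parent[k]); k <- parent[k] }
      out
    }
    tries <- 0L
    added <- 0L
    have <- paste(edges$from, edges$to)
    while (added < n_back) {
      tries <- tries + 1L
      if (tries > 1000L) return(NULL)
      src <- sample(setdiff(seq_len(n), stim), 1)
      anc <- setdiff(ancestors(src), stim)
      if (!length(anc)) next
      tgt <- if (length(anc) == 1) anc else sample(anc, 1)
      if (paste(src, tgt) %in% have) next
      edges <- rbind(edges, data.frame(from = src, to = tgt))
      have <- c(have, paste(src, tgt))
      added <- added + 1L
    }
    m <- n
    B <- matrix(0L, m, m, dimnames = list(nodes, nodes))
    B[cbind(edges$from, edges$to)] <- 1L
    R <- matrix(1L, m, m, dimnames = list(nodes, nodes))
    inh <- runif(nrow(edges)) < spec$inhibition_fraction
    R[cbind(edges$from, edges$to)] <- ifelse(inh, 0L, 1L)
    C <- matrix(1L, m, m, dimnames = list(nodes, nodes))
    # default gates: every regulator its own OR'd clause
    for (j in seq_len(m)) {
      par <- which(B[, j] == 1L)
      if (length(par)) C[par, j] <- seq_along(par)
    }
    if (spec$n_and_gates > 0) {
      multi <- which(colSums(B) >= 2L)
      if (length(multi) < spec$n_and_gates) return(NULL)
      pick <- if (length(multi) == 1) multi else
        sample(multi, spec$n_and_gates)
      for (j in pick) {
        par <- which(B[, j] == 1L)
        labs <- C[par, j]
        labs[2] <- labs[1]
        C[par, j] <- match(labs, unique(labs))
      }
    }
    roles <- setNames(rep("measured", n), nodes)
    roles[stim] <- "stimulated"
    g <- igraph::graph_from_edgelist(as.matrix(edges), directed = TRUE)
    if (igraph::vcount(g) < n || !igraph::is_connected(g, mode = "weak"))
      return(NULL)
    logic_model(nodes, B, R, C, roles = roles)
}

#' The bundled 9-node benchmark network
#'
#' A fixed 9-node, 10-edge signaling network with two stimulated inputs
#' (`a`, `b`), a negative feedback loop `c -> h -> j -| c`, and one AND
#' gate combining `c` and `d` into `f`. All non-input nodes are measured.
#' The topology beyond these structural facts is a synthetic stand-in
#' chosen by this package for benchmarking.
#'
#' @return a [logic_model()].
#' @export
toy9_network <- function() {
  nodes <- c("a", "b", "c", "d", "e", "f", "g", "h", "j")
  edges <- data.frame(
    source = c("a", "b", "c", "d", "c", "h", "j", "d", "g", "h"),
    target = c("c", "d", "f", "f", "h", "j", "c", "g", "e", "e"),
    sign   = c(1L,  1L,  1L,  1L,  1L,  1L,  -1L, 1L,  1L,  1L),
    stringsAsFactors = FALSE)
  m <- length(nodes)
  B <- matrix(0L, m, m, dimnames = list(nodes, nodes))
  R <- matrix(1L, m, m, dimnames = list(nodes, nodes))
  C <- matrix(1L, m, m, dimnames = list(nodes, nodes))
  B[cbind(edges$source, edges$target)] <- 1L
  R[cbind(edges$source, edges$target)] <- ifelse(edges$sign == 1L, 1L, 0L)
  # gates: (c AND d) -> f is one clause; every other multi-input node ORs
  C["c", "f"] <- 1L; C["d", "f"] <- 1L
  C["a", "c"] <- 1L; C["j", "c"] <- 2L
  C["g", "e"] <- 1L; C["h", "e"] <- 2L
  roles <- setNames(rep("measured", m), nodes)
  roles[c("a", "b")] <- "stimulated"
  logic_model(nodes, B, R, C, roles = roles)
}

#' Boolean trajectories from random initial states
#'
#' Synchronous Boolean simulation (identity transfer) from uniformly
#' random binary initial states; input nodes (no regulators) simply hold
#' their initial value.
#'
#' @param model a [logic_model()].
#' @param n_series number of trajectories (default 5).
#' @param length states per trajectory including the initial one
#'   (default 10).
#' @param seed random seed.
#' @return list of `length`-by-m binary state matrices.
#' @export
boolean_trajectories <- function(model, n_series = 5L, length = 10L,
                                 seed = 1L) {
  cfg <- simulation_config(mode = "boolean")
  withr::with_seed(seed, {
    lapply(seq_len(n_series), function(s) {
      init <- rbinom(model$m, 1L, 0.5)
      names(init) <- model$nodes
      simulate_timeseries(model, init, n_points = length, config = cfg)
    })
  })
}

#' Randomly subsample time points of a trajectory
#'
#' @param series state matrix (rows = time points).
#' @param k number of points to keep (1..nrow).
#' @param keep_first always keep the initial state (default TRUE).
#' @param seed random seed.
#' @return list with `values` (the subsampled rows) and `idx` (their
#'   original 1-based time indices, strictly increasing).
#' @export
subsample_timepoints <- function(series, k, keep_first = TRUE, seed = 1L) {
  n <- nrow(series)
  if (k < 1 || k > n) stop("k must lie in 1..nrow(series)")
  idx <- withr::with_seed(seed, {
    if (keep_first) sort(c(1L, sample(2:n, k - 1L)))
    else sort(sample.int(n, k))
  })
  list(values = series[idx, , drop = FALSE], idx = idx)
}

#' Steady-state perturbation panel from a known model
#'
#' Simulates each condition to steady state in fuzzy mode, records the
#' measured nodes, and adds Gaussian noise truncated to \[0, 1\].
#' Non-convergent conditions are flagged and their last state used.
#'
#' @param model a [logic_model()] with roles set.
#' @param conditions list of conditions (`stimuli` named numeric clamps
#'   covering all stimulated nodes, optional `inhibitors`).
#' @param noise_sd standard deviation of the additive noise (default 0).
#' @param seed random seed.
#' @param sim_cfg a [simulation_config()].
#' @return a [steady_state_dataset()]; the per-condition convergence flags
#'   are attached as attribute `converged`.
#' @export
make_steady_state_panel <- function(model, conditions, noise_sd = 0,
                                    seed = 1L,
                                    sim_cfg = simulation_config()) {
  measured <- model$nodes[model$roles == "measured"]
  if (!length(measured)) stop("model has no measured nodes")
  Y <- matrix(NA_real_, length(conditions), length(measured),
              dimnames = list(NULL, measured))
  conv <- logical(length(conditions))
  for (c in seq_along(conditions)) {
    cond <- conditions[[c]]
    st <- simulate_steady_state(
      model, condition_clamps(model, cond$stimuli, cond$inhibitors), sim_cfg)
    conv[c] <- st$converged
    Y[c, ] <- st$state[measured]
  }
  if (noise_sd > 0)
    Y <- withr::with_seed(seed,
           matrix(pmin(1, pmax(0, Y + rnorm(length(Y), 0, noise_sd))),
                  nrow(Y), ncol(Y), dimnames = dimnames(Y)))
  ds <- steady_state_dataset(conditions, Y)
  attr(ds, "converged") <- conv
  ds
}

#' Prior network sampled from a ground truth with noise edges
#'
#' Samples `round(prior_ratio * n_true)` true edges uniformly without
#' replacement, adds `round(noise_ratio * n_prior)` false edges drawn
#' uniformly from the non-true ordered pairs (no self-loops, none into
#' stimulated nodes), and assigns every edge a Uniform(0, 1) confidence.
#' True edges keep their true sign; noise edges get a random sign.
#'
#' @param truth a [logic_model()] ground truth.
#' @param prior_ratio fraction of true edges given as prior (0..1).
#' @param noise_ratio false edges as a fraction of the sampled prior
#'   edges (>= 0).
#' @param seed random seed.
#' @param d_max indegree cap stored in the prior (default 2).
#' @return a [prior_network()].
#' @export
perturb_prior <- function(truth, prior_ratio, noise_ratio = 0, seed = 1L,
                          d_max = 2L) {
  if (prior_ratio < 0 || prior_ratio > 1) stop("prior_ratio must lie in [0, 1]")
  if (noise_ratio < 0) stop("noise_ratio must be non-negative")
  te <- model_edges(truth)
  withr::with_seed(seed, {
    n_prior <- round(prior_ratio * nrow(te))
    keep <- if (n_prior > 0) sample.int(nrow(te), n_prior) else integer()
    pe <- te[keep, c("source", "target", "sign"), drop = FALSE]
    n_noise <- round(noise_ratio * n_prior)
    if (n_noise > 0) {
      stim <- truth$nodes[truth$roles == "stimulated"]
      pool <- expand.grid(source = truth$nodes, target = truth$nodes,
                          stringsAsFactors = FALSE)
      pool <- pool[pool$source != pool$target &
                   !(pool$target %in% stim), , drop = FALSE]
      pool <- pool[!(edge_key(pool$source, pool$target) %in%
                     edge_key(te$source, te$target)), , drop = FALSE]
      if (n_noise > nrow(pool))
        stop("noise pool exhausted: asked for ", n_noise,
             " false edges but only ", nrow(pool), " non-true pairs exist")
      fe <- pool[sample.int(nrow(pool), n_noise), , drop = FALSE]
      fe$sign <- sample(c(1L, -1L), n_noise, replace = TRUE)
      pe <- rbind(pe, fe)
    }
    pe$confidence <- runif(nrow(pe))
    prior_network(pe, roles = truth$roles, d_max = d_max)
  })
}
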