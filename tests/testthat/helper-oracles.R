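# Independent oracles and fixture builders used across the suite.

# --- exhaustive warping-path oracle -----------------------------------------
# Enumerates every admissible warp path (pinned endpoints, monotone,
# unit steps in a, b or both) and minimizes the accumulated squared
# difference; among minimal-cost paths the shortest is taken. Only usable
# for short sequences.
enumerate_warp_paths <- function(n, m) {
  paths <- list()
  rec <- function(i, j, a, b) {
    if (i == n && j == m) {
      paths[[length(paths) + 1L]] <<- cbind(a = a, b = b)
      return(invisible())
    }
    if (i < n) rec(i + 1L, j, c(a, i + 1L), c(b, j))
    if (j < m) rec(i, j + 1L, c(a, i), c(b, j + 1L))
    if (i < n && j < m) rec(i + 1L, j + 1L, c(a, i + 1L), c(b, j + 1L))
  }
  rec(1L, 1L, 1L, 1L)
  paths
}

dtw_oracle <- function(y, z) {
  paths <- enumerate_warp_paths(length(y), length(z))
  tot <- vapply(paths, function(p) sum((y[p[, "a"]] - z[p[, "b"]])^2),
                numeric(1))
  S <- vapply(paths, nrow, numeric(1))
  best <- min(tot)
  sel <- tot <= best + 1e-12
  best / min(S[sel])
}

# --- Boolean DNF oracle ------------------------------------------------------
# Evaluates an OR of AND clauses over possibly negated binary inputs with
# logical operators (no min/max), independent of the package's gate code.
dnf_oracle <- function(inputs, signs, labels) {
  lits <- ifelse(signs == 1L, inputs == 1L, inputs == 0L)
  clauses <- split(lits, labels)
  as.integer(any(vapply(clauses, all, logical(1))))
}

# --- reference synchronous simulation in R ----------------------------------
# Slow but direct re-evaluation of the update relation with node_update();
# used to cross-check the compiled simulator.
r_simulate <- function(model, init, n_points, mode = "boolean",
                       clamps = numeric()) {
  state <- init[model$nodes]
  out <- matrix(NA_real_, n_points, model$m, dimnames = list(NULL, model$nodes))
  if (length(clamps)) state[names(clamps)] <- clamps
  out[1, ] <- state
  for (t in seq_len(n_points - 1L)) {
    nxt <- state
    for (j in seq_len(model$m)) {
      if (model$nodes[j] %in% names(clamps)) next
      if (sum(model$B[, j]) == 0) next
      nxt[j] <- node_update(state, j, model, mode = mode)
    }
    state <- nxt
    out[t + 1L, ] <- state
  }
  out
}

# --- small fixtures ----------------------------------------------------------
# Linear chain s -> a -> b (all activations), s stimulated, a and b measured.
chain3_model <- function(h = 0.5) {
  nodes <- c("s", "a", "b")
  B <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  B["s", "a"] <- 1L
  B["a", "b"] <- 1L
  roles <- c(s = "stimulated", a = "measured", b = "measured")
  logic_model(nodes, B, hill = hill_params(2, h), roles = roles)
}

# Two-node negative feedback oscillator: u -> v, v -| u (no inputs held).
oscillator2_model <- function() {
  nodes <- c("u", "v")
  B <- matrix(0L, 2, 2, dimnames = list(nodes, nodes))
  B["u", "v"] <- 1L
  B["v", "u"] <- 1L
  R <- matrix(1L, 2, 2, dimnames = list(nodes, nodes))
  R["v", "u"] <- 0L
  logic_model(nodes, B, R, roles = c(u = "measured", v = "measured"))
}

# Time-series dataset for the bundled 9-node benchmark: 5 Boolean
# trajectories of 10 states, randomly subsampled to 6 or 7 points.
toy9_dataset <- function(seed = 11L) {
  truth <- toy9_network()
  traj <- boolean_trajectories(truth, n_series = 5L, length = 10L, seed = seed)
  series <- lapply(seq_along(traj), function(s) {
    k <- withr::with_seed(seed + 50L + s, sample(6:7, 1))
    ss <- subsample_timepoints(traj[[s]], k, seed = seed + s)
    list(values = ss$values, time = ss$idx)
  })
  timeseries_dataset(series)
}

# Small chain problem for GA-vs-oracle batteries: an n-node activation
# chain driven by one stimulated input, a noise-free steady-state panel
# over a few stimulus levels, and a restricted candidate universe (true
# edges plus decoys).
small_problem <- function(seed, n_nodes = 3L, n_decoys = 2L, h = 0.5) {
  withr::with_seed(seed, {
    nodes <- letters[seq_len(n_nodes)]
    B <- matrix(0L, n_nodes, n_nodes, dimnames = list(nodes, nodes))
    for (k in 2:n_nodes) B[nodes[k - 1L], nodes[k]] <- 1L
    R <- matrix(1L, n_nodes, n_nodes, dimnames = list(nodes, nodes))
    if (n_nodes > 2 && runif(1) < 0.5) R[nodes[n_nodes - 1L], nodes[n_nodes]] <- 0L
    roles <- setNames(c("stimulated", rep("measured", n_nodes - 1L)), nodes)
    truth <- logic_model(nodes, B, R, hill = hill_params(2, h), roles = roles)
    conditions <- lapply(c(0, 0.4, 0.7, 1), function(v)
      list(stimuli = setNames(v, nodes[1]), inhibitors = character()))
    ds <- make_steady_state_panel(truth, conditions)
    prior <- prior_network(
      cbind(model_edges(truth)[, c("source", "target", "sign")],
            confidence = 0.8),
      roles = roles, d_max = 2L)
    # candidate universe: true edges + random decoys
    pool <- expand.grid(source = nodes, target = nodes,
                        stringsAsFactors = FALSE)
    pool <- pool[pool$source != pool$target & pool$target != nodes[1], ]
    te <- model_edges(truth)
    pool <- pool[!(paste(pool$source, pool$target) %in%
                   paste(te$source, te$target)), ]
    decoys <- pool[sample.int(nrow(pool), min(n_decoys, nrow(pool))), ]
    universe <- rbind(te[, c("source", "target")], decoys)
    space <- search_space(prior, hill_grid = c(0.3, 0.5, 0.7),
                          candidate_edges = universe)
    list(truth = truth, dataset = ds, prior = prior, space = space)
  })
}
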