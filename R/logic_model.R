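# Executable fuzzy logic networks: B/C/R gate encoding, normalized Hill
# transfer, synchronous simulation (fuzzy or Boolean mode).

#' Hill transfer parameters
#'
#' @param p positive integer Hill coefficient (steepness); default 2.
#' @param h sensitivity in (0, 1): the midpoint of the transfer,
#'   `hill_transfer(h, ...) == 0.5`. The default grid used during inference
#'   is 0.2, 0.3, ..., 0.8.
#' @return list of class `hill_params`.
#' @export
hill_params <- function(p = 2L, h = 0.5) {
  if (length(p) != 1 || p < 1 || p != round(p)) stop("p must be a positive integer")
  if (length(h) != 1 || h <= 0 || h >= 1) stop("h must lie in (0, 1)")
  structure(list(p = as.integer(p), h = as.numeric(h)), class = "hill_params")
}

#' Default sensitivity grid for inference
#' @return numeric vector 0.2, 0.3, ..., 0.8.
#' @export
default_hill_grid <- function() seq(0.2, 0.8, by = 0.1)

#' Normalized Hill transfer function
#'
#' Maps an input activity in \[0, 1\] to an activation effect
#' `x^p / (x^p + h^p)`, a sigmoid with midpoint at `x = h` (where it equals
#' 0.5) and range \[0, 1). The inhibition effect of an input is
#' `1 - hill_transfer(x, hill)`.
#'
#' @param x numeric values in \[0, 1\].
#' @param hill a [hill_params()].
#' @return transformed values in \[0, 1).
#' @export
hill_transfer <- function(x, hill = hill_params()) {
  if (any(x < 0 | x > 1)) stop("input activity must lie in [0, 1]")
  xp <- x^hill$p
  xp / (xp + hill$h^hill$p)
}

#' Construct a fuzzy logic network model
#'
#' A model over `m` nodes is encoded by three m-by-m matrices: adjacency
#' `B` (`B[i, j] = 1` iff node i regulates node j), sign `R`
#' (`R[i, j] = 1` activation, 0 inhibition) and clause membership `C`
#' (regulators of j sharing a `C` value are ANDed into one clause; distinct
#' clauses are ORed), i.e. each node's update rule is a disjunctive normal
#' form in which every regulator appears in exactly one AND clause.
#'
#' @param nodes character vector of node names.
#' @param B m-by-m binary adjacency matrix (rows = regulators,
#'   columns = targets).
#' @param R m-by-m binary sign matrix; defaults to all activations.
#' @param C m-by-m integer clause matrix; entries are meaningful only where
#'   `B == 1` and must lie in 1..indegree; defaults to a single AND clause
#'   per target (all regulators ANDed).
#' @param hill a [hill_params()].
#' @param roles optional named role vector (see [prior_network()]);
#'   stimulated nodes must have no regulators.
#' @return object of class `logic_model`.
#' @export
logic_model <- function(nodes, B, R = NULL, C = NULL, hill = hill_params(),
                        roles = NULL) {
  m <- length(nodes)
  if (anyDuplicated(nodes)) stop("node names must be unique")
  B <- matrix(as.integer(B), m, m, dimnames = list(nodes, nodes))
  if (!all(B %in% c(0L, 1L))) stop("B must be binary")
  if (any(diag(B) != 0L)) stop("self-loops are not supported")
  if (is.null(R)) R <- matrix(1L, m, m)
  R <- matrix(as.integer(R), m, m, dimnames = list(nodes, nodes))
  if (!all(R %in% c(0L, 1L))) stop("R must be binary")
  if (is.null(C)) C <- matrix(1L, m, m)
  C <- matrix(as.integer(C), m, m, dimnames = list(nodes, nodes))
  indeg <- colSums(B)
  for (j in seq_len(m)) {
    cj <- C[B[, j] == 1L, j]
    if (length(cj) && (any(cj < 1L) || any(cj > indeg[j])))
      stop("clause labels of node ", nodes[j], " must lie in 1..indegree")
  }
  if (!is.null(roles)) {
    check_roles(roles)
    full <- setNames(rep("undesignated", m), nodes)
    full[intersect(names(roles), nodes)] <- roles[intersect(names(roles), nodes)]
    roles <- full
    stim <- nodes[roles == "stimulated"]
    if (any(indeg[stim] > 0))
      stop("stimulated nodes must have no incoming edges")
  } else {
    roles <- setNames(rep("undesignated", m), nodes)
  }
  stopifnot(inherits(hill, "hill_params"))
  structure(list(nodes = nodes, m = m, B = B, R = R, C = C, hill = hill,
                 roles = roles),
            class = "logic_model")
}

#' @export
print.logic_model <- function(x, ...) {
  cat("Fuzzy logic network:", x$m, "nodes,", sum(x$B), "edges; p =",
      x$hill$p, ", h =", x$hill$h, "\n")
  invisible(x)
}

#' Edge list of a logic model
#'
#' @param model a [logic_model()].
#' @return data frame with columns `source`, `target`, `sign` (1/-1) and
#'   `clause` (AND-clause label within the target's gate).
#' @export
model_edges <- function(model) {
  idx <- which(model$B == 1L, arr.ind = TRUE)
  data.frame(source = model$nodes[idx[, 1]],
             target = model$nodes[idx[, 2]],
             sign = ifelse(model$R[idx] == 1L, 1L, -1L),
             clause = model$C[idx],
             stringsAsFactors = FALSE)
}

#' Update one node from the previous global state
#'
#' Reference implementation of the gate semantics: for each AND clause of
#' node `j` take the min over its members of the activation effect
#' (`hill_transfer(x_i)`, or `x_i` in Boolean mode) or inhibition effect
#' (one minus that), then take the max over clauses.
#'
#' @param state numeric state vector (length m, values in \[0, 1\]).
#' @param j node index or name; must have at least one regulator.
#' @param model a [logic_model()].
#' @param mode `"fuzzy"` (Hill transfer) or `"boolean"` (identity transfer).
#' @return the updated value of node `j`.
#' @export
node_update <- function(state, j, model, mode = c("fuzzy", "boolean")) {
  mode <- match.arg(mode)
  if (is.character(j)) j <- match(j, model$nodes)
  parents <- which(model$B[, j] == 1L)
  if (!length(parents))
    stop("node has no regulators; input nodes are held fixed by the caller")
  eff <- if (mode == "boolean") state[parents]
         else hill_transfer(state[parents], model$hill)
  eff <- ifelse(model$R[parents, j] == 1L, eff, 1 - eff)
  clause <- model$C[parents, j]
  max(tapply(eff, clause, min))
}

#' Enumerate distinct AND/OR gate structures for k regulators
#'
#' Because every regulator joins exactly one AND clause, the distinct gate
#' structures are the set partitions of the k regulators (Bell(k) of them).
#' Partitions are returned as canonical clause-label vectors (restricted
#' growth strings: first element labelled 1, each later element at most one
#' more than the running maximum).
#'
#' @param k indegree (>= 0).
#' @return list of integer label vectors of length `k`; empty list for k = 0.
#' @export
enumerate_gate_encodings <- function(k) {
  if (k < 0) stop("k must be non-negative")
  if (k == 0) return(list())
  out <- list(1L)
  if (k == 1) return(out)
  for (pos in 2:k) {
    nxt <- list()
    for (lab in out) {
      top <- max(lab)
      for (v in seq_len(top + 1L)) nxt[[length(nxt) + 1L]] <- c(lab, v)
    }
    out <- nxt
  }
  out
}

#' Simulation configuration
#'
#' @param epsilon convergence tolerance on the max absolute state change
#'   between successive synchronous updates (default 1e-6).
#' @param max_iter_factor steady-state iteration cap as a multiple of the
#'   node count (default 5: at most `5 m` updates).
#' @param ts_length_factor simulated time-series length as a multiple of
#'   the experimental series length (default 3).
#' @param mode `"fuzzy"` or `"boolean"`.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(epsilon = 1e-6, max_iter_factor = 5L,
                              ts_length_factor = 3L,
                              mode = c("fuzzy", "boolean")) {
  mode <- match.arg(mode)
  if (epsilon <= 0) stop("epsilon must be positive")
  structure(list(epsilon = epsilon,
                 max_iter_factor = as.integer(max_iter_factor),
                 ts_length_factor = as.integer(ts_length_factor),
                 mode = mode),
            class = "simulation_config")
}

.clamp_vector <- function(model, inputs) {
  clamp <- rep(NA_real_, model$m)
  names(clamp) <- model$nodes
  if (length(inputs)) {
    unknown <- setdiff(names(inputs), model$nodes)
    if (length(unknown)) stop("unknown clamped node(s): ",
                              paste(unknown, collapse = ", "))
    clamp[names(inputs)] <- as.numeric(inputs)
  }
  clamp
}

#' Clamp map for one experimental condition
#'
#' Builds the clamp vector for a condition: stimulated nodes held at their
#' stimulus value and chemically inhibited nodes held at 0 for the whole
#' simulation.
#'
#' @param model a [logic_model()].
#' @param stimuli named numeric vector of stimulus values.
#' @param inhibitors character vector of inhibited node names.
#' @return named numeric clamp map.
#' @export
condition_clamps <- function(model, stimuli = numeric(), inhibitors = character()) {
  clamps <- as.numeric(stimuli)
  names(clamps) <- names(stimuli)
  if (length(inhibitors)) clamps[inhibitors] <- 0
  clamps
}

#' Simulate to steady state
#'
#' Synchronous updates of all non-clamped nodes from an all-zero start
#' (clamped nodes at their clamp value) until the maximum absolute state
#' change drops below `epsilon` or `max_iter_factor * m` iterations are
#' reached. Non-convergence (e.g. oscillation around a feedback loop) is
#' reported through the `converged` flag, never as an error; the last state
#' is returned either way.
#'
#' @param model a [logic_model()].
#' @param inputs named numeric clamp map; must cover all stimulated nodes.
#' @param config a [simulation_config()].
#' @return list with `state` (named vector), `converged`, `iterations`.
#' @export
simulate_steady_state <- function(model, inputs = numeric(),
                                  config = simulation_config()) {
  clamp <- .clamp_vector(model, inputs)
  stim <- model$nodes[model$roles == "stimulated"]
  if (any(is.na(clamp[stim])))
    stop("all stimulated nodes must be clamped: ",
         paste(stim[is.na(clamp[stim])], collapse = ", "))
  res <- .sim_steady_cpp(model$B, model$R, model$C, model$hill$p,
                         model$hill$h, unname(clamp), config$epsilon,
                         config$max_iter_factor * model$m,
                         config$mode == "boolean")
  names(res$state) <- model$nodes
  res
}

#' Simulate a synchronous time series
#'
#' @param model a [logic_model()].
#' @param init named or plain numeric initial state (length m, in \[0, 1\]).
#' @param inputs named numeric clamp map held fixed for the whole run.
#' @param n_points number of returned time points including the initial
#'   state (callers fitting data pass `ts_length_factor * n_y`).
#' @param config a [simulation_config()].
#' @return `n_points` by `m` matrix of states, columns named by node.
#' @export
simulate_timeseries <- function(model, init, inputs = numeric(), n_points,
                                config = simulation_config()) {
  if (n_points < 1) stop("n_points must be >= 1")
  if (!is.null(names(init))) init <- init[model$nodes]
  if (length(init) != model$m || any(is.na(init)) ||
      any(init < 0 | init > 1))
    stop("init must give a value in [0, 1] for every node")
  clamp <- .clamp_vector(model, inputs)
  out <- .sim_sync_cpp(model$B, model$R, model$C, model$hill$p,
                       model$hill$h, as.numeric(init), unname(clamp),
                       as.integer(n_points), config$mode == "boolean")
  colnames(out) <- model$nodes
  out
}
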