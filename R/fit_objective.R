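# Scoring candidate models against perturbation data: MSE for steady-state
# panels, dynamic time warping for time series, plus the quantitative-prior
# and indegree regularizers.

#' Steady-state perturbation dataset
#'
#' @param conditions list of conditions, each a list with elements
#'   `stimuli` (named numeric clamp values) and `inhibitors` (character
#'   vector of chemically inhibited nodes, clamped to 0).
#' @param measurements numeric matrix, one row per condition, one column
#'   per measured node (column names required); values in \[0, 1\].
#' @return object of class `perturbation_dataset` with `kind = "steady_state"`.
#' @export
steady_state_dataset <- function(conditions, measurements) {
  measurements <- as.matrix(measurements)
  if (is.null(colnames(measurements)))
    stop("measurement columns must be named by measured node")
  if (length(conditions) != nrow(measurements))
    stop("one measurement row per condition required")
  if (any(measurements < 0 | measurements > 1))
    stop("measured values must lie in [0, 1]; normalize the data first")
  structure(list(kind = "steady_state", conditions = conditions,
                 measurements = measurements,
                 measured = colnames(measurements)),
            class = "perturbation_dataset")
}

#' Time-series perturbation dataset
#'
#' @param series list of experimental series; each series is a list with
#'   `values` (n_y-by-n_measured matrix, named columns, values in \[0, 1\],
#'   n_y >= 2), optional `time` stamps (kept as metadata) and optional
#'   `clamps` (named numeric clamp map held fixed during simulation of that
#'   series).
#' @return object of class `perturbation_dataset` with `kind = "time_series"`.
#' @export
timeseries_dataset <- function(series) {
  if (!length(series)) stop("at least one series is required")
  measured <- colnames(series[[1]]$values)
  for (s in series) {
    v <- as.matrix(s$values)
    if (is.null(colnames(v)) || !identical(colnames(v), measured))
      stop("all series must share the same named measured-node columns")
    if (nrow(v) < 2) stop("time series need at least 2 time points")
    if (any(v < 0 | v > 1))
      stop("measured values must lie in [0, 1]; normalize the data first")
  }
  structure(list(kind = "time_series", series = series, measured = measured),
            class = "perturbation_dataset")
}

#' @export
print.perturbation_dataset <- function(x, ...) {
  if (x$kind == "steady_state")
    cat("Steady-state perturbation dataset:", length(x$conditions),
        "conditions x", length(x$measured), "measured nodes\n")
  else
    cat("Time-series perturbation dataset:", length(x$series), "series,",
        length(x$measured), "measured nodes,",
        nrow(x$series[[1]]$values), "time points\n")
  invisible(x)
}

#' Mean squared error between experimental and predicted values
#'
#' @param y,z numeric matrices (or vectors) of identical shape:
#'   conditions by measured nodes.
#' @return mean over all cells of the squared difference.
#' @export
mse_loss <- function(y, z) {
  if (!identical(dim(as.matrix(y)), dim(as.matrix(z))))
    stop("y and z must have identical shape")
  mean((as.matrix(y) - as.matrix(z))^2)
}

#' Dynamic time warping alignment of two series
#'
#' Aligns `y` (length `n_y`) with `z` (length `n_z`) under the classical
#' warping-path constraints: pinned endpoints, monotone indices, and
#' continuity (each step advances one index or both by exactly 1). The
#' dynamic program minimizes the accumulated squared difference; among
#' minimal-cost paths the shorter is preferred, then the one advancing
#' both indices. The reported loss is the accumulated cost divided by the
#' path length `S`, so losses are comparable across alignments of
#' different lengths.
#'
#' @param y,z numeric sequences.
#' @return list with `a`, `b` (1-based aligned index vectors into `y` and
#'   `z`), `S` (path length), `total` (accumulated cost) and `loss`
#'   (`total / S`).
#' @export
dtw_align <- function(y, z) {
  if (!length(y) || !length(z)) stop("sequences must be non-empty")
  .dtw_align_cpp(as.numeric(y), as.numeric(z))
}

#' Normalized DTW loss (no path)
#' @inheritParams dtw_align
#' @return the normalized loss, as in [dtw_align()].
#' @export
dtw_loss <- function(y, z) {
  if (!length(y) || !length(z)) stop("sequences must be non-empty")
  .dtw_loss_cpp(as.numeric(y), as.numeric(z))
}

#' DTW loss of a time-series dataset against simulated trajectories
#'
#' Per measured node, the experimental series is aligned against the
#' simulated series (by default the full window of length
#' `window_factor * n_y`); the total loss is the sum over measured nodes
#' and series. With `window` and `stride` set, the simulated series is cut
#' into sliding windows and the minimum per-node loss over window
#' placements is used.
#'
#' @param dataset a time-series [timeseries_dataset()].
#' @param simulated list (one per series) of simulated matrices with
#'   columns covering the measured nodes, or one matrix if the dataset has
#'   one series.
#' @param window optional window length; default `NULL` aligns the full
#'   simulated series.
#' @param stride window stride when `window` is set.
#' @return total DTW loss (sum over measured nodes and series).
#' @export
timeseries_loss <- function(dataset, simulated, window = NULL, stride = 1L) {
  stopifnot(dataset$kind == "time_series")
  if (is.matrix(simulated)) simulated <- list(simulated)
  if (length(simulated) != length(dataset$series))
    stop("one simulated matrix per experimental series required")
  total <- 0
  for (s in seq_along(dataset$series)) {
    y <- dataset$series[[s]]$values
    z <- simulated[[s]]
    missing <- setdiff(colnames(y), colnames(z))
    if (length(missing))
      stop("simulation lacks measured node(s): ", paste(missing, collapse = ", "))
    for (node in colnames(y)) {
      zj <- z[, node]
      if (is.null(window)) {
        total <- total + .dtw_loss_cpp(y[, node], zj)
      } else {
        starts <- seq(1L, max(1L, length(zj) - window + 1L), by = stride)
        total <- total + min(vapply(starts, function(s0)
          .dtw_loss_cpp(y[, node], zj[s0:(s0 + min(window, length(zj) - s0 + 1L) - 1L)]),
          numeric(1)))
      }
    }
  }
  total
}

# Prior confidence matrix over the model's node universe (0 where absent).
.prior_weight_matrix <- function(prior, nodes) {
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  e <- prior$edges
  e <- e[e$source %in% nodes & e$target %in% nodes, , drop = FALSE]
  for (k in seq_len(nrow(e)))
    W[e$source[k], e$target[k]] <- max(W[e$source[k], e$target[k]],
                                       e$confidence[k])
  W
}

#' Quantitative prior-violation penalty
#'
#' Sum over ordered node pairs of `|b_ij - w_ij|`, where `w_ij` is the
#' prior confidence of edge i -> j (0 for pairs absent from the prior).
#' Including a prior edge of confidence w costs `1 - w`, excluding it costs
#' `w`, and a non-prior edge costs 1; with all confidences in {0, 1} this
#' is exactly the qualitative disagreement count against the prior edge
#' set and its complement.
#'
#' @param B binary adjacency matrix (dimnames = nodes) or a [logic_model()].
#' @param prior a [prior_network()] over (a superset of) the same nodes.
#' @return non-negative penalty.
#' @export
prior_penalty <- function(B, prior) {
  if (inherits(B, "logic_model")) B <- B$B
  nodes <- rownames(B)
  W <- .prior_weight_matrix(prior, nodes)
  diag(W) <- 0
  sum(abs(B - W))
}

#' Indegree-excess penalty
#'
#' Penalizes each node by the number of incoming edges above its
#' knowledge-derived cap: `sum_j max(0, indegree_j - d_max_j)`.
#'
#' @param B binary adjacency matrix or a [logic_model()].
#' @param d_max single integer cap or named per-node integer vector.
#' @return non-negative penalty.
#' @export
indegree_penalty <- function(B, d_max) {
  if (inherits(B, "logic_model")) B <- B$B
  indeg <- colSums(B)
  if (!is.null(names(d_max))) d_max <- d_max[colnames(B)]
  sum(pmax(0, indeg - d_max))
}

#' Objective configuration
#'
#' @param gamma non-negative weight of the prior-violation penalty.
#' @param lam non-negative weight of the indegree penalty; defaults to
#'   `gamma` (equal confidence in the two kinds of prior knowledge).
#' @param window_factor simulated-window length as a multiple of the
#'   experimental series length (default 3).
#' @return list of class `objective_config`.
#' @export
objective_config <- function(gamma = 0.5, lam = gamma, window_factor = 3L) {
  if (gamma < 0 || lam < 0) stop("gamma and lam must be non-negative")
  structure(list(gamma = gamma, lam = lam,
                 window_factor = as.integer(window_factor)),
            class = "objective_config")
}

# Precompute the simulation inputs of a dataset for repeated objective
# evaluation: clamp matrices, initial states, measured-node indices.
.dataset_sim_inputs <- function(dataset, nodes, roles, sim_cfg) {
  meas_idx <- match(dataset$measured, nodes)
  if (any(is.na(meas_idx)))
    stop("measured node(s) absent from the model: ",
         paste(dataset$measured[is.na(meas_idx)], collapse = ", "))
  if (dataset$kind == "steady_state") {
    m <- length(nodes)
    clamps <- matrix(NA_real_, length(dataset$conditions), m)
    for (c in seq_along(dataset$conditions)) {
      cond <- dataset$conditions[[c]]
      cl <- condition_clamps(NULL, stimuli = cond$stimuli,
                             inhibitors = cond$inhibitors)
      clamps[c, match(names(cl), nodes)] <- cl
    }
    list(kind = "steady_state", clamps = clamps,
         Y = dataset$measurements[, dataset$measured, drop = FALSE],
         meas_idx = meas_idx,
         eps = sim_cfg$epsilon, max_iter = sim_cfg$max_iter_factor * m)
  } else {
    inits <- list(); ys <- list(); clamps <- list()
    for (s in seq_along(dataset$series)) {
      ser <- dataset$series[[s]]
      init <- rep(0, length(nodes))
      init[meas_idx] <- ser$values[1, ]
      inits[[s]] <- init
      ys[[s]] <- as.matrix(ser$values)
      clamp <- rep(NA_real_, length(nodes))
      if (!is.null(ser$clamps))
        clamp[match(names(ser$clamps), nodes)] <- ser$clamps
      clamps[[s]] <- clamp
    }
    n_ys <- vapply(dataset$series, function(s) nrow(s$values), integer(1))
    list(kind = "time_series", inits = inits, ys = ys, meas_idx = meas_idx,
         clamps_ts = clamps, n_ys = n_ys)
  }
}

.sim_loss <- function(B, R, C, p, h, si, boolean_mode, window_factor = 3L) {
  if (si$kind == "steady_state") {
    .ss_loss_cpp(B, R, C, p, h, si$clamps, si$Y, si$meas_idx, si$eps,
                 si$max_iter, boolean_mode)
  } else {
    .ts_loss_cpp(B, R, C, p, h, si$inits, si$ys, si$meas_idx,
                 as.integer(window_factor * si$n_ys), si$clamps_ts,
                 boolean_mode)
  }
}

#' Knowledge-guided objective of a candidate model
#'
#' `total = L(y, z) + gamma * prior_penalty + lam * indegree_penalty`,
#' where L is the MSE for steady-state data (simulating every condition to
#' steady state) or the summed DTW loss for time series (simulating
#' `window_factor * n_y` synchronous steps per series, with measured nodes
#' initialized at their first experimental value and all others at 0).
#'
#' @param model a [logic_model()].
#' @param dataset a `perturbation_dataset`.
#' @param prior a [prior_network()] (supplies confidences and `d_max`).
#' @param cfg an [objective_config()].
#' @param sim_cfg a [simulation_config()].
#' @return list with `total`, `loss`, `prior_penalty`, `indegree_penalty`
#'   and the weighted `parts`.
#' @export
objective <- function(model, dataset, prior, cfg = objective_config(),
                      sim_cfg = simulation_config()) {
  si <- .dataset_sim_inputs(dataset, model$nodes, model$roles, sim_cfg)
  loss <- .sim_loss(model$B, model$R, model$C, model$hill$p, model$hill$h,
                    si, sim_cfg$mode == "boolean", cfg$window_factor)
  pp <- prior_penalty(model$B, prior)
  ip <- indegree_penalty(model$B, prior$d_max)
  list(total = loss + cfg$gamma * pp + cfg$lam * ip,
       loss = loss, prior_penalty = pp, indegree_penalty = ip,
       parts = c(loss = loss, prior = cfg$gamma * pp,
                 indegree = cfg$lam * ip))
}

#' Per-node squared-error tables for a steady-state fit
#'
#' Reports, for each measured node, the least squared error (LSE, summed
#' over conditions) and the MSE (LSE divided by the number of conditions),
#' plus their totals, after simulating every condition to steady state.
#'
#' @inheritParams objective
#' @return data frame with columns `node`, `lse`, `mse`; totals are
#'   attached as attributes `total_lse` and `total_mse`.
#' @export
lse_table <- function(model, dataset, sim_cfg = simulation_config()) {
  stopifnot(dataset$kind == "steady_state")
  n_cond <- length(dataset$conditions)
  Z <- matrix(NA_real_, n_cond, length(dataset$measured),
              dimnames = list(NULL, dataset$measured))
  for (c in seq_len(n_cond)) {
    cond <- dataset$conditions[[c]]
    st <- simulate_steady_state(
      model, condition_clamps(model, cond$stimuli, cond$inhibitors), sim_cfg)
    Z[c, ] <- st$state[dataset$measured]
  }
  lse <- colSums((dataset$measurements[, dataset$measured, drop = FALSE] - Z)^2)
  out <- data.frame(node = dataset$measured, lse = unname(lse),
                    mse = unname(lse) / n_cond, stringsAsFactors = FALSE)
  attr(out, "total_lse") <- sum(lse)
  attr(out, "total_mse") <- sum(lse) / n_cond
  out
}
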