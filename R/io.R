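# Readers and writers for the plain-text interchange formats: network TSV
# (SIF plus a confidence column), role TSV, endorsement TSV, MIDAS-style
# steady-state CSV, time-series CSV, and a YAML model serialization.

.FLOAT_FMT <- "%.6g"

#' Read a signed, confidence-weighted network TSV
#'
#' Tab-separated with header `source sign target confidence`; `sign` must
#' be 1 or -1 and `confidence` in \[0, 1\]. Malformed rows are reported
#' with their line number.
#'
#' @param path file path.
#' @param roles optional named role vector passed to [prior_network()].
#' @param d_max indegree cap for the resulting prior.
#' @return a [prior_network()].
#' @export
read_network_tsv <- function(path, roles = character(), d_max = 2L) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "sign", "target", "confidence")
  if (!all(need %in% names(df)))
    stop("network TSV must have columns: ", paste(need, collapse = ", "))
  bad <- which(!(df$sign %in% c(1, -1)))
  if (length(bad))
    stop("invalid sign value '", df$sign[bad[1]], "' on line ", bad[1] + 1L,
         " of ", path, " (must be 1 or -1)")
  bad <- which(df$confidence < 0 | df$confidence > 1 | is.na(df$confidence))
  if (length(bad))
    stop("confidence out of [0, 1] on line ", bad[1] + 1L, " of ", path)
  prior_network(df[, need][, c("source", "target", "sign", "confidence")],
                roles = roles, d_max = d_max)
}

#' Write a network TSV
#'
#' Rows are sorted and floats formatted `%.6g`, so identical networks
#' produce byte-identical files.
#'
#' @param net a [prior_network()] or [logic_model()] (confidence 1 for
#'   model edges).
#' @param path output path.
#' @export
write_network_tsv <- function(net, path) {
  if (inherits(net, "logic_model")) {
    e <- model_edges(net)
    e$confidence <- 1
  } else e <- net$edges
  e <- e[order(e$source, e$target, e$sign), , drop = FALSE]
  out <- data.frame(source = e$source, sign = e$sign, target = e$target,
                    confidence = sprintf(.FLOAT_FMT, e$confidence))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a node-role TSV (`node<TAB>role`)
#' @param path file path.
#' @return named character vector suitable for [prior_network()].
#' @export
read_roles_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node", "role") %in% names(df)))
    stop("roles TSV must have columns node, role")
  roles <- setNames(df$role, df$node)
  check_roles(roles)
  roles
}

#' Write a node-role TSV
#' @param roles named character role vector.
#' @param path output path.
#' @export
write_roles_tsv <- function(roles, path) {
  check_roles(roles)
  df <- data.frame(node = names(roles), role = unname(roles))
  df <- df[order(df$node), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an endorsement TSV
#'
#' Tab-separated with header
#' `source sign target n_low n_high`: per signed edge, the counts of low-
#' and high-throughput endorsing publications.
#'
#' @param path file path.
#' @return data frame of endorsement records for [build_prior()].
#' @export
read_endorsements_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "sign", "target", "n_low", "n_high")
  if (!all(need %in% names(df)))
    stop("endorsement TSV must have columns: ", paste(need, collapse = ", "))
  if (any(df$n_low < 0) || any(df$n_high < 0))
    stop("endorsement counts must be non-negative")
  df[, need]
}

#' Read a MIDAS-style steady-state CSV
#'
#' Columns `TR:<node>` give treatments (value 1 clamps the stimulus to 1;
#' the suffix convention `TR:<node>:i` flags a chemical inhibitor, clamped
#' to 0), `DA:` columns carry acquisition times (kept as metadata) and
#' `DV:<node>` columns carry measured values in \[0, 1\]. A plain wide
#' dialect with a leading `condition` column and one column per measured
#' node is also accepted when `dialect = "wide"` (all nodes unclamped).
#'
#' @param path file path.
#' @param dialect `"midas"` (default) or `"wide"`.
#' @return a [steady_state_dataset()].
#' @export
read_midas_csv <- function(path, dialect = c("midas", "wide")) {
  dialect <- match.arg(dialect)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "wide") {
    vals <- as.matrix(df[, setdiff(names(df), "condition"), drop = FALSE])
    if (any(vals < 0 | vals > 1))
      stop("measured values outside [0, 1]; normalize the data first ",
           "(see minmax_normalize)")
    conds <- replicate(nrow(vals),
                       list(stimuli = numeric(), inhibitors = character()),
                       simplify = FALSE)
    return(steady_state_dataset(conds, vals))
  }
  tr_cols <- grep("^TR:", names(df), value = TRUE)
  dv_cols <- grep("^DV:", names(df), value = TRUE)
  if (!length(dv_cols)) stop("MIDAS file has no DV: (measured value) columns")
  vals <- as.matrix(df[, dv_cols, drop = FALSE])
  colnames(vals) <- sub("^DV:", "", dv_cols)
  if (any(vals < 0 | vals > 1))
    stop("measured values outside [0, 1]; normalize the data first ",
         "(see minmax_normalize)")
  inhib_cols <- grep(":i$", tr_cols, value = TRUE)
  stim_cols <- setdiff(tr_cols, inhib_cols)
  conds <- lapply(seq_len(nrow(df)), function(r) {
    # absent stimuli clamp their receptor to 0, so every TR column is kept
    stim <- numeric()
    for (cc in stim_cols) stim[sub("^TR:", "", cc)] <- df[r, cc]
    inh <- character()
    for (cc in inhib_cols)
      if (df[r, cc] != 0) inh <- c(inh, sub(":i$", "", sub("^TR:", "", cc)))
    list(stimuli = stim, inhibitors = inh)
  })
  steady_state_dataset(conds, vals)
}

#' Read a time-series CSV
#'
#' First column `time` (strictly increasing stamps, kept as metadata);
#' each remaining column is one measured node. At least two rows are
#' required and column names must be unique.
#'
#' @param path file path.
#' @param clamps optional named clamp map applied during simulation of
#'   this series.
#' @return a [timeseries_dataset()] with one series.
#' @export
read_timeseries_csv <- function(path, clamps = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!("time" %in% names(df))) stop("time-series CSV needs a 'time' column")
  nodes <- names(df)[names(df) != "time"]
  if (anyDuplicated(nodes))
    stop("duplicate measured-node column(s): ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  if (nrow(df) < 2) stop("time series need at least 2 time points")
  if (any(diff(df$time) <= 0)) stop("time stamps must be strictly increasing")
  vals <- as.matrix(df[, nodes, drop = FALSE])
  timeseries_dataset(list(list(values = vals, time = df$time,
                               clamps = clamps)))
}

#' Write a simulated state matrix as a time-series CSV
#' @param states matrix from [simulate_timeseries()].
#' @param path output path.
#' @export
write_timeseries_csv <- function(states, path) {
  fmt <- matrix(sprintf(.FLOAT_FMT, states), nrow(states), ncol(states),
                dimnames = dimnames(states))
  df <- data.frame(time = seq_len(nrow(states)) - 1L, fmt,
                   check.names = FALSE)
  write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a logic model to YAML
#'
#' Stores nodes, roles, Hill parameters and the edge records
#' `(source, target, sign, clause)`; [read_model_yaml()] restores an
#' identical model.
#'
#' @param model a [logic_model()].
#' @param path output path.
#' @export
write_model_yaml <- function(model, path) {
  e <- model_edges(model)
  obj <- list(nodes = as.list(model$nodes),
              roles = as.list(model$roles),
              hill = list(p = model$hill$p, h = model$hill$h),
              edges = lapply(seq_len(nrow(e)), function(k)
                list(source = e$source[k], target = e$target[k],
                     sign = e$sign[k], clause = e$clause[k])))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a logic model from YAML
#' @param path file written by [write_model_yaml()].
#' @return a [logic_model()].
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  nodes <- unlist(obj$nodes)
  m <- length(nodes)
  B <- matrix(0L, m, m, dimnames = list(nodes, nodes))
  R <- matrix(1L, m, m, dimnames = list(nodes, nodes))
  C <- matrix(1L, m, m, dimnames = list(nodes, nodes))
  for (e in obj$edges) {
    B[e$source, e$target] <- 1L
    R[e$source, e$target] <- if (e$sign == 1) 1L else 0L
    C[e$source, e$target] <- as.integer(e$clause)
  }
  logic_model(nodes, B, R, C,
              hill = hill_params(obj$hill$p, obj$hill$h),
              roles = unlist(obj$roles))
}

#' Load a structured run configuration
#'
#' Reads a YAML file with any of the sections `objective`
#' (gamma, lam, window_factor), `simulation` (epsilon, max_iter_factor,
#' ts_length_factor, mode), `ga` (pop_size, generations, crossover_rate,
#' mutation_rate, elitism, n_restarts, tournament_size, seed) and
#' `hill_grid`; missing entries take the package defaults.
#'
#' @param path YAML file path (optional; `NULL` gives all defaults).
#' @return list with `objective`, `simulation`, `ga` config objects and
#'   `hill_grid`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  merge_args <- function(fn, args) do.call(fn, args[!vapply(args, is.null, TRUE)])
  list(objective = merge_args(objective_config, raw$objective %||% list()),
       simulation = merge_args(simulation_config, raw$simulation %||% list()),
       ga = merge_args(ga_config, raw$ga %||% list()),
       hill_grid = raw$hill_grid %||% default_hill_grid())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
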