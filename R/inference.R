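# Structure learning: the constrained nonlinear integer program over
# (B, C, R, h) solved by a multi-restart genetic algorithm, plus an
# exhaustive enumerator used as its optimality oracle on small problems.

#' Genetic algorithm configuration
#'
#' @param pop_size population size.
#' @param generations number of generations per restart.
#' @param crossover_rate probability that a selected pair undergoes
#'   uniform crossover.
#' @param mutation_rate per-gene mutation probability; default
#'   `1 / chromosome length`.
#' @param elitism number of best individuals copied unchanged.
#' @param n_restarts independent restarts (seeded `seed`, `seed + 1`, ...);
#'   the best of all restarts is returned.
#' @param tournament_size tournament selection size.
#' @param seed base random seed.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100L, generations = 200L,
                      crossover_rate = 0.8, mutation_rate = NULL,
                      elitism = 2L, n_restarts = 50L, tournament_size = 2L,
                      seed = 1L) {
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  if (crossover_rate < 0 || crossover_rate > 1) stop("rates must lie in [0, 1]")
  if (!is.null(mutation_rate) && (mutation_rate < 0 || mutation_rate > 1))
    stop("rates must lie in [0, 1]")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism),
                 n_restarts = as.integer(n_restarts),
                 tournament_size = as.integer(tournament_size),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Search space of candidate models
#'
#' The genotype holds, for every candidate edge (ordered node pair whose
#' target is not stimulated), an inclusion bit, a sign bit and a clause
#' label, plus one global gene indexing the Hill sensitivity grid.
#'
#' @param prior a [prior_network()] defining nodes, roles and `d_max`.
#' @param hill_grid discrete grid of candidate `h` values.
#' @param p Hill coefficient (fixed during search; default 2).
#' @param candidate_edges optional data frame (`source`, `target`)
#'   restricting the edge universe (e.g. prior edges plus a user-supplied
#'   addition set for large problems); default is the full ordered-pair
#'   space.
#' @param max_clause_labels range of the raw clause gene; raw labels are
#'   reduced modulo the realized indegree at decode time, so any value
#'   >= the largest expected indegree covers all gate partitions.
#' @param fix_prior_signs if `TRUE`, sign genes of edges present in the
#'   prior are pinned to the prior sign.
#' @return list of class `search_space`.
#' @export
search_space <- function(prior, hill_grid = default_hill_grid(), p = 2L,
                         candidate_edges = NULL, max_clause_labels = 4L,
                         fix_prior_signs = FALSE) {
  nodes <- prior$nodes
  roles <- prior$roles
  if (is.null(candidate_edges)) {
    grid <- expand.grid(source = nodes, target = nodes,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$source != grid$target &
                 roles[grid$target] != "stimulated", , drop = FALSE]
  } else {
    grid <- as.data.frame(candidate_edges, stringsAsFactors = FALSE)
    stopifnot(all(c("source", "target") %in% names(grid)))
    if (any(grid$source == grid$target)) stop("self-loops are not searchable")
    if (any(roles[grid$target] == "stimulated"))
      stop("stimulated nodes cannot receive candidate edges")
  }
  grid <- grid[order(grid$target, grid$source), , drop = FALSE]
  grid <- grid[!duplicated(paste(grid$source, grid$target)), , drop = FALSE]
  rownames(grid) <- NULL
  if (!nrow(grid)) stop("empty candidate edge universe (all nodes stimulated?)")
  fixed_sign <- rep(NA_integer_, nrow(grid))
  if (fix_prior_signs && nrow(prior$edges)) {
    key <- edge_key(grid$source, grid$target)
    pe <- prior$edges
    pk <- edge_key(pe$source, pe$target)
    hit <- match(key, pk)
    fixed_sign[!is.na(hit)] <- ifelse(pe$sign[hit[!is.na(hit)]] == 1L, 1L, 0L)
  }
  structure(list(nodes = nodes, roles = roles,
                 edges = grid, E = nrow(grid),
                 from_idx = match(grid$source, nodes),
                 to_idx = match(grid$target, nodes),
                 hill_grid = hill_grid, p = as.integer(p),
                 c_max = as.integer(max_clause_labels),
                 fixed_sign = fixed_sign,
                 n_genes = 3L * nrow(grid) + 1L),
            class = "search_space")
}

# Chromosome -> (B, R, C, h) without logic_model validation overhead.
.chrom_to_matrices <- function(chrom, space) {
  E <- space$E
  m <- length(space$nodes)
  B <- matrix(0L, m, m)
  R <- matrix(1L, m, m)
  C <- matrix(1L, m, m)
  inc <- chrom[seq_len(E)] == 1L
  if (any(inc)) {
    fi <- space$from_idx[inc]
    ti <- space$to_idx[inc]
    B[cbind(fi, ti)] <- 1L
    r <- chrom[E + seq_len(E)][inc]
    fx <- space$fixed_sign[inc]
    r[!is.na(fx)] <- fx[!is.na(fx)]
    R[cbind(fi, ti)] <- r
    craw <- chrom[2L * E + seq_len(E)][inc]
    for (j in unique(ti)) {
      sel <- ti == j
      k <- sum(sel)
      raw <- ((craw[sel] - 1L) %% k) + 1L
      C[cbind(fi[sel], j)] <- match(raw, unique(raw))
    }
  }
  list(B = B, R = R, C = C, h = space$hill_grid[chrom[space$n_genes]])
}

#' Decode a chromosome into a logic model
#'
#' Deterministic genotype-to-model mapping: inclusion bits select edges,
#' sign bits set activation/inhibition, clause genes are reduced modulo
#' the realized indegree and renumbered canonically (order of first
#' appearance), and the final gene picks `h` from the grid. Clause and
#' sign genes of excluded edges are ignored, so chromosomes differing only
#' there (or by a clause-label permutation) decode to semantically
#' identical models.
#'
#' @param chromosome integer vector of length `space$n_genes`.
#' @param space a [search_space()].
#' @return a [logic_model()].
#' @export
decode <- function(chromosome, space) {
  if (length(chromosome) != space$n_genes)
    stop("chromosome length must be ", space$n_genes)
  mat <- .chrom_to_matrices(as.integer(chromosome), space)
  dimnames(mat$B) <- dimnames(mat$R) <- dimnames(mat$C) <-
    list(space$nodes, space$nodes)
  logic_model(space$nodes, mat$B, mat$R, mat$C,
              hill = hill_params(space$p, mat$h), roles = space$roles)
}

#' Encode a logic model as a chromosome
#'
#' Inverse of [decode()] up to gate semantics: `decode(encode(m))` has the
#' same gates, signs and `h` as `m`.
#'
#' @param model a [logic_model()] over the space's nodes.
#' @param space a [search_space()].
#' @return integer chromosome.
#' @export
encode <- function(model, space) {
  E <- space$E
  chrom <- c(rep(0L, E), rep(1L, E), rep(1L, E), 1L)
  idx <- cbind(space$from_idx, space$to_idx)
  b <- model$B[idx]
  chrom[seq_len(E)] <- b
  chrom[E + seq_len(E)] <- model$R[idx]
  lab <- model$C[idx]
  if (any(lab[b == 1L] > space$c_max))
    stop("model uses more clause labels than the space allows")
  chrom[2L * E + seq_len(E)] <- lab
  hi <- which.min(abs(space$hill_grid - model$hill$h))
  if (abs(space$hill_grid[hi] - model$hill$h) > 1e-9)
    stop("model h is not on the space's hill grid")
  chrom[space$n_genes] <- hi
  mb <- model$B
  dimnames(mb) <- NULL
  covered <- matrix(0L, length(space$nodes), length(space$nodes))
  covered[idx] <- 1L
  if (any(mb == 1L & covered == 0L))
    stop("model contains edges outside the candidate universe")
  chrom
}

# (fitness, prior penalty, edge count, lexicographic chromosome) tie-break.
.better_candidate <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (a$fitness != b$fitness) return(a$fitness < b$fitness)
  if (a$pp != b$pp) return(a$pp < b$pp)
  if (a$n_edges != b$n_edges) return(a$n_edges < b$n_edges)
  d <- a$chrom - b$chrom
  nz <- which(d != 0)
  if (!length(nz)) return(FALSE)
  d[nz[1]] < 0
}

.make_fitness <- function(dataset, prior, space, obj_cfg, sim_cfg) {
  si <- .dataset_sim_inputs(dataset, space$nodes, space$roles, sim_cfg)
  W <- .prior_weight_matrix(prior, space$nodes)
  diag(W) <- 0
  d_max <- prior$d_max[space$nodes]
  boolean_mode <- sim_cfg$mode == "boolean"
  p <- space$p
  wf <- obj_cfg$window_factor
  function(chrom) {
    mat <- .chrom_to_matrices(chrom, space)
    loss <- .sim_loss(mat$B, mat$R, mat$C, p, mat$h, si, boolean_mode, wf)
    pp <- sum(abs(mat$B - W))
    ip <- sum(pmax(0, colSums(mat$B) - d_max))
    c(fitness = loss + obj_cfg$gamma * pp + obj_cfg$lam * ip,
      loss = loss, pp = pp, ip = ip)
  }
}

.random_chromosome <- function(space) {
  E <- space$E
  c(rbinom(E, 1L, 0.5),
    rbinom(E, 1L, 0.5),
    sample.int(space$c_max, E, replace = TRUE),
    sample.int(length(space$hill_grid), 1L))
}

.prior_chromosome <- function(space, prior) {
  E <- space$E
  chrom <- c(rep(0L, E), rep(1L, E), rep(1L, E),
             sample.int(length(space$hill_grid), 1L))
  if (nrow(prior$edges)) {
    key <- edge_key(space$edges$source, space$edges$target)
    pe <- prior$edges
    hit <- match(key, edge_key(pe$source, pe$target))
    chrom[seq_len(E)][!is.na(hit)] <- 1L
    chrom[E + seq_len(E)][!is.na(hit)] <-
      ifelse(pe$sign[hit[!is.na(hit)]] == 1L, 1L, 0L)
  }
  chrom
}

.mutate <- function(chrom, space, rate) {
  E <- space$E
  hit <- which(runif(space$n_genes) < rate)
  for (g in hit) {
    if (g <= 2L * E) chrom[g] <- 1L - chrom[g]
    else if (g <= 3L * E) chrom[g] <- sample.int(space$c_max, 1L)
    else chrom[g] <- sample.int(length(space$hill_grid), 1L)
  }
  chrom
}

.ga_run <- function(fitness_fn, space, prior, ga_cfg, obj_cfg) {
  len <- space$n_genes
  mut <- if (is.null(ga_cfg$mutation_rate)) 1 / len else ga_cfg$mutation_rate
  n <- ga_cfg$pop_size
  pop <- replicate(n, .random_chromosome(space), simplify = FALSE)
  pop[[1]] <- .prior_chromosome(space, prior)
  fits <- vapply(pop, function(ch) fitness_fn(ch)[["fitness"]], numeric(1))
  trace <- numeric(ga_cfg$generations)
  for (gen in seq_len(ga_cfg$generations)) {
    ord <- order(fits)
    elite_idx <- ord[seq_len(min(ga_cfg$elitism, n))]
    newpop <- pop[elite_idx]
    while (length(newpop) < n) {
      pick <- function() {
        cand <- sample.int(n, ga_cfg$tournament_size)
        cand[which.min(fits[cand])]
      }
      p1 <- pop[[pick()]]; p2 <- pop[[pick()]]
      if (runif(1) < ga_cfg$crossover_rate) {
        mask <- runif(len) < 0.5
        c1 <- ifelse(mask, p1, p2)
        c2 <- ifelse(mask, p2, p1)
      } else { c1 <- p1; c2 <- p2 }
      newpop[[length(newpop) + 1L]] <- .mutate(c1, space, mut)
      if (length(newpop) < n)
        newpop[[length(newpop) + 1L]] <- .mutate(c2, space, mut)
    }
    pop <- newpop
    fits <- vapply(pop, function(ch) fitness_fn(ch)[["fitness"]], numeric(1))
    trace[gen] <- min(fits)
  }
  best_i <- which.min(fits)
  parts <- fitness_fn(pop[[best_i]])
  list(chrom = pop[[best_i]], fitness = parts[["fitness"]],
       pp = parts[["pp"]], n_edges = sum(pop[[best_i]][seq_len(space$E)]),
       parts = parts, trace = cummin(trace))
}

#' Compare a learned model with the prior support
#'
#' @param learned a [logic_model()] (or its adjacency matrix).
#' @param prior a [prior_network()].
#' @return list with data frames `added` (edges in the model but not the
#'   prior) and `removed` (prior edges not in the model).
#' @export
edge_diff <- function(learned, prior) {
  if (inherits(learned, "logic_model")) learned <- model_edges(learned)
  lk <- edge_key(learned$source, learned$target)
  pk <- edge_key(prior$edges$source, prior$edges$target)
  list(added = learned[!(lk %in% pk), c("source", "target"), drop = FALSE],
       removed = prior$edges[!(pk %in% lk),
                             c("source", "target", "sign", "confidence"),
                             drop = FALSE])
}

#' Fit a knowledge-guided fuzzy logic network
#'
#' Minimizes the knowledge-guided objective (data loss plus the weighted
#' prior-violation and indegree penalties) over (B, C, R, h) with a
#' multi-restart genetic algorithm. Each restart is an independent run
#' seeded `seed + restart - 1`; the prior-support chromosome is included
#' in every initial population. The best model over all restarts is
#' returned, ties broken by lower prior penalty, then fewer edges, then
#' lexicographically smaller chromosome. The whole procedure is a pure
#' function of its inputs and the seed.
#'
#' @param dataset a `perturbation_dataset` (steady-state or time-series).
#' @param prior a [prior_network()].
#' @param obj_cfg an [objective_config()].
#' @param ga_cfg a [ga_config()].
#' @param sim_cfg a [simulation_config()].
#' @param space optional [search_space()]; defaults to the full
#'   ordered-pair universe over the prior's nodes.
#' @return object of class `inference_result`: `model`, `objective`
#'   decomposition, `best_fitness`, per-restart `traces`, and `added` /
#'   `removed` edges relative to the prior.
#' @export
fit <- function(dataset, prior, obj_cfg = objective_config(),
                ga_cfg = ga_config(), sim_cfg = simulation_config(),
                space = NULL) {
  if (is.null(space)) space <- search_space(prior)
  if (!all(dataset$measured %in% space$nodes))
    stop("dataset nodes must be a subset of the prior nodes")
  fitness_fn <- .make_fitness(dataset, prior, space, obj_cfg, sim_cfg)
  best <- NULL
  traces <- vector("list", ga_cfg$n_restarts)
  for (r in seq_len(ga_cfg$n_restarts)) {
    run <- withr::with_seed(ga_cfg$seed + r - 1L,
                            .ga_run(fitness_fn, space, prior, ga_cfg, obj_cfg))
    traces[[r]] <- run$trace
    if (.better_candidate(run, best)) best <- run
  }
  model <- decode(best$chrom, space)
  diff <- edge_diff(model, prior)
  structure(list(model = model,
                 objective = list(total = best$parts[["fitness"]],
                                  loss = best$parts[["loss"]],
                                  prior_penalty = best$parts[["pp"]],
                                  indegree_penalty = best$parts[["ip"]]),
                 best_fitness = best$fitness,
                 traces = traces,
                 added = diff$added, removed = diff$removed,
                 chromosome = best$chrom, space = space),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat("Knowledge-guided inference result\n")
  cat(sprintf("  objective %.6g = loss %.6g + prior %.6g + indegree %.6g\n",
              x$objective$total, x$objective$loss,
              x$objective$prior_penalty, x$objective$indegree_penalty))
  cat("  edges:", sum(x$model$B), "(", nrow(x$added), "added,",
      nrow(x$removed), "removed vs prior )\n")
  invisible(x)
}

# All (parents, signs, clause partition) configurations of one target node.
.node_configs <- function(parent_rows) {
  out <- list(list(parents = integer(), signs = integer(), labels = integer()))
  n <- length(parent_rows)
  if (!n) return(out)
  for (k in seq_len(n)) {
    subsets <- utils::combn(parent_rows, k, simplify = FALSE)
    partitions <- enumerate_gate_encodings(k)
    signs <- as.matrix(expand.grid(rep(list(c(0L, 1L)), k)))
    for (ps in subsets)
      for (srow in seq_len(nrow(signs)))
        for (lab in partitions)
          out[[length(out) + 1L]] <- list(parents = ps,
                                          signs = unname(signs[srow, ]),
                                          labels = lab)
  }
  out
}

#' Exhaustive structure search (oracle for the genetic algorithm)
#'
#' Enumerates every admissible (B, C, R, h): for each non-input node all
#' parent subsets of the candidate universe, all sign assignments and all
#' gate partitions, crossed over nodes and the Hill grid, and returns the
#' exact optimum of the knowledge-guided objective. Only feasible for
#' small problems; errors if the space exceeds `max_models`.
#'
#' @inheritParams fit
#' @param max_models enumeration cap (default 2e6).
#' @return an `inference_result` (with `traces` empty).
#' @export
exhaustive_fit <- function(dataset, prior, obj_cfg = objective_config(),
                           sim_cfg = simulation_config(), space = NULL,
                           max_models = 2e6) {
  if (is.null(space)) space <- search_space(prior)
  m <- length(space$nodes)
  si <- .dataset_sim_inputs(dataset, space$nodes, space$roles, sim_cfg)
  W <- .prior_weight_matrix(prior, space$nodes)
  diag(W) <- 0
  d_max <- prior$d_max[space$nodes]
  boolean_mode <- sim_cfg$mode == "boolean"
  targets <- which(tabulate(space$to_idx, m) > 0L)
  configs <- lapply(targets, function(j)
    .node_configs(space$from_idx[space$to_idx == j]))
  counts <- vapply(configs, length, numeric(1))
  total <- prod(counts) * length(space$hill_grid)
  if (total > max_models)
    stop("search space too large for exhaustive enumeration (",
         format(total, big.mark = ","), " models)")
  best <- NULL
  idx <- rep(1L, length(targets))
  repeat {
    B <- matrix(0L, m, m); R <- matrix(1L, m, m); C <- matrix(1L, m, m)
    for (t in seq_along(targets)) {
      cf <- configs[[t]][[idx[t]]]
      if (length(cf$parents)) {
        j <- targets[t]
        B[cf$parents, j] <- 1L
        R[cf$parents, j] <- cf$signs
        C[cf$parents, j] <- cf$labels
      }
    }
    pp <- sum(abs(B - W))
    ip <- sum(pmax(0, colSums(B) - d_max))
    for (hi in seq_along(space$hill_grid)) {
      h <- space$hill_grid[hi]
      loss <- .sim_loss(B, R, C, space$p, h, si, boolean_mode,
                        obj_cfg$window_factor)
      cand <- list(fitness = loss + obj_cfg$gamma * pp + obj_cfg$lam * ip,
                   loss = loss, pp = pp, ip = ip, n_edges = sum(B),
                   B = B, R = R, C = C, hi = hi,
                   chrom = rep(0L, space$n_genes))
      if (.better_candidate(cand, best)) best <- cand
    }
    # odometer increment
    t <- 1L
    while (t <= length(targets)) {
      idx[t] <- idx[t] + 1L
      if (idx[t] <= counts[t]) break
      idx[t] <- 1L
      t <- t + 1L
    }
    if (t > length(targets)) break
  }
  dimnames(best$B) <- dimnames(best$R) <- dimnames(best$C) <-
    list(space$nodes, space$nodes)
  model <- logic_model(space$nodes, best$B, best$R, best$C,
                       hill = hill_params(space$p, space$hill_grid[best$hi]),
                       roles = space$roles)
  diff <- edge_diff(model, prior)
  structure(list(model = model,
                 objective = list(total = best$fitness, loss = best$loss,
                                  prior_penalty = best$pp,
                                  indegree_penalty = best$ip),
                 best_fitness = best$fitness,
                 traces = list(),
                 added = diff$added, removed = diff$removed,
                 chromosome = NULL, space = space),
            class = "inference_result")
}
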