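# Prior knowledge network: publication-derived confidence scoring and
# compression of undesignated pass-through proteins.

# Confidence score lookup for reactions endorsed by a single study type
# (counts 0, 1, 2, 3, >= 4).
.LT_SCORES <- c(0, 0.8, 0.9, 0.95, 0.95)
.HT_SCORES <- c(0, 0.25, 0.5, 0.75, 0.85)
.SCORE_CAP <- 0.95
.HT_INCREMENT <- 0.05

#' Classify a publication as high- or low-throughput
#'
#' Publications endorsing many distinct reactions are treated as
#' high-throughput screens, whose individual reaction calls are less
#' reliable than focused low-throughput studies. A publication is
#' high-throughput iff it endorses strictly more than `ht_threshold`
#' reactions.
#'
#' @param n_reactions positive integer count(s) of distinct reactions the
#'   publication endorses.
#' @param ht_threshold positive integer cutoff; the default 111 corresponds
#'   to the 90th percentile of reactions-per-publication in a large pathway
#'   database snapshot. See [ht_threshold_from_counts()] to recompute it for
#'   another snapshot.
#' @return character vector, `"high_throughput"` or `"low_throughput"`.
#' @seealso [score_reaction()]
#' @export
classify_publication <- function(n_reactions, ht_threshold = 111L) {
  if (any(n_reactions < 1) || any(n_reactions != round(n_reactions)))
    stop("n_reactions must be positive integer(s)")
  if (length(ht_threshold) != 1 || ht_threshold < 1)
    stop("ht_threshold must be a positive integer")
  ifelse(n_reactions > ht_threshold, "high_throughput", "low_throughput")
}

#' Derive the high-throughput cutoff from an endorsement table
#'
#' Computes the reactions-per-publication count below which the given
#' fraction of publications fall, so that roughly the top `1 - prob` of
#' publications (by reaction count) are classified high-throughput by
#' [classify_publication()].
#'
#' @param counts integer vector: number of distinct reactions endorsed by
#'   each publication.
#' @param prob quantile, default 0.9.
#' @return integer threshold usable as `ht_threshold`.
#' @export
ht_threshold_from_counts <- function(counts, prob = 0.9) {
  if (!length(counts) || any(counts < 0)) stop("counts must be non-negative")
  as.integer(quantile(counts, prob, type = 1, names = FALSE))
}

#' Confidence score of a reaction from publication endorsements
#'
#' Reactions endorsed only by low-throughput studies score 0, 0.8, 0.9,
#' 0.95, 0.95 for 0, 1, 2, 3, >= 4 endorsements; only by high-throughput
#' studies 0, 0.25, 0.5, 0.75, 0.85. A reaction endorsed by both types
#' scores the low-throughput value plus 0.05 per high-throughput
#' endorsement. Scores never exceed 0.95.
#'
#' @param n_low,n_high non-negative integer endorsement counts (vectorized).
#' @return confidence score(s) in \[0, 0.95\].
#' @export
score_reaction <- function(n_low, n_high) {
  if (any(n_low < 0) || any(n_high < 0)) stop("endorsement counts must be non-negative")
  n <- max(length(n_low), length(n_high))
  n_low <- rep_len(as.integer(n_low), n)
  n_high <- rep_len(as.integer(n_high), n)
  lt <- .LT_SCORES[pmin(n_low, 4L) + 1L]
  ht <- .HT_SCORES[pmin(n_high, 4L) + 1L]
  score <- ifelse(n_high == 0L, lt,
           ifelse(n_low == 0L, ht, lt + .HT_INCREMENT * n_high))
  pmin(score, .SCORE_CAP)
}

.normalize_sign <- function(sign) {
  if (is.character(sign)) {
    s <- ifelse(sign %in% c("activation", "1", "+"), 1L,
         ifelse(sign %in% c("inhibition", "-1", "-"), -1L, NA_integer_))
  } else {
    s <- ifelse(sign %in% c(1, -1), as.integer(sign), NA_integer_)
  }
  if (any(is.na(s))) stop("edge sign must be activation/inhibition or 1/-1")
  s
}

#' Construct a prior signaling network
#'
#' @param edges data frame with columns `source`, `target`, `sign`
#'   (1/-1 or activation/inhibition) and `confidence` in \[0, 1\].
#' @param roles named character vector mapping every node to one of
#'   `stimulated`, `inhibited`, `measured`, `undesignated`; nodes appearing
#'   in `edges` but not in `roles` default to `undesignated`.
#' @param d_max per-node cap on incoming edges used by the indegree
#'   regularizer: a single integer or a named integer vector.
#' @return an object of class `prior_network` with fields `nodes`, `edges`,
#'   `roles` and `d_max`.
#' @export
prior_network <- function(edges, roles = character(), d_max = 2L) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    stopifnot(all(c("source", "target", "sign", "confidence") %in% names(edges)))
    edges$sign <- .normalize_sign(edges$sign)
    if (any(edges$confidence < 0 | edges$confidence > 1))
      stop("edge confidence must lie in [0, 1]")
  } else {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), confidence = numeric())
  }
  check_roles(roles)
  nodes <- sort(unique(c(edges$source, edges$target, names(roles))))
  if (!length(nodes)) stop("network has no nodes")
  full_roles <- setNames(rep("undesignated", length(nodes)), nodes)
  full_roles[names(roles)] <- roles
  if (length(d_max) == 1 && is.null(names(d_max))) {
    d_max <- setNames(rep(as.integer(d_max), length(nodes)), nodes)
  } else {
    dm <- setNames(rep(2L, length(nodes)), nodes)
    dm[names(d_max)] <- as.integer(d_max)
    d_max <- dm
  }
  if (any(d_max < 0)) stop("d_max must be non-negative")
  edges <- edges[order(edges$source, edges$target, edges$sign), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, roles = full_roles,
                 d_max = d_max),
            class = "prior_network")
}

#' @export
print.prior_network <- function(x, ...) {
  cat("Prior signaling network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$roles)),
                                table(x$roles)), collapse = " "), "\n")
  invisible(x)
}

#' Build a scored prior network from endorsement records
#'
#' Each record is one (source, target, sign) reaction with counts of low-
#' and high-throughput endorsing publications. Duplicate records for the
#' same signed edge have their counts summed before scoring with
#' [score_reaction()].
#'
#' @param records data frame with columns `source`, `target`, `sign`,
#'   `n_low`, `n_high`.
#' @inheritParams prior_network
#' @return a [prior_network()].
#' @export
build_prior <- function(records, roles = character(), d_max = 2L) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "sign", "n_low", "n_high") %in% names(records)))
  if (nrow(records)) {
    records$sign <- .normalize_sign(records$sign)
    key <- paste(records$source, records$target, records$sign, sep = "\r")
    agg_low <- tapply(records$n_low, key, sum)
    agg_high <- tapply(records$n_high, key, sum)
    first <- !duplicated(key)
    edges <- data.frame(source = records$source[first],
                        target = records$target[first],
                        sign = records$sign[first],
                        stringsAsFactors = FALSE)
    k <- key[first]
    edges$confidence <- score_reaction(agg_low[k], agg_high[k])
  } else {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), confidence = numeric())
  }
  prior_network(edges, roles = roles, d_max = d_max)
}

# Drop duplicate (source, target, sign) edges keeping the larger confidence.
.dedup_edges <- function(edges) {
  if (!nrow(edges)) return(edges)
  o <- order(edges$source, edges$target, edges$sign, -edges$confidence)
  edges <- edges[o, , drop = FALSE]
  key <- paste(edges$source, edges$target, edges$sign, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Compress undesignated pass-through nodes out of a prior network
#'
#' Iteratively removes undesignated nodes that only relay signal: linear
#' cascade nodes (one in, one out), nodes where several edges converge
#' before a single outgoing edge, and nodes from which several edges
#' diverge after a single incoming edge. Nodes with several incoming *and*
#' several outgoing edges are kept, as merging them would manufacture
#' all-pairs edges not supported by the prior. Each merge of two tandem
#' edges keeps the smaller of the two confidences (the bottleneck of the
#' path) and composes signs multiplicatively (two inhibitions make an
#' activation). Designated nodes (stimulated, inhibited or measured) are
#' never removed; self-loops created by merging are dropped; duplicate
#' merged edges keep the larger confidence; incoming edges of stimulated
#' nodes are removed. Iteration over candidate nodes is in sorted node
#' order, repeated to a fixed point, so the result is deterministic and the
#' operation idempotent.
#'
#' @param net a [prior_network()].
#' @return the compressed `prior_network`.
#' @export
compress_network <- function(net) {
  stopifnot(inherits(net, "prior_network"))
  edges <- net$edges
  roles <- net$roles
  # stimulated nodes are inputs: their incoming edges are unidentifiable
  edges <- edges[!(edges$target %in% names(roles)[roles == "stimulated"]), ,
                 drop = FALSE]
  nodes <- net$nodes
  repeat {
    changed <- FALSE
    undes <- sort(nodes[!is_designated(roles[nodes])])
    for (u in undes) {
      loop <- edges$source == u & edges$target == u
      ins <- edges[edges$target == u & !loop, , drop = FALSE]
      outs <- edges[edges$source == u & !loop, , drop = FALSE]
      if (nrow(ins) >= 1 && nrow(outs) >= 1 &&
          (nrow(ins) == 1 || nrow(outs) == 1)) {
        merged <- expand.grid(i = seq_len(nrow(ins)), o = seq_len(nrow(outs)))
        new_edges <- data.frame(
          source = ins$source[merged$i],
          target = outs$target[merged$o],
          sign = ins$sign[merged$i] * outs$sign[merged$o],
          confidence = pmin(ins$confidence[merged$i], outs$confidence[merged$o]),
          stringsAsFactors = FALSE)
        new_edges <- new_edges[new_edges$source != new_edges$target, ,
                               drop = FALSE]
        edges <- edges[edges$source != u & edges$target != u, , drop = FALSE]
        edges <- .dedup_edges(rbind(edges, new_edges))
        nodes <- setdiff(nodes, u)
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  prior_network(edges, roles = roles[nodes], d_max = net$d_max[nodes])
}
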