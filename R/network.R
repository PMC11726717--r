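#' @title Dynamical network construction and interrogation
#' @description Contact-gated residue graphs weighted by the correlation
#'   of motion, and the path/community machinery used to trace allosteric
#'   communication through them.
#' @name network
NULL

new_dynet <- function(graph, params, provenance = list()) {
  structure(list(graph = graph, params = params, provenance = provenance),
            class = "allodyn_network")
}

#' @export
print.allodyn_network <- function(x, ...) {
  cat("<allodyn_network> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges",
      if (!is.null(x$provenance$condition))
        paste0(" [", x$provenance$condition, "]"), "\n", sep = "")
  invisible(x)
}

#' Network construction parameters
#'
#' @param cutoff contact distance gate in Angstrom (recorded provenance;
#'   the gate itself is applied when the contact table is computed).
#' @param persistency_threshold minimum contact persistency (%) for an
#'   edge; the comparison is inclusive, so exactly-threshold pairs gate in.
#' @param exclude_consecutive drop edges between sequence neighbours
#'   (|i - j| = 1).
#' @param corr_floor minimum |C| for a finite weight; gated pairs at or
#'   below the floor are dropped with a warning.
#' @param log_base base of the logarithm in `W = -log_base(|C|)`. The
#'   base uniformly rescales all weights, so paths and communities are
#'   invariant to it.
#' @return a list of class `network_params`.
#' @export
network_params <- function(cutoff = 4.5, persistency_threshold = 75,
                           exclude_consecutive = TRUE, corr_floor = 1e-6,
                           log_base = exp(1)) {
  stopifnot(persistency_threshold > 0, persistency_threshold <= 100,
            corr_floor >= 0, corr_floor < 1, log_base > 1)
  structure(list(cutoff = cutoff,
                 persistency_threshold = persistency_threshold,
                 exclude_consecutive = exclude_consecutive,
                 corr_floor = corr_floor, log_base = log_base),
            class = "network_params")
}

#' Build the contact-gated dynamical network
#'
#' Nodes are the residues of the correlation matrix. An edge (i, j)
#' exists iff the pair's contact persistency is at least the threshold,
#' the residues are non-consecutive (when exclusion is on) and
#' `|C_ij|` exceeds the floor; its weight is `W_ij = -log(|C_ij|)` in the
#' configured base.
#'
#' @param corr a `corr_matrix` from [correlation_matrix()].
#' @param contacts a `contact_table` over the same residues.
#' @param params a `network_params` list.
#' @param condition optional condition label stored as provenance.
#' @return an `allodyn_network`; edges carry `weight`, `corr` and
#'   `persistency` attributes.
#' @export
build_network <- function(corr, contacts, params = network_params(),
                          condition = NULL) {
  stopifnot(inherits(corr, "corr_matrix"), inherits(contacts, "contact_table"))
  resno <- as.integer(rownames(corr))
  extra <- setdiff(unique(c(contacts$resno_a, contacts$resno_b)), resno)
  if (length(extra))
    stop("contact table references residues absent from the correlation ",
         "matrix: ", paste(head(extra, 5L), collapse = ", "))
  gate <- contacts$persistency >= params$persistency_threshold - 1e-9
  if (params$exclude_consecutive)
    gate <- gate & abs(contacts$resno_a - contacts$resno_b) > 1L
  gate <- gate & contacts$resno_a != contacts$resno_b
  cand <- contacts[gate, , drop = FALSE]
  ci <- match(cand$resno_a, resno)
  cj <- match(cand$resno_b, resno)
  cmag <- abs(corr[cbind(ci, cj)])
  dropped <- cmag <= params$corr_floor
  if (any(dropped))
    warning(sum(dropped), " gated pair(s) dropped: |C| at or below the ",
            "floor (", params$corr_floor, ") would give infinite weight")
  cand <- cand[!dropped, , drop = FALSE]
  cmag <- cmag[!dropped]
  g <- igraph::make_empty_graph(n = length(resno), directed = FALSE)
  igraph::V(g)$name <- as.character(resno)
  if (nrow(cand)) {
    g <- igraph::add_edges(g, rbind(match(cand$resno_a, resno),
                                    match(cand$resno_b, resno)))
    igraph::E(g)$weight <- -log(cmag) / log(params$log_base)
    igraph::E(g)$corr <- cmag
    igraph::E(g)$persistency <- cand$persistency
  }
  new_dynet(g, params,
            provenance = list(condition = condition,
                              nframes = attr(contacts, "nframes")))
}

#' Build a dynamical network directly from an edge list
#'
#' Constructor for pre-gated graphs (planted benchmarks, hand-built
#' examples): supply either correlation magnitudes (`corr`, from which
#' `weight = -log_base(corr)` is derived) or weights directly.
#'
#' @param edges data frame with columns `from`, `to` (residue numbers)
#'   and `corr` and/or `weight`.
#' @param nodes optional full node set (residue numbers); defaults to the
#'   residues appearing in `edges`.
#' @param log_base logarithm base relating weights and correlations.
#' @param condition optional provenance label.
#' @return an `allodyn_network`.
#' @export
network_from_edges <- function(edges, nodes = NULL, log_base = exp(1),
                               condition = NULL) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (is.null(edges$weight) && is.null(edges$corr))
    stop("edges need a 'corr' or 'weight' column")
  if (is.null(edges$weight)) edges$weight <- -log(edges$corr) / log(log_base)
  if (is.null(edges$corr)) edges$corr <- log_base^(-edges$weight)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- as.character(nodes)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges$from, nodes),
                                    match(edges$to, nodes)))
    igraph::E(g)$weight <- edges$weight
    igraph::E(g)$corr <- edges$corr
    if (!is.null(edges$persistency))
      igraph::E(g)$persistency <- edges$persistency
  }
  new_dynet(g, network_params(log_base = log_base),
            provenance = list(condition = condition))
}

#' Edge list of a dynamical network
#'
#' @param net an `allodyn_network`.
#' @return data frame `from`, `to` (residue numbers, `from < to`),
#'   `weight`, and `corr`/`persistency` when present.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "allodyn_network"))
  g <- net$graph
  if (igraph::ecount(g) == 0L)
    return(data.frame(from = integer(), to = integer(), weight = numeric()))
  el <- igraph::as_edgelist(g)
  a <- as.integer(el[, 1L]); b <- as.integer(el[, 2L])
  out <- data.frame(from = pmin(a, b), to = pmax(a, b),
                    weight = igraph::E(g)$weight)
  if (!is.null(igraph::E(g)$corr)) out$corr <- igraph::E(g)$corr
  if (!is.null(igraph::E(g)$persistency))
    out$persistency <- igraph::E(g)$persistency
  out[order(out$from, out$to), , drop = FALSE]
}

node_index <- function(net, residue) {
  i <- match(as.character(residue), igraph::V(net$graph)$name)
  if (is.na(i)) stop("residue ", residue, " is not a network node")
  i
}

#' Minimum-weight path between two residues
#'
#' Dijkstra shortest path on the `-log|C|` weights. Ties are broken
#' deterministically: among equal-cost paths the lexicographically
#' smallest node sequence is returned.
#'
#' @param net an `allodyn_network`.
#' @param source,sink residue numbers.
#' @return list with `found`, `path` (residue sequence) and `cost`
#'   (total weight); `found = FALSE` with an infinite cost when the nodes
#'   are disconnected.
#' @export
net_shortest_path <- function(net, source, sink) {
  s <- node_index(net, source); t <- node_index(net, sink)
  g <- net$graph
  sp <- suppressWarnings(
    igraph::all_shortest_paths(g, from = s, to = t,
                               weights = igraph::E(g)$weight))
  if (!length(sp$vpaths))
    return(list(found = FALSE, path = integer(), cost = Inf))
  seqs <- lapply(sp$vpaths, function(p) as.integer(names(p)))
  best <- seqs[[lex_min(seqs)]]
  list(found = TRUE, path = best, cost = path_cost(net, best))
}

lex_min <- function(seqs) {
  best <- 1L
  for (k in seq_along(seqs)[-1L])
    if (lex_less(seqs[[k]], seqs[[best]])) best <- k
  best
}

lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

path_cost <- function(net, path) {
  if (length(path) < 2L) return(0)
  g <- net$graph
  ids <- igraph::get_edge_ids(g, rbind(match(as.character(path[-length(path)]),
                                             igraph::V(g)$name),
                                       match(as.character(path[-1L]),
                                             igraph::V(g)$name)))
  sum(igraph::E(g)$weight[ids])
}

#' Optimal and suboptimal communication paths
#'
#' Enumerates every simple path from source to sink whose total weight is
#' within `tolerance` of the optimum (depth-first search pruned by the
#' remaining shortest distance to the sink), and tallies per-edge usage
#' counts -- the "structural information" rendered as edge thickness in
#' network figures.
#'
#' @param net an `allodyn_network`.
#' @param source,sink residue numbers.
#' @param tolerance admissible excess weight over the optimal path.
#' @param max_paths enumeration guard; if hit, the ensemble is truncated
#'   and flagged.
#' @return a `path_ensemble`: list with `paths` (residue sequences sorted
#'   by cost then lexicographically), `costs`, `optimal_cost`,
#'   `edge_usage` (data frame `from`, `to`, `count`), `truncated`.
#' @export
suboptimal_paths <- function(net, source, sink, tolerance = 0,
                             max_paths = 10000L) {
  stopifnot(tolerance >= 0)
  s <- node_index(net, source); t <- node_index(net, sink)
  g <- net$graph
  dist_to_sink <- as.numeric(igraph::distances(g, to = t,
                                               weights = igraph::E(g)$weight))
  if (!is.finite(dist_to_sink[s]))
    stop("no path between ", source, " and ", sink)
  budget <- dist_to_sink[s] + tolerance + 1e-9
  adj <- lapply(seq_len(igraph::vcount(g)), function(v) {
    es <- igraph::incident(g, v)
    heads <- igraph::ends(g, es, names = FALSE)
    other <- ifelse(heads[, 1L] == v, heads[, 2L], heads[, 1L])
    ord <- order(other)
    list(to = other[ord], w = igraph::E(g)$weight[as.integer(es)][ord])
  })
  env <- new.env(parent = emptyenv())
  env$paths <- vector("list", 256L); env$costs <- numeric(256L)
  env$n <- 0L; env$truncated <- FALSE
  visited <- rep(FALSE, igraph::vcount(g))
  walk <- function(v, cost, trail) {
    if (env$truncated) return()
    if (v == t) {
      env$n <- env$n + 1L
      if (env$n > max_paths) { env$truncated <- TRUE; env$n <- max_paths; return() }
      if (env$n > length(env$paths)) {
        length(env$paths) <- 2L * length(env$paths)
        length(env$costs) <- 2L * length(env$costs)
      }
      env$paths[[env$n]] <- trail
      env$costs[env$n] <- cost
      return()
    }
    visited[v] <<- TRUE
    nb <- adj[[v]]
    for (k in seq_along(nb$to)) {
      u <- nb$to[k]
      if (!visited[u] && cost + nb$w[k] + dist_to_sink[u] <= budget)
        walk(u, cost + nb$w[k], c(trail, u))
    }
    visited[v] <<- FALSE
  }
  walk(s, 0, s)
  n <- env$n
  paths <- lapply(env$paths[seq_len(n)], function(p)
    as.integer(igraph::V(g)$name[p]))
  costs <- env$costs[seq_len(n)]
  ord <- order(costs, vapply(paths, function(p)
    paste(formatC(p, width = 9L, flag = "0"), collapse = ","), ""))
  paths <- paths[ord]; costs <- costs[ord]
  usage <- list()
  for (p in paths) {
    if (length(p) < 2L) next
    k <- paste(pmin(p[-length(p)], p[-1L]), pmax(p[-length(p)], p[-1L]),
               sep = ":")
    for (e in k) usage[[e]] <- (usage[[e]] %||% 0L) + 1L
  }
  eu <- if (length(usage)) {
    sp <- do.call(rbind, strsplit(names(usage), ":", fixed = TRUE))
    data.frame(from = as.integer(sp[, 1L]), to = as.integer(sp[, 2L]),
               count = as.integer(unlist(usage)))
  } else data.frame(from = integer(), to = integer(), count = integer())
  eu <- eu[order(eu$from, eu$to), , drop = FALSE]
  rownames(eu) <- NULL
  structure(list(source = source, sink = sink, paths = paths, costs = costs,
                 optimal_cost = if (n) costs[1L] else Inf,
                 edge_usage = eu, truncated = env$truncated,
                 tolerance = tolerance),
            class = "path_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.path_ensemble <- function(x, ...) {
  cat("<path_ensemble> ", x$source, " -> ", x$sink, ": ", length(x$paths),
      " path(s), optimal cost ", sprintf("%.4f", x$optimal_cost),
      if (x$truncated) " [TRUNCATED]", "\n", sep = "")
  invisible(x)
}

#' Weighted edge betweenness
#'
#' Shortest-path edge betweenness over all unordered node pairs, with
#' edge weights treated as distances.
#'
#' @param net an `allodyn_network`.
#' @return data frame `from`, `to`, `betweenness`.
#' @export
net_edge_betweenness <- function(net) {
  stopifnot(inherits(net, "allodyn_network"))
  g <- net$graph
  if (igraph::ecount(g) == 0L)
    return(data.frame(from = integer(), to = integer(),
                      betweenness = numeric()))
  b <- igraph::edge_betweenness(g, weights = igraph::E(g)$weight,
                                directed = FALSE)
  out <- network_edges(net)[, c("from", "to")]
  # edge_betweenness returns in edge-id order; re-derive in the same order
  el <- igraph::as_edgelist(g)
  a1 <- as.integer(el[, 1L]); a2 <- as.integer(el[, 2L])
  d <- data.frame(from = pmin(a1, a2), to = pmax(a1, a2), betweenness = b)
  d <- d[order(d$from, d$to), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Girvan--Newman community detection
#'
#' Iteratively removes the edge of highest weighted betweenness (weights
#' as distances; ties broken by the lexicographically smallest residue
#' pair), scoring every partition in the removal hierarchy by weighted
#' modularity with the correlation magnitudes `|C| = base^-W` as edge
#' strengths. The partition at maximum modularity is returned (the
#' earliest, coarsest one on ties), so results are deterministic and
#' invariant to node relabelling and to the logarithm base.
#'
#' @param net an `allodyn_network`.
#' @return a `community_partition`: list with `membership` (named by
#'   residue, labels canonicalised in node order), `modularity`,
#'   `n_communities`.
#' @export
detect_communities <- function(net) {
  stopifnot(inherits(net, "allodyn_network"))
  g0 <- net$graph
  strengths <- igraph::E(g0)$corr %||%
    net$params$log_base^(-igraph::E(g0)$weight)
  score <- function(membership)
    igraph::modularity(g0, membership, weights = strengths)
  g <- g0
  memb <- igraph::components(g)$membership
  best <- list(membership = memb, modularity = score(memb))
  while (igraph::ecount(g) > 0L) {
    eb <- igraph::edge_betweenness(g, weights = igraph::E(g)$weight,
                                   directed = FALSE)
    cand <- which(eb >= max(eb) - 1e-9)
    if (length(cand) > 1L) {
      el <- igraph::as_edgelist(g)[cand, , drop = FALSE]
      a <- as.integer(el[, 1L]); b <- as.integer(el[, 2L])
      key <- cbind(pmin(a, b), pmax(a, b))
      cand <- cand[order(key[, 1L], key[, 2L])[1L]]
    }
    g <- igraph::delete_edges(g, cand)
    memb <- igraph::components(g)$membership
    q <- score(memb)
    if (q > best$modularity + 1e-12) best <- list(membership = memb,
                                                  modularity = q)
  }
  memb <- canonical_labels(best$membership)
  names(memb) <- igraph::V(g0)$name
  structure(list(membership = memb, modularity = best$modularity,
                 n_communities = length(unique(memb))),
            class = "community_partition")
}

canonical_labels <- function(m) as.integer(match(m, unique(m)))

#' @export
print.community_partition <- function(x, ...) {
  cat("<community_partition> ", x$n_communities, " communities, ",
      "modularity ", sprintf("%.4f", x$modularity), "\n", sep = "")
  invisible(x)
}

#' Agreement between a detected partition and ground-truth labels
#'
#' Fraction of nodes whose community matches the truth under the best
#' mapping of detected labels onto true labels (exhaustive over label
#' permutations; intended for small planted-partition studies).
#'
#' @param partition a `community_partition` or membership vector.
#' @param truth ground-truth labels in node order.
#' @return agreement fraction in `[0, 1]`.
#' @export
partition_agreement <- function(partition, truth) {
  m <- if (inherits(partition, "community_partition"))
    partition$membership else partition
  m <- canonical_labels(m); truth <- canonical_labels(truth)
  stopifnot(length(m) == length(truth))
  k <- max(m, max(truth))
  if (k > 7L) stop("partition_agreement supports at most 7 labels")
  perms <- permutations_of(seq_len(k))
  best <- 0
  for (p in perms) best <- max(best, mean(p[m] == truth))
  best
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(permutations_of(x[-i]), function(p) c(x[i], p)))
  out
}

#' Induced subnetwork over a residue set
#'
#' @param net an `allodyn_network`.
#' @param residues residue numbers, or BW labels/ranges (requires
#'   `topology` with a BW map), e.g. `"7.40-7.49"`.
#' @param topology optional `allodyn_topology` for BW resolution.
#' @param paths optional `path_ensemble`; if given, the summary reports
#'   the total path usage carried by edges inside the subnetwork.
#' @return list with `network` (induced `allodyn_network`) and `summary`
#'   (data frame: nodes, edges, total_weight, total_usage).
#' @export
subnetwork <- function(net, residues, topology = NULL, paths = NULL) {
  stopifnot(inherits(net, "allodyn_network"))
  if (is.character(residues)) {
    if (is.null(topology) || is.null(topology$bw))
      stop("BW residue sets need a topology with a BW map")
    residues <- unlist(lapply(residues, function(r)
      bw_range_residues(topology$bw, r, r)))
  }
  residues <- sort(unique(as.integer(residues)))
  keep <- which(igraph::V(net$graph)$name %in% as.character(residues))
  if (!length(keep)) stop("empty induced residue set")
  sg <- igraph::induced_subgraph(net$graph, keep)
  sub <- new_dynet(sg, net$params,
                   c(net$provenance, list(subset = residues)))
  total_usage <- NA_integer_
  if (!is.null(paths)) {
    eu <- paths$edge_usage
    inside <- eu$from %in% residues & eu$to %in% residues
    total_usage <- sum(eu$count[inside])
  }
  list(network = sub,
       summary = data.frame(nodes = igraph::vcount(sg),
                            edges = igraph::ecount(sg),
                            total_weight = sum(igraph::E(sg)$weight %||% 0),
                            total_usage = total_usage))
}

#' Compare two dynamical networks edge by edge
#'
#' Classifies edges as common to both networks, lost (present in A,
#' absent from B) or gained (absent from A, present in B); common edges
#' are annotated with the weight change `delta_w = W_B - W_A`.
#'
#' @param net_a,net_b `allodyn_network`s over a shared node universe.
#' @return data frame `from`, `to`, `status`
#'   (`common` / `lost` / `gained`), `weight_a`, `weight_b`, `delta_w`.
#' @export
compare_networks <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "allodyn_network"),
            inherits(net_b, "allodyn_network"))
  na <- igraph::V(net_a$graph)$name; nb <- igraph::V(net_b$graph)$name
  if (!length(intersect(na, nb)))
    stop("networks have disjoint node universes")
  ea <- network_edges(net_a); eb <- network_edges(net_b)
  key <- function(d) paste(d$from, d$to, sep = ":")
  keys <- union(key(ea), key(eb))
  ka <- match(keys, key(ea)); kb <- match(keys, key(eb))
  sp <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  out <- data.frame(from = as.integer(sp[, 1L]), to = as.integer(sp[, 2L]),
                    status = ifelse(!is.na(ka) & !is.na(kb), "common",
                                    ifelse(!is.na(ka), "lost", "gained")),
                    weight_a = ifelse(is.na(ka), NA, ea$weight[ka]),
                    weight_b = ifelse(is.na(kb), NA, eb$weight[kb]))
  out$delta_w <- out$weight_b - out$weight_a
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}
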