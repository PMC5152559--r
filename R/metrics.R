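#' Node degree
#'
#' @param net a [binary_network].
#' @return Integer vector of connection counts per node.
#' @export
node_degree <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  as.integer(rowSums(net$adjacency))
}

#' Node clustering coefficient
#'
#' Fraction of a node's neighbour pairs that are themselves connected
#' (triangles over `k(k-1)/2`). Nodes of degree < 2, for which the ratio is
#' undefined, carry the sentinel value -1.
#'
#' @param net a [binary_network].
#' @return Numeric vector in `[0, 1]`, or -1 for degree < 2.
#' @export
node_clustering <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  a <- net$adjacency
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2    # closed triangles through each node
  cc <- ifelse(k >= 2, tri / (k * (k - 1) / 2), -1)
  as.numeric(cc)
}

#' Node mean shortest-path length
#'
#' Mean geodesic distance from each node to the nodes it can reach
#' (unreachable pairs are excluded, not penalised). Isolated nodes carry the
#' sentinel value -1.
#'
#' @param net a [binary_network].
#' @return Numeric vector of mean distances, or -1 for isolated nodes.
#' @export
nodal_path_length <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  d <- igraph::distances(as_igraph(net))
  diag(d) <- Inf
  vapply(seq_len(nrow(d)), function(i) {
    reach <- is.finite(d[i, ])
    if (!any(reach)) -1 else mean(d[i, reach])
  }, numeric(1))
}

#' Global efficiency with a fixed normalising node count
#'
#' Sum of inverse geodesic distances over ordered reachable pairs, divided
#' by `normalization_n * (normalization_n - 1)`. Unreachable pairs
#' contribute zero, so efficiency is well defined on disconnected graphs.
#' Holding `normalization_n` at the intact network's size while nodes are
#' removed makes efficiencies comparable across removals (the convention
#' under which deleting an isolated node changes nothing).
#'
#' @param net a [binary_network] (or bare adjacency matrix).
#' @param normalization_n node count used in the denominator; defaults to
#'   the network's own size.
#' @return Efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(net, normalization_n = NULL) {
  adj <- if (inherits(net, "binary_network")) net$adjacency else
    as.matrix(net)
  if (is.null(normalization_n)) normalization_n <- nrow(adj)
  stopifnot(normalization_n >= 2)
  if (nrow(adj) < 2 || sum(adj) == 0) return(0)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  d <- igraph::distances(g)
  diag(d) <- Inf
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  sum(inv) / (normalization_n * (normalization_n - 1))
}

#' Information centrality
#'
#' Percentage change in global efficiency caused by deleting each node in
#' turn: `IC_i = 100 (E(G - i) - E(G)) / E(G)`, with both efficiencies
#' normalised by the ORIGINAL node count. Under this fixed-denominator
#' convention an isolated node's removal leaves efficiency unchanged, so its
#' centrality is exactly 0.
#'
#' @param net a [binary_network].
#' @return Numeric vector of signed percentages (negative when removal
#'   hurts efficiency).
#' @export
information_centrality <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  n <- nrow(net$adjacency)
  e0 <- global_efficiency(net, normalization_n = n)
  if (e0 == 0)
    stop("global efficiency of the intact network is 0; information ",
         "centrality is undefined")
  vapply(seq_len(n), function(i) {
    sub <- net$adjacency[-i, -i, drop = FALSE]
    100 * (global_efficiency(sub, normalization_n = n) - e0) / e0
  }, numeric(1))
}

#' Giant component membership
#'
#' Largest connected component; among equally large components the one
#' containing the smallest parcel id wins.
#'
#' @param net a [binary_network].
#' @return Integer vector of node indices (positions, 1..n) in the giant
#'   component, with attribute `"parcel_ids"`.
#' @export
giant_component <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  comp <- igraph::components(as_igraph(net))
  best_size <- max(comp$csize)
  cand <- which(comp$csize == best_size)
  if (length(cand) > 1L) {
    ## tie: smallest minimum parcel id
    min_ids <- vapply(cand, function(cm)
      min(net$parcel_ids[comp$membership == cm]), numeric(1))
    cand <- cand[which.min(min_ids)]
  } else cand <- cand[1]
  idx <- which(comp$membership == cand)
  attr(idx, "parcel_ids") <- net$parcel_ids[idx]
  idx
}

#' Per-node metrics table
#'
#' Degree, clustering, mean path length and information centrality for every
#' parcel, using the sentinel conventions of [node_clustering()] and
#' [nodal_path_length()] (and IC fixed at 0 for isolated nodes, which is
#' what the fixed-denominator convention yields).
#'
#' @param net a [binary_network].
#' @param atlas optional [parcel_atlas] supplying side and abbreviation.
#' @return Data frame of class `node_metrics`: columns `parcel_id`, `side`,
#'   `abbreviation`, `degree`, `clustering`, `path_length`,
#'   `information_centrality`.
#' @export
node_metrics <- function(net, atlas = NULL) {
  stopifnot(inherits(net, "binary_network"))
  ids <- net$parcel_ids
  if (!is.null(atlas)) {
    at <- atlas[match(ids, atlas$id), ]
    side <- at$hemisphere
    abbrev <- at$abbreviation
  } else {
    side <- rep(NA_character_, length(ids))
    abbrev <- as.character(ids)
  }
  df <- data.frame(parcel_id = ids, side = side, abbreviation = abbrev,
                   degree = node_degree(net),
                   clustering = node_clustering(net),
                   path_length = nodal_path_length(net),
                   information_centrality = information_centrality(net),
                   stringsAsFactors = FALSE)
  class(df) <- c("node_metrics", "data.frame")
  df
}

#' Hub table ranked by degree
#'
#' Sorts the node-metrics table by descending degree (ties alphabetically by
#' abbreviation, then by side) — the conventional presentation in which the
#' top rows are the network's hubs.
#'
#' @param metrics a [node_metrics()] table.
#' @param atlas optional [parcel_atlas] to (re)attach side/abbreviation.
#' @return The reordered `node_metrics` data frame with columns `side`,
#'   `abbreviation`, `degree`, `clustering`, `path_length`,
#'   `information_centrality` first.
#' @export
hub_table <- function(metrics, atlas = NULL) {
  stopifnot(inherits(metrics, "node_metrics"))
  if (!is.null(atlas)) {
    at <- atlas[match(metrics$parcel_id, atlas$id), ]
    metrics$side <- at$hemisphere
    metrics$abbreviation <- at$abbreviation
  }
  ord <- order(-metrics$degree, metrics$abbreviation, metrics$side)
  out <- metrics[ord, c("side", "abbreviation", "degree", "clustering",
                        "path_length", "information_centrality",
                        "parcel_id")]
  rownames(out) <- NULL
  class(out) <- c("node_metrics", "data.frame")
  out
}

#' Small-world index from normalized clustering and path length
#'
#' @param gamma normalized clustering coefficient `C_net / C_random`.
#' @param lambda normalized path length `L_net / L_random`.
#' @return `delta = gamma / lambda`; values above 1 indicate small-world
#'   topology.
#' @export
small_world_index <- function(gamma, lambda) gamma / lambda

## Degree-preserving Maslov-Sneppen rewiring, 10 * m swap attempts.
.rewired_null <- function(net) {
  g <- as_igraph(net)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * net$m))
  adj <- as.matrix(igraph::as_adjacency_matrix(g2, type = "both"))
  binary_network(adj, parcel_ids = net$parcel_ids)
}

#' Small-world summary against degree-preserving rewired nulls
#'
#' `L_net` is the mean nodal path length over the giant component and
#' `C_net` the mean clustering over nodes of degree >= 2. The same
#' quantities are averaged over `n_nulls` Maslov-Sneppen rewirings
#' (degree sequence preserved, 10 m swap attempts each) to give `L_random`
#' and `C_random`, from which `lambda = L_net / L_random`,
#' `gamma = C_net / C_random` and `delta = gamma / lambda`.
#'
#' @param net a [binary_network] whose giant component has >= 4 nodes.
#' @param n_nulls ensemble size (default 100).
#' @param seed integer seed for the rewirings.
#' @return Object of class `network_summary` with fields `L_net`, `C_net`,
#'   `lambda`, `gamma`, `delta`, `L_random`, `C_random`, and
#'   `null_ensemble` (per-realization `L` and `C`, `n_nulls`, `seed`).
#' @export
small_world_summary <- function(net, n_nulls = 100L, seed = 1L) {
  stopifnot(inherits(net, "binary_network"), n_nulls >= 1L)
  if (length(giant_component(net)) < 4L)
    stop("giant component has fewer than 4 nodes")
  summ <- function(bn) {
    gc <- giant_component(bn)
    pl <- nodal_path_length(bn)
    cl <- node_clustering(bn)
    k <- node_degree(bn)
    c(L = mean(pl[gc]), C = mean(cl[k >= 2]))
  }
  obs <- summ(net)
  set.seed(as.integer(seed))
  nulls <- vapply(seq_len(n_nulls), function(i) summ(.rewired_null(net)),
                  numeric(2))
  L_random <- mean(nulls["L", ])
  C_random <- mean(nulls["C", ])
  lambda <- obs[["L"]] / L_random
  gamma <- obs[["C"]] / C_random
  structure(list(L_net = obs[["L"]], C_net = obs[["C"]],
                 L_random = L_random, C_random = C_random,
                 lambda = lambda, gamma = gamma,
                 delta = small_world_index(gamma, lambda),
                 null_ensemble = list(n_nulls = as.integer(n_nulls),
                                      seed = as.integer(seed),
                                      L = unname(nulls["L", ]),
                                      C = unname(nulls["C", ]))),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(paste0("<network_summary> L_net = %.2f, C_net = %.2f, ",
                     "lambda = %.2f, gamma = %.2f, delta = %.2f ",
                     "(%d rewired nulls)\n"),
              x$L_net, x$C_net, x$lambda, x$gamma, x$delta,
              x$null_ensemble$n_nulls))
  invisible(x)
}

#' Write a node-metrics table as TSV / a network summary as JSON
#'
#' @param metrics a [node_metrics()] or [hub_table()] data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_metrics <- function(metrics, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(list()), con)
  utils::write.table(metrics, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @param summary a [small_world_summary()] result.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "network_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
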