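# Small graph constructors and independent brute-force oracles used across
# the metric tests. The oracles deliberately avoid igraph (the package's
# backend) so the two routes are independent.

adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1L
    a[e[2], e[1]] <- 1L
  }
  a
}

net_k3 <- function() binary_network(adj_from_edges(3, list(c(1, 2), c(1, 3),
                                                           c(2, 3))))
net_p3 <- function() binary_network(adj_from_edges(3, list(c(1, 2), c(2, 3))))

random_net <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  if (sum(a) == 0L) a[1, 2] <- 1L   # keep efficiency-based metrics defined
  binary_network(a + t(a))
}

# O(n^3) triangle-count clustering
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1L)
    k <- length(nb)
    if (k < 2) return(-1)
    tri <- 0L
    for (u in nb) for (v in nb) if (u < v && adj[u, v] == 1L) tri <- tri + 1L
    tri / (k * (k - 1) / 2)
  })
}

# Floyd-Warshall all-pairs distances
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1L] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_path_length <- function(adj) {
  d <- oracle_distances(adj)
  diag(d) <- Inf
  sapply(seq_len(nrow(d)), function(i) {
    reach <- is.finite(d[i, ])
    if (!any(reach)) -1 else mean(d[i, reach])
  })
}

oracle_efficiency <- function(adj, norm_n = nrow(adj)) {
  if (sum(adj) == 0) return(0)
  d <- oracle_distances(adj)
  diag(d) <- Inf
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  sum(inv) / (norm_n * (norm_n - 1))
}

# union-find giant component size
oracle_gc_size <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  es <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  for (r in seq_len(nrow(es))) {
    a <- find(es[r, 1]); b <- find(es[r, 2])
    if (a != b) parent[a] <- b
  }
  max(table(sapply(seq_len(n), find)))
}

# tiny deterministic atlas: 2 lobes x 2 hemispheres x k parcels, paired
toy_atlas <- function(k = 2) {
  rows <- list()
  id <- 0L
  for (lobe in c("frontal", "parietal")) for (i in seq_len(k))
    for (side in c("l", "r")) {
      id <- id + 1L
      rows[[id]] <- data.frame(id = id,
                               abbreviation = paste0(toupper(substr(lobe, 1, 1)), i),
                               name = paste(lobe, i), hemisphere = side,
                               lobe = lobe,
                               x = ifelse(side == "l", -40, 40),
                               y = 10 * i, z = 0, homolog_id = NA_integer_)
    }
  df <- do.call(rbind, rows)
  odd <- seq(1, nrow(df), by = 2)
  df$homolog_id[odd] <- df$id[odd + 1L]
  df$homolog_id[odd + 1L] <- df$id[odd]
  parcel_atlas(df)
}
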