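#' Binary network container
#'
#' A thresholded, undirected, unweighted connectome: a symmetric 0/1
#' adjacency matrix with zero diagonal plus the thresholding provenance.
#'
#' @param adjacency symmetric 0/1 matrix, zero diagonal.
#' @param R correlation threshold that produced it (if any).
#' @param k_net target mean degree (if any).
#' @param alpha_fdr FDR level used for admissibility (if any).
#' @param scale wavelet scale index (if any).
#' @param parcel_ids integer ids of the nodes (defaults to `1:n`).
#' @param generator label for simulated graphs.
#' @param seed seed for simulated graphs.
#' @return Object of class `binary_network`.
#' @export
binary_network <- function(adjacency, R = NA_real_, k_net = NA_real_,
                           alpha_fdr = NA_real_, scale = NA_integer_,
                           parcel_ids = NULL, generator = NA_character_,
                           seed = NA_integer_) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square")
  if (!all(adjacency %in% c(0L, 1L))) stop("adjacency must be 0/1")
  if (any(diag(adjacency) != 0L)) stop("adjacency must have zero diagonal")
  if (!all(adjacency == t(adjacency))) stop("adjacency must be symmetric")
  if (is.null(parcel_ids)) parcel_ids <- seq_len(n)
  structure(list(adjacency = adjacency,
                 m = sum(adjacency) %/% 2L,
                 R = R, k_net = k_net, alpha_fdr = alpha_fdr,
                 scale = as.integer(scale),
                 parcel_ids = as.integer(parcel_ids),
                 generator = generator, seed = seed),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat("<binary_network> ", n, " nodes, ", x$m, " edges (density ",
      sprintf("%.1f%%", 100 * x$m / (n * (n - 1) / 2)), ")", sep = "")
  if (!is.na(x$scale)) cat(", scale ", x$scale, sep = "")
  if (!is.na(x$R)) cat(", R = ", sprintf("%.3f", x$R), sep = "")
  if (!is.na(x$generator)) cat(", generator ", x$generator, sep = "")
  cat("\n")
  invisible(x)
}

#' Convert a binary network to an igraph graph
#'
#' @param net a [binary_network].
#' @return An igraph undirected graph whose vertices carry `parcel_id`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                           diag = FALSE)
  igraph::V(g)$parcel_id <- net$parcel_ids
  g
}

#' Target edge count for small-world estimation
#'
#' The mean degree is fixed at `k_net = 2 ln(n)` (natural log: for n = 116
#' this gives 9.5 and 551 retained edges, the sparsity at which small-world
#' indices are estimable), so the undirected edge budget is
#' `m = round(n * k_net / 2)`.
#'
#' @param n number of nodes (>= 2).
#' @return Named list with `m` (edge count) and `k_net` (target mean degree).
#' @export
target_edge_count <- function(n) {
  stopifnot(n >= 2)
  k_net <- 2 * log(n)
  list(m = as.integer(round(n * k_net / 2)), k_net = k_net)
}

#' Benjamini-Hochberg edge rejection set
#'
#' Applies the BH step-up procedure to the upper-triangle p-values and
#' returns the edges surviving at level `alpha`.
#'
#' @param sig a `significance_matrix` (or bare symmetric p matrix).
#' @param alpha FDR level in (0, 1).
#' @return Two-column integer matrix (`i`, `j` with `i < j`) of rejected
#'   edges, with attribute `"p_bh"` carrying their adjusted p-values.
#' @export
fdr_reject_set <- function(sig, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  p <- if (inherits(sig, "significance_matrix")) sig$p else as.matrix(sig)
  ut <- which(upper.tri(p), arr.ind = TRUE)
  pv <- p[upper.tri(p)]
  adj <- stats::p.adjust(pv, method = "BH")
  keep <- which(adj <= alpha)
  out <- ut[keep, , drop = FALSE]
  colnames(out) <- c("i", "j")
  attr(out, "p_bh") <- adj[keep]
  out
}

#' Threshold a correlation matrix into a sparse binary network
#'
#' Retains the `m = target_edge_count(n)$m` largest correlations; the
#' correlation threshold `R` is the smallest retained r. The result is
#' admissible only if every retained edge also survives Benjamini-Hochberg
#' FDR control at `alpha` — otherwise an `inadmissible_network` is returned
#' recording the maximal achievable significant edge count. Rank-m ties are
#' broken deterministically: larger r first, then lexicographic parcel-id
#' order.
#'
#' @param cm a [correlation_matrix].
#' @param sig the matching `significance_matrix`; defaults to
#'   [correlation_pvalues()] of `cm`.
#' @param alpha FDR level (default 0.05).
#' @param parcel_ids node ids (default `1:n`).
#' @return A [binary_network], or an object of class `inadmissible_network`
#'   with fields `scale`, `m_required`, `m_significant`.
#' @export
threshold_network <- function(cm, sig = correlation_pvalues(cm),
                              alpha = 0.05, parcel_ids = NULL) {
  stopifnot(inherits(cm, "correlation_matrix"))
  p <- if (inherits(sig, "significance_matrix")) sig$p else as.matrix(sig)
  if (!all(dim(p) == dim(cm$r)))
    stop("correlation and significance matrices are not conformal")
  n <- nrow(cm$r)
  tgt <- target_edge_count(n)
  ut <- which(upper.tri(cm$r), arr.ind = TRUE)
  rv <- cm$r[upper.tri(cm$r)]
  if (anyNA(rv))
    stop("correlation matrix contains NA off-diagonal entries ",
         "(zero-variance parcels); cannot threshold")
  ## deterministic ranking: r descending, then (i, j) lexicographic
  ord <- order(-rv, ut[, 1], ut[, 2])
  keep <- ord[seq_len(tgt$m)]
  R <- min(rv[keep])
  rejected <- fdr_reject_set(p, alpha)
  sig_keys <- rejected[, "i"] + n * rejected[, "j"]
  keep_keys <- ut[keep, 1] + n * ut[keep, 2]
  if (!all(keep_keys %in% sig_keys)) {
    out <- structure(list(scale = cm$scale, m_required = tgt$m,
                          m_significant = nrow(rejected),
                          k_net = tgt$k_net, alpha_fdr = alpha),
                     class = "inadmissible_network")
    return(out)
  }
  adj <- matrix(0L, n, n, dimnames = dimnames(cm$r))
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  binary_network(adj, R = R, k_net = tgt$k_net, alpha_fdr = alpha,
                 scale = cm$scale, parcel_ids = parcel_ids)
}

#' @export
print.inadmissible_network <- function(x, ...) {
  cat("<inadmissible_network> scale ", x$scale, ": required ", x$m_required,
      " edges at mean degree ", sprintf("%.2f", x$k_net), " but only ",
      x$m_significant, " edges survive FDR at alpha = ", x$alpha_fdr,
      "\n", sep = "")
  invisible(x)
}

#' Is a thresholding result admissible?
#'
#' @param x result of [threshold_network()].
#' @return `TRUE` for a [binary_network], `FALSE` for an inadmissible scale.
#' @export
is_admissible <- function(x) inherits(x, "binary_network")

#' Write a binary network's adjacency matrix and edge list
#'
#' The adjacency matrix is written as a square whitespace-delimited 0/1
#' matrix (BrainNet Viewer `.edge` compatible, no header); the edge list as
#' a TSV of `parcel_a`, `parcel_b` and (when a correlation matrix is
#' supplied) `r`.
#'
#' @param net a [binary_network].
#' @param adjacency_path,edgelist_path output paths (either may be `NULL`).
#' @param atlas optional [parcel_atlas] for labelled edge lists.
#' @param cm optional [correlation_matrix] to annotate edge weights.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, adjacency_path = NULL, edgelist_path = NULL,
                          atlas = NULL, cm = NULL) {
  stopifnot(inherits(net, "binary_network"))
  written <- character(0)
  if (!is.null(adjacency_path)) {
    utils::write.table(net$adjacency, adjacency_path, sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    written <- c(written, adjacency_path)
  }
  if (!is.null(edgelist_path)) {
    ut <- which(upper.tri(net$adjacency) & net$adjacency == 1L,
                arr.ind = TRUE)
    labels <- if (!is.null(atlas)) .parcel_labels(atlas)
              else as.character(net$parcel_ids)
    df <- data.frame(parcel_a = labels[ut[, 1]], parcel_b = labels[ut[, 2]])
    if (!is.null(cm)) df$r <- cm$r[ut]
    con <- file(edgelist_path, "w")
    writeLines(provenance_header(list(scale = net$scale, R = net$R,
                                      alpha_fdr = net$alpha_fdr)), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    written <- c(written, edgelist_path)
  }
  invisible(written)
}
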