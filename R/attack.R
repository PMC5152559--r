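## Giant-component size and fixed-denominator efficiency along one removal
## order. Returns a (n+1) x 2 matrix for fractions 0, 1/n, ..., 1.
.attack_trajectory <- function(adj, order_idx, n_intact) {
  n <- nrow(adj)
  gc0 <- .gc_size(adj)
  e0 <- global_efficiency(adj, normalization_n = n_intact)
  rel_g <- numeric(n + 1L)
  rel_e <- numeric(n + 1L)
  rel_g[1] <- 1
  rel_e[1] <- 1
  alive <- rep(TRUE, n)
  for (step in seq_len(n)) {
    alive[order_idx[step]] <- FALSE
    if (!any(alive)) {
      rel_g[step + 1L] <- 0
      rel_e[step + 1L] <- 0
      next
    }
    sub <- adj[alive, alive, drop = FALSE]
    rel_g[step + 1L] <- .gc_size(sub) / gc0
    rel_e[step + 1L] <- if (e0 > 0)
      global_efficiency(sub, normalization_n = n_intact) / e0 else 0
  }
  cbind(rel_giant = rel_g, rel_efficiency = rel_e)
}

.gc_size <- function(adj) {
  if (nrow(adj) == 0L) return(0L)
  if (sum(adj) == 0L) return(1L)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  max(igraph::components(g)$csize)
}

#' Random-error and targeted-attack robustness curves
#'
#' Removes nodes one at a time (a grid of fractions `0, 1/n, ..., 1`) and
#' tracks the giant-component size and global efficiency relative to the
#' intact network. Targeted attack removes nodes in descending order of the
#' INTACT network's degree (static ranking, ties by parcel id); random
#' error averages over `n_repeats` seeded random orders. Efficiency keeps
#' the intact node count in its denominator throughout, so curves from
#' different removal stages are comparable.
#'
#' @param net a [binary_network] with >= 2 nodes.
#' @param mode `"random"` or `"targeted"`.
#' @param n_repeats number of random removal orders (ignored for targeted).
#' @param seed integer seed.
#' @return Object of class `attack_curve`: `mode`, `fractions_removed`,
#'   `rel_giant`, `rel_efficiency` (mean curves), `realizations` (list of
#'   per-order matrices in random mode), `n_repeats`, `seed`.
#' @export
attack <- function(net, mode = c("random", "targeted"), n_repeats = 100L,
                   seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "binary_network"), n_repeats >= 1L)
  n <- nrow(net$adjacency)
  stopifnot(n >= 2L)
  fractions <- seq(0, n) / n
  if (mode == "targeted") {
    deg <- node_degree(net)
    ord <- order(-deg, net$parcel_ids)
    traj <- .attack_trajectory(net$adjacency, ord, n)
    realizations <- list(traj)
  } else {
    set.seed(as.integer(seed))
    realizations <- lapply(seq_len(n_repeats), function(i)
      .attack_trajectory(net$adjacency, sample.int(n), n))
    traj <- Reduce(`+`, realizations) / n_repeats
  }
  structure(list(mode = mode, fractions_removed = fractions,
                 rel_giant = unname(traj[, "rel_giant"]),
                 rel_efficiency = unname(traj[, "rel_efficiency"]),
                 realizations = realizations,
                 n_repeats = if (mode == "random") as.integer(n_repeats)
                             else 1L,
                 seed = as.integer(seed)),
            class = "attack_curve")
}

#' @export
print.attack_curve <- function(x, ...) {
  half <- which.min(abs(x$fractions_removed - 0.5))
  cat("<attack_curve> ", x$mode, " removal over ",
      length(x$fractions_removed) - 1L, " nodes",
      if (x$mode == "random") paste0(" (", x$n_repeats, " repeats)"),
      sprintf(": rel_giant at 50%% removal = %.2f\n", x$rel_giant[half]),
      sep = "")
  invisible(x)
}

#' Area under an attack curve
#'
#' Trapezoidal area under the relative giant-component (or efficiency)
#' trajectory; smaller area means faster degradation.
#'
#' @param curve an [attack()] result.
#' @param what `"rel_giant"` or `"rel_efficiency"`.
#' @return Scalar area in `[0, 1]`.
#' @export
attack_auc <- function(curve, what = c("rel_giant", "rel_efficiency")) {
  what <- match.arg(what)
  y <- curve[[what]]
  x <- curve$fractions_removed
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Attack curves for the network and its null families
#'
#' Runs random-error and targeted-attack simulations for the input network,
#' for degree-matched rewired null graphs and for scale-free null graphs of
#' the same node and edge count, giving the three-family comparison of
#' robustness.
#'
#' @param net a [binary_network].
#' @param n_realizations null graphs per family (default 10).
#' @param n_repeats random-error orders per graph (default 20).
#' @param seed integer seed.
#' @return Object of class `null_comparison`: nested list
#'   `curves[[family]][[mode]]` holding per-realization [attack()] results
#'   (`family` in `brain`, `random`, `scale_free`; the brain family has a
#'   single realization), plus a `mean_curves` summary data frame.
#' @export
compare_null_models <- function(net, n_realizations = 10L, n_repeats = 20L,
                                seed = 1L) {
  stopifnot(inherits(net, "binary_network"), n_realizations >= 1L)
  n <- nrow(net$adjacency)
  seed <- as.integer(seed)
  deg <- node_degree(net)
  make_family <- function(family, k) {
    switch(family,
      brain = net,
      random = make_null_graph("random", n, net$m,
                               params = list(degree_sequence = deg),
                               seed = seed + 1000L * k),
      scale_free = make_null_graph("scale_free", n, net$m,
                                   seed = seed + 2000L * k))
  }
  families <- c("brain", "random", "scale_free")
  curves <- lapply(families, function(fam) {
    n_real <- if (fam == "brain") 1L else n_realizations
    reals <- lapply(seq_len(n_real), function(k) {
      g <- make_family(fam, k)
      list(random = attack(g, "random", n_repeats = n_repeats,
                           seed = seed + 10L * k),
           targeted = attack(g, "targeted", seed = seed + 10L * k))
    })
    list(random = lapply(reals, `[[`, "random"),
         targeted = lapply(reals, `[[`, "targeted"))
  })
  names(curves) <- families
  mean_curves <- do.call(rbind, lapply(families, function(fam)
    do.call(rbind, lapply(c("random", "targeted"), function(mode) {
      cs <- curves[[fam]][[mode]]
      data.frame(family = fam, mode = mode,
                 fraction = cs[[1]]$fractions_removed,
                 rel_giant = rowMeans(sapply(cs, `[[`, "rel_giant")),
                 rel_efficiency = rowMeans(sapply(cs, `[[`,
                                                  "rel_efficiency")))
    }))))
  structure(list(curves = curves, mean_curves = mean_curves,
                 n_realizations = as.integer(n_realizations),
                 seed = seed),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat("<null_comparison> targeted-attack giant-component AUC:\n")
  for (fam in names(x$curves)) {
    aucs <- vapply(x$curves[[fam]]$targeted, attack_auc, numeric(1))
    cat(sprintf("  %-10s %.3f\n", fam, mean(aucs)))
  }
  invisible(x)
}

#' Write attack curves as long-format TSV
#'
#' Columns: family, mode, realization, fraction, rel_giant, rel_efficiency.
#'
#' @param comparison a [compare_null_models()] result (or a single
#'   [attack()] curve).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_attack_curves <- function(comparison, path) {
  rows <- if (inherits(comparison, "attack_curve")) {
    data.frame(family = "network", mode = comparison$mode, realization = 1L,
               fraction = comparison$fractions_removed,
               rel_giant = comparison$rel_giant,
               rel_efficiency = comparison$rel_efficiency)
  } else {
    do.call(rbind, lapply(names(comparison$curves), function(fam)
      do.call(rbind, lapply(c("random", "targeted"), function(mode) {
        cs <- comparison$curves[[fam]][[mode]]
        do.call(rbind, lapply(seq_along(cs), function(k)
          data.frame(family = fam, mode = mode, realization = k,
                     fraction = cs[[k]]$fractions_removed,
                     rel_giant = cs[[k]]$rel_giant,
                     rel_efficiency = cs[[k]]$rel_efficiency)))
      }))))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(list()), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Lesion "connections-at-risk" report
#'
#' Enumerates the edges incident to a set of tumour-adjacent parcels — the
#' connections an extended resection could sever — and classifies each by
#' anatomical range from the atlas labels: `intra_lobar` (same lobe, same
#' hemisphere), `intra_hemispheric` (same hemisphere, different lobe) or
#' `inter_hemispheric`. The same enumeration on the contralateral homolog
#' parcels provides the within-subject control. Lesion parcels without a
#' homolog are reported and excluded from the contrast.
#'
#' @param net a [binary_network] whose `parcel_ids` index into `atlas`.
#' @param atlas a [parcel_atlas].
#' @param lesion_parcels integer ids of tumour-adjacent parcels.
#' @return Object of class `lesion_report`: `at_risk_parcels`,
#'   `at_risk_edges` and `contralateral_edges` (data frames with parcel ids,
#'   labels and `class`), `class_counts` (matrix classes x side),
#'   `unmatched_parcels`.
#' @export
connections_at_risk <- function(net, atlas, lesion_parcels) {
  stopifnot(inherits(net, "binary_network"), inherits(atlas, "parcel_atlas"))
  lesion_parcels <- as.integer(lesion_parcels)
  unknown <- setdiff(lesion_parcels, atlas$id)
  if (length(unknown) > 0L)
    stop("lesion parcels not in atlas: ", paste(unknown, collapse = ", "))
  homologs <- atlas$homolog_id[match(lesion_parcels, atlas$id)]
  unmatched <- lesion_parcels[is.na(homologs)]
  if (length(unmatched) > 0L)
    warning("lesion parcel(s) without contralateral homolog excluded from ",
            "the contrast: ", paste(unmatched, collapse = ", "))
  matched <- lesion_parcels[!is.na(homologs)]
  contralateral <- homologs[!is.na(homologs)]
  classes <- c("intra_lobar", "intra_hemispheric", "inter_hemispheric")
  enumerate <- function(focus) {
    idx <- which(net$parcel_ids %in% focus)
    ut <- which(upper.tri(net$adjacency) & net$adjacency == 1L,
                arr.ind = TRUE)
    touch <- ut[, 1] %in% idx | ut[, 2] %in% idx
    ut <- ut[touch, , drop = FALSE]
    ids_a <- net$parcel_ids[ut[, 1]]
    ids_b <- net$parcel_ids[ut[, 2]]
    a <- atlas[match(ids_a, atlas$id), ]
    b <- atlas[match(ids_b, atlas$id), ]
    cls <- ifelse(a$hemisphere != b$hemisphere, "inter_hemispheric",
                  ifelse(a$lobe == b$lobe, "intra_lobar",
                         "intra_hemispheric"))
    data.frame(parcel_a = ids_a, parcel_b = ids_b,
               label_a = .parcel_labels(atlas)[match(ids_a, atlas$id)],
               label_b = .parcel_labels(atlas)[match(ids_b, atlas$id)],
               class = factor(cls, levels = classes),
               stringsAsFactors = FALSE)
  }
  at_risk <- enumerate(lesion_parcels)
  contra <- enumerate(contralateral)
  counts <- cbind(at_risk = table(at_risk$class),
                  contralateral = table(contra$class))
  structure(list(at_risk_parcels = sort(lesion_parcels),
                 lesioned_with_homolog = matched,
                 contralateral_parcels = contralateral,
                 unmatched_parcels = unmatched,
                 at_risk_edges = at_risk,
                 contralateral_edges = contra,
                 class_counts = counts),
            class = "lesion_report")
}

#' @export
print.lesion_report <- function(x, ...) {
  cat("<lesion_report> ", length(x$at_risk_parcels), " at-risk parcels, ",
      nrow(x$at_risk_edges), " at-risk edges (contralateral: ",
      nrow(x$contralateral_edges), ")\n", sep = "")
  print(x$class_counts)
  invisible(x)
}

#' Write a lesion report as TSV edge list plus JSON summary
#'
#' @param report a [connections_at_risk()] result.
#' @param edges_path TSV path for the combined at-risk/contralateral edge
#'   list (side column distinguishes them); may be `NULL`.
#' @param summary_path JSON path for the per-class counts; may be `NULL`.
#' @return Invisibly, the paths written.
#' @export
write_lesion_report <- function(report, edges_path = NULL,
                                summary_path = NULL) {
  stopifnot(inherits(report, "lesion_report"))
  written <- character(0)
  if (!is.null(edges_path)) {
    tag <- function(df, side) {
      df$side <- rep(side, nrow(df))    # safe for zero-row edge lists
      df[, c("side", setdiff(names(df), "side"))]
    }
    both <- rbind(tag(report$at_risk_edges, "at_risk"),
                  tag(report$contralateral_edges, "contralateral"))
    con <- file(edges_path, "w")
    writeLines(provenance_header(list()), con)
    utils::write.table(both, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    written <- c(written, edges_path)
  }
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      list(at_risk_parcels = report$at_risk_parcels,
           unmatched_parcels = report$unmatched_parcels,
           class_counts = as.data.frame.matrix(report$class_counts)),
      summary_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, summary_path)
  }
  invisible(written)
}
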