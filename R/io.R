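#' Provenance header lines for text outputs
#'
#' Every text artifact the package writes starts with `#`-prefixed comment
#' lines recording the package version and any stage-specific fields
#' (seeds, thresholds, configuration hash), so an output file is traceable
#' to the run that produced it.
#'
#' @param fields named list of values to record.
#' @return Character vector of comment lines.
#' @export
provenance_header <- function(fields = list()) {
  base <- list(generator = paste0("lesionnet ",
                                  as.character(utils::packageVersion("lesionnet"))))
  fields <- c(base, fields)
  fields <- fields[!vapply(fields, function(v) is.null(v) ||
                             (length(v) == 1 && is.na(v)), TRUE)]
  vapply(names(fields), function(nm)
    sprintf("# %s: %s", nm, paste(format(fields[[nm]]), collapse = ",")),
    character(1), USE.NAMES = FALSE)
}

#' Write / read a per-scale correlation matrix
#'
#' Square whitespace-delimited text with a parcel-label header row and
#' column, preceded by a provenance comment block.
#'
#' @param cm a [correlation_matrix].
#' @param path file path.
#' @return `read_correlation_matrix()` returns a [correlation_matrix].
#' @export
write_correlation_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "correlation_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(list(scale = cm$scale,
                                    n_usable = cm$n_usable)), con)
  utils::write.table(cm$r, con, sep = " ", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_correlation_matrix
#' @export
read_correlation_matrix <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_field <- function(key) {
    hit <- grep(sprintf("^# %s: ", key), meta, value = TRUE)
    if (length(hit) == 0L) NA else sub(sprintf("^# %s: ", key), "", hit[1])
  }
  r <- as.matrix(utils::read.table(text = lines[!startsWith(lines, "#")],
                                   header = TRUE, row.names = 1,
                                   check.names = FALSE))
  correlation_matrix(r,
                     scale = suppressWarnings(as.integer(get_field("scale"))),
                     n_usable = suppressWarnings(
                       as.integer(get_field("n_usable"))))
}

## integer colour index per lobe, stable across exports
.lobe_codes <- function(atlas) {
  lobes <- c("frontal", "central", "limbic", "occipital", "parietal",
             "temporal", "insula", "subcortical", "cerebellum", "vermis")
  extra <- setdiff(unique(atlas$lobe), lobes)
  match(atlas$lobe, c(lobes, extra))
}

#' Export a network for the BrainNet Viewer
#'
#' Writes the `.node` file (six whitespace columns: x, y, z, colour index
#' coding the lobe, node size, label) and the `.edge` file (square 0/1
#' matrix). Node sizes are the selected metric linearly rescaled to
#' `[1, 10]`; a constant metric maps to size 5.
#'
#' @param net a [binary_network].
#' @param atlas a [parcel_atlas] covering `net$parcel_ids`.
#' @param node_size_metric numeric vector (one value per node), e.g. degree
#'   or clustering; defaults to degree.
#' @param node_path,edge_path output paths.
#' @return Invisibly, the two paths.
#' @export
export_brainnet <- function(net, atlas, node_size_metric = NULL,
                            node_path, edge_path) {
  stopifnot(inherits(net, "binary_network"), inherits(atlas, "parcel_atlas"))
  at <- atlas[match(net$parcel_ids, atlas$id), ]
  if (anyNA(at$id))
    stop("atlas does not cover all network parcel ids")
  if (is.null(node_size_metric)) node_size_metric <- node_degree(net)
  if (length(node_size_metric) != nrow(at))
    stop("node_size_metric must have one value per node")
  rng <- range(node_size_metric)
  size <- if (diff(rng) == 0) rep(5, nrow(at))
          else 1 + 9 * (node_size_metric - rng[1]) / diff(rng)
  node <- data.frame(x = at$x, y = at$y, z = at$z,
                     colour = .lobe_codes(at),
                     size = round(size, 4),
                     label = gsub(" ", ".", .parcel_labels(at)))
  utils::write.table(node, node_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(net$adjacency, edge_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(node_path, edge_path))
}

#' Export circular-plot (Circos-style) tables
#'
#' Writes the three tables a circular connectogram needs: a band table
#' (lobe, hemisphere, parcel, anterior-posterior order within the lobe), a
#' link table (`parcel_a`, `parcel_b`, `at_risk` flag) and a heatmap table
#' (degree, clustering, information centrality per parcel — the three inner
#' rings).
#'
#' @param net a [binary_network].
#' @param metrics a [node_metrics()] table for the same network.
#' @param atlas a [parcel_atlas].
#' @param lesion optional [connections_at_risk()] report; its at-risk edges
#'   are flagged in the link table.
#' @param band_path,link_path,heatmap_path output paths.
#' @return Invisibly, the three paths.
#' @export
export_circular <- function(net, metrics, atlas, lesion = NULL,
                            band_path, link_path, heatmap_path) {
  stopifnot(inherits(net, "binary_network"), inherits(metrics, "node_metrics"),
            inherits(atlas, "parcel_atlas"))
  at <- atlas[match(net$parcel_ids, atlas$id), ]
  ## bands: parcels grouped by hemisphere then lobe, ordered
  ## anterior -> posterior (descending y) within each lobe
  ord <- order(at$hemisphere, .lobe_codes(at), -at$y)
  band <- data.frame(lobe = at$lobe[ord], hemisphere = at$hemisphere[ord],
                     parcel = .parcel_labels(at)[ord],
                     ap_order = stats::ave(seq_along(ord), at$hemisphere[ord],
                                           at$lobe[ord],
                                           FUN = seq_along))
  utils::write.table(band, band_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ut <- which(upper.tri(net$adjacency) & net$adjacency == 1L,
              arr.ind = TRUE)
  ids_a <- net$parcel_ids[ut[, 1]]
  ids_b <- net$parcel_ids[ut[, 2]]
  at_risk <- rep(FALSE, nrow(ut))
  if (!is.null(lesion)) {
    stopifnot(inherits(lesion, "lesion_report"))
    key <- paste(pmin(ids_a, ids_b), pmax(ids_a, ids_b))
    risk_key <- paste(pmin(lesion$at_risk_edges$parcel_a,
                           lesion$at_risk_edges$parcel_b),
                      pmax(lesion$at_risk_edges$parcel_a,
                           lesion$at_risk_edges$parcel_b))
    at_risk <- key %in% risk_key
  }
  link <- data.frame(parcel_a = .parcel_labels(atlas)[match(ids_a, atlas$id)],
                     parcel_b = .parcel_labels(atlas)[match(ids_b, atlas$id)],
                     at_risk = at_risk)
  utils::write.table(link, link_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hm <- data.frame(parcel = .parcel_labels(at),
                   degree = metrics$degree,
                   clustering = metrics$clustering,
                   information_centrality = metrics$information_centrality)
  utils::write.table(hm, heatmap_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(band_path, link_path, heatmap_path))
}
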