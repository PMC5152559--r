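#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with validated defaults
#' mirroring the packaged study conditions: TR 2.42 s, 15 s initial
#' discard, wavelet scales 1-5, FDR level 0.05, 100-graph null ensembles
#' and 100 random-error repeats.
#'
#' @param tr_seconds repetition time (s).
#' @param discard_seconds initial steady-state interval to drop (s).
#' @param scales wavelet scale indices to analyse.
#' @param alpha_fdr FDR level for thresholding admissibility.
#' @param n_nulls rewired-null ensemble size for small-world indices.
#' @param attack_repeats random-error removal orders.
#' @param null_realizations null graphs per family in robustness
#'   comparisons.
#' @param seed master integer seed.
#' @param wavelet wavelet filter name.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(tr_seconds = 2.42, discard_seconds = 15,
                            scales = 1:5, alpha_fdr = 0.05,
                            n_nulls = 100L, attack_repeats = 100L,
                            null_realizations = 10L, seed = 1L,
                            wavelet = "la8") {
  stopifnot(tr_seconds > 0, discard_seconds >= 0, length(scales) >= 1,
            all(scales >= 1), alpha_fdr > 0, alpha_fdr < 1,
            n_nulls >= 1, attack_repeats >= 1, null_realizations >= 1)
  structure(list(tr_seconds = tr_seconds,
                 discard_seconds = discard_seconds,
                 scales = as.integer(scales), alpha_fdr = alpha_fdr,
                 n_nulls = as.integer(n_nulls),
                 attack_repeats = as.integer(attack_repeats),
                 null_realizations = as.integer(null_realizations),
                 seed = as.integer(seed), wavelet = wavelet),
            class = "pipeline_config")
}

#' Run the full connectome pipeline on a cohort
#'
#' Orchestrates the analysis end to end: per-subject MODWT decomposition
#' and wavelet correlation, group averaging per scale, fixed-mean-degree
#' thresholding with the FDR admissibility veto, small-world and nodal
#' metrics on the analysis network, degree-distribution model selection,
#' robustness simulation against null families, and — when a lesion parcel
#' set is supplied — the connections-at-risk report. Each stage failure
#' aborts with the stage name.
#'
#' @param cohort a [simulate_cohort()] result, or a list of [bold_ts]
#'   objects (e.g. from [read_timeseries()]).
#' @param atlas a [parcel_atlas]; defaults to the cohort's ground-truth
#'   atlas or [default_atlas()].
#' @param config a [pipeline_config()].
#' @param lesion_parcels optional integer ids of tumour-adjacent parcels.
#' @param analysis_scale which admissible scale to carry into metrics and
#'   robustness; default picks the admissible scale with the highest
#'   small-world delta.
#' @param output_dir optional directory; when given, all artifact files
#'   (correlation matrices, adjacency, metrics, fit report, attack curves,
#'   lesion report, BrainNet and circular exports) are written there.
#' @return Object of class `pipeline_result`: `group_matrices`, `networks`
#'   (per requested scale: [binary_network] or `inadmissible_network`),
#'   `admissible_scales`, `analysis_scale`, `summaries` (per admissible
#'   scale [small_world_summary()]), `metrics`, `hub_table`,
#'   `degree_selection`, `robustness`, `lesion_report`, `config`.
#' @export
run_pipeline <- function(cohort, atlas = NULL, config = pipeline_config(),
                         lesion_parcels = NULL, analysis_scale = NULL,
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  subjects <- if (inherits(cohort, "bold_cohort")) cohort$subjects
              else cohort
  if (is.null(atlas)) {
    atlas <- if (inherits(cohort, "bold_cohort")) cohort$ground_truth$atlas
             else default_atlas()
  }
  max_scale <- max(config$scales)

  per_subject <- stage("wavelet_correlation", lapply(subjects, function(ts) {
    ts2 <- bold_ts(unclass(ts), config$tr_seconds,
                   subject_id = attr(ts, "subject_id") %||% "s",
                   discard_seconds = config$discard_seconds)
    wavelet_correlation(modwt(ts2, max_scale = max_scale,
                              wavelet = config$wavelet))
  }))
  group <- stage("group_average", lapply(seq_along(config$scales),
    function(k) {
      j <- config$scales[k]
      group_average(lapply(per_subject, function(ms)
        ms[[which(vapply(ms, `[[`, 0L, "scale") == j)]]))
    }))
  names(group) <- paste0("scale", config$scales)

  networks <- stage("threshold", lapply(group, function(cm)
    threshold_network(cm, alpha = config$alpha_fdr,
                      parcel_ids = atlas$id)))
  admissible <- config$scales[vapply(networks, is_admissible, TRUE)]
  if (length(admissible) == 0L)
    stop("pipeline stage 'threshold' failed: no wavelet scale produced an ",
         "admissible network at the required mean degree", call. = FALSE)

  summaries <- stage("small_world", lapply(admissible, function(j) {
    small_world_summary(networks[[paste0("scale", j)]],
                        n_nulls = config$n_nulls, seed = config$seed)
  }))
  names(summaries) <- paste0("scale", admissible)

  if (is.null(analysis_scale)) {
    deltas <- vapply(summaries, `[[`, 0, "delta")
    analysis_scale <- admissible[which.max(deltas)]
  } else if (!analysis_scale %in% admissible) {
    stop("pipeline stage 'small_world' failed: requested analysis scale ",
         analysis_scale, " is not admissible", call. = FALSE)
  }
  net <- networks[[paste0("scale", analysis_scale)]]

  metrics <- stage("metrics", node_metrics(net, atlas))
  hubs <- stage("metrics", hub_table(metrics, atlas))
  degsel <- stage("degreefit",
                  select_degree_model(metrics$degree[metrics$degree >= 1],
                                      seed = config$seed))
  robustness <- stage("attack",
                      compare_null_models(net,
                                          n_realizations =
                                            config$null_realizations,
                                          n_repeats = config$attack_repeats,
                                          seed = config$seed))
  lesion <- if (!is.null(lesion_parcels))
    stage("lesion", connections_at_risk(net, atlas, lesion_parcels))

  result <- structure(list(group_matrices = group, networks = networks,
                           admissible_scales = admissible,
                           analysis_scale = analysis_scale,
                           summaries = summaries, metrics = metrics,
                           hub_table = hubs, degree_selection = degsel,
                           robustness = robustness, lesion_report = lesion,
                           atlas = atlas, config = config),
                      class = "pipeline_result")
  if (!is.null(output_dir))
    stage("export", .write_pipeline_artifacts(result, output_dir))
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> scales analysed: ",
      paste(x$config$scales, collapse = ", "),
      "; admissible: ", paste(x$admissible_scales, collapse = ", "),
      "; analysis scale: ", x$analysis_scale, "\n", sep = "")
  print(x$summaries[[paste0("scale", x$analysis_scale)]])
  cat("degree distribution best fit: ", x$degree_selection$best, "\n",
      sep = "")
  if (!is.null(x$lesion_report)) print(x$lesion_report)
  invisible(x)
}

.write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(result$group_matrices))
    write_correlation_matrix(result$group_matrices[[nm]],
                             file.path(dir, paste0("correlation_", nm,
                                                   ".txt")))
  net <- result$networks[[paste0("scale", result$analysis_scale)]]
  write_network(net, file.path(dir, "network.edge"),
                file.path(dir, "network_edges.tsv"), atlas = result$atlas,
                cm = result$group_matrices[[paste0("scale",
                                                   result$analysis_scale)]])
  write_metrics(result$hub_table, file.path(dir, "node_metrics.tsv"))
  for (nm in names(result$summaries))
    write_summary(result$summaries[[nm]],
                  file.path(dir, paste0("small_world_", nm, ".json")))
  write_degree_report(result$degree_selection,
                      result$metrics$degree,
                      file.path(dir, "degree_fit.tsv"),
                      file.path(dir, "degree_histogram.tsv"))
  write_attack_curves(result$robustness, file.path(dir, "attack_curves.tsv"))
  export_brainnet(net, result$atlas,
                  node_size_metric = result$metrics$clustering,
                  node_path = file.path(dir, "network.node"),
                  edge_path = file.path(dir, "network_adjacency.edge"))
  if (!is.null(result$lesion_report)) {
    write_lesion_report(result$lesion_report,
                        file.path(dir, "lesion_edges.tsv"),
                        file.path(dir, "lesion_summary.json"))
    export_circular(net, result$metrics, result$atlas,
                    lesion = result$lesion_report,
                    band_path = file.path(dir, "circular_bands.tsv"),
                    link_path = file.path(dir, "circular_links.tsv"),
                    heatmap_path = file.path(dir, "circular_heatmap.tsv"))
  } else {
    export_circular(net, result$metrics, result$atlas,
                    band_path = file.path(dir, "circular_bands.tsv"),
                    link_path = file.path(dir, "circular_links.tsv"),
                    heatmap_path = file.path(dir, "circular_heatmap.tsv"))
  }
  invisible(dir)
}
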