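#' Modular small-world covariance ground truth
#'
#' Builds the block-structured covariance matrix a synthetic cohort is drawn
#' from: parcels are assigned to `n_modules` communities (contiguous blocks
#' of the atlas ordering, so left/right homolog pairs fall in the same
#' module), with off-diagonal covariance `within_r` inside a module and
#' `between_r` across modules, unit diagonal. The result is projected to the
#' nearest positive-semidefinite matrix (negative eigenvalues clipped to 0,
#' diagonal renormalised to 1) if the block construction is not already PSD.
#'
#' @param atlas a [parcel_atlas].
#' @param n_modules number of communities, >= 1.
#' @param within_r,between_r off-diagonal correlations; require
#'   `0 <= between_r < within_r < 1` (equality of the two is allowed and
#'   yields an exchangeable covariance).
#' @param seed integer seed recorded in the object (generation itself is
#'   deterministic).
#' @return Object of class `ground_truth`: `covariance`, `module_assignment`
#'   (integer per parcel), `lesioned_parcels` (empty), `attenuation` (1),
#'   `atlas`, `seed`.
#' @export
make_ground_truth <- function(atlas, n_modules = 4L, within_r = 0.5,
                              between_r = 0.1, seed = 1L) {
  stopifnot(inherits(atlas, "parcel_atlas"), n_modules >= 1L,
            between_r >= 0, within_r < 1, between_r <= within_r)
  n <- nrow(atlas)
  modules <- if (n_modules == 1L) rep(1L, n)
             else as.integer(cut(seq_len(n), breaks = n_modules,
                                 labels = FALSE))
  sigma <- matrix(between_r, n, n)
  same <- outer(modules, modules, `==`)
  sigma[same] <- within_r
  diag(sigma) <- 1
  labels <- .parcel_labels(atlas)
  dimnames(sigma) <- list(labels, labels)
  sigma <- .project_psd(sigma)
  structure(list(covariance = sigma,
                 module_assignment = stats::setNames(modules, labels),
                 lesioned_parcels = integer(0),
                 attenuation = 1,
                 atlas = atlas,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$covariance), " parcels, ",
      length(unique(x$module_assignment)), " modules", sep = "")
  if (length(x$lesioned_parcels) > 0L)
    cat(", lesion on ", length(x$lesioned_parcels),
        " parcels (attenuation ", x$attenuation, ")", sep = "")
  cat("\n")
  invisible(x)
}

## Nearest-PSD repair: clip negative eigenvalues, renormalise diagonal to 1.
.project_psd <- function(sigma, tol = 1e-10) {
  eg <- eigen(sigma, symmetric = TRUE)
  if (min(eg$values) >= -tol * max(abs(eg$values))) return(sigma)
  vals <- pmax(eg$values, 0)
  rep_ <- eg$vectors %*% (vals * t(eg$vectors))
  d <- sqrt(pmax(diag(rep_), .Machine$double.eps))
  rep_ <- rep_ / outer(d, d)
  rep_ <- (rep_ + t(rep_)) / 2
  diag(rep_) <- 1
  dimnames(rep_) <- dimnames(sigma)
  eg2 <- eigen(rep_, symmetric = TRUE, only.values = TRUE)$values
  if (min(eg2) < -1e-8)
    stop("covariance not positive semidefinite after projection (min ",
         "eigenvalue ", format(min(eg2)), ")")
  rep_
}

#' Attenuate a lesioned parcel set in the ground truth
#'
#' Scales the off-diagonal covariance of the flagged parcels by a factor in
#' `[0, 1]`, leaving the diagonal at 1, emulating a focal lesion that
#' weakens a region's coupling at local, intra-hemispheric and
#' inter-hemispheric range alike. The operation is `D S D` with `D` diagonal
#' (factor on lesioned parcels) followed by resetting the lesioned diagonal
#' to 1, which preserves positive semidefiniteness; a PSD projection is
#' still applied as a guard.
#'
#' @param gt a [make_ground_truth()] object.
#' @param parcels integer parcel ids to lesion (must exist in the atlas).
#' @param attenuation multiplicative factor in `[0, 1]`; 1 is a no-op, 0
#'   decorrelates the parcels completely.
#' @return A new `ground_truth` with updated covariance and lesion fields.
#' @export
apply_lesion <- function(gt, parcels, attenuation = 0.3) {
  stopifnot(inherits(gt, "ground_truth"),
            attenuation >= 0, attenuation <= 1)
  parcels <- as.integer(parcels)
  unknown <- setdiff(parcels, gt$atlas$id)
  if (length(unknown) > 0L)
    stop("unknown parcel id(s): ", paste(unknown, collapse = ", "))
  idx <- match(parcels, gt$atlas$id)
  d <- rep(1, nrow(gt$covariance))
  d[idx] <- attenuation
  sigma <- gt$covariance * outer(d, d)
  diag(sigma) <- 1
  gt$covariance <- .project_psd(sigma)
  gt$lesioned_parcels <- sort(unique(c(gt$lesioned_parcels, parcels)))
  gt$attenuation <- attenuation
  gt
}

#' Simulate a cohort of parcel time series
#'
#' Each subject's series is a zero-mean multivariate Gaussian with the
#' ground-truth covariance, passed through an AR(1) temporal filter
#' (coefficient `ar_coef`, then rescaled to unit marginal variance) so the
#' wavelet scales carry unequal power as BOLD-like 1/f spectra do, plus
#' independent white measurement noise of standard deviation `noise_sd`.
#' Per-subject seeds are derived deterministically from the master seed.
#'
#' @param gt a `ground_truth`.
#' @param n_subjects number of subjects (default 5).
#' @param n_volumes volumes per subject (default 269); must exceed 32 so
#'   that scale 3 retains non-boundary coefficients.
#' @param tr_seconds repetition time (default 2.42 s).
#' @param noise_sd white-noise standard deviation relative to the
#'   unit-variance latent signal (default 1).
#' @param ar_coef AR(1) smoothing coefficient in `[0, 1)` (default 0.3).
#' @param seed master integer seed.
#' @return Object of class `bold_cohort`: list of [bold_ts] `subjects`,
#'   plus `ground_truth`, `tr_seconds`, `seed`.
#' @export
simulate_cohort <- function(gt, n_subjects = 5L, n_volumes = 269L,
                            tr_seconds = 2.42, noise_sd = 1,
                            ar_coef = 0.3, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"), n_subjects >= 1L,
            noise_sd >= 0, ar_coef >= 0, ar_coef < 1)
  if (n_volumes <= 32L)
    stop("n_volumes must exceed 32: scale 3 needs (2^3 - 1) * 7 = 49 ",
         "boundary coefficients plus usable ones; shorter series leave ",
         "no non-boundary wavelet coefficients at scale 3")
  sigma <- gt$covariance
  n <- nrow(sigma)
  eg <- eigen(sigma, symmetric = TRUE)
  root <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sub_seed <- (as.integer(seed) + 7919L * s) %% .Machine$integer.max
    set.seed(sub_seed)
    z <- matrix(stats::rnorm(n_volumes * n), n_volumes, n) %*% root
    if (ar_coef > 0) {
      z <- apply(z, 2L, function(col)
        stats::filter(col, ar_coef, method = "recursive"))
      z <- z * sqrt(1 - ar_coef^2)   # restore unit marginal variance
    }
    if (noise_sd > 0)
      z <- z + noise_sd * matrix(stats::rnorm(n_volumes * n), n_volumes, n)
    colnames(z) <- colnames(sigma)
    subjects[[s]] <- bold_ts(z, tr_seconds,
                             subject_id = sprintf("sub-%02d", s))
  }
  structure(list(subjects = subjects, ground_truth = gt,
                 tr_seconds = tr_seconds, seed = as.integer(seed)),
            class = "bold_cohort")
}

#' @export
print.bold_cohort <- function(x, ...) {
  cat("<bold_cohort> ", length(x$subjects), " subjects x ",
      nrow(x$subjects[[1]]), " volumes x ", ncol(x$subjects[[1]]),
      " parcels, TR ", x$tr_seconds, " s, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write a cohort as per-subject TSVs plus a ground-truth sidecar
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bold_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort$subjects, function(ts) {
    p <- file.path(dir, paste0(attr(ts, "subject_id"), ".tsv"))
    write_timeseries(ts, p)
    p
  }, character(1))
  gt <- cohort$ground_truth
  sidecar <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(seed = cohort$seed, tr_seconds = cohort$tr_seconds,
         n_subjects = length(cohort$subjects),
         n_volumes = nrow(cohort$subjects[[1]]),
         module_assignment = unname(gt$module_assignment),
         lesioned_parcels = gt$lesioned_parcels,
         attenuation = gt$attenuation),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sidecar))
}

#' Simulated comparison graphs
#'
#' Generates the null-model graphs the empirical network is compared with:
#' uniform random graphs (or degree-preserving rewirings of a reference
#' degree sequence), scale-free graphs with a power-law degree distribution
#' (preferential attachment), and graphs with an exponentially truncated
#' power-law degree sequence. Every generator is followed by random edge
#' addition/removal so the result has exactly `n_edges` edges at `n_nodes`
#' nodes, matching the empirical graph's size.
#'
#' @param kind `"random"`, `"scale_free"` or `"truncated_power_law"`.
#' @param n_nodes,n_edges graph size; `n_edges <= n_nodes (n_nodes - 1) / 2`.
#' @param params optional list: `degree_sequence` (random kind: rewire this
#'   sequence instead of uniform sampling), `alpha` (scale-free power-law
#'   exponent; by default calibrated so the expected mean degree matches
#'   `2 n_edges / n_nodes`), `alpha` and `k_c` (truncated power law;
#'   defaults 1.5 and 20).
#' @param seed integer seed.
#' @return A [binary_network] with `n_edges` edges.
#' @export
make_null_graph <- function(kind = c("random", "scale_free",
                                     "truncated_power_law"),
                            n_nodes, n_edges, params = list(), seed = 1L) {
  kind <- match.arg(kind)
  n_possible <- n_nodes * (n_nodes - 1) / 2
  stopifnot(n_nodes >= 2, n_edges >= 0, n_edges <= n_possible)
  set.seed(as.integer(seed))
  g <- switch(kind,
    random = {
      if (!is.null(params$degree_sequence)) {
        ds <- as.integer(params$degree_sequence)
        if (sum(ds) %% 2L != 0L || length(ds) != n_nodes)
          stop("infeasible degree sequence")
        g0 <- .graph_from_degseq(ds)
        igraph::rewire(g0, igraph::keeping_degseq(niter = 10 * sum(ds) / 2))
      } else {
        igraph::sample_gnm(n_nodes, n_edges)
      }
    },
    scale_free = {
      ## power-law degree sequence P(k) ~ k^-alpha via the configuration
      ## model; alpha calibrated so E[k] matches the target mean degree
      k <- seq_len(n_nodes - 1L)
      target_k <- 2 * n_edges / n_nodes
      alpha <- params$alpha %||% {
        mean_k <- function(a) sum(k^(1 - a)) / sum(k^(-a))
        if (mean_k(1.01) < target_k) 1.01
        else stats::uniroot(function(a) mean_k(a) - target_k,
                            c(1.01, 10))$root
      }
      ds <- sample(k, n_nodes, replace = TRUE, prob = k^(-alpha))
      if (sum(ds) %% 2L != 0L) ds[which.max(ds)] <- ds[which.max(ds)] - 1L
      .graph_from_degseq(ds)
    },
    truncated_power_law = {
      alpha <- params$alpha %||% 1.5
      k_c <- params$k_c %||% 20
      k_max <- n_nodes - 1L
      k <- seq_len(k_max)
      pk <- k^(alpha - 1) * exp(-k / k_c)
      ds <- sample(k, n_nodes, replace = TRUE, prob = pk)
      if (sum(ds) %% 2L != 0L) ds[which.max(ds)] <- ds[which.max(ds)] - 1L
      .graph_from_degseq(ds)
    })
  g <- igraph::simplify(g)
  g <- .adjust_edge_count(g, n_edges)
  adj <- as.matrix(igraph::as_adjacency_matrix(g, type = "both"))
  binary_network(adj, generator = kind, seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Simple graph realising a degree sequence: MCMC edge switching first
## (exact degrees, tolerates zeros), then the Viger-Latapy sampler, then a
## simplified configuration model as last resort.
.graph_from_degseq <- function(ds) {
  for (method in c("edge.switching.simple", "vl", "configuration")) {
    g <- try(suppressWarnings(igraph::sample_degseq(ds, method = method)),
             silent = TRUE)
    if (!inherits(g, "try-error"))
      return(if (method == "configuration") igraph::simplify(g) else g)
    last <- attr(g, "condition")$message
  }
  stop("infeasible degree sequence: ", last)
}

## Add or remove uniformly random edges until the graph has exactly m edges.
.adjust_edge_count <- function(g, m) {
  m_now <- igraph::gsize(g)
  if (m_now > m) {
    drop <- sample.int(m_now, m_now - m)
    g <- igraph::delete_edges(g, drop)
  } else if (m_now < m) {
    n <- igraph::vcount(g)
    adj <- as.matrix(igraph::as_adjacency_matrix(g, type = "both")) > 0
    free <- which(upper.tri(adj) & !adj)
    add <- sample(free, m - m_now)
    ij <- arrayInd(add, dim(adj))
    g <- igraph::add_edges(g, as.vector(t(ij)))
  }
  g
}
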