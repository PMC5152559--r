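#' Parcel-mean BOLD time series
#'
#' Wraps a T x n numeric matrix of parcel-mean signals with its repetition
#' time. An initial steady-state interval can be discarded: `floor(discard_
#' seconds / tr_seconds)` leading volumes are dropped, the closest integer
#' approximation to the requested interval.
#'
#' @param values T x n numeric matrix, columns named by parcel abbreviation.
#' @param tr_seconds repetition time in seconds.
#' @param subject_id subject label.
#' @param discard_seconds initial interval to drop (default 0).
#' @return Object of class `bold_ts` (a matrix with attributes).
#' @export
bold_ts <- function(values, tr_seconds, subject_id = "s1",
                    discard_seconds = 0) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("time series contain missing values")
  stopifnot(tr_seconds > 0, discard_seconds >= 0)
  n_drop <- floor(discard_seconds / tr_seconds)
  if (n_drop >= nrow(values) - 1L)
    stop("discard interval leaves fewer than 2 volumes")
  if (n_drop > 0L)
    values <- values[-seq_len(n_drop), , drop = FALSE]
  structure(values, tr_seconds = tr_seconds, subject_id = subject_id,
            n_discarded = n_drop, class = c("bold_ts", "matrix", "array"))
}

#' @export
print.bold_ts <- function(x, ...) {
  cat("<bold_ts> subject ", attr(x, "subject_id"), ": ", nrow(x),
      " volumes x ", ncol(x), " parcels, TR ", attr(x, "tr_seconds"),
      " s (", attr(x, "n_discarded"), " leading volumes discarded)\n",
      sep = "")
  invisible(x)
}

#' Read / write a subject time-series TSV
#'
#' One row per volume, one column per parcel; the header row carries parcel
#' abbreviations (hemisphere-prefixed, e.g. `l.PQ`).
#'
#' @param path file path.
#' @param tr_seconds repetition time in seconds.
#' @param subject_id subject label; defaults to the file name.
#' @param discard_seconds initial interval to drop.
#' @return A [bold_ts].
#' @export
read_timeseries <- function(path, tr_seconds,
                            subject_id = sub("\\.[^.]*$", "", basename(path)),
                            discard_seconds = 0) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE)
  bold_ts(as.matrix(df), tr_seconds, subject_id, discard_seconds)
}

#' @rdname read_timeseries
#' @param ts a [bold_ts].
#' @export
write_timeseries <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(list(subject_id = attr(ts, "subject_id"),
                                    tr_seconds = attr(ts, "tr_seconds"))),
             con)
  utils::write.table(unclass(ts), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-scale wavelet correlation matrices
#'
#' Pearson correlation between every pair of parcels' MODWT detail
#' coefficients, computed over non-boundary coefficients only. A parcel with
#' zero variance at a scale yields `NA` correlations for its pairs and a
#' warning naming the parcel; the diagonal is always 1.
#'
#' @param decomp a `wavelet_decomp` object (from [modwt()]).
#' @param scales which scale indices to correlate (default: all computed).
#' @return List of `correlation_matrix` objects, one per scale: fields `r`
#'   (n x n symmetric), `scale`, `n_usable`, `mean_r` (mean upper-triangle
#'   correlation) and `band`.
#' @export
wavelet_correlation <- function(decomp, scales = NULL) {
  stopifnot(inherits(decomp, "wavelet_decomp"))
  if (is.null(scales)) scales <- vapply(decomp$scales, `[[`, 0L, "j")
  L <- attr(decomp, "filter_length")
  n_time <- attr(decomp, "n_time")
  lapply(scales, function(j) {
    sc <- decomp$scales[[j]]
    if (sc$n_usable < 8L)
      stop(sprintf("scale %d has only %d usable coefficients (need >= 8)",
                   j, sc$n_usable))
    first <- n_time - sc$n_usable + 1L
    w <- sc$detail[first:n_time, , drop = FALSE]
    sds <- apply(w, 2L, stats::sd)
    degenerate <- which(sds == 0)
    if (length(degenerate) > 0L)
      warning("zero-variance parcel(s) at scale ", j, ": ",
              paste(colnames(w)[degenerate], collapse = ", "),
              "; their correlations are NA")
    r <- suppressWarnings(stats::cor(w))
    r <- (r + t(r)) / 2          # enforce exact symmetry
    diag(r) <- 1
    correlation_matrix(r, scale = j, n_usable = sc$n_usable,
                       band = sc$band)
  })
}

#' Correlation matrix container
#'
#' @param r symmetric correlation matrix with unit diagonal.
#' @param scale wavelet scale index.
#' @param n_usable number of coefficients the correlations were estimated
#'   from (effective sample size).
#' @param band optional frequency band (Hz).
#' @return Object of class `correlation_matrix`.
#' @export
correlation_matrix <- function(r, scale = NA_integer_, n_usable = NA_integer_,
                               band = NULL) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("correlation matrix must be square")
  if (max(abs(r - t(r)), na.rm = TRUE) > 1e-8)
    stop("correlation matrix must be symmetric")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  ut <- upper.tri(r)
  structure(list(r = r, scale = as.integer(scale),
                 n_usable = as.integer(n_usable),
                 mean_r = mean(r[ut], na.rm = TRUE), band = band),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix> ", nrow(x$r), " parcels, scale ", x$scale,
      ", mean r = ", sprintf("%.3f", x$mean_r),
      ", n_usable = ", x$n_usable, "\n", sep = "")
  invisible(x)
}

#' Two-sided p-values for wavelet correlations
#'
#' Each correlation is transformed to Student's t with `effective_df =
#' n_usable - 2` degrees of freedom (boundary coefficients excluded, no
#' further autocorrelation correction) and converted to a two-sided p-value
#' for the null r = 0. `|r| = 1` maps to p = 0 exactly.
#'
#' @param cm a [correlation_matrix].
#' @param effective_df override the degrees of freedom (default
#'   `cm$n_usable - 2`).
#' @return Object of class `significance_matrix`: fields `p` (symmetric,
#'   diagonal `NA`) and `effective_df`.
#' @export
correlation_pvalues <- function(cm, effective_df = NULL) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (is.null(effective_df)) {
    if (is.na(cm$n_usable)) stop("correlation matrix carries no n_usable; ",
                                 "supply effective_df")
    effective_df <- cm$n_usable - 2L
  }
  if (effective_df < 1L) stop("effective_df must be >= 1")
  r <- cm$r
  p <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  off <- !diag(nrow(r))
  rv <- pmin(pmax(r[off], -1), 1)
  tv <- abs(rv) * sqrt(effective_df / pmax(1 - rv^2, .Machine$double.xmin))
  pv <- 2 * stats::pt(tv, df = effective_df, lower.tail = FALSE)
  pv[abs(rv) == 1] <- 0
  p[off] <- pv
  structure(list(p = p, effective_df = effective_df, scale = cm$scale),
            class = "significance_matrix")
}

#' Entrywise group average of correlation matrices
#'
#' Averages r for each edge across subjects, one wavelet scale at a time.
#'
#' @param matrices list of [correlation_matrix] objects at the same scale
#'   and dimension.
#' @return A [correlation_matrix]; `n_usable` is the minimum across
#'   subjects (the conservative effective sample size for significance).
#' @export
group_average <- function(matrices) {
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, TRUE, "correlation_matrix")))
  scales <- vapply(matrices, `[[`, 0L, "scale")
  if (length(unique(scales)) != 1L)
    stop("cannot average across different wavelet scales: ",
         paste(unique(scales), collapse = ", "))
  ns <- vapply(matrices, function(m) nrow(m$r), 0L)
  if (length(unique(ns)) != 1L)
    stop("correlation matrices differ in dimension")
  r_mean <- Reduce(`+`, lapply(matrices, `[[`, "r")) / length(matrices)
  correlation_matrix(r_mean, scale = scales[1],
                     n_usable = min(vapply(matrices, `[[`, 0L, "n_usable")),
                     band = matrices[[1]]$band)
}
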