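#' Wavelet filters for the MODWT
#'
#' Returns the scaling (low-pass) and wavelet (high-pass) filters, already
#' rescaled by 1/sqrt(2) as the maximal overlap discrete wavelet transform
#' requires. `"la8"` is the Daubechies least-asymmetric filter of length 8;
#' `"haar"` is provided for hand-checkable tests.
#'
#' @param name filter name, `"la8"` or `"haar"`.
#' @return list with elements `g` (scaling), `h` (wavelet), `L` (length).
#' @export
wavelet_filter <- function(name = c("la8", "haar")) {
  name <- match.arg(name)
  g <- switch(name,
    la8 = c(-0.0757657147893407, -0.0296355276459541,  0.4976186676324578,
             0.8037387518052163,  0.2978577956055422, -0.0992195435769354,
            -0.0126039672622612,  0.0322231006040713),
    haar = c(1, 1) / sqrt(2))
  L <- length(g)
  ## quadrature mirror: h_l = (-1)^l * g_{L-1-l}
  h <- rev(g) * (-1)^(seq_len(L) - 1L)
  list(name = name, g = g / sqrt(2), h = h / sqrt(2), L = L)
}

#' Frequency band of a wavelet scale
#'
#' The MODWT detail coefficients at scale `j` capture the dyadic frequency
#' band `[f_N / 2^j, f_N / 2^(j-1)]` where `f_N = 1/(2 TR)` is the Nyquist
#' frequency of the sampling. The upper edge of scale 1 is the Nyquist
#' frequency itself.
#'
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param j wavelet scale index, >= 1.
#' @return Named numeric vector `c(band_low_hz, band_high_hz)`.
#' @export
scale_band <- function(tr_seconds, j) {
  stopifnot(tr_seconds > 0, j >= 1, j == as.integer(j))
  f_nyquist <- 1 / (2 * tr_seconds)
  c(band_low_hz = f_nyquist / 2^j, band_high_hz = f_nyquist / 2^(j - 1))
}

#' Number of MODWT coefficients unaffected by the boundary
#'
#' At scale `j` the equivalent filter has width `(2^j - 1)(L - 1) + 1`; the
#' first `(2^j - 1)(L - 1)` coefficients mix in boundary-extended values and
#' are excluded from correlation estimates.
#'
#' @param n_time number of time points.
#' @param j scale index.
#' @param filter_length wavelet filter length `L`.
#' @return Integer count, floored at 0.
#' @export
n_usable_coefficients <- function(n_time, j, filter_length = 8L) {
  max(0L, as.integer(n_time - (2^j - 1) * (filter_length - 1)))
}

## One MODWT pyramid stage by circular filtering: given the approximation
## v (a T x p matrix) at level j-1, returns detail and approximation at
## level j using the filter upsampled by 2^(j-1).
.modwt_stage <- function(v, filt, j) {
  n <- nrow(v)
  w_out <- matrix(0, n, ncol(v))
  v_out <- matrix(0, n, ncol(v))
  shift <- 2^(j - 1L)
  t_idx <- seq_len(n)
  for (l in seq_len(filt$L)) {
    src <- ((t_idx - 1L - (l - 1L) * shift) %% n) + 1L
    w_out <- w_out + filt$h[l] * v[src, , drop = FALSE]
    v_out <- v_out + filt$g[l] * v[src, , drop = FALSE]
  }
  list(w = w_out, v = v_out)
}

#' Maximal overlap discrete wavelet transform
#'
#' Undecimated wavelet decomposition of each column of a time-series matrix.
#' Each scale retains one detail coefficient per time point; coefficients
#' whose equivalent filter overlaps the series boundary are flagged via
#' `n_usable`. With `boundary = "reflection"` the series is extended by its
#' time-reverse before circular filtering and the leading `T` coefficients
#' are kept; with `"periodic"` the series is treated as circular, in which
#' case the transform conserves energy exactly.
#'
#' @param x numeric matrix (T x p) or [bold_ts]; columns are parcels.
#' @param max_scale deepest scale J to compute.
#' @param wavelet filter name passed to [wavelet_filter()].
#' @param boundary `"reflection"` (default) or `"periodic"`.
#' @return Object of class `wavelet_decomp`: list with per-scale entries
#'   (`j`, `detail` T x p matrix, `n_usable`, `band` when the sampling
#'   interval is known), the final approximation `smooth`, and attributes.
#' @export
modwt <- function(x, max_scale = 5L, wavelet = "la8",
                  boundary = c("reflection", "periodic")) {
  boundary <- match.arg(boundary)
  tr <- attr(x, "tr_seconds")
  x <- as.matrix(unclass(x))
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("time series contain missing values")
  n_time <- nrow(x)
  filt <- wavelet_filter(wavelet)
  usable <- vapply(seq_len(max_scale), n_usable_coefficients,
                   integer(1), n_time = n_time, filter_length = filt$L)
  if (usable[max_scale] < 8L)
    stop(sprintf(paste0("series of length %d leaves only %d non-boundary ",
                        "coefficients at scale %d (need >= 8); reduce ",
                        "max_scale"), n_time, usable[max_scale], max_scale))
  v <- if (boundary == "reflection") rbind(x, x[n_time:1L, , drop = FALSE])
       else x
  scales <- vector("list", max_scale)
  for (j in seq_len(max_scale)) {
    st <- .modwt_stage(v, filt, j)
    scales[[j]] <- list(
      j = j,
      detail = st$w[seq_len(n_time), , drop = FALSE],
      n_usable = usable[j],
      band = if (!is.null(tr)) scale_band(tr, j) else NULL)
    v <- st$v
  }
  structure(list(scales = scales,
                 smooth = v[seq_len(n_time), , drop = FALSE]),
            n_time = n_time, wavelet = wavelet, boundary = boundary,
            tr_seconds = tr, filter_length = filt$L,
            parcels = colnames(x),
            class = "wavelet_decomp")
}

#' @export
print.wavelet_decomp <- function(x, ...) {
  cat("<wavelet_decomp> ", length(x$scales), " scales, ",
      attr(x, "n_time"), " time points, ",
      ncol(x$scales[[1]]$detail), " parcels, filter ",
      attr(x, "wavelet"), " (", attr(x, "boundary"), " boundary)\n", sep = "")
  for (s in x$scales) {
    cat(sprintf("  scale %d: n_usable = %d", s$j, s$n_usable))
    if (!is.null(s$band))
      cat(sprintf(", band %.4f-%.4f Hz", s$band[1], s$band[2]))
    cat("\n")
  }
  invisible(x)
}
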