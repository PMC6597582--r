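#' Quantile normalization across samples
#'
#' Classic rank-mean quantile normalization: each column is sorted, the
#' reference distribution is the mean across columns at each rank, and every
#' entry is replaced by the reference value at its within-column rank.  Ties
#' within a column receive the mean of the reference values over the tied
#' rank range.  After normalization all columns share the same multiset of
#' values while within-column ranks are preserved; the transform is
#' idempotent.
#'
#' @param m A numeric matrix, bins in rows and samples in columns, all
#'   entries finite.
#' @return A matrix of the same shape.
#' @export
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m) || any(!is.finite(m))) abort("`m` must contain only finite values")
  if (nrow(m) < 1) abort("`m` must have at least one row")
  if (ncol(m) == 1) {
    inform("quantile_normalize: single sample, returned unchanged")
    return(m)
  }
  ref <- rowMeans(apply(m, 2, sort, method = "radix"))
  out <- m
  n <- nrow(m)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    r <- integer(n)
    r[order(col, method = "radix")] <- seq_len(n)  # positional ranks, ties in input order
    v <- ref[r]
    if (anyDuplicated(col)) v <- ave(v, col, FUN = mean)  # tie-group mean of reference
    out[, j] <- v
  }
  out
}

#' Per-bin standard value across samples
#'
#' Reduces a bins-by-samples matrix to one value per bin: the empirical
#' quantile across samples (linear interpolation between order statistics;
#' at 0.5 with an even sample count, the mean of the two central values).
#' The default, the median, makes the summary robust to high-signal outliers
#' from individual cell types (e.g. copy-number variants) and to low signal
#' from failed inputs.
#'
#' @param m Numeric matrix, bins x samples.
#' @param quantile Probability in `[0, 1]`; default 0.5.
#' @return Numeric vector with one value per bin.
#' @export
standard_value <- function(m, quantile = 0.5) {
  m <- as.matrix(m)
  if (!is_scalar_number(quantile) || quantile < 0 || quantile > 1) {
    abort("`quantile` must be a single number in [0, 1]")
  }
  if (ncol(m) == 1) return(as.numeric(m[, 1]))
  # row-wise type-7 quantile, vectorised over bins
  sorted <- t(apply(m, 1, sort, method = "radix"))
  h <- (ncol(m) - 1) * quantile + 1
  lo <- floor(h); hi <- ceiling(h)
  sorted[, lo] * (1 - (h - lo)) + sorted[, hi] * (h - lo)
}

#' Quantile-normalize a panel and reduce to per-bin standard values
#'
#' Normalizes the depth and multimapping metrics independently across samples
#' (genome-wide, all bins jointly) and selects the 50% quantile across
#' samples as each bin's standard value, giving a cell-type-agnostic signal
#' unaffected by outlying individual samples.
#'
#' @param x A `bin_signal` tibble from [bin_signal()].
#' @param quantile Quantile used for the per-bin standard value.
#' @return A `normalized_signal` tibble: the grid columns plus `zero_map`,
#'   matrix columns `depth_qn`, `multi_qn`, and per-bin `depth_std`,
#'   `multi_std`.
#' @export
normalize_signal <- function(x, quantile = 0.5) {
  if (!inherits(x, "bin_signal")) abort("`x` must be a `bin_signal` object")
  depth_qn <- quantile_normalize(x$depth)
  multi_qn <- quantile_normalize(x$multi)
  out <- tibble(chrom = x$chrom, start = x$start, end = x$end, bin = x$bin,
                mappable = x$mappable, zero_map = x$zero_map)
  out$depth_qn <- depth_qn
  out$multi_qn <- multi_qn
  out$depth_std <- standard_value(depth_qn, quantile)
  out$multi_std <- standard_value(multi_qn, quantile)
  for (a in c("bin_size", "step", "chrom_order")) attr(out, a) <- attr(x, a)
  attr(out, "sample_ids") <- attr(x, "sample_ids")
  attr(out, "quantile") <- quantile
  class(out) <- c("normalized_signal", class(out))
  out
}

#' @method glance normalized_signal
#' @export
glance.normalized_signal <- function(x, ...) {
  tibble(
    n_bins = nrow(x),
    n_samples = length(attr(x, "sample_ids")),
    n_zero_map = sum(x$zero_map),
    depth_std_median = median(x$depth_std),
    multi_std_median = median(x$multi_std)
  )
}

#' Export per-bin standard values as a bedGraph-like table
#'
#' @param x A `normalized_signal` tibble.
#' @param metric `"depth"` or `"multi"`.
#' @return A 4-column tibble (`chrom`, `start`, `end`, `value`).
#' @export
standard_track <- function(x, metric = c("depth", "multi")) {
  metric <- match.arg(metric)
  tibble(chrom = x$chrom, start = x$start, end = x$end,
         value = x[[paste0(metric, "_std")]])
}
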