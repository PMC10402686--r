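# Slice-wise 2-D window filters with replicated borders.
#
# The mean filter accumulates the k*k shifted copies of the padded slice in
# a fixed scan order, so its floating-point result is bit-identical to a
# direct double-loop windowed mean; the median is an exact order statistic.

pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

window_stack <- function(m, k) {
  r <- (k - 1L) %/% 2L
  p <- pad_replicate(m, r)
  n <- length(m)
  out <- matrix(0, n, k * k)
  col <- 0L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    col <- col + 1L
    out[, col] <- as.vector(p[di + seq_len(nrow(m)), dj + seq_len(ncol(m))])
  }
  out
}

filter_slice_mean <- function(m, k) {
  r <- (k - 1L) %/% 2L
  p <- pad_replicate(m, r)
  acc <- matrix(0, nrow(m), ncol(m))
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L))
    acc <- acc + p[di + seq_len(nrow(m)), dj + seq_len(ncol(m))]
  acc / (k * k)
}

filter_slice_median <- function(m, k) {
  w <- window_stack(m, k)
  matrix(row_medians(w), nrow(m), ncol(m))
}

# row-wise median of a matrix with an odd number of columns: the mid order
# statistic (exact, no interpolation)
row_medians <- function(w) {
  if (requireNamespace("matrixStats", quietly = TRUE))
    return(matrixStats::rowMedians(w))
  mid <- (ncol(w) + 1L) %/% 2L
  apply(w, 1L, function(row) sort.int(row, partial = mid)[mid])
}

apply_slicewise <- function(v, fun, k) {
  if (k %% 2L == 0L) stop("kernel size must be odd", call. = FALSE)
  if (k < 1L) stop("kernel size must be >= 1", call. = FALSE)
  out <- v$data
  if (k > 1L) for (s in seq_len(dim(out)[3]))
    out[, , s] <- fun(v$data[, , s], k)
  ct_volume(out, spacing = v$spacing, modality = v$modality,
            value_domain = v$value_domain)
}

#' Mean (average) pre-filter for the reference MVCBCT
#'
#' Slice-wise 2-D uniform mean filter over a square `kernel` x `kernel`
#' window with replicated borders, applied to each axial slice. The
#' combiner smooths the reference MVCBCT this way before assigning voxels
#' to HU bins, so bin membership reflects local tissue rather than noise.
#'
#' @param mvcbct a [ct_volume()] in HU.
#' @param kernel odd window size (default 5).
#' @return The smoothed [ct_volume()].
#' @export
smooth_reference <- function(mvcbct, kernel = 5L) {
  stopifnot(inherits(mvcbct, "ct_volume"))
  if (mvcbct$value_domain != "HU")
    stop("smooth_reference expects an HU volume", call. = FALSE)
  apply_slicewise(mvcbct, filter_slice_mean, as.integer(kernel))
}

#' Median post-filter for the stitched volume
#'
#' Slice-wise 2-D median over a square `kernel` x `kernel` window with
#' replicated borders. Applied to the stitched combination to soften the
#' seams between candidate regions; the output is conventionally named
#' sCT_Blur.
#'
#' @param v a [ct_volume()] in HU.
#' @param kernel odd window size (default 5).
#' @return The filtered [ct_volume()].
#' @export
median_smooth <- function(v, kernel = 5L) {
  stopifnot(inherits(v, "ct_volume"))
  if (v$value_domain != "HU")
    stop("median_smooth expects an HU volume", call. = FALSE)
  apply_slicewise(v, filter_slice_median, as.integer(kernel))
}
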