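#' Stabilizing constants for the structural similarity index
#'
#' SSIM uses two small constants `c1 = (k1 L)^2` and `c2 = (k2 L)^2` to
#' stabilize the luminance and contrast/structure quotients, where `L` is
#' the dynamic range of the data. The default `L = 4000` HU spans the CT
#' range \[-1000, 3000\]; `k1 = 0.01`, `k2 = 0.03` are the conventional
#' choices.
#'
#' @param L dynamic range in HU.
#' @param k1,k2 small positive constants.
#' @return An object of class `ssim_params` with fields `c1`, `c2`, `L`,
#'   `k1`, `k2`.
#' @export
ssim_params <- function(L = 4000, k1 = 0.01, k2 = 0.03) {
  if (L <= 0 || k1 <= 0 || k2 <= 0)
    stop("L, k1, k2 must be positive", call. = FALSE)
  structure(list(c1 = (k1 * L)^2, c2 = (k2 * L)^2, L = L, k1 = k1, k2 = k2),
            class = "ssim_params")
}

masked_pair <- function(a, b, mask) {
  stopifnot(inherits(a, "ct_volume"), inherits(b, "ct_volume"),
            inherits(mask, "mask_volume"))
  stopifnot_same_grid(a, b, mask)
  if (!any(mask$data))
    stop("degenerate input: empty mask", call. = FALSE)
  list(x = a$data[mask$data], y = b$data[mask$data])
}

#' Mean absolute error over a masked region
#'
#' Average of `|a - b|` over the voxels selected by `mask`, in HU.
#'
#' @param a,b [ct_volume()]s on the same grid.
#' @param mask a [mask_volume()] selecting the evaluated voxels.
#' @return MAE in HU.
#' @export
mae <- function(a, b, mask) {
  p <- masked_pair(a, b, mask)
  mean(abs(p$x - p$y))
}

#' Root mean square error over a masked region
#'
#' More sensitive to outlying voxel deviations than [mae()]; always
#' `>= mae` on the same mask (power-mean inequality).
#'
#' @inheritParams mae
#' @return RMSE in HU.
#' @export
rmse <- function(a, b, mask) {
  p <- masked_pair(a, b, mask)
  sqrt(mean((p$x - p$y)^2))
}

#' Peak signal-to-noise ratio over a masked region
#'
#' `10 * log10(MAX^2 / RMSE^2)` in dB. In `"auto"` mode `MAX` is the
#' maximum value of the reference volume `b` within the mask. Identical
#' inputs give `Inf`.
#'
#' @inheritParams mae
#' @param max_value `"auto"` or a fixed HU ceiling (e.g. 3000).
#' @return PSNR in dB (`Inf` if the masked volumes are identical).
#' @export
psnr <- function(a, b, mask, max_value = "auto") {
  p <- masked_pair(a, b, mask)
  mx <- if (identical(max_value, "auto")) max(p$y) else as.numeric(max_value)
  r2 <- mean((p$x - p$y)^2)
  if (r2 == 0) return(Inf)
  10 * log10(mx^2 / r2)
}

ssim_scalar <- function(x, y, params) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  ((2 * mx * my + params$c1) * (2 * cxy + params$c2)) /
    ((mx^2 + my^2 + params$c1) * (vx + vy + params$c2))
}

#' Structural similarity index over a masked region
#'
#' The luminance/contrast/structure similarity
#' \deqn{SSIM = \frac{(2\mu_1\mu_2 + c_1)(2\sigma_{12} + c_2)}
#'                   {(\mu_1^2+\mu_2^2+c_1)(\sigma_1^2+\sigma_2^2+c_2)}}
#' computed on the masked voxel populations: means, variances and the
#' covariance are taken over the selected voxels only (population moments),
#' not over sliding windows. The score lies in (-1, 1\] and equals 1 iff
#' the masked values are identical.
#'
#' @inheritParams mae
#' @param params an [ssim_params()] object.
#' @return SSIM score.
#' @export
ssim <- function(a, b, mask, params = ssim_params()) {
  stopifnot(inherits(params, "ssim_params"))
  p <- masked_pair(a, b, mask)
  ssim_scalar(p$x, p$y, params)
}

#' Default tissue HU ranges for masked evaluation
#'
#' Cavity \[-1000, -400) HU, soft tissue \[-400, 150) HU, bony tissue
#' \[150, 3000\] HU. Membership intervals are half-open with the last
#' closed, so shared endpoints belong to the lower range and the three
#' ranges partition the in-body voxels.
#'
#' @return 3 x 2 matrix of HU bounds with rownames cavity/soft/bone.
#' @export
tissue_ranges <- function() {
  m <- rbind(c(-1000, -400), c(-400, 150), c(150, 3000))
  dimnames(m) <- list(c("cavity", "soft", "bone"), c("lo", "hi"))
  m
}

metric_row <- function(label, x, y, params) {
  n <- length(x)
  m <- mean(abs(x - y))
  r2 <- mean((x - y)^2)
  r <- sqrt(r2)
  mx <- max(y)
  data.frame(mask = label, n = n, mae = m, rmse = r,
             psnr = if (r2 == 0) Inf else 10 * log10(mx^2 / r2),
             ssim = ssim_scalar(x, y, params),
             row.names = NULL)
}

#' Tissue-range quality report
#'
#' Evaluates a candidate volume against the reference planning CT inside
#' the body, overall and per tissue range. Range membership is decided by
#' the reference CT's HU value, so every candidate is scored on identical
#' voxel sets. Ranges are half-open with the last closed; voxels below the
#' first edge or above the last are folded into the end ranges, so the
#' per-range voxel counts sum to the body count.
#'
#' @param sct candidate [ct_volume()] (HU).
#' @param ct reference planning-CT [ct_volume()] (HU).
#' @param body body [mask_volume()]; voxels outside it are excluded.
#' @param ranges n x 2 matrix of HU bounds with rownames (default
#'   [tissue_ranges()]).
#' @param params [ssim_params()].
#' @return data.frame with one row per tissue range plus an `"body"`
#'   overall row: mask, n, mae, rmse, psnr, ssim. Empty ranges are omitted.
#' @export
tissue_report <- function(sct, ct, body, ranges = tissue_ranges(),
                          params = ssim_params()) {
  p <- masked_pair(sct, ct, body)
  edges <- c(ranges[, 1], ranges[nrow(ranges), 2])
  idx <- findInterval(p$y, edges, rightmost.closed = TRUE, all.inside = TRUE)
  out <- list(metric_row("body", p$x, p$y, params))
  for (i in seq_len(nrow(ranges))) {
    sel <- idx == i
    if (any(sel))
      out[[length(out) + 1]] <-
        metric_row(rownames(ranges)[i], p$x[sel], p$y[sel], params)
  }
  do.call(rbind, out)
}

#' Organ-at-risk quality report
#'
#' Per-OAR evaluation of a candidate volume against the reference CT:
#' summary metrics, the voxel-level signed-error samples (for error
#' distribution plots), and a per-axial-slice MAE series over the slices
#' intersecting each mask.
#'
#' @param sct,ct [ct_volume()]s on the same grid (HU).
#' @param oar_masks named list of [mask_volume()]s.
#' @param params [ssim_params()].
#' @return list with `report` (data.frame as in [tissue_report()]),
#'   `errors` (named list of signed sCT - CT samples) and `slice_mae`
#'   (named list of data.frames slice/n/mae). OARs with empty masks are
#'   omitted.
#' @export
oar_report <- function(sct, ct, oar_masks, params = ssim_params()) {
  stopifnot(is.list(oar_masks))
  if (is.null(names(oar_masks)))
    names(oar_masks) <- vapply(oar_masks, `[[`, "", "label")
  rows <- list(); errs <- list(); slc <- list()
  for (nm in names(oar_masks)) {
    m <- oar_masks[[nm]]
    stopifnot_same_grid(sct, ct, m)
    if (!any(m$data)) next
    x <- sct$data[m$data]; y <- ct$data[m$data]
    rows[[nm]] <- metric_row(nm, x, y, params)
    errs[[nm]] <- x - y
    ks <- which(apply(m$data, 3, any))
    slc[[nm]] <- do.call(rbind, lapply(ks, function(k) {
      sel <- m$data[, , k]
      data.frame(slice = k, n = sum(sel),
                 mae = mean(abs(sct$data[, , k][sel] - ct$data[, , k][sel])))
    }))
  }
  if (length(rows) == 0)
    stop("degenerate input: all OAR masks empty", call. = FALSE)
  list(report = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       errors = errs, slice_mae = slc)
}

#' Quantile-quantile pairs and joint 2-D histogram
#'
#' Distributional comparison of two masked HU populations: matched
#' quantile pairs of the two distributions (a Q-Q plot lying on the
#' 45-degree line means identical distributions) and a joint 2-D histogram
#' of (reference, candidate) voxel pairs over a square HU range. Values
#' outside the range are folded into the edge bins, so the histogram
#' counts sum to the masked voxel count.
#'
#' @param sct,ct [ct_volume()]s (HU) on the same grid.
#' @param body body [mask_volume()].
#' @param range HU interval covered by the histogram axes.
#' @param n_quantiles number of matched quantiles.
#' @param n_bins number of histogram bins per axis.
#' @return list with `quantiles` (data.frame p/ct/sct) and `hist2d`
#'   (n_bins x n_bins count matrix; rows follow the reference CT axis,
#'   with bin `edges` as an attribute).
#' @export
qq_and_hist2d <- function(sct, ct, body, range = c(-1000, 3000),
                          n_quantiles = 100, n_bins = 64) {
  p <- masked_pair(sct, ct, body)
  probs <- seq(0, 1, length.out = n_quantiles)
  qs <- data.frame(p = probs,
                   ct = unname(stats::quantile(p$y, probs, type = 7)),
                   sct = unname(stats::quantile(p$x, probs, type = 7)))
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  bin <- function(v) findInterval(clip(v, range[1], range[2]), edges,
                                  rightmost.closed = TRUE, all.inside = TRUE)
  h <- table(factor(bin(p$y), levels = seq_len(n_bins)),
             factor(bin(p$x), levels = seq_len(n_bins)))
  h <- matrix(as.integer(h), n_bins, n_bins)
  attr(h, "edges") <- edges
  list(quantiles = qs, hist2d = h)
}
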