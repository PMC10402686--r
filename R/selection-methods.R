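#' @export
print.selection_map <- function(x, ...) {
  part <- x$partition
  cat(sprintf("Region-wise sCT selection map (%d bins of %g HU over [%g, %g] HU)\n",
              part$n_bins, part$bin_width, part$lo, part$hi))
  cat(sprintf("Fitted on %d training case(s); candidates: %s\n",
              x$n_cases, paste(x$candidate_ids, collapse = ", ")))
  cat(sprintf("Supported bins: %d/%d (min support %d voxels)\n",
              sum(x$supported), part$n_bins, x$config$min_support))
  runs <- rle(x$winner)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cat("Winners by contiguous HU range:\n")
  for (i in seq_along(runs$values))
    cat(sprintf("  [%6g, %6g) HU -> %s\n",
                part$edges[starts[i]], part$edges[ends[i] + 1],
                runs$values[i]))
  invisible(x)
}

#' Summarize a fitted selection map
#'
#' @param object a `selection_map` from [fit_selection()].
#' @param ... unused.
#' @return data.frame with one row per bin: bin index, HU range, pooled
#'   training-voxel count, support flag, winner, and one SSIM column per
#'   candidate.
#' @export
summary.selection_map <- function(object, ...) {
  part <- object$partition
  df <- data.frame(bin = seq_len(part$n_bins),
                   lo = part$edges[-(part$n_bins + 1)],
                   hi = part$edges[-1],
                   n_voxels = object$n_voxels,
                   supported = object$supported,
                   winner = object$winner)
  cbind(df, as.data.frame(object$scores))
}

#' Per-bin winners of a fitted selection map
#'
#' @param object a `selection_map`.
#' @param ... unused.
#' @return named character vector: bin HU range -> winning candidate id.
#' @export
coef.selection_map <- function(object, ...) {
  part <- object$partition
  stats::setNames(object$winner,
                  vapply(seq_len(part$n_bins), bin_label, "", part = part))
}

#' Apply a fitted selection map to a new case
#'
#' Runs the stitch (and optionally the median blur) on a new
#' [candidate_set()], using the settings the map was fitted with.
#'
#' @param object a `selection_map`.
#' @param case a [candidate_set()] containing all winning candidate ids.
#' @param type `"both"` (list with `combine` and `blur`), `"combine"` or
#'   `"blur"` (a single [ct_volume()]).
#' @param config override the stored [combiner_config()].
#' @param ... unused.
#' @return See `type`.
#' @export
predict.selection_map <- function(object, case,
                                  type = c("both", "combine", "blur"),
                                  config = object$config, ...) {
  type <- match.arg(type)
  if (type == "combine") return(stitch(case, object, config))
  res <- combine_case(case, object, config)
  if (type == "blur") res$blur else res
}

#' Plot per-bin candidate scores of a selection map
#'
#' One line per candidate of its per-bin SSIM against the planning CT,
#' with the winning candidate marked along the top.
#'
#' @param x a `selection_map`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.selection_map <- function(x, ...) {
  part <- x$partition
  mids <- (part$edges[-1] + part$edges[-(part$n_bins + 1)]) / 2
  graphics::matplot(mids, x$scores, type = "l", lty = 1,
                    col = seq_along(x$candidate_ids),
                    xlab = "reference HU bin center",
                    ylab = "region SSIM vs planning CT", ...)
  win_col <- match(x$winner, x$candidate_ids)
  graphics::points(mids, rep(max(x$scores, na.rm = TRUE), length(mids)),
                   pch = 15, col = win_col, cex = 0.6)
  graphics::legend("bottomright", legend = x$candidate_ids,
                   col = seq_along(x$candidate_ids), lty = 1, bty = "n")
  invisible(x)
}
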