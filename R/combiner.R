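#' HU-bin partition of the reference range
#'
#' Partition of the MVCBCT HU range into equal-width bins used for
#' region-wise candidate selection. The default is 48 bins of 50 HU over
#' \[-1000, 1400\]. Bins are half-open `[edge_k, edge_{k+1})` except the
#' last, which is closed; values below `lo` clamp to bin 1 and above `hi`
#' to the last bin.
#'
#' @param lo,hi HU range covered.
#' @param bin_width bin width in HU; must divide `hi - lo` exactly.
#' @return An object of class `hu_partition` with fields `lo`, `hi`,
#'   `bin_width`, `n_bins`, `edges`.
#' @export
hu_partition <- function(lo = -1000, hi = 1400, bin_width = 50) {
  if (hi <= lo) stop("need hi > lo", call. = FALSE)
  n <- (hi - lo) / bin_width
  if (abs(n - round(n)) > 1e-9)
    stop("bin_width must divide hi - lo exactly", call. = FALSE)
  n <- as.integer(round(n))
  structure(list(lo = lo, hi = hi, bin_width = bin_width, n_bins = n,
                 edges = seq(lo, hi, by = bin_width)),
            class = "hu_partition")
}

#' @export
print.hu_partition <- function(x, ...) {
  cat(sprintf("<hu_partition> %d bins of %g HU over [%g, %g] HU\n",
              x$n_bins, x$bin_width, x$lo, x$hi))
  invisible(x)
}

bin_label <- function(part, k)
  sprintf("[%g, %g)", part$edges[k], part$edges[k + 1])

#' Combiner configuration
#'
#' @param smooth_kernel odd window size of the mean pre-filter applied to
#'   the reference MVCBCT before bin assignment (default 5).
#' @param blur_kernel odd window size of the median post-filter applied to
#'   the stitched volume (default 5).
#' @param min_support minimum pooled training-voxel count for a bin to be
#'   scored directly; sparser bins inherit the winner of the nearest
#'   supported bin (ties toward lower HU).
#' @param outside_body_fill `"base_candidate"` (voxels outside the body are
#'   copied from `base_candidate`) or `"air"` (-1000 HU).
#' @param base_candidate candidate id used for the outside-body fill;
#'   `NULL` selects the lexicographically first id at apply time.
#' @return An object of class `combiner_config`.
#' @export
combiner_config <- function(smooth_kernel = 5L, blur_kernel = 5L,
                            min_support = 100L,
                            outside_body_fill = c("base_candidate", "air"),
                            base_candidate = NULL) {
  outside_body_fill <- match.arg(outside_body_fill)
  for (k in c(smooth_kernel, blur_kernel))
    if (k < 1 || k %% 2 == 0)
      stop("kernel sizes must be odd and >= 1", call. = FALSE)
  structure(list(smooth_kernel = as.integer(smooth_kernel),
                 blur_kernel = as.integer(blur_kernel),
                 min_support = as.integer(min_support),
                 outside_body_fill = outside_body_fill,
                 base_candidate = base_candidate),
            class = "combiner_config")
}

#' Candidate set: one case's aligned volumes
#'
#' Bundles the co-registered volumes of one case: the reference MVCBCT
#' (whose smoothed HU values define the regions), the named candidate sCT
#' volumes, the body mask, and (for training cases) the planning CT ground
#' truth. All grids must agree in shape and spacing; this package requires
#' pre-aligned inputs and does not register.
#'
#' @param reference_mvcbct [ct_volume()] (HU).
#' @param candidates named list of candidate [ct_volume()]s (HU).
#' @param body body [mask_volume()].
#' @param planning_ct optional planning-CT [ct_volume()] (HU); required
#'   for fitting.
#' @param id optional case identifier.
#' @return An object of class `candidate_set`.
#' @export
candidate_set <- function(reference_mvcbct, candidates, body,
                          planning_ct = NULL, id = NULL) {
  stopifnot(inherits(reference_mvcbct, "ct_volume"),
            inherits(body, "mask_volume"), is.list(candidates))
  ids <- names(candidates)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids))
    stop("candidates must have unique non-empty names", call. = FALSE)
  for (cv in candidates) {
    stopifnot(inherits(cv, "ct_volume"))
    stopifnot_same_grid(reference_mvcbct, cv, body)
    if (!isTRUE(all.equal(cv$spacing, reference_mvcbct$spacing)))
      stop("candidate spacing differs from reference", call. = FALSE)
  }
  if (!is.null(planning_ct)) {
    stopifnot(inherits(planning_ct, "ct_volume"))
    stopifnot_same_grid(reference_mvcbct, planning_ct)
  }
  structure(list(reference_mvcbct = reference_mvcbct,
                 planning_ct = planning_ct,
                 candidates = candidates, body = body, id = id),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  d <- dim(x$reference_mvcbct$data)
  cat(sprintf("<candidate_set>%s %d x %d x %d, %d candidates (%s), %s CT\n",
              if (is.null(x$id)) "" else paste0(" '", x$id, "'"),
              d[1], d[2], d[3], length(x$candidates),
              paste(names(x$candidates), collapse = ", "),
              if (is.null(x$planning_ct)) "no planning" else "with planning"))
  invisible(x)
}

#' Assign in-body voxels to HU bins
#'
#' Labels every in-body voxel of the smoothed reference with its bin index
#' (1-based); out-of-body voxels are labelled 0. Values below the
#' partition's range clamp into the first bin, values above into the last.
#'
#' @param smoothed_mvcbct the mean-filtered reference [ct_volume()].
#' @param body body [mask_volume()].
#' @param partition an [hu_partition()].
#' @return integer array of bin labels on the same grid.
#' @export
partition_regions <- function(smoothed_mvcbct, body,
                              partition = hu_partition()) {
  stopifnot(inherits(partition, "hu_partition"))
  stopifnot_same_grid(smoothed_mvcbct, body)
  idx <- findInterval(smoothed_mvcbct$data, partition$edges,
                      rightmost.closed = TRUE, all.inside = TRUE)
  lab <- array(as.integer(idx), dim = dim(smoothed_mvcbct$data))
  lab[!body$data] <- 0L
  lab
}

#' Region-restricted structural similarity
#'
#' SSIM ([ssim()]'s formula) evaluated over the voxel population of an
#' arbitrary region mask: means, variances and covariance are computed over
#' the region voxels only. This is the selection score used to pick the
#' most accurate candidate per HU bin.
#'
#' @param candidate,reference_ct [ct_volume()]s (HU).
#' @param region logical array (or [mask_volume()]) selecting the region.
#' @param params [ssim_params()].
#' @return SSIM score in (-1, 1\], or `NA` for an empty region (the caller
#'   applies the sparse-bin fallback).
#' @export
region_ssim <- function(candidate, reference_ct, region,
                        params = ssim_params()) {
  if (inherits(region, "mask_volume")) region <- region$data
  if (!any(region)) return(NA_real_)
  ssim_scalar(candidate$data[region], reference_ct$data[region], params)
}

#' Fit a region-wise candidate selection map
#'
#' The fitting step of the combination algorithm. For every HU bin of the
#' partition, the training voxels falling in that bin (by the smoothed
#' reference MVCBCT, inside the body) are pooled across all training
#' cases; each candidate is scored there by masked SSIM against the
#' planning CT, and the best-scoring candidate is recorded as the bin's
#' winner. Bins whose pooled support is below `config$min_support` inherit
#' the winner of the nearest supported bin (ties toward lower HU). Exact
#' score ties break toward the lexicographically smaller candidate id.
#'
#' @param training_cases list of [candidate_set()]s, each with a planning
#'   CT; all cases must share one candidate-id set.
#' @param partition an [hu_partition()] (default 48 bins of 50 HU).
#' @param config a [combiner_config()].
#' @param params [ssim_params()].
#' @return An object of class `selection_map` with per-bin winners, score
#'   matrix, support counts, and the settings used. Methods: `print`,
#'   `summary`, `coef` (named winner vector), `predict` (apply to a new
#'   case), `plot`.
#' @seealso [predict.selection_map()], [combine_case()]
#' @export
fit_selection <- function(training_cases, partition = hu_partition(),
                          config = combiner_config(),
                          params = ssim_params()) {
  stopifnot(length(training_cases) >= 1)
  ids <- sort(names(training_cases[[1]]$candidates))
  for (cs in training_cases) {
    stopifnot(inherits(cs, "candidate_set"))
    if (is.null(cs$planning_ct))
      stop("every training case needs a planning CT", call. = FALSE)
    if (!identical(sort(names(cs$candidates)), ids))
      stop("training cases do not share one candidate-id set", call. = FALSE)
  }
  nb <- partition$n_bins
  # pool per-bin voxel values across cases
  ct_pool <- vector("list", nb)
  cand_pool <- lapply(ids, function(i) vector("list", nb))
  names(cand_pool) <- ids
  for (ci in seq_along(training_cases)) {
    cs <- training_cases[[ci]]
    sm <- smooth_reference(cs$reference_mvcbct, config$smooth_kernel)
    lab <- partition_regions(sm, cs$body, partition)
    inb <- lab > 0L
    labv <- lab[inb]
    ctv <- cs$planning_ct$data[inb]
    groups <- split(seq_along(labv), factor(labv, levels = seq_len(nb)))
    for (k in seq_len(nb)) ct_pool[[k]][[ci]] <- ctv[groups[[k]]]
    for (id in ids) {
      cv <- cs$candidates[[id]]$data[inb]
      for (k in seq_len(nb)) cand_pool[[id]][[k]][[ci]] <- cv[groups[[k]]]
    }
  }
  scores <- matrix(NA_real_, nb, length(ids), dimnames = list(NULL, ids))
  n_vox <- integer(nb)
  for (k in seq_len(nb)) {
    y <- unlist(ct_pool[[k]], use.names = FALSE)
    n_vox[k] <- length(y)
    if (n_vox[k] == 0) next
    for (id in ids)
      scores[k, id] <- ssim_scalar(
        unlist(cand_pool[[id]][[k]], use.names = FALSE), y, params)
  }
  supported <- n_vox >= config$min_support
  if (!any(supported))
    stop("degenerate input: no bin reaches min_support", call. = FALSE)
  winner <- rep(NA_character_, nb)
  for (k in which(supported)) {
    s <- scores[k, ]
    winner[k] <- ids[which(s == max(s))[1]]   # ids sorted: lexicographic tie
  }
  sup_idx <- which(supported)
  for (k in which(!supported)) {
    d <- abs(sup_idx - k)
    nearest <- sup_idx[d == min(d)]
    winner[k] <- winner[min(nearest)]         # tie toward lower HU
  }
  structure(list(partition = partition, winner = winner, scores = scores,
                 n_voxels = n_vox, supported = supported,
                 candidate_ids = ids, config = config, ssim_params = params,
                 n_cases = length(training_cases)),
            class = "selection_map")
}

#' Stitch candidate volumes according to a fitted selection map
#'
#' The apply step: the reference MVCBCT is smoothed and binned exactly as
#' during fitting, and every in-body voxel is copied from the candidate
#' that won its bin. Out-of-body voxels are filled from the base candidate
#' or with -1000 HU air per the config. The result is the raw combined
#' volume (sCT_Combine), before median smoothing.
#'
#' @param case a [candidate_set()]; must contain every winning candidate id.
#' @param selection a fitted `selection_map`.
#' @param config a [combiner_config()]; defaults to the one stored in the
#'   selection map.
#' @return The stitched [ct_volume()] (attribute `name = "sCT_Combine"`).
#' @export
stitch <- function(case, selection, config = selection$config) {
  stopifnot(inherits(case, "candidate_set"),
            inherits(selection, "selection_map"))
  missing_ids <- setdiff(unique(selection$winner), names(case$candidates))
  if (length(missing_ids))
    stop("case lacks candidate(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  sm <- smooth_reference(case$reference_mvcbct, config$smooth_kernel)
  lab <- partition_regions(sm, case$body, selection$partition)
  base_id <- config$base_candidate
  if (is.null(base_id)) base_id <- sort(names(case$candidates))[1]
  out <- if (config$outside_body_fill == "air")
    array(-1000, dim = dim(lab))
  else
    case$candidates[[base_id]]$data
  for (id in unique(selection$winner)) {
    sel <- lab > 0L & selection$winner[pmax(lab, 1L)] == id
    out[sel] <- case$candidates[[id]]$data[sel]
  }
  v <- ct_volume(out, spacing = case$reference_mvcbct$spacing,
                 modality = "SCT", value_domain = "HU")
  attr(v, "name") <- "sCT_Combine"
  v
}

#' Run the full combination pipeline on one case
#'
#' smooth reference, assign bins, stitch winners, median-smooth the seams.
#'
#' @inheritParams stitch
#' @return list with `combine` (the stitched sCT_Combine volume) and
#'   `blur` (the median-filtered sCT_Blur volume).
#' @export
combine_case <- function(case, selection, config = selection$config) {
  sc <- stitch(case, selection, config)
  bl <- median_smooth(sc, config$blur_kernel)
  attr(bl, "name") <- "sCT_Blur"
  list(combine = sc, blur = bl)
}

#' Serialize / load a fitted selection map as JSON
#'
#' @param selection a `selection_map`.
#' @param path JSON file path.
#' @return `write_selection`: `path` invisibly; `read_selection`: a
#'   `selection_map` (with the config/ssim settings it was fitted under).
#' @export
write_selection <- function(selection, path) {
  stopifnot(inherits(selection, "selection_map"))
  part <- selection$partition
  bins <- lapply(seq_len(part$n_bins), function(k) {
    sc <- selection$scores[k, ]
    scl <- as.list(sc)
    scl[is.na(sc)] <- list(NULL)
    list(index = k, hu_range = c(part$edges[k], part$edges[k + 1]),
         winner = selection$winner[k],
         supported = selection$supported[k],
         n_voxels = selection$n_voxels[k],
         scores = scl)
  })
  doc <- list(partition = list(lo = part$lo, hi = part$hi,
                               bin_width = part$bin_width),
              candidate_ids = selection$candidate_ids,
              config = unclass(selection$config),
              ssim_params = unclass(selection$ssim_params)[c("L", "k1", "k2")],
              n_cases = selection$n_cases,
              bins = bins)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  part <- hu_partition(doc$partition$lo, doc$partition$hi,
                       doc$partition$bin_width)
  ids <- unlist(doc$candidate_ids)
  cfg <- doc$config
  config <- combiner_config(cfg$smooth_kernel, cfg$blur_kernel,
                            cfg$min_support, cfg$outside_body_fill,
                            cfg$base_candidate)
  params <- ssim_params(doc$ssim_params$L, doc$ssim_params$k1,
                        doc$ssim_params$k2)
  nb <- part$n_bins
  winner <- character(nb); n_vox <- integer(nb); supported <- logical(nb)
  scores <- matrix(NA_real_, nb, length(ids), dimnames = list(NULL, ids))
  for (b in doc$bins) {
    k <- b$index
    winner[k] <- b$winner
    n_vox[k] <- b$n_voxels
    supported[k] <- isTRUE(b$supported)
    for (id in names(b$scores))
      if (!is.null(b$scores[[id]])) scores[k, id] <- b$scores[[id]]
  }
  structure(list(partition = part, winner = winner, scores = scores,
                 n_voxels = n_vox, supported = supported,
                 candidate_ids = ids, config = config, ssim_params = params,
                 n_cases = doc$n_cases),
            class = "selection_map")
}
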