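#' 3-D scalar volume container
#'
#' A `ct_volume` wraps a 3-D numeric array together with the physical voxel
#' spacing, the acquisition modality and the value domain of its voxels.
#' All pipeline stages (normalization, combination, evaluation) consume and
#' produce `ct_volume` objects, so shape/spacing compatibility is checked in
#' one place.
#'
#' @param data 3-D numeric array. HU values for `value_domain = "HU"`,
#'   otherwise normalized units.
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param modality one of `"CT"`, `"MVCBCT"`, `"SCT"`.
#' @param value_domain one of `"HU"` (Hounsfield units), `"NORM01"`
#'   (values in \[0, 1\]) or `"NORM11"` (values in \[-1, 1\]).
#' @return An object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(0, c(4, 4, 2)), spacing = c(1, 1, 3))
#' dim(v$data)
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1),
                      modality = c("CT", "MVCBCT", "SCT"),
                      value_domain = c("HU", "NORM01", "NORM11")) {
  modality <- match.arg(modality)
  value_domain <- match.arg(value_domain)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("volume contains non-finite values", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers", call. = FALSE)
  if (value_domain == "NORM01" && (min(data) < 0 || max(data) > 1))
    stop("NORM01 volume has values outside [0, 1]", call. = FALSE)
  if (value_domain == "NORM11" && (min(data) < -1 || max(data) > 1))
    stop("NORM11 volume has values outside [-1, 1]", call. = FALSE)
  structure(list(data = data, spacing = spacing, modality = modality,
                 value_domain = value_domain),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm, %s [%s]\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              x$modality, x$value_domain))
  cat(sprintf("  value range: [%.2f, %.2f]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Boolean mask volume
#'
#' A logical grid annotating a [ct_volume()] (body/skin, organ-at-risk
#' contour, tissue compartment, ...). The grid shape must match the volume
#' it annotates; this is checked wherever a mask is consumed.
#'
#' @param data 3-D logical (or coercible) array.
#' @param label free-text role, e.g. `"body"`, `"oral_cavity"`, `"parotid"`.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, label = "mask") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask contains NA", call. = FALSE)
  structure(list(data = data, label = as.character(label)[1]),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mask_volume> '%s' %d x %d x %d, %d voxels set\n",
              x$label, d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

stopifnot_same_grid <- function(...) {
  objs <- list(...)
  dims <- lapply(objs, function(o) dim(o$data))
  ref <- dims[[1]]
  for (d in dims[-1]) {
    if (!identical(d, ref))
      stop("volumes/masks do not share one grid shape", call. = FALSE)
  }
  invisible(TRUE)
}

#' Default HU ceilings per modality
#'
#' Planning CT values do not exceed 3000 HU and MVCBCT values do not exceed
#' 1400 HU in this pipeline; the floor is -1000 HU (air) for all modalities.
#'
#' @param modality `"CT"`, `"MVCBCT"` or `"SCT"` (SCT shares the CT range).
#' @return numeric length-2 `(lo, hi)` in HU.
#' @export
modality_bounds <- function(modality = c("CT", "MVCBCT", "SCT")) {
  modality <- match.arg(modality)
  if (modality == "MVCBCT") c(-1000, 1400) else c(-1000, 3000)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Read a volume from disk
#'
#' Reads a NIfTI (.nii / .nii.gz) file into a [ct_volume()]. Stored integer
#' values are converted to real HU through the format's scale slope and
#' intercept. On ingest, values are optionally clipped to the modality's HU
#' range (floor -1000 HU; ceiling 3000 HU for CT/SCT, 1400 HU for MVCBCT).
#'
#' DICOM series input is not supported by this build; pre-convert series to
#' NIfTI with standard tools.
#'
#' @param path file path.
#' @param format only `"nifti"` is supported.
#' @param modality modality tag recorded on the volume.
#' @param value_domain value domain of the stored data (default HU).
#' @param clip_hu clip to the modality HU bounds on ingest (HU volumes only).
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, format = c("nifti", "dicom_series"),
                        modality = c("CT", "MVCBCT", "SCT"),
                        value_domain = c("HU", "NORM01", "NORM11"),
                        clip_hu = TRUE) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  value_domain <- match.arg(value_domain)
  if (format == "dicom_series")
    stop("DICOM series input is not supported; convert to NIfTI first",
         call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)   # applies scl_slope / scl_inter
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D image, got ", length(dim(arr)), " dimensions",
         call. = FALSE)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  arr <- array(as.double(arr), dim = dim(arr))   # plain array, no NIfTI attrs
  if (value_domain == "HU" && clip_hu) {
    b <- modality_bounds(modality)
    arr <- clip(arr, b[1], b[2])
  }
  ct_volume(arr, spacing = spacing, modality = modality,
            value_domain = value_domain)
}

#' Write a volume to disk
#'
#' Writes a [ct_volume()] as NIfTI with 64-bit floating point storage, so
#' a write/read round trip is voxel-exact and preserves spacing metadata.
#'
#' @param v a [ct_volume()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "ct_volume"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  tryCatch(RNifti::writeNifti(img, path, datatype = "double"),
           error = function(e) stop("cannot write volume to ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read / write mask volumes
#'
#' Masks are stored either as 0/1 NIfTI volumes or as a run-length-encoded
#' JSON document (`{"shape": [...], "label": ..., "rle": [len0_0, len1, ...]}`,
#' alternating zero-runs and one-runs in column-major order, starting with
#' the length of the initial zero-run).
#'
#' @param path file path; `.json` selects the RLE codec, otherwise NIfTI.
#' @param label label recorded on the mask when reading NIfTI.
#' @return [mask_volume()] for `read_mask`; `path` invisibly for `write_mask`.
#' @export
read_mask <- function(path, label = "mask") {
  if (grepl("\\.json$", path)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    n <- prod(doc$shape)
    runs <- as.numeric(doc$rle)
    if (sum(runs) != n) stop("RLE runs do not cover the grid", call. = FALSE)
    bits <- rep(rep(c(FALSE, TRUE), length.out = length(runs)), runs)
    mask_volume(array(bits, dim = doc$shape),
                label = if (!is.null(doc$label)) doc$label else label)
  } else {
    v <- read_volume(path, "nifti", clip_hu = FALSE)
    mask_volume(v$data > 0.5, label = label)
  }
}

#' @param m a [mask_volume()].
#' @rdname read_mask
#' @export
write_mask <- function(m, path) {
  stopifnot(inherits(m, "mask_volume"))
  if (grepl("\\.json$", path)) {
    x <- as.integer(m$data)
    r <- rle(x)
    # force the encoded stream to start with a zero-run
    lens <- r$lengths
    if (length(lens) && r$values[1] == 1L) lens <- c(0L, lens)
    jsonlite::write_json(list(shape = dim(m$data), label = m$label,
                              rle = lens),
                         path, auto_unbox = TRUE)
  } else {
    img <- RNifti::asNifti(array(as.numeric(m$data), dim = dim(m$data)))
    RNifti::writeNifti(img, path, datatype = "uint8")
  }
  invisible(path)
}

# 3-D 6-connectivity labeling: EBImage::bwlabel per axial slice, then a
# union-find merge of labels that touch across adjacent slices.
label_components_3d <- function(fg) {
  d <- dim(fg)
  labels <- array(0L, d)
  offset <- 0L
  for (k in seq_len(d[3])) {
    sl <- matrix(as.integer(EBImage::bwlabel(fg[, , k])), d[1], d[2])
    nk <- max(sl)
    if (nk > 0) labels[, , k] <- ifelse(sl > 0L, sl + offset, 0L)
    offset <- offset + nk
  }
  if (offset == 0L) return(labels)
  parent <- seq_len(offset)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (d[3] > 1) for (k in seq_len(d[3] - 1)) {
    a <- labels[, , k]; b <- labels[, , k + 1]
    touch <- a > 0 & b > 0
    if (any(touch)) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  labels[labels > 0] <- roots[labels[labels > 0]]
  labels
}

#' Derive a body (skin) mask from a CT volume
#'
#' Thresholds the volume at `threshold` HU, keeps the largest 6-connected
#' 3-D foreground component, and fills interior holes slice-wise, yielding
#' the "inside the skin" region used to restrict all evaluations. Isolated
#' foreground blobs smaller than `min_component_fraction` of the total
#' foreground can never be selected.
#'
#' @param ct a [ct_volume()] in HU.
#' @param threshold HU threshold separating body from surrounding air
#'   (default -400 HU, the cavity/soft-tissue boundary).
#' @param min_component_fraction smallest fraction of the foreground a
#'   component may hold and still be eligible as the body.
#' @return A [mask_volume()] labelled `"body"`.
#' @export
body_mask <- function(ct, threshold = -400, min_component_fraction = 0.1) {
  stopifnot(inherits(ct, "ct_volume"))
  if (ct$value_domain != "HU")
    stop("body_mask expects an HU volume", call. = FALSE)
  fg <- ct$data > threshold
  nfg <- sum(fg)
  if (nfg == 0)
    stop("degenerate input: no voxels above threshold ", threshold,
         call. = FALSE)
  labels <- label_components_3d(fg)
  sizes <- tabulate(labels[labels > 0])
  best <- which.max(sizes)
  if (sizes[best] < min_component_fraction * nfg)
    stop("degenerate input: largest component below min_component_fraction",
         call. = FALSE)
  body <- labels == best
  for (k in seq_len(dim(body)[3])) {
    sl <- body[, , k]
    if (any(sl)) body[, , k] <- EBImage::fillHull(sl) > 0
  }
  mask_volume(body, label = "body")
}
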