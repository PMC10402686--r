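#' Normalization method specification
#'
#' A `norm_spec` describes one intensity-normalization preprocess applied to
#' CT or MVCBCT volumes before model training. Three kinds exist:
#' * `linear01`: min-max scaling of the modality HU range onto \[0, 1\];
#' * `linear11`: the same scaling onto \[-1, 1\];
#' * `tanh`: `N = tanh((HU - a) / b)`, a sigmoid feature scaling whose
#'   center `a` (HU) and scale `b` (HU) choose which tissue band receives
#'   the widest share of the normalized range.
#'
#' Parameters are per modality: `ct` and `mvcbct` each carry
#' `hu_min`/`hu_max` (linear kinds) or `a`/`b` (tanh kind).
#'
#' @param id method label, e.g. `"III"` or a custom name.
#' @param kind `"linear01"`, `"linear11"` or `"tanh"`.
#' @param ct,mvcbct named lists of per-modality parameters.
#' @return An object of class `norm_spec`.
#' @examples
#' norm_spec("III", "tanh", ct = list(a = 0, b = 400),
#'           mvcbct = list(a = 0, b = 400))
#' @export
norm_spec <- function(id, kind = c("linear01", "linear11", "tanh"),
                      ct, mvcbct = ct) {
  kind <- match.arg(kind)
  chk <- function(p, modality) {
    if (kind == "tanh") {
      if (is.null(p$a) || is.null(p$b))
        stop("tanh spec needs a and b for ", modality, call. = FALSE)
      if (p$b <= 0) stop("tanh scale b must be > 0", call. = FALSE)
    } else {
      if (is.null(p$hu_min) || is.null(p$hu_max))
        stop("linear spec needs hu_min and hu_max for ", modality,
             call. = FALSE)
      if (p$hu_max <= p$hu_min)
        stop("hu_max must exceed hu_min", call. = FALSE)
    }
  }
  chk(ct, "CT"); chk(mvcbct, "MVCBCT")
  structure(list(id = as.character(id)[1], kind = kind,
                 params = list(CT = ct, MVCBCT = mvcbct)),
            class = "norm_spec")
}

#' @export
print.norm_spec <- function(x, ...) {
  fmt <- function(p) {
    if (x$kind == "tanh") sprintf("a = %g, b = %g", p$a, p$b)
    else sprintf("[%g, %g] HU", p$hu_min, p$hu_max)
  }
  cat(sprintf("<norm_spec> %s (%s)  CT: %s  MVCBCT: %s\n", x$id, x$kind,
              fmt(x$params$CT), fmt(x$params$MVCBCT)))
  invisible(x)
}

#' Built-in registry of the seven normalization methods
#'
#' Methods I and II are linear min-max scalings of the fixed modality HU
#' ranges (CT \[-1000, 3000\], MVCBCT \[-1000, 1400\]) onto \[0, 1\] and
#' \[-1, 1\]. Methods III-VII are tanh scalings whose centers/scales target
#' the whole image (III), cavities (IV), soft tissue (V), bony tissue (VI)
#' and dental tissue (VII). Their trained sCT outputs are conventionally
#' named Linear_1, Linear_2 and Tanh_0 ... Tanh_4.
#'
#' @return Named list of [norm_spec()] objects, names `"I"` ... `"VII"`.
#' @export
norm_methods <- function() {
  lin_ct <- list(hu_min = -1000, hu_max = 3000)
  lin_mv <- list(hu_min = -1000, hu_max = 1400)
  list(
    I   = norm_spec("I",   "linear01", ct = lin_ct, mvcbct = lin_mv),
    II  = norm_spec("II",  "linear11", ct = lin_ct, mvcbct = lin_mv),
    III = norm_spec("III", "tanh", ct = list(a = 0, b = 400),
                    mvcbct = list(a = 0, b = 400)),
    IV  = norm_spec("IV",  "tanh", ct = list(a = -575, b = 425),
                    mvcbct = list(a = -600, b = 400)),
    V   = norm_spec("V",   "tanh", ct = list(a = 0, b = 300),
                    mvcbct = list(a = 0, b = 150)),
    VI  = norm_spec("VI",  "tanh", ct = list(a = 600, b = 450),
                    mvcbct = list(a = 375, b = 175)),
    VII = norm_spec("VII", "tanh", ct = list(a = 2025, b = 975),
                    mvcbct = list(a = 900, b = 500))
  )
}

norm_params <- function(spec, modality) {
  modality <- if (modality == "SCT") "CT" else modality
  p <- spec$params[[modality]]
  if (is.null(p))
    stop("no ", modality, " parameters in method ", spec$id, call. = FALSE)
  p
}

#' Map HU values through a normalization method
#'
#' Scalar/vector version of [normalize_volume()]: HU values are clipped to
#' the modality bounds, then passed through the method's formula.
#'
#' @param hu numeric HU values.
#' @param spec a [norm_spec()].
#' @param modality `"CT"`, `"MVCBCT"` or `"SCT"` (uses CT parameters).
#' @return numeric normalized values.
#' @examples
#' mapped_value(-400, norm_methods()$I)         # 0.15
#' mapped_value(150, norm_methods()$III)        # tanh(0.375)
#' @export
mapped_value <- function(hu, spec, modality = "CT") {
  stopifnot(inherits(spec, "norm_spec"))
  p <- norm_params(spec, modality)
  b <- modality_bounds(modality)
  hu <- clip(hu, b[1], b[2])
  switch(spec$kind,
         linear01 = (hu - p$hu_min) / (p$hu_max - p$hu_min),
         linear11 = 2 * (hu - p$hu_min) / (p$hu_max - p$hu_min) - 1,
         tanh = tanh((hu - p$a) / p$b))
}

inverse_mapped_value <- function(x, spec, modality = "CT", eps = 1e-7) {
  p <- norm_params(spec, modality)
  switch(spec$kind,
         linear01 = p$hu_min + x * (p$hu_max - p$hu_min),
         linear11 = p$hu_min + (x + 1) / 2 * (p$hu_max - p$hu_min),
         tanh = p$a + p$b * atanh(clip(x, -1 + eps, 1 - eps)))
}

#' Normalize an HU volume
#'
#' Applies a normalization method element-wise after clipping to the
#' modality HU bounds. Output `value_domain` is `NORM01` for `linear01`
#' and `NORM11` otherwise.
#'
#' @param v a [ct_volume()] with `value_domain = "HU"`.
#' @param spec a [norm_spec()].
#' @param modality modality whose parameters to use; defaults to the
#'   volume's own modality tag.
#' @return A normalized [ct_volume()].
#' @export
normalize_volume <- function(v, spec, modality = v$modality) {
  stopifnot(inherits(v, "ct_volume"))
  if (v$value_domain != "HU")
    stop("normalize_volume expects an HU volume", call. = FALSE)
  out <- mapped_value(v$data, spec, modality)
  ct_volume(out, spacing = v$spacing, modality = v$modality,
            value_domain = if (spec$kind == "linear01") "NORM01" else "NORM11")
}

#' Invert a normalization
#'
#' Exact algebraic inverse of [normalize_volume()]. For tanh methods the
#' input is clamped to `[-1 + eps, 1 - eps]` before the inverse hyperbolic
#' tangent so saturated values map to finite HU. Within the modality bounds
#' and away from tanh saturation (`|(HU - a)/b| <= 5`) a round trip
#' recovers HU to well under 0.5 HU.
#'
#' @param v a normalized [ct_volume()].
#' @param spec the [norm_spec()] used to produce it.
#' @param modality modality whose parameters to use.
#' @param eps saturation clamp for the tanh inverse.
#' @return A [ct_volume()] in HU.
#' @export
denormalize_volume <- function(v, spec, modality = v$modality, eps = 1e-7) {
  stopifnot(inherits(v, "ct_volume"))
  expected <- if (spec$kind == "linear01") "NORM01" else "NORM11"
  if (v$value_domain != expected)
    stop("volume value_domain ", v$value_domain,
         " does not match method kind ", spec$kind, call. = FALSE)
  hu <- inverse_mapped_value(v$data, spec, modality, eps = eps)
  ct_volume(hu, spacing = v$spacing, modality = v$modality,
            value_domain = "HU")
}

#' Share of the normalized range occupied by an HU interval
#'
#' `100 * (N(hi) - N(lo)) / W`, where `N` is the method's mapping and `W`
#' is the full width of its normalized range (1 for `linear01`, else 2).
#' This quantifies how much of the trainable value range a tissue band
#' receives: e.g. soft tissue \[-400, 150\] HU holds 13.75% under linear
#' scaling of the CT range but 56% under the centred tanh method.
#'
#' @param lo,hi HU interval bounds, `lo < hi`.
#' @inheritParams mapped_value
#' @return percentage (0-100).
#' @export
interval_proportion <- function(lo, hi, spec, modality = "CT") {
  if (!(lo < hi)) stop("need lo < hi", call. = FALSE)
  W <- if (spec$kind == "linear01") 1 else 2
  100 * (mapped_value(hi, spec, modality) -
           mapped_value(lo, spec, modality)) / W
}

#' Round half away from zero
#'
#' The rounding convention used for report tables (0.625 -> 0.63,
#' -0.425 -> -0.43), unlike [round()]'s round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' The CT-number partition used throughout the head analyses
#'
#' Cavity, soft tissue, bony tissue (excluding teeth) and dental tissue.
#' @return 4 x 2 matrix of HU interval bounds.
#' @export
hu_range_partition <- function() {
  m <- rbind(c(-1000, -400), c(-400, 150), c(150, 1500), c(1500, 3000))
  dimnames(m) <- list(c("cavity", "soft", "bone", "teeth"), c("lo", "hi"))
  m
}

#' Mapped-value table for a set of methods
#'
#' One row per method, one column per HU probe point: the normalized voxel
#' value each method assigns to that CT number.
#'
#' @param specs list of [norm_spec()] (default: the built-in registry).
#' @param hu_points HU probe points.
#' @param modality modality whose parameters to use.
#' @param digits rounding (half away from zero); `NULL` for full precision.
#' @return data.frame with a `method` column and one column per HU point.
#' @export
mapped_value_table <- function(specs = norm_methods(),
                               hu_points = c(-1000, -400, 150, 1500, 3000),
                               modality = "CT", digits = 2) {
  rows <- lapply(specs, function(s) {
    v <- vapply(hu_points, mapped_value, numeric(1), spec = s,
                modality = modality)
    if (!is.null(digits)) v <- round_half_away(v, digits)
    v
  })
  out <- data.frame(method = vapply(specs, `[[`, "", "id"),
                    do.call(rbind, rows), row.names = NULL,
                    check.names = FALSE)
  names(out)[-1] <- paste0("HU_", hu_points)
  out
}

#' Interval-occupancy report across methods
#'
#' For each method and each interval of a contiguous, ordered HU partition,
#' the percentage of the normalized range the interval occupies
#' ([interval_proportion()]). Over a partition of the full modality range
#' the row proportions telescope to 100 (linear kinds exactly; tanh kinds
#' up to endpoint saturation).
#'
#' @param partition n x 2 matrix (or list of length-2 vectors) of HU
#'   intervals, contiguous and ordered.
#' @param specs list of [norm_spec()].
#' @param modality modality whose parameters to use.
#' @param digits rounding (half away from zero); `NULL` for full precision.
#' @return data.frame: method, interval label, lo, hi, proportion_pct.
#' @export
distribution_report <- function(partition = hu_range_partition(),
                                specs = norm_methods(),
                                modality = "CT", digits = 2) {
  if (is.list(partition)) partition <- do.call(rbind, partition)
  partition <- as.matrix(partition)
  if (ncol(partition) != 2) stop("partition must be n x 2", call. = FALSE)
  n <- nrow(partition)
  if (any(partition[, 1] >= partition[, 2]))
    stop("each interval needs lo < hi", call. = FALSE)
  if (n > 1) {
    if (any(partition[-1, 1] < partition[-n, 2]))
      stop("intervals overlap", call. = FALSE)
    if (any(partition[-1, 1] != partition[-n, 2]))
      stop("intervals are not contiguous", call. = FALSE)
  }
  labels <- rownames(partition)
  if (is.null(labels))
    labels <- sprintf("[%g, %g]", partition[, 1], partition[, 2])
  rows <- do.call(rbind, lapply(specs, function(s) {
    p <- vapply(seq_len(n), function(i)
      interval_proportion(partition[i, 1], partition[i, 2], s, modality),
      numeric(1))
    if (!is.null(digits)) p <- round_half_away(p, digits)
    data.frame(method = s$id, interval = labels,
               lo = partition[, 1], hi = partition[, 2],
               proportion_pct = p, row.names = NULL)
  }))
  rownames(rows) <- NULL
  rows
}

#' Histogram of voxel values
#'
#' Bin counts of a volume's voxel values, optionally after normalization by
#' a method. Used to inspect how a preprocess redistributes the trainable
#' value range across tissues.
#'
#' @param v a [ct_volume()].
#' @param spec optional [norm_spec()]; if given, `v` must be in HU and the
#'   histogram is taken over the normalized values.
#' @param bins number of equal-width bins (>= 1).
#' @param modality modality for the normalization parameters.
#' @return data.frame: bin lo/hi edges, midpoint, count. The counts sum to
#'   the voxel count.
#' @export
voxel_value_histogram <- function(v, spec = NULL, bins = 100,
                                  modality = v$modality) {
  stopifnot(inherits(v, "ct_volume"))
  if (bins < 1) stop("bins must be >= 1", call. = FALSE)
  x <- if (is.null(spec)) as.vector(v$data)
       else as.vector(mapped_value(v$data, spec, modality))
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  data.frame(lo = edges[-(bins + 1)], hi = edges[-1],
             mid = (edges[-(bins + 1)] + edges[-1]) / 2,
             count = tabulate(idx, nbins = bins))
}

#' Serialize / load a method registry
#'
#' The registry is stored as a JSON list of
#' `{id, kind, ct: {...}, mvcbct: {...}}` entries.
#'
#' @param specs named list of [norm_spec()].
#' @param path JSON file path.
#' @return `write_norm_registry`: `path` invisibly; `read_norm_registry`:
#'   a named list of [norm_spec()].
#' @export
write_norm_registry <- function(specs, path) {
  entries <- lapply(specs, function(s)
    list(id = s$id, kind = s$kind, ct = s$params$CT, mvcbct = s$params$MVCBCT))
  jsonlite::write_json(unname(entries), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_norm_registry
#' @export
read_norm_registry <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(entries) == 0) stop("empty method registry", call. = FALSE)
  specs <- lapply(entries, function(e)
    norm_spec(e$id, e$kind, ct = e$ct, mvcbct = e$mvcbct))
  names(specs) <- vapply(specs, `[[`, "", "id")
  specs
}
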