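#' Synthetic head-phantom specification
#'
#' Generative parameters for a head-like CT phantom built from nested
#' ellipsoids: an elliptical body (soft tissue) containing an air cavity,
#' a mandible-like bone compartment with high-HU teeth-like insets, and a
#' pair of parotid-like soft-tissue OARs. Default tissue volume fractions
#' follow the head composition typical of this anatomy: cavity 0.95%,
#' soft tissue 75.55%, bone 21.44%, teeth 2.06% of the in-body voxels.
#' Sub-structure sizes are derived analytically from the fractions
#' (ellipsoid volume scales with the product of semi-axes), so realized
#' fractions track the targets for any body size.
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing voxel spacing in mm.
#' @param body_semiaxes body ellipsoid semi-axes in mm.
#' @param fractions named target volume fractions (cavity, soft, bone,
#'   teeth); must sum to 1 within 0.01.
#' @param hu_means,hu_sds named per-tissue HU distribution parameters.
#' @param noise_sigma global additive Gaussian noise sigma in HU.
#' @param seed RNG seed making generation a pure function of the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 24L), spacing = c(2, 2, 5),
                         body_semiaxes = c(80, 88, 52),
                         fractions = c(cavity = 0.0095, soft = 0.7555,
                                       bone = 0.2144, teeth = 0.0206),
                         hu_means = c(cavity = -700, soft = 30,
                                      bone = 700, teeth = 2200),
                         hu_sds = c(cavity = 80, soft = 40,
                                    bone = 200, teeth = 250),
                         noise_sigma = 10, seed = 1L) {
  tissues <- c("cavity", "soft", "bone", "teeth")
  stopifnot(all(tissues %in% names(fractions)),
            all(tissues %in% names(hu_means)),
            all(tissues %in% names(hu_sds)))
  if (abs(sum(fractions) - 1) > 0.01)
    stop("tissue fractions must sum to 1 (+- 0.01)", call. = FALSE)
  sx <- body_semiaxes / (shape * spacing / 2)
  if (any(sx >= 1))
    stop("infeasible geometry: body ellipsoid exceeds the grid",
         call. = FALSE)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 body_semiaxes = as.numeric(body_semiaxes),
                 fractions = fractions[tissues], hu_means = hu_means[tissues],
                 hu_sds = hu_sds[tissues],
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# squared normalized distance to an ellipsoid (center/semi-axes in mm,
# relative to the grid center)
ellipsoid_d2 <- function(shape, spacing, center, semiaxes) {
  ax <- lapply(1:3, function(i) {
    co <- (seq_len(shape[i]) - (shape[i] + 1) / 2) * spacing[i]
    ((co - center[i]) / semiaxes[i])^2
  })
  outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
}

#' Generate a head-like CT phantom
#'
#' Builds the labelled geometry of a [phantom_spec()], draws per-voxel HU
#' values from each tissue's normal distribution, adds global noise, and
#' clips to \[-1000, 3000\] HU. Deterministic given the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with `ct` (a [ct_volume()]), `labels` (integer array:
#'   0 air, 1 cavity, 2 soft, 3 bone, 4 teeth) and `masks` (named list of
#'   [mask_volume()]s: body, oral_cavity, mandible, teeth, parotid).
#' @export
generate_ct <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape; sp <- spec$spacing; ba <- spec$body_semiaxes
  f <- spec$fractions
  # sub-structure scales: ellipsoid volume ~ product of semi-axes, so a
  # fraction f of the body needs semi-axes scaled by f^(1/3); teeth are
  # carved out of the bone compartment, so bone is sized for bone + teeth
  s_bone <- (f[["bone"]] + f[["teeth"]])^(1 / 3)
  s_teeth <- f[["teeth"]]^(1 / 3)
  s_cav <- f[["cavity"]]^(1 / 3)
  ell <- function(center_rel, scale)
    ellipsoid_d2(sh, sp, center_rel * ba, scale * ba) <= 1
  body <- ell(c(0, 0, 0), 1)
  if (!any(body))
    stop("infeasible geometry: empty body", call. = FALSE)
  bone <- ell(c(0, 0.25, 0), s_bone) & body
  teeth <- ell(c(0, 0.45, 0), s_teeth) & body
  cavity <- ell(c(0, -0.45, 0), s_cav) & body
  parotid_scale <- c(0.12, 0.12, 0.25)
  parotid <- (ell(c(0.55, 0, 0), parotid_scale) |
                ell(c(-0.55, 0, 0), parotid_scale)) & body
  labels <- array(0L, sh)
  labels[body] <- 2L      # soft
  labels[bone] <- 3L
  labels[cavity] <- 1L
  labels[teeth] <- 4L
  means <- c(-1000, spec$hu_means)   # air + tissues, indexed by label + 1
  sds <- c(0, spec$hu_sds)
  set.seed(spec$seed)
  n <- prod(sh)
  hu <- means[labels + 1L] + stats::rnorm(n) * sds[labels + 1L] +
    stats::rnorm(n) * spec$noise_sigma
  hu <- clip(array(hu, sh), -1000, 3000)
  list(ct = ct_volume(hu, spacing = sp, modality = "CT"),
       labels = labels,
       masks = list(body = mask_volume(labels > 0L, "body"),
                    oral_cavity = mask_volume(labels == 1L, "oral_cavity"),
                    mandible = mask_volume(labels == 3L, "mandible"),
                    teeth = mask_volume(labels == 4L, "teeth"),
                    parotid = mask_volume(parotid & labels == 2L, "parotid")))
}

#' MVCBCT degradation specification
#'
#' Parameters of the CT -> MVCBCT degradation: a monotone piecewise-linear
#' contrast map with a 1400 HU ceiling (megavoltage imaging compresses
#' high-HU contrast), a radial "cup" bias field (HU underestimated toward
#' the reconstruction center, `amplitude * (1 - (r/R)^exponent)` with R
#' the body edge radius), and additive Gaussian noise.
#'
#' @param contrast_knots k x 2 matrix (HU in, HU out) of the piecewise-
#'   linear map; must be non-decreasing with outputs <= 1400.
#' @param cup_amplitude cup bias at the center axis, in HU.
#' @param cup_exponent radial profile exponent.
#' @param noise_sigma Gaussian noise sigma in HU.
#' @param seed RNG seed.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(contrast_knots = rbind(c(-1000, -1000),
                                                    c(400, 400),
                                                    c(3000, 1400)),
                             cup_amplitude = 80, cup_exponent = 2,
                             noise_sigma = 25, seed = 1L) {
  contrast_knots <- as.matrix(contrast_knots)
  if (any(diff(contrast_knots[, 1]) <= 0) || any(diff(contrast_knots[, 2]) < 0))
    stop("contrast map must be monotone non-decreasing", call. = FALSE)
  if (max(contrast_knots[, 2]) > 1400)
    stop("contrast map output must not exceed 1400 HU", call. = FALSE)
  structure(list(contrast_knots = contrast_knots,
                 cup_amplitude = cup_amplitude,
                 cup_exponent = cup_exponent,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Degrade a CT volume into an MVCBCT counterpart
#'
#' Applies the contrast map, subtracts the radial cup bias field (maximal
#' on the volume center axis, zero at the body edge radius, estimated from
#' the in-plane extent of voxels above -400 HU), adds Gaussian noise, and
#' clips to \[-1000, 1400\] HU. Deterministic given the spec's seed.
#'
#' @param ct a [ct_volume()] in HU.
#' @param spec a [degradation_spec()].
#' @return A [ct_volume()] with modality `"MVCBCT"`.
#' @export
degrade_to_mvcbct <- function(ct, spec = degradation_spec()) {
  stopifnot(inherits(ct, "ct_volume"), inherits(spec, "degradation_spec"))
  if (ct$value_domain != "HU")
    stop("degrade_to_mvcbct expects an HU volume", call. = FALSE)
  sh <- dim(ct$data); sp <- ct$spacing
  hu <- stats::approx(spec$contrast_knots[, 1], spec$contrast_knots[, 2],
                      xout = as.vector(ct$data), rule = 2)$y
  hu <- array(hu, sh)
  if (spec$cup_amplitude != 0) {
    xs <- (seq_len(sh[1]) - (sh[1] + 1) / 2) * sp[1]
    ys <- (seq_len(sh[2]) - (sh[2] + 1) / 2) * sp[2]
    r2 <- outer(xs^2, ys^2, `+`)
    fg <- apply(ct$data > -400, c(1, 2), any)
    R <- if (any(fg)) sqrt(max(r2[fg])) else sqrt(max(r2))
    bias <- spec$cup_amplitude *
      pmax(0, 1 - (sqrt(r2) / R)^spec$cup_exponent)
    hu <- hu - as.vector(bias)   # recycled across slices (column-major)
  }
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    hu <- hu + stats::rnorm(length(hu), 0, spec$noise_sigma)
  }
  ct_volume(clip(array(hu, sh), -1000, 1400), spacing = sp,
            modality = "MVCBCT", value_domain = "HU")
}

#' Band-accuracy profile for a simulated candidate sCT
#'
#' Describes a candidate volume that reproduces the ground-truth CT inside
#' a designated reference-HU band and is corrupted (constant bias plus
#' noise) outside it. A set of profiles whose bands partition the MVCBCT
#' range \[-1000, 1400\] emulates the premise that differently-normalized
#' models are each accurate in different tissue bands.
#'
#' @param id candidate identifier.
#' @param band length-2 HU interval (half-open; the topmost band is closed).
#' @param bias out-of-band additive bias in HU.
#' @param out_sigma out-of-band Gaussian noise sigma in HU.
#' @param in_sigma in-band noise sigma in HU (default 0: exact in band).
#' @return An object of class `band_profile`.
#' @export
band_profile <- function(id, band, bias = 300, out_sigma = 30,
                         in_sigma = 0) {
  if (band[2] <= band[1]) stop("band must have lo < hi", call. = FALSE)
  structure(list(id = as.character(id), band = as.numeric(band),
                 bias = bias, out_sigma = out_sigma, in_sigma = in_sigma),
            class = "band_profile")
}

#' @rdname band_profile
#' @export
default_band_profiles <- function() {
  list(band_profile("sCT_A", c(-1000, -150)),
       band_profile("sCT_B", c(-150, 350)),
       band_profile("sCT_C", c(350, 1400)))
}

check_band_partition <- function(profiles, lo = -1000, hi = 1400) {
  bands <- do.call(rbind, lapply(profiles, `[[`, "band"))
  o <- order(bands[, 1])
  bands <- bands[o, , drop = FALSE]
  if (nrow(bands) > 1 && any(bands[-1, 1] < bands[-nrow(bands), 2]))
    stop("candidate bands overlap", call. = FALSE)
  if (bands[1, 1] > lo || bands[nrow(bands), 2] < hi ||
      (nrow(bands) > 1 && any(bands[-1, 1] != bands[-nrow(bands), 2])))
    stop("candidate bands must partition [", lo, ", ", hi, "] HU",
         call. = FALSE)
  invisible(TRUE)
}

#' Simulate band-accurate candidate sCT volumes
#'
#' Constructs one candidate volume per [band_profile()]: equal to the
#' ground-truth CT (up to `in_sigma` noise) where the smoothed MVCBCT HU
#' falls inside the profile's band, and biased/noisy elsewhere. Band
#' membership is decided on the same smoothed reference the combiner
#' partitions, so the designed bin-to-candidate assignment is recoverable
#' exactly. Deterministic given `seed`.
#'
#' @param ct ground-truth planning-CT [ct_volume()].
#' @param mvcbct degraded reference [ct_volume()].
#' @param profiles list of [band_profile()]s whose bands partition
#'   \[-1000, 1400\] HU.
#' @param seed RNG seed.
#' @param smooth_kernel mean-filter window used for band membership
#'   (match the combiner's `smooth_kernel`).
#' @param body optional body [mask_volume()]; derived with [body_mask()]
#'   from the CT when absent.
#' @return A [candidate_set()] with the planning CT attached.
#' @export
simulate_candidates <- function(ct, mvcbct,
                                profiles = default_band_profiles(),
                                seed = 1L, smooth_kernel = 5L,
                                body = NULL) {
  stopifnot(inherits(ct, "ct_volume"), inherits(mvcbct, "ct_volume"))
  check_band_partition(profiles)
  if (is.null(body)) body <- body_mask(ct)
  sm <- smooth_reference(mvcbct, smooth_kernel)
  set.seed(seed)
  n <- length(ct$data)
  cands <- list()
  for (p in profiles) {
    in_band <- sm$data >= p$band[1] &
      (sm$data < p$band[2] | (p$band[2] >= 1400 & sm$data <= p$band[2]))
    out_band <- !in_band
    noise <- stats::rnorm(n) * ifelse(out_band, p$out_sigma, p$in_sigma)
    vals <- ct$data + p$bias * out_band + array(noise, dim(ct$data))
    cands[[p$id]] <- ct_volume(vals, spacing = ct$spacing,
                               modality = "SCT", value_domain = "HU")
  }
  candidate_set(reference_mvcbct = mvcbct, candidates = cands,
                body = body, planning_ct = ct)
}

#' The designed bin-to-candidate assignment of a profile set
#'
#' For each bin of `partition`, the id of the profile whose band contains
#' the bin's midpoint — the ground-truth selection map the combiner is
#' expected to recover on supported bins.
#'
#' @param profiles list of [band_profile()]s.
#' @param partition an [hu_partition()].
#' @return character vector of candidate ids, one per bin.
#' @export
designed_winners <- function(profiles, partition = hu_partition()) {
  mids <- (partition$edges[-1] + partition$edges[-(partition$n_bins + 1)]) / 2
  vapply(mids, function(m) {
    for (p in profiles)
      if (m >= p$band[1] && m < p$band[2]) return(p$id)
    profiles[[length(profiles)]]$id
  }, "")
}

#' Generate a paired train/test phantom dataset
#'
#' Produces `n_train + n_test` cases, each a [candidate_set()] built from
#' an independently jittered phantom (body semi-axes scaled by a uniform
#' factor in \[0.9, 1.1\] per axis), its MVCBCT degradation, and
#' band-accurate candidates. All case seeds are drawn up front from the
#' master seed, disjointly across splits, so the whole dataset is a pure
#' function of `(specs, seed)`.
#'
#' @param n_train,n_test case counts (>= 1).
#' @param spec a [phantom_spec()] template.
#' @param deg_spec a [degradation_spec()] template.
#' @param profiles list of [band_profile()]s.
#' @param seed master RNG seed.
#' @return list with `train` and `test` lists of [candidate_set()]s.
#' @export
generate_dataset <- function(n_train = 3L, n_test = 1L,
                             spec = phantom_spec(),
                             deg_spec = degradation_spec(),
                             profiles = default_band_profiles(),
                             seed = 1L) {
  stopifnot(n_train >= 1, n_test >= 1)
  n <- n_train + n_test
  set.seed(seed)
  case_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 3L * n), n, 3L)
  jitter <- matrix(stats::runif(3L * n, 0.9, 1.1), n, 3L)
  make_case <- function(i, id) {
    ps <- spec
    ps$body_semiaxes <- spec$body_semiaxes * jitter[i, ]
    ps$seed <- case_seeds[i, 1]
    ds <- deg_spec
    ds$seed <- case_seeds[i, 2]
    ph <- generate_ct(ps)
    mv <- degrade_to_mvcbct(ph$ct, ds)
    cs <- simulate_candidates(ph$ct, mv, profiles,
                              seed = case_seeds[i, 3],
                              body = ph$masks$body)
    cs$id <- id
    cs
  }
  list(train = lapply(seq_len(n_train), function(i)
         make_case(i, sprintf("train_%d", i))),
       test = lapply(seq_len(n_test), function(j)
         make_case(n_train + j, sprintf("test_%d", j))))
}
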