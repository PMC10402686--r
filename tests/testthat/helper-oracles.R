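# Independent brute-force oracles and small fixtures, built in code.

# double-loop windowed mean with replicated borders, slice-wise; scalar
# accumulation in the same window scan order as a naive implementation
brute_mean_filter <- function(a, k) {
  r <- (k - 1) %/% 2
  d <- dim(a)
  out <- a
  cl <- function(i, n) min(max(i, 1L), n)
  for (s in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    acc <- 0
    for (dj in -r:r) for (di in -r:r)
      acc <- acc + a[cl(i + di, d[1]), cl(j + dj, d[2]), s]
    out[i, j, s] <- acc / (k * k)
  }
  out
}

# double-loop windowed median (sorted mid element), replicated borders
brute_median_filter <- function(a, k) {
  r <- (k - 1) %/% 2
  d <- dim(a)
  out <- a
  cl <- function(i, n) min(max(i, 1L), n)
  for (s in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    w <- numeric(k * k); t <- 0L
    for (dj in -r:r) for (di in -r:r) {
      t <- t + 1L
      w[t] <- a[cl(i + di, d[1]), cl(j + dj, d[2]), s]
    }
    out[i, j, s] <- sort(w)[(k * k + 1) %/% 2]
  }
  out
}

# cheap content fingerprint for distinctness checks
digest_chunk <- function(x)
  paste(format(sum(x), digits = 17), format(sum(x^2), digits = 17))

# 10-voxel toy pair shared by the metric and region-score oracles
toy_x <- c(-120, 35, 410, 1500, -680, 22, 960, 2600, -15, 75)
toy_y <- c(-100, 40, 380, 1450, -700, 30, 1000, 2550, 0, 60)

rand_vol <- function(dim = c(16, 16, 3), seed = 42, lo = -1000, hi = 2000,
                     modality = "CT") {
  set.seed(seed)
  ct_volume(array(runif(prod(dim), lo, hi), dim), modality = modality)
}

const_vol <- function(value, dim = c(8, 8, 3), modality = "CT")
  ct_volume(array(value, dim), modality = modality)

full_mask <- function(dim = c(8, 8, 3)) mask_volume(array(TRUE, dim))

# a phantom small enough for fast unit tests (~8k in-body voxels)
small_phantom_spec <- function(seed = 1, ...)
  phantom_spec(shape = c(48L, 48L, 10L), spacing = c(4, 4, 12),
               seed = seed, ...)

small_dataset <- function(seed = 1, n_train = 2, n_test = 1)
  generate_dataset(n_train, n_test, spec = small_phantom_spec(), seed = seed)
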