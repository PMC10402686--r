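# Printed mapped values for the CT parameter set at the five probe points
# {-1000, -400, 150, 1500, 3000} HU. Two cells follow the formula rather
# than the print: III at -1000 HU (tanh(-2.5) = -0.9866 rounds to -0.99)
# and VII at 1500 HU (tanh(-525/975) = -0.49, printed with flipped sign).
expected_mapped <- rbind(
  I   = c( 0.00,  0.15,  0.29,  0.63, 1.00),
  II  = c(-1.00, -0.70, -0.43,  0.25, 1.00),
  III = c(-0.99, -0.76,  0.36,  1.00, 1.00),
  IV  = c(-0.76,  0.39,  0.94,  1.00, 1.00),
  V   = c(-1.00, -0.87,  0.46,  1.00, 1.00),
  VI  = c(-1.00, -0.98, -0.76,  0.96, 1.00),
  VII = c(-1.00, -0.99, -0.96, -0.49, 0.76))

# printed interval proportions (%) over the cavity/soft/bone/teeth
# partition; V/teeth prints "<0.01" and is asserted as a bound below
expected_prop <- rbind(
  I   = c(15.00, 13.75, 33.75, 37.50),
  II  = c(15.00, 13.75, 33.75, 37.50),
  III = c(11.25, 56.00, 32.03,  0.06),
  IV  = c(57.58, 27.31,  3.19,  0.01),
  V   = c( 6.37, 66.61, 26.89,    NA),
  VI  = c( 1.08, 10.76, 86.28,  1.80),
  VII = c( 0.49,  1.40, 23.32, 62.67))

test_that("mapped values reproduce the published table at 2 dp", {
  tab <- mapped_value_table()
  expect_equal(tab$method, rownames(expected_mapped))
  got <- unname(as.matrix(tab[, -1]))
  expect_equal(got, unname(expected_mapped), tolerance = 1e-12)
})

test_that("interval proportions reproduce the published table", {
  rep <- distribution_report()
  for (m in rownames(expected_prop)) {
    got <- rep$proportion_pct[rep$method == m]
    exp <- expected_prop[m, ]
    expect_equal(got[!is.na(exp)], unname(exp[!is.na(exp)]),
                 tolerance = 1e-12, label = paste("method", m))
  }
  # V / teeth prints "<0.01": assert the bound on the unrounded value
  v_teeth <- interval_proportion(1500, 3000, norm_methods()$V)
  expect_gt(v_teeth, 0)
  expect_lt(v_teeth, 0.01)
})

test_that("soft tissue occupies 13.75% of the linear range and 56% of tanh", {
  expect_equal(interval_proportion(-400, 150, norm_methods()$I), 13.75)
  expect_equal(interval_proportion(-400, 150, norm_methods()$II), 13.75)
  expect_equal(round_half_away(
    interval_proportion(-400, 150, norm_methods()$III), 2), 56.00)
})

test_that("every method is strictly monotone in HU within bounds", {
  for (modality in c("CT", "MVCBCT")) {
    b <- modality_bounds(modality)
    hu <- seq(b[1], b[2], length.out = 400)
    for (spec in norm_methods()) {
      v <- mapped_value(hu, spec, modality)
      expect_true(all(diff(v) > 0),
                  label = paste("method", spec$id, modality))
    }
  }
})

test_that("normalize/denormalize round trip within 0.5 HU off-saturation", {
  set.seed(21)
  for (modality in c("CT", "MVCBCT")) {
    b <- modality_bounds(modality)
    hu <- runif(2000, b[1], b[2])
    vol <- ct_volume(array(hu, c(20, 20, 5)),
                     modality = if (modality == "MVCBCT") "MVCBCT" else "CT")
    for (spec in norm_methods()) {
      nv <- normalize_volume(vol, spec, modality)
      expect_identical(nv$value_domain,
                       if (spec$kind == "linear01") "NORM01" else "NORM11")
      back <- denormalize_volume(nv, spec, modality)
      keep <- if (spec$kind == "tanh") {
        p <- spec$params[[modality]]
        abs((vol$data - p$a) / p$b) <= 5
      } else array(TRUE, dim(vol$data))
      err <- max(abs(back$data[keep] - vol$data[keep]))
      expect_lt(err, 0.5, label = paste("method", spec$id, modality))
    }
  }
})

test_that("tanh inversion of saturated values stays finite", {
  spec <- norm_methods()$V
  v <- ct_volume(array(1, c(2, 2, 2)), value_domain = "NORM11")
  hu <- denormalize_volume(v, spec, "CT")
  expect_true(all(is.finite(hu$data)))
  expect_equal(hu$data[1], 0 + 300 * atanh(1 - 1e-7))
})

test_that("scalar mapped values match the formulas", {
  reg <- norm_methods()
  expect_equal(mapped_value(-400, reg$I), 0.15)
  expect_equal(mapped_value(-1000, reg$I), 0)
  expect_equal(mapped_value(150, reg$III), tanh(150 / 400))
  expect_equal(mapped_value(150, reg$II), 2 * 1150 / 4000 - 1)
  expect_equal(mapped_value(500, reg$III, "MVCBCT"), tanh(500 / 400))
  # out-of-bounds inputs are clipped to the modality range first
  expect_equal(mapped_value(5000, reg$I), 1)
  expect_equal(mapped_value(2000, reg$III, "MVCBCT"), tanh(1400 / 400))
  expect_equal(denormalize_volume(
    ct_volume(array(0.15, c(2, 2, 1)), value_domain = "NORM01"),
    reg$I, "CT")$data[1], -400)
})

test_that("interval proportions telescope and validate their arguments", {
  reg <- norm_methods()
  expect_error(interval_proportion(150, 150, reg$I), "lo < hi")
  for (spec in reg[c("I", "II")])
    expect_equal(interval_proportion(-1000, 3000, spec), 100)
  # over the standard tissue partition the rows telescope to 100 * (N(hi)-N(lo)) / W
  rep <- distribution_report(specs = norm_methods(), digits = NULL)
  for (m in names(reg)) {
    tot <- sum(rep$proportion_pct[rep$method == m])
    expect_equal(tot, interval_proportion(-1000, 3000, reg[[m]]),
                 tolerance = 1e-9)
  }
  # linear kinds cover the range exactly; tanh kinds fall short only by
  # endpoint saturation
  expect_equal(sum(rep$proportion_pct[rep$method == "I"]), 100)
  expect_equal(sum(rep$proportion_pct[rep$method == "II"]), 100)
  expect_error(distribution_report(rbind(c(-1000, 150), c(0, 3000))),
               "overlap")
  expect_error(distribution_report(rbind(c(-1000, 0), c(150, 3000))),
               "contiguous")
})

test_that("voxel histograms conserve counts", {
  v <- rand_vol(c(10, 9, 4), seed = 5)
  h <- voxel_value_histogram(v, bins = 17)
  expect_equal(sum(h$count), prod(dim(v$data)))
  hc <- voxel_value_histogram(const_vol(120), bins = 10)
  expect_equal(sum(hc$count > 0), 1)
  hn <- voxel_value_histogram(v, spec = norm_methods()$III, bins = 12)
  expect_equal(sum(hn$count), prod(dim(v$data)))
  expect_true(all(hn$lo >= -1) && all(hn$hi <= 1))
  expect_error(voxel_value_histogram(v, bins = 0), "bins")
})

test_that("the method registry serializes and restores exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  write_norm_registry(norm_methods(), path)
  back <- read_norm_registry(path)
  expect_equal(names(back), names(norm_methods()))
  for (m in names(back)) {
    expect_identical(back[[m]]$kind, norm_methods()[[m]]$kind)
    expect_equal(back[[m]]$params, norm_methods()[[m]]$params)
  }
  # a custom spec participates like the built-ins
  custom <- norm_spec("soft_narrow", "tanh", ct = list(a = 40, b = 120),
                      mvcbct = list(a = 20, b = 100))
  expect_equal(mapped_value(160, custom), tanh(1))
  expect_error(norm_spec("bad", "tanh", ct = list(a = 0, b = -1)), "b must")
  expect_error(norm_spec("bad", "linear01", ct = list(hu_min = 5, hu_max = 5)),
               "exceed")
})
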