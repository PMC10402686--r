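test_that("the HU partition follows the edge conventions", {
  part <- hu_partition()
  expect_equal(part$n_bins, 48L)
  expect_error(hu_partition(-1000, 1400, 33), "divide")
  body <- full_mask(c(4, 2, 1))
  lab_of <- function(hu) {
    v <- ct_volume(array(hu, c(4, 2, 1)), modality = "MVCBCT")
    partition_regions(v, body, part)[1]
  }
  expect_equal(lab_of(-1000), 1L)
  expect_equal(lab_of(1399.9), 48L)
  expect_equal(lab_of(1400), 48L)    # closed last bin
  expect_equal(lab_of(-30), 20L)     # floor((-30 + 1000)/50) = 19 (0-based)
  expect_equal(lab_of(-2000), 1L)    # clamp below
  expect_equal(lab_of(9000), 48L)    # clamp above
})

test_that("bin labels conserve the body voxel count", {
  ph <- generate_ct(small_phantom_spec(seed = 3))
  mv <- degrade_to_mvcbct(ph$ct)
  sm <- smooth_reference(mv, 5)
  lab <- partition_regions(sm, ph$masks$body, hu_partition())
  expect_equal(sum(lab > 0), sum(ph$masks$body$data))
  expect_true(all(lab[!ph$masks$body$data] == 0))
})

test_that("region SSIM scores masked populations per the formula", {
  d <- c(5, 2, 1)
  a <- ct_volume(array(toy_x, d)); b <- ct_volume(array(toy_y, d))
  reg <- array(TRUE, d)
  expect_equal(region_ssim(a, b, reg), 0.999368501190805, tolerance = 1e-12)
  expect_equal(region_ssim(a, a, reg), 1)
  expect_lt(region_ssim(ct_volume(array(toy_x + 500, d)), a, reg), 1)
  expect_true(is.na(region_ssim(a, b, array(FALSE, d))))
})

test_that("fitting with one candidate or tied candidates is deterministic", {
  ds <- small_dataset(seed = 5, n_train = 1, n_test = 1)
  tr <- ds$train[[1]]
  solo <- candidate_set(tr$reference_mvcbct, tr$candidates["sCT_B"],
                        tr$body, tr$planning_ct)
  sel <- fit_selection(list(solo), config = combiner_config(min_support = 10))
  expect_true(all(sel$winner == "sCT_B"))
  # two bitwise-identical candidates: lexicographically smaller id wins
  twin <- candidate_set(tr$reference_mvcbct,
                        list(zed = tr$candidates$sCT_B,
                             alpha = tr$candidates$sCT_B),
                        tr$body, tr$planning_ct)
  sel2 <- fit_selection(list(twin))
  expect_true(all(sel2$winner == "alpha"))
  expect_error(fit_selection(list(candidate_set(
    tr$reference_mvcbct, tr$candidates, tr$body))), "planning CT")
})

test_that("fitting recovers the designed band owners on supported bins", {
  ds <- small_dataset(seed = 1, n_train = 2, n_test = 1)
  sel <- fit_selection(ds$train)
  truth <- designed_winners(default_band_profiles(), sel$partition)
  expect_true(all(sel$winner[sel$supported] == truth[sel$supported]))
  expect_gt(sum(sel$supported), 5)
  expect_equal(sum(sel$n_voxels),
               sum(vapply(ds$train, function(cs) sum(cs$body$data),
                          numeric(1))))
})

test_that("stitching selects candidate voxels and fills outside the body", {
  ds <- small_dataset(seed = 2, n_train = 1, n_test = 1)
  sel <- fit_selection(ds$train)
  te <- ds$test[[1]]
  st <- stitch(te, sel)
  inb <- te$body$data
  cand_stack <- vapply(te$candidates, function(cv) cv$data[inb],
                       numeric(sum(inb)))
  # every in-body voxel value comes from one of the candidates
  expect_true(all(apply(abs(cand_stack - st$data[inb]) < 1e-9, 1, any)))
  # outside-body fill copies the base candidate (first id by default)
  base <- te$candidates[[sort(names(te$candidates))[1]]]
  expect_identical(st$data[!inb], base$data[!inb])
  # air fill mode
  st_air <- stitch(te, sel, combiner_config(outside_body_fill = "air"))
  expect_true(all(st_air$data[!inb] == -1000))
  expect_identical(st_air$data[inb], st$data[inb])
  # a selection naming a missing candidate errors
  sel_bad <- sel
  sel_bad$winner[] <- "nope"
  expect_error(stitch(te, sel_bad), "lacks candidate")
})

test_that("one global winner makes the stitched body equal that candidate", {
  ds <- small_dataset(seed = 3, n_train = 1, n_test = 1)
  tr <- ds$train[[1]]
  solo <- candidate_set(tr$reference_mvcbct, tr$candidates["sCT_A"],
                        tr$body, tr$planning_ct)
  sel <- fit_selection(list(solo), config = combiner_config(min_support = 10))
  st <- stitch(solo, sel)
  expect_identical(st$data[tr$body$data],
                   tr$candidates$sCT_A$data[tr$body$data])
})

test_that("combine_case is deterministic and blur kernel 1 is the identity", {
  ds <- small_dataset(seed = 4, n_train = 1, n_test = 1)
  sel <- fit_selection(ds$train)
  te <- ds$test[[1]]
  r1 <- combine_case(te, sel)
  r2 <- combine_case(te, sel)
  expect_identical(r1$combine$data, r2$combine$data)
  expect_identical(r1$blur$data, r2$blur$data)
  r3 <- combine_case(te, sel, combiner_config(blur_kernel = 1))
  expect_identical(r3$blur$data, r3$combine$data)
  expect_identical(attr(r1$combine, "name"), "sCT_Combine")
  expect_identical(attr(r1$blur, "name"), "sCT_Blur")
})

test_that("the fitted object supports the modelling-method surface", {
  ds <- small_dataset(seed = 6, n_train = 1, n_test = 1)
  sel <- fit_selection(ds$train)
  expect_s3_class(sel, "selection_map")
  expect_output(print(sel), "selection map")
  sm <- summary(sel)
  expect_equal(nrow(sm), 48)
  expect_true(all(c("bin", "winner", "n_voxels") %in% names(sm)))
  cf <- coef(sel)
  expect_length(cf, 48)
  expect_match(names(cf)[1], "-1000")
  pr <- predict(sel, ds$test[[1]])
  expect_named(pr, c("combine", "blur"))
  pb <- predict(sel, ds$test[[1]], type = "blur")
  expect_identical(pb$data, pr$blur$data)
  pdf(NULL)
  on.exit(dev.off(), add = TRUE)
  expect_invisible(plot(sel))
})

test_that("selection maps survive a JSON round trip", {
  ds <- small_dataset(seed = 7, n_train = 1, n_test = 1)
  sel <- fit_selection(ds$train)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, path)
  back <- read_selection(path)
  expect_identical(back$winner, sel$winner)
  expect_equal(back$scores, sel$scores)
  expect_identical(back$supported, sel$supported)
  expect_equal(back$n_voxels, sel$n_voxels)
  r1 <- predict(sel, ds$test[[1]], type = "combine")
  r2 <- predict(back, ds$test[[1]], type = "combine")
  expect_identical(r1$data, r2$data)
})

test_that("candidate sets validate geometry and naming", {
  ds <- small_dataset(seed = 8, n_train = 1, n_test = 1)
  tr <- ds$train[[1]]
  expect_error(candidate_set(tr$reference_mvcbct,
                             unname(tr$candidates), tr$body),
               "unique non-empty names")
  small <- ct_volume(array(0, c(4, 4, 2)))
  expect_error(candidate_set(tr$reference_mvcbct, list(x = small), tr$body),
               "share one grid")
})
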