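# Area histogram, first-peak model and nuclear-quantity assignment.

test_that("histogram bins tally areas exactly", {
  h <- build_area_histogram(c(50, 50, 50), bin_width = 10)
  expect_equal(sum(h$count > 0), 1L)
  expect_equal(h$count[h$bin_lower == 50], 3L)

  h2 <- build_area_histogram(c(50, 51, 52, 100, 101), bin_width = 5)
  expect_equal(sort(h2$count[h2$count > 0]), c(2L, 3L))
  expect_equal(sum(h2$count), 5L)

  set.seed(9)
  areas <- sample(20:400, 1000, replace = TRUE)
  h3 <- build_area_histogram(areas, bin_width = 10)
  for (i in sample(nrow(h3), 20)) {
    brute <- sum(areas >= h3$bin_lower[i] & areas < h3$bin_upper[i])
    expect_identical(h3$count[i], as.integer(brute))
  }
  expect_error(build_area_histogram(numeric(0)),
               class = "cfc_calibration_error")
})

test_that("user-bound calibration takes the exact mean inside the bounds", {
  areas <- c(rep(48, 30), rep(96, 10))
  h <- build_area_histogram(areas, bin_width = 10)
  cal <- fit_calibration(h, bounds = c(40, 60))
  expect_identical(cal$source, "USER_BOUNDS")
  expect_equal(cal$mean_single_area, 48)
  expect_equal(cal$n_singles, 30L)
  expect_error(fit_calibration(h, bounds = c(200, 300)),
               class = "cfc_calibration_error")
  expect_error(fit_calibration(h, bounds = c(60, 40)),
               class = "cfc_param_error")
})

test_that("automatic peak finding recovers a degenerate unimodal ensemble", {
  h <- build_area_histogram(rep(50, 25), bin_width = 10)
  expect_warning(cal <- fit_calibration(h), "single-bin")
  expect_true(cal$first_peak_lower <= 50 && 50 <= cal$first_peak_upper)
  expect_equal(cal$mean_single_area, 50)
  expect_identical(cal$source, "AUTO")
})

test_that("automatic calibration recovers the single-nucleus mean of a mixture", {
  set.seed(123)
  singles <- rnorm(350, 60, 5)
  doublets <- rnorm(150, 120, 8)
  h <- build_area_histogram(c(singles, doublets), bin_width = 10)
  cal <- fit_calibration(h)
  expect_lt(abs(cal$mean_single_area - 60) / 60, 0.10)
  expect_identical(cal$source, "AUTO")
  td <- tidy(cal)
  expect_identical(td$mean_single_area, cal$mean_single_area)
})

test_that("quantity assignment is 1 in the peak, area ratio outside", {
  regions <- tibble::tibble(label = 1:4,
                            area_px = c(60, 180, 20, 45),
                            centroid_row = 1, centroid_col = 1)
  model <- fit_calibration(build_area_histogram(rep(60, 10), bin_width = 10),
                           bounds = c(50, 70))
  nuc <- assign_nuclear_quantities(regions, model)
  expect_equal(nuc$nuclear_quantity[1], 1)          # inside bounds
  expect_equal(nuc$nuclear_quantity[2], 3)          # 3x the mean
  expect_equal(nuc$nuclear_quantity[3], 20 / 60)    # sub-peak debris
  expect_true(all(nuc$in_first_peak == c(TRUE, FALSE, FALSE, FALSE)))
  expect_true(all(is.na(nuc$assigned_mhc_label)))

  # min_area filter discards debris rows entirely
  nuc2 <- assign_nuclear_quantities(regions, model, min_area = 30)
  expect_identical(nrow(nuc2), 3L)
  expect_false(20 %in% nuc2$area_px)
})

test_that("total quantity is conserved and scale-equivariant", {
  set.seed(5)
  areas <- c(rnorm(100, 60, 4), rnorm(30, 125, 10))
  regions <- tibble::tibble(label = seq_along(areas), area_px = areas,
                            centroid_row = 1, centroid_col = 1)
  model <- fit_calibration(build_area_histogram(areas, bin_width = 10),
                           bounds = c(45, 75))
  nuc <- assign_nuclear_quantities(regions, model)
  in_peak <- areas >= 45 & areas <= 75
  expect_equal(sum(nuc$nuclear_quantity),
               sum(in_peak) + sum(areas[!in_peak]) / model$mean_single_area,
               tolerance = 1e-12)

  # doubling every area and both bounds leaves quantities unchanged
  regions2 <- dplyr::mutate(regions, area_px = area_px * 2)
  model2 <- fit_calibration(build_area_histogram(areas * 2, bin_width = 10),
                            bounds = c(90, 150))
  nuc2 <- assign_nuclear_quantities(regions2, model2)
  expect_equal(nuc2$nuclear_quantity, nuc$nuclear_quantity, tolerance = 1e-12)
})

test_that("an ensemble of equal in-peak singles totals exactly its count", {
  areas <- rep(63, 17)
  model <- fit_calibration(build_area_histogram(areas, bin_width = 10),
                           bounds = c(55, 70))
  nuc <- assign_nuclear_quantities(
    tibble::tibble(label = 1:17, area_px = areas,
                   centroid_row = 1, centroid_col = 1), model)
  expect_identical(sum(nuc$nuclear_quantity), 17)
})

test_that("synthetic singles + doublets ensembles recover s + 2d within 5%", {
  set.seed(31)
  for (rep in 1:3) {
    s <- 160; d <- 40
    singles <- rnorm(s, 60, 5)
    doublets <- rnorm(d, 120, 8)   # clean doublets: area ~ 2x single
    areas <- c(singles, doublets)
    model <- fit_calibration(build_area_histogram(areas, bin_width = 10))
    nuc <- assign_nuclear_quantities(
      tibble::tibble(label = seq_along(areas), area_px = areas,
                     centroid_row = 1, centroid_col = 1), model)
    expect_lt(abs(sum(nuc$nuclear_quantity) - (s + 2 * d)) / (s + 2 * d), 0.05)
  }
})
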