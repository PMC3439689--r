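# Micrograph reading, channel extraction, overlays and the results CSV.

test_that("channel intensities are scaled linearly from the source bit depth", {
  f <- withr::local_tempfile(fileext = ".png")
  arr <- array(0, dim = c(2, 2, 3))
  arr[, , 1] <- 1                      # pure red at full scale
  png::writePNG(arr, f)
  m <- read_micrograph(f)
  expect_equal(m$red, matrix(1, 2, 2))
  expect_equal(m$blue, matrix(0, 2, 2))

  arr2 <- array(0, dim = c(2, 2, 3))
  arr2[, , 3] <- 128 / 255             # mid-scale blue, 8-bit
  png::writePNG(arr2, f)
  m2 <- read_micrograph(f)
  expect_equal(m2$blue, matrix(128 / 255, 2, 2), tolerance = 1e-12)
})

test_that("a synthetic colony survives a PNG write/read round trip losslessly", {
  col <- generate_colony(colony_spec(seed = 11, width = 64, height = 64,
                                     n_singles = 3, n_doublets = 1,
                                     n_multiplets = 0, n_mhc_regions = 1))
  f <- withr::local_tempfile(fileext = ".png")
  # quantize to the 8-bit grid first so the written file represents the
  # planes exactly
  q <- function(x) round(x * 255) / 255
  m <- col$micrograph
  m$red <- q(m$red); m$green <- q(m$green); m$blue <- q(m$blue)
  write_micrograph(m, f)
  back <- read_micrograph(f)
  expect_equal(back$red, m$red, tolerance = 1e-12)
  expect_equal(back$green, m$green, tolerance = 1e-12)
  expect_equal(back$blue, m$blue, tolerance = 1e-12)
  expect_identical(back$image_id, tools::file_path_sans_ext(basename(f)))
})

test_that("grayscale input is rejected and RGBA alpha is dropped with a warning", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 4, 4), f)
  expect_error(read_micrograph(f), class = "cfc_channel_error")

  rgba <- array(runif(4 * 4 * 4), dim = c(4, 4, 4))
  png::writePNG(rgba, f)
  expect_warning(m <- read_micrograph(f), "alpha")
  expect_length(dim(m$red), 2)

  expect_error(read_micrograph(file.path(tempdir(), "nope.png")),
               class = "cfc_io_error")
  f2 <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", f2)
  expect_error(read_micrograph(f2), class = "cfc_decode_error")
})

test_that("extract_channel projects the right untouched plane", {
  blue <- matrix(runif(12), 3, 4)
  red <- matrix(runif(12), 3, 4)
  m <- micrograph(red = red, green = matrix(0, 3, 4), blue = blue, "im1")
  expect_identical(extract_channel(m, "DAPI_BLUE")$pixels, blue)
  expect_identical(extract_channel(m, "MHC_RED")$pixels, red)
  # planes are independent copies
  p <- extract_channel(m, "DAPI_BLUE")
  p$pixels[1, 1] <- 0.123
  expect_identical(m$blue, blue)
  # all-black image
  z <- micrograph(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2), "z")
  expect_true(all(extract_channel(z, "MHC_RED")$pixels == 0))
})

test_that("overlay paints MHC pixels red, nuclei by size class, background black", {
  m <- micrograph(matrix(0, 12, 12), matrix(0, 12, 12), matrix(0, 12, 12), "ov")
  empty <- label_regions(matrix(FALSE, 12, 12))
  ov0 <- render_overlay(m, assign_nuclear_quantities(
    empty, structure(list(first_peak_lower = 1, first_peak_upper = 2,
                          mean_single_area = 1.5, n_singles = 1,
                          source = "USER_BOUNDS"),
                     class = "nucleus_calibration")), empty, empty)
  expect_true(all(ov0 == 0))

  mhc_mask <- matrix(FALSE, 12, 12); mhc_mask[1:10, 1:3] <- TRUE
  mhc <- label_regions(mhc_mask)
  ov1 <- render_overlay(m, assign_nuclear_quantities(
    empty, structure(list(first_peak_lower = 1, first_peak_upper = 2,
                          mean_single_area = 1.5, n_singles = 1,
                          source = "USER_BOUNDS"),
                     class = "nucleus_calibration")), empty, mhc)
  expect_true(all(ov1[, , 1][mhc_mask] == 1))
  expect_true(all(ov1[, , 2][mhc_mask] == 0))

  # ground-truth nucleus pixels are non-black in a full rendering
  col <- generate_colony(colony_spec(seed = 5, width = 96, height = 96,
                                     n_singles = 4, n_doublets = 1,
                                     n_multiplets = 0, n_mhc_regions = 1,
                                     background_noise_sd = 0, speck_count = 0))
  res <- analyze_colony(col, model = structure(
    list(first_peak_lower = 1, first_peak_upper = 1e5,
         mean_single_area = 60, n_singles = 1, source = "USER_BOUNDS"),
    class = "nucleus_calibration"))
  dapi_full <- segment_channel(extract_channel(col$micrograph, "DAPI_BLUE"),
                               dapi_params())
  mhc_full <- detect_mhc_regions(extract_channel(col$micrograph, "MHC_RED"),
                                 mhc_params())
  ov <- render_overlay(col$micrograph, res$nuclei, dapi_full, mhc_full)
  tot <- ov[, , 1] + ov[, , 2] + ov[, , 3]
  for (i in seq_len(nrow(col$truth$nuclei)))
    expect_gt(tot[col$truth$nuclei$row[i], col$truth$nuclei$col[i]], 0)

  bad <- label_regions(matrix(FALSE, 5, 5))
  expect_error(render_overlay(m, res$nuclei, bad, bad),
               class = "cfc_dim_error")
})

test_that("results CSV appends one row per colony and round-trips exactly", {
  f <- withr::local_tempfile(fileext = ".csv")
  met <- tibble::tibble(image_id = "a", total_nuclei = 10.25,
                        stain_negative_nuclei = 4.125,
                        mhc_positive_nuclei = 6.125,
                        df = 6.125 / 10.25, ui = 1 / 3,
                        mono_count = 2L, bi_count = 1L, multi_count = 1L,
                        anucleate_count = 0L)
  append_results_csv(f, met)
  expect_length(readLines(f), 2L)
  for (i in 1:3) append_results_csv(f, met)
  expect_length(readLines(f), 5L)

  back <- read_results_csv(f)
  expect_identical(back$image_id[1], "a")
  expect_identical(back$df[1], met$df)          # full double precision
  expect_identical(back$ui[1], met$ui)
  expect_identical(back$total_nuclei[1], met$total_nuclei)

  # header mismatch refuses to append
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("foo,bar", f2)
  expect_error(append_results_csv(f2, met), class = "cfc_format_error")
})
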