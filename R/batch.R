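# Batch driver: directory scan, two-pass calibration + analysis, CSV /
# overlay / histogram / summary artifacts, logging.

#' Configuration for a batch run
#'
#' @param input_dir directory of `.png` / `.tif` / `.tiff` micrographs.
#' @param output_dir directory for all artifacts (created if needed).
#' @param dapi_radius,dapi_threshold opening radius and threshold for the
#'   blue (DAPI) channel.
#' @param mhc_radius,mhc_threshold opening radius and threshold for the red
#'   (MHC) channel.
#' @param peak_lower,peak_upper optional user-selected first-peak area
#'   bounds (px); both `NULL` selects automatic peak finding.
#' @param bin_width area histogram bin width (px).
#' @param min_area discard DAPI+ regions smaller than this before quantity
#'   assignment (0 = off).
#' @param overlays write a rasterized overlay PNG per image.
#' @param group_name label used in the summary CSV; defaults to the input
#'   directory name.
#' @param log_level `"info"` or `"quiet"`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir,
                       dapi_radius = 2, dapi_threshold = 0.3,
                       mhc_radius = 3, mhc_threshold = 0.3,
                       peak_lower = NULL, peak_upper = NULL,
                       bin_width = 10, min_area = 0,
                       overlays = FALSE, group_name = NULL,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (xor(is.null(peak_lower), is.null(peak_upper)))
    stop_cfc("peak_lower and peak_upper must be given together",
             class = "cfc_param_error")
  if (!is.null(peak_lower) && peak_lower > peak_upper)
    stop_cfc("peak_lower must not exceed peak_upper",
             class = "cfc_param_error")
  # parameter validation is delegated to segmentation_params
  dapi <- segmentation_params(dapi_radius, dapi_threshold, "DAPI_BLUE")
  mhc <- segmentation_params(mhc_radius, mhc_threshold, "MHC_RED")
  if (is.null(group_name)) group_name <- basename(normalizePath(input_dir,
                                                                mustWork = FALSE))
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 dapi = dapi, mhc = mhc,
                 peak_bounds = if (is.null(peak_lower)) NULL
                               else c(peak_lower, peak_upper),
                 bin_width = bin_width, min_area = min_area,
                 overlays = isTRUE(overlays), group_name = group_name,
                 log_level = log_level),
            class = "run_config")
}

discover_images <- function(input_dir) {
  files <- list.files(input_dir, pattern = "\\.(tif|tiff|png)$",
                      ignore.case = TRUE, full.names = TRUE)
  # byte-order sort: processing order must not depend on the locale
  files[order(basename(files), method = "radix")]
}

make_logger <- function(path, level) {
  con <- file(path, open = "w", encoding = "UTF-8")
  list(
    log = function(...) {
      line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
      writeLines(line, con)
      if (level == "info") message(line)
    },
    close = function() close(con))
}

# pass 1: segment the DAPI channel of every readable image
segment_pass <- function(files, config, logger) {
  per_image <- list()
  skipped <- character(0)
  for (f in files) {
    res <- tryCatch({
      m <- read_micrograph(f)
      dapi <- segment_channel(extract_channel(m, "DAPI_BLUE"), config$dapi,
                              boundaries = FALSE)
      list(micrograph = m, dapi = dapi)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, f)
      logger$log("SKIP ", f, ": ", conditionMessage(res))
    } else {
      per_image[[res$micrograph$image_id]] <- res
      logger$log("read ", basename(f), ": ",
                 nrow(res$dapi$regions), " DAPI+ region(s)")
    }
  }
  list(per_image = per_image, skipped = skipped)
}

calibrate_from_pass <- function(per_image, config, logger) {
  all_areas <- unlist(lapply(per_image, function(x) x$dapi$regions$area_px))
  hist <- build_area_histogram(all_areas, bin_width = config$bin_width)
  model <- fit_calibration(hist, bounds = config$peak_bounds)
  logger$log(sprintf(
    "calibration [%s]: first peak [%g, %g] px, mean single area %.2f (n=%d)",
    model$source, model$first_peak_lower, model$first_peak_upper,
    model$mean_single_area, model$n_singles))
  list(hist = hist, model = model)
}

write_histogram_artifacts <- function(hist, output_dir) {
  hcsv <- file.path(output_dir, "histogram.csv")
  utils::write.csv(
    data.frame(bin_lower = hist$bin_lower, bin_upper = hist$bin_upper,
               count = hist$count),
    hcsv, row.names = FALSE)
  hpng <- file.path(output_dir, "histogram.png")
  ggplot2::ggsave(hpng, ggplot2::autoplot(hist),
                  width = 6, height = 4, dpi = 150, device = "png")
  c(hcsv, hpng)
}

#' Run the full batch analysis over a directory of micrographs
#'
#' Two passes over the images, in lexicographic (byte-order) filename
#' order. Pass 1 segments every blue channel and fits the dataset-wide
#' size calibration (user bounds if configured, automatic first-peak
#' detection otherwise). Pass 2 assigns nuclear quantities, detects MHC+
#' regions, maps centroids, computes per-colony metrics and appends each
#' colony's row to `results.csv`, writing an overlay PNG per image when
#' requested. The run ends with `summary.csv` (group mean and 95% CI of
#' total nuclei, df and ui), `histogram.csv`/`histogram.png`, and a plain
#' text `run.log`. Unreadable images are logged and skipped; outputs are
#' rewritten from scratch on every run so identical inputs and
#' configuration reproduce identical CSVs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list of class `cfc_batch`: `metrics` (per-colony
#'   tibble), `calibration`, `summary`, `skipped`, `paths`.
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "run_config"))
  files <- discover_images(config$input_dir)
  if (length(files) == 0L)
    stop_cfc("no readable images (.png/.tif/.tiff) in ", config$input_dir,
             class = "cfc_io_error")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logger <- make_logger(file.path(config$output_dir, "run.log"),
                        config$log_level)
  on.exit(logger$close())
  logger$log("batch start: ", length(files), " image file(s) in ",
             config$input_dir)

  pass1 <- segment_pass(files, config, logger)
  if (length(pass1$per_image) == 0L)
    stop_cfc("no image in ", config$input_dir, " could be processed",
             class = "cfc_io_error")
  cal <- calibrate_from_pass(pass1$per_image, config, logger)

  results_csv <- file.path(config$output_dir, "results.csv")
  if (file.exists(results_csv)) unlink(results_csv)
  metrics_rows <- list()
  for (id in names(pass1$per_image)) {
    item <- pass1$per_image[[id]]
    nuclei <- assign_nuclear_quantities(item$dapi, cal$model,
                                        min_area = config$min_area)
    mhc <- detect_mhc_regions(extract_channel(item$micrograph, "MHC_RED"),
                              config$mhc, boundaries = FALSE)
    asg <- assign_nuclei_to_mhc(nuclei, mhc)
    met <- compute_colony_metrics(asg$nuclei, asg$mhc, id)
    append_results_csv(results_csv, met)
    metrics_rows[[id]] <- met
    logger$log(sprintf(
      "%s: total %.2f nuclei, df %.4f, ui %.4f (%d MHC+ region(s))",
      id, met$total_nuclei, met$df, met$ui, nrow(asg$mhc)))
    if (config$overlays) {
      ov <- render_overlay(item$micrograph, asg$nuclei, item$dapi, mhc)
      png::writePNG(ov, file.path(config$output_dir,
                                  paste0(id, "_overlay.png")))
    }
  }
  metrics <- dplyr::bind_rows(metrics_rows)

  summary_tbl <- dplyr::bind_rows(lapply(c("TOTAL", "DF", "UI"), function(mm)
    summarize_group(metrics, mm)))
  summary_tbl <- dplyr::mutate(summary_tbl, group = config$group_name,
                               .after = "metric")
  summary_csv <- file.path(config$output_dir, "summary.csv")
  utils::write.csv(summary_tbl, summary_csv, row.names = FALSE)
  hist_paths <- write_histogram_artifacts(cal$hist, config$output_dir)
  logger$log("batch done: ", nrow(metrics), " colonies, ",
             length(pass1$skipped), " skipped")

  invisible(structure(
    list(metrics = metrics, calibration = cal$model, summary = summary_tbl,
         skipped = pass1$skipped,
         paths = list(results = results_csv, summary = summary_csv,
                      histogram = hist_paths[1],
                      histogram_plot = hist_paths[2],
                      log = file.path(config$output_dir, "run.log"))),
    class = "cfc_batch"))
}

#' @export
print.cfc_batch <- function(x, ...) {
  cat(sprintf("<cfc_batch>  %d colonies (%d skipped), calibration [%s]\n",
              nrow(x$metrics), length(x$skipped), x$calibration$source))
  print(x$summary, ...)
  invisible(x)
}

#' Calibration-only pass over a directory
#'
#' Runs pass 1 only and writes the pooled DAPI+ area histogram
#' (`histogram.csv` and `histogram.png`) so the user can pick first-peak
#' bounds, supporting the iterate-on-R-and-T calibration workflow before a
#' full [run_batch()].
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `histogram`, `model` (the automatic or
#'   user-bound fit) and `skipped`.
#' @export
run_calibrate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  files <- discover_images(config$input_dir)
  if (length(files) == 0L)
    stop_cfc("no readable images (.png/.tif/.tiff) in ", config$input_dir,
             class = "cfc_io_error")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logger <- make_logger(file.path(config$output_dir, "run.log"),
                        config$log_level)
  on.exit(logger$close())
  pass1 <- segment_pass(files, config, logger)
  if (length(pass1$per_image) == 0L)
    stop_cfc("no image in ", config$input_dir, " could be processed",
             class = "cfc_io_error")
  cal <- calibrate_from_pass(pass1$per_image, config, logger)
  write_histogram_artifacts(cal$hist, config$output_dir)
  invisible(list(histogram = cal$hist, model = cal$model,
                 skipped = pass1$skipped))
}
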