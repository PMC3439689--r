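# Reading micrographs, splitting channels, overlay rendering, CSV output.

#' Construct a micrograph from channel matrices
#'
#' A micrograph holds the three colour planes of a merged RGB fluorescence
#' image as numeric matrices with intensities in `[0, 1]`. Blue carries the
#' DAPI nuclear counterstain, red the MHC (sarcomeric myosin heavy chain)
#' immunostain; green is retained but unused by the analysis.
#'
#' @param red,green,blue numeric matrices of identical dimension, values in
#'   `[0, 1]`. Row 1 is the top of the image; indices are 1-based.
#' @param image_id non-empty string identifying the image within a batch.
#' @return an object of class `micrograph`.
#' @export
micrograph <- function(red, green, blue, image_id) {
  if (!is.character(image_id) || length(image_id) != 1L || !nzchar(image_id))
    stop_cfc("image_id must be a non-empty string", class = "cfc_value_error")
  planes <- list(red = red, green = green, blue = blue)
  dims <- lapply(planes, dim)
  if (any(!vapply(planes, is.matrix, logical(1))) ||
      !all(vapply(dims, identical, logical(1), dims[[1]])))
    stop_cfc("red, green and blue must be matrices of identical dimensions",
             class = "cfc_dim_error")
  rng <- range(unlist(lapply(planes, range)))
  if (rng[1] < 0 || rng[2] > 1)
    stop_cfc("intensities must lie in [0, 1]", class = "cfc_value_error")
  structure(list(image_id = image_id, red = red, green = green, blue = blue),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  d <- dim(x$red)
  cat(sprintf("<micrograph '%s'>  %d x %d px, RGB in [0,1]\n",
              x$image_id, d[1], d[2]))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$red)

#' Read an RGB micrograph from disk
#'
#' Decodes a TIFF or PNG raster and normalizes intensities to `[0, 1]` by
#' dividing by the maximum representable value of the source bit depth, so a
#' pixel at full scale maps to exactly 1 regardless of whether the file is
#' 8- or 16-bit. Grayscale images are rejected because the method needs the
#' blue (DAPI) and red (MHC) planes to be separable; an alpha plane, a common
#' microscope-export artifact, is dropped with a warning.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return a [micrograph] whose `image_id` is the file name without extension.
#' @export
#' @examples
#' spec <- colony_spec(seed = 1, n_singles = 5, n_doublets = 0,
#'                     n_multiplets = 0, n_mhc_regions = 1)
#' col <- generate_colony(spec)
#' f <- file.path(tempdir(), "colony.png")
#' write_micrograph(col$micrograph, f)
#' m <- read_micrograph(f)
read_micrograph <- function(path) {
  if (!file.exists(path))
    stop_cfc("file does not exist: ", path, class = "cfc_io_error")
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = ,
           tiff = tiff::readTIFF(path),
           stop_cfc("unsupported image extension '", ext, "' for: ", path,
                    class = "cfc_io_error")),
    error = function(e) {
      if (inherits(e, "cfcquant_error")) stop(e)
      stop_cfc("failed to decode image: ", path, " (", conditionMessage(e), ")",
               class = "cfc_decode_error")
    })
  if (is.matrix(arr) || (length(dim(arr)) == 3L && dim(arr)[3] %in% c(1L, 2L)))
    stop_cfc("grayscale image has no blue/red channel separation: ", path,
             class = "cfc_channel_error")
  if (length(dim(arr)) != 3L)
    stop_cfc("not an RGB raster: ", path, class = "cfc_decode_error")
  if (dim(arr)[3] == 4L) {
    warning("dropping alpha plane of RGBA image: ", path, call. = FALSE)
    arr <- arr[, , 1:3, drop = FALSE]
  }
  micrograph(red = arr[, , 1], green = arr[, , 2], blue = arr[, , 3],
             image_id = tools::file_path_sans_ext(basename(path)))
}

#' Write a micrograph to disk as PNG or TIFF
#'
#' @param m a [micrograph].
#' @param path destination path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(m, path) {
  stopifnot(inherits(m, "micrograph"))
  arr <- array(c(m$red, m$green, m$blue), dim = c(dim(m$red), 3L))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(arr, path),
         tif = ,
         tiff = tiff::writeTIFF(arr, path),
         stop_cfc("unsupported image extension '", ext, "'",
                  class = "cfc_io_error"))
  invisible(path)
}

#' Extract one analysis channel from a micrograph
#'
#' The nuclear count uses only the blue (DAPI) plane and MHC detection only
#' the red plane; the method assumes negligible bleed-through between them.
#'
#' @param m a [micrograph].
#' @param channel `"DAPI_BLUE"` or `"MHC_RED"`.
#' @return an object of class `channel_plane` with fields `channel`,
#'   `pixels` (numeric matrix in `[0, 1]`) and `source_image_id`.
#' @export
extract_channel <- function(m, channel) {
  stopifnot(inherits(m, "micrograph"))
  channel <- match_channel(channel)
  px <- if (channel == "DAPI_BLUE") m$blue else m$red
  structure(list(channel = channel, pixels = px,
                 source_image_id = m$image_id),
            class = "channel_plane")
}

#' @export
print.channel_plane <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<channel_plane %s of '%s'>  %d x %d px\n",
              x$channel, x$source_image_id, d[1], d[2]))
  invisible(x)
}

# colour code for the overlay: size class from the rounded nuclear quantity
overlay_palette <- list(
  single  = c(0.15, 0.35, 1.00),  # blue: in-peak / rounds to <= 1
  doublet = c(0.00, 0.85, 0.85),  # cyan: rounds to 2
  larger  = c(1.00, 0.20, 1.00)   # magenta: rounds to >= 3
)

#' Render a rasterized overlay of the analysed colony
#'
#' Produces the visual-QC rendering written next to the results: MHC+
#' cytoplasm in red, each DAPI+ region coloured by its size class under the
#' calibration (blue for single-nucleus regions, cyan for doublet-scale
#' regions, magenta for larger clumps), background black. Nuclei are drawn
#' over MHC pixels.
#'
#' @param m the source [micrograph].
#' @param nuclei nucleus record tibble from [assign_nuclear_quantities()]
#'   (columns `label`, `nuclear_quantity`).
#' @param dapi_regions the DAPI [label_regions()] region set the nuclei were derived from.
#' @param mhc_regions the MHC [label_regions()] region set (may contain zero regions).
#' @return an `height x width x 3` numeric array in `[0, 1]`.
#' @export
render_overlay <- function(m, nuclei, dapi_regions, mhc_regions) {
  stopifnot(inherits(m, "micrograph"))
  d <- dim(m$red)
  if (!identical(d, dim(dapi_regions$labels)) ||
      !identical(d, dim(mhc_regions$labels)))
    stop_cfc("label images do not match micrograph dimensions",
             class = "cfc_dim_error")
  out <- array(0, dim = c(d, 3L))
  red <- matrix(0, d[1], d[2]); grn <- red; blu <- red
  red[mhc_regions$labels > 0] <- 1
  if (nrow(nuclei) > 0) {
    cls <- pmin(pmax(round_half_up(nuclei$nuclear_quantity), 1), 3)
    lab <- dapi_regions$labels
    idx <- which(lab > 0)
    lab_cls <- rep(NA_real_, max(lab))
    lab_cls[nuclei$label] <- cls
    px_cls <- lab_cls[lab[idx]]
    keep <- !is.na(px_cls)
    idx <- idx[keep]; px_cls <- px_cls[keep]
    pal <- rbind(overlay_palette$single, overlay_palette$doublet,
                 overlay_palette$larger)
    red[idx] <- pal[px_cls, 1]
    grn[idx] <- pal[px_cls, 2]
    blu[idx] <- pal[px_cls, 3]
  }
  out[, , 1] <- red; out[, , 2] <- grn; out[, , 3] <- blu
  out
}

results_csv_header <- c("image_id", "total_nuclei", "stain_negative_nuclei",
                        "mhc_positive_nuclei", "df", "ui",
                        "mono_count", "bi_count", "multi_count")

#' Append per-colony metrics to a results CSV
#'
#' Creates the file with a header row on first use, then appends one data
#' row per colony. Columns, in order: `image_id`, `total_nuclei`,
#' `stain_negative_nuclei`, `mhc_positive_nuclei`, `df`, `ui`, `mono_count`,
#' `bi_count`, `multi_count`. Numeric values are written at full double
#' precision so a parsed-back row reproduces the metrics exactly.
#'
#' @param path CSV destination.
#' @param metrics one or more rows of colony metrics
#'   (see [compute_colony_metrics()]).
#' @return `path`, invisibly.
#' @export
append_results_csv <- function(path, metrics) {
  stopifnot(is.data.frame(metrics))
  missing_cols <- setdiff(results_csv_header, names(metrics))
  if (length(missing_cols))
    stop_cfc("metrics is missing columns: ",
             paste(missing_cols, collapse = ", "), class = "cfc_value_error")
  if (file.exists(path)) {
    existing <- readLines(path, n = 1L, encoding = "UTF-8")
    if (!identical(existing, paste(results_csv_header, collapse = ",")))
      stop_cfc("existing file has a different header, refusing to append: ",
               path, class = "cfc_format_error")
    lines <- character(0)
  } else {
    lines <- paste(results_csv_header, collapse = ",")
  }
  rows <- vapply(seq_len(nrow(metrics)), function(i) {
    r <- metrics[i, ]
    paste(c(r$image_id,
            format_full(c(r$total_nuclei, r$stain_negative_nuclei,
                          r$mhc_positive_nuclei, r$df, r$ui)),
            sprintf("%d", c(r$mono_count, r$bi_count, r$multi_count))),
          collapse = ",")
  }, character(1))
  con <- file(path, open = "a", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(lines, rows), con)
  invisible(path)
}

#' Read a results CSV written by [append_results_csv()]
#'
#' @param path CSV path.
#' @return a tibble with the results schema.
#' @export
read_results_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character"))
  tibble::as_tibble(df)
}
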