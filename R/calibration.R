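# Dataset-wide nuclear size calibration: pooled DAPI+ area histogram,
# first-peak identification, probabilistic nuclear-quantity assignment.

extract_areas <- function(x) {
  if (inherits(x, "region_set")) x <- x$regions
  if (is.data.frame(x)) {
    if (!"area_px" %in% names(x))
      stop_cfc("region table has no area_px column", class = "cfc_value_error")
    x <- x$area_px
  }
  as.numeric(x)
}

#' Build the pooled DAPI+ region size histogram
#'
#' Areas of every DAPI+ region across *all* images of a dataset are pooled
#' into one histogram — calibration is explicitly dataset-wide, not
#' per-image. In a typical colony dataset the lowest-area mode (the "first
#' peak") collects the single nuclei, followed by a broader doublet/triplet
#' peak and a long tail of larger clumps.
#'
#' @param areas numeric vector of region areas in pixels, or a region table
#'   / [label_regions()] region set with an `area_px` column, or a list of such objects
#'   (pooled).
#' @param bin_width bin width in pixels (default 10).
#' @return an object of class `area_histogram`: a tibble with columns
#'   `bin_lower`, `bin_upper`, `count`, carrying the raw areas and binning
#'   attributes.
#' @export
build_area_histogram <- function(areas, bin_width = 10) {
  if (is.list(areas) && !is.data.frame(areas) && !inherits(areas, "region_set"))
    areas <- unlist(lapply(areas, extract_areas))
  else areas <- extract_areas(areas)
  if (length(areas) == 0L)
    stop_cfc("no DAPI+ regions found: cannot calibrate",
             class = "cfc_calibration_error")
  if (!is_scalar_number(bin_width) || bin_width < 1)
    stop_cfc("bin_width must be >= 1", class = "cfc_param_error")
  lo <- bin_width * floor(min(areas) / bin_width)
  edges <- seq(lo, max(areas) + bin_width, by = bin_width)
  # bin i covers [edges[i], edges[i + 1]); the final value falls in the
  # last bin because edges extend one bin past the maximum
  bin <- findInterval(areas, edges, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  out <- quick_tibble(list(bin_lower = edges[-length(edges)],
                           bin_upper = edges[-1],
                           count = counts))
  structure(out,
            class = c("area_histogram", class(out)),
            areas = areas, bin_width = bin_width,
            total_regions = length(areas))
}

#' @export
print.area_histogram <- function(x, ...) {
  cat(sprintf("<area_histogram>  %d regions, bin width %g px\n",
              attr(x, "total_regions"), attr(x, "bin_width")))
  NextMethod()
}

# 3-bin moving average with shrinking window at the ends
smooth3 <- function(counts) {
  n <- length(counts)
  vapply(seq_len(n), function(i)
    mean(counts[max(1, i - 1):min(n, i + 1)]), numeric(1))
}

#' Fit the first-peak calibration model
#'
#' The faithful mode is user-selected bounds: the user inspects the area
#' histogram and marks the lower and upper area of the first peak, ideally
#' the smallest and largest single nucleus. The mean DAPI+ area within
#' those bounds becomes the single-nucleus reference size. Without bounds
#' an automatic mode smooths the counts with a 3-bin moving average, takes
#' the first local maximum scanning from small areas upward, and extends
#' the peak outward to the nearest enclosing local minima (or histogram
#' ends).
#'
#' @param hist an `area_histogram` from [build_area_histogram()].
#' @param bounds optional numeric `c(lower, upper)` area bounds in pixels.
#' @param areas raw areas; defaults to those carried by `hist`.
#' @return an object of class `nucleus_calibration` with fields
#'   `first_peak_lower`, `first_peak_upper`, `mean_single_area`,
#'   `n_singles` and `source` (`"USER_BOUNDS"` or `"AUTO"`).
#' @export
fit_calibration <- function(hist, bounds = NULL, areas = attr(hist, "areas")) {
  stopifnot(inherits(hist, "area_histogram"))
  areas <- as.numeric(areas)
  if (!is.null(bounds)) {
    if (length(bounds) != 2L || !all(is.finite(bounds)) ||
        bounds[1] > bounds[2] || bounds[1] <= 0)
      stop_cfc("bounds must be positive and ordered (lower <= upper)",
               class = "cfc_param_error")
    lower <- bounds[1]; upper <- bounds[2]; source <- "USER_BOUNDS"
  } else {
    s <- smooth3(hist$count)
    n <- length(s)
    if (n == 1L) {
      warning("degenerate single-bin histogram; first peak spans it",
              call. = FALSE)
      p <- 1L
    } else {
      pad <- c(-Inf, s, -Inf)
      is_max <- s >= pad[seq_len(n)] & s > pad[seq_len(n) + 2L] & s > 0
      # plateau peaks: also accept the first bin of a flat top that later drops
      if (!any(is_max)) is_max <- s >= pad[seq_len(n)] & s >= pad[seq_len(n) + 2L] & s > 0
      p <- which(is_max)[1]
    }
    # walk down both flanks; ties are treated as still descending so a
    # noisy shoulder does not stop the walk before the true valley
    l <- p
    while (l > 1L && s[l - 1L] <= s[l]) l <- l - 1L
    r <- p
    while (r < length(s) && s[r + 1L] <= s[r]) r <- r + 1L
    lower <- hist$bin_lower[l]
    upper <- hist$bin_upper[r]
    source <- "AUTO"
  }
  inside <- areas >= lower & areas <= upper
  if (!any(inside))
    stop_cfc("no region areas fall inside the first-peak bounds [",
             lower, ", ", upper, "]", class = "cfc_calibration_error")
  structure(list(first_peak_lower = lower,
                 first_peak_upper = upper,
                 mean_single_area = mean(areas[inside]),
                 n_singles = sum(inside),
                 source = source,
                 bin_width = attr(hist, "bin_width")),
            class = "nucleus_calibration")
}

#' @export
print.nucleus_calibration <- function(x, ...) {
  cat(sprintf(paste0("<nucleus_calibration [%s]>\n",
                     "  first peak: [%g, %g] px\n",
                     "  mean single-nucleus area: %.2f px (n = %d)\n"),
              x$source, x$first_peak_lower, x$first_peak_upper,
              x$mean_single_area, x$n_singles))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy nucleus_calibration
#' @export
tidy.nucleus_calibration <- function(x, ...) {
  quick_tibble(list(first_peak_lower = x$first_peak_lower,
                    first_peak_upper = x$first_peak_upper,
                    mean_single_area = x$mean_single_area,
                    n_singles = x$n_singles,
                    source = x$source))
}

#' @method glance nucleus_calibration
#' @export
glance.nucleus_calibration <- function(x, ...) tidy(x)

#' Assign a probabilistic nuclear quantity to every DAPI+ region
#'
#' Regions whose area falls inside the first peak are taken to be single
#' nuclei and given a quantity of exactly 1. Every region outside the peak
#' — larger clumps of overlapping nuclei, but also sub-peak debris — has
#' its area divided by the mean single-nucleus area, yielding a fractional
#' estimate of how many nuclei it contains. Quantities are never rounded
#' here; rounding happens only when fibers are classified. An optional
#' `min_area` filter discards regions below a stated area before
#' assignment, for datasets with non-nuclear specks.
#'
#' @param regions a [label_regions()] region set or region tibble from the DAPI channel.
#' @param model a [fit_calibration()] model.
#' @param min_area discard regions with `area_px < min_area` (default 0,
#'   off).
#' @return a nucleus record tibble: the region columns plus
#'   `nuclear_quantity`, `in_first_peak` and `assigned_mhc_label`
#'   (`NA` until [assign_nuclei_to_mhc()]).
#' @export
assign_nuclear_quantities <- function(regions, model, min_area = 0) {
  stopifnot(inherits(model, "nucleus_calibration"))
  if (inherits(regions, "region_set")) regions <- regions$regions
  stopifnot(is.data.frame(regions))
  if (model$mean_single_area <= 0)
    stop_cfc("mean_single_area must be positive", class = "cfc_param_error")
  out <- dplyr::filter(regions, .data$area_px >= min_area)
  out <- dplyr::mutate(
    out,
    in_first_peak = .data$area_px >= model$first_peak_lower &
      .data$area_px <= model$first_peak_upper,
    nuclear_quantity = ifelse(.data$in_first_peak, 1,
                              .data$area_px / model$mean_single_area),
    assigned_mhc_label = NA_integer_)
  out
}
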