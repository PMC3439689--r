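# MHC+ region detection in the red channel, centroid-to-region mapping,
# and mono/bi/multinucleated fiber classification.

#' Detect MHC+ cytoplasm regions in the red channel
#'
#' Runs the same open-threshold-label pipeline as the nuclear counting, but
#' on the red plane with the MHC channel's own radius and threshold. The
#' labeled regions are candidate myofibers/myocytes whose nuclear content
#' is then determined by centroid mapping.
#'
#' @param plane a `channel_plane` with `channel == "MHC_RED"`.
#' @param params a [segmentation_params] for `MHC_RED`.
#' @param boundaries passed to [label_regions()].
#' @return a [label_regions()] region set of MHC+ regions.
#' @export
detect_mhc_regions <- function(plane, params, boundaries = TRUE) {
  stopifnot(inherits(plane, "channel_plane"))
  if (plane$channel != "MHC_RED")
    stop_cfc("detect_mhc_regions expects the MHC_RED plane",
             class = "cfc_param_error")
  segment_channel(plane, params, boundaries = boundaries)
}

#' Classify a fiber by its (estimated) nuclear content
#'
#' The probabilistic nuclei total of an MHC+ region is rounded half-up to
#' an integer `n`; `n = 0` is `ANUCLEATE`, `n = 1` `MONO`, `n = 2` `BI`,
#' and `n >= 3` `MULTI`. Only MULTI fibers — more than two nuclei in one
#' cytoplasm — count as definitive fusion products, since a binucleated
#' cell could merely be dividing.
#'
#' @param nuclei_total numeric vector of per-region nuclei totals.
#' @return a factor with levels `ANUCLEATE`, `MONO`, `BI`, `MULTI`.
#' @export
classify_fiber <- function(nuclei_total) {
  if (any(nuclei_total < 0, na.rm = TRUE))
    stop_cfc("nuclei_total must be non-negative", class = "cfc_value_error")
  n <- round_half_up(nuclei_total)
  cls <- ifelse(n <= 0, "ANUCLEATE",
                ifelse(n == 1, "MONO", ifelse(n == 2, "BI", "MULTI")))
  factor(cls, levels = c("ANUCLEATE", "MONO", "BI", "MULTI"))
}

#' Map nuclear centroids into MHC+ regions
#'
#' Each nucleus record's centroid is snapped to the nearest pixel (halves
#' round toward the larger index) and looked up in the MHC label image. If
#' the centre of a DAPI+ area falls on an MHC+ pixel, the entire DAPI+
#' area — its full nuclear quantity — is attributed to that MHC+ region;
#' a nucleus whose region overlaps an MHC+ area but whose centroid lies
#' outside remains stain-negative. Per-region totals are the sums of the
#' assigned (unrounded) quantities, and each region is classified with
#' [classify_fiber()]; regions containing no centroid are `ANUCLEATE`.
#'
#' @param nuclei nucleus record tibble from [assign_nuclear_quantities()].
#' @param mhc a [label_regions()] region set from [detect_mhc_regions()], whose label image
#'   matches the nuclei's source image dimensions.
#' @return a list with `nuclei` (input tibble with `assigned_mhc_label`
#'   filled in) and `mhc` (region tibble with `nuclei_total`,
#'   `member_nucleus_labels` and `fiber_class` columns).
#' @export
assign_nuclei_to_mhc <- function(nuclei, mhc) {
  stopifnot(is.data.frame(nuclei), inherits(mhc, "region_set"))
  lab <- mhc$labels
  nr <- nrow(lab); nc <- ncol(lab)
  if (nrow(nuclei)) {
    r <- round_half_up(nuclei$centroid_row)
    c <- round_half_up(nuclei$centroid_col)
    if (any(r < 1 | r > nr | c < 1 | c > nc))
      stop_cfc("nucleus centroids fall outside the MHC label image; ",
               "dimension mismatch between channels", class = "cfc_dim_error")
    hit <- lab[cbind(r, c)]
    nuclei$assigned_mhc_label <- ifelse(hit > 0L, hit, NA_integer_)
  }
  regions <- mhc$regions
  k <- nrow(regions)
  totals <- numeric(k)
  members <- rep(list(integer(0)), k)
  if (nrow(nuclei) && k) {
    assigned <- dplyr::filter(nuclei, !is.na(.data$assigned_mhc_label))
    if (nrow(assigned)) {
      agg <- dplyr::summarise(
        dplyr::group_by(assigned, .data$assigned_mhc_label),
        nuclei_total = sum(.data$nuclear_quantity),
        member_nucleus_labels = list(.data$label))
      totals[agg$assigned_mhc_label] <- agg$nuclei_total
      members[agg$assigned_mhc_label] <- agg$member_nucleus_labels
    }
  }
  regions$nuclei_total <- totals
  regions$member_nucleus_labels <- members
  regions$fiber_class <- classify_fiber(totals)
  list(nuclei = nuclei, mhc = regions)
}
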