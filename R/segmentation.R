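# Channel plane -> labeled foreground regions:
# grayscale opening (background removal), value thresholding, 8-connected
# component labeling with areas, centroids and traced boundaries.

#' Segmentation parameters for one channel
#'
#' The pipeline exposes two user-tunable knobs per channel, set
#' independently for the DAPI and MHC stains: the radius `R` of the flat
#' disk structuring element used by the morphological opening, and the
#' intensity threshold `T` that binarizes the opened image. Larger `R` and
#' `T` help separate nuclei with fuzzy boundaries; lowering `T` on the red
#' channel increases sensitivity to dim MHC staining.
#'
#' @param radius non-negative integer, disk radius in pixels (`0` disables
#'   the opening).
#' @param threshold intensity in `[0, 1]`; pixels strictly above it are
#'   foreground.
#' @param channel `"DAPI_BLUE"` or `"MHC_RED"`.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(radius, threshold, channel) {
  if (!is_scalar_number(radius) || radius < 0 || radius != floor(radius))
    stop_cfc("radius must be a non-negative integer",
             class = "cfc_param_error")
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 1)
    stop_cfc("threshold must lie in [0, 1]", class = "cfc_param_error")
  structure(list(radius = as.integer(radius), threshold = threshold,
                 channel = match_channel(channel)),
            class = "segmentation_params")
}

#' Exact Euclidean disk structuring element
#'
#' All pixel offsets at Euclidean distance at most `radius` from the
#' centre. This is the exact disk rather than MATLAB-style decomposed
#' approximations, chosen for reproducibility; `radius = 0` gives the
#' 1 x 1 identity element.
#'
#' @param radius non-negative integer.
#' @return a square 0/1 numeric matrix of side `2 * radius + 1`.
#' @export
disk_kernel <- function(radius) {
  if (!is_scalar_number(radius) || radius < 0 || radius != floor(radius))
    stop_cfc("radius must be a non-negative integer",
             class = "cfc_param_error")
  off <- -radius:radius
  d2 <- outer(off^2, off^2, `+`)
  (d2 <= radius^2) * 1
}

#' Remove background by grayscale morphological opening
#'
#' Erosion followed by dilation with a flat disk of the given radius,
#' applied to the grayscale plane before thresholding. Bright features
#' narrower than the disk (debris, noise specks) are suppressed; larger
#' structures keep their interior intensity. The opening is anti-extensive
#' and idempotent; radius 0 is the identity.
#'
#' @param plane a `channel_plane`.
#' @param radius non-negative integer disk radius in pixels.
#' @return a `channel_plane` with opened pixels.
#' @export
remove_background <- function(plane, radius) {
  stopifnot(inherits(plane, "channel_plane"))
  if (!is_scalar_number(radius) || radius < 0 || radius != floor(radius))
    stop_cfc("radius must be a non-negative integer",
             class = "cfc_param_error")
  if (radius == 0) return(plane)
  px <- plane$pixels
  opened <- EBImage::opening(px, disk_kernel(radius))
  plane$pixels <- matrix(pmin(pmax(as.numeric(opened), 0), 1),
                         nrow(px), ncol(px))
  plane
}

#' Threshold a channel plane to a binary foreground mask
#'
#' A pixel is foreground iff its intensity is strictly greater than `T`,
#' so `T = 0` selects every pixel with any signal and `T = 1` selects none.
#' Plain value thresholding is used throughout; adaptive methods such as
#' Otsu's are deliberately not offered.
#'
#' @param plane a `channel_plane`.
#' @param threshold intensity cutoff in `[0, 1]`.
#' @return a logical matrix of the plane's dimensions.
#' @export
threshold_plane <- function(plane, threshold) {
  stopifnot(inherits(plane, "channel_plane"))
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 1)
    stop_cfc("threshold must lie in [0, 1]", class = "cfc_param_error")
  plane$pixels > threshold
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so components that
# touch only diagonally are merged afterwards with a small union-find over
# the 4-connected labels.
label_mask_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nr, nc)
  k <- max(lab)
  if (k > 1L && nr > 1L && nc > 1L) {
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
    a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # up-right diagonal
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]),
                          cbind(a2[sel2], b2[sel2])))
    if (nrow(pairs)) {
      parent <- seq_len(k)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (p in seq_len(nrow(pairs))) {
        ra <- find(pairs[p, 1]); rb <- find(pairs[p, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(k), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  # relabel to 1..K in order of first appearance (column-major scan)
  if (max(lab) > 0L) {
    present <- unique(lab[lab > 0L])
    remap <- integer(max(present))
    remap[present] <- seq_along(present)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Label connected foreground regions
#'
#' Finds all 8-connected components of a binary mask. Each region carries
#' its pixel count (`area_px`; interior holes are not members and do not
#' count), its centroid as the unweighted mean of member pixel `(row, col)`
#' coordinates (1-based, row 1 at the top), and, optionally, its traced
#' outer boundary as an ordered matrix of perimeter pixels. Regions touching
#' the image border are retained.
#'
#' @param mask logical (or 0/1) matrix.
#' @param boundaries trace outer boundaries (`TRUE`, the default) or skip
#'   them for speed.
#' @return an object of class `region_set`: a list with `regions` (a tibble
#'   with columns `label`, `area_px`, `centroid_row`, `centroid_col` and,
#'   when requested, a `boundary` list-column), `labels` (the integer label
#'   image, 0 = background), `channel` and `source_image_id`.
#' @export
label_regions <- function(mask, boundaries = TRUE) {
  if (!is.matrix(mask)) stop_cfc("mask must be a matrix",
                                 class = "cfc_param_error")
  mask <- mask > 0
  lab <- label_mask_8(mask)
  k <- max(lab)
  if (k == 0L) {
    regions <- quick_tibble(list(label = integer(0), area_px = integer(0),
                                 centroid_row = numeric(0),
                                 centroid_col = numeric(0)))
    if (boundaries) regions$boundary <- list()
  } else {
    idx <- which(lab > 0L)
    l <- lab[idx]
    nr <- nrow(mask)
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    area <- tabulate(l, nbins = k)
    regions <- quick_tibble(list(
      label = seq_len(k),
      area_px = area,
      centroid_row = as.numeric(rowsum(as.numeric(r), l)) / area,
      centroid_col = as.numeric(rowsum(as.numeric(c), l)) / area))
    if (boundaries) {
      oc <- EBImage::ocontour(lab)
      bnd <- vector("list", k)
      for (nm in names(oc)) {
        b <- oc[[nm]] + 1L
        colnames(b) <- c("row", "col")
        bnd[[as.integer(nm)]] <- b
      }
      regions$boundary <- bnd
    }
  }
  structure(list(regions = regions, labels = lab,
                 channel = NA_character_, source_image_id = NA_character_),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set>  %d region(s)%s, %d x %d px label image\n",
              nrow(x$regions),
              if (is.na(x$channel)) "" else paste0(" [", x$channel, "]"),
              nrow(x$labels), ncol(x$labels)))
  print(x$regions, ...)
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble region_set
#' @export
as_tibble.region_set <- function(x, ...) x$regions

#' Segment one channel into labeled regions
#'
#' The per-channel pipeline: grayscale opening with the disk of radius `R`,
#' strict thresholding at `T`, then 8-connected labeling. On the blue plane
#' the resulting regions are DAPI+ areas (one or more overlapping nuclei);
#' on the red plane they are MHC+ cytoplasm.
#'
#' @param plane a `channel_plane`.
#' @param params a [segmentation_params] whose `channel` matches the plane.
#' @param boundaries passed to [label_regions()].
#' @return a [label_regions()] region set tagged with the plane's channel and image id.
#' @export
segment_channel <- function(plane, params, boundaries = TRUE) {
  stopifnot(inherits(plane, "channel_plane"),
            inherits(params, "segmentation_params"))
  if (!identical(plane$channel, params$channel))
    stop_cfc("params are for channel ", params$channel,
             " but plane is ", plane$channel, class = "cfc_param_error")
  opened <- remove_background(plane, params$radius)
  mask <- threshold_plane(opened, params$threshold)
  rs <- label_regions(mask, boundaries = boundaries)
  rs$channel <- plane$channel
  rs$source_image_id <- plane$source_image_id
  rs
}
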