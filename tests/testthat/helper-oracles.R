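# Independent brute-force references used to check the pipeline.
# These deliberately share no code with the package internals.

# 8-connected components by breadth-first flood fill
oracle_label <- function(mask) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    k <- k + 1L
    queue <- matrix(c(i, j), 1, 2)
    lab[i, j] <- k
    while (nrow(queue) > 0) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ii <- cur[1] + di; jj <- cur[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- k
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

# per-component (area, centroid) table from any label image, sorted so two
# labelings can be compared irrespective of label numbering
region_signature <- function(lab) {
  k <- max(lab)
  if (k == 0L) return(matrix(numeric(0), 0, 3))
  sig <- t(vapply(seq_len(k), function(l) {
    w <- which(lab == l, arr.ind = TRUE)
    c(nrow(w), mean(w[, 1]), mean(w[, 2]))
  }, numeric(3)))
  sig[order(sig[, 1], sig[, 2], sig[, 3]), , drop = FALSE]
}

# direct flat grayscale erosion/dilation; outside-image pixels are ignored
# (min/max over the offsets that fall inside), matching the opening used
# by the package only if that border policy is really what it implements
oracle_opening <- function(px, radius) {
  off <- -radius:radius
  keep <- which(outer(off^2, off^2, `+`) <= radius^2, arr.ind = TRUE)
  offs <- cbind(off[keep[, 1]], off[keep[, 2]])
  nr <- nrow(px); nc <- ncol(px)
  apply_op <- function(m, f) {
    out <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      ii <- i + offs[, 1]; jj <- j + offs[, 2]
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      out[i, j] <- f(m[cbind(ii[ok], jj[ok])])
    }
    out
  }
  apply_op(apply_op(px, min), max)
}

# closed-form two-sided t interval for a mean
oracle_t_ci <- function(x, level = 0.95) {
  n <- length(x)
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(x) / sqrt(n)
  c(mean(x) - half, mean(x) + half)
}

# convenience: channel plane from a bare matrix
as_plane <- function(px, channel = "DAPI_BLUE", id = "test") {
  m <- structure(list(channel = channel, pixels = px, source_image_id = id),
                 class = "channel_plane")
  m
}

# default segmentation parameters used by the synthetic study conditions
dapi_params <- function() segmentation_params(2, 0.3, "DAPI_BLUE")
mhc_params <- function() segmentation_params(3, 0.3, "MHC_RED")

# run the in-memory pipeline on one generated colony with a fixed
# calibration model (or fit one from this image alone if model is NULL)
analyze_colony <- function(col, model = NULL, min_area = 0) {
  m <- col$micrograph
  dapi <- segment_channel(extract_channel(m, "DAPI_BLUE"), dapi_params(),
                          boundaries = FALSE)
  if (is.null(model)) {
    h <- build_area_histogram(dapi, bin_width = 10)
    model <- fit_calibration(h)
  }
  nuclei <- assign_nuclear_quantities(dapi, model, min_area = min_area)
  mhc <- detect_mhc_regions(extract_channel(m, "MHC_RED"), mhc_params(),
                            boundaries = FALSE)
  asg <- assign_nuclei_to_mhc(nuclei, mhc)
  list(metrics = compute_colony_metrics(asg$nuclei, asg$mhc, m$image_id),
       nuclei = asg$nuclei, mhc = asg$mhc, dapi = dapi, model = model)
}
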