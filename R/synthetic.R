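# Deterministic synthetic-colony generator with exported ground truth.
# Emulates the structures the analysis must handle: disk-like nuclei with a
# unimodal single-nucleus size distribution, clusters of overlapping nuclei
# that merge into larger DAPI+ regions, contiguous MHC+ cytoplasm enclosing
# known subsets of nuclei, sub-nuclear debris specks, and Gaussian
# background noise.

#' Specify a synthetic colony
#'
#' All randomness derives from `seed`; the same spec always renders a
#' bit-identical image and truth table. Nucleus centres are placed on the
#' integer pixel grid, singles separated by more than twice the maximum
#' radius, cluster members at `cluster_spacing` times the local radius so
#' clusters merge into single DAPI+ regions. MHC+ cytoplasm is rendered as
#' elongated axis-aligned rectangles; nuclei assigned to a region are kept
#' a margin inside it and all others a margin outside, so the ground-truth
#' membership is unambiguous.
#'
#' @param seed integer RNG seed.
#' @param width,height image size in pixels.
#' @param n_singles,n_doublets,n_multiplets counts of isolated nuclei,
#'   two-nucleus clusters and larger clusters.
#' @param multiplet_size_range inclusive integer range of multiplet sizes.
#' @param nucleus_radius_mean,nucleus_radius_sd radius distribution in px
#'   (normal, truncated at 3 sd).
#' @param n_mhc_regions number of MHC+ rectangles.
#' @param fraction_nuclei_in_mhc target fraction of nuclei whose centres
#'   lie inside MHC+ cytoplasm (met as closely as whole clusters allow,
#'   never exceeded).
#' @param background_noise_sd additive Gaussian noise sd (intensity units).
#' @param speck_count number of 1-5 px bright debris dots in the blue
#'   plane.
#' @param nucleus_intensity,mhc_intensity foreground intensities in
#'   `[0, 1]`.
#' @param cluster_spacing centre separation of adjacent cluster members,
#'   in units of the local nucleus radius.
#' @param image_id identifier; default `sprintf("colony_s%04d", seed)`.
#' @return an object of class `colony_spec`.
#' @export
colony_spec <- function(seed,
                        width = 384, height = 384,
                        n_singles = 30, n_doublets = 6, n_multiplets = 3,
                        multiplet_size_range = c(3, 5),
                        nucleus_radius_mean = 4.5, nucleus_radius_sd = 0.3,
                        n_mhc_regions = 4,
                        fraction_nuclei_in_mhc = 0.5,
                        background_noise_sd = 0.02,
                        speck_count = 10,
                        nucleus_intensity = 0.9, mhc_intensity = 0.8,
                        cluster_spacing = 1.7,
                        image_id = NULL) {
  stopifnot(is_scalar_number(seed),
            width >= 64, height >= 64,
            n_singles >= 0, n_doublets >= 0, n_multiplets >= 0,
            multiplet_size_range[1] >= 3,
            multiplet_size_range[2] >= multiplet_size_range[1],
            nucleus_radius_mean > 1, nucleus_radius_sd >= 0,
            n_mhc_regions >= 0,
            fraction_nuclei_in_mhc >= 0, fraction_nuclei_in_mhc <= 1,
            background_noise_sd >= 0, speck_count >= 0,
            nucleus_intensity > 0, nucleus_intensity <= 1,
            mhc_intensity > 0, mhc_intensity <= 1,
            cluster_spacing > 0)
  if (is.null(image_id)) image_id <- sprintf("colony_s%04d", as.integer(seed))
  structure(as.list(environment()), class = "colony_spec")
}

# additively blend one soft-edged disk into a plane (union via pmax)
paint_disk <- function(plane, row, col, radius, intensity) {
  nr <- nrow(plane); nc <- ncol(plane)
  ext <- ceiling(radius) + 1L
  rr <- max(1L, row - ext):min(nr, row + ext)
  cc <- max(1L, col - ext):min(nc, col + ext)
  d <- sqrt(outer((rr - row)^2, (cc - col)^2, `+`))
  prof <- intensity * pmin(1, pmax(0, radius + 0.5 - d))
  plane[rr, cc] <- pmax(plane[rr, cc], prof)
  plane
}

rect_gap <- function(a, b) {
  # distance between two axis-aligned rectangles (0 if overlapping)
  dr <- max(0, max(a[1], b[1]) - min(a[2], b[2]))
  dc <- max(0, max(a[3], b[3]) - min(a[4], b[4]))
  max(dr, dc)
}

place_mhc_rects <- function(spec) {
  rects <- matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("row_min", "row_max",
                                          "col_min", "col_max")))
  if (spec$n_mhc_regions == 0) return(rects)
  for (i in seq_len(spec$n_mhc_regions)) {
    ok <- FALSE
    for (try in 1:2000) {
      hh <- stats::runif(1, 18, 26)
      wh <- stats::runif(1, 34, 55)
      if (stats::runif(1) < 0.5) { tmp <- hh; hh <- wh; wh <- tmp }
      hh <- min(hh, (spec$height - 16) / 2)
      wh <- min(wh, (spec$width - 16) / 2)
      cr <- stats::runif(1, 8 + hh, spec$height - 8 - hh)
      cc <- stats::runif(1, 8 + wh, spec$width - 8 - wh)
      cand <- c(round(cr - hh), round(cr + hh), round(cc - wh), round(cc + wh))
      if (nrow(rects) == 0 ||
          all(apply(rects, 1, rect_gap, b = cand) >= 12)) {
        rects <- rbind(rects, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop_cfc("infeasible packing: could not place MHC region ", i,
               class = "cfc_generation_error")
  }
  rects
}

# relative integer offsets for a cluster of the given member radii
cluster_offsets <- function(radii, spacing) {
  k <- length(radii)
  pos <- matrix(0, k, 2)
  ang <- stats::runif(1, 0, 2 * pi)
  for (j in seq_len(k)[-1]) {
    # strong turns keep larger clusters compact enough to sit inside
    # an MHC region
    ang <- ang + stats::runif(1, 0.7, 1.5) * sample(c(-1, 1), 1)
    step <- spacing * (radii[j - 1] + radii[j]) / 2
    pos[j, ] <- pos[j - 1, ] + step * c(sin(ang), cos(ang))
  }
  round(sweep(pos, 2, colMeans(pos)))
}

#' Generate one synthetic colony with ground truth
#'
#' Renders the micrograph described by a [colony_spec()] and returns it
#' together with a complete truth table: every nucleus centre, radius and
#' cluster id, every MHC+ region's extent and true contained-nucleus
#' count, and the true totals (`total_nuclei`, `df_true`, `ui_true`)
#' recomputable from the per-nucleus table.
#'
#' @param spec a [colony_spec()].
#' @return a list of class `synthetic_colony` with elements `micrograph`
#'   (a [micrograph]) and `truth` (list of tibbles `nuclei`,
#'   `mhc_regions`, `summary`).
#' @export
generate_colony <- function(spec) {
  stopifnot(inherits(spec, "colony_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  maxr <- spec$nucleus_radius_mean + 3 * spec$nucleus_radius_sd
  sep <- 2 * maxr + 2        # minimum centre distance between units

  rects <- place_mhc_rects(spec)

  sizes <- c(rep(1L, spec$n_singles), rep(2L, spec$n_doublets),
             if (spec$n_multiplets > 0)
               sample(seq(spec$multiplet_size_range[1],
                          spec$multiplet_size_range[2]),
                      spec$n_multiplets, replace = TRUE))
  total_n <- sum(sizes)
  units <- if (length(sizes)) sample(seq_along(sizes)) else integer(0)

  # whole clusters go inside or outside MHC; greedy fill toward the target
  target_in <- round(spec$fraction_nuclei_in_mhc * total_n)
  in_mhc_unit <- logical(length(sizes))
  placed_in <- 0L
  if (nrow(rects) > 0) {
    for (u in units) {
      if (placed_in + sizes[u] <= target_in) {
        in_mhc_unit[u] <- TRUE
        placed_in <- placed_in + sizes[u]
      }
    }
  }

  draw_radius <- function(n) {
    r <- stats::rnorm(n, spec$nucleus_radius_mean, spec$nucleus_radius_sd)
    pmin(pmax(r, spec$nucleus_radius_mean - 3 * spec$nucleus_radius_sd),
         spec$nucleus_radius_mean + 3 * spec$nucleus_radius_sd)
  }

  centers <- matrix(numeric(0), 0, 2)  # all placed nucleus centres
  nuc_rows <- list()
  nucleus_id <- 0L
  # biggest clusters first: they need the most free space
  for (u in order(-sizes)) {
    k <- sizes[u]
    radii <- draw_radius(k)
    off <- cluster_offsets(radii, spec$cluster_spacing)
    ext <- max(sqrt(rowSums(off^2)) + radii)    # cluster bounding radius
    rect_id <- NA_integer_
    if (in_mhc_unit[u]) {
      # only rectangles that can hold the whole cluster with margin
      m_in <- ext + 3
      feasible <- which(rects[, 1] + m_in <= rects[, 2] - m_in &
                          rects[, 3] + m_in <= rects[, 4] - m_in)
      if (length(feasible) == 0L) in_mhc_unit[u] <- FALSE
    }
    placed <- FALSE
    for (try in 1:2000) {
      if (in_mhc_unit[u]) {
        rect_id <- feasible[sample.int(length(feasible), 1)]
        rc <- rects[rect_id, ]
        m <- ext + 3                      # keep whole cluster inside
        anchor <- c(round(stats::runif(1, rc[1] + m, rc[2] - m)),
                    round(stats::runif(1, rc[3] + m, rc[4] - m)))
      } else {
        m <- ext + 2
        anchor <- c(round(stats::runif(1, 1 + m, H - m)),
                    round(stats::runif(1, 1 + m, W - m)))
        # stay clear of every MHC rectangle
        if (nrow(rects) > 0 &&
            any(apply(rects, 1, function(rc)
              anchor[1] > rc[1] - m - 2 && anchor[1] < rc[2] + m + 2 &&
              anchor[2] > rc[3] - m - 2 && anchor[2] < rc[4] + m + 2)))
          next
      }
      pts <- sweep(off, 2, anchor, `+`)
      if (nrow(centers) > 0) {
        d2 <- outer(pts[, 1], centers[, 1], `-`)^2 +
          outer(pts[, 2], centers[, 2], `-`)^2
        if (min(d2) < sep^2) next
      }
      centers <- rbind(centers, pts)
      nuc_rows[[u]] <- quick_tibble(list(
        nucleus_id = nucleus_id + seq_len(k),
        image_id = rep(spec$image_id, k),
        row = pts[, 1], col = pts[, 2],
        radius = radii,
        cluster_id = rep(u, k),
        cluster_size = rep(k, k),
        mhc_id = rep(if (in_mhc_unit[u]) rect_id else NA_integer_, k),
        in_mhc = rep(in_mhc_unit[u], k)))
      nucleus_id <- nucleus_id + k
      placed <- TRUE
      break
    }
    if (!placed)
      stop_cfc("infeasible packing: could not place nucleus cluster ", u,
               " (", k, " nuclei)", class = "cfc_generation_error")
  }
  nuclei <- if (length(nuc_rows)) {
    nn <- dplyr::bind_rows(nuc_rows)
    nn$nucleus_id <- seq_len(nrow(nn))   # renumber in table order
    nn
  }
            else quick_tibble(list(nucleus_id = integer(0),
                                   image_id = character(0),
                                   row = numeric(0), col = numeric(0),
                                   radius = numeric(0),
                                   cluster_id = integer(0),
                                   cluster_size = integer(0),
                                   mhc_id = integer(0), in_mhc = logical(0)))

  blue <- matrix(0, H, W)
  for (i in seq_len(nrow(nuclei)))
    blue <- paint_disk(blue, nuclei$row[i], nuclei$col[i], nuclei$radius[i],
                       spec$nucleus_intensity)
  # debris specks: tiny bright dots kept off the nuclei
  for (s in seq_len(spec$speck_count)) {
    for (try in 1:50) {
      p <- c(sample(H, 1), sample(W, 1))
      if (nrow(centers) == 0 ||
          min((p[1] - centers[, 1])^2 + (p[2] - centers[, 2])^2) >
            (maxr + 4)^2) break
    }
    blue <- paint_disk(blue, p[1], p[2],
                       sample(c(0.5, 1, 1.5), 1), 0.85)
  }
  red <- matrix(0, H, W)
  for (i in seq_len(nrow(rects)))
    red[rects[i, 1]:rects[i, 2], rects[i, 3]:rects[i, 4]] <-
      spec$mhc_intensity
  green <- matrix(0, H, W)
  if (spec$background_noise_sd > 0) {
    blue <- blue + stats::rnorm(H * W, 0, spec$background_noise_sd)
    red <- red + stats::rnorm(H * W, 0, spec$background_noise_sd)
    green <- green + stats::rnorm(H * W, 0, spec$background_noise_sd)
  }
  clip01 <- function(x) pmin(pmax(x, 0), 1)  # x first so dims survive
  m <- micrograph(red = clip01(red), green = clip01(green),
                  blue = clip01(blue), image_id = spec$image_id)

  per_rect <- if (nrow(rects)) {
    cnt <- tabulate(nuclei$mhc_id[!is.na(nuclei$mhc_id)], nbins = nrow(rects))
    quick_tibble(list(mhc_id = seq_len(nrow(rects)),
                      image_id = rep(spec$image_id, nrow(rects)),
                      row_min = rects[, 1], row_max = rects[, 2],
                      col_min = rects[, 3], col_max = rects[, 4],
                      true_nucleus_count = cnt))
  } else {
    quick_tibble(list(mhc_id = integer(0), image_id = character(0),
                      row_min = numeric(0), row_max = numeric(0),
                      col_min = numeric(0), col_max = numeric(0),
                      true_nucleus_count = integer(0)))
  }
  n_in <- sum(nuclei$in_mhc)
  multi_rects <- per_rect$mhc_id[per_rect$true_nucleus_count >= 3]
  n_fused <- sum(nuclei$mhc_id %in% multi_rects)
  truth_summary <- quick_tibble(list(
    image_id = spec$image_id,
    total_nuclei = total_n,
    n_in_mhc = n_in,
    n_stain_negative = total_n - n_in,
    df_true = if (total_n > 0) n_in / total_n else 0,
    ui_true = if (total_n > 0) n_fused / total_n else 0,
    n_multi_regions_true = length(multi_rects)))

  structure(list(micrograph = m,
                 truth = list(nuclei = nuclei, mhc_regions = per_rect,
                              summary = truth_summary)),
            class = "synthetic_colony")
}

#' @export
print.synthetic_colony <- function(x, ...) {
  s <- x$truth$summary
  cat(sprintf(paste0("<synthetic_colony '%s'>  %d nuclei ",
                     "(%d in MHC+), df_true = %.3f, ui_true = %.3f\n"),
              s$image_id, s$total_nuclei, s$n_in_mhc, s$df_true, s$ui_true))
  invisible(x)
}

#' Generate a batch of synthetic colonies on disk
#'
#' Writes one PNG per spec plus machine-readable truth tables
#' (`truth_nuclei.csv`, `truth_mhc.csv`, `truth_summary.csv`) into
#' `out_dir`, supporting end-to-end pipeline tests.
#'
#' @param specs list of [colony_spec()] objects with distinct `image_id`s.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the truth summary tibble (one row per image).
#' @export
generate_batch <- function(specs, out_dir) {
  stopifnot(length(specs) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cols <- lapply(specs, generate_colony)
  for (col in cols)
    write_micrograph(col$micrograph,
                     file.path(out_dir,
                               paste0(col$micrograph$image_id, ".png")))
  truth_nuclei <- dplyr::bind_rows(lapply(cols, function(x) x$truth$nuclei))
  truth_mhc <- dplyr::bind_rows(lapply(cols, function(x) x$truth$mhc_regions))
  truth_summary <- dplyr::bind_rows(lapply(cols,
                                           function(x) x$truth$summary))
  utils::write.csv(truth_nuclei, file.path(out_dir, "truth_nuclei.csv"),
                   row.names = FALSE)
  utils::write.csv(truth_mhc, file.path(out_dir, "truth_mhc.csv"),
                   row.names = FALSE)
  utils::write.csv(truth_summary, file.path(out_dir, "truth_summary.csv"),
                   row.names = FALSE)
  invisible(truth_summary)
}
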