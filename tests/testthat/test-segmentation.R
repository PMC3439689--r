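# Opening, thresholding and 8-connected labeling.

test_that("the structuring element is the exact Euclidean disk", {
  expect_identical(disk_kernel(0), matrix(1, 1, 1))
  k2 <- disk_kernel(2)
  # radius 2: 13 offsets (corners at distance 2*sqrt(2) excluded,
  # axis tips at distance 2 included)
  expect_equal(sum(k2), 13)
  expect_equal(k2[1, 1], 0)
  expect_equal(k2[3, 1], 1)
  expect_error(disk_kernel(-1), class = "cfc_param_error")
})

test_that("opening with radius 0 is the identity and removes sub-element features", {
  set.seed(1)
  p <- as_plane(matrix(runif(400), 20, 20))
  expect_identical(remove_background(p, 0)$pixels, p$pixels)

  px <- matrix(0, 15, 15); px[8, 8] <- 1
  opened <- remove_background(as_plane(px), 2)$pixels
  expect_equal(max(opened), 0)
  expect_error(remove_background(p, -2), class = "cfc_param_error")
})

test_that("opening matches a direct erode-then-dilate reference and a wide disk survives", {
  px <- matrix(0.05, 64, 64)
  cc <- expand.grid(r = 1:64, c = 1:64)
  inside <- (cc$r - 32)^2 + (cc$c - 32)^2 <= 6^2
  px[cbind(cc$r[inside], cc$c[inside])] <- 0.9
  opened <- remove_background(as_plane(px), 3)$pixels
  expect_equal(opened, oracle_opening(px, 3), tolerance = 1e-12)
  # interior of the radius-6 disk survives R = 3 with intensity unchanged
  core <- (cc$r - 32)^2 + (cc$c - 32)^2 <= 2^2
  expect_true(all(opened[cbind(cc$r[core], cc$c[core])] == 0.9))
})

test_that("opening is anti-extensive and idempotent on random planes", {
  set.seed(42)
  for (rep in 1:10) {
    px <- matrix(runif(32 * 32), 32, 32)
    p <- as_plane(px)
    o1 <- remove_background(p, 2)
    expect_true(all(o1$pixels <= px + 1e-12))
    o2 <- remove_background(o1, 2)
    expect_equal(o2$pixels, o1$pixels, tolerance = 1e-12)
  }
})

test_that("thresholding is strict and monotone in T", {
  u <- as_plane(matrix(0.5, 8, 8))
  expect_false(any(threshold_plane(u, 0.5)))
  expect_true(all(threshold_plane(u, 0.49)))
  expect_false(any(threshold_plane(u, 1)))

  set.seed(7)
  px <- matrix(runif(900), 30, 30)
  p <- as_plane(px)
  for (T in c(0, 0.2, 0.7)) {
    expect_equal(sum(threshold_plane(p, T)), sum(px > T))
  }
  counts <- vapply(seq(0, 1, by = 0.1),
                   function(T) sum(threshold_plane(p, T)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(threshold_plane(p, 1.5), class = "cfc_param_error")
})

test_that("labeling is 8-connected with correct areas, centroids and boundaries", {
  expect_identical(nrow(label_regions(matrix(FALSE, 5, 5))$regions), 0L)

  # touching diagonally = one region
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  rs <- label_regions(m)
  expect_identical(nrow(rs$regions), 1L)
  expect_equal(rs$regions$area_px, 2)
  expect_equal(rs$regions$centroid_row, 1.5)
  expect_equal(rs$regions$centroid_col, 1.5)

  # labels 1..K with no gaps; region areas partition the foreground
  set.seed(3)
  mask <- matrix(runif(64 * 64) < 0.3, 64, 64)
  rs2 <- label_regions(mask)
  expect_identical(sort(unique(as.vector(rs2$labels[rs2$labels > 0]))),
                   rs2$regions$label)
  expect_equal(sum(rs2$regions$area_px), sum(mask))

  # areas and centroids agree with the flood-fill oracle
  expect_equal(region_signature(rs2$labels), region_signature(oracle_label(mask)),
               tolerance = 1e-12)

  # boundary pixels are member pixels on the region's rim
  rect <- matrix(FALSE, 10, 10); rect[3:6, 4:8] <- TRUE
  b <- label_regions(rect)$regions$boundary[[1]]
  expect_true(all(rect[b]))
  expect_true(all(b[, "row"] %in% c(3, 6) | b[, "col"] %in% c(4, 8)))
})

test_that("five disjoint rectangles match the flood-fill oracle", {
  mask <- matrix(FALSE, 64, 64)
  rects <- list(c(2, 6, 2, 10), c(20, 25, 5, 9), c(40, 60, 40, 44),
                c(2, 4, 50, 60), c(55, 60, 2, 12))
  for (r in rects) mask[r[1]:r[2], r[3]:r[4]] <- TRUE
  rs <- label_regions(mask)
  expect_identical(nrow(rs$regions), 5L)
  expect_equal(region_signature(rs$labels), region_signature(oracle_label(mask)),
               tolerance = 1e-12)
})

test_that("segment_channel composes open, threshold and label", {
  # all-dark plane -> nothing
  dark <- as_plane(matrix(0, 32, 32))
  expect_identical(nrow(segment_channel(dark, dapi_params())$regions), 0L)

  # 10 well-separated bright disks -> exactly 10 regions; T above the
  # disk intensity -> none
  px <- matrix(0, 96, 96)
  centers <- expand.grid(r = c(15, 40, 65, 88), c = c(15, 45, 75))[1:10, ]
  cc <- expand.grid(r = 1:96, c = 1:96)
  for (i in 1:10) {
    inside <- (cc$r - centers$r[i])^2 + (cc$c - centers$c[i])^2 <= 4^2
    px[cbind(cc$r[inside], cc$c[inside])] <- 0.8
  }
  plane <- as_plane(px)
  rs <- segment_channel(plane, segmentation_params(1, 0.3, "DAPI_BLUE"))
  expect_identical(nrow(rs$regions), 10L)
  rs_hi <- segment_channel(plane, segmentation_params(1, 0.9, "DAPI_BLUE"))
  expect_identical(nrow(rs_hi$regions), 0L)

  # channel mismatch is refused
  expect_error(segment_channel(plane, mhc_params()), class = "cfc_param_error")
})
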