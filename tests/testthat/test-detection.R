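test_that("absolute contrast is the pixelwise magnitude", {
  m <- matrix(c(-0.02, 0, 0.03, -1), 2, 2)
  expect_equal(absolute_contrast(m), abs(m))
})

test_that("segmentation matches a recursive flood-fill oracle", {
  set.seed(11)
  for (conn in c(4, 8)) {
    for (rep in 1:5) {
      mask <- matrix(runif(16 * 16) < 0.35, 16, 16)
      img <- matrix(0, 16, 16); img[mask] <- 1
      seg <- segment(img, detection_config(0.5, min_area_px = 1,
                                           connectivity = conn,
                                           edge_margin_px = 0))
      oracle <- flood_fill_label(mask, conn)
      expect_true(same_partition(seg$labels, oracle))
    }
  }
})

test_that("segmentation against an independent 4-connectivity labeller", {
  set.seed(3)
  mask <- matrix(runif(20 * 20) < 0.4, 20, 20)
  img <- matrix(0, 20, 20); img[mask] <- 1
  seg <- segment(img, detection_config(0.5, min_area_px = 1,
                                       connectivity = 4, edge_margin_px = 0))
  ref <- EBImage::bwlabel(img)
  expect_true(same_partition(seg$labels, matrix(as.integer(ref), 20, 20)))
})

test_that("a sub-threshold gap separates regions; diagonal contact joins under 8-connectivity", {
  img <- matrix(0, 5, 7)
  img[3, 2] <- 1; img[3, 4] <- 1  # gap at column 3
  seg <- segment(img, detection_config(0.5, 1, 8, 0))
  expect_equal(length(seg$ids), 2)

  # mixed-sign dipole blob: both lobes survive |c| thresholding as one
  # region when diagonally contiguous
  dip <- matrix(0, 6, 6)
  dip[2:3, 2:3] <- 0.05   # bright lobe
  dip[4:5, 4:5] <- -0.05  # dark lobe, diagonal contact at (3,3)-(4,4)
  seg8 <- segment(absolute_contrast(dip), detection_config(0.02, 1, 8, 0))
  expect_equal(length(seg8$ids), 1)
  seg4 <- segment(absolute_contrast(dip), detection_config(0.02, 1, 4, 0))
  expect_equal(length(seg4$ids), 2)
})

test_that("min_area and edge margin filters apply", {
  img <- matrix(0, 8, 8)
  img[1, 1] <- 1            # touches border
  img[4:5, 4:5] <- 1        # area 4 interior
  img[7, 3] <- 1            # area 1 interior
  seg <- segment(img, detection_config(0.5, min_area_px = 4,
                                       connectivity = 8, edge_margin_px = 1))
  expect_equal(length(seg$ids), 1)
  areas <- tabulate(seg$labels[seg$labels > 0])
  expect_equal(sum(areas > 0), 1)
  expect_equal(max(areas), 4)
})

test_that("weighted centroid: symmetry, arithmetic, and an independent sum", {
  # symmetric blob about the centre of 0-based pixel (5, 5) -> 5.5 px
  img <- matrix(0, 11, 11)
  img[5:7, 5:7] <- matrix(c(1, 2, 1, 2, 5, 2, 1, 2, 1), 3, 3)
  lab <- matrix(0L, 11, 11); lab[img > 0] <- 1L
  loc <- weighted_centroid(img, lab, 1L, pixel_nm = 33)
  expect_equal(loc$x_px, 5.5)
  expect_equal(loc$y_px, 5.5)
  expect_equal(loc$x_nm, 5.5 * 33)

  # weight 1 at x = 0, weight 3 at x = 2 -> weighted mean 1.5 + 0.5 centre
  img2 <- matrix(0, 3, 3)
  img2[2, 1] <- 1; img2[2, 3] <- 3
  lab2 <- matrix(0L, 3, 3); lab2[img2 > 0] <- 1L
  loc2 <- weighted_centroid(img2, lab2, 1L, pixel_nm = 100)
  expect_equal(loc2$x_px, 2.0)  # 0-based coordinates 0.5 and 2.5

  # random region equals a brute-force summation oracle
  set.seed(9)
  img3 <- matrix(runif(64), 8, 8)
  lab3 <- matrix(0L, 8, 8)
  sel <- cbind(sample(2:7, 5, TRUE), sample(2:7, 5, TRUE))
  lab3[unique(sel)] <- 1L
  loc3 <- weighted_centroid(img3, lab3, 1L, pixel_nm = 33)
  idx <- which(lab3 == 1L, arr.ind = TRUE)
  w <- img3[idx]
  expect_equal(loc3$x_px, sum((idx[, 2] - 0.5) * w) / sum(w),
               tolerance = 1e-12)
  expect_equal(loc3$y_px, sum((idx[, 1] - 0.5) * w) / sum(w),
               tolerance = 1e-12)
  expect_equal(loc3$mean_abs_contrast, mean(w), tolerance = 1e-12)

  expect_error(weighted_centroid(img3 * 0, lab3, 1L, 33),
               class = "iscattrack_invalid")
})

test_that("detection is equivariant under whole-pixel translation", {
  base <- spot_frame(24, 24, list(list(x = 8, y = 9, amp = 0.1)))
  cfg <- detection_config(0.02, min_area_px = 1, edge_margin_px = 0,
                          smooth_sigma_px = 0, peak_min_sep_px = 0,
                          centroid_sigma_px = 0)
  l1 <- detect_frame(base, cfg, pixel_nm = 33, frame = 1L)
  shifted <- matrix(0, 24, 24)
  shifted[4:24, 3:24] <- base[1:21, 1:22]  # shift by (+3 rows, +2 cols)
  l2 <- detect_frame(shifted, cfg, pixel_nm = 33, frame = 1L)
  expect_equal(nrow(l1), 1)
  expect_equal(nrow(l2), 1)
  expect_equal(l2$x_px - l1$x_px, 2, tolerance = 1e-9)
  expect_equal(l2$y_px - l1$y_px, 3, tolerance = 1e-9)
})

test_that("all-below-threshold frame yields no localizations", {
  cfg <- detection_config(0.5, 1, 8, 0)
  expect_equal(nrow(detect_frame(matrix(0.01, 10, 10), cfg, 33)), 0)
})

test_that("peak splitting separates two merged blobs", {
  img <- spot_frame(40, 40, list(list(x = 12, y = 20, amp = 0.2),
                                 list(x = 28, y = 20, amp = 0.2)),
                    sigma_px = 4)
  # single connected region at this low threshold
  seg <- segment(img, detection_config(0.01, 1, 8, 0))
  expect_equal(length(seg$ids), 1)
  cfg <- detection_config(0.01, min_area_px = 1, edge_margin_px = 0,
                          smooth_sigma_px = 0, peak_min_sep_px = 8,
                          centroid_sigma_px = 0)
  locs <- detect_frame(img, cfg, pixel_nm = 33)
  expect_equal(nrow(locs), 2)
  expect_equal(sort(locs$x_px), c(12, 28), tolerance = 0.05)
})

test_that("threshold estimate tracks the noise floor", {
  set.seed(5)
  arr <- array(rnorm(40 * 40 * 20, 0, 0.01), c(40, 40, 20))
  cs <- structure(list(frames = arr, pixel_nm = 33, frame_rate_hz = 90.5,
                       valid_frame_offset = 0L, raw_frame_index = 1:20),
                  class = "contrast_stack")
  thr <- estimate_threshold(cs, k = 8, smooth_sigma_px = 0)
  # |N(0, 0.01)|: median ~ 0.0067, sd-equivalent MAD ~ 0.0074
  expect_gt(thr, 0.02)
  expect_lt(thr, 0.2)
  # detection on pure noise with this threshold yields almost nothing
  locs <- detect_stack(cs, detection_config(thr, min_area_px = 4,
                                            smooth_sigma_px = 0,
                                            centroid_sigma_px = 0))
  expect_lt(nrow(locs), 5)
})
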