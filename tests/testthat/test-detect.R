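# Nuclei detection: preprocessing, segmentation, fused-object splitting,
# centroid records.

test_that("preprocessing removes flat background and smooth gradients", {
  p <- detection_params()
  expect_equal(max(abs(preprocess(matrix(500, 60, 60), p))), 0)
  # a pure linear shade gradient is suppressed to near nothing
  g <- outer(seq_len(80), rep(1, 80)) * 50   # range 0..4000
  filt <- preprocess(g, p)
  expect_lt(max(abs(filt)), 0.02 * diff(range(g)))
  expect_error(preprocess(matrix(1, 4, 4), p), "smaller")
})

test_that("detection is independent of the background gradient", {
  # one nucleus on increasing planar gradients: same detection, same centroid
  base <- matrix(1000, 100, 100)
  img0 <- draw_disc(base, 50.5, 40.5, 10, amp = 20000)
  p <- detection_params()
  centr <- function(img) {
    f <- preprocess(img + matrix(rnorm(1e4, 0, 300), 100), p)
    lab <- split_fused(segment(f, p), f, p)
    reduce_to_centroids(lab, f)
  }
  set.seed(404)
  r0 <- centr(img0)
  grad <- outer(seq_len(100) / 100, rep(1, 100))
  r1 <- centr(img0 + 10000 * grad)   # gradient 50% of nucleus contrast
  expect_equal(nrow(r0), 1)
  expect_equal(nrow(r1), 1)
  expect_lt(abs(r0$x_px - r1$x_px), 1)
  expect_lt(abs(r0$y_px - r1$y_px), 1)
  # background subtraction with the (even) 10 px window anchors half a pixel
  # off-centre, so the preprocessed-path centroid is accurate to ~1 px
  expect_lt(abs(r0$x_px - 50.5), 1)
})

test_that("segmentation finds exactly the rendered objects", {
  p <- detection_params()
  expect_equal(max(segment(matrix(0, 50, 50) - 1, p)), 0)  # empty image
  img <- matrix(0, 120, 120)
  pos <- cbind(c(25, 60, 95, 30, 90), c(30, 80, 25, 95, 95))
  for (i in seq_len(nrow(pos))) img <- draw_disc(img, pos[i, 1], pos[i, 2], 8, 5000)
  lab <- segment(img, p)
  expect_equal(max(lab), 5)
  # threshold above the global maximum finds nothing
  p_hi <- detection_params(maxima_threshold = max(img) + 1)
  expect_equal(max(segment(img, p_hi)), 0)
  # objects below the minimum area are discarded as noise
  img2 <- img; img2[5, 5] <- 6000; img2[5, 6] <- 6000
  expect_equal(max(segment(img2, p)), 5)
})

test_that("oversized fused objects split into their constituent nuclei", {
  # fixture: several isolated nuclei incl. sub-median partial profiles (as
  # chord sections produce), plus one fused pair overlapping ~20%
  img <- matrix(0, 160, 160)
  r <- 8
  # three partial-chord (sub-median) profiles, one full nucleus, one pair
  singles <- cbind(c(25, 60, 130, 130), c(30, 120, 40, 120), c(5, 5, 6, r))
  for (i in seq_len(nrow(singles)))
    img <- draw_disc(img, singles[i, 1], singles[i, 2], singles[i, 3], 5000)
  cx1 <- 90; cx2 <- 90 + 1.35 * r           # centres 1.35 r apart: heavy overlap
  img <- draw_disc(img, cx1, 70, r, 5000)
  img <- draw_disc(img, cx2, 70, r, 5000)
  p <- detection_params()
  lab0 <- segment(img, p)
  expect_equal(max(lab0), 5)                 # pair fused into one object
  lab <- split_fused(lab0, img, p)
  expect_equal(max(lab), 6)
  rec <- reduce_to_centroids(lab, img)
  pair <- rec[rec$y_px > 60 & rec$y_px < 80, ]
  expect_equal(nrow(pair), 2)
  expect_lt(min(abs(pair$x_px - cx1)), 1)
  expect_lt(min(abs(pair$x_px - cx2)), 1)
  # idempotence: a second pass changes nothing
  lab2 <- split_fused(lab, img, p)
  expect_equal(as.vector(lab2 > 0), as.vector(lab > 0))
  expect_equal(max(lab2), max(lab))
  expect_equal(attr(lab2, "n_split"), 0L)
})

test_that("the median-area gate leaves homogeneous objects alone", {
  img <- matrix(0, 120, 120)
  for (pos in list(c(25, 25), c(60, 60), c(95, 30), c(30, 95)))
    img <- draw_disc(img, pos[1], pos[2], 8, 5000)
  p <- detection_params()
  lab <- segment(img, p)
  out <- split_fused(lab, img, p)
  expect_equal(max(out), 4)
  expect_equal(attr(out, "n_split"), 0L)
  # a single large nucleus (one interior maximum) three times the median
  # area stays whole
  img2 <- img
  img2 <- draw_disc(img2, 85, 90, 8 * sqrt(3), 5000)
  lab2 <- segment(img2, p)
  out2 <- split_fused(lab2, img2, p)
  expect_equal(max(out2), 5)
})

test_that("centroids are sub-pixel accurate and mask-aware", {
  img <- draw_disc(matrix(0, 60, 60), 30.5, 25.5, 9, 4000)
  lab <- segment(img, detection_params())
  mask <- matrix(0L, 60, 60); mask[, 1:40] <- 2L
  rec <- reduce_to_centroids(lab, img, mask, section = 4, pixel_size_um = 0.5)
  expect_equal(nrow(rec), 1)
  expect_lt(abs(rec$x_px - 30.5), 0.5)       # symmetric disc: geometric centre
  expect_lt(abs(rec$y_px - 25.5), 0.5)
  expect_equal(rec$material, 2L)
  expect_equal(rec$section, 4L)
  expect_equal(rec$x_um, (rec$x_px - 0.5) * 0.5)
  # centroid on background material is kept but flagged excluded
  mask0 <- matrix(0L, 60, 60)
  rec0 <- reduce_to_centroids(lab, img, mask0)
  expect_true(rec0$excluded)
})

test_that("stack detection matches the phantom truth at high accuracy", {
  fx <- small_rendered()
  records <- detect_nuclei(fx$stack)
  dt <- detectable_truth(fx$truth, fx$spec)
  m <- match_records(records, dt, radius_um = 2)
  expect_gte(m["recall"], 0.98)
  expect_gte(m["precision"], 0.98)
  # control image renders without error and marks the centroids
  ctrl <- detection_control_image(fx$stack, records, 1)
  expect_true(all(ctrl >= 0 & ctrl <= 1))
})
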