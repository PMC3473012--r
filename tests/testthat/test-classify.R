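# Per-nucleus analogue classification, threshold calibration, compensation.

# build a 3-nucleus single-section fixture: two adjacent nuclei (one labelled)
# plus one isolated nucleus, on a flat background
three_nucleus_fixture <- function(bg = 100, amp = 900) {
  img_nuc <- matrix(1000, 90, 90)
  for (pos in list(c(25, 45), c(43, 45), c(70, 45)))
    img_nuc <- draw_disc(img_nuc, pos[1], pos[2], 7, 20000)
  analogue <- matrix(bg, 90, 90)
  analogue <- draw_disc(analogue, 43, 45, 5, amp, power = 0)  # labelled, flat fill
  p <- detection_params()
  f <- preprocess(img_nuc, p)
  lab <- split_fused(segment(f, p), f, p)
  records <- reduce_to_centroids(lab, f, matrix(1L, 90, 90))
  records$record <- seq_len(nrow(records))
  attr(records, "label_stacks") <- list(lab)
  list(records = records, lab = lab, analogue = analogue)
}

test_that("signal measurement separates nucleus, annulus and exclusion zone", {
  fx <- three_nucleus_fixture()
  ch <- array(fx$analogue, c(90, 90, 1))
  m <- measure_signal(fx$records, ch, params = classification_params(),
                      prefix = "a")
  expect_equal(nrow(m), 3)
  # uniform background: all background means equal the constant, sd ~ 0
  expect_equal(m$a_mean_bg, rep(100, 3), tolerance = 1e-6)
  expect_equal(m$a_sd_bg, rep(0, 3), tolerance = 1e-6)
  # the labelled nucleus reads the fill; unlabelled ones read background
  ord <- order(m$x_px)
  expect_gt(m$a_mean_in[ord[2]], 900)
  expect_lt(abs(m$a_mean_in[ord[1]] - 100), 1e-6)
  expect_lt(abs(m$a_mean_in[ord[3]] - 100), 1e-6)
  # the unlabelled neighbour's background excludes the labelled nucleus:
  # its mean_bg equals the isolated nucleus's mean_bg exactly
  expect_equal(m$a_mean_bg[ord[1]], m$a_mean_bg[ord[3]], tolerance = 1e-9)
})

test_that("positivity is thresholded on the standardised difference", {
  expect_false(classify_positive(10, 10, overall_sd_bg = 2, k_sd = 1))
  expect_true(classify_positive(13, 10, overall_sd_bg = 2, k_sd = 1))
  p <- classify_positive(13, 10, overall_sd_bg = 2, k_sd = 1)
  expect_equal(attr(p, "z"), 1.5)
  # degenerate noiseless case reduces to a strict comparison
  expect_true(classify_positive(11, 10, overall_sd_bg = 0))
  expect_false(classify_positive(10, 10, overall_sd_bg = 0))
  # threshold monotonicity: positives at k + delta are a subset
  set.seed(31)
  mi <- rnorm(300, 5); mb <- rnorm(300, 4.5)
  for (k in c(0.5, 1, 2)) {
    a <- classify_positive(mi, mb, 1, k)
    b <- classify_positive(mi, mb, 1, k + 0.7)
    expect_true(all(a[b]))
  }
})

test_that("compensation divides the long count by the detection ratio", {
  expect_equal(compensate_long_fraction(928, 0.928), 1000)
  expect_equal(compensate_long_fraction(0, 0.928), 0)
  expect_equal(compensate_long_fraction(250, 1), 250)
  expect_error(compensate_long_fraction(-1), "non-negative")
  expect_error(compensate_long_fraction(10, 1.2), "\\(0, 1\\]")
})

test_that("phantom classification is accurate against the label truth", {
  fx <- small_rendered()
  records <- detect_nuclei(fx$stack)
  records <- classify_nuclei(records, fx$stack)
  calib <- calibrate_short_threshold(records)
  records <- apply_short_threshold(records, calib$k_short_sd)
  dt <- detectable_truth(fx$truth, fx$spec)
  # match records to truth objects and compare label calls
  hits <- 0; total <- 0; short_hits <- 0
  for (s in unique(dt$section)) {
    a <- dt[dt$section == s, ]
    b <- records[records$section == s, ]
    D <- outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2
    j <- apply(D, 1, which.min)
    ok <- D[cbind(seq_len(nrow(a)), j)] <= 4
    total <- total + sum(ok)
    hits <- hits + sum(a$labelled_long[ok] == b$positive_long[j[ok]])
    short_hits <- short_hits + sum(a$labelled_short[ok] == b$positive_short[j[ok]])
  }
  expect_gte(hits / total, 0.98)
  expect_gte(short_hits / total, 0.98)
})

test_that("short-threshold calibration matches the realized efficiency", {
  fx <- small_rendered()
  records <- detect_nuclei(fx$stack)
  records <- classify_nuclei(records, fx$stack)
  calib <- calibrate_short_threshold(records)
  app <- section_appearances(fx$truth, fx$spec)
  realized <- mean(app$labelled_long[app$labelled_short])
  expect_lt(abs(calib$achieved_ratio - realized), 0.01)
  expect_gt(calib$k_short_sd, 0)
  expect_true(all(c("k", "ratio", "iso_ratio", "n", "mirror_frac") %in%
                    names(calib$trace)))
})

test_that("calibration handles clean data and degenerate inputs", {
  # well-separated synthetic standardised differences, efficiency 1:
  # the ratio is 1 at the lower bound
  rec <- tibble::tibble(
    excluded = FALSE,
    z_short = c(rep(0, 400), rep(8, 100)),   # noiseless channels
    positive_long = c(rep(FALSE, 400), rep(TRUE, 100)))
  cal <- calibrate_short_threshold(rec, target_double_ratio = 0.99)
  expect_equal(cal$achieved_ratio, 1)
  expect_equal(cal$k_short_sd, 0.1)          # lower bound of the search
  # no short positives at any threshold
  rec0 <- tibble::tibble(excluded = FALSE, z_short = rep(-5, 50),
                         positive_long = FALSE)
  expect_error(calibrate_short_threshold(rec0), "no short-positive")
  # a target far above what the data support fails with the achieved ratio
  rec_low <- tibble::tibble(
    excluded = FALSE,
    z_short = c(rnorm(400, 0, 0.1), rnorm(400, 8, 0.5)),
    positive_long = c(rep(FALSE, 400), runif(400) < 0.5))
  expect_error(calibrate_short_threshold(rec_low, target_double_ratio = 0.95),
               "not\\s+attainable")
})
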