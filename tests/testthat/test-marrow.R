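make_suv <- function(vals, dims = NULL) {
  if (is.null(dims)) dims <- dim(vals)
  voxel_grid(array(vals, dims), spacing = c(2, 2, 2), role = "PET")
}

test_that("vertebral statistics use mean and sample (n-1) SD", {
  suv <- make_suv(2, c(4, 4, 4))
  all_on <- array(TRUE, c(4, 4, 4))
  st <- vertebral_statistics(suv, all_on, all_on)
  expect_equal(st$mean_suv, 2)
  expect_equal(st$sd_suv, 0)
  expect_equal(st$voxel_count, 64L)

  suv3 <- make_suv(0, c(3, 1, 1))
  suv3$data[] <- c(1, 2, 3)
  on3 <- array(TRUE, c(3, 1, 1))
  st3 <- vertebral_statistics(suv3, on3, on3)
  expect_equal(st3$mean_suv, 2)
  expect_equal(st3$sd_suv, 1)  # sample SD, denominator n-1

  off <- array(FALSE, c(3, 1, 1))
  expect_error(vertebral_statistics(suv3, on3, off), "misses trabecular")
  expect_error(vertebral_statistics(suv3, on3, on3, multiplier = 0), "multiplier")
})

test_that("vertebral statistics recover a known normal distribution", {
  n <- 3000
  set.seed(13)
  vals <- rnorm(n, 2.0, 0.2)
  suv <- make_suv(vals, c(n, 1, 1))
  on <- array(TRUE, c(n, 1, 1))
  st <- vertebral_statistics(suv, on, on)
  expect_lt(abs(st$mean_suv - 2.0), 3 * 0.2 / sqrt(n))
  expect_lt(abs(st$sd_suv - 0.2), 3 * 0.2 / sqrt(2 * n))
})

test_that("red threshold is mean - k*SD, monotone in k, negative allowed", {
  st <- structure(list(mean_suv = 2, sd_suv = 0, voxel_count = 10L,
                       multiplier = 2.5), class = "vertebral_statistics")
  expect_equal(red_threshold(st), 2)
  st$sd_suv <- 1
  expect_warning(thr <- red_threshold(st), "negative")
  expect_equal(thr, -0.5)
  thrs <- sapply(c(0.5, 1, 2, 3), function(k) {
    st$multiplier <- k
    suppressWarnings(red_threshold(st))
  })
  expect_true(all(diff(thrs) < 0))  # strictly decreasing in k for sd > 0
})

test_that("marrow segmentation: strict cut, ties to yellow, exclusions honored", {
  suv <- make_suv(c(0.1, 0.5, 1.0, 2.0, 0.5, 3.0, 0.2, 0.8), c(2, 2, 2))
  trab <- array(TRUE, c(2, 2, 2))
  seg <- segment_marrow(suv, trab, threshold = 0.5)
  expect_false(seg$red[2, 1, 1])   # SUV == threshold -> yellow (strict >)
  expect_true(seg$yellow[2, 1, 1])
  expect_identical(seg$red | seg$yellow, seg$analyzed)
  expect_false(any(seg$red & seg$yellow))

  # vacuous cuts
  expect_equal(sum(segment_marrow(suv, trab, -1)$yellow), 0L)
  expect_equal(sum(segment_marrow(suv, trab, 99)$red), 0L)

  # a negative threshold makes every analyzed (non-negative) voxel red
  expect_equal(segment_marrow(suv, trab, -0.5)$red, trab)

  excl <- array(FALSE, c(2, 2, 2)); excl[1, 1, 1] <- TRUE
  seg2 <- segment_marrow(suv, trab, 0.5, exclude = excl)
  expect_false(seg2$analyzed[1, 1, 1])
  expect_equal(sum(seg2$analyzed), 7L)
  expect_error(segment_marrow(suv, array(TRUE, c(3, 3, 3)), 0.5), "dimensions")
})

test_that("volumes convert voxel counts exactly and conserve the partition", {
  red <- array(FALSE, c(20, 10, 10)); red[1:10, , ] <- TRUE  # 1000 voxels
  trab <- array(TRUE, c(20, 10, 10))
  seg <- structure(list(red = red, yellow = trab & !red, analyzed = trab,
                        threshold = 1), class = "marrow_segmentation")
  v <- compute_volumes(seg, trab, spacing = c(2, 2, 2))
  expect_equal(v$rbv_ml, 8)  # 1000 voxels x 8 mm^3
  expect_equal(v$rbv_ml + v$ybv_ml, v$analyzed_ml)
  expect_equal(v$red_fraction, 0.5)
  expect_equal(v$ibv_ml, 16)
})

test_that("RBV + YBV = analyzed volume for every threshold (conservation)", {
  set.seed(17)
  suv <- make_suv(abs(rnorm(6^3, 1, 0.8)), c(6, 6, 6))
  trab <- array(runif(6^3) < 0.7, c(6, 6, 6))
  for (thr in c(-1, 0, 0.3, 1, 2.5, 10)) {
    seg <- segment_marrow(suv, trab, thr)
    v <- compute_volumes(seg, trab, c(2, 2, 2))
    expect_identical(v$n_red + v$n_yellow, v$n_analyzed)
    expect_equal(v$rbv_ml + v$ybv_ml, v$analyzed_ml)
  }
})

test_that("multiplicative SUV rescaling leaves the segmentation unchanged", {
  set.seed(23)
  suv <- make_suv(abs(rnorm(5^3, 1.5, 0.6)), c(5, 5, 5))
  trab <- array(runif(5^3) < 0.8, c(5, 5, 5))
  vert <- array(runif(5^3) < 0.5, c(5, 5, 5)) & trab
  st <- vertebral_statistics(suv, trab, vert)
  seg <- segment_marrow(suv, trab, suppressWarnings(red_threshold(st)))
  for (c_scale in c(0.2, 3.7)) {
    suv2 <- make_suv(c_scale * suv$data, c(5, 5, 5))
    st2 <- vertebral_statistics(suv2, trab, vert)
    seg2 <- segment_marrow(suv2, trab, suppressWarnings(red_threshold(st2)))
    expect_identical(seg2$red, seg$red)
    expect_identical(seg2$yellow, seg$yellow)
  }
})

test_that("spine versus rest-of-body SUV summary behaves as a mean ratio", {
  u <- make_suv(1.4, c(4, 4, 4))
  trab <- array(TRUE, c(4, 4, 4))
  spine <- array(FALSE, c(4, 4, 4)); spine[, , 1:2] <- TRUE
  s <- suv_summary(u, trab, spine)
  expect_equal(s$spine_to_rob_ratio, 1)  # homogeneous field

  u2 <- make_suv(0.8, c(4, 4, 4)); u2$data[, , 1:2] <- 2.0
  s2 <- suv_summary(u2, trab, spine)
  expect_equal(s2$spinal_mean_suv, 2.0)
  expect_equal(s2$rob_mean_suv, 0.8)
  expect_equal(s2$spine_to_rob_ratio, 2.5)

  # excluding a high-uptake skull lowers nothing but the ROB denominator side
  skull <- array(FALSE, c(4, 4, 4)); skull[, , 4] <- TRUE
  u3 <- u2; u3$data[, , 4] <- 5
  with_sk <- suv_summary(u3, trab, spine)
  wo_sk <- suv_summary(u3, trab, spine, skull_roi = skull)
  expect_lt(wo_sk$rob_mean_suv, with_sk$rob_mean_suv)
  expect_gt(wo_sk$spine_to_rob_ratio, with_sk$spine_to_rob_ratio)

  expect_error(suv_summary(u, trab, array(FALSE, c(4, 4, 4))), "spine")
  expect_error(suv_summary(u, trab, trab), "rest-of-body")
})
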