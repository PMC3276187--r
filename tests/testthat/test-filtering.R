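test_that("blue weight follows the linear fade and clamps", {
  fp <- filter_params()
  expect_equal(blue_weight(0, fp), 0.35)
  expect_equal(blue_weight(25000, fp), 0.175)
  expect_equal(blue_weight(50000, fp), 0)
  expect_equal(blue_weight(80000, fp), 0)         # clamped below at 0
  expect_equal(blue_weight(10000, fp), 0.35 * 40000 / 50000)
  expect_error(blue_weight(-1, fp), "nonnegative")
  fp2 <- filter_params(blue_weight_base = 0.2, reference_area = 10000)
  expect_equal(blue_weight(0, fp2), 0.2)
  expect_equal(blue_weight(5000, fp2), 0.1)
})

test_that("filter parameter validation rejects bad inputs", {
  expect_error(filter_params(blue_weight_base = 1.2), "\\[0, 1\\]")
  expect_error(filter_params(reference_area = 0), "positive")
  expect_error(filter_params(rb_weights = c(0.7, 0.7)), "summing to 1")
  expect_error(filter_params(rb_weights = c(-0.5, 1.5)), "summing to 1")
  expect_error(threshold_params(c2_intraday = 0), "positive")
  expect_error(threshold_params(c3_noon = -1), "nonnegative")
  expect_error(threshold_params(c1_spring = NA), "finite")
})

test_that("intra-day and noon filters match hand-computed pixel values", {
  fp <- filter_params()
  px <- array(rep(c(0.2, 0.5, 0.4), each = 4), c(2, 2, 3))  # R G B
  # D = 0.35, RB = 0.3:
  # intra-day (0.5-0.2+0.4)*0.65 + (0.5-0.3+0.4)*0.35 = 0.455 + 0.21
  expect_equal(filter_intraday(px, 0.35, fp)[1, 1], 0.665)
  # noon: 0.3*0.65 + 0.2*0.35
  expect_equal(filter_noon(px, 0.35, fp)[1, 1], 0.265)
  # D = 0 reduces to G - R (+ offset)
  expect_equal(filter_intraday(px, 0, fp)[1, 1], 0.7)
  expect_equal(filter_noon(px, 0, fp)[1, 1], 0.3)
  # D = 1 uses the RB mixture only
  expect_equal(filter_noon(px, 1, fp)[1, 1], 0.2)
  expect_error(filter_intraday(px, 1.5, fp), "\\[0, 1\\]")
  # asymmetric RB weights
  fp3 <- filter_params(rb_weights = c(0.2, 0.8))
  expect_equal(filter_noon(px, 1, fp3)[1, 1], 0.5 - (0.2 * 0.2 + 0.8 * 0.4))
})

test_that("filters accept flat_image objects and preserve dimensions", {
  px <- array(runif(5 * 7 * 3), c(5, 7, 3))
  fi <- flat_image(px, as.POSIXct("2024-03-05 12:00:00", tz = "UTC"))
  expect_equal(filter_intraday(fi, 0.2), filter_intraday(px, 0.2))
  expect_equal(dim(filter_noon(px, 0.2)), c(5, 7))
})

test_that("threshold models evaluate the affine formulas exactly", {
  tp <- threshold_params()
  expect_identical(threshold_noon(0, 0, tp), 0.12)
  expect_equal(threshold_noon(0.4, 1000, tp), 0.12 + 0.475 * 0.4 - 0.0000013 * 1000)
  expect_error(threshold_noon(0.1, -5, tp), "nonnegative")
  expect_identical(threshold_intraday(0, 0, "spring", tp), 0.335)
  expect_identical(threshold_intraday(0, 0, "summer", tp), 0.305)
  expect_equal(threshold_intraday(0.5, 100000, "spring", tp),
               0.335 + 0.470 * 0.5 - 0.00000146 * 100000)
  expect_error(threshold_intraday(0, 0, "winter", tp))
})

test_that("staged grid calibration recovers known threshold constants exactly", {
  # Three frame groups pin the three constants in turn. Filtered values are a
  # fine gradient through the true threshold, so any misfit misclassifies
  # pixels and the objective has a unique grid minimum at the truth.
  true_c1 <- 0.30; true_c2 <- 0.45; true_c3 <- 1e-06
  grad_frame <- function(U, A, early) {
    Tstar <- true_c1 + true_c2 * U - true_c3 * A
    f <- matrix(seq(Tstar - 0.1, Tstar + 0.1, length.out = 2001), 2001, 1)
    list(filtered = f, truth_mask = f >= Tstar, U = U, area_anchor = A,
         season = "spring", early = early)
  }
  training <- list(
    grad_frame(U = 0,   A = 0,      early = TRUE),   # pins C1
    grad_frame(U = 0,   A = 100000, early = FALSE),  # pins C3
    grad_frame(U = 0.4, A = 0,      early = FALSE))  # pins C2
  fit <- calibrate_threshold_params(
    training,
    c1_grid = round(seq(0.20, 0.40, by = 0.01), 2),
    c2_grid = round(seq(0.30, 0.60, by = 0.05), 2),
    c3_grid = c(0, 5e-07, 1e-06, 2e-06))
  expect_equal(fit$params$c1_spring, true_c1)
  expect_equal(fit$params$c2_intraday, true_c2)
  expect_equal(fit$params$c3_intraday, true_c3)
  expect_equal(fit$disagreement, 0)
  expect_s3_class(fit$params, "threshold_params")
  expect_error(calibrate_threshold_params(list(), 0.3, 0.4, 0), "empty training")
})
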