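test_that("binarize keeps pixels at or above the threshold", {
  F <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  expect_identical(binarize(F, 0.2), F >= 0.2)
  expect_true(binarize(matrix(0.2), 0.2)[1, 1])   # boundary is foreground
})

test_that("radius measurement matches analytic geometry", {
  sp <- segmentation_params()
  # single pixel: centroid on the pixel, radius is the half-pixel pad
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  det1 <- merge_and_measure(matrix(as.integer(one), 5, 5),
                            data.frame(label = 1L), sp)
  expect_equal(det1$area, 1)
  expect_equal(det1$radius, 0.5)
  expect_equal(unname(det1$centroid), c(2, 2))    # 0-based
  # 10 x 10 square: corner at distance sqrt(2) * 4.5 from the centroid
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  det2 <- merge_and_measure(matrix(as.integer(sq), 20, 20),
                            data.frame(label = 1L), sp)
  expect_equal(det2$area, 100)
  expect_equal(det2$radius, sqrt(2 * 4.5^2) + 0.5)
  # disk: radius close to the generating radius, circular area covers it
  dk <- disk_mask(101, 101, 50, 50, 20)
  det3 <- merge_and_measure(matrix(as.integer(dk), 101, 101),
                            data.frame(label = 1L), sp)
  expect_equal(det3$radius, 20.5, tolerance = 0.03)
  expect_gte(pi * det3$radius^2, det3$area)
})

test_that("object labelling separates distinct objects and measures them", {
  fg <- disk_mask(80, 160, 40, 40, 12) | disk_mask(80, 160, 120, 40, 12)
  lab <- label_objects(fg)
  expect_equal(nrow(lab$objects), 2)
  expect_equal(sum(lab$objects$area), sum(fg))
  expect_equal(sort(lab$objects$centroid_x), c(40, 120), tolerance = 0.01)
  expect_equal(lab$objects$centroid_y, c(40, 40), tolerance = 0.01)
  # perimeter of a 10x10 square is its 36 boundary pixels
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  expect_equal(label_objects(sq)$objects$perimeter, 36)
  # empty foreground
  lab0 <- label_objects(matrix(FALSE, 10, 10))
  expect_equal(nrow(lab0$objects), 0)
  expect_true(all(lab0$labels == 0L))
})

test_that("noise pruning applies the three clauses with the N switch", {
  sp <- segmentation_params()
  objects <- data.frame(label = 1:5,
                        area      = c(29, 40, 45, 300, 60),
                        perimeter = c(40, 29, 40, 100, 40),
                        centroid_x = 0, centroid_y = 0)
  pr <- prune_noise(objects, prev_area = 1000, sp)      # N = 30
  expect_equal(pr$N, 30)
  expect_equal(pr$kept$label, c(4L, 5L))
  expect_equal(pr$removed$label, c(1L, 2L, 3L))
  expect_match(pr$removed$reason[1], "area<N")
  expect_match(pr$removed$reason[2], "perimeter<N")
  expect_match(pr$removed$reason[3], "ratio<min")
  # large-plant switch: N = 60 removes more
  pr2 <- prune_noise(objects, prev_area = 25000, sp)
  expect_equal(pr2$N, 60)
  expect_equal(pr2$kept$label, 4L)
  # the switch boundary itself still uses the small N
  expect_equal(prune_noise(objects, prev_area = 20000, sp)$N, 30)
  expect_equal(prune_noise(objects, prev_area = 20001, sp)$N, 60)
  # clause boundaries: area == N and ratio == ratio_min are kept
  edge <- data.frame(label = 1:2, area = c(30, 60), perimeter = c(30, 40),
                     centroid_x = 0, centroid_y = 0)
  pre <- prune_noise(edge, 0, sp)
  expect_equal(pre$kept$label, 2L)                 # 60/40 = 1.5 kept
  expect_match(pre$removed$reason, "ratio<min")    # 30/30 = 1 < 1.5
  expect_error(prune_noise(objects, -1, sp), "nonnegative")
})

test_that("merging returns an empty detection when nothing is kept", {
  lab <- matrix(0L, 10, 10)
  det <- merge_and_measure(lab, data.frame(label = integer()), threshold = 0.4)
  expect_equal(det$area, 0)
  expect_equal(det$radius, 0)
  expect_true(all(is.na(det$centroid)))
  expect_equal(det$threshold, 0.4)
})

test_that("frame segmentation removes thin bright lines but keeps the rosette", {
  # a disk plus a 1-px-wide bright line (a pot edge): the line fails the
  # area/perimeter ratio clause and must not contaminate the measurement
  F <- matrix(0, 120, 120)
  dk <- disk_mask(120, 120, 60, 60, 15)
  F[dk] <- 0.8
  F[, 5] <- 0.8
  det <- segment_frame(F, 0.5, prev_area = 1000)
  expect_equal(det$area, sum(dk))
  expect_false(any(det$mask[, 5]))
  expect_true(any(grepl("ratio<min", det$removed$reason)))
})
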