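test_that("flat_image validates its inputs", {
  ts <- as.POSIXct("2024-03-05 12:00:00", tz = "UTC")
  px <- array(runif(4 * 4 * 3), c(4, 4, 3))
  fi <- flat_image(px, ts, flat_id = "flatA", season = "summer")
  expect_s3_class(fi, "flat_image")
  expect_equal(fi$season, "summer")
  expect_error(flat_image(matrix(0, 4, 4), ts), "H x W x 3")
  expect_error(flat_image(array(0, c(4, 4, 4)), ts), "H x W x 3")
  expect_error(flat_image(px * 2, ts), "\\[0, 1\\]")
  expect_error(flat_image(px - 1, ts), "\\[0, 1\\]")
  expect_error(flat_image(px, "2024-03-05"), "POSIXct")
})

test_that("PNG round trip preserves 8-bit pixel values", {
  set.seed(11)
  img <- round(array(runif(20 * 30 * 3), c(20, 30, 3)) * 255) / 255
  p <- file.path(tempdir(), "roundtrip.png")
  write_rgb(img, p)
  back <- read_rgb(p)
  expect_equal(dim(back), c(20, 30, 3))
  expect_equal(back, img, tolerance = 1e-9)
  expect_error(read_rgb(file.path(tempdir(), "x.tif")), "unsupported")
  unlink(p)
})

test_that("flat index parses timestamps, windows, and sorts", {
  d <- file.path(tempdir(), "idx_test")
  dir.create(d, showWarnings = FALSE)
  on.exit(unlink(d, recursive = TRUE))
  good <- c("flatA_20240305_120000.png", "flatA_20240305_060000.png",
            "flatA_20240306_120000.png", "flatA_20240307_120000.jpg")
  for (f in c(good, "notes.png", "flatA_20241399_120000.png"))
    file.create(file.path(d, f))
  ws <- as.POSIXct("2024-03-05 00:00:00", tz = "UTC")
  we <- as.POSIXct("2024-03-06 23:59:59", tz = "UTC")
  idx <- suppressWarnings(build_flat_index(d, ws, we))
  expect_equal(idx$filename,
               c("flatA_20240305_060000.png", "flatA_20240305_120000.png",
                 "flatA_20240306_120000.png"))
  expect_true(all(diff(as.numeric(idx$timestamp)) > 0))
  w <- capture_warnings(build_flat_index(d, ws, we))
  expect_match(w, "notes.png", all = FALSE)
  expect_match(w, "invalid timestamp", all = FALSE)
  # corrupt exclusion and empty-window error
  idx2 <- suppressWarnings(
    build_flat_index(d, ws, we, corrupt = "flatA_20240305_060000.png"))
  expect_false("flatA_20240305_060000.png" %in% idx2$filename)
  expect_error(suppressWarnings(
    build_flat_index(d, ws + 900 * 86400, we + 900 * 86400)), "no usable")
  expect_error(build_flat_index(d, we, ws), "precede")
})

test_that("day/night cutoff splits a bimodal series and classifies exactly", {
  set.seed(3)
  night <- runif(20, 0.005, 0.022)
  day <- runif(60, 0.055, 0.25)
  v <- sample(c(night, day))
  cut <- suggest_cutoff(v)
  expect_gt(cut, max(night))
  expect_lt(cut, min(day))
  lab <- classify_day_night(v, cut)
  expect_identical(lab, ifelse(v %in% day, "day", "night"))
  expect_error(suggest_cutoff(rep(0.1, 10)), "no bimodality")
  expect_error(classify_day_night(numeric(), 0.1), "empty")
})

test_that("coordinate maps validate, select by time, and crop correctly", {
  d <- tempdir()
  csv <- file.path(d, "coords_test.csv")
  writeLines(c(
    "flat_id,valid_from,pot_id,center_x,center_y,crop_w,crop_h,accession",
    "flatA,2024-03-05 00:00:00,pot01,50,50,100,100,accA",
    "flatA,2024-03-05 00:00:00,pot02,150,50,100,100,accB",
    "flatA,2024-03-07 00:00:00,pot01,52,50,100,100,accA",
    "flatA,2024-03-07 00:00:00,pot02,152,50,100,100,accB"), csv)
  maps <- read_coordinate_maps(csv)
  expect_equal(nrow(maps), 4)
  m1 <- map_for_time(maps, "flatA", as.POSIXct("2024-03-06 12:00:00", tz = "UTC"))
  expect_equal(m1$center_x, c(50, 150))      # earlier map still valid
  m2 <- map_for_time(maps, "flatA", as.POSIXct("2024-03-08 12:00:00", tz = "UTC"))
  expect_equal(m2$center_x, c(52, 152))      # later map supersedes
  expect_error(map_for_time(maps, "flatA",
                            as.POSIXct("2024-03-01 00:00:00", tz = "UTC")),
               "no coordinate map")
  # duplicate pot within one map rejected
  writeLines(c(
    "flat_id,valid_from,pot_id,center_x,center_y,crop_w,crop_h,accession",
    "flatA,2024-03-05 00:00:00,pot01,50,50,100,100,accA",
    "flatA,2024-03-05 00:00:00,pot01,150,50,100,100,accB"), csv)
  expect_error(read_coordinate_maps(csv), "duplicate pot_id")
  unlink(csv)
})

test_that("mean filtered intensity is the whole-frame mean of G - R", {
  px <- array(0, c(2, 2, 3))
  px[, , 1] <- 0.1; px[, , 2] <- c(0.3, 0.5, 0.3, 0.5)
  expect_equal(mean_filtered_intensity(px), mean(c(0.2, 0.4, 0.2, 0.4)))
})
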