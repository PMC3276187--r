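test_that("the logistic growth model hits its analytic limits", {
  plants <- data.frame(plant_id = "p1", pot_id = "pot01", genotype = "a",
                       value = 0)
  gm <- growth_model(plants)
  expect_equal(true_area(gm, gm$plants$rate[1], 0), gm$area0)
  expect_equal(true_area(gm, gm$plants$rate[1], 1000), gm$asymptote,
               tolerance = 1e-6)
  tt <- seq(0, 10, by = 0.25)
  a <- true_area(gm, gm$plants$rate[1], tt)
  expect_true(all(diff(a) > 0))                     # strictly increasing
  expect_true(all(a <= gm$asymptote))
  expect_error(growth_model(plants[, -4]), "columns")
})

test_that("rendered rosette masks cover the target area", {
  for (case in list(c(500, 4), c(5000, 8), c(20000, 12))) {
    rm <- render_rosette_mask(case[1], case[2], c(120, 120), 240, 240,
                              base_angle = 0.7)
    expect_equal(sum(rm$mask), case[1], tolerance = 0.05)
    # every mask pixel lies within the analytic tip radius of the centre
    idx <- which(rm$mask, arr.ind = TRUE)
    d <- sqrt((idx[, 2] - 1 - 120)^2 + (idx[, 1] - 1 - 120)^2)
    expect_lte(max(d), rm$radius + 1)
  }
})

test_that("the frame schedule covers the photoperiod plus night checks", {
  spec <- scene_spec(rows = 1, cols = 2, pot_px = 120, n_days = 3,
                     frame_interval_min = 120)
  sched <- frame_schedule(spec)
  per_day <- (spec$day_end - spec$day_start) * 60 / spec$frame_interval_min
  expect_equal(sum(sched$is_day), 3 * per_day)
  expect_equal(sum(!sched$is_day), 2 * 2)           # 2 night frames, between days
  expect_true(!is.unsorted(sched$timestamp))
  expect_true(all(sched$light_frac[!sched$is_day] == 0))
  expect_error(scene_spec(frame_interval_min = 23), "divide")
})

test_that("simulated populations have the requested size and variance split", {
  gm <- simulate_phenotypes(5, 5, h2_target = 0.8, seed = 3)
  expect_equal(nrow(gm$plants), 25)
  expect_equal(length(unique(gm$plants$genotype)), 5)
  # genotype effects are constant within genotype
  expect_true(all(tapply(gm$plants$genotype_effect, gm$plants$genotype,
                         function(x) diff(range(x))) == 0))
  expect_equal(gm$plants$value,
               gm$plants$genotype_effect + gm$plants$residual_effect)
  # h2 = 0 means no genotype variance at all
  gm0 <- simulate_phenotypes(5, 5, h2_target = 0, seed = 3)
  expect_true(all(gm0$plants$genotype_effect == 0))
  expect_error(simulate_phenotypes(5, 5, h2_target = 1.2), "\\[0, 1\\]")
  # determinism
  gm2 <- simulate_phenotypes(5, 5, h2_target = 0.8, seed = 3)
  expect_identical(gm$plants, gm2$plants)
})

test_that("stage truth times bracket the leaf-count crossings", {
  plants <- data.frame(plant_id = c("p1", "p2"), pot_id = c("pot01", "pot02"),
                       genotype = "a", value = c(0, 0),
                       dev_value = c(0, -2))    # p2 develops far too slowly
  gm <- growth_model(plants)
  spec <- scene_spec(rows = 1, cols = 2, pot_px = 120, n_days = 7)
  st <- true_stage_times(gm, spec)
  expect_false(any(is.na(st[st$plant_id == "p1", -1])))
  expect_true(all(is.na(st[st$plant_id == "p2", -1])))
  expect_true(st$t_110[1] > st$t_104[1])
  # leaf counts are nondecreasing and start at n0
  lc <- leaf_count(gm, gm$plants$dev_rate[1], seq(0, 7, by = 0.1))
  expect_equal(lc[1], gm$n0_leaves)
  expect_true(all(diff(lc) >= 0))
})

test_that("rendering is deterministic and writes a complete truth bundle", {
  spec <- scene_spec(rows = 1, cols = 2, pot_px = 120, n_days = 2,
                     frame_interval_min = 280, jitter_px = 4)
  plants <- data.frame(plant_id = c("p1", "p2"), pot_id = c("pot01", "pot02"),
                       genotype = c("a", "b"), value = c(0, 0.1))
  gm <- growth_model(plants)
  d1 <- file.path(tempdir(), "rs1"); d2 <- file.path(tempdir(), "rs2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  tr1 <- render_series(spec, gm, seed = 9, out_dir = d1)
  tr2 <- render_series(spec, gm, seed = 9, out_dir = d2)
  # files: 3 day frames per day x 2 days + 2 night checks between the days
  expect_equal(nrow(tr1$index), 8)
  expect_true(all(file.exists(file.path(tr1$image_dir, tr1$index$filename))))
  for (f in c("coords.csv", "stages.csv", "genotypes.csv", "truth_areas.csv"))
    expect_true(file.exists(file.path(d1, f)))
  # bit-identical across identical seeds
  md5 <- function(d) unname(tools::md5sum(list.files(
    file.path(d, "images"), full.names = TRUE)))
  expect_identical(md5(d1), md5(d2))
  # truth areas equal their masks
  a1 <- tr1$areas[1, ]
  expect_equal(a1$true_area, sum(tr1$masks[[a1$plant_id]][[a1$filename]]))
  # night frames are darker in green-minus-red than day frames
  mi <- vapply(file.path(tr1$image_dir, tr1$index$filename),
               function(p) mean_filtered_intensity(read_rgb(p)), numeric(1))
  expect_lt(max(mi[!tr1$index$is_day]), min(mi[tr1$index$is_day]))
  # coordinate map is consumable and covers both pots
  maps <- read_coordinate_maps(file.path(d1, "coords.csv"))
  expect_equal(sort(maps$pot_id), c("pot01", "pot02"))
})

test_that("different seeds change the soil but not the layout metadata", {
  spec <- scene_spec(rows = 1, cols = 1, pot_px = 120, n_days = 1,
                     frame_interval_min = 420, jitter_px = 0)
  plants <- data.frame(plant_id = "p1", pot_id = "pot01", genotype = "a",
                       value = 0)
  gm <- growth_model(plants)
  d1 <- file.path(tempdir(), "sd1"); d2 <- file.path(tempdir(), "sd2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  tr1 <- render_series(spec, gm, seed = 1, out_dir = d1)
  tr2 <- render_series(spec, gm, seed = 2, out_dir = d2)
  expect_identical(tr1$coords, tr2$coords)
  expect_identical(tr1$index$filename, tr2$index$filename)
  i1 <- read_rgb(file.path(tr1$image_dir, tr1$index$filename[1]))
  i2 <- read_rgb(file.path(tr2$image_dir, tr2$index$filename[1]))
  expect_false(identical(i1, i2))
})
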