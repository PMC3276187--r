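# Synthetic flat-image generator with ground truth.
#
# Emulates the chamber scenes the pipeline was designed for: a 6 x 6 pot flat
# seen from above, speckled bright soil (perlite/vermiculite reflections with
# G ~ R, suppressed by the green-minus-red filter), blue pot edges (thin
# structures the noise filter's area/perimeter clause removes), green
# rosettes drawn as unions of rotated elliptical leaves whose count and size
# follow a logistic growth model, a diurnal light curve peaking at noon, dim
# green-LED night frames, a seasonal brightness multiplier, and
# genotype-structured growth-rate variation with chosen variance components.
# Fully deterministic given a seed.

#' Scene specification for the synthetic flat generator
#'
#' Defaults emulate the chamber study conditions: 6 x 6 pots, frames every
#' 20 min through a 06:00-20:00 photoperiod plus two dim green-lit night
#' frames, soil with a slight daytime green bias, bright speckles, blue pot
#' edges, and a sinusoidal within-day light curve.
#'
#' @param rows,cols pot grid (default 6 x 6).
#' @param pot_px pot pitch in pixels; the image is `rows*pot_px` by
#'   `cols*pot_px` and each pot's crop box is `pot_px` square (default 240,
#'   sized so a mature rosette reaches roughly 20000-26000 px).
#' @param edge_px width of the blue pot-edge lines (default 2).
#' @param n_days number of simulated days (default 7).
#' @param start_date first calendar date (`Date`).
#' @param day_start,day_end photoperiod in hours (default 6 and 20).
#' @param frame_interval_min daytime frame interval in minutes (default 20).
#' @param night_hours clock hours of the night frames (default 22:00 and
#'   02:00; values below `day_start` fall on the following date).
#' @param light_base,light_amp diurnal light multiplier
#'   `L = base + amp * sin(pi * f)` with `f` the within-photoperiod fraction.
#' @param night_light,night_green night brightness multiplier and additive
#'   green-LED wash.
#' @param season `"spring"` or `"summer"`; `summer_mult` scales brightness in
#'   summer (default 0.92).
#' @param soil_base,soil_green_bias,soil_blue_off soil base reflectance, its
#'   daytime green bias (chamber light colour) and blue offset.
#' @param speckle_density,speckle_bright fraction and brightness of white
#'   soil speckles.
#' @param texture_sd,sensor_sd static channel-common soil texture noise and
#'   per-frame per-channel sensor noise (sd).
#' @param plant_rgb,pot_edge_rgb base RGB reflectance of leaf and pot-edge
#'   pixels.
#' @param jitter_px maximum per-plant offset of the rosette centre from the
#'   pot centre (default 8).
#' @param flat_id flat identifier used in file names.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(rows = 6, cols = 6, pot_px = 240, edge_px = 2,
                       n_days = 7, start_date = as.Date("2024-03-05"),
                       day_start = 6, day_end = 20, frame_interval_min = 20,
                       night_hours = c(22, 2),
                       light_base = 0.7, light_amp = 0.3,
                       night_light = 0.04, night_green = 0.015,
                       season = c("spring", "summer"), summer_mult = 0.92,
                       soil_base = 0.30, soil_green_bias = 0.08,
                       soil_blue_off = -0.04,
                       speckle_density = 0.04, speckle_bright = 0.85,
                       texture_sd = 0.04, sensor_sd = 0.008,
                       plant_rgb = c(0.12, 0.55, 0.10),
                       pot_edge_rgb = c(0.15, 0.25, 0.65),
                       jitter_px = 8, flat_id = "flatA") {
  season <- match.arg(season)
  stopifnot(rows >= 1, cols >= 1, pot_px >= 40, n_days >= 1,
            light_base > 0, night_light > 0, frame_interval_min > 0)
  if (((day_end - day_start) * 60) %% frame_interval_min != 0)
    stop("frame interval must divide the photoperiod")
  structure(as.list(environment()), class = "scene_spec")
}

#' Growth model for a population of plants
#'
#' Per-plant logistic rosette-area curves
#' `A(t) = K A0 e^{rt} / (K + A0 (e^{rt} - 1))` (t in days) plus a sequential
#' leaf-initiation schedule: the plant starts with `n0_leaves` leaves and
#' initiates one new leaf every `plastochron * base_rate / rate` days, so
#' faster-growing plants also develop faster.
#'
#' @param plants `data.frame` with columns `plant_id`, `pot_id`, `genotype`,
#'   `value` (standardized growth deviation; genotype + plant residual) and
#'   optionally `dev_value`, the corresponding developmental deviation
#'   scaling leaf initiation (defaults to `value`, i.e. fully coupled
#'   growth and development).
#' @param base_rate population logistic rate per day (default 0.9); a plant's
#'   expansion rate is `base_rate * exp(value)` and its leaf-initiation
#'   interval `plastochron * exp(-dev_value)`.
#' @param area0 initial rosette area in px (default 150).
#' @param asymptote logistic asymptote K in px (default 26000).
#' @param plastochron base days per leaf initiation (default 0.55).
#' @param n0_leaves leaves present at t = 0 (default 3).
#' @return a `growth_model` list.
#' @export
growth_model <- function(plants, base_rate = 0.9, area0 = 150,
                         asymptote = 26000, plastochron = 0.55, n0_leaves = 3) {
  need <- c("plant_id", "pot_id", "genotype", "value")
  if (!all(need %in% names(plants)))
    stop("plants must have columns: ", paste(need, collapse = ", "))
  stopifnot(base_rate > 0, area0 > 0, asymptote > area0, plastochron > 0)
  if (is.null(plants$dev_value)) plants$dev_value <- plants$value
  plants$rate <- base_rate * exp(plants$value)
  plants$dev_rate <- base_rate * exp(plants$dev_value)
  structure(list(plants = plants, base_rate = base_rate, area0 = area0,
                 asymptote = asymptote, plastochron = plastochron,
                 n0_leaves = n0_leaves),
            class = "growth_model")
}

#' True rosette area of a plant at a time
#'
#' @param gm a [growth_model()].
#' @param rate plant logistic rate (per day).
#' @param t_days time in days since simulation start (vectorized).
#' @return expected rosette area in px.
#' @export
true_area <- function(gm, rate, t_days) {
  # decaying-exponential form stays finite for arbitrarily large t
  gm$asymptote / (1 + (gm$asymptote / gm$area0 - 1) * exp(-rate * t_days))
}

leaf_count <- function(gm, dev_rate, t_days) {
  gm$n0_leaves + floor(pmax(0, t_days) / (gm$plastochron * gm$base_rate / dev_rate))
}

#' True stage times for every plant
#'
#' Stage 1.04 is anchored at the beginning of the calendar day on which the
#' leaf count reaches 4, stage 1.10 at the end of the day on which it reaches
#' 10 (the leaf-count schedule stands in for the 10-px leaf-length
#' criterion). Plants that do not reach stage 1.10 within the simulated
#' window get `NA`.
#'
#' @param gm a [growth_model()].
#' @param spec a [scene_spec()].
#' @return `data.frame`: `plant_id`, `t_104`, `t_110` (`POSIXct`).
#' @export
true_stage_times <- function(gm, spec) {
  day0 <- as.POSIXct(paste(spec$start_date, "00:00:00"), tz = "UTC")
  res <- lapply(seq_len(nrow(gm$plants)), function(i) {
    pl <- gm$plastochron * gm$base_rate / gm$plants$dev_rate[i]
    t4 <- (4 - gm$n0_leaves) * pl
    t10 <- (10 - gm$n0_leaves) * pl
    t104 <- day0 + floor(t4) * 86400
    t110 <- day0 + (floor(t10) + 1) * 86400
    if (t10 > spec$n_days) { t104 <- as.POSIXct(NA); t110 <- as.POSIXct(NA) }
    data.frame(plant_id = gm$plants$plant_id[i], t_104 = t104, t_110 = t110)
  })
  do.call(rbind, res)
}

# relative sizes of the leaves, newest last (youngest leaves still expanding)
leaf_rels <- function(n) {
  rels <- rep(1, n)
  if (n >= 1) rels[n] <- 0.5
  if (n >= 2) rels[n - 1] <- 0.75
  rels
}

GOLDEN_ANGLE <- 137.50776 * pi / 180
LEAF_B_RATIO <- 0.45   # ellipse minor/major ratio
LEAF_OFFSET <- 0.55    # leaf centre offset from rosette centre, units of a

.s_cache <- new.env(parent = emptyenv())

# union area of the unit rosette (a = 1) with n leaves, by grid quadrature;
# rosette area scales exactly as a^2
union_scale <- function(n) {
  key <- as.character(n)
  if (!is.null(.s_cache[[key]])) return(.s_cache[[key]])
  h <- 0.01
  g <- seq(-1.6, 1.6, by = h)
  xx <- rep(g, times = length(g)); yy <- rep(g, each = length(g))
  inside <- rosette_inside(xx, yy, 1, n, base_angle = 0)
  s <- sum(inside) * h * h
  .s_cache[[key]] <- s
  s
}

# vectorized point-in-rosette test for a rosette with semi-major a, n leaves
rosette_inside <- function(x, y, a, n, base_angle) {
  rels <- leaf_rels(n)
  inside <- rep(FALSE, length(x))
  for (i in seq_len(n)) {
    ai <- a * rels[i]; bi <- LEAF_B_RATIO * ai
    ang <- base_angle + i * GOLDEN_ANGLE
    lcx <- LEAF_OFFSET * ai * cos(ang); lcy <- LEAF_OFFSET * ai * sin(ang)
    dx <- x - lcx; dy <- y - lcy
    u <- cos(ang) * dx + sin(ang) * dy
    v <- -sin(ang) * dx + cos(ang) * dy
    inside <- inside | (u / ai)^2 + (v / bi)^2 <= 1
  }
  inside
}

#' Render a rosette mask
#'
#' Draws a rosette of `n_leaves` rotated elliptical leaves in a golden-angle
#' spiral, scaled so the union covers approximately `area` pixels, centred at
#' `center` (0-based x, y) on an `H x W` grid.
#'
#' @param area target union area in px.
#' @param n_leaves number of leaves.
#' @param center numeric `(x, y)` centre, 0-based pixel coordinates.
#' @param H,W grid dimensions.
#' @param base_angle rotation of the whole rosette (radians).
#' @return list with `mask` (logical `H x W`), `a` (leaf semi-major axis in
#'   px) and `radius` (analytic max centre-to-tip distance).
#' @export
render_rosette_mask <- function(area, n_leaves, center, H, W, base_angle = 0) {
  stopifnot(area > 0, n_leaves >= 1)
  a <- sqrt(area / union_scale(n_leaves))
  xs <- (0:(W - 1)) - center[1]
  ys <- (0:(H - 1)) - center[2]
  xx <- rep(xs, each = H); yy <- rep(ys, times = W)
  m <- rosette_inside(xx, yy, a, n_leaves, base_angle)
  list(mask = matrix(m, H, W), a = a,
       radius = (LEAF_OFFSET + 1) * a * max(leaf_rels(n_leaves)))
}

# frame schedule: data.frame(timestamp, day, is_day, light_frac)
frame_schedule <- function(spec) {
  day0 <- as.POSIXct(paste(spec$start_date, "00:00:00"), tz = "UTC")
  rows <- list()
  for (d in seq_len(spec$n_days)) {
    secs <- seq(spec$day_start * 3600, spec$day_end * 3600 - 1,
                by = spec$frame_interval_min * 60)
    frac <- (secs / 3600 - spec$day_start) / (spec$day_end - spec$day_start)
    rows[[length(rows) + 1L]] <-
      data.frame(timestamp = day0 + (d - 1) * 86400 + secs, day = d,
                 is_day = TRUE, light_frac = frac)
    if (d < spec$n_days) {
      nh <- spec$night_hours
      nsec <- ifelse(nh >= spec$day_start, nh * 3600, (nh + 24) * 3600)
      rows[[length(rows) + 1L]] <-
        data.frame(timestamp = day0 + (d - 1) * 86400 + nsec, day = d,
                   is_day = FALSE, light_frac = 0)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$timestamp), , drop = FALSE]
}

#' Simulate a plant population with a target heritability
#'
#' Draws genotype growth effects `~ N(0, h2 * sd^2)` and plant residuals
#' `~ N(0, (1 - h2) * sd^2)`, so the broad-sense heritability of the summed
#' growth deviation `value` is `h2_target`. The deviation acts
#' multiplicatively on the logistic expansion rate
#' (`rate = base_rate * exp(value)`). A separate developmental deviation
#' `dev_value` (same variance structure, correlated `dev_cor` with the
#' growth deviation at both the genotype and the residual level) scales the
#' leaf-initiation schedule: development and expansion covary but are not
#' identical, so genotype differences in expansion survive normalization
#' onto the relative developmental timescale.
#'
#' @param n_geno number of genotypes (accessions).
#' @param n_rep replicates per genotype.
#' @param h2_target target heritability in \[0, 1\].
#' @param seed RNG seed.
#' @param sd_total total standard deviation of the growth deviation
#'   (default 0.15).
#' @param dev_cor correlation between the growth and developmental
#'   deviations (default 0.6, reflecting that late staging is largely
#'   predicted by early staging while expansion retains its own variation).
#' @param dev_sd total standard deviation of the developmental deviation
#'   (default 0.10).
#' @param ... passed to [growth_model()].
#' @return a [growth_model()] whose `plants` table carries
#'   `genotype_effect`, `residual_effect`, their sum `value`, and
#'   `dev_value`.
#' @export
simulate_phenotypes <- function(n_geno, n_rep, h2_target, seed = 1,
                                sd_total = 0.15, dev_cor = 0.6,
                                dev_sd = 0.10, ...) {
  if (h2_target < 0 || h2_target > 1) stop("h2_target must be in [0, 1]")
  set.seed(seed)
  n <- n_geno * n_rep
  g <- rnorm(n_geno, 0, sqrt(h2_target) * sd_total)
  e <- rnorm(n, 0, sqrt(1 - h2_target) * sd_total)
  # developmental deviations, correlated with the growth deviations
  mix <- function(z, z2) dev_cor * z + sqrt(1 - dev_cor^2) * z2
  g_dev <- mix(scale_to(g, sqrt(h2_target) * dev_sd),
               rnorm(n_geno, 0, sqrt(h2_target) * dev_sd))
  e_dev <- mix(scale_to(e, sqrt(1 - h2_target) * dev_sd),
               rnorm(n, 0, sqrt(1 - h2_target) * dev_sd))
  geno <- rep(sprintf("acc%02d", seq_len(n_geno)), each = n_rep)
  plants <- data.frame(
    plant_id = sprintf("p%03d", seq_len(n)),
    pot_id = sprintf("pot%02d", seq_len(n)),
    genotype = geno,
    genotype_effect = rep(g, each = n_rep),
    residual_effect = e)
  plants$value <- plants$genotype_effect + plants$residual_effect
  plants$dev_value <- rep(g_dev, each = n_rep) + e_dev
  growth_model(plants, ...)
}

# rescale a draw to a target sd without changing its direction
scale_to <- function(z, sd_target) {
  s <- stats::sd(z)
  if (!is.finite(s) || s == 0) return(z * 0)
  z * sd_target / s
}

soil_canvas <- function(spec) {
  H <- spec$rows * spec$pot_px; W <- spec$cols * spec$pot_px
  base <- c(spec$soil_base, spec$soil_base + spec$soil_green_bias,
            spec$soil_base + spec$soil_blue_off)
  tex <- matrix(stats::runif(H * W, -spec$texture_sd, spec$texture_sd), H, W)
  speckle <- matrix(stats::runif(H * W) < spec$speckle_density, H, W)
  canvas <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    m <- base[ch] + tex
    m[speckle] <- spec$speckle_bright + tex[speckle]
    canvas[, , ch] <- m
  }
  # blue pot edges along the pot grid (including the outer border), edge_px wide
  line_px <- function(p, lim)
    pmax(1, pmin(lim, p + seq_len(spec$edge_px) - floor(spec$edge_px / 2)))
  eh <- unlist(lapply(0:spec$rows * spec$pot_px, line_px, lim = H))
  ew <- unlist(lapply(0:spec$cols * spec$pot_px, line_px, lim = W))
  for (ch in 1:3) {
    m <- canvas[, , ch]
    m[unique(eh), ] <- spec$pot_edge_rgb[ch]
    m[, unique(ew)] <- spec$pot_edge_rgb[ch]
    canvas[, , ch] <- m
  }
  canvas
}

#' Render a synthetic flat image series with ground truth
#'
#' Writes one image per scheduled frame to `out_dir/images/` together with a
#' coordinate-map CSV, stage-time CSV, genotype CSV and per-frame true areas;
#' returns the full ground truth. Deterministic given `seed`.
#'
#' @param spec a [scene_spec()].
#' @param gm a [growth_model()]; plants are placed row-major into the pot
#'   grid and there must be at most `rows * cols` of them.
#' @param seed RNG seed.
#' @param out_dir output directory (created).
#' @param format `"png"` (default) or `"jpeg"`.
#' @param quality JPEG quality.
#' @param write_masks also write per-plant truth masks of daytime frames as
#'   PNG under `out_dir/masks/` (default `FALSE`).
#' @param keep_masks return daytime truth masks in memory (default `TRUE`).
#' @return list: `index` (frames: `filename`, `timestamp`, `day`, `is_day`,
#'   `light`), `areas` (per plant x frame truth), `stages`, `coords`,
#'   `plants`, `masks` (nested list `[[plant_id]][[filename]]` if kept).
#' @export
render_series <- function(spec, gm, seed = 1, out_dir, format = c("png", "jpeg"),
                          quality = 0.95, write_masks = FALSE, keep_masks = TRUE) {
  format <- match.arg(format)
  plants <- gm$plants
  n_pots <- spec$rows * spec$cols
  if (nrow(plants) > n_pots) stop("more plants than pots")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  if (write_masks)
    dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  H <- spec$rows * spec$pot_px; W <- spec$cols * spec$pot_px
  base_canvas <- soil_canvas(spec)

  # pot placement, row-major; static per-plant jitter and rotation
  pot_row <- (seq_len(nrow(plants)) - 1) %/% spec$cols
  pot_col <- (seq_len(nrow(plants)) - 1) %% spec$cols
  cx <- pot_col * spec$pot_px + spec$pot_px / 2 +
    round(stats::runif(nrow(plants), -spec$jitter_px, spec$jitter_px))
  cy <- pot_row * spec$pot_px + spec$pot_px / 2 +
    round(stats::runif(nrow(plants), -spec$jitter_px, spec$jitter_px))
  rot <- stats::runif(nrow(plants), 0, 2 * pi)

  sched <- frame_schedule(spec)
  season_mult <- if (spec$season == "summer") spec$summer_mult else 1
  day0 <- as.POSIXct(paste(spec$start_date, "00:00:00"), tz = "UTC")

  ext <- if (format == "jpeg") "jpg" else "png"
  fnames <- paste0(spec$flat_id, "_", format(sched$timestamp, "%Y%m%d_%H%M%S"),
                   ".", ext)
  areas <- list(); masks <- list(); overflow <- character()

  for (f in seq_len(nrow(sched))) {
    t_days <- as.numeric(difftime(sched$timestamp[f], day0, units = "days"))
    L <- if (sched$is_day[f])
      (spec$light_base + spec$light_amp * sin(pi * sched$light_frac[f])) * season_mult
    else spec$night_light
    canvas <- base_canvas
    for (p in seq_len(nrow(plants))) {
      A <- true_area(gm, plants$rate[p], t_days)
      nl <- leaf_count(gm, plants$dev_rate[p], t_days)
      # render within the pot's sub-window
      x0 <- pot_col[p] * spec$pot_px; y0 <- pot_row[p] * spec$pot_px
      rm <- render_rosette_mask(A, nl, c(cx[p] - x0, cy[p] - y0),
                                spec$pot_px, spec$pot_px, base_angle = rot[p])
      if (rm$radius > spec$pot_px / 2 - spec$edge_px - 1)
        overflow <- union(overflow, paste0(plants$plant_id[p], "@day", sched$day[f]))
      ys <- (y0 + 1):(y0 + spec$pot_px); xs <- (x0 + 1):(x0 + spec$pot_px)
      for (ch in 1:3) {
        sub <- canvas[ys, xs, ch]
        sub[rm$mask] <- spec$plant_rgb[ch]
        canvas[ys, xs, ch] <- sub
      }
      if (sched$is_day[f]) {
        areas[[length(areas) + 1L]] <- data.frame(
          plant_id = plants$plant_id[p], filename = fnames[f],
          timestamp = sched$timestamp[f], day = sched$day[f],
          true_area = sum(rm$mask), true_radius = rm$radius,
          true_leaves = nl)
        if (keep_masks) masks[[plants$plant_id[p]]][[fnames[f]]] <- rm$mask
        if (write_masks)
          png::writePNG(rm$mask * 1,
                        file.path(out_dir, "masks",
                                  paste0(plants$plant_id[p], "_",
                                         format(sched$timestamp[f], "%Y%m%d_%H%M%S"),
                                         ".png")))
      }
    }
    canvas <- canvas * L
    if (!sched$is_day[f]) canvas[, , 2] <- canvas[, , 2] + spec$night_green
    canvas <- canvas + array(stats::rnorm(length(canvas), 0, spec$sensor_sd),
                             dim(canvas))
    canvas[canvas < 0] <- 0; canvas[canvas > 1] <- 1
    canvas <- round(canvas * 255) / 255   # 8-bit quantization
    write_rgb(canvas, file.path(out_dir, "images", fnames[f]), quality = quality)
  }
  if (length(overflow) > 0)
    warning("rosettes overflow their crop boxes: ",
            paste(overflow, collapse = ", "), call. = FALSE)

  coords <- data.frame(flat_id = spec$flat_id,
                       valid_from = format(day0, "%Y-%m-%d %H:%M:%S"),
                       pot_id = plants$pot_id,
                       center_x = pot_col * spec$pot_px + spec$pot_px / 2,
                       center_y = pot_row * spec$pot_px + spec$pot_px / 2,
                       crop_w = spec$pot_px, crop_h = spec$pot_px,
                       accession = plants$genotype)
  stages <- true_stage_times(gm, spec)
  genotypes <- data.frame(plant_id = plants$plant_id, pot_id = plants$pot_id,
                          accession = plants$genotype,
                          environment = spec$season)
  utils::write.csv(coords, file.path(out_dir, "coords.csv"), row.names = FALSE)
  utils::write.csv(stages, file.path(out_dir, "stages.csv"), row.names = FALSE)
  utils::write.csv(genotypes, file.path(out_dir, "genotypes.csv"), row.names = FALSE)
  areas <- do.call(rbind, areas)
  utils::write.csv(areas, file.path(out_dir, "truth_areas.csv"), row.names = FALSE)

  list(index = data.frame(filename = fnames, timestamp = sched$timestamp,
                          day = sched$day, is_day = sched$is_day),
       areas = areas, stages = stages, coords = coords, plants = plants,
       masks = if (keep_masks) masks else NULL,
       image_dir = file.path(out_dir, "images"))
}
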