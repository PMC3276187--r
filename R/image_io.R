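#' @importFrom stats aov ave cor median predict rnorm runif smooth.spline spline var
#' @importFrom utils read.csv write.csv
NULL

# Images are stored as plain numeric arrays dim c(H, W, 3), channels ordered
# R, G, B, all intensities on [0, 1] (8-bit values divided by 255). Pixel
# coordinates are 0-based with x rightward (columns) and y downward (rows).

#' Construct a flat image record
#'
#' A `flat_image` is one time-stamped top-view RGB frame of a multi-pot flat.
#'
#' @param pixels numeric array `H x W x 3`, channels R, G, B, values in \[0, 1\].
#' @param timestamp a `POSIXct` acquisition time.
#' @param flat_id character identifier of the flat.
#' @param season `"spring"` or `"summer"`; selects the seasonal intercept of
#'   the background-threshold model.
#' @return an object of class `flat_image`.
#' @export
flat_image <- function(pixels, timestamp, flat_id = "flat", season = c("spring", "summer")) {
  season <- match.arg(season)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image dimensions must be positive")
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1)
    stop("channel values must lie in [0, 1]")
  if (!inherits(timestamp, "POSIXct")) stop("timestamp must be POSIXct")
  structure(list(pixels = pixels, timestamp = timestamp,
                 flat_id = flat_id, season = season),
            class = "flat_image")
}

#' Read an RGB image from disk
#'
#' Reads 8-bit JPEG or PNG into an `H x W x 3` array on the \[0, 1\] scale.
#' Grayscale input is replicated across channels; an alpha channel is dropped.
#'
#' @param path file path (`.png`, `.jpg`, `.jpeg`).
#' @return numeric array `H x W x 3`.
#' @export
read_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image to disk
#'
#' @param img numeric array `H x W x 3` (or `H x W` for masks), values in \[0, 1\].
#' @param path destination; format from the extension (`.png`, `.jpg`).
#' @param quality JPEG quality in (0, 1\].
#' @return `path`, invisibly.
#' @export
write_rgb <- function(img, path, quality = 0.95) {
  img[img < 0] <- 0; img[img > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(img, path),
    jpg  = ,
    jpeg = jpeg::writeJPEG(img, path, quality = quality),
    stop("unsupported image format: ", ext))
  invisible(path)
}

#' Index a directory of time-stamped flat images
#'
#' Scans `image_dir` for image files, parses acquisition times from the file
#' names, restricts to the analysis window (from thinning to first bolting),
#' drops known-corrupt files, and returns the series in time order.
#'
#' @param image_dir directory containing the frames.
#' @param window_start,window_end `POSIXct` bounds of the analysis window
#'   (inclusive).
#' @param corrupt character vector of file names to exclude.
#' @param pattern regular expression with two capture groups, date
#'   (`YYYYMMDD`) and time (`HHMMSS`), applied to the base file name.
#' @param tz time zone used when parsing.
#' @return `data.frame` with columns `filename`, `timestamp`, sorted by
#'   timestamp then filename.
#' @details Files whose names do not match `pattern` are excluded with a
#'   warning. An empty result is an error.
#' @export
build_flat_index <- function(image_dir, window_start, window_end,
                             corrupt = character(),
                             pattern = "_(\\d{8})_(\\d{6})\\.(png|jpe?g)$",
                             tz = "UTC") {
  stopifnot(inherits(window_start, "POSIXct"), inherits(window_end, "POSIXct"))
  if (!(window_start < window_end)) stop("window_start must precede window_end")
  files <- list.files(image_dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE)
  files <- setdiff(files, corrupt)
  m <- regmatches(files, regexec(pattern, files))
  ok <- lengths(m) >= 3L
  if (any(!ok)) {
    for (f in files[!ok]) warning("cannot parse timestamp from '", f, "'; excluded",
                                  call. = FALSE)
  }
  files <- files[ok]
  ts <- vapply(m[ok], function(g) paste0(g[2], g[3]), character(1))
  ts <- as.POSIXct(ts, format = "%Y%m%d%H%M%S", tz = tz)
  bad <- is.na(ts)
  if (any(bad)) {
    for (f in files[bad]) warning("invalid timestamp in '", f, "'; excluded",
                                  call. = FALSE)
    files <- files[!bad]; ts <- ts[!bad]
  }
  keep <- ts >= window_start & ts <= window_end
  files <- files[keep]; ts <- ts[keep]
  if (length(files) == 0L) stop("no usable images in the analysis window")
  ord <- order(ts, files)
  data.frame(filename = files[ord], timestamp = ts[ord],
             stringsAsFactors = FALSE)
}

#' Mean green-minus-red intensity of a frame
#'
#' The day/night discriminator: the whole-frame mean of `G - R`. Daytime
#' chamber light leaves a green bias over plants and soil; dim green-LED night
#' frames score close to zero.
#'
#' @param img a `flat_image` or an `H x W x 3` array.
#' @return scalar in \[-1, 1\].
#' @export
mean_filtered_intensity <- function(img) {
  px <- if (inherits(img, "flat_image")) img$pixels else img
  mean(px[, , 2] - px[, , 1])
}

#' Suggest a day/night cutoff from a bimodal intensity series
#'
#' One-dimensional Otsu-style split on the log scale: the threshold between
#' the two classes is searched exhaustively over the sorted log intensities,
#' minimizing within-class variance; the suggested cutoff is the geometric
#' mean of the two class means. Chamber illumination acts multiplicatively,
#' so the day cluster (which spreads as plants grow) and the dim night
#' cluster separate far more reliably on log intensity than on the raw
#' scale. The suggestion is for operator review, not an unattended decision.
#'
#' @param values numeric vector of per-frame mean filtered intensities;
#'   values below `floor` are clipped before taking logs.
#' @param floor positive clipping floor (default 1e-4).
#' @return scalar cutoff, on the raw intensity scale.
#' @export
suggest_cutoff <- function(values, floor = 1e-4) {
  v <- sort(log(pmax(values, floor)))
  n <- length(v)
  if (n < 2L || diff(range(v)) == 0) stop("no bimodality in intensity series")
  best <- Inf; split <- NA_integer_
  for (i in seq_len(n - 1L)) {
    lo <- v[seq_len(i)]; hi <- v[(i + 1L):n]
    w <- (length(lo) * var1(lo) + length(hi) * var1(hi)) / n
    if (w < best) { best <- w; split <- i }
  }
  exp((mean(v[seq_len(split)]) + mean(v[(split + 1L):n])) / 2)
}

var1 <- function(x) if (length(x) < 2L) 0 else stats::var(x)

#' Classify frames as daytime or nighttime
#'
#' A frame is daytime iff its mean green-minus-red intensity exceeds `cutoff`.
#'
#' @param intensity numeric vector of per-frame mean filtered intensities.
#' @param cutoff scalar cutoff (see [suggest_cutoff()]).
#' @return character vector, `"day"` or `"night"` per frame.
#' @export
classify_day_night <- function(intensity, cutoff) {
  if (length(intensity) == 0L) stop("empty intensity series")
  ifelse(intensity > cutoff, "day", "night")
}

#' Read pot coordinate maps
#'
#' A coordinate map assigns each pot of a flat a crop box and accession. A
#' flat may have several maps with different `valid_from` times (the flat can
#' shift slightly during an experiment); a map applies from its `valid_from`
#' until the next map's.
#'
#' @param path CSV with header
#'   `flat_id,valid_from,pot_id,center_x,center_y,crop_w,crop_h,accession`.
#' @param tz time zone for `valid_from`.
#' @return `data.frame` of pot entries.
#' @export
read_coordinate_maps <- function(path, tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("flat_id", "valid_from", "pot_id", "center_x", "center_y",
            "crop_w", "crop_h", "accession")
  if (!all(need %in% names(df)))
    stop("coordinate map must have columns: ", paste(need, collapse = ", "))
  df$valid_from <- as.POSIXct(df$valid_from, tz = tz)
  validate_coordinate_map(df)
  df
}

validate_coordinate_map <- function(maps) {
  by_win <- split(maps, list(maps$flat_id, maps$valid_from), drop = TRUE)
  for (w in by_win) {
    if (anyDuplicated(w$pot_id)) stop("duplicate pot_id within a coordinate map")
    if (nrow(w) > 36L) stop("at most 36 pots per flat")
  }
  invisible(maps)
}

# crop box: half-open [center - w/2, center + w/2) in 0-based pixel coords
crop_bounds <- function(center, width) {
  lo <- as.integer(ceiling(center - width / 2))
  c(lo, lo + as.integer(width) - 1L)
}

crop_frame <- function(pixels, entry) {
  xb <- crop_bounds(entry$center_x, entry$crop_w)
  yb <- crop_bounds(entry$center_y, entry$crop_h)
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  if (xb[1] < 0L || yb[1] < 0L || xb[2] >= W || yb[2] >= H)
    stop("crop box out of bounds for pot ", entry$pot_id)
  pixels[(yb[1] + 1L):(yb[2] + 1L), (xb[1] + 1L):(xb[2] + 1L), , drop = FALSE]
}

map_for_time <- function(maps, flat_id, t) {
  m <- maps[maps$flat_id == flat_id & maps$valid_from <= t, , drop = FALSE]
  if (nrow(m) == 0L)
    stop("no coordinate map valid at ", format(t), " for flat ", flat_id)
  m[m$valid_from == max(m$valid_from), , drop = FALSE]
}

#' Crop a flat image series into per-plant stacks
#'
#' Daytime frames are cropped at each pot's box under the coordinate map valid
#' at the frame's time; night frames are discarded. Each pot yields one
#' `plant_stack` whose frames carry a day index `k` (1 on the first daytime
#' calendar date) and a within-day index `j` (time order within the day).
#'
#' @param image_dir directory holding the indexed frames.
#' @param index frame index from [build_flat_index()].
#' @param maps coordinate maps from [read_coordinate_maps()].
#' @param labels day/night labels aligned with `index` rows.
#' @param flat_id flat identifier.
#' @param season `"spring"` or `"summer"`, attached to every frame.
#' @return named list of `plant_stack` objects (one per pot).
#' @export
crop_to_stacks <- function(image_dir, index, maps, labels,
                           flat_id = maps$flat_id[1],
                           season = c("spring", "summer")) {
  season <- match.arg(season)
  stopifnot(nrow(index) == length(labels))
  day_rows <- which(labels == "day")
  if (length(day_rows) == 0L) stop("no daytime frames to crop")
  day_ts <- index$timestamp[day_rows]
  dates <- as.Date(day_ts, tz = attr(day_ts, "tzone") %||% "UTC")
  k <- as.integer(dates - min(dates)) + 1L
  j <- stats::ave(seq_along(day_rows), k, FUN = seq_along)

  pots <- unique(maps$pot_id)
  stacks <- lapply(pots, function(p) {
    list(pot_id = p, flat_id = flat_id, accession = NA_character_,
         season = season, frames = vector("list", length(day_rows)))
  })
  names(stacks) <- pots

  for (i in seq_along(day_rows)) {
    r <- day_rows[i]
    px <- read_rgb(file.path(image_dir, index$filename[r]))
    m <- map_for_time(maps, flat_id, index$timestamp[r])
    for (p in seq_len(nrow(m))) {
      entry <- m[p, ]
      st <- stacks[[as.character(entry$pot_id)]]
      st$accession <- entry$accession
      st$frames[[i]] <- list(timestamp = index$timestamp[r],
                             pixels = crop_frame(px, entry),
                             day_index = k[i], within_day = j[i])
      stacks[[as.character(entry$pot_id)]] <- st
    }
  }
  lapply(stacks, function(st) {
    st$frames <- Filter(Negate(is.null), st$frames)
    dims <- vapply(st$frames, function(f) dim(f$pixels)[1:2], integer(2))
    if (ncol(dims) > 0 && any(dims != dims[, 1]))
      stop("inconsistent crop dimensions within stack for pot ", st$pot_id)
    class(st) <- "plant_stack"
    st
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.plant_stack <- function(x, ...) {
  cat("<plant_stack>", x$pot_id, "accession:", x$accession,
      "frames:", length(x$frames), "days:",
      length(unique(vapply(x$frames, function(f) as.integer(f$day_index),
                           integer(1)))), "\n")
  invisible(x)
}
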