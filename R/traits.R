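# Noon-anchored daily detection loop and growth-trait extraction.
#
# Day k of a plant stack is processed in two passes. Pass 1 picks the noon
# frame (highest mean G - R), filters and thresholds it with the noon model
# anchored on the previous day's area A_{k-1} (A_1 = 1000 px on day one), and
# detects the rosette to give A_k. Pass 2 re-processes every frame of the day
# (noon included, so the trait series stays homogeneous) with the intra-day
# model anchored on A_k. Traits per frame: rosette area RA, radius, circular
# area CA = pi * radius^2, compactness = RA / CA.

#' Select a day's noon frame
#'
#' The noon frame is the one with the highest mean green-minus-red channel
#' intensity; ties take the earliest.
#'
#' @param day_frames list of frame records, each with a `pixels` array.
#' @return index of the noon frame within `day_frames`.
#' @export
select_noon_frame <- function(day_frames) {
  if (length(day_frames) == 0L) stop("empty day")
  gr <- vapply(day_frames, function(f) mean_filtered_intensity(f$pixels), numeric(1))
  which.max(gr)  # which.max returns the first maximum
}

#' Process one day of a plant stack
#'
#' Runs the two-pass noon-anchored detection for a single day.
#'
#' @param day_frames time-ordered list of the day's frame records
#'   (`timestamp`, `pixels`, `day_index`, `within_day`).
#' @param prev_area previous-day noon area `A_(k-1)` in pixels (the day-one
#'   prior on the first day).
#' @param season `"spring"` or `"summer"`.
#' @param fparams,tparams,sparams parameter objects ([filter_params()],
#'   [threshold_params()], [segmentation_params()]).
#' @return list with `area` (the day's noon area `A_k`), `noon_index`, and
#'   `frames`, a `data.frame` of per-frame traits (`timestamp`, `day`,
#'   `frame`, `RA_px`, `radius_px`, `CA_px`, `compactness`, `is_noon`,
#'   `threshold`, `U`, `D`).
#' @export
process_day <- function(day_frames, prev_area, season = c("spring", "summer"),
                        fparams = filter_params(), tparams = threshold_params(),
                        sparams = segmentation_params()) {
  season <- match.arg(season)
  if (prev_area < 0) stop("prev_area must be nonnegative")
  noon <- select_noon_frame(day_frames)

  # pass 1: noon detection anchored on the previous day
  D_noon <- blue_weight(prev_area, fparams)
  Fn <- filter_noon(day_frames[[noon]]$pixels, D_noon, fparams)
  Un <- mean(Fn)
  Tn <- threshold_noon(Un, prev_area, tparams)
  det_noon <- segment_frame(Fn, Tn, prev_area, sparams)
  A_k <- det_noon$area
  if (A_k == 0)
    warning("noon detection empty on day ", day_frames[[noon]]$day_index,
            "; using A_k = 0", call. = FALSE)

  # pass 2: every frame of the day with the intra-day model anchored on A_k
  D_day <- blue_weight(A_k, fparams)
  rows <- lapply(seq_along(day_frames), function(i) {
    fr <- day_frames[[i]]
    Fi <- filter_intraday(fr$pixels, D_day, fparams)
    Ui <- mean(Fi)
    Ti <- threshold_intraday(Ui, A_k, season, tparams)
    det <- segment_frame(Fi, Ti, A_k, sparams)
    ca <- pi * det$radius^2
    data.frame(timestamp = fr$timestamp, day = fr$day_index,
               frame = fr$within_day, RA_px = det$area,
               radius_px = det$radius, CA_px = ca,
               compactness = if (det$area > 0) det$area / ca else NA_real_,
               is_noon = (i == noon), threshold = Ti, U = Ui, D = D_day)
  })
  list(area = A_k, noon_index = noon, frames = do.call(rbind, rows))
}

#' Run the daily detection loop over a plant stack
#'
#' Iterates [process_day()] over the stack's days in order, threading the
#' noon-area state `A_k` across days (the only cross-frame coupling). Day
#' indices need not be contiguous; missing days are simply absent.
#'
#' @param stack a `plant_stack` from [crop_to_stacks()].
#' @param season `"spring"` or `"summer"`; defaults to the stack's season.
#' @param day_one_area day-one prior for `A_(k-1)` (default 1000 px).
#' @param empty_day what anchors the next day after an empty noon detection:
#'   `"zero"` (default; the failure stays visible in QC) or `"carry"` (carry
#'   the previous day's area forward).
#' @param fparams,tparams,sparams parameter objects.
#' @return list with `traits` (per-frame trait `data.frame`, with `pot_id`
#'   and `accession`) and `daily` (`data.frame` of `day`, `noon_area`).
#' @export
run_stack <- function(stack, season = NULL, day_one_area = 1000,
                      empty_day = c("zero", "carry"),
                      fparams = filter_params(), tparams = threshold_params(),
                      sparams = segmentation_params()) {
  if (length(stack$frames) == 0L) stop("empty plant stack")
  empty_day <- match.arg(empty_day)
  season <- season %||% stack$season %||% "spring"
  days <- vapply(stack$frames, function(f) as.integer(f$day_index), integer(1))
  prev <- day_one_area
  traits <- list(); daily <- list()
  for (k in sort(unique(days))) {
    res <- process_day(stack$frames[days == k], prev, season,
                       fparams, tparams, sparams)
    traits[[as.character(k)]] <- res$frames
    daily[[as.character(k)]] <- data.frame(day = k, noon_area = res$area)
    prev <- if (res$area == 0 && empty_day == "carry") prev else res$area
  }
  tr <- do.call(rbind, traits)
  rownames(tr) <- NULL
  tr <- cbind(pot_id = stack$pot_id, accession = stack$accession, tr)
  list(traits = tr, daily = do.call(rbind, c(daily, list(make.row.names = FALSE))))
}

#' Write a per-plant trait table to CSV
#'
#' @param traits trait `data.frame` from [run_stack()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_csv <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE)
  invisible(path)
}
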