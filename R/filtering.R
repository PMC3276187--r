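# Size-weighted colour filter and hierarchical background-threshold model.
#
# Intra-day filter:  F = (G - R + offset) (1 - D) + (G - RB + offset) D
# Noon filter:       F = (G - R) (1 - D) + (G - RB) D
# Blue weight:       D = 0.35 (50000 - A) / 50000, clamped to [0, 0.35]
# Intra-day threshold: T = C_s + 0.470 U - 0.00000146 A_k     (C_spring 0.335, C_summer 0.305)
# Noon threshold:      T = 0.12 + 0.475 U - 0.00000130 A_{k-1}
# where U is the mean filtered intensity of the frame and A an area anchor in
# pixels (noon area of the current day for intra-day frames, previous-day noon
# area for the noon frame). All intensities are on the [0, 1] scale.

#' Colour-filter parameters
#'
#' @param offset additive offset of the intra-day filter (default 0.4).
#' @param blue_weight_base maximum blue-channel weight (default 0.35); blue
#'   pot edges blend into the foreground only while plants are small, so the
#'   blue correction fades out as the rosette grows.
#' @param reference_area rosette area (px) at which the blue weight reaches 0
#'   (default 50000).
#' @param rb_weights nonnegative weights of red and blue in the RB mixture;
#'   must sum to 1 (default equal weights).
#' @return a `filter_params` list.
#' @export
filter_params <- function(offset = 0.4, blue_weight_base = 0.35,
                          reference_area = 50000, rb_weights = c(0.5, 0.5)) {
  if (blue_weight_base < 0 || blue_weight_base > 1)
    stop("blue_weight_base must be in [0, 1]")
  if (reference_area <= 0) stop("reference_area must be positive")
  if (length(rb_weights) != 2L || any(rb_weights < 0) ||
      abs(sum(rb_weights) - 1) > 1e-8)
    stop("rb_weights must be two nonnegative values summing to 1")
  structure(list(offset = offset, blue_weight_base = blue_weight_base,
                 reference_area = reference_area, rb_weights = rb_weights),
            class = "filter_params")
}

#' Background-threshold parameters
#'
#' Defaults are the calibrated constants of the hierarchical threshold model:
#' a seasonal intercept (`c1_spring`, `c1_summer`) plus a light term
#' (`c2 * U`, mean filtered intensity) minus a size term (`c3 * A`, rosette
#' area anchor in pixels), with a separate intercept/slope set for the
#' noon-anchor pass.
#'
#' @param c1_spring,c1_summer seasonal intercepts of the intra-day model.
#' @param c2_intraday,c3_intraday light and size coefficients (intra-day).
#' @param c1_noon,c2_noon,c3_noon the noon-pass model coefficients.
#' @return a `threshold_params` list.
#' @export
threshold_params <- function(c1_spring = 0.335, c1_summer = 0.305,
                             c2_intraday = 0.470, c3_intraday = 0.00000146,
                             c1_noon = 0.12, c2_noon = 0.475,
                             c3_noon = 0.00000130) {
  vals <- c(c1_spring, c1_summer, c2_intraday, c3_intraday,
            c1_noon, c2_noon, c3_noon)
  if (any(!is.finite(vals))) stop("threshold parameters must be finite")
  if (c2_intraday <= 0 || c2_noon <= 0) stop("c2 coefficients must be positive")
  if (c3_intraday < 0 || c3_noon < 0) stop("c3 coefficients must be nonnegative")
  structure(list(c1_spring = c1_spring, c1_summer = c1_summer,
                 c2_intraday = c2_intraday, c3_intraday = c3_intraday,
                 c1_noon = c1_noon, c2_noon = c2_noon, c3_noon = c3_noon),
            class = "threshold_params")
}

#' Blue-channel weighting factor
#'
#' `D = base * (reference_area - area_anchor) / reference_area`, clamped to
#' `[0, base]`. The anchor is the noon rosette area of the current day for
#' intra-day frames and the previous day's noon area for the noon frame.
#'
#' @param area_anchor rosette area anchor in pixels (>= 0).
#' @param params a [filter_params()] object.
#' @return scalar weight in `[0, blue_weight_base]`.
#' @export
blue_weight <- function(area_anchor, params = filter_params()) {
  if (any(area_anchor < 0)) stop("area_anchor must be nonnegative")
  d <- params$blue_weight_base *
    (params$reference_area - area_anchor) / params$reference_area
  pmin(pmax(d, 0), params$blue_weight_base)
}

rb_mix <- function(img, params) {
  params$rb_weights[1] * img[, , 1] + params$rb_weights[2] * img[, , 3]
}

#' Apply the intra-day colour filter
#'
#' Per pixel: `F = (G - R + offset)(1 - D) + (G - RB + offset) D`, where RB is
#' the weighted red/blue mixture. Output is not clipped; thresholds operate on
#' the raw affine scale.
#'
#' @param img `H x W x 3` array (or `flat_image`) on the \[0, 1\] scale.
#' @param D blue weight from [blue_weight()], in \[0, 1\].
#' @param params a [filter_params()] object.
#' @return numeric `H x W` matrix of filtered intensities.
#' @export
filter_intraday <- function(img, D, params = filter_params()) {
  if (D < 0 || D > 1) stop("D must be in [0, 1]")
  px <- if (inherits(img, "flat_image")) img$pixels else img
  G <- px[, , 2]; R <- px[, , 1]
  (G - R + params$offset) * (1 - D) + (G - rb_mix(px, params) + params$offset) * D
}

#' Apply the noon colour filter
#'
#' As [filter_intraday()] but without the additive offset:
#' `F = (G - R)(1 - D) + (G - RB) D`.
#'
#' @inheritParams filter_intraday
#' @return numeric `H x W` matrix.
#' @export
filter_noon <- function(img, D, params = filter_params()) {
  if (D < 0 || D > 1) stop("D must be in [0, 1]")
  px <- if (inherits(img, "flat_image")) img$pixels else img
  G <- px[, , 2]; R <- px[, , 1]
  (G - R) * (1 - D) + (G - rb_mix(px, params)) * D
}

#' Intra-day background threshold
#'
#' `T = C_s + c2 * U - c3 * A` with the season-dependent intercept `C_s`.
#'
#' @param U mean filtered intensity of the frame.
#' @param area_anchor current-day noon rosette area `A_k` (px).
#' @param season `"spring"` or `"summer"`.
#' @param params a [threshold_params()] object.
#' @return scalar threshold.
#' @export
threshold_intraday <- function(U, area_anchor, season = c("spring", "summer"),
                               params = threshold_params()) {
  season <- match.arg(season)
  c1 <- if (season == "spring") params$c1_spring else params$c1_summer
  c1 + params$c2_intraday * U - params$c3_intraday * area_anchor
}

#' Noon background threshold
#'
#' `T = c1 + c2 * U - c3 * A_prev`, anchored on the previous day's noon area.
#'
#' @param U mean filtered intensity of the noon frame.
#' @param prev_area previous-day noon rosette area `A_(k-1)` (px, >= 0).
#' @param params a [threshold_params()] object.
#' @return scalar threshold.
#' @export
threshold_noon <- function(U, prev_area, params = threshold_params()) {
  if (any(prev_area < 0)) stop("prev_area must be nonnegative")
  params$c1_noon + params$c2_noon * U - params$c3_noon * prev_area
}

mask_disagreement <- function(filtered, truth, T) {
  mask <- filtered >= T
  sum(xor(mask, truth)) / max(1, sum(truth))
}

stage_objective <- function(training, c1, c2, c3, subset = seq_along(training)) {
  d <- vapply(subset, function(i) {
    tr <- training[[i]]
    T <- c1 + c2 * tr$U - c3 * tr$area_anchor
    mask_disagreement(tr$filtered, tr$truth_mask, T)
  }, numeric(1))
  mean(d)
}

grid_best <- function(grid, f) {
  vals <- vapply(grid, f, numeric(1))
  list(value = grid[[which.min(vals)]], objective = min(vals))
}

#' Calibrate threshold parameters against ground-truth masks
#'
#' Staged exhaustive grid search over the threshold model
#' `T = C1 + C2 * U - C3 * A`, minimizing the mean pixel-wise disagreement
#' (symmetric difference divided by truth area) between the thresholded mask
#' and the ground truth. Stages mirror the original calibration procedure:
#' `C1` is fit on early-stage frames (small plants, where the light and size
#' terms are negligible) with `C2 = C3 = 0`; then `C3` with `C1` fixed; then
#' `C2` with `C1` and `C3` fixed. If training frames span both seasons, `C1`
#' is fit per season. Deterministic: ties take the first-best in grid order.
#'
#' @param training list of records, each with fields `filtered` (filtered
#'   intensity matrix), `truth_mask` (logical matrix), `U` (mean filtered
#'   intensity), `area_anchor` (px), `season`, and optionally `early`
#'   (logical; defaults to `area_anchor <= early_area_max`).
#' @param c1_grid,c2_grid,c3_grid numeric candidate grids.
#' @param early_area_max area (px) below which a frame counts as early-stage
#'   for the `C1` fit (default 3000, roughly the six-leaf stage).
#' @return list with `params` (a [threshold_params()] with fitted intra-day
#'   slots; fitted seasonal intercepts only for seasons present in training),
#'   `disagreement` (final mean objective) and `path` (per-stage fits).
#' @export
calibrate_threshold_params <- function(training, c1_grid, c2_grid, c3_grid,
                                       early_area_max = 3000) {
  if (length(training) == 0L) stop("empty training set")
  if (length(c1_grid) == 0L || length(c2_grid) == 0L || length(c3_grid) == 0L)
    stop("empty parameter grid")
  seasons <- vapply(training, function(tr) tr$season %||% "spring", character(1))
  early <- vapply(training, function(tr) {
    if (!is.null(tr$early)) tr$early else tr$area_anchor <= early_area_max
  }, logical(1))

  c1_fit <- list()
  for (s in unique(seasons)) {
    idx <- which(seasons == s & early)
    if (length(idx) == 0L) idx <- which(seasons == s)
    c1_fit[[s]] <- grid_best(as.list(c1_grid), function(c1)
      stage_objective(training, c1, 0, 0, idx))
  }
  c1_of <- function(i) c1_fit[[seasons[i]]]$value

  obj_fixed_c1 <- function(c2, c3) {
    mean(vapply(seq_along(training), function(i) {
      tr <- training[[i]]
      T <- c1_of(i) + c2 * tr$U - c3 * tr$area_anchor
      mask_disagreement(tr$filtered, tr$truth_mask, T)
    }, numeric(1)))
  }
  c3_fit <- grid_best(as.list(c3_grid), function(c3) obj_fixed_c1(0, c3))
  c2_fit <- grid_best(as.list(c2_grid), function(c2) obj_fixed_c1(c2, c3_fit$value))

  params <- threshold_params()
  if ("spring" %in% names(c1_fit)) params$c1_spring <- c1_fit$spring$value
  if ("summer" %in% names(c1_fit)) params$c1_summer <- c1_fit$summer$value
  params$c2_intraday <- c2_fit$value
  params$c3_intraday <- c3_fit$value
  list(params = params,
       disagreement = c2_fit$objective,
       path = list(c1 = c1_fit, c3 = c3_fit, c2 = c2_fit))
}
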