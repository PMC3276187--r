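# Rosette detection: threshold -> distance map -> watershed -> noise pruning
# -> merge + hull/edge measurements.

#' Segmentation parameters
#'
#' @param watershed_tolerance minimum object-peak height difference for the
#'   watershed split (default 1, in distance-map units).
#' @param watershed_extension neighbourhood radius used by the watershed when
#'   merging nearby seeds (default 3).
#' @param n_small,n_large minimum surface area and perimeter `N` applied by
#'   the noise filter; `n_small` (default 30) while the previous-day area is
#'   at most `area_switch`, else `n_large` (default 60).
#' @param area_switch previous-day area (px) switching `N` (default 20000).
#' @param ratio_min minimum surface-area/perimeter ratio (default 1.5); thin
#'   bright structures such as pot edges fall below it and are removed.
#' @param radius_pad half-pixel padding added to the maximum centroid-to-edge
#'   distance so a discretized disk's circular area covers its own pixel area
#'   (default 0.5).
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(watershed_tolerance = 1, watershed_extension = 3,
                                n_small = 30, n_large = 60, area_switch = 20000,
                                ratio_min = 1.5, radius_pad = 0.5) {
  if (any(c(watershed_tolerance, watershed_extension, n_small, n_large,
            area_switch, ratio_min) <= 0))
    stop("segmentation parameters must be positive")
  if (n_small > n_large) stop("n_small must not exceed n_large")
  structure(list(watershed_tolerance = watershed_tolerance,
                 watershed_extension = watershed_extension,
                 n_small = n_small, n_large = n_large,
                 area_switch = area_switch, ratio_min = ratio_min,
                 radius_pad = radius_pad),
            class = "segmentation_params")
}

#' Threshold a filtered frame into foreground
#'
#' Pixels with filtered intensity `>= T` are foreground (pixels below the
#' background threshold are set to background).
#'
#' @param F numeric matrix of filtered intensities.
#' @param T scalar threshold.
#' @return logical matrix.
#' @export
binarize <- function(F, T) F >= T

# boundary pixels: object pixels with at least one 4-neighbour (or the image
# border) carrying a different label
boundary_mask <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  pad <- matrix(-1L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- labels
  ctr <- pad[2:(H + 1L), 2:(W + 1L)]
  (ctr != pad[1:H, 2:(W + 1L)] | ctr != pad[3:(H + 2L), 2:(W + 1L)] |
   ctr != pad[2:(H + 1L), 1:W] | ctr != pad[2:(H + 1L), 3:(W + 2L)]) & ctr > 0L
}

#' Index foreground objects by distance-map watershed
#'
#' Computes the Euclidean distance map of the foreground and applies the
#' watershed transform (`tolerance`, `ext` from `params`) to split touching
#' objects. For each labelled object it reports the surface area, the
#' perimeter (boundary pixel count: object pixels with a 4-neighbour outside
#' the object) and the centroid in 0-based pixel coordinates.
#'
#' @param foreground logical matrix from [binarize()].
#' @param params a [segmentation_params()] object.
#' @return list with `labels` (integer matrix, 0 = background) and `objects`
#'   (`data.frame`: `label`, `area`, `perimeter`, `centroid_x`, `centroid_y`).
#' @export
label_objects <- function(foreground, params = segmentation_params()) {
  empty <- data.frame(label = integer(), area = numeric(), perimeter = numeric(),
                      centroid_x = numeric(), centroid_y = numeric())
  if (!any(foreground))
    return(list(labels = matrix(0L, nrow(foreground), ncol(foreground)),
                objects = empty))
  dm <- EBImage::distmap(foreground * 1)
  labels <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                               ext = params$watershed_extension)
  labels <- matrix(as.integer(labels), nrow(foreground), ncol(foreground))
  ids <- sort(unique(labels[labels > 0L]))
  bnd <- boundary_mask(labels)
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  area <- as.numeric(table(factor(lab, levels = ids)))
  perim <- as.numeric(table(factor(labels[bnd], levels = ids)))
  cx <- tapply(idx[, 2] - 1, factor(lab, levels = ids), mean)
  cy <- tapply(idx[, 1] - 1, factor(lab, levels = ids), mean)
  list(labels = labels,
       objects = data.frame(label = ids, area = area, perimeter = perim,
                            centroid_x = as.numeric(cx),
                            centroid_y = as.numeric(cy)))
}

#' Remove noise objects
#'
#' An object is noise if its surface area or perimeter is below `N`, or its
#' area/perimeter ratio is below `ratio_min`. `N` is `n_small` when the
#' previous-day noon area is at most `area_switch`, else `n_large`.
#'
#' @param objects object table from [label_objects()].
#' @param prev_area previous-day noon rosette area (px, >= 0).
#' @param params a [segmentation_params()] object.
#' @return list with `kept` and `removed` object tables; `removed` gains a
#'   `reason` column.
#' @export
prune_noise <- function(objects, prev_area, params = segmentation_params()) {
  if (prev_area < 0) stop("prev_area must be nonnegative")
  N <- if (prev_area <= params$area_switch) params$n_small else params$n_large
  small_area <- objects$area < N
  small_perim <- objects$perimeter < N
  thin <- objects$area / objects$perimeter < params$ratio_min
  drop <- small_area | small_perim | thin
  removed <- objects[drop, , drop = FALSE]
  if (nrow(removed) > 0) {
    removed$reason <- apply(cbind(small_area, small_perim, thin)[drop, , drop = FALSE],
                            1, function(f)
      paste(c("area<N", "perimeter<N", "ratio<min")[f], collapse = ";"))
  } else removed$reason <- character(0)
  list(kept = objects[!drop, , drop = FALSE], removed = removed, N = N)
}

#' Merge kept objects into one rosette and measure it
#'
#' Combines the kept objects into a single mask, then measures the rosette:
#' surface area (pixel count), centroid (mean of 0-based pixel coordinates)
#' and radius, the maximum Euclidean distance from the centroid to a mask
#' boundary pixel centre plus `radius_pad`. An empty kept set yields area 0,
#' radius 0.
#'
#' @param labels label matrix from [label_objects()].
#' @param kept kept object table from [prune_noise()].
#' @param params a [segmentation_params()] object.
#' @param threshold threshold recorded in the result (bookkeeping only).
#' @return a `detection_result` list: `mask`, `area`, `radius`, `centroid`,
#'   `threshold`.
#' @export
merge_and_measure <- function(labels, kept, params = segmentation_params(),
                              threshold = NA_real_) {
  mask <- matrix(labels %in% kept$label & labels > 0L, nrow(labels), ncol(labels))
  area <- sum(mask)
  if (area == 0L) {
    return(structure(list(mask = mask, area = 0, radius = 0,
                          centroid = c(NA_real_, NA_real_),
                          threshold = threshold),
                     class = "detection_result"))
  }
  idx <- which(mask, arr.ind = TRUE)
  cx <- mean(idx[, 2] - 1); cy <- mean(idx[, 1] - 1)
  bnd <- boundary_mask(mask * 1L)
  bidx <- which(bnd, arr.ind = TRUE)
  d <- sqrt((bidx[, 2] - 1 - cx)^2 + (bidx[, 1] - 1 - cy)^2)
  structure(list(mask = mask, area = as.numeric(area),
                 radius = max(d) + params$radius_pad,
                 centroid = c(x = cx, y = cy), threshold = threshold),
            class = "detection_result")
}

#' Segment one filtered frame end to end
#'
#' Convenience wrapper: [binarize()], [label_objects()], [prune_noise()],
#' [merge_and_measure()].
#'
#' @param F filtered intensity matrix.
#' @param T scalar background threshold.
#' @param prev_area previous-day noon area anchoring the noise filter.
#' @param params a [segmentation_params()] object.
#' @return a `detection_result` with the candidate-object tables attached as
#'   `objects` (all candidates) and `removed`.
#' @export
segment_frame <- function(F, T, prev_area, params = segmentation_params()) {
  lab <- label_objects(binarize(F, T), params)
  pr <- prune_noise(lab$objects, prev_area, params)
  res <- merge_and_measure(lab$labels, pr$kept, params, threshold = T)
  res$objects <- lab$objects
  res$removed <- pr$removed
  res
}
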