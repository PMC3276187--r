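# Normalization of growth curves onto the relative developmental timescale.
#
# Plants are staged by leaf emergence (Boyes-style): T1.04 is the beginning
# of the day on which the fourth true leaf reached ~10 px, T1.10 the end of
# the day on which the tenth did. The window [T1.04, T1.10] is mapped
# linearly onto [0, 1], removing developmental heterogeneity so growth can be
# compared across plants at the same stage.

#' Stage annotation for one plant
#'
#' @param plant_id plant identifier.
#' @param t104,t110 `POSIXct` (or numeric) times of stages 1.04 and 1.10;
#'   `t104` must precede `t110`.
#' @return a `stage_annotation` list.
#' @export
stage_annotation <- function(plant_id, t104, t110) {
  if (!(as.numeric(t110) > as.numeric(t104)))
    stop("T1.10 must be after T1.04 for plant ", plant_id)
  structure(list(plant_id = plant_id, t104 = t104, t110 = t110),
            class = "stage_annotation")
}

#' Read stage annotations from CSV
#'
#' @param path CSV with columns `plant_id`, `t_104`, `t_110` (ISO timestamps).
#' @param tz time zone used when parsing.
#' @return named list of [stage_annotation()] objects.
#' @export
read_stage_annotations <- function(path, tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "t_104", "t_110")
  if (!all(need %in% names(df)))
    stop("stage annotation CSV must have columns: ", paste(need, collapse = ", "))
  unstaged <- is.na(df$t_104) | is.na(df$t_110)
  if (any(unstaged)) {
    message("dropping ", sum(unstaged), " plant(s) without complete stage times")
    df <- df[!unstaged, , drop = FALSE]
  }
  ann <- lapply(seq_len(nrow(df)), function(i)
    stage_annotation(df$plant_id[i],
                     as.POSIXct(df$t_104[i], tz = tz),
                     as.POSIXct(df$t_110[i], tz = tz)))
  names(ann) <- df$plant_id
  ann
}

#' Relative developmental time
#'
#' `(t - T1.04) / (T1.10 - T1.04)`: 0 at stage 1.04, 1 at stage 1.10. Values
#' outside \[0, 1\] indicate frames outside the stage window and are excluded
#' downstream.
#'
#' @param t time (`POSIXct` or numeric), vectorized.
#' @param ann a [stage_annotation()].
#' @return numeric relative time.
#' @export
relative_time <- function(t, ann) {
  t0 <- as.numeric(ann$t104); t1 <- as.numeric(ann$t110)
  if (!(t1 > t0)) stop("T1.10 must be after T1.04")
  (as.numeric(t) - t0) / (t1 - t0)
}

#' Fit a developmental growth curve for one plant
#'
#' Fits a cubic smoothing spline (smoothing chosen by generalized
#' cross-validation) to one trait's noon values against relative time within
#' the stage window, and evaluates it on a uniform grid over \[0, 1\]. Grid
#' points outside the observed data range are left `NA` (no extrapolation).
#'
#' @param times observation times (`POSIXct` or numeric).
#' @param values trait values at `times`.
#' @param ann a [stage_annotation()] for the plant.
#' @param grid_n grid size (default 101 points, 0 to 1 inclusive).
#' @param method `"smooth"` (default, GCV smoothing spline) or `"interp"`
#'   (natural interpolating spline).
#' @return a `relative_curve` list: `plant_id`, `grid`, `values`, `n_points`.
#' @export
fit_growth_curve <- function(times, values, ann, grid_n = 101,
                             method = c("smooth", "interp")) {
  method <- match.arg(method)
  stopifnot(length(times) == length(values))
  rt <- relative_time(times, ann)
  keep <- rt >= 0 & rt <= 1 & is.finite(values)
  rt <- rt[keep]; y <- values[keep]
  if (length(unique(rt)) < 4L)
    stop("plant ", ann$plant_id, ": need >= 4 noon points inside the stage window")
  grid <- seq(0, 1, length.out = grid_n)
  fitted <- rep(NA_real_, grid_n)
  inside <- grid >= min(rt) - 1e-9 & grid <= max(rt) + 1e-9
  if (method == "smooth") {
    fit <- stats::smooth.spline(rt, y, cv = FALSE)
    fitted[inside] <- stats::predict(fit, grid[inside])$y
  } else {
    fitted[inside] <- stats::spline(rt, y, xout = grid[inside],
                                    method = "natural")$y
  }
  structure(list(plant_id = ann$plant_id, grid = grid, values = fitted,
                 n_points = length(rt)),
            class = "relative_curve")
}

#' Assemble the plants-by-grid phenotype table
#'
#' Joins per-plant relative curves of one trait with genotype and environment
#' metadata into a wide table, one row per plant and one column per grid
#' point (`g000` ... `g<grid_n-1>`).
#'
#' @param curves list of `relative_curve` objects (same grid).
#' @param metadata `data.frame` with columns `plant_id`, `accession`,
#'   `environment`; must cover every plant in `curves`.
#' @param trait trait name recorded in the table.
#' @return `data.frame`: `plant_id`, `accession`, `environment`, `trait`,
#'   then the grid columns.
#' @export
assemble_phenotype_table <- function(curves, metadata, trait = "RA") {
  if (length(curves) == 0L) stop("no curves supplied")
  gn <- length(curves[[1]]$grid)
  for (cv in curves) {
    if (length(cv$grid) != gn) stop("curves have inconsistent grids")
    if (!cv$plant_id %in% metadata$plant_id)
      stop("no metadata for plant ", cv$plant_id)
  }
  gcols <- sprintf("g%03d", seq_len(gn) - 1L)
  vals <- do.call(rbind, lapply(curves, `[[`, "values"))
  colnames(vals) <- gcols
  ids <- vapply(curves, `[[`, character(1), "plant_id")
  meta <- metadata[match(ids, metadata$plant_id), c("plant_id", "accession", "environment")]
  out <- cbind(meta, trait = trait, as.data.frame(vals))
  rownames(out) <- NULL
  out
}

#' Write / read a phenotype table
#'
#' CSV round trip for [assemble_phenotype_table()] output, lossless to full
#' double precision.
#'
#' @param table phenotype `data.frame`.
#' @param path CSV path.
#' @return `path` invisibly / the table.
#' @export
write_phenotype_table <- function(table, path) {
  gcols <- grep("^g\\d+$", names(table), value = TRUE)
  tab <- table
  for (g in gcols) tab[[g]] <- sprintf("%.17g", tab[[g]])
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_phenotype_table
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  gcols <- grep("^g\\d+$", names(df), value = TRUE)
  for (g in gcols) df[[g]] <- suppressWarnings(as.numeric(df[[g]]))
  df
}
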