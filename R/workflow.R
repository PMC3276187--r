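# Reproducible multi-stage workflow: config, manifests, stage skipping.
#
# Canonical stage order: simulate -> preprocess -> detect -> traits ->
# normalize -> genetics. Every tunable lives in a sectioned key-value config
# whose defaults reproduce the calibrated pipeline constants exactly; a
# manifest records config hashes and input hashes per stage so unchanged
# stages are skipped on re-runs.

PIPELINE_STAGES <- c("simulate", "preprocess", "detect", "traits",
                     "normalize", "genetics")

#' Default run configuration
#'
#' Nested list of all pipeline tunables, by section: `io`, `filter`,
#' `threshold`, `segmentation`, `traits`, `devtime`, `genetics`, `simulate`,
#' `run`. Defaults equal the calibrated model constants.
#'
#' @return nested named list.
#' @export
default_run_config <- function() {
  list(
    io = list(image_dir = "", coords = "", cutoff = "auto",
              window_start = "", window_end = "", season = "spring",
              tz = "UTC"),
    filter = list(offset = 0.4, blue_weight_base = 0.35,
                  reference_area = 50000, rb_weight_red = 0.5),
    threshold = list(c1_spring = 0.335, c1_summer = 0.305,
                     c2_intraday = 0.470, c3_intraday = 0.00000146,
                     c1_noon = 0.12, c2_noon = 0.475, c3_noon = 0.00000130),
    segmentation = list(watershed_tolerance = 1, watershed_extension = 3,
                        n_small = 30, n_large = 60, area_switch = 20000,
                        ratio_min = 1.5, radius_pad = 0.5),
    traits = list(day_one_area = 1000, empty_day = "zero"),
    devtime = list(grid_n = 101, spline = "smooth"),
    genetics = list(traits = "RA,CA,compactness"),
    simulate = list(rows = 3, cols = 3, pot_px = 240, n_days = 5,
                    frame_interval_min = 84, n_geno = 3, n_rep = 3,
                    h2 = 0.6, sd_total = 0.15, season = "spring",
                    format = "png"),
    run = list(seed = 1)
  )
}

#' Read a sectioned key-value config file
#'
#' Plain-text format: `[section]` headers and `key = value` lines; `#`
#' comments and blank lines ignored. Unknown sections or keys are rejected;
#' values are coerced to the type of the corresponding default.
#'
#' @param path config file path.
#' @param defaults reference config (default [default_run_config()]).
#' @return nested named list, defaults overridden by the file.
#' @export
read_run_config <- function(path, defaults = default_run_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- defaults
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% names(cfg)) stop("unknown config section [", section, "]")
    } else if (grepl("=", ln)) {
      if (is.null(section)) stop("key outside any section: ", ln)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      if (!key %in% names(cfg[[section]]))
        stop("unknown config key ", section, ".", key)
      ref <- defaults[[section]][[key]]
      cfg[[section]][[key]] <- if (is.numeric(ref) && val != "auto")
        as.numeric(val) else val
    } else stop("cannot parse config line: ", ln)
  }
  cfg
}

#' Write a config to file
#'
#' @param cfg nested config list.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  out <- character()
  for (s in names(cfg)) {
    out <- c(out, paste0("[", s, "]"))
    for (k in names(cfg[[s]]))
      out <- c(out, paste(k, "=", format(cfg[[s]][[k]], scientific = FALSE)))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

config_params <- function(cfg) {
  list(fparams = filter_params(offset = cfg$filter$offset,
                               blue_weight_base = cfg$filter$blue_weight_base,
                               reference_area = cfg$filter$reference_area,
                               rb_weights = c(cfg$filter$rb_weight_red,
                                              1 - cfg$filter$rb_weight_red)),
       tparams = do.call(threshold_params, cfg$threshold),
       sparams = do.call(segmentation_params, cfg$segmentation))
}

md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(obj), collapse = ""), f)
  unname(tools::md5sum(f))
}

stage_hash <- function(cfg, sections, input_files) {
  files <- sort(unique(as.character(unlist(lapply(input_files, Sys.glob)))))
  md5_of(list(cfg = cfg[sections], seed = cfg$run$seed,
              inputs = unname(tools::md5sum(files))))
}

read_manifest <- function(out_dir) {
  p <- file.path(out_dir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p) else list(stages = list())
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

# stage definitions: config sections and input/output files relative to out_dir
stage_spec_tbl <- function(out_dir) list(
  simulate = list(sections = c("simulate"),
                  inputs = character(),
                  outputs = file.path(out_dir, "simulate",
                                      c("coords.csv", "stages.csv",
                                        "genotypes.csv", "truth_areas.csv"))),
  preprocess = list(sections = c("io"),
                    inputs = file.path(out_dir, "simulate",
                                       c("coords.csv", "truth_areas.csv")),
                    outputs = file.path(out_dir, "preprocess",
                                        "stack_manifest.csv")),
  detect = list(sections = c("io", "filter", "threshold", "segmentation", "traits"),
                inputs = file.path(out_dir, "preprocess", "stack_manifest.csv"),
                outputs = file.path(out_dir, "detect", "daily_areas.csv")),
  traits = list(sections = c("traits"),
                inputs = file.path(out_dir, c("detect/daily_areas.csv",
                                              "detect/*_traits.csv",
                                              "simulate/genotypes.csv")),
                outputs = file.path(out_dir, "traits", "traits.csv")),
  normalize = list(sections = c("devtime"),
                   inputs = file.path(out_dir, c("traits/traits.csv",
                                                 "simulate/stages.csv",
                                                 "simulate/genotypes.csv")),
                   outputs = file.path(out_dir, "normalize", "phenotypes.csv")),
  genetics = list(sections = c("genetics"),
                  inputs = file.path(out_dir, "normalize", "phenotypes.csv"),
                  outputs = file.path(out_dir, "genetics", "h2_RA.csv"))
)

run_stage_simulate <- function(cfg, out_dir) {
  sc <- cfg$simulate
  spec <- scene_spec(rows = sc$rows, cols = sc$cols, pot_px = sc$pot_px,
                     n_days = sc$n_days,
                     frame_interval_min = sc$frame_interval_min,
                     season = sc$season)
  if (sc$n_geno * sc$n_rep > sc$rows * sc$cols)
    stop("simulate: population larger than the pot grid")
  gm <- simulate_phenotypes(sc$n_geno, sc$n_rep, sc$h2, seed = cfg$run$seed,
                            sd_total = sc$sd_total)
  render_series(spec, gm, seed = cfg$run$seed,
                out_dir = file.path(out_dir, "simulate"),
                format = sc$format, keep_masks = FALSE)
  invisible(NULL)
}

run_stage_preprocess <- function(cfg, out_dir) {
  io <- cfg$io
  image_dir <- if (nzchar(io$image_dir)) io$image_dir
               else file.path(out_dir, "simulate", "images")
  coords <- if (nzchar(io$coords)) io$coords
            else file.path(out_dir, "simulate", "coords.csv")
  if (!dir.exists(image_dir)) stop("preprocess: missing input ", image_dir)
  maps <- read_coordinate_maps(coords, tz = io$tz)
  ws <- if (nzchar(io$window_start)) as.POSIXct(io$window_start, tz = io$tz)
        else as.POSIXct("1970-01-01", tz = "UTC")
  we <- if (nzchar(io$window_end)) as.POSIXct(io$window_end, tz = io$tz)
        else as.POSIXct("2100-01-01", tz = "UTC")
  index <- build_flat_index(image_dir, ws, we, tz = io$tz)
  mi <- vapply(file.path(image_dir, index$filename),
               function(p) mean_filtered_intensity(read_rgb(p)), numeric(1))
  cutoff <- if (identical(io$cutoff, "auto")) suggest_cutoff(mi)
            else as.numeric(io$cutoff)
  labels <- classify_day_night(mi, cutoff)
  stacks <- crop_to_stacks(image_dir, index, maps, labels,
                           season = io$season)
  sdir <- file.path(out_dir, "preprocess", "stacks")
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (st in stacks) {
    pdir <- file.path(sdir, st$pot_id)
    dir.create(pdir, showWarnings = FALSE)
    for (fr in st$frames) {
      fn <- paste0(format(fr$timestamp, "%Y%m%d_%H%M%S"), ".png")
      png::writePNG(fr$pixels, file.path(pdir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        pot_id = st$pot_id, accession = st$accession, season = st$season,
        filename = file.path(st$pot_id, fn),
        timestamp = format(fr$timestamp, "%Y-%m-%d %H:%M:%S"),
        day_index = fr$day_index, within_day = fr$within_day)
    }
  }
  man <- do.call(rbind, rows)
  utils::write.csv(man, file.path(out_dir, "preprocess", "stack_manifest.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

load_stacks <- function(out_dir, tz = "UTC") {
  mpath <- file.path(out_dir, "preprocess", "stack_manifest.csv")
  if (!file.exists(mpath)) stop("detect: missing input ", mpath)
  man <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  sdir <- file.path(out_dir, "preprocess", "stacks")
  lapply(split(man, man$pot_id), function(m) {
    m <- m[order(m$timestamp), , drop = FALSE]
    frames <- lapply(seq_len(nrow(m)), function(i)
      list(timestamp = as.POSIXct(m$timestamp[i], tz = tz),
           pixels = read_rgb(file.path(sdir, m$filename[i])),
           day_index = m$day_index[i], within_day = m$within_day[i]))
    structure(list(pot_id = m$pot_id[1], accession = m$accession[1],
                   season = m$season[1], frames = frames),
              class = "plant_stack")
  })
}

run_stage_detect <- function(cfg, out_dir) {
  stacks <- load_stacks(out_dir, tz = cfg$io$tz)
  pars <- config_params(cfg)
  ddir <- file.path(out_dir, "detect")
  dir.create(ddir, recursive = TRUE, showWarnings = FALSE)
  daily <- list()
  for (st in stacks) {
    rs <- run_stack(st, day_one_area = cfg$traits$day_one_area,
                    empty_day = cfg$traits$empty_day,
                    fparams = pars$fparams, tparams = pars$tparams,
                    sparams = pars$sparams)
    write_trait_csv(rs$traits, file.path(ddir, paste0(st$pot_id, "_traits.csv")))
    daily[[st$pot_id]] <- cbind(pot_id = st$pot_id, rs$daily)
  }
  utils::write.csv(do.call(rbind, c(daily, list(make.row.names = FALSE))),
                   file.path(ddir, "daily_areas.csv"), row.names = FALSE)
  invisible(NULL)
}

run_stage_traits <- function(cfg, out_dir) {
  ddir <- file.path(out_dir, "detect")
  files <- list.files(ddir, pattern = "_traits\\.csv$", full.names = TRUE)
  if (length(files) == 0L) stop("traits: no detection outputs under ", ddir)
  tr <- do.call(rbind, lapply(files, utils::read.csv, stringsAsFactors = FALSE))
  gpath <- file.path(out_dir, "simulate", "genotypes.csv")
  if (file.exists(gpath)) {
    gen <- utils::read.csv(gpath, stringsAsFactors = FALSE)
    tr$plant_id <- gen$plant_id[match(tr$pot_id, gen$pot_id)]
    tr$environment <- gen$environment[match(tr$pot_id, gen$pot_id)]
  } else {
    tr$plant_id <- tr$pot_id
    tr$environment <- cfg$io$season
  }
  tdir <- file.path(out_dir, "traits")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tr, file.path(tdir, "traits.csv"), row.names = FALSE)
  invisible(NULL)
}

run_stage_normalize <- function(cfg, out_dir) {
  tr <- utils::read.csv(file.path(out_dir, "traits", "traits.csv"),
                        stringsAsFactors = FALSE)
  tr$timestamp <- as.POSIXct(tr$timestamp, tz = cfg$io$tz)
  ann <- read_stage_annotations(file.path(out_dir, "simulate", "stages.csv"),
                                tz = cfg$io$tz)
  gen <- utils::read.csv(file.path(out_dir, "simulate", "genotypes.csv"),
                         stringsAsFactors = FALSE)
  noon <- tr[tr$is_noon %in% c(TRUE, "TRUE"), , drop = FALSE]
  tabs <- list()
  for (trait in c("RA", "CA", "compactness")) {
    col <- c(RA = "RA_px", CA = "CA_px", compactness = "compactness")[[trait]]
    curves <- list()
    for (pid in unique(noon$plant_id)) {
      a <- ann[[pid]]
      if (is.null(a) || is.na(a$t104) || is.na(a$t110)) next
      rows <- noon[noon$plant_id == pid, ]
      cv <- tryCatch(fit_growth_curve(rows$timestamp, rows[[col]], a,
                                      grid_n = cfg$devtime$grid_n,
                                      method = cfg$devtime$spline),
                     error = function(e) NULL)
      if (!is.null(cv)) curves[[pid]] <- cv
    }
    if (length(curves) > 0)
      tabs[[trait]] <- assemble_phenotype_table(curves, gen, trait = trait)
  }
  if (length(tabs) == 0L) stop("normalize: no plant had enough staged noon points")
  ndir <- file.path(out_dir, "normalize")
  dir.create(ndir, recursive = TRUE, showWarnings = FALSE)
  write_phenotype_table(do.call(rbind, c(tabs, list(make.row.names = FALSE))),
                        file.path(ndir, "phenotypes.csv"))
  invisible(NULL)
}

run_stage_genetics <- function(cfg, out_dir) {
  tab <- read_phenotype_table(file.path(out_dir, "normalize", "phenotypes.csv"))
  gdir <- file.path(out_dir, "genetics")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  traits <- strsplit(cfg$genetics$traits, ",")[[1]]
  for (trait in intersect(traits, unique(tab$trait))) {
    h2 <- tryCatch(h2_trajectory(tab, trait), error = function(e) NULL)
    if (!is.null(h2))
      utils::write.csv(h2$trajectory,
                       file.path(gdir, paste0("h2_", trait, ".csv")),
                       row.names = FALSE)
  }
  if (all(c("RA", "CA") %in% tab$trait)) {
    rc <- trait_correlation(tab, "RA", "CA")
    utils::write.csv(rc$by_point, file.path(gdir, "correlation_RA_CA.csv"),
                     row.names = FALSE)
  }
  if (length(unique(tab$environment)) >= 2) {
    long <- phenotypes_to_long(tab, stages = c(1/6, 2/6, 3/6))
    for (trait in intersect(traits, unique(long$trait))) {
      vp <- variance_partition(long[long$trait == trait, ])
      utils::write.csv(vp, file.path(gdir, paste0("anova_", trait, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(NULL)
}

#' Reshape a phenotype table to long form at selected stages
#'
#' Extracts the grid points closest to the requested relative times as
#' categorical development stages, yielding the long table the
#' variance-partition model consumes.
#'
#' @param tab phenotype table (possibly several environments row-bound).
#' @param stages relative times to extract (default 1/6, 2/6, 3/6, i.e.
#'   stages 1.05, 1.06 and 1.07 under the linear leaf-stage mapping).
#' @return `data.frame`: `value`, `environment`, `development`, `genotype`,
#'   `trait`, `plant_id`.
#' @export
phenotypes_to_long <- function(tab, stages = c(1/6, 2/6, 3/6)) {
  gcols <- grep("^g\\d+$", names(tab), value = TRUE)
  grid <- seq(0, 1, length.out = length(gcols))
  rows <- list()
  for (s in stages) {
    g <- gcols[which.min(abs(grid - s))]
    rows[[length(rows) + 1L]] <- data.frame(
      value = tab[[g]], environment = tab$environment,
      development = sprintf("stage_%.3f", s), genotype = tab$accession,
      trait = tab$trait, plant_id = tab$plant_id)
  }
  out <- do.call(rbind, rows)
  out[is.finite(out$value), , drop = FALSE]
}

#' Run the pipeline
#'
#' Executes the requested stages in canonical order
#' (`simulate, preprocess, detect, traits, normalize, genetics`), recording a
#' manifest (per-stage config/input hashes, outputs, package version) under
#' `out_dir`. Re-runs skip stages whose hash is unchanged and whose outputs
#' exist, unless `force`.
#'
#' @param config nested config list (see [default_run_config()]).
#' @param out_dir working/output directory.
#' @param stages subset of the canonical stages to run.
#' @param force re-run even if up to date.
#' @return invisibly, a `data.frame` of `stage`, `action` (`ran`/`skipped`).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         stages = PIPELINE_STAGES, force = FALSE) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_manifest(out_dir)
  spec_tbl <- stage_spec_tbl(out_dir)
  runners <- list(simulate = run_stage_simulate, preprocess = run_stage_preprocess,
                  detect = run_stage_detect, traits = run_stage_traits,
                  normalize = run_stage_normalize, genetics = run_stage_genetics)
  status <- list()
  for (s in stages) {
    sp <- spec_tbl[[s]]
    h <- stage_hash(config, sp$sections, sp$inputs)
    prev <- manifest$stages[[s]]
    up_to_date <- !force && !is.null(prev) && identical(prev$hash, h) &&
      all(file.exists(unlist(sp$outputs)))
    if (up_to_date) {
      status[[s]] <- "skipped"
      next
    }
    runners[[s]](config, out_dir)
    # inputs may not have existed before the stage ran upstream; re-hash
    manifest$stages[[s]] <- list(hash = stage_hash(config, sp$sections, sp$inputs),
                                 outputs = unlist(sp$outputs),
                                 package_version = as.character(utils::packageVersion("rosettrack")),
                                 time = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
    write_manifest(manifest, out_dir)
    status[[s]] <- "ran"
  }
  invisible(data.frame(stage = names(status), action = unlist(status),
                       row.names = NULL))
}
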