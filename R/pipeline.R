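#' Run configuration for the end-to-end pipeline
#'
#' Assembles and validates the knobs of [run_pipeline()]. Configurations
#' can also be read from a flat `key = value` text file with
#' [read_run_config()].
#'
#' @param dem Path to the input DEM (`.asc`); `NULL` to simulate one.
#' @param polygons Path to the coral polygon GeoJSON; `NULL` to simulate.
#' @param codebook Path to the species codebook CSV; `NULL` for
#'   [default_codebook()].
#' @param out_dir Output directory (created if missing).
#' @param wavelet_order,levels Daubechies order and decomposition depth.
#' @param evaluation_length Ra window length in meters.
#' @param window_mode `"sliding"` or `"tiled"` Ra windows.
#' @param subsample Cell cap for the reconstruction rank test.
#' @param target_area Optional standardized analysis area in m^2
#'   (`NA` = no crop).
#' @param seed Master seed for simulation, subsampling and tie-breaks.
#' @return A `run_config` list.
#' @export
run_config <- function(dem = NULL, polygons = NULL, codebook = NULL,
                       out_dir = ".", wavelet_order = 4L, levels = 4L,
                       evaluation_length = 0.05,
                       window_mode = c("sliding", "tiled"),
                       subsample = 100000L, target_area = NA_real_,
                       seed = 1L) {
  window_mode <- match.arg(window_mode)
  structure(list(dem = dem, polygons = polygons, codebook = codebook,
                 out_dir = out_dir,
                 wavelet_order = as.integer(wavelet_order),
                 levels = as.integer(levels),
                 evaluation_length = as.numeric(evaluation_length),
                 window_mode = window_mode,
                 subsample = as.integer(subsample),
                 target_area = as.numeric(target_area),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a flat key = value configuration file
#'
#' Lines are `key = value` (or `key: value`); `#` starts a comment. Keys
#' match the arguments of [run_config()].
#'
#' @param path Config file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  args <- stats::setNames(lapply(kv, function(p) {
    v <- paste(p[-1], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }), vapply(kv, `[[`, character(1), 1L))
  do.call(run_config, args)
}

.log_info <- function(...) message("[reefwave] ", ...)

#' Run the full multiscale complexity pipeline
#'
#' Wires all stages end to end: read (or simulate) the DEM, decompose it
#' row-wise into local and global surfaces, verify reconstruction
#' equivalence, derive the DLC and DGC Ra rasters, rasterize the coral
#' polygons, extract per-group complexity samples, run the statistical
#' battery (Kruskal-Wallis across groups with Dunn's post-hoc, and the
#' log-cover regression over groups), and write every artifact plus a
#' provenance record to `out_dir`:
#' `local.asc`, `global.asc`, `dlc_ra.asc`, `dgc_ra.asc`, `cover.asc`,
#' `extractions.csv` (`group,pixel_row,pixel_col,dlc,dgc`), `report.json`,
#' `provenance.json`.
#'
#' @param config A [run_config()] or path to a config file.
#' @return Invisibly, a list with the in-memory stages (`dem`, `comps`,
#'   `stack`, `reports`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  dem <- stage("dem_io", {
    if (is.null(config$dem)) {
      .log_info("no DEM given; simulating a synthetic reef (seed ",
                config$seed, ")")
      generate_reef_dem(synthetic_reef_spec(seed = config$seed))
    } else {
      .log_info("reading DEM ", config$dem)
      read_dem(config$dem)
    }
  })
  cb <- stage("codebook", {
    if (is.null(config$codebook)) default_codebook()
    else read_codebook(config$codebook)
  })
  layer <- stage("polygons", {
    if (is.null(config$polygons)) {
      .log_info("no polygon layer given; simulating coral cover")
      generate_cover_layer(synthetic_cover_spec(seed = config$seed), dem)
    } else read_polygons(config$polygons)
  })

  spec <- wavelet_spec(order = config$wavelet_order, J = config$levels)
  comps <- stage("decomposition", decompose_dem(dem, spec))
  .log_info("decomposed: ", sum(!comps$local$mask), " cells processed, ",
            comps$skipped_cells, " skipped")
  recon <- stage("decomposition",
                 verify_reconstruction(dem, comps, config$subsample,
                                       config$seed))
  .log_info(sprintf("reconstruction: max |err| = %.3g m, p = %.3g (%s)",
                    recon$extras$max_abs_error, recon$p_value,
                    if (recon$extras$equivalent) "equivalent" else
                      "NOT equivalent"))

  cfg_ra <- ra_config(config$evaluation_length, dem$pixel_size)
  dlc <- stage("roughness", ra_raster(comps$local, "DLC", cfg_ra,
                                      mode = config$window_mode))
  dgc <- stage("roughness", ra_raster(comps$global, "DGC", cfg_ra,
                                      mode = config$window_mode))
  cover <- stage("overlay", rasterize_polygons(layer, cb, dem))
  stack <- stage("overlay", complexity_stack(dlc, dgc, cover))
  if (!is.na(config$target_area))
    stack <- stage("overlay",
                   crop_to_area(stack, config$target_area, config$seed))

  groups <- intersect(agrra_groups(), unique(cb$group_name))
  extr <- stage("overlay", {
    rows <- lapply(groups, function(gn) {
      codes <- cb$raster_code[cb$group_name == gn]
      sel <- which(stack$cover$values %in% codes &
                     !stack$dlc$mask & !stack$dgc$mask, arr.ind = TRUE)
      if (nrow(sel) == 0L) return(NULL)
      data.frame(group = gn, pixel_row = sel[, 1], pixel_col = sel[, 2],
                 dlc = stack$dlc$values[sel], dgc = stack$dgc$values[sel],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  reports <- list(reconstruction = recon)
  if (!is.null(extr) && length(unique(extr$group)) >= 2L) {
    samples <- split(extr$dlc, extr$group)
    reports$kruskal_dlc <- stage("stats", kruskal_wallis(samples))
    if (reports$kruskal_dlc$p_value < 0.05 && length(samples) >= 3L)
      reports$dunn_dlc <- stage("stats", dunn_posthoc(samples))
    areas <- vapply(names(samples), function(gn)
      cover_area(stack$cover, gn), numeric(1))
    med_dlc <- vapply(samples, stats::median, numeric(1))
    if (length(areas) >= 3L && all(areas > 0))
      reports$regression_dlc_cover <- stage("stats",
        linear_regression(areas, med_dlc, log_x = TRUE))
  }

  out <- function(f) file.path(config$out_dir, f)
  stage("write", {
    write_raster(comps$local, out("local.asc"))
    write_raster(comps$global, out("global.asc"))
    write_raster(stack$dlc, out("dlc_ra.asc"))
    write_raster(stack$dgc, out("dgc_ra.asc"))
    write_raster(stack$cover, out("cover.asc"))
    if (!is.null(extr))
      utils::write.csv(extr, out("extractions.csv"), row.names = FALSE)
    jsonlite::write_json(.report_json(reports), out("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    prov <- list(
      package = "reefwave",
      version = as.character(utils::packageVersion("reefwave")),
      config = unclass(config),
      inputs = .input_checksums(config),
      timestamp = NULL)
    jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
  })
  .log_info("artifacts written to ", config$out_dir)
  invisible(list(dem = dem, comps = comps, stack = stack, reports = reports,
                 extractions = extr, out_dir = config$out_dir))
}

.input_checksums <- function(config) {
  paths <- Filter(Negate(is.null),
                  config[c("dem", "polygons", "codebook")])
  paths <- Filter(function(p) is.character(p) && file.exists(p), paths)
  if (!length(paths)) return(list())
  lapply(paths, function(p) unname(tools::md5sum(p)))
}

.report_json <- function(reports) {
  lapply(reports, function(r) {
    if (inherits(r, "stat_report")) {
      ex <- r$extras
      list(test = r$test_name, statistic = r$statistic, p_value = r$p_value,
           groups = r$group_labels, extras = ex)
    } else if (inherits(r, "regression_result")) {
      unclass(r)
    } else r
  })
}

.parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      v <- args[i + 1L]
      num <- suppressWarnings(as.numeric(v))
      out[[key]] <- if (!is.na(num)) num else v
      i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `decompose`, `complexity`,
#' `overlay`, `stats` and `run` (the all-in-one pipeline). Invoke from a
#' shell via the wrapper script `system.file("cli", "reefwave.R",
#' package = "reefwave")`, e.g.
#' `Rscript <wrapper> run --out-dir out --seed 1`. Returns (and, from the
#' wrapper, exits with) 0 on success, 1 on any stage error.
#'
#' @param args Character vector of arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
reefwave_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: reefwave <simulate|decompose|complexity|overlay|stats|run> [--key value ...]",
    "  simulate    --out dem.asc [--cover cover.geojson] [--codebook cb.csv] [--seed 1]",
    "  decompose   --dem in.asc [--wavelet 4] [--levels 4] --out-local l.asc --out-global g.asc [--report r.json]",
    "  complexity  --component l.asc --layer DLC [--eval-length 0.05] --out ra.asc",
    "  overlay     --dlc dlc.asc --dgc dgc.asc --polygons c.geojson --codebook cb.csv --out-dir dir",
    "  stats       --input extractions.csv --value dlc --group group [--posthoc dunn] --out report.json",
    "  run         [--config file] [--dem in.asc] [--polygons c.geojson] [--codebook cb.csv] --out-dir dir [--seed 1]",
    sep = "\n")
  status <- tryCatch({
    if (length(args) == 0L) stop(usage, call. = FALSE)
    cmd <- args[1]
    opt <- .parse_cli_args(args[-1])
    switch(cmd,
      simulate = {
        seed <- as.integer(opt$seed %||% 1L)
        dem <- generate_reef_dem(synthetic_reef_spec(seed = seed))
        write_raster(dem, opt$out %||% stop("simulate needs --out"))
        if (!is.null(opt$cover)) {
          layer <- generate_cover_layer(synthetic_cover_spec(seed = seed), dem)
          write_polygons(layer, opt$cover)
        }
        if (!is.null(opt$codebook)) write_codebook(default_codebook(), opt$codebook)
      },
      decompose = {
        dem <- read_dem(opt$dem %||% stop("decompose needs --dem"))
        spec <- wavelet_spec(order = opt$wavelet %||% 4, J = opt$levels %||% 4)
        comps <- decompose_dem(dem, spec)
        write_raster(comps$local, opt$out_local %||% stop("need --out-local"))
        write_raster(comps$global, opt$out_global %||% stop("need --out-global"))
        if (!is.null(opt$report)) {
          rec <- verify_reconstruction(dem, comps,
                                       seed = as.integer(opt$seed %||% 1L))
          jsonlite::write_json(.report_json(list(reconstruction = rec)),
                               opt$report, auto_unbox = TRUE, digits = NA,
                               pretty = TRUE)
        }
      },
      complexity = {
        comp <- read_dem(opt$component %||% stop("complexity needs --component"))
        cfg <- ra_config(opt$eval_length %||% 0.05, comp$pixel_size)
        ra <- ra_raster(comp, opt$layer %||% "DLC", cfg)
        write_raster(ra, opt$out %||% stop("need --out"))
      },
      overlay = {
        dlc <- read_dem(opt$dlc %||% stop("overlay needs --dlc"))
        dgc <- read_dem(opt$dgc %||% stop("overlay needs --dgc"))
        dlc <- .new_raster(dlc$values, dlc$pixel_size, dlc$origin, dlc$crs_id,
                           dlc$mask, "complexity_raster",
                           list(layer = "DLC", evaluation_length = NA_real_))
        dgc <- .new_raster(dgc$values, dgc$pixel_size, dgc$origin, dgc$crs_id,
                           dgc$mask, "complexity_raster",
                           list(layer = "DGC", evaluation_length = NA_real_))
        cb <- read_codebook(opt$codebook %||% stop("need --codebook"))
        layer <- read_polygons(opt$polygons %||% stop("need --polygons"))
        cover <- rasterize_polygons(layer, cb, dlc)
        stack <- complexity_stack(dlc, dgc, cover)
        dir.create(opt$out_dir %||% stop("need --out-dir"),
                   recursive = TRUE, showWarnings = FALSE)
        write_raster(cover, file.path(opt$out_dir, "cover.asc"))
        rows <- do.call(rbind, lapply(unique(cb$group_name), function(gn) {
          codes <- cb$raster_code[cb$group_name == gn]
          sel <- which(cover$values %in% codes & !dlc$mask & !dgc$mask,
                       arr.ind = TRUE)
          if (nrow(sel) == 0L) return(NULL)
          data.frame(group = gn, pixel_row = sel[, 1], pixel_col = sel[, 2],
                     dlc = dlc$values[sel], dgc = dgc$values[sel])
        }))
        utils::write.csv(rows, file.path(opt$out_dir, "extractions.csv"),
                         row.names = FALSE)
      },
      stats = {
        df <- utils::read.csv(opt$input %||% stop("stats needs --input"))
        val <- opt$value %||% "dlc"
        grp <- opt$group %||% "group"
        samples <- split(df[[val]], df[[grp]])
        reports <- list(kruskal = kruskal_wallis(samples))
        if (identical(opt$posthoc, "dunn"))
          reports$dunn <- dunn_posthoc(samples)
        jsonlite::write_json(.report_json(reports),
                             opt$out %||% stop("need --out"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      run = {
        cfg <- if (!is.null(opt$config)) read_run_config(opt$config)
               else run_config()
        for (k in intersect(names(opt),
                            c("dem", "polygons", "codebook", "out_dir",
                              "wavelet_order", "levels", "evaluation_length",
                              "window_mode", "subsample", "target_area",
                              "seed")))
          cfg[[k]] <- opt[[k]]
        cfg$seed <- as.integer(cfg$seed)
        run_pipeline(cfg)
      },
      stop(usage, call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
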