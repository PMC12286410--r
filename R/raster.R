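#' Georeferenced elevation raster
#'
#' In-memory container for a single-band elevation grid in meters on a
#' projected (linear-unit) grid with square pixels. The grid is north-up:
#' row 1 is the northern edge, `origin` is the map coordinate of the
#' top-left corner, and pixel centers sit at
#' `x = origin[1] + (col - 0.5) * pixel_size`,
#' `y = origin[2] - (row - 0.5) * pixel_size`.
#'
#' @param values Numeric matrix of elevations (m). Non-finite cells are
#'   masked automatically.
#' @param pixel_size Pixel edge length in meters (> 0); pixels are square.
#' @param origin Length-2 numeric, map x/y of the top-left corner.
#' @param crs_id Opaque CRS identifier string (e.g. `"EPSG:32616"`); carried
#'   as metadata only.
#' @param mask Optional logical matrix, `TRUE` = invalid cell; merged with
#'   the non-finite cells of `values`.
#' @return An object of class `elevation_raster`.
#' @export
elevation_raster <- function(values, pixel_size, origin = c(0, 0), crs_id = "",
                             mask = NULL) {
  .new_raster(values, pixel_size, origin, crs_id, mask,
              class = "elevation_raster")
}

.new_raster <- function(values, pixel_size, origin, crs_id, mask, class,
                        extra = list()) {
  if (!is.matrix(values)) stop("values must be a matrix")
  storage.mode(values) <- "double"
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || !is.finite(pixel_size) ||
      pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("origin must be two finite map coordinates")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(values), ncol(values))
  if (!identical(dim(mask), dim(values)))
    stop("values and mask must have identical shape")
  mask <- mask | !is.finite(values)
  values[mask] <- NA_real_
  structure(c(list(values = values, mask = mask,
                   pixel_size = as.numeric(pixel_size),
                   origin = as.numeric(origin), crs_id = as.character(crs_id)),
              extra),
            class = c(class, "reef_raster"))
}

#' @export
print.reef_raster <- function(x, ...) {
  cat(sprintf("<%s> %d x %d, pixel %.4g m, origin (%.6g, %.6g)%s, %d masked\n",
              class(x)[1], nrow(x$values), ncol(x$values), x$pixel_size,
              x$origin[1], x$origin[2],
              if (nzchar(x$crs_id)) paste0(", ", x$crs_id) else "",
              sum(x$mask)))
  invisible(x)
}

#' Grid geometry of a raster
#'
#' @param r A `reef_raster` (elevation, complexity or cover raster).
#' @return A list with `nrow`, `ncol`, `pixel_size`, `origin`, `crs_id`.
#' @export
grid_geometry <- function(r) {
  list(nrow = nrow(r$values), ncol = ncol(r$values),
       pixel_size = r$pixel_size, origin = r$origin, crs_id = r$crs_id)
}

#' Check that two rasters are co-registered
#'
#' Same shape, pixel size and origin (to a 1e-6-pixel tolerance). The CRS
#' strings must match when both are non-empty.
#'
#' @param a,b `reef_raster` objects.
#' @return `TRUE` invisibly; raises an error otherwise.
#' @export
assert_coregistered <- function(a, b) {
  tol <- 1e-6 * a$pixel_size
  if (!identical(dim(a$values), dim(b$values)))
    stop("rasters are not co-registered: shapes differ")
  if (abs(a$pixel_size - b$pixel_size) > tol)
    stop("rasters are not co-registered: pixel sizes differ")
  if (any(abs(a$origin - b$origin) > tol))
    stop("rasters are not co-registered: origins differ")
  if (nzchar(a$crs_id) && nzchar(b$crs_id) && !identical(a$crs_id, b$crs_id))
    stop("rasters are not co-registered: CRS identifiers differ")
  invisible(TRUE)
}

.NODATA_DEFAULT <- -9999

#' Read a DEM from an ESRI ASCII grid
#'
#' Reads a single-band plain-text raster (`.asc`). Cells equal to the
#' header's `NODATA_value` and any non-finite cells are masked. If a sidecar
#' `<path>.prj` (or the path with extension replaced by `.prj`) exists, its
#' contents become the opaque `crs_id`; a CRS that looks geographic
#' (degree units) is rejected, since all lengths in the pipeline are metric.
#'
#' @param path Path to the `.asc` file.
#' @return An [elevation_raster()].
#' @export
read_dem <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- list()
  n_hdr <- 0L
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unreadable raster (no data rows): ", path)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) == 2L && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else {
      seek(con, pos)
      break
    }
    if (n_hdr > 10L) stop("unreadable raster header: ", path)
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr)))
    stop("unreadable raster: missing ncols/nrows header in ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  if (is.null(cs)) {
    # some writers emit dx/dy instead of cellsize; require square pixels
    if (is.null(hdr$dx) || is.null(hdr$dy))
      stop("unreadable raster: no cellsize in ", path)
    if (abs(hdr$dx - hdr$dy) > 0.01 * max(hdr$dx, hdr$dy))
      stop("non-square pixels (dx = ", hdr$dx, ", dy = ", hdr$dy,
           ") exceed the 1% tolerance")
    cs <- (hdr$dx + hdr$dy) / 2
  }
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2 else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2 else 0
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else .NODATA_DEFAULT
  vals <- scan(con, what = double(), n = nr * nc, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("unreadable raster: expected ", nr * nc, " cells, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- (m == nodata) | !is.finite(m)
  crs_id <- ""
  for (prj in c(paste0(path, ".prj"), sub("\\.[^.]+$", ".prj", path))) {
    if (file.exists(prj)) {
      crs_id <- paste(readLines(prj, warn = FALSE), collapse = " ")
      break
    }
  }
  if (grepl("GEOGCS|longlat|EPSG:4326|\\bdegree", crs_id, ignore.case = TRUE) &&
      !grepl("PROJCS", crs_id, ignore.case = TRUE))
    stop("geographic (degree-unit) CRS '", crs_id,
         "': a projected CRS with linear (meter) units is required")
  elevation_raster(m, pixel_size = cs, origin = c(xll, yll + nr * cs),
                   crs_id = crs_id, mask = mask)
}

#' Write a raster to an ESRI ASCII grid
#'
#' Writes an [elevation_raster()], [complexity_raster] or [cover_raster]
#' as a plain-text `.asc` file. Values round-trip bit-identically
#' (17 significant digits); masked cells are stored as the nodata sentinel
#' (-9999). A non-empty `crs_id` is written to a `<path>.prj` sidecar.
#'
#' @param raster The raster to write.
#' @param path Output path; its directory must exist.
#' @param nodata Sentinel for masked cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, nodata = .NODATA_DEFAULT) {
  if (!dir.exists(dirname(path)))
    stop("output directory does not exist: ", dirname(path))
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  num <- function(x) sprintf("%.17g", x)
  hdr <- c(paste("ncols", nc),
           paste("nrows", nr),
           paste("xllcorner", num(raster$origin[1])),
           paste("yllcorner", num(raster$origin[2] - nr * raster$pixel_size)),
           paste("cellsize", num(raster$pixel_size)),
           paste("NODATA_value", num(nodata)))
  v[raster$mask] <- nodata
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  if (nzchar(raster$crs_id)) writeLines(raster$crs_id, paste0(path, ".prj"))
  invisible(path)
}

#' Contiguous valid runs of a raster row
#'
#' Splits every row into maximal runs of consecutive unmasked cells and
#' returns the runs of at least `min_length` cells, the unit of work for the
#' row-wise wavelet decomposition. Shorter runs are counted as skipped.
#'
#' @param raster An [elevation_raster()] (or any `reef_raster`).
#' @param min_length Minimum run length in pixels (>= 2); the decomposition
#'   requires `2^J`.
#' @return A list of `row_segment` objects (fields `row`, `start_col`,
#'   `values`, 1-based indices), ordered by row then start column, with
#'   attributes `skipped_cells` and `skipped_runs` counting valid cells/runs
#'   left out for being shorter than `min_length`.
#' @export
extract_row_segments <- function(raster, min_length = 2L) {
  min_length <- as.integer(min_length)
  if (is.na(min_length) || min_length < 2L) stop("min_length must be >= 2")
  segs <- list()
  skipped_cells <- 0L
  skipped_runs <- 0L
  for (i in seq_len(nrow(raster$values))) {
    ok <- !raster$mask[i, ]
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      len <- r$lengths[k]
      if (len >= min_length) {
        segs[[length(segs) + 1L]] <- structure(
          list(row = i, start_col = starts[k],
               values = raster$values[i, starts[k]:ends[k]]),
          class = "row_segment")
      } else {
        skipped_cells <- skipped_cells + len
        skipped_runs <- skipped_runs + 1L
      }
    }
  }
  structure(segs, skipped_cells = skipped_cells, skipped_runs = skipped_runs)
}
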