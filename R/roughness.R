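#' Ra evaluation window configuration
#'
#' The roughness Ra of a profile is the arithmetic mean of the absolute
#' deviations of the height from the mean line over an evaluation length.
#' The evaluation length defaults to 0.05 m (5 cm), the minimum diameter of
#' a digitizable coral colony; on a 0.008 m grid that is a 6-pixel window
#' (round half away from zero).
#'
#' @param evaluation_length Window length in meters (> 0).
#' @param pixel_size Pixel size in meters used to derive the window width.
#' @return An object of class `ra_config` with fields `evaluation_length`
#'   and `window_pixels` (>= 2).
#' @export
#' @examples
#' ra_config(0.05, 0.008)$window_pixels  # 6
ra_config <- function(evaluation_length = 0.05, pixel_size) {
  if (!is.numeric(evaluation_length) || evaluation_length <= 0)
    stop("evaluation_length must be > 0")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  w <- max(2L, as.integer(floor(evaluation_length / pixel_size + 0.5)))
  structure(list(evaluation_length = evaluation_length, window_pixels = w),
            class = "ra_config")
}

#' Per-pixel Ra roughness of a 1-D profile
#'
#' For every position the centered window of `window_pixels` cells is taken
#' (truncated where it overhangs the ends of the profile), the window mean
#' (the "mean line") is subtracted, and the mean absolute deviation is
#' returned. Output has the input's length. Ra is invariant to adding a
#' constant and absolutely homogeneous: `ra(c*x) = |c|*ra(x)`.
#'
#' @param values Numeric profile (m), length >= 2, finite.
#' @param window_pixels Window width in pixels (>= 2). For even widths the
#'   window extends one cell further right than left of the center pixel.
#' @param mode `"sliding"` (default) evaluates a truncated centered window
#'   at every pixel; `"tiled"` cuts the profile into disjoint windows and
#'   assigns each block's Ra to all its pixels; `"strict"` is sliding but
#'   returns `NA` where the full window does not fit.
#' @return Numeric vector of Ra values (m), same length as `values`.
#' @export
ra_profile <- function(values, window_pixels,
                       mode = c("sliding", "tiled", "strict")) {
  mode <- match.arg(mode)
  n <- length(values)
  if (n == 0L) stop("empty series")
  if (n < 2L) stop("series length must be >= 2")
  if (any(!is.finite(values))) stop("values must be finite")
  w <- as.integer(window_pixels)
  if (is.na(w) || w < 2L) stop("window_pixels must be >= 2")
  if (mode == "tiled") {
    block <- (seq_len(n) - 1L) %/% w
    out <- numeric(n)
    for (b in unique(block)) {
      v <- values[block == b]
      out[block == b] <- mean(abs(v - mean(v)))
    }
    return(out)
  }
  lo <- (w - 1L) %/% 2L
  offs <- seq.int(-lo, w - 1L - lo)
  idx <- outer(seq_len(n), offs, `+`)
  idx[idx < 1L | idx > n] <- NA_integer_
  m <- matrix(values[idx], nrow = n)
  mu <- rowMeans(m, na.rm = TRUE)
  out <- rowMeans(abs(m - mu), na.rm = TRUE)
  if (mode == "strict") out[rowSums(is.na(idx)) > 0L] <- NA_real_
  out
}

#' Per-pixel Ra complexity raster of a component surface
#'
#' Applies [ra_profile()] to every contiguous valid row run of a component
#' surface (the `local` or `global` grid of [decompose_dem()]), storing each
#' Ra value at its source pixel. Masked cells stay masked.
#'
#' @param surface An [elevation_raster()] component surface.
#' @param layer `"DLC"` (from the local component) or `"DGC"` (global).
#' @param config An [ra_config()]; defaults to a 5 cm evaluation length on
#'   the surface's own pixel size.
#' @param mode Window mode passed to [ra_profile()].
#' @return A `complexity_raster`: a `reef_raster` whose `values` hold Ra in
#'   meters (all unmasked values >= 0) with a `layer` tag, co-registered to
#'   the source grid.
#' @export
ra_raster <- function(surface, layer = c("DLC", "DGC"),
                      config = ra_config(0.05, surface$pixel_size),
                      mode = c("sliding", "tiled", "strict")) {
  layer <- match.arg(layer)
  mode <- match.arg(mode)
  segs <- extract_row_segments(surface, min_length = 2L)
  if (length(segs) == 0L) stop("no valid run of >= 2 pixels")
  longest <- max(vapply(segs, function(s) length(s$values), integer(1)))
  if (config$window_pixels > longest)
    stop("window of ", config$window_pixels,
         " pixels exceeds the longest valid run (", longest, " pixels)")
  out <- matrix(NA_real_, nrow(surface$values), ncol(surface$values))
  for (s in segs) {
    cols <- s$start_col + seq_along(s$values) - 1L
    out[s$row, cols] <- ra_profile(s$values, config$window_pixels, mode)
  }
  .new_raster(out, surface$pixel_size, surface$origin, surface$crs_id,
              mask = !is.finite(out), class = "complexity_raster",
              extra = list(layer = layer,
                           evaluation_length = config$evaluation_length))
}

#' Digital chain-method rugosity of a profile
#'
#' The classic rugosity index: the length of the surface contour divided by
#' the straight-line distance between its ends, computed on a pixel profile
#' as the sum of per-step Euclidean lengths `sqrt(pixel_size^2 + dz^2)` over
#' the chord `(n-1) * pixel_size`. Equals 1 exactly on a flat profile and
#' exceeds 1 otherwise.
#'
#' @param values Numeric elevation profile (m), length >= 2, finite.
#' @param pixel_size Horizontal step in meters.
#' @return Dimensionless ratio >= 1.
#' @export
#' @examples
#' linear_rugosity(rep(1.5, 10), 0.008)  # exactly 1
linear_rugosity <- function(values, pixel_size) {
  if (length(values) < 2L) stop("profile must contain at least 2 samples")
  if (any(!is.finite(values))) stop("values must be finite")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  dz <- diff(values)
  sum(sqrt(pixel_size^2 + dz^2)) / ((length(values) - 1L) * pixel_size)
}

#' Row-wise chain rugosity of a DEM
#'
#' The field chain method follows a linear transect, so the digital analog
#' is computed along rows: one ratio per valid row run of at least
#' `min_length` pixels, summarized by the median.
#'
#' @param raster An [elevation_raster()].
#' @param min_length Minimum run length in pixels.
#' @return List with `per_segment` (data.frame: row, start_col, n, rugosity)
#'   and `median`.
#' @export
chain_rugosity <- function(raster, min_length = 2L) {
  segs <- extract_row_segments(raster, min_length = min_length)
  if (length(segs) == 0L) stop("no valid run of >= ", min_length, " pixels")
  df <- data.frame(
    row = vapply(segs, `[[`, integer(1), "row"),
    start_col = vapply(segs, `[[`, integer(1), "start_col"),
    n = vapply(segs, function(s) length(s$values), integer(1)),
    rugosity = vapply(segs, function(s)
      linear_rugosity(s$values, raster$pixel_size), numeric(1)))
  list(per_segment = df, median = stats::median(df$rugosity))
}
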