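#' Synthetic reef DEM specification
#'
#' Describes a two-scale reef surface: broad calcareous-matrix relief (a sum
#' of two orthogonal sinusoids, optionally plus Gaussian bumps) whose
#' wavelength is far above the decomposition cutoff `2^J * pixel_size`, and
#' fine biotic texture (correlated Gaussian noise) well below it, plus a
#' nodata margin mimicking plot edges. Defaults follow the surveyed plots:
#' 0.008 m pixels, decimeter-scale relief, centimeter-scale texture.
#'
#' @param n_rows,n_cols Grid size in pixels.
#' @param pixel_size Pixel size in meters.
#' @param base_depth Mean elevation in meters (negative = below datum).
#' @param relief_amplitude Amplitude of the broad relief in meters; each of
#'   the two orthogonal sinusoids gets half of it.
#' @param relief_wavelength Relief wavelength in meters; must exceed
#'   `2^J * pixel_size` for the smooth band to capture it (`J = 4` assumed
#'   for the check).
#' @param roughness_sd Standard deviation of the fine texture in meters.
#' @param roughness_corr_length Correlation length of the texture in meters
#'   (Gaussian-kernel sd).
#' @param n_bumps Optional count of broad Gaussian bumps added to the
#'   relief.
#' @param bump_amplitude,bump_sd Bump height (m) and footprint sd (m).
#' @param nodata_margin Width in pixels of the masked border.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `synthetic_reef_spec`.
#' @export
synthetic_reef_spec <- function(n_rows = 500L, n_cols = 500L,
                                pixel_size = 0.008, base_depth = -8,
                                relief_amplitude = 0.3,
                                relief_wavelength = 1.0,
                                roughness_sd = 0.02,
                                roughness_corr_length = 0.02,
                                n_bumps = 0L, bump_amplitude = 0.2,
                                bump_sd = 0.3,
                                nodata_margin = 0L, seed = 1L) {
  if (n_rows < 2L || n_cols < 2L) stop("degenerate grid")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (relief_amplitude < 0 || roughness_sd < 0 || bump_amplitude < 0)
    stop("amplitudes must be >= 0")
  if (relief_wavelength <= 16 * pixel_size)
    stop("relief_wavelength must exceed 2^J * pixel_size = ",
         16 * pixel_size, " m to separate the scales")
  if (nodata_margin < 0 || 2 * nodata_margin >= min(n_rows, n_cols))
    stop("nodata_margin leaves no valid cells")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_size = pixel_size, base_depth = base_depth,
                 relief_amplitude = relief_amplitude,
                 relief_wavelength = relief_wavelength,
                 roughness_sd = roughness_sd,
                 roughness_corr_length = roughness_corr_length,
                 n_bumps = as.integer(n_bumps),
                 bump_amplitude = bump_amplitude, bump_sd = bump_sd,
                 nodata_margin = as.integer(nodata_margin),
                 seed = as.integer(seed)),
            class = "synthetic_reef_spec")
}

# circular separable Gaussian smoothing, kernel L2-normalized so white-noise
# variance is preserved (texture sd stays interpretable)
.gaussian_texture <- function(nr, nc, sd_pixels) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sd_pixels <= 0) return(z)
  rad <- max(1L, ceiling(4 * sd_pixels))
  k <- stats::dnorm(seq.int(-rad, rad), sd = sd_pixels)
  k <- k / sqrt(sum(k^2))
  smooth1 <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    n <- nrow(m)
    for (i in seq_along(k)) {
      off <- i - rad - 1L
      out <- out + k[i] * m[((seq_len(n) - 1L + off) %% n) + 1L, , drop = FALSE]
    }
    out
  }
  t(smooth1(t(smooth1(z))))
}

#' Generate a synthetic reef DEM
#'
#' Builds `base_depth + relief + texture` per [synthetic_reef_spec()],
#' applies the nodata margin, and returns an [elevation_raster()]. The
#' texture is Gaussian-filtered white noise with an L2-normalized kernel,
#' so its pointwise standard deviation equals `roughness_sd` regardless of
#' the correlation length. Identical seeds give bit-identical rasters; the
#' caller's RNG stream is untouched.
#'
#' @param spec A [synthetic_reef_spec()].
#' @return An [elevation_raster()] with `crs_id = "EPSG:32616"` (the
#'   arbitrary projected CRS convention for plot-local coordinates).
#' @export
generate_reef_dem <- function(spec) {
  stopifnot(inherits(spec, "synthetic_reef_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols; ps <- spec$pixel_size
  x <- (seq_len(nc) - 0.5) * ps
  y <- (seq_len(nr) - 0.5) * ps
  a <- spec$relief_amplitude / 2
  relief <- outer(a * cos(2 * pi * y / spec$relief_wavelength),
                  rep(1, nc)) +
    outer(rep(1, nr), a * sin(2 * pi * x / spec$relief_wavelength))
  z <- .with_seed(spec$seed, {
    zz <- relief
    if (spec$n_bumps > 0L) {
      cx <- stats::runif(spec$n_bumps, 0, nc * ps)
      cy <- stats::runif(spec$n_bumps, 0, nr * ps)
      for (b in seq_len(spec$n_bumps)) {
        zz <- zz + spec$bump_amplitude *
          outer(exp(-(y - cy[b])^2 / (2 * spec$bump_sd^2)),
                exp(-(x - cx[b])^2 / (2 * spec$bump_sd^2)))
      }
    }
    if (spec$roughness_sd > 0) {
      zz <- zz + spec$roughness_sd *
        .gaussian_texture(nr, nc, spec$roughness_corr_length / ps)
    }
    zz
  })
  z <- z + spec$base_depth
  mask <- matrix(FALSE, nr, nc)
  m <- spec$nodata_margin
  if (m > 0L) {
    mask[c(seq_len(m), nr - seq_len(m) + 1L), ] <- TRUE
    mask[, c(seq_len(m), nc - seq_len(m) + 1L)] <- TRUE
  }
  elevation_raster(z, ps, origin = c(0, nr * ps), crs_id = "EPSG:32616",
                   mask = mask)
}

#' Synthetic coral cover specification
#'
#' Disk-shaped colonies are dropped at random positions until the
#' rasterized cover fraction reaches the target; groups are drawn from the
#' five AGRRA morphological groups with the given weights, species from
#' [default_codebook()]. The minimum colony radius honors the 5 cm minimum
#' digitizable colony diameter.
#'
#' @param target_cover_fraction Fraction of grid cells to cover, in
#'   `[0, 0.95]`.
#' @param group_mix Named or positional weights over the five AGRRA groups;
#'   normalized to sum to 1.
#' @param colony_radius_range Min/max colony radius in meters (min
#'   >= 0.025).
#' @param seed Integer seed.
#' @return An object of class `synthetic_cover_spec`.
#' @export
synthetic_cover_spec <- function(target_cover_fraction = 0.15,
                                 group_mix = rep(1, 5),
                                 colony_radius_range = c(0.025, 0.15),
                                 seed = 1L) {
  if (target_cover_fraction < 0) stop("target fraction must be >= 0")
  if (target_cover_fraction > 0.95)
    stop("infeasible target cover fraction > 0.95")
  if (length(group_mix) != 5L || any(group_mix < 0) || sum(group_mix) <= 0)
    stop("group_mix must be 5 non-negative weights")
  if (colony_radius_range[1] < 0.025)
    stop("minimum colony radius is 0.025 m (5 cm diameter)")
  if (diff(colony_radius_range) < 0) stop("radius range must be increasing")
  structure(list(target_cover_fraction = target_cover_fraction,
                 group_mix = group_mix / sum(group_mix),
                 colony_radius_range = colony_radius_range,
                 seed = as.integer(seed)),
            class = "synthetic_cover_spec")
}

#' Generate a synthetic coral polygon layer
#'
#' @param spec A [synthetic_cover_spec()].
#' @param grid A `reef_raster` or [grid_geometry()] list defining the
#'   target grid (pixel centers are used to track the realized cover
#'   fraction).
#' @param seed Optional seed overriding `spec$seed`.
#' @param n_vertices Vertices per colony polygon (disk approximation).
#' @return A [coral_polygon_layer()] whose species codes come from
#'   [default_codebook()].
#' @export
generate_cover_layer <- function(spec, grid, seed = spec$seed,
                                 n_vertices = 24L) {
  stopifnot(inherits(spec, "synthetic_cover_spec"))
  geo <- if (inherits(grid, "reef_raster")) grid_geometry(grid) else grid
  cb <- default_codebook()
  groups <- agrra_groups()
  if (spec$target_cover_fraction == 0)
    return(coral_polygon_layer(list(), geo$crs_id))
  ps <- geo$pixel_size
  xc <- geo$origin[1] + (seq_len(geo$ncol) - 0.5) * ps
  yc <- geo$origin[2] - (seq_len(geo$nrow) - 0.5) * ps
  covered <- matrix(FALSE, geo$nrow, geo$ncol)
  total <- geo$nrow * geo$ncol
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  features <- .with_seed(seed, {
    out <- list()
    for (it in seq_len(10000L)) {
      if (mean(covered) >= spec$target_cover_fraction) break
      r <- stats::runif(1, spec$colony_radius_range[1],
                        spec$colony_radius_range[2])
      cx <- stats::runif(1, min(xc) + r, max(xc) - r)
      cy <- stats::runif(1, min(yc) + r, max(yc) - r)
      gi <- sample.int(5L, 1L, prob = spec$group_mix)
      sp <- sample(cb$species_code[cb$group_name == groups[gi]], 1L)
      ring <- cbind(cx + r * cos(ang), cy + r * sin(ang))
      out[[length(out) + 1L]] <- list(rings = list(ring), species_code = sp)
      ci <- which(abs(xc - cx) <= r)
      ri <- which(abs(yc - cy) <= r)
      if (length(ci) && length(ri)) {
        px <- rep(xc[ci], each = length(ri))
        py <- rep(yc[ri], times = length(ci))
        inside <- .points_in_ring(px, py, ring)
        covered[cbind(rep(ri, times = length(ci))[inside],
                      rep(ci, each = length(ri))[inside])] <- TRUE
      }
    }
    out
  })
  coral_polygon_layer(features, geo$crs_id)
}
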