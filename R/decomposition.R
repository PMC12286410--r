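#' Row-wise wavelet decomposition of a DEM into local and global surfaces
#'
#' Treats each row of the DEM as a 1-D elevation profile, runs the MODWT
#' multiresolution analysis on every contiguous valid run of at least `2^J`
#' pixels, and assembles two co-registered component surfaces:
#'
#' * `local` — the sum of all detail series `D1 + ... + DJ`, the fine-scale
#'   relief attributable to live benthic cover (basis of the DLC);
#' * `global` — the smooth series `SJ`, the broad-scale relief of the
#'   underlying reef matrix (basis of the DGC).
#'
#' `local + global` equals the source DEM at every processed cell. Valid
#' runs shorter than `2^J` pixels are skipped (left masked) rather than
#' processed at a reduced depth, so one wavelet spec describes the whole
#' raster; their cell count is reported in `skipped_cells`.
#'
#' @param raster An [elevation_raster()].
#' @param spec A [wavelet_spec()].
#' @return An object of class `component_surfaces`: list with `local` and
#'   `global` (both [elevation_raster()]s on the source grid), `spec`, and
#'   `skipped_cells`.
#' @export
decompose_dem <- function(raster, spec = wavelet_spec()) {
  segs <- extract_row_segments(raster, min_length = 2L^spec$J)
  if (length(segs) == 0L)
    stop("no row segment of length >= 2^J = ", 2L^spec$J,
         " pixels; nothing to decompose")
  dims <- dim(raster$values)
  loc <- matrix(NA_real_, dims[1], dims[2])
  glo <- matrix(NA_real_, dims[1], dims[2])
  for (s in segs) {
    mra <- modwt_mra(s$values, spec)
    cols <- s$start_col + seq_along(s$values) - 1L
    loc[s$row, cols] <- Reduce(`+`, mra$details)
    glo[s$row, cols] <- mra$smooth
  }
  mk <- function(m) elevation_raster(m, raster$pixel_size, raster$origin,
                                     raster$crs_id, mask = !is.finite(m))
  structure(list(local = mk(loc), global = mk(glo), spec = spec,
                 skipped_cells = attr(segs, "skipped_cells")),
            class = "component_surfaces")
}

#' @export
print.component_surfaces <- function(x, ...) {
  cat(sprintf("<component_surfaces> db%d J=%d, %d x %d, %d cells processed, %d skipped\n",
              x$spec$order, x$spec$J, nrow(x$local$values), ncol(x$local$values),
              sum(!x$local$mask), x$skipped_cells))
  invisible(x)
}

#' Verify that local + global reconstructs the DEM
#'
#' Compares the source DEM with the sum of its wavelet components over all
#' processed cells: reports the maximum absolute reconstruction error and a
#' two-sided Mann-Whitney U test between the original and reconstructed
#' values (a seeded subsample is used when the processed-cell count exceeds
#' `subsample`, since rank-testing tens of millions of pixels is needless).
#' Equivalence is declared when p > 0.05.
#'
#' @param raster The source [elevation_raster()].
#' @param comps The [decompose_dem()] output for that raster.
#' @param subsample Maximum number of cells entering the rank test.
#' @param seed Integer seed for the subsample.
#' @return A `stat_report` (see [mann_whitney_u()]) with extras
#'   `max_abs_error`, `n_cells`, `equivalent`.
#' @export
verify_reconstruction <- function(raster, comps, subsample = 100000L, seed = 1L) {
  assert_coregistered(raster, comps$local)
  ok <- !comps$local$mask & !raster$mask
  n_ok <- sum(ok)
  if (n_ok == 0L) stop("zero processed cells; cannot verify reconstruction")
  orig <- raster$values[ok]
  recon <- comps$local$values[ok] + comps$global$values[ok]
  err <- max(abs(orig - recon))
  if (n_ok > subsample) {
    idx <- .with_seed(seed, sample.int(n_ok, subsample))
    orig <- orig[idx]
    recon <- recon[idx]
  }
  rep <- mann_whitney_u(orig, recon)
  rep$test_name <- "reconstruction_equivalence"
  rep$extras <- c(rep$extras,
                  list(max_abs_error = err, n_cells = length(orig),
                       equivalent = rep$p_value > 0.05))
  rep
}

# evaluate `code` under `seed` without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}
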