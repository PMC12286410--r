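#' AGRRA morphological group names
#'
#' The five coral morphological groups of the Atlantic and Gulf Rapid Reef
#' Assessment protocol used to aggregate digitized colonies.
#'
#' @return Character vector of the five group names.
#' @export
agrra_groups <- function() {
  c("Branching", "Meandroid", "Flower and Solitary", "Agariciid",
    "Mound and Boulder")
}

#' Species-to-group codebook
#'
#' Maps each species code found on digitized colony polygons to an AGRRA
#' morphological group and a positive integer raster code (0 is reserved
#' for background).
#'
#' @param df A data.frame with columns `species_code`, `group_name`,
#'   `raster_code`.
#' @return An object of class `group_codebook` (the validated data.frame).
#' @export
group_codebook <- function(df) {
  need <- c("species_code", "group_name", "raster_code")
  if (!all(need %in% names(df))) stop("codebook needs columns ",
                                      paste(need, collapse = ", "))
  df <- df[, need]
  df$species_code <- as.character(df$species_code)
  df$group_name <- as.character(df$group_name)
  df$raster_code <- as.integer(df$raster_code)
  if (any(!nzchar(df$species_code)) || anyNA(df$species_code))
    stop("species_code must be non-empty")
  if (anyDuplicated(df$species_code))
    stop("duplicate species_code in codebook")
  bad <- setdiff(unique(df$group_name), agrra_groups())
  if (length(bad)) stop("unknown group name(s): ", paste(bad, collapse = ", "))
  if (any(df$raster_code < 1L) || anyNA(df$raster_code))
    stop("raster codes must be integers >= 1 (0 is background)")
  if (anyDuplicated(df$raster_code)) stop("raster codes must be unique")
  structure(df, class = c("group_codebook", "data.frame"))
}

#' @rdname group_codebook
#' @param path CSV file with header `species_code,group_name,raster_code`.
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  group_codebook(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname group_codebook
#' @param codebook A `group_codebook` to write.
#' @export
write_codebook <- function(codebook, path) {
  utils::write.csv(as.data.frame(codebook), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Synthetic default codebook
#'
#' Two placeholder species per AGRRA group with raster codes 1..10; used by
#' the synthetic cover generator and as a template for real codebooks.
#'
#' @return A [group_codebook()].
#' @export
default_codebook <- function() {
  groups <- agrra_groups()
  abbr <- c("BRA", "MEA", "FLS", "AGA", "MOB")
  group_codebook(data.frame(
    species_code = paste0(rep(abbr, each = 2), 1:2),
    group_name = rep(groups, each = 2),
    raster_code = 1:10,
    stringsAsFactors = FALSE))
}

#' Digitized coral colony polygon layer
#'
#' @param features List of features; each feature is a list with `rings`
#'   (list of n x 2 coordinate matrices in map units; first ring is the
#'   outer boundary, further rings are holes, interpreted even-odd) and
#'   `species_code` (non-empty string).
#' @param crs_id Opaque CRS identifier; must match the raster grid's.
#' @return An object of class `coral_polygon_layer`.
#' @export
coral_polygon_layer <- function(features, crs_id = "") {
  for (f in features) {
    if (is.null(f$rings) || !length(f$rings)) stop("feature without rings")
    for (rg in f$rings) {
      if (!is.matrix(rg) || ncol(rg) != 2L || nrow(rg) < 3L)
        stop("each ring must be an n x 2 matrix with n >= 3")
      if (any(!is.finite(rg))) stop("non-finite ring coordinates")
    }
    if (is.null(f$species_code) || !nzchar(f$species_code))
      stop("species_code must be non-empty")
  }
  structure(list(features = features, crs_id = as.character(crs_id)),
            class = "coral_polygon_layer")
}

#' @export
print.coral_polygon_layer <- function(x, ...) {
  cat(sprintf("<coral_polygon_layer> %d polygon(s)%s\n", length(x$features),
              if (nzchar(x$crs_id)) paste0(", ", x$crs_id) else ""))
  invisible(x)
}

#' Read a coral polygon layer from GeoJSON
#'
#' Supports FeatureCollections of Polygon / MultiPolygon features with a
#' `species_code` property. Closed rings (last vertex repeating the first)
#' are accepted and deduplicated.
#'
#' @param path GeoJSON file path.
#' @return A [coral_polygon_layer()].
#' @export
read_polygons <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  crs_id <- ""
  if (!is.null(gj$crs$properties$name)) crs_id <- gj$crs$properties$name
  as_ring <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  features <- list()
  for (ft in gj$features) {
    sc <- ft$properties$species_code
    if (is.null(sc)) stop("feature without species_code property")
    geom <- ft$geometry
    polys <- switch(geom$type,
                    Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates,
                    stop("unsupported geometry type: ", geom$type))
    for (poly in polys) {
      features[[length(features) + 1L]] <-
        list(rings = lapply(poly, as_ring), species_code = as.character(sc))
    }
  }
  coral_polygon_layer(features, crs_id)
}

#' Write a coral polygon layer to GeoJSON
#'
#' @param layer A [coral_polygon_layer()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(layer, path) {
  ft <- lapply(layer$features, function(f) {
    coords <- lapply(f$rings, function(rg) {
      rg <- rbind(rg, rg[1, ])  # close the ring
      lapply(seq_len(nrow(rg)), function(i) c(rg[i, 1], rg[i, 2]))
    })
    list(type = "Feature",
         properties = list(species_code = f$species_code),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  gj <- list(type = "FeatureCollection", features = ft)
  if (nzchar(layer$crs_id))
    gj$crs <- list(type = "name", properties = list(name = layer$crs_id))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# even-odd ray casting: which of the points (px, py) fall inside the ring
.points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if (yi != yj) {
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

.points_in_polygon <- function(px, py, rings) {
  inside <- logical(length(px))
  for (rg in rings) inside <- xor(inside, .points_in_ring(px, py, rg))
  inside
}

#' Rasterize coral polygons onto a raster grid
#'
#' Burns each polygon's raster code into every pixel whose center lies
#' inside the polygon (even-odd rule; holes supported). Overlapping
#' polygons are resolved later-record-wins, with one warning per
#' overlapping feature.
#'
#' @param layer A [coral_polygon_layer()]; its CRS must match the grid's
#'   when both are set.
#' @param codebook A [group_codebook()] covering every species code in the
#'   layer.
#' @param grid A `reef_raster` (or [grid_geometry()] list) defining the
#'   target grid.
#' @return A `cover_raster`: `reef_raster` whose `values` are integer codes
#'   (0 = background) with the codebook attached as `$codebook`.
#' @export
rasterize_polygons <- function(layer, codebook, grid) {
  geo <- if (inherits(grid, "reef_raster")) grid_geometry(grid) else grid
  if (nzchar(layer$crs_id) && nzchar(geo$crs_id) &&
      !identical(layer$crs_id, geo$crs_id))
    stop("polygon layer CRS (", layer$crs_id, ") differs from grid CRS (",
         geo$crs_id, ")")
  codes <- vapply(layer$features, `[[`, character(1), "species_code")
  unknown <- setdiff(unique(codes), codebook$species_code)
  if (length(unknown))
    stop("species code(s) absent from codebook: ",
         paste(unknown, collapse = ", "))
  ps <- geo$pixel_size
  out <- matrix(0L, geo$nrow, geo$ncol)
  xc <- geo$origin[1] + (seq_len(geo$ncol) - 0.5) * ps
  yc <- geo$origin[2] - (seq_len(geo$nrow) - 0.5) * ps
  n_overlap <- 0L
  for (fi in seq_along(layer$features)) {
    f <- layer$features[[fi]]
    code <- codebook$raster_code[match(f$species_code, codebook$species_code)]
    bb <- do.call(rbind, f$rings)
    ci <- which(xc >= min(bb[, 1]) - ps & xc <= max(bb[, 1]) + ps)
    ri <- which(yc >= min(bb[, 2]) - ps & yc <= max(bb[, 2]) + ps)
    if (!length(ci) || !length(ri)) next
    px <- rep(xc[ci], each = length(ri))
    py <- rep(yc[ri], times = length(ci))
    inside <- .points_in_polygon(px, py, f$rings)
    if (!any(inside)) next
    sel <- cbind(rep(ri, times = length(ci))[inside],
                 rep(ci, each = length(ri))[inside])
    prev <- out[sel]
    if (any(prev != 0L & prev != code)) n_overlap <- n_overlap + 1L
    out[sel] <- code
  }
  if (n_overlap > 0L)
    warning(n_overlap, " polygon(s) overlapped earlier records; ",
            "later records win")
  .new_raster(out + 0.0, ps, geo$origin, geo$crs_id, mask = NULL,
              class = "cover_raster", extra = list(codebook = codebook))
}

#' Vectorize a cover raster into per-pixel squares
#'
#' Inverse of [rasterize_polygons()] at pixel granularity: every coded pixel
#' becomes one square polygon carrying (the first) species code of its
#' raster code. Rasterizing the result reproduces the code grid exactly.
#'
#' @param cover A `cover_raster`.
#' @return A [coral_polygon_layer()].
#' @export
vectorize_cover <- function(cover) {
  ps <- cover$pixel_size
  cb <- cover$codebook
  features <- list()
  idx <- which(cover$values != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1]; cc <- idx[k, 2]
    code <- cover$values[r, cc]
    sp <- cb$species_code[match(code, cb$raster_code)]
    x0 <- cover$origin[1] + (cc - 1) * ps
    y0 <- cover$origin[2] - r * ps
    ring <- cbind(c(x0, x0 + ps, x0 + ps, x0), c(y0, y0, y0 + ps, y0 + ps))
    features[[length(features) + 1L]] <- list(rings = list(ring),
                                              species_code = sp)
  }
  coral_polygon_layer(features, cover$crs_id)
}

#' Three-layer complexity stack (DLC, DGC, cover)
#'
#' The per-pixel data cube used for the cover-based analysis: the DLC and
#' DGC Ra rasters in the first two layers and the integer cover raster in
#' the third, all co-registered.
#'
#' @param dlc,dgc `complexity_raster`s with layer tags `"DLC"` / `"DGC"`.
#' @param cover A `cover_raster` on the same grid.
#' @return An object of class `complexity_stack`.
#' @export
complexity_stack <- function(dlc, dgc, cover) {
  if (!identical(dlc$layer, "DLC")) stop("first layer must be tagged DLC")
  if (!identical(dgc$layer, "DGC")) stop("second layer must be tagged DGC")
  assert_coregistered(dlc, dgc)
  assert_coregistered(dlc, cover)
  structure(list(dlc = dlc, dgc = dgc, cover = cover),
            class = "complexity_stack")
}

#' @export
print.complexity_stack <- function(x, ...) {
  cat(sprintf("<complexity_stack> %d x %d, %.4g m pixels, %d coded pixel(s)\n",
              nrow(x$dlc$values), ncol(x$dlc$values), x$dlc$pixel_size,
              sum(x$cover$values != 0)))
  invisible(x)
}

#' Extract paired DLC / DGC samples beneath one coral group
#'
#' Returns the unmasked DLC and DGC values at exactly the pixels whose
#' cover code maps to the requested morphological group (complexity beneath
#' live coral of that group).
#'
#' @param stack A [complexity_stack()].
#' @param group_name One of [agrra_groups()], present in the codebook.
#' @return List with numeric vectors `dlc_values` and `dgc_values`, equal
#'   length, and `n_pixels`.
#' @export
filter_by_group <- function(stack, group_name) {
  cb <- stack$cover$codebook
  codes <- cb$raster_code[cb$group_name == group_name]
  if (!length(codes)) stop("unknown group: ", group_name)
  sel <- stack$cover$values %in% codes &
    !stack$dlc$mask & !stack$dgc$mask
  list(dlc_values = stack$dlc$values[sel],
       dgc_values = stack$dgc$values[sel],
       n_pixels = sum(sel))
}

#' Coral cover area
#'
#' Pixel-count area of one morphological group (or of all coral, any
#' nonzero code): `count * pixel_size^2`, in square meters.
#'
#' @param cover A `cover_raster`.
#' @param group_name A group name from the codebook, or `"all"`.
#' @return Area in square meters.
#' @export
cover_area <- function(cover, group_name = "all") {
  if (identical(group_name, "all")) {
    n <- sum(cover$values != 0)
  } else {
    cb <- cover$codebook
    codes <- cb$raster_code[cb$group_name == group_name]
    if (!length(codes)) stop("unknown group: ", group_name)
    n <- sum(cover$values %in% codes)
  }
  n * cover$pixel_size^2
}

#' Crop a stack to a standard analysis area
#'
#' Restricts the stack to the contiguous full-width row band whose unmasked
#' area (by the DLC mask) is closest to `target_area`, so per-reef
#' comparisons run over a standardized area. Ties between equally close
#' bands are broken by a seeded draw; this band convention is a
#' deterministic stand-in for an unspecified field subset procedure.
#'
#' @param stack A [complexity_stack()].
#' @param target_area Target unmasked area in square meters; must not
#'   exceed the stack's total unmasked area.
#' @param seed Integer seed for the tie-break.
#' @return The cropped [complexity_stack()] (origin shifted accordingly).
#' @export
crop_to_area <- function(stack, target_area, seed = 1L) {
  px2 <- stack$dlc$pixel_size^2
  valid <- rowSums(!stack$dlc$mask)
  total <- sum(valid) * px2
  if (target_area > total + 1e-9)
    stop("target area ", target_area, " m2 exceeds available ",
         signif(total, 6), " m2")
  cs <- c(0, cumsum(valid))
  nr <- length(valid)
  best <- NULL
  best_err <- Inf
  for (r0 in seq_len(nr)) {
    areas <- (cs[(r0 + 1):(nr + 1)] - cs[r0]) * px2
    errs <- abs(areas - target_area)
    k <- which.min(errs)
    if (errs[k] < best_err - 1e-12) {
      best_err <- errs[k]
      best <- list(cbind(r0, r0 + k - 1L))
    } else if (errs[k] <= best_err + 1e-12) {
      best[[length(best) + 1L]] <- cbind(r0, r0 + k - 1L)
    }
  }
  pick <- if (length(best) > 1L)
    best[[.with_seed(seed, sample.int(length(best), 1L))]] else best[[1L]]
  rows <- pick[1]:pick[2]
  sub <- function(r, class, extra) {
    v <- r$values[rows, , drop = FALSE]
    .new_raster(v, r$pixel_size,
                c(r$origin[1], r$origin[2] - (pick[1] - 1L) * r$pixel_size),
                r$crs_id, mask = r$mask[rows, , drop = FALSE],
                class = class, extra = extra)
  }
  complexity_stack(
    sub(stack$dlc, "complexity_raster",
        list(layer = "DLC", evaluation_length = stack$dlc$evaluation_length)),
    sub(stack$dgc, "complexity_raster",
        list(layer = "DGC", evaluation_length = stack$dgc$evaluation_length)),
    sub(stack$cover, "cover_raster", list(codebook = stack$cover$codebook)))
}
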