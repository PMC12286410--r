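grid_16 <- function() {
  # 16 x 16 grid, 1 m pixels, origin (0, 16): pixel centers at x,y = 0.5..15.5
  elevation_raster(matrix(0, 16, 16), 1, origin = c(0, 16))
}

test_that("codebook validation catches structural errors", {
  cb <- default_codebook()
  expect_s3_class(cb, "group_codebook")
  expect_setequal(unique(cb$group_name), agrra_groups())
  expect_error(group_codebook(data.frame(species_code = "X",
                                         group_name = "Tabular",
                                         raster_code = 1)),
               "unknown group")
  expect_error(group_codebook(data.frame(species_code = c("A", "A"),
                                         group_name = agrra_groups()[1:2],
                                         raster_code = 1:2)),
               "duplicate")
  expect_error(group_codebook(data.frame(species_code = c("A", "B"),
                                         group_name = agrra_groups()[1:2],
                                         raster_code = c(1, 1))),
               "unique")
  expect_error(group_codebook(data.frame(species_code = "A",
                                         group_name = agrra_groups()[1],
                                         raster_code = 0)),
               "background")
})

test_that("codebook CSV round-trips", {
  p <- file.path(tempdir(), "cb.csv")
  write_codebook(default_codebook(), p)
  cb2 <- read_codebook(p)
  expect_equal(as.data.frame(cb2), as.data.frame(default_codebook()))
})

test_that("GeoJSON polygon layers round-trip through disk", {
  layer <- coral_polygon_layer(
    list(make_square_feature(2, 3, 4, "AGA1"),
         make_square_feature(8.5, 1.5, 2, "BRA2")),
    crs_id = "EPSG:32616")
  p <- file.path(tempdir(), "corals.geojson")
  write_polygons(layer, p)
  back <- read_polygons(p)
  expect_length(back$features, 2)
  expect_identical(back$crs_id, "EPSG:32616")
  expect_identical(vapply(back$features, `[[`, "", "species_code"),
                   c("AGA1", "BRA2"))
  expect_equal(back$features[[1]]$rings[[1]], layer$features[[1]]$rings[[1]])
})

test_that("rasterization burns exactly the pixel centers inside", {
  cb <- default_codebook()
  # square [2, 5.2] x [3, 6.2]: centers x in {2.5, 3.5, 4.5}, y in
  # {3.5, 4.5, 5.5} -> exactly 3 x 3 = 9 pixels
  layer <- coral_polygon_layer(list(make_square_feature(2, 3, 3.2, "AGA1")))
  cov <- rasterize_polygons(layer, cb, grid_16())
  code <- cb$raster_code[cb$species_code == "AGA1"]
  expect_equal(sum(cov$values == code), 9)
  expect_equal(sum(cov$values != 0), 9)
  # geometry: y 3.5..5.5 are rows 11..13 (origin_y 16), x 2.5..4.5 cols 3..5
  expect_true(all(cov$values[11:13, 3:5] == code))

  empty <- rasterize_polygons(coral_polygon_layer(list()), cb, grid_16())
  expect_true(all(empty$values == 0))
})

test_that("overlaps resolve later-record-wins with a warning", {
  cb <- default_codebook()
  layer <- coral_polygon_layer(list(
    make_square_feature(2, 2, 4.2, "AGA1"),   # centers 2.5..5.5 each axis
    make_square_feature(4, 4, 4.2, "MOB1")))  # centers 4.5..7.5 each axis
  expect_warning(cov <- rasterize_polygons(layer, cb, grid_16()), "overlap")
  code2 <- cb$raster_code[cb$species_code == "MOB1"]
  # intersection centers: x, y in {4.5, 5.5} -> rows 11:12, cols 5:6 ->
  # second record's code
  expect_true(all(cov$values[11:12, 5:6] == code2))
  expect_equal(sum(cov$values == code2), 16)
})

test_that("unknown species codes are reported by name", {
  layer <- coral_polygon_layer(list(make_square_feature(1, 1, 2, "NOPE9")))
  expect_error(rasterize_polygons(layer, default_codebook(), grid_16()),
               "NOPE9")
})

test_that("holes are honored via the even-odd rule", {
  cb <- default_codebook()
  outer_ring <- cbind(c(2, 10, 10, 2), c(2, 2, 10, 10))
  hole <- cbind(c(4, 8, 8, 4), c(4, 4, 8, 8))
  layer <- coral_polygon_layer(list(list(rings = list(outer_ring, hole),
                                         species_code = "MEA1")))
  cov <- rasterize_polygons(layer, cb, grid_16())
  expect_equal(sum(cov$values != 0), 64 - 16)
  expect_equal(cov$values[11, 6], 0)   # center (5.5, 5.5) inside the hole
  expect_gt(cov$values[11, 9], 0)      # center (8.5, 5.5) in the rim
})

test_that("rasterize(vectorize(cover)) is the identity", {
  cb <- default_codebook()
  layer <- coral_polygon_layer(list(make_square_feature(2, 3, 3.2, "AGA1"),
                                    make_square_feature(9, 9, 2.2, "FLS2")))
  cov <- rasterize_polygons(layer, cb, grid_16())
  again <- rasterize_polygons(vectorize_cover(cov), cb, grid_16())
  expect_identical(again$values, cov$values)
})

make_stack_16 <- function(layer = NULL) {
  cb <- default_codebook()
  if (is.null(layer))
    layer <- coral_polygon_layer(list(make_square_feature(2, 3, 3.2, "AGA1"),
                                      make_square_feature(9, 9, 2.2, "BRA1")))
  set.seed(55)
  base <- elevation_raster(matrix(rnorm(256, sd = 0.05), 16, 16), 1,
                           origin = c(0, 16))
  dlc <- ra_raster(base, "DLC", ra_config(4, 1))
  dgc <- ra_raster(base, "DGC", ra_config(4, 1))
  cov <- rasterize_polygons(layer, cb, base)
  complexity_stack(dlc, dgc, cov)
}

test_that("filter_by_group returns paired samples at the coded pixels", {
  st <- make_stack_16()
  s <- filter_by_group(st, "Agariciid")
  expect_equal(s$n_pixels, 9)
  expect_length(s$dlc_values, 9)
  expect_length(s$dgc_values, 9)
  code <- default_codebook()
  aga <- code$raster_code[code$group_name == "Agariciid"]
  sel <- st$cover$values %in% aga
  expect_setequal(s$dlc_values, st$dlc$values[sel])

  none <- filter_by_group(st, "Meandroid")
  expect_equal(none$n_pixels, 0)
  expect_length(none$dlc_values, 0)
  expect_error(filter_by_group(st, "Tabular"), "unknown group")

  # partition: group counts + background = all unmasked pixels
  counts <- vapply(agrra_groups(), function(g)
    filter_by_group(st, g)$n_pixels, numeric(1))
  background <- sum(st$cover$values == 0 & !st$dlc$mask)
  expect_equal(sum(counts) + background, sum(!st$dlc$mask))
})

test_that("cover_area is pixel count times pixel area and partitions", {
  st <- make_stack_16()
  expect_equal(cover_area(st$cover, "Agariciid"), 9 * 1^2)
  expect_equal(cover_area(st$cover, "Meandroid"), 0)
  per_group <- vapply(agrra_groups(), function(g)
    cover_area(st$cover, g), numeric(1))
  expect_equal(cover_area(st$cover, "all"), sum(per_group))
  expect_error(cover_area(st$cover, "Tabular"), "unknown group")

  # paper-scale arithmetic: 9 pixels at 0.008 m
  tiny <- rasterize_polygons(
    coral_polygon_layer(list(make_square_feature(0.002, 0.002, 0.025, "AGA1"))),
    default_codebook(),
    elevation_raster(matrix(0, 8, 8), 0.008, origin = c(0, 8 * 0.008)))
  expect_equal(cover_area(tiny, "all"), sum(tiny$values != 0) * 6.4e-5)
})

test_that("crop_to_area selects the closest row band, deterministically", {
  st <- make_stack_16()
  full <- crop_to_area(st, 256, seed = 3)
  expect_identical(dim(full$dlc$values), dim(st$dlc$values))
  expect_identical(full$dlc$values, st$dlc$values)

  half <- crop_to_area(st, 128, seed = 3)
  expect_equal(nrow(half$dlc$values), 8)
  expect_equal(ncol(half$dlc$values), 16)
  half2 <- crop_to_area(st, 128, seed = 3)
  expect_identical(half$dlc$origin, half2$dlc$origin)
  expect_identical(half$dlc$values, half2$dlc$values)

  expect_error(crop_to_area(st, 1000, seed = 1), "exceeds")
})
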