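test_that("CSV layer round-trips and maps absent cells to missing", {
  g <- grid_spec(3, 3, xmin = 0, ymax = 1, resolution_arcmin = 20)
  vals <- c(1, 2, 3, 4, NA, 6, 7, 8, 9)
  layer <- raster_layer(g, "x", vals)
  path <- withr::local_tempfile(fileext = ".csv")
  write_layer(layer, path)
  back <- read_layer(path, g)
  expect_identical(back$values, vals)

  # one cell missing from the file -> one missing value
  tab <- utils::read.csv(path)
  expect_equal(nrow(tab), 8)
})

test_that("a TIFF fraction layer reads onto the grid in row-major order", {
  skip_if_not_installed("tiff")
  g <- grid_spec(4, 5, xmin = 0, ymax = 1, resolution_arcmin = 12)
  vals <- seq(0.02, by = 0.05, length.out = 20) # a [0,1] fraction layer
  path <- withr::local_tempfile(fileext = ".tif")
  m <- matrix(vals, nrow = 4, ncol = 5, byrow = TRUE)
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  back <- read_layer(path, g)
  expect_equal(back$values, vals, tolerance = 1e-4)
  expect_error(write_layer(raster_layer(g, "x", vals), path), "CSV only")
})

test_that("nearest-neighbour resampling follows index arithmetic on a 2x2 coarse grid", {
  # coarse 2x2 at 30 arcmin over lon [0,1], lat [0,1]; fine grid at 5 arcmin
  coarse <- grid_spec(2, 2, xmin = 0, ymax = 1, resolution_arcmin = 30)
  fine <- grid_spec(12, 12, xmin = 0, ymax = 1, resolution_arcmin = 5)
  layer <- raster_layer(coarse, "x", c(10, 20, 30, 40))
  out <- resample_nearest(layer, fine)

  # oracle: each 5-arcmin cell takes its containing coarse cell's value
  expected <- numeric(144)
  for (r in 1:12) {
    for (c in 1:12) {
      cr <- ceiling(r / 6); cc <- ceiling(c / 6)
      expected[(r - 1) * 12 + c] <- c(10, 20, 30, 40)[(cr - 1) * 2 + cc]
    }
  }
  expect_identical(out$values, expected)
  # nothing is conserved by design, but every output value is an input value
  expect_true(all(out$values %in% layer$values))
})

test_that("read_layer refuses a grid mismatch unless resampling is enabled", {
  coarse <- grid_spec(2, 2, xmin = 0, ymax = 1, resolution_arcmin = 30)
  fine <- grid_spec(12, 12, xmin = 0, ymax = 1, resolution_arcmin = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_layer(raster_layer(coarse, "x", 1:4), path)
  expect_error(read_layer(path, fine, source_grid = coarse),
               "resample")
  out <- read_layer(path, fine, source_grid = coarse, resample = "nearest")
  expect_length(out$values, 144)
})

test_that("align_layers keeps rows with missing inputs and matches the area count", {
  g <- grid_spec(2, 3, xmin = 0, ymax = 1, resolution_arcmin = 30)
  area_corn <- raster_layer(g, "area_corn", c(200, 0, NA, 150, 300, 120))
  yield_corn <- raster_layer(g, "yield_corn", c(5000, 1, 1, 4000, 3000, 2500))
  area_rice <- raster_layer(g, "area_rice", c(NA, NA, 100, NA, 250, NA))
  yield_rice <- raster_layer(g, "yield_rice", rep(3500, 6))
  pest <- raster_layer(g, "pesticides", c(2, 2, 2, NA, 1, 1))
  tab <- align_layers(list(
    area_corn = area_corn, yield_corn = yield_corn,
    area_rice = area_rice, yield_rice = yield_rice, pesticides = pest
  ), g)

  # row count = sum over crops of cells with positive area
  expect_equal(nrow(tab), 4 + 2)
  # a missing source layer yields a missing field, not a dropped row
  corn4 <- tab[tab$crop == "corn" & tab$cell_id == 4, ]
  expect_equal(nrow(corn4), 1)
  expect_true(is.na(corn4$pesticides))
  # two crops sharing a cell -> two rows with the same cell_id
  expect_equal(sum(tab$cell_id == 5), 2)
})

test_that("align_layers rejects duplicate layer names and allows zero overlap", {
  g <- grid_spec(1, 2, xmin = 0, ymax = 1, resolution_arcmin = 30)
  a <- raster_layer(g, "area_corn", c(100, 200))
  expect_error(align_layers(stats::setNames(list(a, a),
                                            c("area_corn", "area_corn")), g),
               "duplicate")
  empty <- align_layers(list(area_corn = raster_layer(g, "area_corn",
                                                      c(NA, 0))), g)
  expect_equal(nrow(empty), 0)
})

test_that("cell table CSV round-trip is bit-exact", {
  tab <- tiny_table(6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(tab, path)
  back <- read_cell_table(path)
  expect_identical(as.data.frame(back), as.data.frame(tab))
})

test_that("tillage reclassification marks conservation agriculture mechanized and draft systems not", {
  g <- grid_spec(1, 7, xmin = 0, ymax = 1, resolution_arcmin = 60)
  tillage <- raster_layer(g, "tillage", c(1, 2, 3, 4, 5, 6, NA))
  out <- reclassify_tillage(tillage)
  expect_equal(out$values[4], 1)        # conservation agriculture
  expect_equal(out$values[c(2, 6)], c(0, 0)) # human/animal draft systems
  expect_true(is.na(out$values[7]))     # missing stays missing
  expect_true(all(out$values %in% c(0, 1) | is.na(out$values)))

  bad <- raster_layer(g, "tillage", c(1, 9, 2, 3, 4, 5, 6))
  expect_warning(out2 <- reclassify_tillage(bad), "unknown tillage")
  expect_true(is.na(out2$values[2]))
})

test_that("cell table invariants are enforced", {
  tab <- tiny_table(4)
  tab$irrigation_tot[1] <- 1.2
  expect_error(validate_cell_table(tab), "\\[0, 1\\]")
  tab2 <- tiny_table(4)
  tab2$mechanized[1] <- 2
  expect_error(validate_cell_table(tab2), "mechanized")
  tab3 <- rbind(tiny_table(4), tiny_table(4)[1, ])
  expect_error(validate_cell_table(tab3), "duplicated")
})
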