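#' Define a regular lat/lon grid
#'
#' A grid of square cells in geographic coordinates with cell-center
#' registration. Rows are ordered north to south, columns west to east, and
#' `cell_id` is the row-major index (top-left cell is 1). This ordering is
#' load-bearing: the forward-fill step of the cleaning ledger traverses cells
#' in `cell_id` order, so the convention fixes its result.
#'
#' @param n_rows,n_cols Grid dimensions (cells).
#' @param xmin Western edge of the grid in degrees longitude, in
#'   \eqn{[-180, 180)}.
#' @param ymax Northern edge in degrees latitude.
#' @param resolution_arcmin Cell size in arc minutes; 5 matches the common
#'   global crop-production products.
#' @param nodata Sentinel written to rasters for missing cells. All physical
#'   layers here are non-negative, so a negative sentinel never collides with
#'   data.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, xmin = -180, ymax = 90,
                      resolution_arcmin = 5, nodata = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1, resolution_arcmin > 0)
  if (nodata >= 0) {
    stop("nodata sentinel must be negative so it cannot collide with physical values")
  }
  res_deg <- resolution_arcmin / 60
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      xmin = xmin, ymax = ymax,
      xmax = xmin + n_cols * res_deg, ymin = ymax - n_rows * res_deg,
      resolution_arcmin = resolution_arcmin, res_deg = res_deg,
      nodata = nodata
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "grid_spec: %d x %d cells at %g arcmin, lon [%g, %g), lat (%g, %g]\n",
    x$n_rows, x$n_cols, x$resolution_arcmin, x$xmin, x$xmax, x$ymin, x$ymax
  ))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Cell-center coordinates for every cell of a grid
#'
#' @param grid A [grid_spec()].
#' @return Data frame with `cell_id`, `lon`, `lat` in row-major order.
#' @export
grid_coords <- function(grid) {
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  data.frame(
    cell_id = seq_len(n_cells(grid)),
    lon = grid$xmin + (col - 0.5) * grid$res_deg,
    lat = grid$ymax - (row - 0.5) * grid$res_deg
  )
}

#' Construct a raster layer on a grid
#'
#' @param grid A [grid_spec()].
#' @param name Layer identifier.
#' @param values Numeric vector, one value per cell in row-major order; `NA`
#'   marks missing cells.
#' @param units Free-text unit annotation carried along for audit.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(grid, name, values, units = "") {
  stopifnot(inherits(grid, "grid_spec"), is.character(name), length(name) == 1)
  values <- as.numeric(values)
  if (length(values) != n_cells(grid)) {
    stop(sprintf(
      "layer '%s': %d values supplied for a grid of %d cells",
      name, length(values), n_cells(grid)
    ))
  }
  structure(list(grid = grid, name = name, values = values, units = units),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  cat(sprintf(
    "raster_layer '%s' [%s]: %d cells, %d missing\n",
    x$name, x$units, length(x$values), sum(is.na(x$values))
  ))
  invisible(x)
}

#' Read a gridded layer from disk
#'
#' Two plain formats are supported: a two-column CSV (`cell_id,value`, cells
#' absent from the file are missing) and a single-band TIFF whose matrix
#' dimensions match the grid (read via the `tiff` package when installed).
#' Values equal to the grid's nodata sentinel are mapped to missing. If the
#' file was produced on a coarser grid, pass that grid as `source_grid` with
#' `resample = "nearest"` to align it.
#'
#' @param path File path (`.csv`, `.tif`/`.tiff`).
#' @param grid Target [grid_spec()].
#' @param name Layer name; defaults to the file stem.
#' @param units Unit annotation.
#' @param source_grid Grid the file is registered on, when different from
#'   `grid`.
#' @param resample `"none"` or `"nearest"`; required when `source_grid`
#'   differs from `grid`.
#' @return A [raster_layer()] on `grid`.
#' @export
read_layer <- function(path, grid, name = NULL, units = "",
                       source_grid = NULL, resample = c("none", "nearest")) {
  resample <- match.arg(resample)
  if (!file.exists(path)) stop("cannot read layer: no such file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  read_grid <- if (is.null(source_grid)) grid else source_grid

  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "csv") {
    tab <- utils::read.csv(path)
    if (!all(c("cell_id", "value") %in% names(tab))) {
      stop("CSV layer must have columns cell_id,value: ", path)
    }
    if (any(tab$cell_id < 1 | tab$cell_id > n_cells(read_grid))) {
      stop("cell_id outside grid in ", path)
    }
    values <- rep(NA_real_, n_cells(read_grid))
    values[tab$cell_id] <- tab$value
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF layers requires the 'tiff' package")
    }
    # float TIFFs read as stored; integer TIFFs arrive on the [0,1] scale
    # (TIFF convention) — use CSV for class-code layers
    m <- tiff::readTIFF(path)
    if (length(dim(m)) != 2 ||
        nrow(m) != read_grid$n_rows || ncol(m) != read_grid$n_cols) {
      stop(sprintf(
        "TIFF dimensions do not match grid (%d x %d expected): %s",
        read_grid$n_rows, read_grid$n_cols, path
      ))
    }
    values <- as.numeric(t(m)) # row-major
  } else {
    stop("unsupported layer format '.", ext, "' (csv, tif supported): ", path)
  }
  values[!is.na(values) & values == read_grid$nodata] <- NA_real_
  layer <- raster_layer(read_grid, name, values, units)

  if (!same_grid(read_grid, grid)) {
    if (resample == "none") {
      stop(sprintf(
        "layer '%s' is on a %g-arcmin grid but the target is %g arcmin; pass resample = \"nearest\"",
        name, read_grid$resolution_arcmin, grid$resolution_arcmin
      ))
    }
    layer <- resample_nearest(layer, grid)
  }
  layer
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("n_rows", "n_cols", "xmin", "ymax", "res_deg")],
                   b[c("n_rows", "n_cols", "xmin", "ymax", "res_deg")]))
}

#' Nearest-neighbour resampling onto a target grid
#'
#' Each target cell takes the value of the source cell containing its centre.
#' Nearest assignment is used for categorical and rate layers alike: the rate
#' layers are intensive (per-hectare), so no mass needs conserving, and every
#' output value is exactly some input value. Target cells whose centre falls
#' outside the source extent are missing.
#'
#' @param layer A [raster_layer()].
#' @param grid Target [grid_spec()].
#' @return A [raster_layer()] on `grid`.
#' @export
resample_nearest <- function(layer, grid) {
  src <- layer$grid
  cc <- grid_coords(grid)
  col <- floor((cc$lon - src$xmin) / src$res_deg) + 1
  row <- floor((src$ymax - cc$lat) / src$res_deg) + 1
  inside <- col >= 1 & col <= src$n_cols & row >= 1 & row <= src$n_rows
  idx <- (row - 1) * src$n_cols + col
  values <- rep(NA_real_, n_cells(grid))
  values[inside] <- layer$values[idx[inside]]
  raster_layer(grid, layer$name, values, layer$units)
}

#' Write a raster layer
#'
#' CSV is the write format: only non-missing cells are stored
#' (`cell_id,value`) and the round trip through [read_layer()] is bit-exact.
#' TIFF is read-only here — the layers this pipeline produces are
#' tabular, and CSV keeps them diffable and lossless.
#'
#' @param layer A [raster_layer()].
#' @param path Destination (`.csv`).
#' @export
write_layer <- function(layer, path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext != "csv") {
    stop("layers are written as CSV only (got .", ext, ")")
  }
  keep <- !is.na(layer$values)
  df <- data.frame(cell_id = which(keep),
                   value = format_full(layer$values[keep]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision decimal rendering: 17 significant digits round-trip any
# double exactly through read.csv
format_full <- function(v) {
  out <- formatC(v, digits = 17, format = "g")
  out[is.na(v)] <- NA
  trimws(out)
}

# Column order of the long-format cell table; the on-disk CSV header.
CELL_TABLE_COLS <- c(
  "cell_id", "lon", "lat", "region", "crop",
  "yield_kg_ha", "harvested_area_ha",
  "n_fert", "n_manure", "n_total", "pesticides",
  "irrigation_tot", "irrigation_reliant", "mechanized",
  "thz_class", "mst_class", "soil_class"
)

#' Assemble aligned layers into a long per-cell, per-crop table
#'
#' Takes one harvested-area and one yield layer per crop (named
#' `area_<crop>` and `yield_<crop>`) plus the shared input layers, and emits
#' one row per (cell with positive harvested area, crop). Source layers can
#' cover different subsets of cells; where a layer is missing for a retained
#' cell the field is missing in the row rather than the row being dropped —
#' missing-data policy is applied later, in the cleaning ledger.
#'
#' @param layers Named list of [raster_layer()]s on a common grid. Recognised
#'   shared names: `n_fert`, `n_manure`, `pesticides`, `irrigation_tot`,
#'   `irrigation_reliant`, `mechanized`, `thz_class`, `mst_class`,
#'   `soil_class`, `region`.
#' @param grid The common [grid_spec()].
#' @param region_labels Optional character vector translating integer codes in
#'   the `region` layer to continent labels.
#' @return A `cell_table` data frame (see [read_cell_table()] for the schema).
#'   `n_total` is left missing; it is computed during preprocessing, after
#'   outlier trimming of its two components.
#' @export
align_layers <- function(layers, grid, region_labels = NULL) {
  nms <- names(layers)
  if (is.null(nms) || any(nms == "")) stop("layers must be a named list")
  if (anyDuplicated(nms)) {
    stop("duplicate layer names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  for (l in layers) {
    if (!same_grid(l$grid, grid)) {
      stop("layer '", l$name, "' is not on the target grid; resample first")
    }
  }
  crops <- sub("^area_", "", nms[startsWith(nms, "area_")])
  if (length(crops) == 0) stop("no 'area_<crop>' layer supplied")

  cc <- grid_coords(grid)
  shared <- c("n_fert", "n_manure", "pesticides", "irrigation_tot",
              "irrigation_reliant", "mechanized")
  classes <- c("thz_class", "mst_class", "soil_class")

  pick <- function(nm, cells) {
    if (nm %in% nms) layers[[nm]]$values[cells] else rep(NA_real_, length(cells))
  }
  rows <- lapply(crops, function(crop) {
    area <- layers[[paste0("area_", crop)]]$values
    cells <- which(!is.na(area) & area > 0)
    if (length(cells) == 0) return(NULL)
    yl <- paste0("yield_", crop)
    region <- pick("region", cells)
    region_lab <- if (!is.null(region_labels)) {
      ifelse(is.na(region), NA_character_, region_labels[region])
    } else {
      ifelse(is.na(region), NA_character_, as.character(region))
    }
    out <- data.frame(
      cell_id = cells,
      lon = cc$lon[cells], lat = cc$lat[cells],
      region = region_lab, crop = crop,
      yield_kg_ha = if (yl %in% nms) layers[[yl]]$values[cells] else NA_real_,
      harvested_area_ha = area[cells],
      n_fert = pick("n_fert", cells),
      n_manure = pick("n_manure", cells),
      n_total = NA_real_,
      pesticides = pick("pesticides", cells),
      irrigation_tot = pick("irrigation_tot", cells),
      irrigation_reliant = pick("irrigation_reliant", cells),
      mechanized = pick("mechanized", cells),
      stringsAsFactors = FALSE
    )
    for (cl in classes) {
      v <- pick(cl, cells)
      out[[cl]] <- ifelse(is.na(v), NA_character_, as.character(v))
    }
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- as.data.frame(
      stats::setNames(rep(list(logical(0)), length(CELL_TABLE_COLS)),
                      CELL_TABLE_COLS)
    )
  }
  validate_cell_table(out[, CELL_TABLE_COLS])
}

#' Validate a per-cell crop table
#'
#' Checks the schema and physical invariants: non-negative quantities,
#' irrigation fractions in \eqn{[0, 1]}, mechanization in \{0, 1\}, one row
#' per (cell, crop).
#'
#' @param table Data frame.
#' @return The table, invisibly classed as `cell_table`.
#' @export
validate_cell_table <- function(table) {
  missing_cols <- setdiff(CELL_TABLE_COLS, names(table))
  if (length(missing_cols) > 0) {
    stop("cell table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  num <- c("yield_kg_ha", "harvested_area_ha", "n_fert", "n_manure",
           "n_total", "pesticides")
  for (col in num) {
    v <- table[[col]]
    if (any(!is.na(v) & v < 0)) stop("negative values in ", col)
  }
  for (col in c("irrigation_tot", "irrigation_reliant")) {
    v <- table[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop(col, " must lie in [0, 1]")
    }
  }
  m <- table$mechanized
  if (any(!is.na(m) & !m %in% c(0, 1))) stop("mechanized must be 0 or 1")
  if (anyDuplicated(table[, c("cell_id", "crop")])) {
    stop("duplicated (cell_id, crop) rows")
  }
  class(table) <- unique(c("cell_table", class(table)))
  table
}

#' Write a cell table to CSV
#'
#' Numeric columns are rendered with 17 significant digits so the round trip
#' through [read_cell_table()] is bit-exact.
#'
#' @param table A cell table.
#' @param path Destination path.
#' @export
write_cell_table <- function(table, path) {
  out <- as.data.frame(table)[, CELL_TABLE_COLS]
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- format_full(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a cell table from CSV
#'
#' @param path CSV written by [write_cell_table()] (header:
#'   `cell_id,lon,lat,region,crop,yield_kg_ha,...`).
#' @return A validated `cell_table`.
#' @export
read_cell_table <- function(path) {
  char_cols <- c("region", "crop", "thz_class", "mst_class", "soil_class")
  num_cols <- setdiff(CELL_TABLE_COLS, c(char_cols, "cell_id"))
  tab <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                         colClasses = c(
                           stats::setNames(rep("character", length(char_cols)),
                                           char_cols),
                           stats::setNames(rep("numeric", length(num_cols)),
                                           num_cols),
                           cell_id = "integer"
                         ))
  validate_cell_table(tab)
}

# Default reclassification of the six-system tillage product into a
# mechanization proxy. Systems driven by machinery (conventional, reduced,
# rotational tillage and conservation agriculture, the latter machinery-based
# despite near-zero tilling) map to 1; the traditional systems based on human
# and animal draft power map to 0.
DEFAULT_TILLAGE_MAP <- c(
  "1" = 1, # conventional annual tillage
  "2" = 0, # traditional annual tillage (hand / draft animals)
  "3" = 1, # reduced tillage
  "4" = 1, # conservation agriculture
  "5" = 1, # rotational tillage
  "6" = 0  # traditional rotational tillage (hand / draft animals)
)

#' Reclassify tillage systems into a binary mechanization layer
#'
#' @param tillage_layer A [raster_layer()] of tillage-system codes 1-6.
#' @param merge_map Named numeric vector mapping code (as character) to 0/1;
#'   the default maps the traditional (human/animal draft) systems to 0 and
#'   all machinery-based systems, including conservation agriculture, to 1.
#' @return A binary [raster_layer()] named `mechanized`. Unknown codes are
#'   reported via a warning and mapped to missing.
#' @export
reclassify_tillage <- function(tillage_layer, merge_map = DEFAULT_TILLAGE_MAP) {
  v <- tillage_layer$values
  key <- as.character(v)
  out <- unname(merge_map[key])
  unknown <- !is.na(v) & is.na(out)
  if (any(unknown)) {
    warning(sprintf(
      "%d cells with unknown tillage codes (%s) mapped to missing",
      sum(unknown), paste(unique(key[unknown]), collapse = ", ")
    ))
  }
  raster_layer(tillage_layer$grid, "mechanized", out, "0/1")
}
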