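#' Configuration for the synthetic agricultural landscape
#'
#' Describes a landscape with known ground truth: per-crop gamma-distributed
#' yields whose log-mean is linear in the inputs, right-skewed input-rate
#' distributions, spatially blocky agro-climatic classes, missing cells in
#' the pesticide and mechanization layers, and multiplicative outliers in the
#' input rates. Fitting the yield model to data generated from this
#' configuration should recover `coefficients` — that closed loop is what
#' makes the downstream stages testable without the global source datasets.
#'
#' Every random column draws from its own stream derived from `seed`, so
#' switching missingness or outliers on or off does not perturb the yields.
#'
#' @param seed Master seed; all randomness derives from it.
#' @param n_rows,n_cols Grid dimensions (cells).
#' @param crops Character vector of crop names.
#' @param coefficients Named list per crop, each a list with elements
#'   `intercept`, `n_total`, `pesticides`, `irrigation_tot`, `mechanized`
#'   (log-scale slopes) and named vectors `thz`, `mst`, `soil` of effects for
#'   the non-reference merged class levels (references T1, M2, S1). Crops
#'   missing from the list use `default_true_coefficients()`.
#' @param shape True gamma shape \eqn{\alpha}; yields are drawn as
#'   Gamma(shape, scale = \eqn{\mu}/shape) so the mean is \eqn{\mu} and the
#'   coefficient of variation is \eqn{1/\sqrt{\alpha}}.
#' @param input_dist Log-normal (meanlog, sdlog) parameters for the
#'   right-skewed input rates `n_fert`, `n_manure`, `pesticides`.
#' @param area_dist Log-normal parameters for harvested area per cell; the
#'   default spans sub-100-ha cells (removed by the area filter) up to
#'   multi-thousand-hectare cells.
#' @param missingness Named rates in \eqn{[0,1]} for columns left missing at
#'   random. `pesticides` and `mechanized` emulate the sparser coverage of
#'   those products; small rates on `n_fert` and the class columns exercise
#'   forward filling.
#' @param outlier_rate Fraction of rows whose input rates are multiplied by a
#'   factor drawn uniformly from `outlier_range` — implausible values for the
#'   percentile trim to catch.
#' @param outlier_range Multiplicative magnitude range of injected outliers.
#' @param crop_presence Probability a crop is grown in a cell.
#' @param irrigated_frac Probability a cell has any irrigation at all.
#' @param mechanized_prob Probability a cell is mechanized.
#' @param class_block Edge length, in cells, of the square blocks within
#'   which an agro-climatic class is constant (blocky spatial structure).
#' @param regions Continent labels assigned as contiguous longitudinal bands.
#' @param thz_probs,mst_probs,soil_probs Sampling probabilities of the raw
#'   class codes. Defaults make the cold thermal codes (T7-T9) rare, matching
#'   the sparse occupancy that motivates merging them.
#' @param raw_classes If `TRUE` (default) the emitted class columns carry raw
#'   codes (thermal T1-T9, moisture M1-M7) so the class-merging step has work
#'   to do; the yield model itself always acts on the merged levels. Set to
#'   `FALSE` to emit merged codes directly.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_rows = 40, n_cols = 50,
                             crops = c("corn", "rice", "soybean", "wheat"),
                             coefficients = list(),
                             shape = 4,
                             input_dist = list(
                               n_fert = c(meanlog = log(60), sdlog = 0.8),
                               n_manure = c(meanlog = log(15), sdlog = 0.8),
                               pesticides = c(meanlog = log(1.5), sdlog = 0.9)
                             ),
                             area_dist = c(meanlog = log(800), sdlog = 1.5),
                             missingness = c(pesticides = 0.10, mechanized = 0.10,
                                             n_fert = 0.02, classes = 0.02),
                             outlier_rate = 0.002,
                             outlier_range = c(10, 100),
                             crop_presence = 0.6,
                             irrigated_frac = 0.55,
                             mechanized_prob = 0.6,
                             class_block = 5,
                             regions = c("Africa", "Asia", "Europe",
                                         "North America", "Oceania",
                                         "South America"),
                             thz_probs = c(T1 = 0.16, T2 = 0.10, T3 = 0.18,
                                           T4 = 0.14, T5 = 0.12, T6 = 0.22,
                                           T7 = 0.04, T8 = 0.025, T9 = 0.015),
                             mst_probs = c(M1 = 0.06, M2 = 0.12, M3 = 0.22,
                                           M4 = 0.22, M5 = 0.20, M6 = 0.12,
                                           M7 = 0.06),
                             soil_probs = c(S1 = 0.08, S2 = 0.10, S3 = 0.34,
                                            S4 = 0.26, S5 = 0.14, L3 = 0.08),
                             raw_classes = TRUE) {
  stopifnot(shape > 0, outlier_rate >= 0, outlier_rate <= 1,
            crop_presence > 0, crop_presence <= 1,
            all(missingness >= 0), all(missingness <= 1),
            all(thz_probs > 0), all(mst_probs > 0), all(soil_probs > 0))
  cfg <- list(
    seed = as.integer(seed), n_rows = n_rows, n_cols = n_cols, crops = crops,
    coefficients = coefficients, shape = shape, input_dist = input_dist,
    area_dist = area_dist, missingness = missingness,
    outlier_rate = outlier_rate, outlier_range = outlier_range,
    crop_presence = crop_presence, irrigated_frac = irrigated_frac,
    mechanized_prob = mechanized_prob, class_block = class_block,
    regions = regions, thz_probs = thz_probs, mst_probs = mst_probs,
    soil_probs = soil_probs, raw_classes = raw_classes
  )
  structure(cfg, class = "synthetic_config")
}

#' Default ground-truth coefficients
#'
#' Log-scale effects sized so that sweeping each input over a realistic
#' observed range moves the expected yield by roughly a third to a half —
#' the order of magnitude of the input effects the yield model is meant to
#' detect. Class effects are modest (at most ~0.3 on the log scale).
#'
#' @param crop Crop name; the intercept varies slightly by crop.
#' @return Coefficient list as used by [synthetic_config()].
#' @export
default_true_coefficients <- function(crop = "corn") {
  base <- switch(crop,
    corn = log(2200), rice = log(2500), soybean = log(1100),
    wheat = log(1800), log(2000)
  )
  list(
    intercept = base,
    n_total = 0.004,       # per kg N ha^-1
    pesticides = 0.05,     # per kg ha^-1
    irrigation_tot = 0.5,  # fully irrigated vs rain-fed
    mechanized = 0.45,     # machinery vs human/animal draft
    thz = c(T2 = -0.10, T3 = 0.10, T4 = 0.05, T5 = -0.05, T6 = 0.15,
            T7 = -0.30),
    mst = c(M3 = 0.10, M4 = 0.20, M5 = 0.25, M6 = 0.30),
    soil = c(S2 = -0.05, S3 = 0.25, S4 = 0.10, S5 = -0.20, L3 = 0.20)
  )
}

# deterministic sub-stream: each named stream gets its own seed derived from
# the master seed, so columns are independent and individually reproducible
stream_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

draw <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(seed, key))
  eval.parent(substitute(expr))
}

# blocky categorical field: one draw per class_block x class_block block
sample_blocky <- function(seed, key, n_rows, n_cols, block, probs) {
  br <- ceiling(n_rows / block)
  bc <- ceiling(n_cols / block)
  block_vals <- draw(seed, key,
    sample(names(probs), br * bc, replace = TRUE, prob = probs))
  row <- rep(seq_len(n_rows), each = n_cols)
  col <- rep(seq_len(n_cols), times = n_rows)
  bidx <- (ceiling(row / block) - 1) * bc + ceiling(col / block)
  block_vals[bidx]
}

#' Generate a synthetic landscape with known ground truth
#'
#' @param config A [synthetic_config()].
#' @return A `cell_table` with one row per (cell, crop) where the crop is
#'   grown. The true linear predictor uses the *merged* class levels and the
#'   true combined nitrogen rate (fertilizer + manure) before outliers and
#'   missingness are injected, so the injected artefacts are measurement
#'   noise, not signal. The attribute `"true_coefficients"` carries the
#'   per-crop ground truth.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  grid <- grid_spec(cfg$n_rows, cfg$n_cols, xmin = -180, ymax = 60)
  nc <- n_cells(grid)
  cc <- grid_coords(grid)

  # contiguous longitudinal bands of regions
  band <- ceiling(seq_len(cfg$n_cols) / (cfg$n_cols / length(cfg$regions)))
  band <- pmin(band, length(cfg$regions))
  col_of <- (seq_len(nc) - 1) %% cfg$n_cols + 1
  region <- cfg$regions[band[col_of]]

  thz_raw <- sample_blocky(cfg$seed, "thz", cfg$n_rows, cfg$n_cols,
                           cfg$class_block, cfg$thz_probs)
  mst_raw <- sample_blocky(cfg$seed, "mst", cfg$n_rows, cfg$n_cols,
                           cfg$class_block, cfg$mst_probs)
  soil <- sample_blocky(cfg$seed, "soil", cfg$n_rows, cfg$n_cols,
                        cfg$class_block, cfg$soil_probs)
  thz_m <- unname(DEFAULT_CLASS_MERGE$thz[thz_raw])
  mst_m <- unname(DEFAULT_CLASS_MERGE$mst[mst_raw])

  ln <- function(key, par) draw(cfg$seed, key,
    stats::rlnorm(nc, par[["meanlog"]], par[["sdlog"]]))
  n_fert <- ln("n_fert", cfg$input_dist$n_fert)
  n_manure <- ln("n_manure", cfg$input_dist$n_manure)
  pesticides <- ln("pesticides", cfg$input_dist$pesticides)
  irrigation_tot <- draw(cfg$seed, "irrigation",
    ifelse(stats::runif(nc) < cfg$irrigated_frac,
           stats::rbeta(nc, 1.2, 2), 0))
  irrigation_reliant <- draw(cfg$seed, "irr_reliant", stats::rbeta(nc, 2, 2))
  mechanized <- draw(cfg$seed, "mechanized",
    as.numeric(stats::runif(nc) < cfg$mechanized_prob))

  coef_of <- function(crop) {
    if (!is.null(cfg$coefficients[[crop]])) cfg$coefficients[[crop]]
    else default_true_coefficients(crop)
  }
  truth <- stats::setNames(lapply(cfg$crops, coef_of), cfg$crops)

  tabs <- lapply(cfg$crops, function(crop) {
    b <- truth[[crop]]
    present <- draw(cfg$seed, paste0("presence_", crop),
      stats::runif(nc) < cfg$crop_presence)
    cells <- which(present)
    n <- length(cells)
    if (n == 0) return(NULL)
    area <- draw(cfg$seed, paste0("area_", crop),
      stats::rlnorm(n, cfg$area_dist[["meanlog"]], cfg$area_dist[["sdlog"]]))
    eta <- b$intercept +
      b$n_total * (n_fert[cells] + n_manure[cells]) +
      b$pesticides * pesticides[cells] +
      b$irrigation_tot * irrigation_tot[cells] +
      b$mechanized * mechanized[cells] +
      ifelse(thz_m[cells] == "T1", 0, b$thz[thz_m[cells]]) +
      ifelse(mst_m[cells] == "M2", 0, b$mst[mst_m[cells]]) +
      ifelse(soil[cells] == "S1", 0, b$soil[soil[cells]])
    mu <- exp(eta)
    y <- draw(cfg$seed, paste0("yield_", crop),
      stats::rgamma(n, shape = cfg$shape, scale = mu / cfg$shape))
    data.frame(
      cell_id = cells, lon = cc$lon[cells], lat = cc$lat[cells],
      region = region[cells], crop = crop,
      yield_kg_ha = y, harvested_area_ha = area,
      n_fert = n_fert[cells], n_manure = n_manure[cells], n_total = NA_real_,
      pesticides = pesticides[cells],
      irrigation_tot = irrigation_tot[cells],
      irrigation_reliant = irrigation_reliant[cells],
      mechanized = mechanized[cells],
      thz_class = if (cfg$raw_classes) thz_raw[cells] else thz_m[cells],
      mst_class = if (cfg$raw_classes) mst_raw[cells] else mst_m[cells],
      soil_class = soil[cells],
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, tabs)

  # implausible-value injection: multiplicative errors in the input rates
  if (cfg$outlier_rate > 0 && nrow(tab) > 0) {
    for (col in c("n_fert", "n_manure", "pesticides")) {
      hit <- draw(cfg$seed, paste0("outlier_sel_", col),
        stats::runif(nrow(tab)) < cfg$outlier_rate)
      mult <- draw(cfg$seed, paste0("outlier_mag_", col),
        stats::runif(nrow(tab), cfg$outlier_range[1], cfg$outlier_range[2]))
      tab[[col]][hit] <- tab[[col]][hit] * mult[hit]
    }
  }

  # missing-at-random holes
  drop_at <- function(col, rate, key) {
    if (rate > 0) {
      hit <- draw(cfg$seed, key, stats::runif(nrow(tab)) < rate)
      tab[[col]][hit] <<- NA
    }
  }
  miss <- cfg$missingness
  drop_at("pesticides", miss[["pesticides"]], "miss_pesticides")
  drop_at("mechanized", miss[["mechanized"]], "miss_mechanized")
  drop_at("n_fert", miss[["n_fert"]], "miss_n_fert")
  if (!is.na(miss["classes"]) && miss[["classes"]] > 0) {
    for (col in c("thz_class", "mst_class", "soil_class")) {
      drop_at(col, miss[["classes"]], paste0("miss_", col))
    }
  }

  tab <- tab[order(tab$crop, tab$cell_id), ]
  rownames(tab) <- NULL
  out <- validate_cell_table(tab)
  attr(out, "true_coefficients") <- truth
  attr(out, "grid") <- grid
  out
}

#' Tiny worked-example fixtures
#'
#' Hand-sized cell tables (one to a few rows) whose expected downstream
#' outputs can be computed on paper; used throughout the test suite and in
#' the documentation.
#'
#' \describe{
#'   \item{`n_phase1_100units`}{A single cell applying 100 units of N on unit
#'     harvested area — the cell *is* the whole world, so under a 10% global
#'     surplus fraction the phase-1 reallocation must return exactly 10
#'     units.}
#'   \item{`draft_cattle_100ha`}{A single 100-ha cell: at 5 ha per head it
#'     needs 20 draft cattle, whose manure works out to
#'     \eqn{39.77 \times 20 / 100 = 7.954} kg N ha^-1.}
#'   \item{`clip_positive_rc`}{A single cell whose observed yield (500 kg/ha)
#'     sits far below what any reasonable fitted response predicts from its
#'     inputs, so the predicted relative change is positive and must be
#'     clipped to zero.}
#' }
#'
#' @param name Fixture name.
#' @return A one-row `cell_table`.
#' @export
make_worked_fixture <- function(name) {
  base_row <- data.frame(
    cell_id = 1L, lon = 0.5 / 24, lat = 60 - 0.5 / 24,
    region = "Europe", crop = "wheat",
    yield_kg_ha = 3000, harvested_area_ha = 1,
    n_fert = 100, n_manure = 0, n_total = NA_real_, pesticides = 2,
    irrigation_tot = 0.5, irrigation_reliant = 0.4, mechanized = 1,
    thz_class = "T6", mst_class = "M4", soil_class = "S3",
    stringsAsFactors = FALSE
  )
  tab <- switch(name,
    n_phase1_100units = base_row,
    draft_cattle_100ha = {
      r <- base_row
      r$harvested_area_ha <- 100
      r$n_fert <- 50
      r
    },
    clip_positive_rc = {
      r <- base_row
      r$yield_kg_ha <- 500
      r$harvested_area_ha <- 1000
      r$n_fert <- 150
      r
    },
    stop("unknown fixture name: ", name,
         " (known: n_phase1_100units, draft_cattle_100ha, clip_positive_rc)")
  )
  validate_cell_table(tab)
}
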