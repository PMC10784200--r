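# Merging of raw agro-climatic codes into the modelling levels.
# Thermal: the sparsely occupied cold codes (temperate cool, boreal, arctic:
# raw T7-T9) collapse into one level T7. Moisture: the two driest (M1, M2)
# and the two wettest (M6, M7) raw growing-period codes collapse into M2
# (LGP < 120 d) and M6 (LGP 270+ d). Soil/terrain codes pass through.
DEFAULT_CLASS_MERGE <- list(
  thz = c(T1 = "T1", T2 = "T2", T3 = "T3", T4 = "T4", T5 = "T5", T6 = "T6",
          T7 = "T7", T8 = "T7", T9 = "T7"),
  mst = c(M1 = "M2", M2 = "M2", M3 = "M3", M4 = "M4", M5 = "M5",
          M6 = "M6", M7 = "M6"),
  soil = c(S1 = "S1", S2 = "S2", S3 = "S3", S4 = "S4", S5 = "S5", L3 = "L3")
)

new_report <- function() {
  structure(
    list(steps = data.frame(step = character(0), rows_in = integer(0),
                            rows_removed = integer(0), rows_out = integer(0),
                            fraction_removed = numeric(0),
                            stringsAsFactors = FALSE),
         thresholds = list(), production_share_removed = NA_real_),
    class = "cleaning_report"
  )
}

add_step <- function(report, step, rows_in, rows_out) {
  removed <- rows_in - rows_out
  stopifnot(removed >= 0)
  report$steps <- rbind(report$steps, data.frame(
    step = step, rows_in = rows_in, rows_removed = removed,
    rows_out = rows_out,
    fraction_removed = if (rows_in > 0) removed / rows_in else 0,
    stringsAsFactors = FALSE
  ))
  report
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("cleaning_report\n")
  print(x$steps, row.names = FALSE)
  if (!is.na(x$production_share_removed)) {
    cat(sprintf("production share removed by area filter: %.4f\n",
                x$production_share_removed))
  }
  if (length(x$thresholds) > 0) {
    cat("trim thresholds:\n")
    for (nm in names(x$thresholds)) {
      th <- x$thresholds[[nm]]
      cat(sprintf("  %s: percentile %.4g -> threshold %s\n",
                  nm, th$percentile, format(th$threshold, digits = 6)))
    }
  }
  invisible(x)
}

#' Write a cleaning report to CSV and a text log
#'
#' @param report A `cleaning_report`.
#' @param path CSV destination; a `.log` sibling with the human-readable form
#'   is written next to it.
#' @export
write_cleaning_report <- function(report, path) {
  utils::write.csv(report$steps, path, row.names = FALSE)
  log_path <- sub("\\.csv$", ".log", path)
  sink(log_path); on.exit(sink())
  print(report)
  invisible(path)
}

merge_reports <- function(a, b) {
  a$steps <- rbind(a$steps, b$steps)
  a$thresholds <- c(a$thresholds, b$thresholds)
  if (is.na(a$production_share_removed)) {
    a$production_share_removed <- b$production_share_removed
  }
  a
}

#' Remove cells with small harvested area
#'
#' Rows whose crop-specific harvested area is strictly below `min_ha` are
#' dropped: tiny slivers would otherwise carry the same weight as
#' multi-thousand-hectare cells. The report records, besides row counts, the
#' share of total production (yield x area) held by the removed rows — the
#' quantity that justifies the filter, since the removed slivers typically
#' hold a few percent of production while being a large fraction of rows.
#'
#' @param table A `cell_table` with harvested area on every row.
#' @param min_ha Threshold in hectares; cells at exactly `min_ha` are kept.
#' @return `list(table, report)`.
#' @export
filter_min_area <- function(table, min_ha = 100) {
  if (any(is.na(table$harvested_area_ha))) {
    stop("harvested_area_ha must be present on all rows")
  }
  keep <- table$harvested_area_ha >= min_ha
  prod_all <- sum(table$yield_kg_ha * table$harvested_area_ha, na.rm = TRUE)
  prod_rm <- sum(table$yield_kg_ha[!keep] * table$harvested_area_ha[!keep],
                 na.rm = TRUE)
  report <- new_report()
  report <- add_step(report, "area_filter", nrow(table), sum(keep))
  report$production_share_removed <- if (prod_all > 0) prod_rm / prod_all else 0
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(table = out, report = report)
}

#' Resolve missing values
#'
#' Two policies, per the provenance of the gaps. Pesticide and mechanization
#' coverage is structurally sparse and has no established dependence on the
#' other variables, so rows missing either are removed outright.  The
#' fertilizer and agro-climatic class layers have small scattered gaps; those
#' are forward-filled (last observation carried forward) within each crop in
#' `cell_id` order, the row-major grid order. Rows whose gap has no preceding
#' value to carry are dropped.
#'
#' @param table A `cell_table`.
#' @return `list(table, report)`.
#' @export
handle_missing <- function(table) {
  ffill_cols <- c("n_fert", "thz_class", "mst_class", "soil_class")
  for (col in c("pesticides", "mechanized", ffill_cols)) {
    if (nrow(table) > 0 && all(is.na(table[[col]]))) {
      stop("column entirely missing, cannot clean: ", col)
    }
  }
  report <- new_report()

  keep <- !is.na(table$pesticides) & !is.na(table$mechanized)
  report <- add_step(report, "drop_missing_pesticides_mechanized",
                     nrow(table), sum(keep))
  tab <- table[keep, , drop = FALSE]

  tab <- tab[order(tab$crop, tab$cell_id), , drop = FALSE]
  locf <- function(x) {
    idx <- cumsum(!is.na(x))
    out <- rep(NA, length(x))
    filled <- idx > 0
    out[filled] <- x[!is.na(x)][idx[filled]]
    out
  }
  n_in <- nrow(tab)
  for (crop in unique(tab$crop)) {
    sel <- tab$crop == crop
    for (col in ffill_cols) tab[[col]][sel] <- locf(tab[[col]][sel])
  }
  complete <- stats::complete.cases(tab[, ffill_cols, drop = FALSE])
  report <- add_step(report, "forward_fill_then_drop_leading", n_in,
                     sum(complete))
  out <- tab[complete, , drop = FALSE]
  rownames(out) <- NULL
  list(table = out, report = report)
}

# percentile with linear interpolation between order statistics
trim_percentile <- function(x, p) stats::quantile(x, p / 100, type = 7,
                                                  names = FALSE)

DEFAULT_TRIM_SPEC <- c(n_fert = 99.9, n_manure = 99, pesticides = 99.9,
                       yield_kg_ha = 99.9)

#' Trim implausibly large values
#'
#' For each crop and each column in `spec`, the per-crop percentile threshold
#' is computed (linear interpolation between order statistics) and rows with
#' values strictly above it are removed. Values exactly at the threshold are
#' retained. Thresholds are recorded in the report so the trim is auditable.
#'
#' @param table A `cell_table`.
#' @param spec Named numeric vector of percentiles, e.g.
#'   `c(n_fert = 99.9, n_manure = 99)`. Defaults trim fertilizer, pesticides
#'   and yield at the 99.9th percentile and manure at the 99th.
#' @return `list(table, report)`.
#' @export
trim_outliers <- function(table, spec = DEFAULT_TRIM_SPEC) {
  report <- new_report()
  tab <- table
  for (col in names(spec)) {
    n_in <- nrow(tab)
    keep <- rep(TRUE, n_in)
    for (crop in unique(tab$crop)) {
      sel <- which(tab$crop == crop)
      v <- tab[[col]][sel]
      ok <- !is.na(v)
      if (!any(ok)) next
      thr <- trim_percentile(v[ok], spec[[col]])
      report$thresholds[[paste(crop, col, sep = ".")]] <-
        list(column = col, crop = crop, percentile = spec[[col]],
             threshold = thr,
             definition = "linear interpolation between order statistics")
      keep[sel][ok & v > thr] <- FALSE
    }
    tab <- tab[keep, , drop = FALSE]
    report <- add_step(report, paste0("trim_", col), n_in, nrow(tab))
  }
  rownames(tab) <- NULL
  list(table = tab, report = report)
}

#' Combine fertilizer and manure nitrogen
#'
#' `n_total = n_fert + n_manure`, computed only after the component columns
#' have been outlier-trimmed (so errors in either source are caught before
#' they are hidden in the sum), followed by a percentile trim of the combined
#' column itself.
#'
#' @param table A `cell_table` with `n_fert` and `n_manure` present.
#' @param percentile Trim percentile for the combined column.
#' @return `list(table, report)`.
#' @export
combine_nitrogen <- function(table, percentile = 99.9) {
  if (any(is.na(table$n_fert)) || any(is.na(table$n_manure))) {
    stop("n_fert and n_manure must be complete before combining")
  }
  table$n_total <- table$n_fert + table$n_manure
  trimmed <- trim_outliers(table, c(n_total = percentile))
  trimmed
}

#' Merge agro-climatic class levels
#'
#' Relabels raw class codes to the merged modelling levels (see
#' `DEFAULT_CLASS_MERGE`): cold thermal codes into one level, the extreme
#' growing-period codes fused pairwise. An unmapped code is an error — the
#' merge map must be a total function on the raw codes.
#'
#' @param table A `cell_table`.
#' @param map List with named character vectors `thz`, `mst`, `soil` mapping
#'   raw code to merged code.
#' @return The relabelled table, with level counts in attribute
#'   `"level_counts"`.
#' @export
merge_classes <- function(table, map = DEFAULT_CLASS_MERGE) {
  cols <- c(thz = "thz_class", mst = "mst_class", soil = "soil_class")
  for (k in names(cols)) {
    col <- cols[[k]]
    v <- table[[col]]
    mapped <- unname(map[[k]][v])
    bad <- !is.na(v) & is.na(mapped)
    if (any(bad)) {
      stop("unmapped ", col, " codes: ",
           paste(unique(v[bad]), collapse = ", "))
    }
    table[[col]] <- mapped
  }
  attr(table, "level_counts") <- lapply(cols, function(col) {
    table(table[[col]], useNA = "ifany")
  })
  table
}

#' Generalized variance inflation factors
#'
#' Multicollinearity diagnostic that remains valid for multi-level
#' categorical predictors. Categorical predictors are dummy-coded; with
#' \eqn{R} the correlation matrix of all dummy-coded predictor columns,
#' \eqn{R_j} its block for predictor \eqn{j} and \eqn{R_{-j}} the block for
#' all others, \eqn{GVIF_j = \det(R_j)\det(R_{-j})/\det(R)}. For comparison
#' across predictors with different numbers of coefficients the scaled form
#' \eqn{GVIF^{1/(2 Df)}} is reported, with \eqn{Df} the number of dummy
#' columns; its square equals the ordinary VIF when \eqn{Df = 1} and is the
#' quantity held against the usual VIF alarm thresholds of 5 and 10.
#'
#' @param table Data frame holding the predictors.
#' @param predictors Character vector of column names (>= 2). Character
#'   columns are treated as categorical and dummy-coded against their first
#'   level.
#' @return Data frame with one row per predictor: `df`, `gvif`,
#'   `gvif_scaled` (\eqn{GVIF^{1/(2Df)}}), `gvif_scaled_sq`, and logical
#'   flags `flag5`, `flag10`. A singular design yields infinite GVIFs and
#'   flags rather than an error.
#' @export
compute_gvif <- function(table, predictors) {
  if (length(predictors) < 2) stop("need at least 2 predictors")
  missing_cols <- setdiff(predictors, names(table))
  if (length(missing_cols) > 0) {
    stop("predictors not in table: ", paste(missing_cols, collapse = ", "))
  }
  dat <- table[, predictors, drop = FALSE]
  if (any(!stats::complete.cases(dat))) {
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  }
  blocks <- list()
  for (p in predictors) {
    v <- dat[[p]]
    if (is.character(v) || is.factor(v)) {
      f <- factor(v)
      if (nlevels(f) < 2) stop("predictor has a single level: ", p)
      m <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(p, levels(f)[-1])
      blocks[[p]] <- m
    } else {
      if (stats::var(v) == 0) stop("constant column: ", p)
      blocks[[p]] <- matrix(v, ncol = 1, dimnames = list(NULL, p))
    }
  }
  X <- do.call(cbind, blocks)
  R <- stats::cor(X)
  detR <- det(R)
  df <- vapply(blocks, ncol, integer(1))
  col_of <- rep(seq_along(blocks), df)

  gvif <- vapply(seq_along(blocks), function(j) {
    jj <- col_of == j
    num <- det(R[jj, jj, drop = FALSE]) * det(R[!jj, !jj, drop = FALSE])
    if (detR <= .Machine$double.eps * nrow(R)) Inf else num / detR
  }, numeric(1))

  scaled <- gvif^(1 / (2 * df))
  out <- data.frame(
    predictor = predictors, df = df, gvif = gvif,
    gvif_scaled = scaled, gvif_scaled_sq = scaled^2,
    flag5 = scaled^2 > 5, flag10 = scaled^2 > 10,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Run the full cleaning ledger
#'
#' Applies the cleaning steps in their fixed order — area filter, missing-data
#' handling, per-column percentile trims, nitrogen merge, post-merge trim of
#' the combined nitrogen, class merge — and accumulates a single telescoping
#' report.
#'
#' @param table A raw `cell_table`.
#' @param min_ha Area threshold (ha).
#' @param trim_spec Percentile spec for [trim_outliers()].
#' @param n_total_percentile Trim percentile for the combined nitrogen.
#' @param class_map Merge map for [merge_classes()].
#' @return `list(table, report)`.
#' @export
clean_cells <- function(table, min_ha = 100, trim_spec = DEFAULT_TRIM_SPEC,
                        n_total_percentile = 99.9,
                        class_map = DEFAULT_CLASS_MERGE) {
  s1 <- filter_min_area(table, min_ha)
  s2 <- handle_missing(s1$table)
  s3 <- trim_outliers(s2$table, trim_spec)
  s4 <- combine_nitrogen(s3$table, n_total_percentile)
  tab <- merge_classes(s4$table, class_map)
  report <- Reduce(merge_reports,
                   list(s1$report, s2$report, s3$report, s4$report))
  list(table = tab, report = report)
}
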