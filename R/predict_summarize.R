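#' Clipped relative yield change
#'
#' \eqn{RC = (Y_{PC} - Y_{ref}) / Y_{ref}}, with values above zero set to
#' zero: a yield *increase* under catastrophic conditions is not credible and
#' a positive prediction is read as "stable yield" instead. The reference is
#' normally the observed baseline yield; the model's own baseline prediction
#' can be supplied instead when the quantity of interest is the pure
#' scenario effect (it makes the no-change scenario map to exactly zero).
#'
#' @param y_pred Predicted yields (kg ha^-1), positive.
#' @param y_ref Reference yields (kg ha^-1), strictly positive.
#' @return Relative change in \eqn{[-1, 0]} per cell.
#' @export
relative_change <- function(y_pred, y_ref) {
  if (any(is.na(y_ref)) || any(y_ref <= 0)) {
    stop("reference yields must be strictly positive")
  }
  pmin((y_pred - y_ref) / y_ref, 0)
}

#' Weighted mean with a normal-approximation confidence interval
#'
#' The interval uses the effective sample size
#' \eqn{n_{eff} = (\sum w)^2 / \sum w^2}, which discounts concentration of
#' weight on few rows; with equal weights it reduces to the ordinary
#' mean-and-CI.
#'
#' @param values Numeric vector.
#' @param weights Non-negative weights with a positive sum.
#' @param conf_level Interval coverage.
#' @return `list(mean, ci_low, ci_high, n_eff)`.
#' @export
weighted_mean_ci <- function(values, weights, conf_level = 0.95) {
  if (length(values) != length(weights)) stop("length mismatch")
  ok <- !is.na(values) & !is.na(weights)
  values <- values[ok]; weights <- weights[ok]
  if (any(weights < 0)) stop("weights must be non-negative")
  sw <- sum(weights)
  if (sw <= 0) stop("weights sum to zero")
  m <- sum(weights * values) / sw
  n_eff <- sw^2 / sum(weights^2)
  v <- sum(weights * (values - m)^2) / sw
  se <- sqrt(v / n_eff)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(mean = m, ci_low = m - z * se, ci_high = m + z * se, n_eff = n_eff)
}

#' Predict yields and relative changes for both phases
#'
#' Builds the phase-1 and phase-2 predictor tables, predicts per-cell yields
#' from the fitted per-crop models, and attaches the clipped relative change
#' against the chosen reference.
#'
#' @param fits Named list of `glm_fit` objects, one per crop.
#' @param table Cleaned baseline `cell_table` (merged classes, `n_total`
#'   present).
#' @param params A [scenario_params()].
#' @param reference `"observed"` compares scenario predictions with the
#'   baseline observed yield (the reported headline quantity);
#'   `"predicted"` compares with the model's prediction at baseline inputs,
#'   isolating the scenario effect.
#' @return A `prediction_table`: one row per (cell, crop, phase) with
#'   `y_pred`, `y_ref`, `rc`, and baseline `production` (yield x area). Rows
#'   whose class levels were not in the model's calibration support get
#'   missing predictions and are counted in attribute `"n_unsupported"`.
#' @export
predict_phases <- function(fits, table, params = scenario_params(),
                           reference = c("observed", "predicted")) {
  reference <- match.arg(reference)
  out <- list()
  n_unsupported <- 0L
  for (phase in c(1, 2)) {
    ptab <- build_phase_inputs(table, params, phase)
    for (crop in unique(table$crop)) {
      fit <- fits[[crop]]
      if (is.null(fit)) stop("no fitted model for crop: ", crop)
      sel <- ptab$crop == crop
      rows <- ptab[sel, , drop = FALSE]
      base_rows <- as.data.frame(table)[table$crop == crop, , drop = FALSE]
      supported <- rep(TRUE, nrow(rows))
      for (col in names(fit$xlevels)) {
        supported <- supported & rows[[col]] %in% fit$xlevels[[col]]
      }
      n_unsupported <- n_unsupported + sum(!supported)
      y_pred <- rep(NA_real_, nrow(rows))
      y_pred[supported] <- predict_mean(fit, rows[supported, , drop = FALSE])
      y_ref <- if (reference == "observed") {
        base_rows$yield_kg_ha
      } else {
        ref <- rep(NA_real_, nrow(rows))
        ref[supported] <- predict_mean(fit,
          base_rows[supported, , drop = FALSE])
        ref
      }
      rc <- rep(NA_real_, nrow(rows))
      ok <- supported & !is.na(y_ref)
      rc[ok] <- relative_change(y_pred[ok], y_ref[ok])
      out[[length(out) + 1L]] <- data.frame(
        cell_id = rows$cell_id, crop = crop, phase = phase,
        region = rows$region,
        y_pred = y_pred, y_ref = y_ref, rc = rc,
        yield_baseline = base_rows$yield_kg_ha,
        harvested_area_ha = rows$harvested_area_ha,
        production = base_rows$yield_kg_ha * rows$harvested_area_ha,
        stringsAsFactors = FALSE
      )
    }
  }
  pred <- do.call(rbind, out)
  rownames(pred) <- NULL
  class(pred) <- unique(c("prediction_table", class(pred)))
  attr(pred, "reference") <- reference
  attr(pred, "n_unsupported") <- n_unsupported
  pred
}

summarize_group <- function(rows, crop, phase, region, conf_level) {
  wy <- weighted_mean_ci(rows$y_pred, rows$harvested_area_ha, conf_level)
  wrc <- weighted_mean_ci(rows$rc, rows$production, conf_level)
  data.frame(
    crop = crop, phase = phase, region = region, n_cells = nrow(rows),
    yield_mean_w = wy$mean, yield_ci_low = wy$ci_low,
    yield_ci_high = wy$ci_high,
    rc_mean_w = wrc$mean, rc_ci_low = wrc$ci_low, rc_ci_high = wrc$ci_high,
    rc_min = min(rows$rc, na.rm = TRUE), rc_max = max(rows$rc, na.rm = TRUE),
    total_production = sum(rows$production, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Aggregate predictions by crop, phase and region
#'
#' Weighted summaries per crop x phase x region, plus "Global" region
#' rollups per crop x phase and all-crop rollups per phase. Predicted yield
#' is weighted by harvested area; relative change is weighted by baseline
#' production (yield x area) — the cells that matter most for food security
#' count most. Cells without model support (missing predictions) are
#' excluded from the weights.
#'
#' @param predictions A `prediction_table` from [predict_phases()].
#' @param conf_level Interval coverage for the weighted means.
#' @return A `summary_stats` data frame, one row per group.
#' @export
summarize_predictions <- function(predictions, conf_level = 0.95) {
  pred <- as.data.frame(predictions)
  if (any(is.na(pred$region))) stop("unmapped cells: region is missing")
  pred_ok <- pred[!is.na(pred$rc) & !is.na(pred$y_pred), , drop = FALSE]
  out <- list()
  for (phase in sort(unique(pred_ok$phase))) {
    pp <- pred_ok[pred_ok$phase == phase, , drop = FALSE]
    for (crop in sort(unique(pp$crop))) {
      pc <- pp[pp$crop == crop, , drop = FALSE]
      for (region in sort(unique(pc$region))) {
        rows <- pc[pc$region == region, , drop = FALSE]
        out[[length(out) + 1L]] <-
          summarize_group(rows, crop, phase, region, conf_level)
      }
      out[[length(out) + 1L]] <-
        summarize_group(pc, crop, phase, "Global", conf_level)
    }
    for (region in sort(unique(pp$region))) {
      rows <- pp[pp$region == region, , drop = FALSE]
      out[[length(out) + 1L]] <-
        summarize_group(rows, "all", phase, region, conf_level)
    }
    out[[length(out) + 1L]] <-
      summarize_group(pp, "all", phase, "Global", conf_level)
  }
  stats_tab <- do.call(rbind, out)
  rownames(stats_tab) <- NULL
  class(stats_tab) <- unique(c("summary_stats", class(stats_tab)))
  stats_tab
}

#' Write summary statistics as long-format CSV
#'
#' @param stats_tab A `summary_stats`.
#' @param path Destination path.
#' @export
write_summary_stats <- function(stats_tab, path) {
  wide <- as.data.frame(stats_tab)
  long <- stats::reshape(
    wide, direction = "long",
    varying = setdiff(names(wide), c("crop", "phase", "region")),
    v.names = "value",
    times = setdiff(names(wide), c("crop", "phase", "region")),
    timevar = "stat", idvar = c("crop", "phase", "region")
  )
  long <- long[order(long$crop, long$phase, long$region), ]
  utils::write.csv(long[, c("crop", "phase", "region", "stat", "value")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Bar chart of weighted yield reductions by crop and phase
#'
#' @param stats_tab A `summary_stats`.
#' @param by `"crop"` (global rollup per crop) or `"region"` (all-crop
#'   reductions per region).
#' @return A ggplot object (requires the `ggplot2` package).
#' @export
plot_reductions <- function(stats_tab, by = c("crop", "region")) {
  by <- match.arg(by)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_reductions requires the 'ggplot2' package")
  }
  df <- as.data.frame(stats_tab)
  df <- if (by == "crop") {
    df[df$region == "Global" & df$crop != "all", ]
  } else {
    df[df$region != "Global", ]
  }
  df$reduction_pct <- -100 * df$rc_mean_w
  df$phase <- factor(df$phase)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[by]], y = .data$reduction_pct, fill = .data$phase
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "production-weighted yield reduction [%]",
                  fill = "phase") +
    ggplot2::theme_minimal()
}
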