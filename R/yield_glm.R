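#' Model specification for the per-crop yield response
#'
#' The response is yield (kg ha^-1); the default predictor set is combined
#' nitrogen, pesticides, irrigated fraction, mechanization, and the three
#' agro-climatic class variables, entered linearly on the log scale with no
#' interactions. Categorical predictors are dummy-coded against fixed
#' reference levels (T1, M2, S1 by default).
#'
#' @param predictors Character vector of predictor columns.
#' @param references Named list of reference levels for the categorical
#'   predictors.
#' @return A `model_spec`.
#' @export
model_spec <- function(predictors = c("n_total", "pesticides",
                                      "irrigation_tot", "mechanized",
                                      "thz_class", "mst_class", "soil_class"),
                       references = list(thz_class = "T1", mst_class = "M2",
                                         soil_class = "S1")) {
  structure(list(predictors = predictors, references = references,
                 response = "yield_kg_ha", link = "log"),
            class = "model_spec")
}

#' Split a table into calibration and validation sets
#'
#' Reproducible random partition: disjoint, exhaustive, sizes differing from
#' the exact split by at most one row.
#'
#' @param table A `cell_table`.
#' @param fraction Calibration fraction, in (0, 1).
#' @param seed Seed for the split. The default is a fixed documented constant
#'   so that a pipeline run is reproducible without configuration.
#' @return `list(calibration, validation, seed)`.
#' @export
split_sample <- function(table, fraction = 0.8, seed = 20101L) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(table)
  if (n < 5) stop("table too small to split (", n, " rows)")
  idx <- draw(seed, "split", sample.int(n, round(fraction * n)))
  cal <- table[sort(idx), , drop = FALSE]
  val <- table[setdiff(seq_len(n), idx), , drop = FALSE]
  rownames(cal) <- rownames(val) <- NULL
  list(calibration = cal, validation = val, seed = seed)
}

prepare_design <- function(table, spec) {
  dat <- as.data.frame(table)
  for (col in names(spec$references)) {
    if (!col %in% spec$predictors) next
    ref <- spec$references[[col]]
    f <- factor(dat[[col]])
    if (!ref %in% levels(f)) {
      # fall back to the best-supported level so contrasts stay estimable
      # on data that happens not to contain the configured reference
      ref <- names(which.max(table(f)))
      message("reference level '", spec$references[[col]], "' absent from ",
              col, "; using most frequent level '", ref, "'")
    }
    dat[[col]] <- stats::relevel(f, ref = ref)
  }
  dat
}

glm_formula <- function(spec) {
  stats::as.formula(paste(spec$response, "~",
                          paste(spec$predictors, collapse = " + ")))
}

#' Fit the per-crop gamma GLM of yield on inputs and classes
#'
#' Yield is modelled as Gamma(shape, scale) with mean
#' \eqn{\mu = shape \times scale} and natural-log link,
#' \eqn{\ln\mu = \beta_0 + \beta_1 x_1 + \dots + \beta_p x_p}.
#' The fit is by iteratively reweighted least squares; the dispersion
#' \eqn{\phi} is the Pearson estimate from the calibration fit and the gamma
#' shape is its reciprocal \eqn{\hat\alpha = 1/\hat\phi}. Confidence
#' intervals are Wald at the given level. An intercept-only gamma GLM is
#' fitted alongside on the same rows as the null reference for the
#' pseudo-R-squared.
#'
#' @param calibration Calibration `cell_table`; response strictly positive.
#' @param spec A [model_spec()].
#' @param conf_level Coverage of the coefficient intervals.
#' @return A `glm_fit` with the coefficient table (estimate, Wald CI,
#'   p-value), shape/dispersion, calibration log-likelihood, row count, and
#'   the underlying fitted objects.
#' @export
fit_gamma_glm <- function(calibration, spec = model_spec(),
                          conf_level = 0.95) {
  dat <- prepare_design(calibration, spec)
  y <- dat[[spec$response]]
  if (any(is.na(y)) || any(y <= 0)) {
    stop("response must be strictly positive and complete for the gamma GLM")
  }
  has_na <- vapply(intersect(spec$predictors, names(dat)),
                   function(p) anyNA(dat[[p]]), logical(1))
  if (any(has_na)) {
    stop("missing values in predictor(s): ",
         paste(names(has_na)[has_na], collapse = ", "),
         " (run the cleaning steps first)")
  }
  form <- glm_formula(spec)
  X <- stats::model.matrix(form, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::glm(form, data = dat, family = stats::Gamma(link = "log"),
                    control = stats::glm.control(maxit = 100))
  smry <- summary(fit) # Pearson dispersion
  dispersion <- smry$dispersion
  shape <- 1 / dispersion

  est <- stats::coef(fit)
  se <- smry$coefficients[, "Std. Error"]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coef_table <- data.frame(
    term = names(est), estimate = unname(est),
    se = unname(se),
    ci_low = unname(est - z * se), ci_high = unname(est + z * se),
    p_value = unname(smry$coefficients[, 4]),
    stringsAsFactors = FALSE
  )
  null_fit <- stats::glm(stats::as.formula(paste(spec$response, "~ 1")),
                         data = dat, family = stats::Gamma(link = "log"))
  mu <- stats::fitted(fit)
  # a perfect (zero-dispersion) fit has no finite gamma likelihood
  loglik <- if (is.finite(shape) && shape > 0) {
    sum(stats::dgamma(y, shape = shape, scale = mu / shape, log = TRUE))
  } else {
    NA_real_
  }
  structure(
    list(spec = spec, glm = fit, null_glm = null_fit,
         coefficients = coef_table, dispersion = dispersion, shape = shape,
         conf_level = conf_level, loglik_calibration = loglik,
         n = nrow(dat), xlevels = fit$xlevels),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf(
    "gamma GLM (log link): %d rows, shape = %.3f (dispersion %.4f)\n",
    x$n, x$shape, x$dispersion
  ))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write the coefficient table of a fit to CSV
#'
#' @param fit A `glm_fit`.
#' @param path Destination path.
#' @export
write_glm_fit <- function(fit, path) {
  utils::write.csv(fit$coefficients, path, row.names = FALSE)
  invisible(path)
}

#' Predicted mean yield
#'
#' Inverse-link prediction \eqn{\mu = \exp(\eta)}; always strictly positive.
#'
#' @param fit A `glm_fit`.
#' @param table Rows with all predictor columns at levels seen in
#'   calibration.
#' @return Numeric vector of predicted yields (kg ha^-1).
#' @export
predict_mean <- function(fit, table) {
  dat <- as.data.frame(table)
  for (col in names(fit$xlevels)) {
    unseen <- setdiff(unique(dat[[col]]), fit$xlevels[[col]])
    if (length(unseen) > 0) {
      stop("unseen level(s) in ", col, ": ", paste(unseen, collapse = ", "))
    }
    dat[[col]] <- factor(dat[[col]], levels = fit$xlevels[[col]])
  }
  as.numeric(stats::predict(fit$glm, newdata = dat, type = "response"))
}

gamma_loglik <- function(y, mu, shape) {
  sum(stats::dgamma(y, shape = shape, scale = mu / shape, log = TRUE))
}

#' McFadden's pseudo-R-squared on held-out data
#'
#' \eqn{\rho^2 = 1 - \ln L_{model} / \ln L_{null}}, the likelihood-ratio
#' goodness-of-fit index for likelihood-based models. Both log-likelihoods
#' are evaluated on the validation rows under the gamma density with the
#' *calibration* shape of the full model, the null being the intercept-only
#' gamma GLM fitted on the calibration set. Values of 0.2-0.4 conventionally
#' indicate an excellent fit.
#'
#' @param fit A `glm_fit`.
#' @param validation Held-out `cell_table`.
#' @return `list(rho2, loglik_model, loglik_null, n)`.
#' @export
mcfadden_rho2 <- function(fit, validation) {
  if (nrow(validation) == 0) stop("validation set is empty")
  supported <- rep(TRUE, nrow(validation))
  for (col in names(fit$xlevels)) {
    supported <- supported & validation[[col]] %in% fit$xlevels[[col]]
  }
  if (!all(supported)) {
    warning(sum(!supported), " validation row(s) with class levels outside ",
            "calibration support excluded from the fit assessment")
    validation <- validation[supported, , drop = FALSE]
    if (nrow(validation) == 0) stop("no supported validation rows")
  }
  y <- validation[[fit$spec$response]]
  if (stats::var(y) == 0) {
    warning("validation response is constant; rho-squared is degenerate")
  }
  mu <- predict_mean(fit, validation)
  mu0 <- rep(exp(stats::coef(fit$null_glm)[[1]]), length(y))
  ll_model <- gamma_loglik(y, mu, fit$shape)
  ll_null <- gamma_loglik(y, mu0, fit$shape)
  list(rho2 = 1 - ll_model / ll_null,
       loglik_model = ll_model, loglik_null = ll_null, n = length(y))
}

#' Maximum attainable effect of a single factor
#'
#' Compares predictions at the observed minimum and maximum of one
#' continuous or binary factor while holding every other predictor constant,
#' expressed as a percentage of the maximum-input prediction:
#' \eqn{(\mu_{min} - \mu_{max})/\mu_{max}}. Under the log link with no
#' interactions this equals \eqn{\exp(\beta_j (x_{min} - x_{max})) - 1} and
#' does not depend on where the other predictors are held.
#'
#' @param fit A `glm_fit`.
#' @param table Table supplying the observed range of the factor.
#' @param factor_name One of the continuous or binary predictors.
#' @return `list(factor, x_min, x_max, mu_min, mu_max, percent_change)`;
#'   `percent_change` is in percent (e.g. -33 for a one-third loss).
#' @export
factor_effect <- function(fit, table, factor_name) {
  if (!factor_name %in% fit$spec$predictors) {
    stop("not a model predictor: ", factor_name)
  }
  v <- table[[factor_name]]
  if (is.character(v) || is.factor(v)) {
    stop("factor_effect is defined for continuous or binary inputs, not ",
         "multi-level categorical predictor '", factor_name, "'")
  }
  x_min <- min(v, na.rm = TRUE)
  x_max <- max(v, na.rm = TRUE)
  at <- as.data.frame(table)[1, , drop = FALSE]
  at_min <- at; at_min[[factor_name]] <- x_min
  at_max <- at; at_max[[factor_name]] <- x_max
  mu_min <- predict_mean(fit, at_min)
  mu_max <- predict_mean(fit, at_max)
  list(factor = factor_name, x_min = x_min, x_max = x_max,
       mu_min = mu_min, mu_max = mu_max,
       percent_change = 100 * (mu_min - mu_max) / mu_max)
}
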