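test_that("area filter is strict at the 100-ha boundary and reports production share", {
  tab <- tiny_table(3)
  tab$harvested_area_ha <- c(99.9, 100, 150)
  res <- filter_min_area(tab)
  expect_equal(res$table$harvested_area_ha, c(100, 150))

  # production share removed: direct summation oracle
  tab2 <- tiny_table(4)
  tab2$harvested_area_ha <- c(50, 200, 300, 400)
  tab2$yield_kg_ha <- c(1000, 2000, 3000, 1000)
  res2 <- filter_min_area(tab2)
  share <- (50 * 1000) / sum(tab2$harvested_area_ha * tab2$yield_kg_ha)
  expect_equal(res2$report$production_share_removed, share)

  empty <- filter_min_area(tiny_table(0))
  expect_equal(nrow(empty$table), 0)
  expect_equal(empty$report$steps$rows_removed, 0)
})

test_that("rows missing pesticides or mechanization are dropped; fertilizer and classes forward-fill", {
  tab <- tiny_table(3)
  tab$pesticides <- c(1, NA, 2)
  res <- handle_missing(tab)
  expect_equal(res$table$pesticides, c(1, 2))

  tab2 <- tiny_table(3)
  tab2$thz_class <- c("T3", NA, NA)
  res2 <- handle_missing(tab2)
  expect_equal(res2$table$thz_class, c("T3", "T3", "T3"))

  # a leading gap has nothing to carry and the row is dropped
  tab3 <- tiny_table(3)
  tab3$thz_class <- c(NA, "T4", NA)
  res3 <- handle_missing(tab3)
  expect_equal(res3$table$cell_id, c(2, 3))
  expect_equal(res3$table$thz_class, c("T4", "T4"))

  tab4 <- tiny_table(3)
  tab4$pesticides <- rep(NA_real_, 3)
  expect_error(handle_missing(tab4), "pesticides")
})

test_that("forward fill respects cell_id order within each crop", {
  a <- tiny_table(3, crop = "corn")
  b <- tiny_table(3, crop = "rice")
  b$n_fert <- c(NA, 10, 20) # leading gap in rice must not borrow from corn
  tab <- validate_cell_table(rbind(a, b))
  res <- handle_missing(tab)
  rice <- res$table[res$table$crop == "rice", ]
  expect_equal(rice$cell_id, c(2, 3))
})

test_that("percentile trim matches the linear-interpolation oracle and is strict", {
  tab <- tiny_table(1000)[rep(1, 1000), ]
  tab$cell_id <- 1:1000
  tab$yield_kg_ha <- c(rep(1.0, 999), 1000.0)
  tab <- validate_cell_table(tab)
  res <- trim_outliers(tab, c(yield_kg_ha = 99.9))
  # oracle: sorted x, h = (n-1)p + 1 = 999.001, threshold = 1 + 0.001*999
  thr <- 1 + 0.001 * (1000 - 1)
  rec <- res$report$thresholds[["corn.yield_kg_ha"]]
  expect_equal(rec$threshold, thr)
  expect_equal(nrow(res$table), 999)

  # equal values: nothing strictly above the percentile, nothing removed
  tab$yield_kg_ha <- rep(5, 1000)
  res2 <- trim_outliers(validate_cell_table(tab), c(yield_kg_ha = 99.9))
  expect_equal(nrow(res2$table), 1000)

  # values exactly at the threshold are retained: with the two largest
  # order statistics equal, the interpolated percentile equals them
  tab$yield_kg_ha <- c(rep(1, 998), 7, 7)
  tab <- validate_cell_table(tab)
  expect_equal(stats::quantile(tab$yield_kg_ha, 0.999, type = 7,
                               names = FALSE), 7)
  res3 <- trim_outliers(tab, c(yield_kg_ha = 99.9))
  expect_equal(nrow(res3$table), 1000)
})

test_that("manure and fertilizer trim at different percentiles on the same table", {
  set.seed(1)
  tab <- tiny_table(500)[rep(1, 500), ]
  tab$cell_id <- 1:500
  tab$n_fert <- rep(60, 500) # constant, so the first trim removes nothing
  tab$n_manure <- stats::rlnorm(500, log(15), 0.6)
  tab <- validate_cell_table(tab)
  res <- trim_outliers(tab, c(n_fert = 99.9, n_manure = 99))
  th <- res$report$thresholds
  expect_equal(th[["corn.n_fert"]]$percentile, 99.9)
  expect_equal(th[["corn.n_manure"]]$percentile, 99)
  expect_equal(th[["corn.n_manure"]]$threshold,
               stats::quantile(tab$n_manure, 0.99, type = 7, names = FALSE))
  expect_equal(nrow(res$table), 500 - sum(tab$n_manure >
                 th[["corn.n_manure"]]$threshold))
})

test_that("nitrogen merge sums the components and re-trims the sum", {
  tab <- tiny_table(3)
  tab$n_fert <- c(50, 50, 0)
  tab$n_manure <- c(20, 20, 0)
  res <- combine_nitrogen(tab)
  expect_equal(res$table$n_total, c(70, 70, 0))

  set.seed(2)
  big <- tiny_table(1000)[rep(1, 1000), ]
  big$cell_id <- 1:1000
  big$n_fert <- stats::rlnorm(1000, log(60), 0.3)
  big$n_manure <- stats::rlnorm(1000, log(15), 0.3)
  big$n_fert[17] <- 1e5 # one extreme combined value
  big <- validate_cell_table(big)
  res2 <- combine_nitrogen(big)
  expect_equal(nrow(res2$table), 999)
  expect_false(17 %in% res2$table$cell_id)
})

test_that("class merge collapses cold thermal and extreme moisture codes", {
  tab <- tiny_table(6)
  tab$thz_class <- c("T8", "T9", "T7", "T3", "T1", "T6")
  tab$mst_class <- c("M1", "M7", "M2", "M6", "M4", "M3")
  out <- merge_classes(tab)
  expect_equal(out$thz_class, c("T7", "T7", "T7", "T3", "T1", "T6"))
  expect_equal(out$mst_class, c("M2", "M6", "M2", "M6", "M4", "M3"))

  tab$thz_class[1] <- "T99"
  expect_error(merge_classes(tab), "unmapped")
})

test_that("cleaning ledger telescopes for arbitrary inputs", {
  for (seed in c(1, 2, 3)) {
    tab <- generate_landscape(synthetic_config(seed = seed, n_rows = 20,
                                               n_cols = 20,
                                               crops = c("corn", "rice")))
    res <- clean_cells(tab)
    steps <- res$report$steps
    expect_equal(steps$rows_out, steps$rows_in - steps$rows_removed)
    # consecutive steps chain
    expect_equal(steps$rows_in[-1], steps$rows_out[-nrow(steps)])
    expect_equal(steps$rows_in[1], nrow(tab))
    expect_equal(steps$rows_out[nrow(steps)], nrow(res$table))
  }
})

test_that("GVIF is 1 for orthogonal predictors and flags a duplicated column", {
  n <- 64
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4) # exactly orthogonal to x1
  tab <- data.frame(x1 = x1, x2 = x2)
  res <- compute_gvif(tab, c("x1", "x2"))
  expect_equal(res$gvif, c(1, 1), tolerance = 1e-12)

  tab$x3 <- tab$x1
  res2 <- compute_gvif(tab, c("x1", "x2", "x3"))
  expect_true(all(is.infinite(res2$gvif[c(1, 3)])))
  expect_true(all(res2$flag10[c(1, 3)]))
})

test_that("GVIF equals 1/(1-r^2) for two predictors with forced correlation 0.8", {
  set.seed(8)
  n <- 200
  z1 <- scale(stats::rnorm(n))[, 1]
  e <- stats::rnorm(n)
  e <- scale(stats::residuals(stats::lm(e ~ z1)))[, 1]
  x2 <- 0.8 * z1 + sqrt(1 - 0.8^2) * e # sample correlation exactly 0.8
  expect_equal(stats::cor(z1, x2), 0.8, tolerance = 1e-12)
  res <- compute_gvif(data.frame(a = z1, b = x2), c("a", "b"))
  expect_equal(res$gvif, rep(1 / (1 - 0.64), 2), tolerance = 1e-10)
  expect_equal(res$gvif[1], 2.7778, tolerance = 1e-4)
})

test_that("GVIF for a one-column predictor satisfies the scaling identity", {
  tab <- generate_landscape(synthetic_config(seed = 4, n_rows = 20,
                                             n_cols = 20, crops = "corn",
                                             raw_classes = FALSE))
  tab <- clean_cells(tab)$table
  res <- compute_gvif(tab, c("n_total", "pesticides", "irrigation_tot",
                             "thz_class", "mst_class", "soil_class"))
  one <- res$df == 1
  # for Df = 1 the squared scaled GVIF is the GVIF itself
  expect_equal(res$gvif_scaled_sq[one], res$gvif[one], tolerance = 1e-10)
  expect_true(all(res$gvif >= 1 - 1e-8))
})

test_that("GVIF agrees with the standard regression-based diagnostic", {
  skip_if_not_installed("car")
  tab <- generate_landscape(synthetic_config(seed = 6, n_rows = 25,
                                             n_cols = 25, crops = "corn",
                                             raw_classes = FALSE))
  tab <- clean_cells(tab)$table
  preds <- c("n_total", "pesticides", "irrigation_tot", "mechanized",
             "thz_class", "mst_class", "soil_class")
  ours <- compute_gvif(tab, preds)
  dat <- tab
  for (col in c("thz_class", "mst_class", "soil_class")) {
    dat[[col]] <- factor(dat[[col]])
  }
  fit <- stats::lm(yield_kg_ha ~ n_total + pesticides + irrigation_tot +
                     mechanized + thz_class + mst_class + soil_class,
                   data = dat)
  ref <- car::vif(fit)
  expect_equal(ours$gvif, unname(ref[, "GVIF"]), tolerance = 1e-6)
})
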