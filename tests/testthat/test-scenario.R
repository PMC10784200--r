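test_that("default scenario constants encode the published accounting", {
  p <- scenario_params()
  expect_equal(p$surplus_ratio_n, 14477 / 118763)
  expect_equal(p$surplus_ratio_pesticides, p$surplus_ratio_n)
  expect_error(scenario_params(t_ng = -1))
  expect_error(scenario_params(surplus_ratio_n = 1.2), "\\(0, 1\\]")
})

test_that("excretion rate derives from the 2014 manure totals", {
  rate <- derive_excretion_rate()
  expect_equal(rate, 131000 * 1e6 * 0.437 / 1.44e9)
  expect_equal(round(rate), 40)
})

test_that("single-cell worked example: 100 units of N become 10 under a 10% surplus", {
  fx <- make_worked_fixture("n_phase1_100units")
  p <- scenario_params(surplus_ratio_n = 0.10)
  n1 <- nitrogen_phase1(fx, p, method = "reallocate")
  expect_equal(n1, 10, tolerance = 1e-12)
})

test_that("two equal-area cells scale by the printed surplus ratio", {
  tab <- tiny_table(2)
  tab$n_fert <- c(100, 50)
  tab$harvested_area_ha <- c(400, 400)
  n1 <- nitrogen_phase1(tab) # default ratio 14477/118763
  expect_equal(n1 / tab$n_fert, rep(14477 / 118763, 2), tolerance = 1e-12)
  expect_equal(n1[1], 100 * 0.121898, tolerance = 1e-4)
})

test_that("reallocation conserves the rationed global totals and equals uniform scaling", {
  for (seed in 1:5) {
    tab <- generate_landscape(synthetic_config(
      seed = seed, n_rows = 8, n_cols = 8, crops = c("corn", "rice"),
      missingness = c(pesticides = 0, mechanized = 0, n_fert = 0,
                      classes = 0), outlier_rate = 0
    ))
    p <- scenario_params()
    n_re <- nitrogen_phase1(tab, p, "reallocate")
    n_sc <- nitrogen_phase1(tab, p, "scale")
    expect_equal(n_re, n_sc, tolerance = 1e-13)
    for (crop in unique(tab$crop)) {
      s <- tab$crop == crop
      expect_equal(sum(n_re[s] * tab$harvested_area_ha[s]),
                   p$surplus_ratio_n *
                     sum(tab$n_fert[s] * tab$harvested_area_ha[s]),
                   tolerance = 1e-13)
    }
  }
})

test_that("pesticide rationing mirrors the nitrogen construction", {
  tab <- tiny_table(1)
  tab$pesticides <- 2.0
  pe1 <- pesticides_phase1(tab)
  expect_equal(pe1, 2.0 * 14477 / 118763, tolerance = 1e-12)
  expect_equal(pe1, 0.2438, tolerance = 1e-3)

  tab$pesticides <- 0
  expect_equal(pesticides_phase1(tab), 0)
})

test_that("draft-cattle manure arithmetic matches the worked example", {
  fx <- make_worked_fixture("draft_cattle_100ha")
  dc <- draft_cattle_manure(fx)
  expect_equal(dc$cattle, 20)                  # 100 ha at 5 ha per head
  expect_equal(dc$manure_rate, 39.77 * 20 / 100)
  expect_equal(dc$manure_rate, 7.954)

  dc2 <- draft_cattle_manure(fx, scenario_params(ha_per_head = 7.4))
  expect_equal(dc2$manure_rate, 39.77 / 7.4, tolerance = 1e-12)
  expect_equal(dc2$manure_rate, 5.374, tolerance = 1e-3)

  bad <- fx; bad$harvested_area_ha <- 0
  expect_error(draft_cattle_manure(bad), "positive")
})

test_that("surviving irrigation is the non-reliant fraction", {
  tab <- tiny_table(3)
  tab$irrigation_tot <- c(0.5, 0.8, 0.7)
  tab$irrigation_reliant <- c(0.4, 1, 0)
  expect_equal(irrigation_gcil(tab), c(0.30, 0, 0.7))

  tab$irrigation_reliant[1] <- 1.5
  expect_error(validate_cell_table(tab))
})

test_that("diesel stocks cover about 1.3 years of agricultural demand", {
  fc <- fuel_coverage()
  expect_equal(fc$coverage_years, 147000 / 111062)
  expect_gte(fc$coverage_years, 1)
  expect_true(fc$mechanization_unchanged)

  even <- scenario_params(fuel_stock_diesel_ktoe = 111062)
  expect_equal(fuel_coverage(even)$coverage_years, 1)
  short <- scenario_params(fuel_stock_diesel_ktoe = 1)
  expect_false(fuel_coverage(short)$mechanization_unchanged)
})

test_that("phase tables implement the stock assumptions", {
  tab <- generate_landscape(clean_config(51, 20, 20, crops = "corn"))
  tab <- clean_cells(tab)$table
  p <- scenario_params()

  ph1 <- build_phase_inputs(tab, p, 1)
  ph2 <- build_phase_inputs(tab, p, 2)

  # phase 2: all industrial inputs zero
  expect_true(all(ph2$n_fert == 0))
  expect_true(all(ph2$pesticides == 0))
  expect_true(all(ph2$mechanized == 0))

  # manure and irrigation identical across phases
  expect_identical(ph1$n_manure, ph2$n_manure)
  expect_identical(ph1$irrigation_tot, ph2$irrigation_tot)

  # phase 1 keeps machinery running on diesel stocks
  expect_identical(ph1$mechanized, tab$mechanized)

  # phase 1 nitrogen combines rationed fertilizer with draft manure
  expect_equal(ph1$n_total,
               p$surplus_ratio_n * tab$n_fert + ph1$n_manure,
               tolerance = 1e-12)

  # monotonicity: every phase-1 input >= its phase-2 counterpart
  for (col in c("n_total", "pesticides", "mechanized", "irrigation_tot")) {
    expect_true(all(ph1[[col]] >= ph2[[col]] - 1e-12))
  }

  expect_error(build_phase_inputs(tab, p, 3), "phase")
})

test_that("phase 1 with ratio 1, no reliant irrigation and matching manure is the identity", {
  tab <- generate_landscape(clean_config(53, 15, 15, crops = "corn"))
  tab <- clean_cells(tab)$table
  p <- scenario_params(surplus_ratio_n = 1)
  tab$irrigation_reliant <- 0
  tab$n_manure <- p$excretion_rate / p$ha_per_head
  tab$n_total <- tab$n_fert + tab$n_manure
  ph1 <- build_phase_inputs(tab, p, 1)
  expect_equal(ph1$n_total, tab$n_total, tolerance = 1e-12)
  expect_equal(ph1$pesticides, tab$pesticides, tolerance = 1e-12)
  expect_equal(ph1$irrigation_tot, tab$irrigation_tot, tolerance = 1e-12)
  expect_identical(ph1$mechanized, tab$mechanized)
})

test_that("depleted fuel stocks degrade phase-1 mechanization with a warning", {
  tab <- generate_landscape(clean_config(57, 10, 10, crops = "corn"))
  tab <- clean_cells(tab)$table
  p <- scenario_params(fuel_stock_diesel_ktoe = 1)
  expect_warning(ph1 <- build_phase_inputs(tab, p, 1), "zeroing")
  expect_true(all(ph1$mechanized == 0))
})
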