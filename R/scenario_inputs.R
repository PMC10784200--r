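#' Scenario constants for the infrastructure-loss phases
#'
#' All defaults are the published global accounting figures the phase
#' scenarios rest on: the projected 2020 global nitrogen use for crop
#' fertilization and its surplus (whose ratio is the phase-1 rationing
#' fraction), the cattle N excretion rate and draft working capacity behind
#' the manure term, the agricultural fuel demand and above-ground fuel
#' stocks behind the mechanization assumption, and the 2014 manure totals
#' from which the excretion rate derives.
#'
#' @param t_ng Global N projected for crop fertilization in 2020 (kt N).
#' @param t_ng1 Projected 2020 N surplus (kt N).
#' @param surplus_ratio_n Phase-1 N rationing fraction; defaults to
#'   `t_ng1 / t_ng` (about 0.122).
#' @param surplus_ratio_pesticides Phase-1 pesticide fraction; no production
#'   surplus data exist for pesticides, so it defaults to the nitrogen
#'   surplus share (about 10%).
#' @param excretion_rate Cattle N excretion (kg N head^-1 yr^-1).
#' @param ha_per_head Area one draft head can work (ha); 5 is the
#'   conservative figure, 7.4 the typical working capacity.
#' @param fuel_demand_ktoe Annual agricultural oil-product demand (ktoe,
#'   2018).
#' @param fuel_stock_gasoline_ktoe,fuel_stock_diesel_ktoe Above-ground
#'   stocks after the catastrophe (ktoe); machinery runs on diesel, gasoline
#'   is reserved for critical transport.
#' @param manure_total_kt Global manure N produced in 2014 (kt N).
#' @param cattle_share Share of that manure produced by cattle.
#' @param cattle_heads Global cattle headcount in 2014.
#' @return A `scenario_params` list.
#' @export
scenario_params <- function(t_ng = 118763,
                            t_ng1 = 14477,
                            surplus_ratio_n = t_ng1 / t_ng,
                            surplus_ratio_pesticides = surplus_ratio_n,
                            excretion_rate = 39.77,
                            ha_per_head = 5,
                            fuel_demand_ktoe = 111062,
                            fuel_stock_gasoline_ktoe = 172000,
                            fuel_stock_diesel_ktoe = 147000,
                            manure_total_kt = 131000,
                            cattle_share = 0.437,
                            cattle_heads = 1.44e9) {
  p <- list(
    t_ng = t_ng, t_ng1 = t_ng1,
    surplus_ratio_n = surplus_ratio_n,
    surplus_ratio_pesticides = surplus_ratio_pesticides,
    excretion_rate = excretion_rate, ha_per_head = ha_per_head,
    fuel_demand_ktoe = fuel_demand_ktoe,
    fuel_stock_gasoline_ktoe = fuel_stock_gasoline_ktoe,
    fuel_stock_diesel_ktoe = fuel_stock_diesel_ktoe,
    manure_total_kt = manure_total_kt, cattle_share = cattle_share,
    cattle_heads = cattle_heads
  )
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num) || any(unlist(p) <= 0)) {
    stop("all scenario parameters must be positive numbers")
  }
  # ratio 1 is admitted as the identity limit (no rationing), useful for
  # validating that the scenario machinery leaves baseline inputs untouched
  if (surplus_ratio_n > 1 || surplus_ratio_pesticides > 1) {
    stop("surplus ratios must lie in (0, 1]")
  }
  structure(p, class = "scenario_params")
}

#' Derive the cattle excretion rate from the published totals
#'
#' Manure N total times the cattle share, divided by the cattle headcount:
#' with the default 2014 figures,
#' \eqn{131000\,kt \times 0.437 / 1.44\times10^9 \approx 39.8} kg N head^-1
#' yr^-1.
#'
#' @param params A [scenario_params()].
#' @return Excretion rate in kg N head^-1 yr^-1.
#' @export
derive_excretion_rate <- function(params = scenario_params()) {
  params$manure_total_kt * 1e6 * params$cattle_share / params$cattle_heads
}

#' Phase-1 nitrogen reallocation
#'
#' Rations the global fertilizer N surplus back over the cells. The
#' bookkeeping path computes, per crop, each cell's fraction of the global
#' application
#' \deqn{N_{frac} = N_{fert} A_{crop} / \sum N_{fert} A_{crop},}
#' the new crop total
#' \deqn{N_{total,crop} = (\sum N_{fert} A_{crop} / T_{NG}) \times T_{NG1},}
#' and the reallocated rate
#' \deqn{N_{fert,1} = N_{total,crop} N_{frac} / A_{crop}.}
#' Algebraically this collapses to uniform scaling
#' \eqn{N_{fert,1} = (T_{NG1}/T_{NG}) N_{fert}}; both paths are implemented
#' and their equality is asserted to machine precision, guarding against a
#' mis-transcription of the bookkeeping.
#'
#' @param table A `cell_table` with `n_fert` and `harvested_area_ha`.
#' @param params A [scenario_params()].
#' @param method `"reallocate"` (the fraction / new-total / reallocate path)
#'   or `"scale"` (direct uniform scaling).
#' @return Numeric vector of phase-1 N application rates (same order as the
#'   table rows).
#' @export
nitrogen_phase1 <- function(table, params = scenario_params(),
                            method = c("reallocate", "scale")) {
  method <- match.arg(method)
  reallocate_rates(table, "n_fert", params$surplus_ratio_n, method)
}

#' Phase-1 pesticide rationing
#'
#' The surplus share of pesticide production is taken to equal the nitrogen
#' surplus share. In the printed bookkeeping the global pesticide total
#' enters the crop total both as divisor and factor, so it cancels and the
#' operation is the same fraction / reallocate construction as for nitrogen
#' with the nitrogen surplus ratio (or a user-supplied pesticide ratio).
#'
#' @inheritParams nitrogen_phase1
#' @return Numeric vector of phase-1 pesticide rates.
#' @export
pesticides_phase1 <- function(table, params = scenario_params(),
                              method = c("reallocate", "scale")) {
  method <- match.arg(method)
  reallocate_rates(table, "pesticides", params$surplus_ratio_pesticides,
                   method)
}

reallocate_rates <- function(table, col, ratio, method) {
  rate <- table[[col]]
  area <- table$harvested_area_ha
  if (any(is.na(rate)) || any(is.na(area))) {
    stop(col, " and harvested_area_ha must be complete")
  }
  out <- rep(NA_real_, nrow(table))
  for (crop in unique(table$crop)) {
    sel <- table$crop == crop
    total <- sum(rate[sel] * area[sel])
    if (total <= 0) {
      if (any(rate[sel] > 0)) stop("zero global ", col, " total for ", crop)
      out[sel] <- 0
      next
    }
    if (method == "scale") {
      out[sel] <- ratio * rate[sel]
    } else {
      frac <- rate[sel] * area[sel] / total     # cell's share of the world
      new_total <- total * ratio                # rationed global amount
      out[sel] <- new_total * frac / area[sel]  # back to a per-ha rate
      # the bookkeeping must collapse to uniform scaling; a discrepancy
      # means the reallocation was mis-implemented
      if (!isTRUE(all.equal(out[sel], ratio * rate[sel],
                            tolerance = 1e-12))) {
        stop("reallocation path disagrees with uniform scaling for ", crop)
      }
    }
  }
  out
}

#' Draft-cattle manure rates
#'
#' After the catastrophe only draft animals are kept; the cattle needed per
#' cell is the harvested area divided by the area one head can work,
#' \eqn{C_{crop} = A_{crop} / ha\_per\_head}, and the manure those animals
#' return is \eqn{M_{n,crop} = excretion \times C_{crop} / A_{crop}} — a
#' constant `excretion_rate / ha_per_head` kg N ha^-1, identical in both
#' phases.
#'
#' @param table A `cell_table` with positive harvested area.
#' @param params A [scenario_params()].
#' @return `list(cattle, manure_rate)`: head of cattle per (cell, crop) and
#'   manure N application rate (kg N ha^-1).
#' @export
draft_cattle_manure <- function(table, params = scenario_params()) {
  area <- table$harvested_area_ha
  if (any(is.na(area)) || any(area <= 0)) {
    stop("harvested_area_ha must be positive")
  }
  cattle <- area / params$ha_per_head
  manure <- params$excretion_rate * cattle / area
  list(cattle = cattle, manure_rate = manure)
}

#' Surviving irrigated fraction without grid power
#'
#' \eqn{I_{gcil} = I_{AC} (1 - I_{RC})}: the currently irrigated fraction
#' stripped of the part reliant on electricity or diesel. Used unchanged in
#' both phases — irrigation infrastructure cannot profit from first-year
#' stocks.
#'
#' @param table A `cell_table` with `irrigation_tot` and
#'   `irrigation_reliant` in \eqn{[0, 1]}.
#' @return Numeric vector of surviving irrigated fractions.
#' @export
irrigation_gcil <- function(table) {
  iac <- table$irrigation_tot
  irc <- table$irrigation_reliant
  if (any(is.na(iac)) || any(is.na(irc)) ||
      any(iac < 0 | iac > 1) || any(irc < 0 | irc > 1)) {
    stop("irrigation fractions must be complete and in [0, 1]")
  }
  iac * (1 - irc)
}

#' Years of agricultural fuel demand covered by diesel stocks
#'
#' With the default figures, 147000 ktoe of diesel against an annual demand
#' of 111062 ktoe covers about 1.3 years, so mechanization is left unchanged
#' in phase 1 (gasoline stays reserved for critical transport). If
#' user-supplied figures cover less than a year the phase-1 scenario departs
#' from the stock assumption and mechanization is zeroed, with a warning.
#'
#' @param params A [scenario_params()].
#' @return `list(coverage_years, mechanization_unchanged)`.
#' @export
fuel_coverage <- function(params = scenario_params()) {
  cov <- params$fuel_stock_diesel_ktoe / params$fuel_demand_ktoe
  list(coverage_years = cov, mechanization_unchanged = cov >= 1)
}

#' Build the predictor table for one scenario phase
#'
#' Phase 1 (first year, stocks rationed): fertilizer N scaled to the surplus
#' ratio and combined with draft-cattle manure into `n_total`, pesticides
#' scaled likewise, mechanization unchanged while diesel stocks cover the
#' year, irrigation reduced to the non-reliant fraction. Phase 2 (stocks
#' depleted): fertilizer, pesticides and mechanization all zero; manure and
#' irrigation as in phase 1.
#'
#' @param table Baseline `cell_table` (cleaned; positive areas).
#' @param params A [scenario_params()].
#' @param phase 1 or 2.
#' @return A `cell_table` with the predictor columns (`n_fert`, `n_manure`,
#'   `n_total`, `pesticides`, `irrigation_tot`, `mechanized`) replaced by
#'   their phase values; attribute `"phase"` records the phase.
#' @export
build_phase_inputs <- function(table, params = scenario_params(), phase) {
  if (!phase %in% c(1, 2)) stop("phase must be 1 or 2")
  out <- as.data.frame(table)
  dc <- draft_cattle_manure(table, params)
  igcil <- irrigation_gcil(table)
  if (phase == 1) {
    n1 <- nitrogen_phase1(table, params)
    out$n_fert <- n1
    out$pesticides <- pesticides_phase1(table, params)
    fc <- fuel_coverage(params)
    if (!fc$mechanization_unchanged) {
      warning(sprintf(
        "diesel stocks cover only %.2f years of demand; zeroing phase-1 mechanization (departure from the stock assumption)",
        fc$coverage_years
      ))
      out$mechanized <- 0
    }
  } else {
    out$n_fert <- 0
    out$pesticides <- 0
    out$mechanized <- 0
  }
  out$n_manure <- dc$manure_rate
  out$n_total <- out$n_fert + out$n_manure
  out$irrigation_tot <- igcil
  out <- validate_cell_table(out)
  attr(out, "phase") <- phase
  attr(out, "cattle") <- dc$cattle
  out
}
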