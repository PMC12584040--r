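# Annual simulation loop under scenario configurations, with stochastic
# parameter ensembles and trajectory summaries.
#
# Each annual step runs, in order: demand projection from income, prices
# and population; trade constrained around current net-import levels;
# least-cost country optimisation of timber area and intensity; global
# market aggregation and price-index update; and (periodically) the
# sliding-window re-estimation of harvest-curve parameters with the
# scenario's potential-yield trend applied multiplicatively in between.
# The first year is the initialisation, not a simulated step.

#' Scenario configuration
#'
#' Drivers are built from world base values with constant growth rates, so
#' a scenario is a compact set of knobs. Sampled-parameter distributions
#' (for ensembles) are `list(name = list(dist, ...))` entries with
#' `dist` one of `"lognormal"` (meanlog, sdlog), `"normal"` (mean, sd) or
#' `"uniform"` (min, max); supported names: `mgmt_cost`, `convert_cost`,
#' `trade_change_cost`, `lambda`, `trade_limit`, `yield_trend`,
#' `income_growth`, `pop_growth`, `ag_growth`.
#'
#' @param label Scenario label (free text, e.g. an SSP-RCP tag).
#' @param years Simulated calendar years (first year = initialisation).
#' @param income_growth,pop_growth,ag_growth Annual growth rates of GDP per
#'   capita, population and agricultural area.
#' @param yield_trend Annual multiplicative trend of potential yield
#'   (climate/CO2 effect applied to the fitted asymptote).
#' @param lambda Price adjustment rate in (0, 1].
#' @param trade_limit Allowed annual net-import change as a fraction of the
#'   current level.
#' @param trade_floor Absolute net-import band for zero-trade entrants
#'   (m3).
#' @param costs A [cost_params()] object.
#' @param viability_threshold Spin-up abandonment threshold (m3/ha/yr).
#' @param refit_every Years between sliding-window re-estimations.
#' @param window Sliding-window length (years).
#' @param sampled Sampled-parameter distributions (see above).
#' @param n_members Ensemble size (>= 1).
#' @param master_seed Master seed for member substreams.
#' @param snapshot_years Years at which cell-level harvest factors are
#'   stored (default first and last simulated year).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(label = "baseline",
                            years = 2020:2060,
                            income_growth = 0.015,
                            pop_growth = 0.005,
                            ag_growth = 0.002,
                            yield_trend = 0.002,
                            lambda = 0.05,
                            trade_limit = 0.15,
                            trade_floor = 1e5,
                            costs = cost_params(),
                            viability_threshold = 0.2,
                            refit_every = 10,
                            window = 160,
                            sampled = list(),
                            n_members = 30,
                            master_seed = 1,
                            snapshot_years = NULL) {
  stop_if(length(years) < 2, "need at least two years")
  stop_if(n_members < 1, "ensemble size must be >= 1")
  if (is.null(snapshot_years)) snapshot_years <- range(years)
  structure(as.list(environment()), class = "scenario_config")
}

# driver value at year t from a base value and a constant growth rate
grow <- function(base, rate, t, t0) base * (1 + rate)^(t - t0)

# Constrain desired net imports to the annual band and rebalance them so
# the global sum stays near zero (imports must be matched by exports on a
# single market); the residual imbalance is absorbed by the global stock.
clear_trade <- function(desired, current, weights, limit, floor_abs) {
  allowed <- constrain_net_imports(desired, current, limit, floor_abs)
  w <- weights / sum(weights)
  for (iter in 1:5) {
    imb <- sum(allowed)
    if (abs(imb) < 1e-9 * max(sum(abs(allowed)), 1)) break
    allowed <- constrain_net_imports(allowed - imb * w, current, limit,
                                     floor_abs)
  }
  allowed
}

# pooled demand per country at year t; returns list with per-commodity and
# pooled totals
project_demand <- function(world, config, year, price_index) {
  t0 <- config$years[1]
  income <- grow(world$countries$gdp_percap, config$income_growth, year, t0)
  pop <- grow(world$countries$population, config$pop_growth, year, t0)
  prices <- cbind(
    world$base_prices$price_industrial_roundwood,
    world$base_prices$price_wood_fuel
  ) * price_index / 100
  pred <- predict_percapita(income, prices, world$true_params)
  data.frame(
    country = world$countries$country,
    population = pop,
    income = income,
    demand_industrial_roundwood = pred$q_industrial_roundwood * pop,
    demand_wood_fuel = pred$q_wood_fuel * pop,
    demand_total = (pred$q_industrial_roundwood + pred$q_wood_fuel) * pop,
    percap_industrial_roundwood = pred$q_industrial_roundwood,
    percap_wood_fuel = pred$q_wood_fuel,
    stringsAsFactors = FALSE
  )
}

# one global-series record
global_record <- function(year, demand, harvest, shortfall, index, stock,
                          cells) {
  timber <- sum(cells$area_ha * cells$frac_timber)
  data.frame(
    year = year,
    demand_industrial_roundwood = sum(demand$demand_industrial_roundwood),
    demand_wood_fuel = sum(demand$demand_wood_fuel),
    demand_total = sum(demand$demand_total),
    harvest = harvest,
    shortfall = shortfall,
    price_index = index,
    stock = stock,
    area_timber_ha = timber,
    area_unmanaged_ha = sum(cells$area_ha * cells$frac_unmanaged),
    area_agri_ha = sum(cells$area_ha * cells$frac_agri),
    mean_intensity = if (timber > 0) {
      sum(cells$area_ha * cells$frac_timber * cells$r) / timber
    } else {
      NA_real_
    }
  )
}

snapshot_cells <- function(cells) {
  data.frame(cell = cells$cell,
             timber_ha = cells$area_ha * cells$frac_timber,
             r = cells$r, ymax = cells$ymax, k = cells$k, p = cells$p,
             stringsAsFactors = FALSE)
}

#' Run one scenario simulation
#'
#' Pure function of (world, config): no random draws occur inside the loop,
#' so repeated calls give identical output.
#'
#' @param world A [make_world()] object.
#' @param config A [scenario_config()].
#' @param refit_cache Optional named list (by year) of precomputed
#'   [sliding_window_refit()] results; the refits depend only on the yield
#'   tables and window, so ensembles share them across members.
#' @return List of class `sim_result`: `global` (annual data.frame),
#'   `country` (annual long data.frame), `snapshots` (named list of
#'   cell-level harvest-factor tables), `config`.
#' @export
run_simulation <- function(world, config, refit_cache = NULL) {
  stop_if(!inherits(world, "wood_world"), "world must be a wood_world")
  stop_if(!inherits(config, "scenario_config"),
          "config must be a scenario_config")
  years <- config$years
  t0 <- years[1]
  ids <- world$countries$country

  cells <- spinup_abandonment(world$cells, config$viability_threshold)
  cells$ymax0 <- cells$ymax # untrended fit, rescaled by the yield trend
  ag0 <- vapply(split(cells$area_ha * cells$frac_agri, cells$country),
                sum, numeric(1))[ids]

  index <- 100
  stock <- 0
  net <- world$base_net_imports[ids]
  net[is.na(net)] <- 0

  # initialisation year: meet base demand net of base trade
  demand <- project_demand(world, config, t0, index)
  harvest_c <- stats::setNames(numeric(length(ids)), ids)
  shortfall_c <- harvest_c
  cost_c <- harvest_c
  for (i in seq_along(ids)) {
    sel <- cells$country == ids[i]
    req <- required_harvest(demand$demand_total[i], net[i])
    dec <- optimize_country(req, cells[sel, ], config$costs)
    cells[sel, ] <- dec$cells[match(cells$cell[sel], dec$cells$cell),
                              names(cells)]
    harvest_c[i] <- dec$harvest
    shortfall_c[i] <- dec$shortfall
    cost_c[i] <- dec$cost
  }
  net <- stats::setNames(demand$demand_total - harvest_c, ids)

  globals <- list(global_record(t0, demand, sum(harvest_c),
                                sum(shortfall_c), index, stock, cells))
  country_rows <- list(cbind(demand, year = t0, harvest = harvest_c,
                             net_imports = net, shortfall = shortfall_c,
                             cost = cost_c))
  snapshots <- list()
  if (t0 %in% config$snapshot_years) {
    snapshots[[as.character(t0)]] <- snapshot_cells(cells)
  }

  for (t in years[-1]) {
    # sliding-window refit plus multiplicative potential-yield trend
    if ((t - t0) %% config$refit_every == 0) {
      fits <- refit_cache[[as.character(t)]]
      if (is.null(fits)) {
        fits <- sliding_window_refit(world$yield_tables, t, config$window)
      }
      idx <- match(cells$cell, names(fits))
      cells$ymax0 <- vapply(fits[idx], function(f) f$ymax, numeric(1))
      cells$k <- vapply(fits[idx], function(f) f$k, numeric(1))
      cells$p <- vapply(fits[idx], function(f) f$p, numeric(1))
    }
    cells$ymax <- cells$ymax0 * (1 + config$yield_trend)^(t - t0)

    demand <- project_demand(world, config, t, index)
    desired <- demand$demand_total - harvest_c
    allowed <- clear_trade(desired, net, demand$demand_total,
                           config$trade_limit, config$trade_floor)
    trade_cost <- config$costs$trade_change * abs(allowed - net)

    for (i in seq_along(ids)) {
      sel <- cells$country == ids[i]
      cells[sel, ] <- apply_agricultural_demand(
        cells[sel, ], grow(ag0[i], config$ag_growth, t, t0)
      )
      req <- required_harvest(demand$demand_total[i], allowed[i])
      dec <- optimize_country(req, cells[sel, ], config$costs)
      cells[sel, ] <- dec$cells[match(cells$cell[sel], dec$cells$cell),
                                names(cells)]
      harvest_c[i] <- dec$harvest
      shortfall_c[i] <- dec$shortfall
      cost_c[i] <- dec$cost + trade_cost[i]
    }
    net <- stats::setNames(allowed, ids)

    D <- sum(demand$demand_total)
    S <- sum(harvest_c)
    # global closure: sum(harvest + net imports - consumption) = stock change
    stock <- stock + S + sum(net) - D
    index <- update_price(index, D, S, config$lambda)

    globals[[length(globals) + 1]] <-
      global_record(t, demand, S, sum(shortfall_c), index, stock, cells)
    country_rows[[length(country_rows) + 1]] <-
      cbind(demand, year = t, harvest = harvest_c, net_imports = net,
            shortfall = shortfall_c, cost = cost_c)
    if (t %in% config$snapshot_years) {
      snapshots[[as.character(t)]] <- snapshot_cells(cells)
    }
  }

  structure(list(
    global = do.call(rbind, globals),
    country = do.call(rbind, country_rows),
    snapshots = snapshots,
    config = config
  ), class = "sim_result")
}

# draw one value from a sampled-parameter distribution spec
draw_param <- function(d) {
  switch(d$dist,
    lognormal = stats::rlnorm(1, d$meanlog, d$sdlog),
    normal = stats::rnorm(1, d$mean, d$sd),
    uniform = stats::runif(1, d$min, d$max),
    stop("unknown distribution: ", d$dist, call. = FALSE)
  )
}

# apply sampled values to a config copy
apply_sampled <- function(config, values) {
  for (nm in names(values)) {
    v <- values[[nm]]
    switch(nm,
      mgmt_cost = { config$costs$mgmt <- max(v, 0) },
      convert_cost = { config$costs$convert <- max(v, 0) },
      trade_change_cost = { config$costs$trade_change <- max(v, 0) },
      lambda = { config$lambda <- min(max(v, 1e-6), 1) },
      trade_limit = { config$trade_limit <- max(v, 1e-6) },
      yield_trend = { config$yield_trend <- v },
      income_growth = { config$income_growth <- v },
      pop_growth = { config$pop_growth <- v },
      ag_growth = { config$ag_growth <- v },
      stop("unknown sampled parameter: ", nm, call. = FALSE)
    )
  }
  config
}

#' Run a scenario ensemble
#'
#' Runs `config$n_members` simulations with parameters drawn per member
#' from `config$sampled`, using seeds derived by hashing (master seed,
#' member index) so ensemble size changes do not perturb earlier members.
#' Failed members are recorded and the summary is computed over completed
#' members with a warning.
#'
#' @param world A [make_world()] object.
#' @param config A [scenario_config()].
#' @return List of class `ensemble_result`: `summary` (per year and
#'   variable: median and 5th-95th percentile band), `members` (list of
#'   global series), `snapshots` (per member), `params` (sampled values per
#'   member), `failed` (indices).
#' @export
run_ensemble <- function(world, config) {
  refit_years <- config$years[-1]
  refit_years <- refit_years[(refit_years - config$years[1]) %%
                               config$refit_every == 0]
  refit_cache <- lapply(refit_years, function(t) {
    sliding_window_refit(world$yield_tables, t, config$window)
  })
  names(refit_cache) <- as.character(refit_years)

  members <- vector("list", config$n_members)
  snaps <- vector("list", config$n_members)
  params <- vector("list", config$n_members)
  failed <- integer(0)
  for (m in seq_len(config$n_members)) {
    set.seed(hash_seed(config$master_seed, m))
    values <- lapply(config$sampled, draw_param)
    cfg <- apply_sampled(config, values)
    res <- tryCatch(run_simulation(world, cfg, refit_cache),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, m)
      next
    }
    members[[m]] <- res$global
    snaps[[m]] <- res$snapshots
    params[[m]] <- values
  }
  if (length(failed) > 0) {
    warning(length(failed), " ensemble member(s) failed; summary over ",
            config$n_members - length(failed), " members")
  }
  ok <- setdiff(seq_len(config$n_members), failed)
  stop_if(length(ok) == 0, "all ensemble members failed")
  structure(list(
    summary = summarise_ensemble(members[ok]),
    members = members[ok],
    snapshots = snaps[ok],
    params = params[ok],
    failed = failed,
    config = config
  ), class = "ensemble_result")
}

#' Summarise ensemble trajectories
#'
#' Per output series and year: the median and the 90% interval (5th-95th
#' percentiles) across members.
#'
#' @param members List of global-series data.frames (same years).
#' @return Long data.frame: `year`, `variable`, `median`, `lower`, `upper`.
#' @export
summarise_ensemble <- function(members) {
  stop_if(length(members) == 0, "no members to summarise")
  years <- members[[1]]$year
  vars <- setdiff(names(members[[1]]), "year")
  out <- list()
  for (v in vars) {
    mat <- vapply(members, function(m) m[[v]], numeric(length(years)))
    mat <- matrix(mat, nrow = length(years))
    qs <- apply(mat, 1, stats::quantile, probs = c(0.05, 0.5, 0.95),
                na.rm = TRUE)
    out[[v]] <- data.frame(year = years, variable = v,
                           median = qs[2, ], lower = qs[1, ],
                           upper = qs[3, ], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ensemble factor decomposition between two snapshot years
#'
#' Applies [decompose_harvest()] to each member's cell snapshots and
#' summarises the multiplicative contributions with the ensemble median and
#' 90% interval.
#'
#' @param ensemble An `ensemble_result` whose config snapshot years include
#'   both years.
#' @param baseline_year,final_year Calendar years to compare.
#' @return data.frame per factor: `factor`, `median_pct`, `lower_pct`,
#'   `upper_pct`.
#' @export
decompose_ensemble <- function(ensemble, baseline_year, final_year) {
  by <- as.character(baseline_year)
  fy <- as.character(final_year)
  per <- lapply(ensemble$snapshots, function(sn) {
    stop_if(!(by %in% names(sn)) || !(fy %in% names(sn)),
            "snapshots missing for the requested years")
    decompose_harvest(harvest_factors(sn[[by]]),
                      harvest_factors(sn[[fy]]))
  })
  factors <- per[[1]]$factor
  out <- lapply(seq_along(factors), function(i) {
    v <- vapply(per, function(d) d$contribution_pct[i], numeric(1))
    data.frame(factor = factors[i],
               median_pct = stats::median(v),
               lower_pct = stats::quantile(v, 0.05, names = FALSE),
               upper_pct = stats::quantile(v, 0.95, names = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
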