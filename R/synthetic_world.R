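# Synthetic world generator: country panels, grids, yield tables and
# driver trajectories with the statistical structure the pipeline assumes,
# so every module is exercisable without external data.
#
# Income-consumption pairs follow the configured Engel structure
# (roundwood demand rising with income, wood-fuel budget share declining at
# high income); bilateral trade is constructed to be globally consistent so
# the apparent-consumption mass balance closes exactly at the world level.

#' Specification of a synthetic world
#'
#' Defaults describe a desk-scale world: 12 countries x 25 cells across
#' three biome archetypes (boreal slow / temperate medium / tropical fast
#' growth), log-normal income and population distributions, and a
#' demand-system parameterisation producing rising roundwood and
#' hump-shaped wood-fuel consumption in income.
#'
#' @param n_countries,cells_per_country World size (counts >= 1).
#' @param seed Master seed; every stream is derived from it.
#' @param base_year First simulated year (the initialisation year).
#' @param horizon Last year covered by driver trajectories.
#' @param income_meanlog,income_sdlog Log-normal GDP per capita
#'   (currency/person/yr).
#' @param pop_meanlog,pop_sdlog Log-normal population.
#' @param base_prices Global base prices (currency/m3) for industrial
#'   roundwood and wood fuel.
#' @param price_sdlog Country price dispersion (lognormal sigma).
#' @param consumption_noise_sd Multiplicative log-noise on generated
#'   per-capita consumption (0 = exact Engel curves).
#' @param trade_spread Half-range of the uniform net-trade share of
#'   consumption.
#' @param true_params Generating [demand_params()]; `NULL` for the default
#'   Engel structure.
#' @param co2_trend Per-year multiplicative yield-table cohort trend.
#' @param target_intensity Baseline area-weighted management intensity used
#'   to calibrate country cell areas (global mean of observed intensities).
#' @return List of class `world_spec`.
#' @export
world_spec <- function(n_countries = 12, cells_per_country = 25, seed = 1,
                       base_year = 2020, horizon = 2060,
                       income_meanlog = log(8000), income_sdlog = 1.1,
                       pop_meanlog = log(8e6), pop_sdlog = 0.8,
                       base_prices = c(industrial_roundwood = 100,
                                       wood_fuel = 50),
                       price_sdlog = 0.1,
                       consumption_noise_sd = 0.1,
                       trade_spread = 0.3,
                       true_params = NULL,
                       co2_trend = 0.001,
                       target_intensity = 0.018) {
  stop_if(n_countries < 1 || cells_per_country < 1, "counts must be >= 1")
  if (is.null(true_params)) {
    true_params <- demand_params(
      gamma = c(0.015, 0.10),
      alpha = c(0.003, 0.015, 0.982),
      beta_star = c(0.0020, 0.00001, 0.99799),
      A = 4000,
      curvature = 1.6
    )
  }
  structure(as.list(environment()), class = "world_spec")
}

# biome archetypes: Chapman-Richards growth parameters and typical latitude
biome_table <- function() {
  data.frame(
    biome = c("boreal", "temperate", "tropical"),
    lat = c(60, 45, 10),
    vmax = c(250, 350, 450),
    growth_rate = c(0.02, 0.035, 0.06),
    shape = c(1.3, 1.5, 1.8),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic world
#'
#' Builds the full fixture set: a base-year wood item record panel (long
#' format, with bilateral-consistent trade), country socioeconomic data,
#' a cell grid with land-cover fractions and growth parameters, stand-age
#' yield tables, and base-year harvest-curve fits. Country cell areas are
#' calibrated so the baseline harvest is met at the target area-weighted
#' management intensity. Bit-identical given the same spec (seed included).
#'
#' @param spec A [world_spec()].
#' @return List of class `wood_world`: `spec`, `countries`, `records`,
#'   `balance`, `observations`, `true_params`, `cells`, `yield_tables`,
#'   `base_net_imports`, `base_prices`.
#' @export
make_world <- function(spec = world_spec()) {
  stop_if(!inherits(spec, "world_spec"), "spec must be a world_spec")
  nc <- spec$n_countries
  ids <- sprintf("C%02d", seq_len(nc))
  biomes <- biome_table()

  set.seed(hash_seed(spec$seed, 1))
  countries <- data.frame(
    country = ids,
    biome = sample(biomes$biome, nc, replace = TRUE),
    population = stats::rlnorm(nc, spec$pop_meanlog, spec$pop_sdlog),
    gdp_percap = stats::rlnorm(nc, spec$income_meanlog, spec$income_sdlog),
    stringsAsFactors = FALSE
  )
  countries$lat <- biomes$lat[match(countries$biome, biomes$biome)] +
    stats::runif(nc, -5, 5)

  # country prices around the global base
  set.seed(hash_seed(spec$seed, 2))
  price_rw <- spec$base_prices[["industrial_roundwood"]] *
    stats::rlnorm(nc, 0, spec$price_sdlog)
  price_wf <- spec$base_prices[["wood_fuel"]] *
    stats::rlnorm(nc, 0, spec$price_sdlog)

  # per-capita consumption along the generating Engel curves (+ noise)
  set.seed(hash_seed(spec$seed, 3))
  pred <- predict_percapita(countries$gdp_percap, cbind(price_rw, price_wf),
                            spec$true_params)
  noise <- function(n) {
    if (spec$consumption_noise_sd > 0) {
      exp(stats::rnorm(n, 0, spec$consumption_noise_sd))
    } else {
      rep(1, n)
    }
  }
  cons <- cbind(
    industrial_roundwood = pred$q_industrial_roundwood * noise(nc) *
      countries$population,
    wood_fuel = pred$q_wood_fuel * noise(nc) * countries$population
  )

  # globally consistent net trade: shares recentred so net imports sum to 0
  set.seed(hash_seed(spec$seed, 4))
  net <- sapply(colnames(cons), function(cm) {
    s <- stats::runif(nc, -spec$trade_spread, spec$trade_spread)
    raw <- s * cons[, cm]
    raw - cons[, cm] * (sum(raw) / sum(cons[, cm]))
  })
  harvest <- cons - net # consumption = harvest + net imports

  # long item records; gross trade adds a matched base flow so every
  # country has observable trade prices
  gross_im <- 0.1 * cons + pmax(net, 0)
  gross_ex <- 0.1 * cons + pmax(-net, 0)
  item_split <- list(
    industrial_roundwood = data.frame(
      item = c("Industrial roundwood", "Wood pulp"),
      share = c(0.7, 0.3), unit = c("m3", "t"), ratio = c(1, 1.48)),
    wood_fuel = data.frame(
      item = c("Wood fuel", "Wood charcoal"),
      share = c(0.8, 0.2), unit = c("m3", "t"), ratio = c(1, 5.99))
  )
  raw_item <- c(industrial_roundwood = "Industrial roundwood",
                wood_fuel = "Wood fuel")
  recs <- list()
  price_mat <- cbind(industrial_roundwood = price_rw, wood_fuel = price_wf)
  for (cm in colnames(cons)) {
    recs[[length(recs) + 1]] <- data.frame(
      country = ids, year = spec$base_year, item = raw_item[[cm]],
      flow = "production", quantity = harvest[, cm], unit = "m3",
      value = NA_real_, stringsAsFactors = FALSE
    )
    sp <- item_split[[cm]]
    for (j in seq_len(nrow(sp))) {
      for (fl in c("import", "export")) {
        vol <- (if (fl == "import") gross_im[, cm] else gross_ex[, cm]) *
          sp$share[j]
        recs[[length(recs) + 1]] <- data.frame(
          country = ids, year = spec$base_year, item = sp$item[j],
          flow = fl, quantity = vol / sp$ratio[j], unit = sp$unit[j],
          value = vol * price_mat[, cm], stringsAsFactors = FALSE
        )
      }
    }
  }
  records <- do.call(rbind, recs)
  balance <- wood_balance(records)

  socio <- countries[, c("country", "population", "gdp_percap")]
  observations <- demand_observations(balance, socio)

  # cell grid with land-cover fractions and growth parameters
  set.seed(hash_seed(spec$seed, 5))
  ncell <- nc * spec$cells_per_country
  cells <- data.frame(
    cell = sprintf("%s_%03d", rep(ids, each = spec$cells_per_country),
                   rep(seq_len(spec$cells_per_country), nc)),
    country = rep(ids, each = spec$cells_per_country),
    stringsAsFactors = FALSE
  )
  cells$lat <- rep(countries$lat, each = spec$cells_per_country) +
    stats::runif(ncell, -3, 3)
  cells$area_ha <- cell_area_ha(cells$lat)
  ft <- stats::runif(ncell, 0.10, 0.35)
  fu <- stats::runif(ncell, 0.25, 0.50)
  fa <- stats::runif(ncell, 0.10, 0.25)
  fo <- stats::runif(ncell, 0.05, 0.30)
  tot <- ft + fu + fa + fo
  cells$frac_timber <- ft / tot
  cells$frac_unmanaged <- fu / tot
  cells$frac_agri <- fa / tot
  cells$frac_other <- fo / tot
  cells$protected <- stats::runif(ncell) < 0.1
  bio <- biomes[match(rep(countries$biome, each = spec$cells_per_country),
                      biomes$biome), ]
  cells$vmax <- bio$vmax * stats::rlnorm(ncell, 0, 0.15)
  cells$growth_rate <- bio$growth_rate * stats::rlnorm(ncell, 0, 0.1)
  cells$shape <- bio$shape

  trend_fun <- function(cohort) (1 + spec$co2_trend)^(cohort - 1850)
  yield_tables <- generate_yield_tables(
    cells, trend = trend_fun, seed = hash_seed(spec$seed, 6)
  )

  # base-year harvest-curve fits, then calibrate country areas so baseline
  # harvest is met at the target area-weighted intensity
  fits <- sliding_window_refit(yield_tables, spec$base_year)
  fit_idx <- match(cells$cell, names(fits))
  cells$ymax <- vapply(fits[fit_idx], function(f) f$ymax, numeric(1))
  cells$k <- vapply(fits[fit_idx], function(f) f$k, numeric(1))
  cells$p <- vapply(fits[fit_idx], function(f) f$p, numeric(1))
  cells$r <- spec$target_intensity

  harvest_pooled <- rowSums(harvest)
  for (i in seq_len(nc)) {
    sel <- cells$country == ids[i]
    cap <- sum(cells$area_ha[sel] * cells$frac_timber[sel] *
                 cell_yield_vec(cells[sel, ],
                                rep(spec$target_intensity, sum(sel))))
    scale <- harvest_pooled[i] / max(cap, 1e-9)
    cells$area_ha[sel] <- cells$area_ha[sel] * scale
  }

  base_net <- rowSums(net)
  names(base_net) <- ids

  structure(list(
    spec = spec,
    countries = countries,
    records = records,
    balance = balance,
    observations = observations,
    true_params = spec$true_params,
    cells = cells,
    yield_tables = yield_tables,
    base_net_imports = base_net,
    base_prices = data.frame(country = ids,
                             price_industrial_roundwood = price_rw,
                             price_wood_fuel = price_wf,
                             stringsAsFactors = FALSE)
  ), class = "wood_world")
}

#' @export
print.wood_world <- function(x, ...) {
  cat(sprintf(
    "Synthetic wood world: %d countries, %d cells, base year %d (seed %d)\n",
    nrow(x$countries), nrow(x$cells), x$spec$base_year, x$spec$seed))
  invisible(x)
}

#' Published summary figures used as arithmetic fixtures
#'
#' Named inputs for desk checks: the 2020 timber and total forest areas
#' (Mha), the median global/regional wood-demand increases to 2100 in a
#' middle-of-the-road scenario (million m3), the global roundwood harvest
#' in 1961 and 2022 (million m3), and the reference management intensity
#' whose reciprocal is a 50-year rotation.
#'
#' @return Named list of numeric fixtures.
#' @export
make_toy_printed_examples <- function() {
  list(
    baseline_areas = c(timber_Mha = 1460, total_forest_Mha = 4102),
    ssp2_demand_increase_Mm3 = c(global = 2935, asia = 987, africa = 1636),
    historical_harvest_Mm3 = c(y1961 = 2517, y2022 = 3983),
    rotation_intensity = 0.02
  )
}
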