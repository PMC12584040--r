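# Shared fixtures: worlds are built once per test session and reused.

.world_cache <- new.env(parent = emptyenv())

# small fast world for scenario tests
test_world_small <- function() {
  if (is.null(.world_cache$small)) {
    .world_cache$small <- make_world(world_spec(
      n_countries = 6, cells_per_country = 8, seed = 7, horizon = 2050
    ))
  }
  .world_cache$small
}

# default desk-scale world
test_world_default <- function() {
  if (is.null(.world_cache$default)) {
    .world_cache$default <- make_world(world_spec())
  }
  .world_cache$default
}

# noiseless world for exact Engel-curve round trips
test_world_noiseless <- function() {
  if (is.null(.world_cache$noiseless)) {
    .world_cache$noiseless <- make_world(world_spec(
      n_countries = 40, cells_per_country = 2, seed = 11,
      consumption_noise_sd = 0
    ))
  }
  .world_cache$noiseless
}

# synthetic demand observations drawn from known parameters
simulate_demand_obs <- function(params, n, seed, noise_sd = 0,
                                income_meanlog = log(8000),
                                income_sdlog = 1.2) {
  set.seed(seed)
  inc <- stats::rlnorm(n, income_meanlog, income_sdlog)
  pw <- cbind(100 * stats::rlnorm(n, 0, 0.15),
              50 * stats::rlnorm(n, 0, 0.15))
  pred <- predict_percapita(inc, pw, params)
  mult <- if (noise_sd > 0) exp(stats::rnorm(2 * n, 0, noise_sd)) else 1
  q <- cbind(pred$q_industrial_roundwood, pred$q_wood_fuel) * mult
  data.frame(
    income = inc,
    price_industrial_roundwood = pw[, 1],
    price_wood_fuel = pw[, 2],
    q_industrial_roundwood = q[, 1],
    q_wood_fuel = q[, 2]
  )
}

# a tiny valid wood record table
toy_records <- function() {
  data.frame(
    country = rep(c("AA", "BB"), each = 5),
    year = 2020,
    item = rep(c("Industrial roundwood", "Wood fuel", "Wood pulp",
                 "Industrial roundwood", "Wood charcoal"), 2),
    flow = rep(c("production", "production", "import", "export", "import"),
               2),
    quantity = c(100, 40, 10, 20, 2, 50, 80, 5, 0, 1),
    unit = rep(c("m3", "m3", "t", "m3", "t"), 2),
    value = c(NA, NA, 1480, 2000, 599, NA, NA, 740, 0, 299.5),
    stringsAsFactors = FALSE
  )
}

# random cell tables for optimizer tests
random_cells <- function(n, seed, protected_prob = 0) {
  set.seed(seed)
  data.frame(
    cell = sprintf("X%02d", seq_len(n)),
    area_ha = stats::runif(n, 5e4, 5e5),
    frac_timber = stats::runif(n, 0.1, 0.4),
    frac_unmanaged = stats::runif(n, 0.2, 0.4),
    frac_agri = 0.1,
    frac_other = NA_real_,
    r = 0.02,
    ymax = stats::runif(n, 100, 400),
    k = -stats::runif(n, 0.5, 8),
    p = -stats::runif(n, 0.2, 0.9),
    protected = stats::runif(n) < protected_prob,
    stringsAsFactors = FALSE
  ) -> cells
  cells$frac_other <- 1 - cells$frac_timber - cells$frac_unmanaged -
    cells$frac_agri
  cells
}

# per-hectare annualised harvest at the upper intensity bound
cell_yield_max <- function(cells) {
  b <- intensity_bounds()[2]
  cells$ymax * (1 - exp(cells$k * b^cells$p)) * b
}
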