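# Yield tables, biomass bookkeeping, and the annualised harvest curve fit.

test_that("harvestable biomass applies the fixed recovery fractions", {
  pools <- split_wood_pool(100) # 65 / 13 / 22 tC
  expect_equal(
    harvestable_biomass(pools$trunk, pools$branches, pools$coarse_roots),
    65 + 0.95 * 13 + 0.10 * 22 # 79.55
  )
  expect_equal(harvestable_biomass(0, 0, 0), 0)
  # linearity
  expect_equal(harvestable_biomass(2 * 65, 2 * 13, 2 * 22),
               2 * harvestable_biomass(65, 13, 22))
  expect_error(harvestable_biomass(-1, 0, 0), "nonnegative")
})

test_that("biomass-volume conversion uses 0.3 tC per m3 and round-trips", {
  expect_equal(biomass_to_volume(3), 10)
  expect_equal(biomass_to_volume(0), 0)
  v <- c(0, 1.7, 250)
  expect_equal(biomass_to_volume(volume_to_biomass(v)), v)
})

test_that("yield tables are deterministic and respect cohort trends", {
  cells <- data.frame(cell = c("a", "b"), vmax = c(300, 420),
                      growth_rate = c(0.03, 0.05), shape = c(1.4, 1.7))
  t1 <- generate_yield_tables(cells, noise_sd = 0.1, seed = 99)
  t2 <- generate_yield_tables(cells, noise_sd = 0.1, seed = 99)
  expect_identical(t1, t2)
  # zero trend: cohorts share the age-yield profile
  t0 <- generate_yield_tables(cells[1, ], cohorts = c(1900, 1960))
  y1 <- t0[t0$cohort == 1900 & t0$age <= 140, ]
  y2 <- t0[t0$cohort == 1960 & t0$age <= 140, ]
  expect_equal(y1$yield_m3_ha[match(y2$age, y1$age)], y2$yield_m3_ha)
  # +20% multiplier on one cohort scales every entry at equal age
  tr <- generate_yield_tables(
    cells[1, ], cohorts = c(1900, 1960),
    trend = function(cohort) if (cohort == 1960) 1.2 else 1
  )
  z1 <- tr[tr$cohort == 1900 & tr$age <= 140, ]
  z2 <- tr[tr$cohort == 1960 & tr$age <= 140, ]
  expect_equal(z2$yield_m3_ha, 1.2 * z1$yield_m3_ha[match(z2$age, z1$age)])
  # yields nondecreasing in stand age
  expect_true(all(diff(t0$yield_m3_ha[t0$cohort == 1900]) >= 0))
  expect_error(generate_yield_tables(
    data.frame(cell = "x", vmax = -5, growth_rate = 0.1, shape = 1)
  ), "asymptote")
})

test_that("curve fit recovers exact in-family parameters", {
  true <- list(ymax = 300, k = -0.15, p = -0.6)
  age <- seq(10, 160, by = 10)
  yield <- per_harvest_yield(1 / age, true)
  fit <- fit_yield_curve(age, yield)
  expect_true(fit$converged)
  expect_lt(abs(fit$ymax - true$ymax) / true$ymax, 1e-6)
  expect_lt(abs(fit$k - true$k) / abs(true$k), 1e-6)
  expect_lt(abs(fit$p - true$p) / abs(true$p), 1e-6)
  # idempotence: refitting the fitted curve's own predictions
  fit2 <- fit_yield_curve(age, per_harvest_yield(1 / age, fit))
  expect_lt(abs(fit2$ymax - fit$ymax) / fit$ymax, 1e-8)
  expect_lt(abs(fit2$k - fit$k) / abs(fit$k), 1e-8)
  expect_lt(abs(fit2$p - fit$p) / abs(fit$p), 1e-8)
})

test_that("cross-family fit matches a brute-force grid oracle", {
  # data from a Chapman-Richards curve, outside the fitted family
  age <- seq(10, 160, by = 5)
  yield <- 350 * (1 - exp(-0.035 * age))^1.5
  fit <- fit_yield_curve(age, yield)
  expect_lt(fit$rmse / mean(yield), 0.05)
  # oracle: dense grid over (ymax, k, p) in the same constrained family
  r <- 1 / age
  best <- Inf
  for (ym in seq(max(yield), 1.6 * max(yield), length.out = 40)) {
    for (kk in -exp(seq(log(0.01), log(50), length.out = 60))) {
      for (pp in seq(-0.99, -0.05, length.out = 40)) {
        sse <- sum((yield - ym * (1 - exp(kk * r^pp)))^2)
        if (sse < best) best <- sse
      }
    }
  }
  oracle_rmse <- sqrt(best / length(yield))
  expect_lte(fit$rmse, oracle_rmse * 1.05)
})

test_that("the Gauss-Newton fit agrees with an independent NLS solver", {
  skip_if_not_installed("minpack.lm")
  true <- list(ymax = 280, k = -0.3, p = -0.45)
  age <- seq(10, 160, by = 10)
  r <- 1 / age
  yield <- per_harvest_yield(r, true)
  fit <- fit_yield_curve(age, yield)
  ext <- minpack.lm::nlsLM(
    yield ~ ymax * (1 - exp(k * r^p)),
    start = list(ymax = max(yield), k = -1, p = -0.5),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(ext)
  expect_equal(fit$ymax, cf[["ymax"]], tolerance = 1e-5)
  expect_equal(fit$k, cf[["k"]], tolerance = 1e-5)
  expect_equal(fit$p, cf[["p"]], tolerance = 1e-5)
})

test_that("constant yield tables give a flat per-harvest curve", {
  age <- seq(10, 160, by = 10)
  fit <- fit_yield_curve(age, rep(120, length(age)))
  yy <- per_harvest_yield(1 / age, fit)
  expect_equal(mean(yy), 120, tolerance = 1e-3)
  expect_lt(diff(range(yy)) / 120, 1e-3)
})

test_that("annualised harvest follows the curve and rejects out-of-bounds", {
  params <- list(ymax = 280, k = -2, p = -0.7)
  # formula oracle: independent element-by-element evaluation
  rg <- seq(0.00625, 0.1, length.out = 23)
  direct <- vapply(rg, function(r) {
    280 * (1 - exp(-2 * r^(-0.7))) * r
  }, numeric(1))
  expect_equal(annualised_harvest(rg, params), direct, tolerance = 1e-12)
  # a 50-year rotation is intensity 0.02
  expect_equal(rotation_period(0.02), 50)
  expect_equal(annualised_harvest(0.02, params),
               per_harvest_yield(1 / 50, params) * 0.02)
  # y -> 0 as r -> lower bound scale
  expect_lt(annualised_harvest(0.00625, params),
            annualised_harvest(0.1, params))
  expect_error(annualised_harvest(0.2, params), "bounds")
  expect_error(annualised_harvest(0.001, params), "bounds")
})

test_that("monotonicity: y nondecreasing and y/r nonincreasing in r", {
  w <- test_world_small()
  rg <- seq(intensity_bounds()[1], intensity_bounds()[2],
            length.out = 100)
  for (i in sample(nrow(w$cells), 12)) {
    params <- list(ymax = w$cells$ymax[i], k = w$cells$k[i],
                   p = w$cells$p[i])
    y <- annualised_harvest(rg, params)
    expect_true(all(diff(y) >= -1e-9 * max(y)))
    expect_true(all(diff(per_harvest_yield(rg, params)) <= 1e-9))
  }
})

test_that("sliding-window refits are stationary for stationary tables", {
  cells <- data.frame(cell = c("u", "v"), vmax = c(300, 200),
                      growth_rate = c(0.04, 0.02), shape = c(1.5, 1.3))
  tabs <- generate_yield_tables(cells) # no trend
  f1 <- sliding_window_refit(tabs, 2020)
  f2 <- sliding_window_refit(tabs, 2045)
  for (cl in names(f1)) {
    expect_equal(f1[[cl]]$ymax, f2[[cl]]$ymax, tolerance = 1e-6)
    expect_equal(f1[[cl]]$k, f2[[cl]]$k, tolerance = 1e-6)
    expect_equal(f1[[cl]]$p, f2[[cl]]$p, tolerance = 1e-6)
  }
  # determinism: same inputs, same year
  f3 <- sliding_window_refit(tabs, 2020)
  expect_equal(f1, f3)
})

test_that("a uniform yield trend moves the fitted asymptote in step", {
  cells <- data.frame(cell = "w", vmax = 320, growth_rate = 0.045,
                      shape = 1.4)
  x <- 0.10 # +10% per 20-year cohort step
  # cohorts reach far enough back that consecutive windows see exactly
  # shifted cohort sets at every admissible age
  tabs <- generate_yield_tables(
    cells, cohorts = seq(1700, 2090, by = 20),
    trend = function(cohort) (1 + x)^((cohort - 1850) / 20)
  )
  f1 <- sliding_window_refit(tabs, 2080)
  f2 <- sliding_window_refit(tabs, 2100)
  ratio <- f2$w$ymax / f1$w$ymax
  # one table interval apart: the asymptote carries the +10% cohort trend
  expect_equal(ratio, 1 + x, tolerance = 1e-4)
})

test_that("the sliding window shifts and flags when coverage is short", {
  cells <- data.frame(cell = "s", vmax = 300, growth_rate = 0.04,
                      shape = 1.5)
  tabs <- generate_yield_tables(cells, cohorts = seq(2000, 2080, 20))
  yw <- yield_window(tabs, 1950) # precedes coverage
  expect_true(attr(yw, "shifted"))
  expect_gt(nrow(yw), 4)
})
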