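# Demand system: prediction identities, the implicit-utility root,
# degenerate limits, and parameter recovery by refitting.

ref_params <- function() {
  demand_params(
    gamma = c(0.015, 0.10),
    alpha = c(0.003, 0.015, 0.982),
    beta_star = c(0.0020, 0.00001, 0.99799),
    A = 4000, curvature = 1.6
  )
}

test_that("predicted demands satisfy adding-up exactly", {
  tp <- ref_params()
  inc <- c(600, 3000, 9000, 40000, 2e5)
  pr <- c(110, 45)
  pred <- predict_percapita(inc, pr, tp)
  # reconstruct the numeraire demand from the marginal-share identity:
  # q0 = (1 - phi_rw - phi_wf) * supernumerary income (numeraire price 1)
  xs <- inc - pr[1] * tp$gamma[1] - pr[2] * tp$gamma[2]
  phi_rw <- (pred$q_industrial_roundwood - tp$gamma[1]) * pr[1] / xs
  phi_wf <- (pred$q_wood_fuel - tp$gamma[2]) * pr[2] / xs
  q0 <- (1 - phi_rw - phi_wf) * xs
  total <- pr[1] * pred$q_industrial_roundwood +
    pr[2] * pred$q_wood_fuel + q0
  expect_true(all(abs(total - inc) / inc < 1e-9))
  expect_true(all(phi_rw > 0 & phi_wf > 0 & phi_rw + phi_wf < 1))
})

test_that("utility root matches an independent dense-grid search", {
  tp <- ref_params()
  pr <- c(100, 50)
  for (inc in c(900, 7000, 60000)) {
    pred <- predict_percapita(inc, pr, tp)
    # independent oracle: bracket the implicit-utility identity on a dense
    # grid, then interpolate the sign change linearly
    ugrid <- seq(-30, 30, length.out = 200001)
    sig <- stats::plogis(tp$curvature * ugrid)
    xs <- inc - sum(pr * tp$gamma)
    pvec <- c(pr, 1)
    g <- vapply(seq_along(ugrid), function(i) {
      phi <- tp$alpha + (tp$beta_star - tp$alpha) * sig[i]
      log(xs) - log(tp$A) - ugrid[i] + sum(phi * (log(phi) - log(pvec))) - 1
    }, numeric(1))
    j <- which(diff(sign(g)) != 0)[1]
    u_oracle <- ugrid[j] - g[j] * (ugrid[j + 1] - ugrid[j]) /
      (g[j + 1] - g[j])
    expect_equal(pred$utility, u_oracle, tolerance = 1e-6)
    # and the demand implied by the oracle utility matches
    phi <- tp$alpha + (tp$beta_star - tp$alpha) *
      stats::plogis(tp$curvature * u_oracle)
    expect_equal(pred$q_industrial_roundwood,
                 tp$gamma[[1]] + phi[[1]] / pr[1] * xs, tolerance = 1e-6)
  }
})

test_that("constant-share degenerate case and saturation limit hold", {
  # alpha = beta*: marginal shares independent of utility, gamma = 0
  aids <- demand_params(gamma = c(0, 0),
                        alpha = c(0.02, 0.03, 0.95),
                        beta_star = c(0.02, 0.03, 0.95))
  inc <- c(500, 5000, 5e4, 5e5)
  pred <- predict_percapita(inc, c(80, 40), aids)
  shares <- pred$q_industrial_roundwood * 80 / inc
  expect_true(all(abs(shares - 0.02) < 1e-9))
  # income -> infinity: marginal shares approach beta*
  tp <- ref_params()
  hi <- predict_percapita(1e9, c(100, 50), tp)
  xs <- 1e9 - sum(c(100, 50) * tp$gamma)
  phi_rw <- (hi$q_industrial_roundwood - tp$gamma[[1]]) * 100 / xs
  expect_equal(phi_rw, tp$beta_star[[1]], tolerance = 1e-3)
})

test_that("income below subsistence expenditure clips at gamma", {
  tp <- demand_params(gamma = c(0.5, 2), alpha = c(0.01, 0.05, 0.94),
                      beta_star = c(0.02, 0.01, 0.97), A = 100)
  pred <- predict_percapita(c(50, 5000), c(100, 60), tp)
  expect_true(pred$clipped[1])
  expect_equal(pred$q_industrial_roundwood[1], 0.5)
  expect_equal(pred$q_wood_fuel[1], 2)
  expect_false(pred$clipped[2])
})

test_that("noiseless refit recovers the generating parameters", {
  tp <- ref_params()
  obs <- simulate_demand_obs(tp, n = 60, seed = 42)
  fit <- fit_demand_system(obs, starts = 4, seed = 1)
  rel <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
  got <- unlist(fit$params[c("gamma", "alpha", "beta_star", "A",
                             "curvature")])
  want <- unlist(tp[c("gamma", "alpha", "beta_star", "A", "curvature")])
  expect_true(max(rel(got, want)) < 0.01)
  expect_lt(fit$loss, 1e-8)
})

test_that("duplicating every observation does not change the fit", {
  tp <- ref_params()
  obs <- simulate_demand_obs(tp, n = 40, seed = 3, noise_sd = 0.05)
  f1 <- fit_demand_system(obs, starts = 2, seed = 5)
  f2 <- fit_demand_system(rbind(obs, obs), starts = 2, seed = 5)
  expect_equal(unlist(f1$params[c("gamma", "alpha", "beta_star", "A")]),
               unlist(f2$params[c("gamma", "alpha", "beta_star", "A")]),
               tolerance = 1e-3)
  expect_equal(f2$loss, 2 * f1$loss, tolerance = 1e-3)
})

test_that("fit rejects degenerate panels", {
  tp <- ref_params()
  obs <- simulate_demand_obs(tp, n = 40, seed = 3)
  obs$income <- 8000
  expect_error(fit_demand_system(obs), "income variation")
  expect_error(fit_demand_system(simulate_demand_obs(tp, 10, 1)),
               "at least 30")
})

test_that("own-price response is non-positive and elasticity income-varying", {
  tp <- ref_params()
  inc <- exp(seq(log(400), log(3e5), length.out = 25))
  el <- demand_elasticities(tp, inc, c(100, 50))
  expect_true(all(el$elas_price_industrial_roundwood <= 0))
  expect_true(all(el$elas_price_wood_fuel <= 0))
  # price elasticity depends on the income level: not constant on the grid
  expect_gt(diff(range(el$elas_price_industrial_roundwood)), 0.05)
  expect_gt(diff(range(el$elas_income_wood_fuel)), 0.05)
})

test_that("Engel shapes: roundwood rises, fuel share falls at high income", {
  tp <- ref_params()
  inc <- exp(seq(log(400), log(3e5), length.out = 40))
  pred <- predict_percapita(inc, c(100, 50), tp)
  expect_true(all(diff(pred$q_industrial_roundwood) > 0))
  fuel_share <- pred$q_wood_fuel * 50 / inc
  hi <- inc > 20000
  expect_true(all(diff(fuel_share[hi]) < 0))
})

test_that("country totals scale linearly with population", {
  tp <- ref_params()
  pred <- predict_percapita(c(2000, 30000), c(100, 50), tp)
  tot <- project_country_demand(pred, c(1e6, 0))
  expect_equal(tot$total_industrial_roundwood[1],
               pred$q_industrial_roundwood[1] * 1e6)
  expect_equal(tot$total_wood_fuel[2], 0)
  # additivity across members of a region
  expect_equal(project_country_demand(0.5, 1e6) +
                 project_country_demand(0.5, 2e6),
               project_country_demand(0.5, 3e6))
})

test_that("parameter files round-trip exactly", {
  tp <- ref_params()
  path <- tempfile(fileext = ".txt")
  write_demand_params(tp, path)
  back <- read_demand_params(path)
  expect_equal(back$gamma, tp$gamma)
  expect_equal(back$alpha, tp$alpha)
  expect_equal(back$beta_star, tp$beta_star)
  expect_equal(back$A, tp$A)
  expect_equal(back$curvature, tp$curvature)
})
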