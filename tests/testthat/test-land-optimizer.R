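# Least-cost country decisions: oracle agreement, conservation laws and
# boundary behaviour.

test_that("required harvest nets out imports and never goes negative", {
  expect_equal(required_harvest(100, 30), 70)
  expect_equal(required_harvest(100, 150), 0)
  expect_equal(required_harvest(c(60, 40), 0), 100) # commodities pooled
  expect_error(required_harvest(-1), "nonnegative")
})

test_that("a single unconstrained cell meets the target at the exact root", {
  cells <- random_cells(1, seed = 2)
  area <- cells$area_ha * cells$frac_timber
  params <- list(ymax = cells$ymax, k = cells$k, p = cells$p)
  target <- 0.6 * area * annualised_harvest(0.1, params)
  dec <- optimize_country(target, cells, cost_params(),
                          allow_expansion = FALSE)
  # bisection oracle for y^-1(target / area)
  root <- uniroot(
    function(r) area * annualised_harvest(r, params, FALSE) - target,
    interval = intensity_bounds(), tol = 1e-12
  )$root
  expect_equal(dec$cells$r, root, tolerance = 1e-8)
  expect_equal(dec$harvest, target, tolerance = 1e-9 * target)
  expect_equal(dec$shortfall, 0)
})

test_that("zero requirement keeps intensity at the lower bound", {
  cells <- random_cells(4, seed = 3)
  dec <- optimize_country(0, cells, cost_params())
  expect_true(all(dec$cells$r == intensity_bounds()[1]))
  expect_equal(dec$cells$frac_timber, cells$frac_timber) # no expansion
  expect_equal(dec$cost,
               sum(cost_params()$mgmt * intensity_bounds()[1] *
                     cells$area_ha * cells$frac_timber))
})

test_that("solver matches the exhaustive oracle on random small instances", {
  set.seed(2024)
  costs <- cost_params(mgmt = 1500, convert = 40)
  worst <- 0
  for (trial in 1:100) {
    n <- sample(1:3, 1)
    cells <- random_cells(n, seed = 10000 + trial)
    cap <- sum(cells$area_ha * cells$frac_timber *
                 cell_yield_max(cells))
    target <- runif(1, 0.1, 0.95) * cap
    dec <- optimize_country(target, cells, costs, allow_expansion = FALSE)
    n_r <- if (n == 3) 60 else 200
    oc <- grid_oracle(target, cells, costs, n_r = n_r)
    expect_gte(dec$harvest, target * (1 - 1e-6))
    rel_gap <- (dec$cost - oc) / oc
    worst <- max(worst, rel_gap)
  }
  expect_lt(worst, 0.005)
})

test_that("solver with expansion stays within the oracle gap", {
  set.seed(77)
  costs <- cost_params(mgmt = 1200, convert = 25)
  for (trial in 1:20) {
    n <- sample(1:2, 1)
    cells <- random_cells(n, seed = 500 + trial)
    cap_all <- sum(cells$area_ha *
                     (cells$frac_timber + cells$frac_unmanaged) *
                     cell_yield_max(cells))
    target <- runif(1, 0.5, 0.9) * cap_all
    dec <- optimize_country(target, cells, costs)
    oc <- grid_oracle(target, cells, costs, n_r = 150, expansion = TRUE)
    if (is.finite(oc)) {
      expect_lte(dec$cost, oc * 1.005 + 1e-6)
      expect_gte(dec$harvest + dec$shortfall, target * (1 - 1e-6))
    }
  }
})

test_that("infeasible targets return maximal harvest with a shortfall", {
  cells <- random_cells(2, seed = 9)
  cap <- sum(cells$area_ha * (cells$frac_timber + cells$frac_unmanaged) *
               cell_yield_max(cells))
  dec <- optimize_country(2 * cap, cells, cost_params())
  expect_true(all(dec$cells$r == intensity_bounds()[2]))
  expect_gt(dec$shortfall, 0)
  expect_equal(dec$harvest + dec$shortfall, 2 * cap, tolerance = 1e-9)
  empty <- optimize_country(10, cells[0, ], cost_params())
  expect_equal(empty$shortfall, 10)
})

test_that("cost is nondecreasing in the required harvest", {
  cells <- random_cells(3, seed = 21)
  costs <- cost_params()
  cap <- sum(cells$area_ha * cells$frac_timber * cell_yield_max(cells))
  targets <- seq(0.05, 0.95, length.out = 12) * cap
  cost <- vapply(targets, function(tg) {
    optimize_country(tg, cells, costs, allow_expansion = FALSE)$cost
  }, numeric(1))
  expect_true(all(diff(cost) >= -1e-6 * max(cost)))
})

test_that("land is conserved and protected cells are never converted", {
  cells <- random_cells(6, seed = 12, protected_prob = 0.5)
  cap <- sum(cells$area_ha * (cells$frac_timber + cells$frac_unmanaged) *
               cell_yield_max(cells))
  dec <- optimize_country(0.8 * cap, cells, cost_params())
  out <- dec$cells[order(dec$cells$cell), ]
  inp <- cells[order(cells$cell), ]
  fr <- out$frac_timber + out$frac_unmanaged + out$frac_agri +
    out$frac_other
  expect_true(all(abs(fr - 1) < 1e-12))
  prot <- inp$protected
  expect_equal(out$frac_unmanaged[prot], inp$frac_unmanaged[prot])
})

test_that("spin-up abandonment moves unviable timber to unmanaged forest", {
  cells <- random_cells(4, seed = 30)
  out <- spinup_abandonment(cells, threshold = 0)
  expect_equal(out, cells) # all viable
  cells$ymax[2] <- 1e-6 # effectively zero yield
  out <- spinup_abandonment(cells, threshold = 0.2)
  expect_equal(out$frac_timber[2], 0)
  expect_equal(out$frac_unmanaged[2],
               cells$frac_unmanaged[2] + cells$frac_timber[2])
  # threshold above everything abandons all timber
  all_gone <- spinup_abandonment(cells, threshold = Inf)
  expect_true(all(all_gone$frac_timber == 0))
  expect_equal(all_gone$frac_timber + all_gone$frac_unmanaged,
               cells$frac_timber + cells$frac_unmanaged)
})

test_that("agricultural demand expands into the least productive land first", {
  cells <- random_cells(5, seed = 40)
  ag0 <- sum(cells$area_ha * cells$frac_agri)
  expect_equal(apply_agricultural_demand(cells, ag0), cells) # flat
  # +10 kha taken from unmanaged forest only
  out <- apply_agricultural_demand(cells, ag0 + 1e4)
  expect_equal(sum(out$area_ha * out$frac_agri), ag0 + 1e4)
  expect_equal(out$frac_timber, cells$frac_timber)
  expect_equal(sum(out$area_ha * (cells$frac_unmanaged -
                                    out$frac_unmanaged)), 1e4)
  # expansion ordering: the touched cells are the lowest-yield ones
  pot <- cell_yield_max(cells)
  touched <- which(out$frac_unmanaged < cells$frac_unmanaged - 1e-15)
  untouched <- setdiff(which(cells$frac_unmanaged > 0), touched)
  if (length(touched) > 0 && length(untouched) > 0) {
    expect_lt(max(pot[touched]), min(pot[untouched]) + 1e-9)
  }
  expect_error(
    apply_agricultural_demand(cells, sum(cells$area_ha) * 2),
    "exceeds"
  )
})
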