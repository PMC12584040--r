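# Income- and price-dependent demand system for industrial roundwood and
# wood fuel (MAIDADS-type: implicitly directly additive, with marginal
# budget shares that move between a low-income and a high-income pattern
# as utility rises).
#
# Demands take the linear-expenditure-like form
#   q_i = gamma_i + phi_i(u) / p_i * (x - sum_j p_j gamma_j)
# with utility-dependent marginal budget shares
#   phi_i(u) = alpha_i + (beta*_i - alpha_i) * logistic(u).
# A residual non-wood numeraire good (price 1, no subsistence quantity)
# closes the budget, so adding-up holds identically because the shares of
# the two wood goods plus the numeraire sum to one at every utility level.
# The utility level is pinned down by the implicit-utility identity
#   ln(x - sum p_j gamma_j) - ln A - u
#     + sum_i phi_i(u) * (ln phi_i(u) - ln p_i) - 1 = 0,
# solved per observation by safeguarded bisection. A is an income-scale
# parameter locating the preference transition.

WOOD_COMMODITIES <- c("industrial_roundwood", "wood_fuel")

#' Construct demand-system parameters
#'
#' @param gamma Length-2 subsistence quantities (m3/person/yr) for
#'   industrial roundwood and wood fuel; nonnegative.
#' @param alpha Length-3 low-income marginal budget shares (roundwood,
#'   wood fuel, numeraire); nonnegative, summing to 1.
#' @param beta_star Length-3 high-income marginal budget shares; same
#'   constraints.
#' @param A Positive income-scale parameter of the utility transition.
#' @param curvature Positive utility-curvature parameter governing how
#'   sharply marginal shares move from `alpha` to `beta_star` as utility
#'   rises (logistic slope; 1 = plain logistic, > 1 sharper).
#' @return Object of class `demand_params`.
#' @export
demand_params <- function(gamma, alpha, beta_star, A = 1, curvature = 1) {
  stop_if(length(gamma) != 2, "gamma must have length 2 (wood goods)")
  stop_if(length(alpha) != 3 || length(beta_star) != 3,
          "alpha and beta_star must have length 3 (wood goods + numeraire)")
  stop_if(any(gamma < 0), "subsistence quantities must be nonnegative")
  stop_if(any(alpha < 0) || any(beta_star < 0),
          "marginal budget shares must be nonnegative")
  stop_if(abs(sum(alpha) - 1) > 1e-8 || abs(sum(beta_star) - 1) > 1e-8,
          "marginal budget shares must sum to 1")
  stop_if(A <= 0, "A must be positive")
  stop_if(curvature <= 0, "curvature must be positive")
  structure(list(
    gamma = stats::setNames(as.numeric(gamma), WOOD_COMMODITIES),
    alpha = stats::setNames(as.numeric(alpha),
                            c(WOOD_COMMODITIES, "numeraire")),
    beta_star = stats::setNames(as.numeric(beta_star),
                                c(WOOD_COMMODITIES, "numeraire")),
    A = as.numeric(A),
    curvature = as.numeric(curvature)
  ), class = "demand_params")
}

#' @export
print.demand_params <- function(x, ...) {
  cat("Demand-system parameters (2 wood goods + numeraire)\n")
  cat("  gamma (m3/person/yr):",
      paste(sprintf("%s=%.4g", names(x$gamma), x$gamma), collapse = ", "),
      "\n")
  cat("  alpha:", sprintf("%.4f", x$alpha), "\n")
  cat("  beta*:", sprintf("%.4f", x$beta_star), "\n")
  cat("  A (income scale):", format(x$A, digits = 4),
      " curvature:", format(x$curvature, digits = 4), "\n")
  invisible(x)
}

# marginal budget shares at utility u (vectorised over u);
# returns matrix length(u) x 3
marginal_shares <- function(u, params) {
  s <- stats::plogis(params$curvature * u)
  outer(1 - s, params$alpha) + outer(s, params$beta_star)
}

# implicit-utility identity residual, vectorised over observations
# xs: supernumerary income (x - sum p gamma), pmat: n x 3 prices
utility_residual <- function(u, xs, pmat, params) {
  phi <- marginal_shares(u, params)
  ent <- rowSums(xlogx(phi) - phi * log(pmat))
  log(xs) - log(params$A) - u + ent - 1
}

# Solve the implicit-utility identity per observation by bisection.
# Lean inner loop: logs precomputed, no intermediate data frames.
solve_utility <- function(xs, pmat, params, tol = 1e-11) {
  n <- length(xs)
  lo <- rep(-700, n)
  hi <- rep(700, n)
  lp <- log(pmat)
  alpha <- params$alpha
  dab <- params$beta_star - params$alpha
  base <- log(xs) - log(params$A) - 1
  cv <- params$curvature
  resid <- function(u) {
    sig <- stats::plogis(cv * u)
    phi <- rep(alpha, each = n) + outer(sig, dab)
    base - u + rowSums(phi * (log(phi) - lp))
  }
  # residual is +Inf-directed at lo, -Inf-directed at hi (the -u term
  # dominates), so a sign change is guaranteed
  for (iter in 1:90) {
    mid <- (lo + hi) / 2
    up <- resid(mid) > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
    if (max(hi - lo) < tol) break
  }
  (lo + hi) / 2
}

# demand matrix (n x 2) without data-frame assembly; used by the fit loss
predict_q <- function(income, pw, params) {
  n <- length(income)
  subsist <- as.numeric(pw %*% params$gamma)
  xs <- income - subsist
  ok <- xs > 0
  q <- matrix(rep(params$gamma, each = n), n, 2)
  if (any(ok)) {
    u <- solve_utility(xs[ok], cbind(pw[ok, , drop = FALSE], 1), params)
    phi <- marginal_shares(u, params)
    q[ok, ] <- rep(params$gamma, each = sum(ok)) +
      phi[, 1:2, drop = FALSE] / pw[ok, , drop = FALSE] * xs[ok]
  }
  q
}

#' Per-capita demand prediction
#'
#' Predicts per-capita demand for industrial roundwood and wood fuel from
#' income and prices. Observations whose income does not cover subsistence
#' expenditure are clipped at the subsistence quantities and flagged.
#'
#' @param income Income (currency/person/yr), vectorised.
#' @param prices Either a length-2 named/ordered vector of wood prices
#'   (currency/m3; roundwood, wood fuel) applied to all observations, or an
#'   n x 2 matrix/data.frame of per-observation prices.
#' @param params A [demand_params()] object.
#' @param elasticities If `TRUE`, append numerical own-price and income
#'   point elasticities.
#' @return data.frame with columns `income`, `price_*`, `q_*` (m3/person/yr),
#'   `utility`, `clipped`, and optionally elasticity columns.
#' @export
predict_percapita <- function(income, prices, params, elasticities = FALSE) {
  stop_if(!inherits(params, "demand_params"), "params must be demand_params")
  n <- length(income)
  pw <- if (is.null(dim(prices))) {
    matrix(rep(as.numeric(prices), each = n), n, 2)
  } else {
    as.matrix(prices)
  }
  stop_if(ncol(pw) != 2, "prices must give the two wood-good prices")
  stop_if(any(pw <= 0), "prices must be positive")
  stop_if(any(income <= 0), "income must be positive")
  pmat <- cbind(pw, 1) # numeraire price 1

  subsist <- as.numeric(pw %*% params$gamma)
  xs <- income - subsist
  ok <- xs > 0

  q <- matrix(rep(params$gamma, each = n), n, 2)
  u <- rep(NA_real_, n)
  if (any(ok)) {
    u[ok] <- solve_utility(xs[ok], pmat[ok, , drop = FALSE], params)
    phi <- marginal_shares(u[ok], params)
    q[ok, ] <- rep(params$gamma, each = sum(ok)) +
      phi[, 1:2, drop = FALSE] / pw[ok, , drop = FALSE] * xs[ok]
  }
  out <- data.frame(
    income = income,
    price_industrial_roundwood = pw[, 1],
    price_wood_fuel = pw[, 2],
    q_industrial_roundwood = q[, 1],
    q_wood_fuel = q[, 2],
    utility = u,
    clipped = !ok
  )
  if (elasticities) {
    el <- demand_elasticities(params, income, pw)
    out <- cbind(out, el[, -1])
  }
  out
}

#' Point price and income elasticities
#'
#' Central finite-difference log-derivatives of predicted demand with
#' respect to own price and income.
#'
#' @param params A [demand_params()] object.
#' @param income Income vector.
#' @param prices Wood prices (vector of 2 or n x 2 matrix).
#' @param h Relative step for the finite difference.
#' @return data.frame with own-price and income elasticities per commodity.
#' @export
demand_elasticities <- function(params, income, prices, h = 1e-4) {
  n <- length(income)
  pw <- if (is.null(dim(prices))) {
    matrix(rep(as.numeric(prices), each = n), n, 2)
  } else {
    as.matrix(prices)
  }
  base <- predict_percapita(income, pw, params)
  qb <- as.matrix(base[, c("q_industrial_roundwood", "q_wood_fuel")])
  eps <- function(qp, qm) (log(pmax(qp, 1e-300)) - log(pmax(qm, 1e-300))) /
    (2 * h)
  inc_p <- predict_percapita(income * (1 + h), pw, params)
  inc_m <- predict_percapita(income * (1 - h), pw, params)
  e_inc <- eps(
    as.matrix(inc_p[, c("q_industrial_roundwood", "q_wood_fuel")]),
    as.matrix(inc_m[, c("q_industrial_roundwood", "q_wood_fuel")])
  )
  e_own <- matrix(NA_real_, n, 2)
  for (j in 1:2) {
    pp <- pw; pp[, j] <- pw[, j] * (1 + h)
    pm <- pw; pm[, j] <- pw[, j] * (1 - h)
    qp <- predict_percapita(income, pp, params)[[paste0("q_", WOOD_COMMODITIES[j])]]
    qm <- predict_percapita(income, pm, params)[[paste0("q_", WOOD_COMMODITIES[j])]]
    e_own[, j] <- eps(qp, qm)
  }
  data.frame(
    income = income,
    elas_income_industrial_roundwood = e_inc[, 1],
    elas_income_wood_fuel = e_inc[, 2],
    elas_price_industrial_roundwood = e_own[, 1],
    elas_price_wood_fuel = e_own[, 2]
  )
}

# free-parameter vector <-> demand_params
theta_to_params <- function(theta) {
  softmax <- function(z) {
    z <- c(z, 0)
    e <- exp(z - max(z))
    e / sum(e)
  }
  demand_params(
    gamma = exp(theta[1:2]),
    alpha = softmax(theta[3:4]),
    beta_star = softmax(theta[5:6]),
    A = exp(theta[7]),
    curvature = exp(theta[8])
  )
}

params_to_theta <- function(params) {
  logit3 <- function(s) log(s[1:2] / s[3])
  c(log(pmax(params$gamma, 1e-8)),
    logit3(pmax(params$alpha, 1e-8)),
    logit3(pmax(params$beta_star, 1e-8)),
    log(params$A),
    log(params$curvature))
}

demand_loss <- function(theta, obs, floor = 1e-6) {
  params <- theta_to_params(theta)
  q <- predict_q(
    obs$income,
    as.matrix(obs[, c("price_industrial_roundwood", "price_wood_fuel")]),
    params
  )
  r1 <- log(pmax(q[, 1], floor)) - log(pmax(obs$q_industrial_roundwood, floor))
  r2 <- log(pmax(q[, 2], floor)) - log(pmax(obs$q_wood_fuel, floor))
  sum(r1^2) + sum(r2^2)
}

#' Fit the demand system to country observations
#'
#' Minimises the sum of squared log-consumption residuals over the two wood
#' goods, with a small floor on modelled and observed values so zero
#' consumption enters the loss smoothly. Non-convexity is mitigated by
#' multi-start local optimisation (Nelder-Mead then BFGS polish) from a
#' data-driven start plus randomly perturbed starts under a fixed seed.
#'
#' @param obs data.frame with columns `income`,
#'   `price_industrial_roundwood`, `price_wood_fuel`,
#'   `q_industrial_roundwood`, `q_wood_fuel` (per-capita m3/person/yr).
#'   See [demand_observations()] to build it from a wood balance.
#' @param starts Number of optimisation starts (>= 1).
#' @param seed Seed for the start perturbations.
#' @param q_floor Consumption floor in the loss (m3/person/yr).
#' @return Object of class `demand_fit`: `params` ([demand_params()]),
#'   `loss`, `converged`, `starts`, `seed`, `n`.
#' @export
fit_demand_system <- function(obs, starts = 10, seed = 1, q_floor = 1e-6) {
  need <- c("income", "price_industrial_roundwood", "price_wood_fuel",
            "q_industrial_roundwood", "q_wood_fuel")
  miss <- setdiff(need, names(obs))
  stop_if(length(miss) > 0,
          "missing observation columns: ", paste(miss, collapse = ", "))
  stop_if(nrow(obs) < 30, "need at least 30 observations")
  stop_if(stats::sd(log(obs$income)) < 1e-8,
          "degenerate panel: no income variation")
  stop_if(any(obs$income <= 0) ||
            any(obs$price_industrial_roundwood <= 0) ||
            any(obs$price_wood_fuel <= 0),
          "income and prices must be positive")
  stop_if(any(obs$q_industrial_roundwood < 0) || any(obs$q_wood_fuel < 0),
          "consumption must be nonnegative")

  # data-driven start: subsistence near low-income consumption, shares from
  # low/high income terciles, transition near median income
  ord <- order(obs$income)
  lowi <- ord[seq_len(max(3, floor(nrow(obs) / 3)))]
  highi <- ord[seq(nrow(obs) - max(3, floor(nrow(obs) / 3)) + 1, nrow(obs))]
  shares <- function(idx) {
    s1 <- mean(obs$price_industrial_roundwood[idx] *
                 obs$q_industrial_roundwood[idx] / obs$income[idx])
    s2 <- mean(obs$price_wood_fuel[idx] * obs$q_wood_fuel[idx] /
                 obs$income[idx])
    s <- pmin(pmax(c(s1, s2), 1e-4), 0.45)
    c(s, 1 - sum(s))
  }
  g0 <- pmax(c(
    stats::quantile(obs$q_industrial_roundwood[lowi], 0.25, names = FALSE),
    stats::quantile(obs$q_wood_fuel[lowi], 0.25, names = FALSE)
  ) * 0.5, 1e-5)
  start0 <- params_to_theta(demand_params(
    gamma = g0, alpha = shares(lowi), beta_star = shares(highi),
    A = stats::median(obs$income)
  ))

  set.seed(seed)
  start_list <- c(list(start0), lapply(seq_len(max(0, starts - 1)),
    function(i) start0 + stats::rnorm(8, sd = c(1, 1, 1, 1, 1, 1, 0.7, 0.4))))

  best <- NULL
  codes <- integer(0)
  for (th0 in start_list) {
    fit1 <- tryCatch(
      stats::optim(th0, demand_loss, obs = obs, floor = q_floor,
                   method = "Nelder-Mead",
                   control = list(maxit = 800, reltol = 1e-11)),
      error = function(e) NULL
    )
    if (is.null(fit1)) next
    fit2 <- tryCatch(
      stats::optim(fit1$par, demand_loss, obs = obs, floor = q_floor,
                   method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-14)),
      error = function(e) fit1
    )
    cand <- if (fit2$value <= fit1$value) fit2 else fit1
    codes <- c(codes, cand$convergence)
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  stop_if(is.null(best), "all optimisation starts failed")
  structure(list(
    params = theta_to_params(best$par),
    loss = best$value,
    converged = best$convergence == 0,
    starts = length(start_list),
    seed = seed,
    floor = q_floor,
    n = nrow(obs)
  ), class = "demand_fit")
}

#' @export
print.demand_fit <- function(x, ...) {
  cat(sprintf("Demand-system fit: n = %d, loss = %.6g, %s (%d starts)\n",
              x$n, x$loss,
              if (x$converged) "converged" else "not converged", x$starts))
  print(x$params)
  invisible(x)
}

#' Build demand observations from a wood balance
#'
#' Joins commodity balances with population and income and converts
#' consumption to per-capita terms. Negative (flagged) apparent consumption
#' is floored at zero.
#'
#' @param balance Output of [wood_balance()], single year.
#' @param socio data.frame with columns `country`, `population`,
#'   `gdp_percap`.
#' @return Wide observation table for [fit_demand_system()].
#' @export
demand_observations <- function(balance, socio) {
  wide <- NULL
  for (cm in WOOD_COMMODITIES) {
    b <- balance[balance$commodity == cm,
                 c("country", "consumption_m3", "price")]
    names(b) <- c("country", paste0("cons_", cm), paste0("price_", cm))
    wide <- if (is.null(wide)) b else merge(wide, b, by = "country")
  }
  out <- merge(wide, socio, by = "country")
  for (cm in WOOD_COMMODITIES) {
    out[[paste0("q_", cm)]] <-
      pmax(out[[paste0("cons_", cm)]], 0) / out$population
  }
  out$income <- out$gdp_percap
  out
}

#' Scale per-capita demand to country totals
#'
#' @param percap Per-capita demands (vector or data.frame columns `q_*`).
#' @param population Country population (recycled).
#' @return Totals in m3/yr (same shape as input).
#' @export
project_country_demand <- function(percap, population) {
  stop_if(any(population < 0), "population must be nonnegative")
  if (is.data.frame(percap)) {
    qcols <- grep("^q_", names(percap), value = TRUE)
    out <- percap[qcols]
    names(out) <- sub("^q_", "total_", qcols)
    out[] <- lapply(out, function(v) v * population)
    cbind(percap["income"], out)
  } else {
    percap * population
  }
}

#' Write fitted demand parameters to a plain-text key-value file
#'
#' @param fit A `demand_fit` or `demand_params` object.
#' @param path Output file path.
#' @export
write_demand_params <- function(fit, path) {
  params <- if (inherits(fit, "demand_fit")) fit$params else fit
  meta <- if (inherits(fit, "demand_fit")) {
    c(sprintf("loss = %.17g", fit$loss),
      sprintf("starts = %d", fit$starts),
      sprintf("seed = %d", fit$seed),
      sprintf("n = %d", fit$n))
  } else character(0)
  lines <- c(
    sprintf("gamma_%s = %.17g", names(params$gamma), params$gamma),
    sprintf("alpha_%s = %.17g", names(params$alpha), params$alpha),
    sprintf("beta_star_%s = %.17g", names(params$beta_star),
            params$beta_star),
    sprintf("A = %.17g", params$A),
    sprintf("curvature = %.17g", params$curvature),
    meta
  )
  writeLines(lines, path)
}

#' Read demand parameters from a key-value file
#'
#' @param path File written by [write_demand_params()].
#' @return A [demand_params()] object.
#' @export
read_demand_params <- function(path) {
  kv <- utils::read.table(path, sep = "=", strip.white = TRUE,
                          stringsAsFactors = FALSE,
                          col.names = c("key", "value"))
  get <- function(k) as.numeric(kv$value[match(k, kv$key)])
  demand_params(
    gamma = get(paste0("gamma_", WOOD_COMMODITIES)),
    alpha = get(paste0("alpha_", c(WOOD_COMMODITIES, "numeraire"))),
    beta_star = get(paste0("beta_star_", c(WOOD_COMMODITIES, "numeraire"))),
    A = get("A"),
    curvature = get("curvature")
  )
}
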