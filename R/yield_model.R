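# Stand-age yield tables and the annualised harvest curve.
#
# A synthetic generator emulates process-model yield tables: cohorts of
# forest established every 20 years from 1850 to 2090, each followed to
# 2100, with potential clear-cut yield (m3/ha) growing with stand age along
# a Chapman-Richards curve, optionally scaled by a multiplicative
# climate/CO2 trend per establishment cohort.
#
# The management model summarises a yield-table slice by the annualised
# harvest function of management intensity r (harvests per year, the
# reciprocal of the rotation period):
#   y(r) = ymax * (1 - exp(k * r^p)) * r,   k < 0, p < 0
# where ymax*(1 - exp(k*r^p)) is the per-harvest (clear-cut) yield at
# rotation 1/r. Parameters are estimated from (rotation, yield) pairs by a
# damped Gauss-Newton method.

#' Admissible management-intensity bounds (1/yr)
#'
#' Lower bound set by the 160-year time scope of the yield tables, upper
#' bound by reported rotation periods (10 years).
#' @return Numeric length-2 vector `c(lower, upper)`.
#' @export
intensity_bounds <- function() c(0.00625, 0.1)

#' Rotation period implied by a management intensity
#'
#' The rotation period is the reciprocal of the harvest frequency: an
#' intensity of 0.02/yr corresponds to a 50-year rotation.
#'
#' @param r Management intensity (1/yr).
#' @return Rotation period in years.
#' @export
rotation_period <- function(r) {
  stop_if(any(r <= 0), "intensity must be positive")
  1 / r
}

#' Harvestable biomass from wood pools
#'
#' Clear-cut removals: 100% of trunk, 95% of twigs and branches, 10% of
#' coarse roots (tC/ha).
#'
#' @param trunk,branches,coarse_roots Pool biomasses (tC/ha).
#' @return Harvestable biomass (tC/ha).
#' @export
harvestable_biomass <- function(trunk, branches, coarse_roots) {
  stop_if(any(c(trunk, branches, coarse_roots) < 0),
          "pools must be nonnegative")
  1.00 * trunk + 0.95 * branches + 0.10 * coarse_roots
}

#' Split a total wood pool into trunk, branches and coarse roots
#'
#' Fixed pool shares: 65% trunk, 13% twigs and branches, 22% coarse roots.
#'
#' @param wood_pool Total wood pool (tC/ha).
#' @return data.frame with the three pools.
#' @export
split_wood_pool <- function(wood_pool) {
  stop_if(any(wood_pool < 0), "wood pool must be nonnegative")
  data.frame(trunk = 0.65 * wood_pool,
             branches = 0.13 * wood_pool,
             coarse_roots = 0.22 * wood_pool)
}

#' Convert biomass carbon to wood volume
#'
#' Fixed conversion factor of 0.3 tC per m3.
#'
#' @param biomass Biomass (tC/ha).
#' @return Volume (m3/ha).
#' @export
biomass_to_volume <- function(biomass) {
  stop_if(any(biomass < 0), "biomass must be nonnegative")
  biomass / 0.3
}

#' @rdname biomass_to_volume
#' @param volume Volume (m3/ha).
#' @export
volume_to_biomass <- function(volume) {
  stop_if(any(volume < 0), "volume must be nonnegative")
  volume * 0.3
}

#' Generate synthetic stand-age yield tables
#'
#' For each grid cell and establishment cohort, the potential clear-cut
#' yield at stand age a follows a Chapman-Richards curve
#' `vmax * (1 - exp(-growth_rate * a))^shape`, multiplied by a cohort trend
#' (e.g. climate/CO2 fertilisation) and optional multiplicative lognormal
#' noise. Deterministic given `seed`.
#'
#' @param cells data.frame with columns `cell`, `vmax` (asymptotic volume,
#'   m3/ha), `growth_rate` (1/yr), `shape` (>= 1).
#' @param cohorts Establishment years (default every 20 years 1850-2090).
#' @param end_year Last calendar year covered (default 2100).
#' @param trend Function of cohort year returning a multiplicative yield
#'   factor (default constant 1).
#' @param noise_sd Lognormal sigma of per-entry noise (default 0, exact
#'   curves).
#' @param seed Seed for the noise stream.
#' @return data.frame with columns `cell`, `cohort`, `year`, `age`,
#'   `yield_m3_ha`.
#' @export
generate_yield_tables <- function(cells,
                                  cohorts = seq(1850, 2090, by = 20),
                                  end_year = 2100,
                                  trend = function(cohort) 1,
                                  noise_sd = 0,
                                  seed = 1) {
  stop_if(!all(c("cell", "vmax", "growth_rate", "shape") %in% names(cells)),
          "cells must have columns cell, vmax, growth_rate, shape")
  stop_if(any(cells$vmax < 0), "negative asymptote")
  stop_if(any(cells$growth_rate <= 0) || any(cells$shape <= 0),
          "growth_rate and shape must be positive")
  cohorts <- cohorts[cohorts < end_year]
  nyr <- end_year - cohorts # rows per cohort
  cohort_v <- rep(cohorts, nyr)
  age_v <- unlist(lapply(nyr, seq_len), use.names = FALSE)
  ncc <- length(cohort_v)
  rows <- data.frame(
    cell = rep(cells$cell, each = ncc),
    cohort = rep(cohort_v, nrow(cells)),
    year = rep(cohort_v + age_v, nrow(cells)),
    age = rep(age_v, nrow(cells)),
    stringsAsFactors = FALSE
  )
  p <- cells[match(rows$cell, cells$cell), ]
  tr_cohort <- vapply(cohorts, trend, numeric(1))
  tr <- rep(rep(tr_cohort, nyr), nrow(cells))
  stop_if(any(tr < 0), "trend multipliers must be nonnegative")
  yield <- p$vmax * (1 - exp(-p$growth_rate * rows$age))^p$shape * tr
  if (noise_sd > 0) {
    set.seed(seed)
    yield <- yield * exp(stats::rnorm(length(yield), 0, noise_sd))
  }
  rows$yield_m3_ha <- yield
  rownames(rows) <- NULL
  rows
}

#' Per-harvest yield of the fitted curve
#'
#' `ymax * (1 - exp(k * r^p))`: the expected clear-cut volume at rotation
#' period 1/r. Nonincreasing in r for k < 0, p < 0.
#'
#' @param r Management intensity (1/yr).
#' @param params A `yield_curve` object or list with `ymax`, `k`, `p`.
#' @return Per-harvest yield (m3/ha).
#' @export
per_harvest_yield <- function(r, params) {
  params$ymax * (1 - exp(params$k * r^params$p))
}

#' Annualised harvest at a management intensity
#'
#' `y(r) = ymax * (1 - exp(k * r^p)) * r` (m3/ha/yr). `r` must lie within
#' [intensity_bounds()] unless `check_bounds = FALSE`.
#'
#' @param r Management intensity (1/yr), vectorised.
#' @param params A `yield_curve` object or list with `ymax`, `k`, `p`.
#' @param check_bounds Reject out-of-bounds intensities (default TRUE).
#' @return Annualised harvest (m3/ha/yr).
#' @export
annualised_harvest <- function(r, params, check_bounds = TRUE) {
  if (check_bounds) {
    b <- intensity_bounds()
    stop_if(any(r < b[1] - 1e-12 | r > b[2] + 1e-12),
            "intensity outside admissible bounds [",
            b[1], ", ", b[2], "]")
  }
  per_harvest_yield(r, params) * r
}

# Gauss-Newton (Levenberg-damped) fit in transformed parameter space:
#   ymax = exp(t1) > 0, k = -exp(t2) < 0, p = -plogis(t3) in (-1, 0).
# p is restricted to (-1, 0): within the admissible intensity range this is
# the subfamily for which the annualised harvest y(r) is nondecreasing in r
# (more frequent harvesting never lowers the long-run annual yield).
gn_fit <- function(r, yield, t0, max_iter = 200, tol = 1e-10) {
  sse <- function(t) {
    ymax <- exp(t[1]); k <- -exp(t[2]); p <- -stats::plogis(t[3])
    sum((yield - ymax * (1 - exp(k * r^p)))^2)
  }
  t <- t0
  lambda <- 1e-3
  cur <- sse(t)
  converged <- FALSE
  iters <- 0
  for (it in seq_len(max_iter)) {
    iters <- it
    ymax <- exp(t[1]); k <- -exp(t[2]); p <- -stats::plogis(t[3])
    s <- r^p
    eks <- exp(k * s)
    m <- ymax * (1 - eks)
    res <- yield - m
    # d model / d t (chain rule through the transforms)
    J <- cbind(
      m,                                  # via ymax
      -ymax * eks * s * k,                # via k
      -ymax * eks * k * s * log(r) * p * (1 + p) # via p
    )
    JtJ <- crossprod(J)
    g <- crossprod(J, res)
    step <- NULL
    for (inner in 1:30) {
      cand <- tryCatch(
        solve(JtJ + lambda * diag(diag(JtJ) + 1e-12), g),
        error = function(e) NULL
      )
      if (!is.null(cand)) {
        tn <- t + as.numeric(cand)
        val <- sse(tn)
        if (is.finite(val) && val <= cur) {
          step <- as.numeric(cand)
          t <- tn
          cur <- val
          lambda <- max(lambda / 3, 1e-12)
          break
        }
      }
      lambda <- lambda * 3
    }
    if (is.null(step)) break
    if (sqrt(sum(step^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(t = t, sse = cur, converged = converged, iterations = iters)
}

#' Fit the annualised harvest curve to rotation-age yields
#'
#' Estimates `(ymax, k, p)` of the per-harvest yield
#' `ymax * (1 - exp(k * r^p))` from (rotation age, clear-cut yield) pairs
#' by damped Gauss-Newton least squares (at most 200 iterations, step-norm
#' convergence 1e-10), with multi-start fallback if the primary start does
#' not converge. Rotation ages map to intensities as `r = 1/age`.
#'
#' @param age Rotation ages (years); at least 4 distinct values.
#' @param yield Per-harvest yields (m3/ha) at those ages.
#' @param window Optional identifier of the yield-table slice fitted.
#' @param max_iter,tol Gauss-Newton controls.
#' @return Object of class `yield_curve`: `ymax`, `k`, `p`, `rmse`,
#'   `converged`, `iterations`, `window`.
#' @export
fit_yield_curve <- function(age, yield, window = NULL,
                            max_iter = 200, tol = 1e-10) {
  stop_if(length(age) != length(yield), "age and yield lengths differ")
  keep <- is.finite(age) & is.finite(yield)
  age <- age[keep]; yield <- yield[keep]
  stop_if(length(unique(age)) < 4, "need at least 4 distinct rotation ages")
  stop_if(any(age <= 0) || any(yield < 0),
          "ages must be positive, yields nonnegative")
  r <- 1 / age

  # heuristic start: linearise log(-log(1 - y/ymax0)) = log(-k) + p*log(r)
  ymax0 <- max(yield) * 1.05 + 1e-9
  z <- pmin(pmax(yield / ymax0, 1e-9), 1 - 1e-9)
  lw <- log(-log(1 - z))
  cf <- tryCatch(stats::coef(stats::lm(lw ~ log(r))),
                 error = function(e) c(0, -0.5))
  p0 <- min(max(cf[2], -0.95), -0.05)
  k0 <- -exp(min(max(cf[1], -20), 20))
  to_t <- function(ymax, k, p) c(log(ymax), log(-k), stats::qlogis(-p))
  starts <- list(
    to_t(ymax0, k0, p0),
    to_t(ymax0, -1, -0.5),
    to_t(max(yield) * 1.5 + 1e-9, -0.1, -0.8),
    to_t(max(yield) * 1.1 + 1e-9, -5, -0.3)
  )

  best <- NULL
  for (t0 in starts) {
    f <- gn_fit(r, yield, t0, max_iter = max_iter, tol = tol)
    if (is.null(best) || f$sse < best$sse ||
        (f$converged && !best$converged && f$sse <= best$sse * (1 + 1e-9))) {
      best <- f
    }
    if (best$converged && best$sse <= f$sse) break
  }
  structure(list(
    ymax = exp(best$t[1]),
    k = -exp(best$t[2]),
    p = -stats::plogis(best$t[3]),
    rmse = sqrt(best$sse / length(yield)),
    converged = best$converged,
    iterations = best$iterations,
    window = window
  ), class = "yield_curve")
}

#' @export
print.yield_curve <- function(x, ...) {
  cat(sprintf(
    "Annualised harvest curve: ymax = %.4g m3/ha, k = %.4g, p = %.4g\n",
    x$ymax, x$k, x$p))
  cat(sprintf("  rmse = %.4g, %s (%d iterations)%s\n", x$rmse,
              if (x$converged) "converged" else "fallback",
              x$iterations,
              if (is.null(x$window)) "" else paste0(", window ", x$window)))
  invisible(x)
}

#' Rotation-age yields visible from a sliding window
#'
#' At simulation year `year`, the admissible slice of the yield tables
#' consists of entries whose harvest calendar year lies in
#' `(year - window, year]`, at stand ages within the rotation range implied
#' by the intensity bounds (10-160 years). Per-harvest yield at each age is
#' averaged over the establishment cohorts present in the window. If the
#' window precedes table coverage it is shifted to the nearest covered
#' span and flagged.
#'
#' @param tables Yield tables from [generate_yield_tables()] (one cell, or
#'   pre-filtered).
#' @param year Simulation calendar year.
#' @param window Window length in years (default 160, the table time
#'   scope).
#' @return data.frame `age`, `yield_m3_ha` (mean over cohorts), with
#'   attribute `shifted = TRUE` if the window had to be moved.
#' @export
yield_window <- function(tables, year, window = 160) {
  b <- intensity_bounds()
  age_rng <- sort(1 / b)
  sel <- tables$year > year - window & tables$year <= year &
    tables$age >= age_rng[1] & tables$age <= age_rng[2]
  shifted <- FALSE
  if (!any(sel)) {
    ymin <- min(tables$year)
    year2 <- min(max(tables$year), ymin + window)
    sel <- tables$year > year2 - window & tables$year <= year2 &
      tables$age >= age_rng[1] & tables$age <= age_rng[2]
    shifted <- TRUE
    stop_if(!any(sel), "yield tables do not cover any admissible window")
  }
  sl <- tables[sel, ]
  m <- tapply(sl$yield_m3_ha, sl$age, mean)
  out <- data.frame(age = as.numeric(names(m)), yield_m3_ha = as.numeric(m))
  attr(out, "shifted") <- shifted
  out
}

#' Re-estimate harvest-curve parameters for each cell at a given year
#'
#' Applies [yield_window()] and [fit_yield_curve()] per cell: the
#' sliding-window re-estimation that keeps the harvest curve aligned with
#' changing (tabulated) yields. Stationary tables give identical parameters
#' at every year.
#'
#' @param tables Yield tables with a `cell` column.
#' @param year Simulation calendar year.
#' @param window Window length (years).
#' @return Named list of `yield_curve` objects, one per cell.
#' @export
sliding_window_refit <- function(tables, year, window = 160) {
  b <- intensity_bounds()
  age_rng <- sort(1 / b)
  sel <- tables$year > year - window & tables$year <= year &
    tables$age >= age_rng[1] & tables$age <= age_rng[2]
  stop_if(!any(sel), "yield tables do not cover the requested window")
  sl <- tables[sel, c("cell", "age", "yield_m3_ha")]
  # mean per (cell, age) over cohorts in the window, all cells at once
  key <- paste(sl$cell, sl$age, sep = "\r")
  sums <- rowsum(cbind(sl$yield_m3_ha, 1), key, reorder = FALSE)
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  agg <- data.frame(
    cell = vapply(parts, `[`, "", 1),
    age = as.numeric(vapply(parts, `[`, "", 2)),
    yield = sums[, 1] / sums[, 2],
    stringsAsFactors = FALSE
  )
  lab <- sprintf("(%d,%d]", as.integer(year - window), as.integer(year))
  out <- lapply(split(agg, agg$cell), function(a) {
    fit_yield_curve(a$age, a$yield, window = lab)
  })
  out[order(names(out))]
}
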