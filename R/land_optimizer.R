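# Per-country least-cost choice of timber-forest area and management
# intensity.
#
# Each country must meet its required harvest (demand net of trade) from
# its grid cells. The annual cost is c*r per hectare of timber forest
# (management) plus an annualised conversion charge per hectare of newly
# converted timber forest. The solver is a shadow-price (Lagrangian)
# bisection: for a multiplier mu on harvest, each cell picks the intensity
# maximising mu*y(r) - c*r on a fine grid (continuous polish at the final
# multiplier), and expands into available unmanaged forest when the
# per-hectare surplus exceeds the conversion charge; mu is bisected until
# the target is met, then the solution is trimmed to the target exactly.

#' Cost parameters for land-use decisions
#'
#' @param mgmt Forest management cost scale c (currency/ha/yr per unit
#'   intensity): managing at intensity r costs `c * r` per hectare-year.
#' @param convert Annualised land-conversion cost (currency/ha/yr) for new
#'   timber forest.
#' @param trade_change Cost per m3 of changing net imports (charged in the
#'   country cost account).
#' @return List of class `cost_params`.
#' @export
cost_params <- function(mgmt = 1000, convert = 30, trade_change = 1) {
  stop_if(any(c(mgmt, convert, trade_change) < 0),
          "costs must be nonnegative")
  structure(list(mgmt = mgmt, convert = convert,
                 trade_change = trade_change),
            class = "cost_params")
}

# checks the land-fraction bookkeeping of a cell table
check_fractions <- function(cells, tol = 1e-9) {
  fr <- cells$frac_timber + cells$frac_unmanaged + cells$frac_agri +
    cells$frac_other
  stop_if(any(abs(fr - 1) > tol), "cell fractions must sum to 1")
  stop_if(any(cells$frac_timber < -tol | cells$frac_unmanaged < -tol |
                cells$frac_agri < -tol | cells$frac_other < -tol),
          "cell fractions must be nonnegative")
  invisible(cells)
}

#' Required harvest net of trade
#'
#' Industrial roundwood and wood fuel demand are pooled (no distinction
#' between wood products is made in harvesting or trade) and reduced by net
#' imports, floored at zero.
#'
#' @param demand Country wood demand (m3/yr); commodities are summed if a
#'   vector is given.
#' @param net_imports Net imports (m3/yr, negative = net exporter).
#' @return Required domestic harvest (m3/yr).
#' @export
required_harvest <- function(demand, net_imports = 0) {
  stop_if(any(demand < 0), "demand must be nonnegative")
  max(0, sum(demand) - net_imports)
}

# annualised harvest per hectare on cell i at intensities r (no bounds
# check; used on in-bounds grids)
cell_yield <- function(cells, i, r) {
  annualised_harvest(
    r, list(ymax = cells$ymax[i], k = cells$k[i], p = cells$p[i]),
    check_bounds = FALSE
  )
}

#' Least-cost country harvest decision
#'
#' Chooses management intensity per cell and expansion of timber forest
#' into unmanaged forest (never on protected cells) to meet `target` at
#' minimal management plus conversion cost. If the target is infeasible
#' even at the upper intensity bound on all available land, the maximal
#' harvest is returned with a positive shortfall (to be met by imports).
#'
#' @param target Required harvest (m3/yr).
#' @param cells Cell table: `cell`, `area_ha`, `frac_timber`,
#'   `frac_unmanaged`, `frac_agri`, `frac_other`, `r`, `ymax`, `k`, `p`,
#'   `protected`.
#' @param costs A [cost_params()] object.
#' @param allow_expansion Permit conversion of unmanaged forest to timber
#'   (default TRUE).
#' @param n_grid Intensity-grid resolution for the cell best response.
#' @return List of class `country_decision`: updated `cells`, `harvest`,
#'   `shortfall`, `cost`, `mu` (shadow price of wood).
#' @export
optimize_country <- function(target, cells, costs = cost_params(),
                             allow_expansion = TRUE, n_grid = 256) {
  stop_if(target < 0, "target must be nonnegative")
  check_fractions(cells)
  b <- intensity_bounds()
  n <- nrow(cells)
  if (n == 0) {
    return(structure(list(cells = cells, harvest = 0, shortfall = target,
                          cost = 0, mu = NA_real_),
                     class = "country_decision"))
  }
  cells <- cells[order(cells$cell), ] # deterministic tie-breaking
  timber_ha <- cells$area_ha * cells$frac_timber
  avail_ha <- if (allow_expansion) {
    cells$area_ha * cells$frac_unmanaged * (1 - as.numeric(cells$protected))
  } else {
    rep(0, n)
  }

  rgrid <- seq(b[1], b[2], length.out = n_grid)
  ygrid <- matrix(0, n, n_grid) # per-ha annualised harvest on the grid
  for (i in seq_len(n)) ygrid[i, ] <- cell_yield(cells, i, rgrid)
  c_mgmt <- costs$mgmt

  # best response at multiplier mu: intensity index per cell, expansion
  respond <- function(mu) {
    net <- mu * ygrid - c_mgmt * matrix(rgrid, n, n_grid, byrow = TRUE)
    idx <- max.col(net, ties.method = "first")
    surplus <- net[cbind(seq_len(n), idx)]
    expand <- allow_expansion & (surplus > costs$convert) & (avail_ha > 0)
    r <- rgrid[idx]
    harvest <- (timber_ha + ifelse(expand, avail_ha, 0)) *
      ygrid[cbind(seq_len(n), idx)]
    list(r = r, expand = expand, harvest = sum(harvest))
  }

  r_opt <- rep(b[1], n)
  e_opt <- rep(0, n)
  mu <- 0

  if (target <= 0) {
    # no requirement: minimal cost is the lower bound everywhere
    harvest <- sum(timber_ha * cell_yield_vec(cells, r_opt))
  } else {
    hmax <- sum((timber_ha + avail_ha) *
                  vapply(seq_len(n), function(i) cell_yield(cells, i, b[2]),
                         numeric(1)))
    if (target >= hmax) {
      r_opt <- rep(b[2], n)
      e_opt <- avail_ha
      harvest <- hmax
      mu <- Inf
    } else {
      # bisection on the shadow price
      lo <- 0
      hi <- c_mgmt / max(max(ygrid), 1e-12) + 1e-6
      while (respond(hi)$harvest < target && hi < 1e18) hi <- hi * 4
      for (iter in 1:90) {
        mid <- (lo + hi) / 2
        if (respond(mid)$harvest >= target) hi <- mid else lo <- mid
      }
      mu <- hi
      # candidate solutions: take the grid best response at either bracket
      # end and balance one marginal cell exactly to the target (adjusting
      # its intensity, or its expansion fraction); keep the cheapest
      # feasible candidate
      cand_cost <- Inf
      consider <- function(r_c, e_c) {
        h <- sum((timber_ha + e_c) * cell_yield_vec(cells, r_c))
        if (h < target * (1 - 1e-9)) return(invisible(NULL))
        cost <- sum(c_mgmt * r_c * (timber_ha + e_c)) +
          costs$convert * sum(e_c)
        if (cost < cand_cost) {
          cand_cost <<- cost
          r_opt <<- r_c
          e_opt <<- e_c
          harvest <<- h
        }
        invisible(NULL)
      }
      for (bp in list(respond(hi), respond(lo))) {
        r_b <- bp$r
        e_b <- ifelse(bp$expand, avail_ha, 0)
        consider(r_b, e_b) # as-is (only feasible for the hi response)
        h_cells <- (timber_ha + e_b) * cell_yield_vec(cells, r_b)
        total <- sum(h_cells)
        for (j in seq_len(n)) {
          a_j <- timber_ha[j] + e_b[j]
          need <- target - (total - h_cells[j])
          if (a_j > 0) {
            # adjust cell j's intensity to hit the target exactly
            h_lo <- a_j * cell_yield(cells, j, b[1])
            h_hi <- a_j * cell_yield(cells, j, b[2])
            if (need <= h_lo) {
              r_c <- r_b; r_c[j] <- b[1]
              consider(r_c, e_b)
            } else if (need <= h_hi) {
              r_j <- stats::uniroot(
                function(r) a_j * cell_yield(cells, j, r) - need,
                lower = b[1], upper = b[2], tol = 1e-14
              )$root
              r_c <- r_b; r_c[j] <- r_j
              consider(r_c, e_b)
            }
          }
          if (avail_ha[j] > 0) {
            # adjust cell j's expansion fraction at its chosen intensity
            base_j <- timber_ha[j] * cell_yield(cells, j, r_b[j])
            need_e <- target - (total - h_cells[j]) - base_j
            y_j <- cell_yield(cells, j, r_b[j])
            if (y_j > 0) {
              e_j <- min(max(need_e / y_j, 0), avail_ha[j])
              e_c <- e_b; e_c[j] <- e_j
              consider(r_b, e_c)
            }
          }
        }
      }
      if (!is.finite(cand_cost)) {
        # fall back to the feasible grid response at the upper bracket
        bp <- respond(hi)
        r_opt <- bp$r
        e_opt <- ifelse(bp$expand, avail_ha, 0)
        harvest <- sum((timber_ha + e_opt) * cell_yield_vec(cells, r_opt))
      }
    }
  }

  shortfall <- max(0, target - harvest)
  cost <- sum(c_mgmt * r_opt * (timber_ha + e_opt)) +
    costs$convert * sum(e_opt)
  out <- cells
  out$r <- r_opt
  out$frac_timber <- out$frac_timber + e_opt / out$area_ha
  out$frac_unmanaged <- out$frac_unmanaged - e_opt / out$area_ha
  check_fractions(out)
  structure(list(cells = out, harvest = harvest, shortfall = shortfall,
                 cost = cost,
                 mu = mu),
            class = "country_decision")
}

# vectorised per-ha yield at cell-specific intensities
cell_yield_vec <- function(cells, r) {
  cells$ymax * (1 - exp(cells$k * r^cells$p)) * r
}

#' Abandon unviable timber forest during spin-up
#'
#' Cells whose maximal achievable annualised yield (at the upper intensity
#' bound) falls below `threshold` have their timber fraction reassigned to
#' unmanaged forest, emulating abandonment of initialised timber forest in
#' low-productivity regions.
#'
#' @param cells Cell table (see [optimize_country()]).
#' @param threshold Viability threshold (m3/ha/yr).
#' @return Updated cell table (land conserved per cell).
#' @export
spinup_abandonment <- function(cells, threshold = 0.2) {
  check_fractions(cells)
  ymax_r <- cell_yield_vec(cells, rep(intensity_bounds()[2], nrow(cells)))
  drop <- ymax_r < threshold & cells$frac_timber > 0
  cells$frac_unmanaged[drop] <- cells$frac_unmanaged[drop] +
    cells$frac_timber[drop]
  cells$frac_timber[drop] <- 0
  check_fractions(cells)
  cells
}

#' Apply an exogenous agricultural land requirement
#'
#' Moves land between agriculture and forest to reach `ag_target` hectares
#' of agriculture in the country. Expansion takes unmanaged forest first
#' (never on protected cells), then timber forest, in ascending order of
#' potential cell yield; contraction returns agricultural land to unmanaged
#' forest. Land is conserved per cell.
#'
#' @param cells Cell table (see [optimize_country()]).
#' @param ag_target Required agricultural area (ha).
#' @return Updated cell table.
#' @export
apply_agricultural_demand <- function(cells, ag_target) {
  check_fractions(cells)
  stop_if(ag_target < 0, "agricultural area must be nonnegative")
  cur <- sum(cells$area_ha * cells$frac_agri)
  delta <- ag_target - cur
  if (abs(delta) < 1e-9) return(cells)
  pot <- cell_yield_vec(cells, rep(intensity_bounds()[2], nrow(cells)))
  if (delta > 0) {
    takeable <- cells$area_ha * cells$frac_unmanaged *
      (1 - as.numeric(cells$protected))
    stop_if(delta > sum(takeable) +
              sum(cells$area_ha * cells$frac_timber) + 1e-6,
            "agricultural trajectory exceeds available country land")
    for (pool in c("unmanaged", "timber")) {
      for (i in order(pot)) {
        if (delta <= 0) break
        avail <- if (pool == "unmanaged") {
          cells$area_ha[i] * cells$frac_unmanaged[i] *
            (1 - as.numeric(cells$protected[i]))
        } else {
          cells$area_ha[i] * cells$frac_timber[i]
        }
        take <- min(avail, delta)
        if (take <= 0) next
        fr <- take / cells$area_ha[i]
        if (pool == "unmanaged") {
          cells$frac_unmanaged[i] <- cells$frac_unmanaged[i] - fr
        } else {
          cells$frac_timber[i] <- cells$frac_timber[i] - fr
        }
        cells$frac_agri[i] <- cells$frac_agri[i] + fr
        delta <- delta - take
      }
    }
  } else {
    rel <- -delta
    for (i in order(pot, decreasing = TRUE)) {
      if (rel <= 0) break
      avail <- cells$area_ha[i] * cells$frac_agri[i]
      give <- min(avail, rel)
      if (give <= 0) next
      fr <- give / cells$area_ha[i]
      cells$frac_agri[i] <- cells$frac_agri[i] - fr
      cells$frac_unmanaged[i] <- cells$frac_unmanaged[i] + fr
      rel <- rel - give
    }
  }
  check_fractions(cells)
  cells
}
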