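# Multiplicative attribution of global harvest change to timber area,
# management intensity, potential yield, and the intensity-yield
# interaction.
#
# Global harvest is H = sum_cells area_i * y(r_i; params_i). Counterfactual
# harvests are formed by combining area, intensity and yield-curve
# parameters from the two epochs (corner counterfactuals). Harvest is
# linear in area, so area carries no interaction; the residual interaction
# is assigned to intensity x yield, whose factors enter y jointly and
# non-linearly.

#' Harvest factor snapshot for one epoch
#'
#' @param cells data.frame with columns `cell`, `timber_ha` (timber area,
#'   ha), `r` (management intensity), `ymax`, `k`, `p`.
#' @return Object of class `harvest_factors` with the implied global
#'   harvest attached.
#' @export
harvest_factors <- function(cells) {
  need <- c("cell", "timber_ha", "r", "ymax", "k", "p")
  miss <- setdiff(need, names(cells))
  stop_if(length(miss) > 0,
          "missing columns: ", paste(miss, collapse = ", "))
  cells <- cells[order(cells$cell), ]
  h <- sum(cells$timber_ha *
             annualised_harvest_raw(cells$r, cells$ymax, cells$k, cells$p))
  structure(list(cells = cells, harvest = h), class = "harvest_factors")
}

# bounds-free vectorised harvest used by the counterfactuals
annualised_harvest_raw <- function(r, ymax, k, p) {
  ymax * (1 - exp(k * r^p)) * r
}

#' Decompose global harvest change into multiplicative factors
#'
#' Computes counterfactual harvests `H(a, b, c)` where `a`, `b`, `c` pick
#' the epoch (baseline/final) of areas, intensities and yield-curve
#' parameters respectively. Factor ratios are
#' `area = H(1,0,0)/H(0,0,0)`, `intensity = H(0,1,0)/H(0,0,0)`,
#' `yield = H(0,0,1)/H(0,0,0)`, and the intensity-yield interaction is the
#' total ratio divided by the three single-factor ratios, so the product of
#' the four ratios equals the total harvest ratio exactly. Contributions
#' are reported as `(ratio - 1) * 100` percent.
#'
#' @param baseline,final [harvest_factors()] snapshots over the same cell
#'   set.
#' @return data.frame with rows area, intensity, potential_yield,
#'   intensity_x_yield, total: columns `factor`, `ratio`,
#'   `contribution_pct`.
#' @export
decompose_harvest <- function(baseline, final) {
  stop_if(!inherits(baseline, "harvest_factors") ||
            !inherits(final, "harvest_factors"),
          "inputs must be harvest_factors snapshots")
  b <- baseline$cells
  f <- final$cells
  stop_if(!identical(b$cell, f$cell),
          "baseline and final must cover the same cells")
  H <- function(a_f, r_f, y_f) {
    area <- if (a_f) f$timber_ha else b$timber_ha
    r <- if (r_f) f$r else b$r
    if (y_f) {
      sum(area * annualised_harvest_raw(r, f$ymax, f$k, f$p))
    } else {
      sum(area * annualised_harvest_raw(r, b$ymax, b$k, b$p))
    }
  }
  h000 <- H(FALSE, FALSE, FALSE)
  stop_if(h000 <= 0, "zero baseline harvest: ratios undefined")
  total <- H(TRUE, TRUE, TRUE) / h000
  area <- H(TRUE, FALSE, FALSE) / h000
  intensity <- H(FALSE, TRUE, FALSE) / h000
  yield <- H(FALSE, FALSE, TRUE) / h000
  interaction <- total / (area * intensity * yield)
  ratios <- c(area = area, intensity = intensity,
              potential_yield = yield,
              intensity_x_yield = interaction, total = total)
  data.frame(
    factor = names(ratios),
    ratio = as.numeric(ratios),
    contribution_pct = (as.numeric(ratios) - 1) * 100,
    stringsAsFactors = FALSE
  )
}
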