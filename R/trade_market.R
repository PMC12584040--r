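# Single global wood market: net-import constraints, balance clearing and
# the endogenous price index (2020 = 100).

#' Constrain desired net imports to the allowed annual band
#'
#' Net-import changes are limited to a fraction of the current trade level;
#' countries with no current trade are admitted up to an absolute floor so
#' entrants are possible.
#'
#' @param desired Desired net imports (m3/yr), vectorised.
#' @param current Current net imports (m3/yr).
#' @param limit_frac Allowed change as a fraction of `abs(current)` (> 0).
#' @param floor_abs Absolute band half-width for zero-trade entrants (m3).
#' @return Allowed net imports, clipped into
#'   `current +/- max(limit_frac * abs(current), floor_abs_if_zero)`.
#' @export
constrain_net_imports <- function(desired, current, limit_frac = 0.1,
                                  floor_abs = 0) {
  stop_if(limit_frac <= 0, "limit fraction must be positive")
  band <- limit_frac * abs(current)
  band[current == 0] <- floor_abs
  pmin(pmax(desired, current - band), current + band)
}

#' Update the wood price index from the global balance
#'
#' Multiplicative excess-demand rule:
#' `index * (1 + lambda * (demand - supply) / max(demand, eps))`.
#' Strictly increasing in excess demand; a cleared market leaves the index
#' unchanged.
#'
#' @param index Current price index (> 0; 100 in the 2020 base year).
#' @param demand,supply Global demand and supply (m3/yr).
#' @param lambda Adjustment rate in (0, 1].
#' @param eps Demand floor guarding the division.
#' @return Updated price index.
#' @export
update_price <- function(index, demand, supply, lambda = 0.5, eps = 1e-9) {
  stop_if(index <= 0, "price index must be positive")
  stop_if(demand < 0 || supply < 0, "demand and supply must be nonnegative")
  stop_if(lambda <= 0 || lambda > 1, "lambda must be in (0, 1]")
  index * (1 + lambda * (demand - supply) / max(demand, eps))
}

#' Construct a market state
#'
#' @param year Calendar year.
#' @param price_index Price index (2020 = 100).
#' @param net_imports Named vector of per-country net imports (m3/yr).
#' @param stock Global stock level (m3).
#' @return List of class `market_state`.
#' @export
market_state <- function(year, price_index = 100,
                         net_imports = numeric(), stock = 0) {
  stop_if(price_index <= 0, "price index must be positive")
  structure(list(year = year, price_index = price_index,
                 net_imports = net_imports, stock = stock),
            class = "market_state")
}
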