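# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

#' Derive a child seed from a master seed and an index
#'
#' Arithmetic hash into 31-bit integer space so that ensemble members and
#' synthetic-world components get independent, reproducible substreams.
#' Growing the ensemble does not perturb seeds of earlier members.
#'
#' @param master Master seed (integer-like).
#' @param index Substream index (integer-like, >= 0).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
hash_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.double(master) %% m
  x <- (s * 48271 + as.double(index) * 30269 + 11213) %% m
  x <- (x * 69621) %% m
  as.integer(max(1, x))
}

#' Area of a latitude-longitude grid cell in hectares
#'
#' Spherical-cap formula for a cell of `res` degrees centred at `lat`.
#'
#' @param lat Centre latitude in degrees.
#' @param res Cell edge in degrees (default 0.5).
#' @param radius_km Earth radius in km.
#' @return Area in hectares.
#' @export
cell_area_ha <- function(lat, res = 0.5, radius_km = 6371) {
  dlon <- res * pi / 180
  lat1 <- pmax(-90, lat - res / 2) * pi / 180
  lat2 <- pmin(90, lat + res / 2) * pi / 180
  area_km2 <- radius_km^2 * dlon * (sin(lat2) - sin(lat1))
  area_km2 * 100
}

# x * log(x) with the 0 * log(0) -> 0 limit, for entropy-like sums
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
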