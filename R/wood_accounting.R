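# Wood accounting: from heterogeneous wood-product statistics to
# commodity-level apparent consumption and prices.
#
# Reported items are mapped to the two model commodities (industrial
# roundwood, wood fuel). Items reported in tonnes are converted to cubic
# metres with fixed conversion ratios; processed items count one-to-one
# against their raw commodity volume (no loss adjustment). Apparent
# consumption is the mass balance
#   consumption = harvest + sum(imports_i) - sum(exports_i)
# and commodity prices are trade-value unit prices, volume-weighted across
# import and export flows, with median imputation where a country reports
# no trade.

#' Wood item vocabulary
#'
#' The ten reported wood items, their model commodity, and the
#' tonne-to-cubic-metre conversion ratio for mass-reported items
#' (`NA` for items already reported in m3). `raw` marks the two items whose
#' domestic production is the commodity harvest itself.
#'
#' @return A data.frame with columns `item`, `commodity`, `ratio`, `raw`.
#' @export
wood_items <- function() {
  data.frame(
    item = c(
      "Industrial roundwood", "Sawnwood", "Wood-based panels",
      "Veneer sheets", "Wood chips, particles and residues",
      "Wood pulp", "Paper and paperboard",
      "Wood fuel", "Wood pellets and other agglomerates", "Wood charcoal"
    ),
    commodity = c(
      rep("industrial_roundwood", 7),
      rep("wood_fuel", 3)
    ),
    ratio = c(NA, NA, NA, NA, NA, 1.48, 1.48, NA, 1.38, 5.99),
    raw = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
            TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Map a wood item to its model commodity
#'
#' @param item Character vector of item names (must be in [wood_items()]).
#' @return Character vector: `"industrial_roundwood"` or `"wood_fuel"`.
#' @export
#' @examples
#' map_item("Sawnwood")
#' map_item("Wood charcoal")
map_item <- function(item) {
  vocab <- wood_items()
  idx <- match(item, vocab$item)
  if (anyNA(idx)) {
    bad <- unique(item[is.na(idx)])
    stop("unknown wood item(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  vocab$commodity[idx]
}

#' Convert a reported quantity to cubic metres
#'
#' Mass-reported items (wood pulp, paper and paperboard, wood pellets and
#' other agglomerates, wood charcoal) are converted with their fixed
#' ratios; items reported in m3 pass through unchanged.
#'
#' @param quantity Nonnegative quantities (tonnes for mass-reported items,
#'   m3 otherwise).
#' @param item Item names, recycled against `quantity`.
#' @return Volumes in m3.
#' @export
#' @examples
#' convert_to_volume(1, "Wood charcoal") # 5.99
convert_to_volume <- function(quantity, item) {
  stop_if(any(quantity < 0), "quantity must be nonnegative")
  vocab <- wood_items()
  idx <- match(item, vocab$item)
  if (anyNA(idx)) {
    stop("unknown wood item(s): ",
         paste(unique(item[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  ratio <- vocab$ratio[idx]
  ratio[is.na(ratio)] <- 1
  quantity * ratio
}

#' Apparent consumption mass balance
#'
#' `harvest + sum(imports) - sum(exports)`. A negative result (inconsistent
#' reported statistics) is returned with attribute `flagged = TRUE`, not
#' rejected.
#'
#' @param harvest Domestic harvest of the raw commodity (m3).
#' @param imports,exports Numeric vectors of item-level trade volumes (m3).
#' @return Apparent consumption in m3.
#' @export
apparent_consumption <- function(harvest, imports = numeric(),
                                 exports = numeric()) {
  stop_if(harvest < 0 || any(imports < 0) || any(exports < 0),
          "volumes must be nonnegative")
  out <- harvest + sum(imports) - sum(exports)
  if (out < 0) attr(out, "flagged") <- TRUE
  out
}

#' Trade-value price estimate for one country and commodity
#'
#' Price = (import value + export value) / (import volume + export volume),
#' i.e. the volume-weighted mean of unit import and export prices. With no
#' trade at all the estimate is absent (`NA`, provenance `"missing"`) and
#' is later median-imputed; value reported against zero volume flags the
#' record as inconsistent.
#'
#' @param import_value,export_value Trade values (currency units).
#' @param import_volume,export_volume Trade volumes (m3).
#' @return data.frame with columns `price` and `provenance`
#'   (`observed` / `missing` / `inconsistent`).
#' @export
estimate_price <- function(import_value, import_volume,
                           export_value, export_volume) {
  stop_if(any(c(import_volume, export_volume) < 0),
          "volumes must be nonnegative")
  stop_if(any(c(import_value, export_value) < 0),
          "values must be nonnegative")
  vol <- import_volume + export_volume
  val <- import_value + export_value
  if (vol == 0) {
    prov <- if (val > 0) "inconsistent" else "missing"
    return(data.frame(price = NA_real_, provenance = prov,
                      stringsAsFactors = FALSE))
  }
  data.frame(price = val / vol, provenance = "observed",
             stringsAsFactors = FALSE)
}

#' Validate a long-format wood record table
#'
#' Expected columns: `country`, `year`, `item`, `flow`
#' (production/import/export), `quantity`, `unit` (`t` or `m3`), `value`.
#'
#' @param records data.frame of wood item records.
#' @return `records`, invisibly, after checks.
#' @export
validate_wood_records <- function(records) {
  need <- c("country", "year", "item", "flow", "quantity", "unit", "value")
  miss <- setdiff(need, names(records))
  stop_if(length(miss) > 0,
          "missing record columns: ", paste(miss, collapse = ", "))
  map_item(unique(records$item)) # errors on out-of-vocabulary items
  stop_if(!all(records$flow %in% c("production", "import", "export")),
          "flow must be production, import or export")
  stop_if(!all(records$unit %in% c("t", "m3")), "unit must be 't' or 'm3'")
  stop_if(any(records$quantity < 0), "quantities must be nonnegative")
  stop_if(any(records$value < 0, na.rm = TRUE),
          "values must be nonnegative")
  invisible(records)
}

#' Apply a correction hook to wood records
#'
#' Reported statistics may need corrections for under-reporting and
#' inconsistencies; the exact procedure is data-source specific, so it is
#' exposed as a pluggable transformation. The default is the identity.
#' Hook output is re-validated; violations of nonnegativity or vocabulary
#' are rejected.
#'
#' @param records Wood record table (see [validate_wood_records()]).
#' @param hook Function `records -> records`; default `identity`.
#' @return Corrected record table.
#' @export
apply_corrections <- function(records, hook = identity) {
  validate_wood_records(records)
  if (!identical(hook, identity)) {
    message("applying non-default correction hook")
  }
  out <- hook(records)
  validate_wood_records(out)
  out
}

#' Commodity balance and prices from wood item records
#'
#' Runs the full accounting chain: optional corrections, tonne-to-m3
#' conversion, mapping of items to commodities, the apparent-consumption
#' mass balance, and trade-based price estimation with global median
#' imputation (per commodity and year, midpoint convention for even
#' counts). Harvest is the production of the raw commodity item; processed
#' items enter through trade only, with one-to-one volume equivalence.
#'
#' @param records Long wood record table (see [validate_wood_records()]).
#' @param hook Correction hook, default identity.
#' @return data.frame with one row per country, year and commodity:
#'   `harvest_m3`, `imports_m3`, `exports_m3`, `consumption_m3`,
#'   `consumption_flagged`, `price`, `price_provenance`.
#' @export
wood_balance <- function(records, hook = identity) {
  records <- apply_corrections(records, hook)
  vocab <- wood_items()
  records$commodity <- map_item(records$item)
  records$volume <- ifelse(
    records$unit == "t",
    convert_to_volume(records$quantity, records$item),
    records$quantity
  )
  records$is_raw <- vocab$raw[match(records$item, vocab$item)]

  key <- interaction(records$country, records$year, records$commodity,
                     drop = TRUE, sep = "\r")
  agg <- function(sel) {
    v <- tapply(records$volume[sel], key[sel], sum)
    v[is.na(v)] <- 0
    out <- stats::setNames(rep(0, nlevels(key)), levels(key))
    out[names(v)] <- v
    out
  }
  harvest <- agg(records$flow == "production" & records$is_raw)
  imports <- agg(records$flow == "import")
  exports <- agg(records$flow == "export")
  val <- function(sel) {
    v <- tapply(records$value[sel], key[sel], sum, na.rm = TRUE)
    v[is.na(v)] <- 0
    out <- stats::setNames(rep(0, nlevels(key)), levels(key))
    out[names(v)] <- v
    out
  }
  imp_val <- val(records$flow == "import")
  exp_val <- val(records$flow == "export")

  parts <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  out <- data.frame(
    country = parts[, 1],
    year = as.integer(parts[, 2]),
    commodity = parts[, 3],
    harvest_m3 = as.numeric(harvest),
    imports_m3 = as.numeric(imports),
    exports_m3 = as.numeric(exports),
    stringsAsFactors = FALSE
  )
  out$consumption_m3 <- out$harvest_m3 + out$imports_m3 - out$exports_m3
  out$consumption_flagged <- out$consumption_m3 < 0

  price <- numeric(nrow(out))
  prov <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    est <- estimate_price(imp_val[i], out$imports_m3[i],
                          exp_val[i], out$exports_m3[i])
    price[i] <- est$price
    prov[i] <- est$provenance
  }
  # median imputation over countries with observed prices, per commodity-year
  for (grp in split(seq_len(nrow(out)),
                    interaction(out$commodity, out$year, drop = TRUE))) {
    obs <- grp[prov[grp] == "observed"]
    nas <- grp[is.na(price[grp])]
    if (length(nas) > 0 && length(obs) > 0) {
      price[nas] <- stats::median(price[obs])
      prov[nas] <- "median-imputed"
    }
  }
  out$price <- price
  out$price_provenance <- prov
  rownames(out) <- NULL
  out[order(out$country, out$year, out$commodity), ]
}

#' Read wood item records from a delimited file
#'
#' @param path CSV file with columns country, year, item, flow, quantity,
#'   unit, value.
#' @return Validated record data.frame.
#' @export
read_wood_records <- function(path) {
  validate_wood_records(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  )
}
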