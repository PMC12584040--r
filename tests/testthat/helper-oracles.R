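# exhaustive grid-search oracle: minimal cost meeting the target with
# intensities on a grid (optionally expansion as a binary per cell)
grid_oracle <- function(target, cells, costs, n_r = 200,
                        expansion = FALSE) {
  b <- intensity_bounds()
  rg <- seq(b[1], b[2], length.out = n_r)
  n <- nrow(cells)
  timber <- cells$area_ha * cells$frac_timber
  avail <- if (expansion) {
    cells$area_ha * cells$frac_unmanaged * (1 - as.numeric(cells$protected))
  } else {
    rep(0, n)
  }
  ylist <- lapply(seq_len(n), function(i) {
    cells$ymax[i] * (1 - exp(cells$k[i] * rg^cells$p[i])) * rg
  })
  e_levels <- if (expansion) c(0, 1) else 0
  combos <- expand.grid(c(rep(list(seq_len(n_r)), n),
                          rep(list(e_levels), n)))
  ridx <- as.matrix(combos[, seq_len(n), drop = FALSE])
  eidx <- as.matrix(combos[, n + seq_len(n), drop = FALSE])
  harvest <- 0
  cost <- 0
  for (i in seq_len(n)) {
    a_i <- timber[i] + eidx[, i] * avail[i]
    harvest <- harvest + a_i * ylist[[i]][ridx[, i]]
    cost <- cost + costs$mgmt * rg[ridx[, i]] * a_i +
      costs$convert * eidx[, i] * avail[i]
  }
  feas <- harvest >= target * (1 - 1e-9)
  if (!any(feas)) return(Inf)
  min(cost[feas])
}
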