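# Builders for small in-code fixtures and independent oracles.

# Minimal specimen table; measurement columns default to NA.
make_specimens <- function(n, taxon = "Taxon A", x = NULL, y = NULL, ...) {
  df <- data.frame(specimen_id = paste0("sp", seq_len(n)),
                   x = if (is.null(x)) seq_len(n) / (n + 1) else x,
                   y = if (is.null(y)) rep(0.5, n) else y,
                   taxon = taxon, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# A surface whose taxa occupy prescribed uptake intervals: one upright
# specimen per row of `bands` (lo = stem, hi = stem + frond).
band_surface <- function(taxa, lo, hi, n_per = 1) {
  rows <- rep(seq_along(taxa), n_per)
  sp <- make_specimens(length(rows),
                       taxon = taxa[rows],
                       stem_length = lo[rows],
                       frond_length = hi[rows] - lo[rows],
                       frond_width = (hi[rows] - lo[rows]) / 2)
  derive_geometry(surface_map(sp, extent = c(0, 1, 0, 1)))
}

# Brute-force DVS-u oracle on a 0.01 mm occupancy grid: per taxon, mark
# grid cells overlapped by any specimen interval; the score is the
# fraction of the taxon's occupied cells not occupied by any other taxon.
grid_dvs_u <- function(intervals_by_taxon, g = 0.01) {
  top <- max(vapply(intervals_by_taxon, function(m) max(m[, 2]), 0))
  ncell <- ceiling(top / g) + 1L
  occ <- sapply(intervals_by_taxon, function(m) {
    cells <- rep(FALSE, ncell)
    for (i in seq_len(nrow(m))) {
      if (m[i, 2] <= m[i, 1]) next
      a <- floor(m[i, 1] / g) + 1L
      b <- ceiling(m[i, 2] / g)
      if (b >= a) cells[a:b] <- TRUE
    }
    cells
  })
  vapply(seq_len(ncol(occ)), function(j) {
    mine <- occ[, j]
    if (!any(mine)) return(NA_real_)
    others <- rowSums(occ[, -j, drop = FALSE]) > 0
    sum(mine & !others) / sum(mine)
  }, 0)
}

# Closed-form W from share vectors (hand-evaluated cumulative curves).
w_from_shares <- function(p, q) {
  p <- 100 * p / sum(p); q <- 100 * q / sum(q)
  S <- length(p)
  sum(cumsum(sort(p, decreasing = TRUE)) -
      cumsum(sort(q, decreasing = TRUE))) / (50 * (S - 1))
}

# Planted-W surface: abundance shares p, expected biomass shares q.
planted_surface <- function(p, q, total_n = 1000, id = "planted",
                            seed = 1L) {
  derive_geometry(generate_surface(synthetic_surface_config(
    planted_share_taxa(p, q), total_n = total_n, surface_id = id,
    seed = seed)))
}
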