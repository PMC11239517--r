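#' Specify a synthetic taxon
#'
#' A taxon's statistical recipe for the community generator: relative
#' abundance weight, spatial point process, size distributions and gross
#' morphology. Sizes are lognormal in mm; widths follow a fixed allometry
#' `width = width_allometry * length`. Reclining taxa have no stem and sit
#' on the substrate (height derives from frond width); stemmed upright
#' taxa get a lognormal stem. Upright and bush/comb forms carry a circular
#' holdfast disc whose diameter is lognormal — the calibration target for
#' retrodeformation.
#'
#' @param name taxon label, e.g. `"Fractofusus misrai"`.
#' @param morphogroup one of `"reclining"`, `"bradgatia"`,
#'   `"pectinifrons"`, `"upright_frond"`, `"other"`.
#' @param abundance_weight positive relative weight.
#' @param spatial list: `type = "poisson"` (uniform) or `type = "thomas"`
#'   with `n_parents`, `cluster_sd` (metres).
#' @param frond_length_dist `c(meanlog, sdlog)` of frond length, mm.
#' @param stem_length_dist `c(meanlog, sdlog)` or NULL for stemless taxa.
#' @param width_allometry frond width / frond length ratio in (0, 1].
#' @param reclining logical; TRUE forces morphogroup `"reclining"`.
#' @param disc logical: does the taxon bear a holdfast disc?
#' @param disc_diameter_dist `c(meanlog, sdlog)` of disc diameter, mm.
#' @return object of class `taxon_spec`.
#' @export
taxon_spec <- function(name, morphogroup = "upright_frond",
                       abundance_weight = 1,
                       spatial = list(type = "poisson"),
                       frond_length_dist = c(log(40), 0.3),
                       stem_length_dist = NULL,
                       width_allometry = 0.4,
                       reclining = morphogroup == "reclining",
                       disc = !reclining,
                       disc_diameter_dist = c(log(15), 0.25)) {
  stopifnot(abundance_weight > 0, width_allometry > 0,
            width_allometry <= 1)
  if (reclining) morphogroup <- "reclining"
  structure(list(name = name, morphogroup = morphogroup,
                 abundance_weight = abundance_weight, spatial = spatial,
                 frond_length_dist = frond_length_dist,
                 stem_length_dist = stem_length_dist,
                 width_allometry = width_allometry,
                 reclining = reclining, disc = disc,
                 disc_diameter_dist = disc_diameter_dist),
            class = "taxon_spec")
}

#' Configure a synthetic surface
#'
#' @param taxa list of [taxon_spec()]s.
#' @param total_n total specimen count.
#' @param extent `c(xmin, xmax, ymin, ymax)` metres; default 10 x 10 m.
#' @param succession_state optional `"early"`, `"intermediate"` or
#'   `"late"`. Controls the covariance of abundance rank and body size by
#'   rescaling frond-size distributions so expected per-taxon biomass
#'   shares are uniform (early: the dominant taxon is the smallest-bodied
#'   and rare taxa are large, guaranteeing expected abundance dominance,
#'   W > 0), proportional to abundance (intermediate, W ~ 0) or
#'   proportional to abundance squared (late: the dominant taxon is also
#'   the largest, biomass dominance, W < 0).
#' @param shear optional list `(factor, orientation_deg)`: forward
#'   area-preserving pure shear applied to the finished surface (see
#'   [shear_surface()]).
#' @param effaced_fraction probability in `[0, 1)` that an upright-frond
#'   specimen is recorded as an effaced frond (true identity retained in a
#'   hidden `true_taxon` column).
#' @param surface_id name for the generated surface.
#' @param seed RNG seed.
#' @return object of class `synthetic_surface_config`.
#' @export
synthetic_surface_config <- function(taxa, total_n = 500,
                                     extent = c(0, 10, 0, 10),
                                     succession_state = NULL,
                                     shear = NULL,
                                     effaced_fraction = 0,
                                     surface_id = "synthetic",
                                     seed = 1L) {
  stopifnot(total_n >= 1, effaced_fraction >= 0, effaced_fraction < 1,
            length(taxa) >= 1)
  if ((extent[2] - extent[1]) * (extent[4] - extent[3]) <= 0)
    stop("zero-area extent", call. = FALSE)
  structure(list(taxa = taxa, total_n = as.integer(total_n),
                 extent = extent, succession_state = succession_state,
                 shear = shear, effaced_fraction = effaced_fraction,
                 surface_id = surface_id, seed = seed),
            class = "synthetic_surface_config")
}

# Draw n positions from a taxon's point process, clipped to the extent.
.draw_positions <- function(n, spatial, extent) {
  if (!n) return(cbind(x = numeric(0), y = numeric(0)))
  if (identical(spatial$type, "thomas")) {
    np <- max(1L, spatial$n_parents)
    px <- stats::runif(np, extent[1], extent[2])
    py <- stats::runif(np, extent[3], extent[4])
    x <- numeric(0); y <- numeric(0)
    while (length(x) < n) {
      k <- sample.int(np, n, replace = TRUE)
      cx <- px[k] + stats::rnorm(n, 0, spatial$cluster_sd)
      cy <- py[k] + stats::rnorm(n, 0, spatial$cluster_sd)
      ok <- cx >= extent[1] & cx <= extent[2] &
            cy >= extent[3] & cy <= extent[4]
      x <- c(x, cx[ok]); y <- c(y, cy[ok])
    }
    cbind(x = x[seq_len(n)], y = y[seq_len(n)])
  } else {
    cbind(x = stats::runif(n, extent[1], extent[2]),
          y = stats::runif(n, extent[3], extent[4]))
  }
}

# Frond-length meanlog offsets that plant a target expected biomass-share
# vector q against abundance shares p: per-specimen mean coverage scales
# as exp(2 * meanlog), so meanlog_t += 0.5 * log(m_t) with m_t = q_t / p_t
# (normalized to leave the community scale unchanged).
.state_meanlog_shift <- function(p, state) {
  q <- switch(state,
              early = rep(1 / length(p), length(p)),
              intermediate = p,
              late = p^2 / sum(p^2),
              stop("unknown succession_state: ", state, call. = FALSE))
  m <- q / p
  0.5 * log(m / exp(mean(log(m))))
}

#' Generate a synthetic surface map
#'
#' Draws a community from a [synthetic_surface_config()]: multinomial
#' specimen counts over abundance weights, positions from each taxon's
#' point process, lognormal sizes with fixed width allometries, optional
#' succession-state size rescaling, optional effacement of upright-frond
#' specimens, and an optional forward tectonic shear. Deterministic under
#' the configured seed.
#'
#' @param cfg a [synthetic_surface_config()].
#' @return a validated `surface_map` (derived geometry not yet computed);
#'   effaced specimens keep their identity in the hidden `true_taxon`
#'   column.
#' @export
generate_surface <- function(cfg) {
  set.seed(cfg$seed)
  w <- vapply(cfg$taxa, function(t) t$abundance_weight, 0)
  p <- w / sum(w)
  counts <- as.integer(stats::rmultinom(1, cfg$total_n, p))
  shift <- if (is.null(cfg$succession_state)) numeric(length(p)) else
    .state_meanlog_shift(p, cfg$succession_state)
  recs <- list()
  for (i in seq_along(cfg$taxa)) {
    tx <- cfg$taxa[[i]]
    n <- counts[i]
    if (!n) next
    xy <- .draw_positions(n, tx$spatial, cfg$extent)
    fl <- stats::rlnorm(n, tx$frond_length_dist[1] + shift[i],
                        tx$frond_length_dist[2])
    fw <- tx$width_allometry * fl
    if (!is.null(tx$stem_length_dist)) {
      sl <- stats::rlnorm(n, tx$stem_length_dist[1] + shift[i],
                          tx$stem_length_dist[2])
      sw <- 0.15 * sl
    } else sl <- sw <- rep(NA_real_, n)
    if (tx$disc) {
      dd <- stats::rlnorm(n, tx$disc_diameter_dist[1],
                          tx$disc_diameter_dist[2])
      dl <- dw <- dd
      dor <- stats::runif(n, 0, 180)
    } else dl <- dw <- dor <- rep(NA_real_, n)
    recs[[length(recs) + 1L]] <- data.frame(
      specimen_id = paste0(cfg$surface_id, "-", i, "-", seq_len(n)),
      x = xy[, "x"], y = xy[, "y"],
      taxon = tx$name, tax_level = "species",
      effaced_frond = FALSE, morphogroup = tx$morphogroup,
      disc_length = dl, disc_width = dw, disc_orientation = dor,
      stem_length = sl, stem_width = sw,
      frond_length = fl, frond_width = fw,
      true_taxon = tx$name)
  }
  sp <- do.call(rbind, recs)
  if (cfg$effaced_fraction > 0) {
    cand <- which(sp$morphogroup == "upright_frond")
    eff <- cand[stats::runif(length(cand)) < cfg$effaced_fraction]
    sp$effaced_frond[eff] <- TRUE
    sp$taxon[eff] <- "Effaced frond"
    sp$tax_level[eff] <- "morphocategory"
  }
  surf <- surface_map(sp, surface_id = cfg$surface_id,
                      extent = cfg$extent)
  if (!is.null(cfg$shear))
    surf <- shear_surface(surf, cfg$shear$factor,
                          cfg$shear$orientation_deg %||% 90)
  surf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Taxa with planted abundance and biomass shares
#'
#' Builds a taxon list whose expected abundance shares are `p` and whose
#' expected biomass (areal coverage) shares are `q`, by setting each
#' taxon's frond-length meanlog so per-specimen mean coverage is
#' proportional to `q / p`. The expected W statistic of the community is
#' then the closed-form ABC value of the share vectors, making planted-W
#' surfaces constructible from first principles.
#'
#' @param p abundance shares (positive, summing to 1).
#' @param q biomass shares (positive, summing to 1), same length.
#' @param names taxon labels; default `T1..Tk`.
#' @param sdlog lognormal spread of frond length (default 0.15; small so
#'   realized biomass shares track their expectation).
#' @param base_meanlog community-scale frond size (default `log(40)` mm).
#' @param morphogroup recycled over taxa.
#' @return list of [taxon_spec()]s.
#' @export
planted_share_taxa <- function(p, q, names = NULL, sdlog = 0.15,
                               base_meanlog = log(40),
                               morphogroup = "upright_frond") {
  stopifnot(length(p) == length(q), all(p > 0), all(q > 0))
  p <- p / sum(p); q <- q / sum(q)
  if (is.null(names)) names <- paste0("T", seq_along(p))
  morphogroup <- rep(morphogroup, length.out = length(p))
  m <- q / p
  mu <- base_meanlog + 0.5 * log(m / exp(mean(log(m))))
  # no discs/stems: coverage is then the frond ellipse alone, so realized
  # biomass shares track q without a constant per-specimen offset
  lapply(seq_along(p), function(i)
    taxon_spec(names[i], morphogroup = morphogroup[i],
               abundance_weight = p[i], disc = FALSE,
               frond_length_dist = c(mu[i], sdlog)))
}

# Community Type templates mirroring a study design of four types told
# apart by their dominant taxon. Uptake bands separate by construction,
# as on real surfaces: recliners hug the substrate (height = width/3,
# a few mm to ~1 cm), while the branching crowns of bush-, comb- and
# frond-shaped taxa start above them (the basal pedicel/stem region is
# recorded as stem, lifting the uptake zone off the sea floor).
.type_templates <- function() {
  frondose_minor <- function(wt)
    list(taxon_spec("Charnia masoni", abundance_weight = wt,
                    frond_length_dist = c(log(80), 0.25),
                    stem_length_dist = c(log(40), 0.25)),
         taxon_spec("Primocandelabrum sp", abundance_weight = wt / 2,
                    frond_length_dist = c(log(60), 0.25),
                    stem_length_dist = c(log(60), 0.25)))
  reclining <- function(name, wt, size)
    taxon_spec(name, morphogroup = "reclining", abundance_weight = wt,
               spatial = list(type = "thomas", n_parents = 12,
                              cluster_sd = 0.6),
               frond_length_dist = c(log(size), 0.25),
               width_allometry = 0.45)
  bradgatia_spec <- function(wt, clustered = FALSE)
    taxon_spec("Bradgatia sp", morphogroup = "bradgatia",
               abundance_weight = wt,
               spatial = if (clustered)
                 list(type = "thomas", n_parents = 15, cluster_sd = 0.8)
               else list(type = "poisson"),
               frond_length_dist = c(log(60), 0.25),
               stem_length_dist = c(log(30), 0.25),
               width_allometry = 0.8)
  pectinifrons_spec <- function(wt)
    taxon_spec("Pectinifrons abyssalis", morphogroup = "pectinifrons",
               abundance_weight = wt,
               frond_length_dist = c(log(45), 0.25),
               stem_length_dist = c(log(25), 0.25),
               width_allometry = 0.3)
  list(
    fractofusus_misrai = c(
      list(reclining("Fractofusus misrai", 7, 55),
           pectinifrons_spec(1.5)),
      frondose_minor(0.8)),
    fractofusus_andersoni = c(
      list(reclining("Fractofusus andersoni", 8, 40),
           bradgatia_spec(0.7)),
      frondose_minor(0.6)),
    bradgatia = c(
      list(bradgatia_spec(7, clustered = TRUE),
           reclining("Fractofusus misrai", 1, 55)),
      frondose_minor(1)),
    frond = list(
      taxon_spec("Charnia masoni", abundance_weight = 5,
                 frond_length_dist = c(log(80), 0.25),
                 stem_length_dist = c(log(40), 0.25)),
      taxon_spec("Charniodiscus procerus", abundance_weight = 3,
                 frond_length_dist = c(log(65), 0.25),
                 stem_length_dist = c(log(55), 0.25)),
      taxon_spec("Primocandelabrum sp", abundance_weight = 2,
                 frond_length_dist = c(log(60), 0.25),
                 stem_length_dist = c(log(45), 0.25)),
      taxon_spec("Beothukis mistakensis", abundance_weight = 1,
                 frond_length_dist = c(log(50), 0.25),
                 stem_length_dist = c(log(35), 0.25))))
}

#' Generate a multi-surface study fixture
#'
#' Emits a small study's worth of synthetic surfaces spanning four planted
#' Community Types (dominated respectively by a reclining taxon in two
#' species' flavours, a bush-like taxon and a mixture of upright fronds)
#' crossed with three successional states, alongside the ground-truth
#' labels. Specimen counts range a few hundred to a couple of thousand and
#' effaced-frond fractions span 0-0.35, mirroring the prevalence of
#' effacement on real surfaces.
#'
#' @param seed RNG seed; each surface derives its own sub-seed.
#' @param n_surfaces 12 (4 types x 3 states) by default.
#' @param total_n_range specimen count range sampled per surface.
#' @return list with `surfaces` (list of `surface_map`s, geometry derived)
#'   and `truth` (data frame surface_id, community_type, stage,
#'   effaced_fraction, n).
#' @export
generate_study_fixture <- function(seed = 1L, n_surfaces = 12,
                                   total_n_range = c(300, 2000)) {
  set.seed(seed)
  templates <- .type_templates()
  types <- rep(names(templates), length.out = n_surfaces)
  states <- rep(c("early", "intermediate", "late"),
                each = length(templates))[seq_len(n_surfaces)]
  ns <- round(stats::runif(n_surfaces, total_n_range[1], total_n_range[2]))
  effs <- stats::runif(n_surfaces, 0, 0.35)
  sub_seeds <- sample.int(2^30, n_surfaces)
  surfaces <- vector("list", n_surfaces)
  for (i in seq_len(n_surfaces)) {
    cfg <- synthetic_surface_config(
      taxa = templates[[types[i]]], total_n = ns[i],
      succession_state = states[i], effaced_fraction = effs[i],
      surface_id = sprintf("S%02d_%s_%s", i, types[i], states[i]),
      seed = sub_seeds[i])
    surfaces[[i]] <- derive_geometry(generate_surface(cfg))
  }
  names(surfaces) <- vapply(surfaces, function(s) s$surface_id, "")
  list(surfaces = surfaces,
       truth = data.frame(surface_id = names(surfaces),
                          community_type = types, stage = states,
                          effaced_fraction = effs, n = ns))
}
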