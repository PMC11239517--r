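# ---- exact interval arithmetic on finite unions of closed intervals ----

# Normalize a two-column matrix of [lo, hi] intervals into a sorted union
# of disjoint closed intervals (touching intervals merge; zero-length
# intervals carry no measure and are kept only if nothing else exists).
interval_union <- function(lo, hi) {
  stopifnot(length(lo) == length(hi), all(hi >= lo))
  keep <- hi > lo
  if (!any(keep)) return(matrix(numeric(0), 0, 2,
                                dimnames = list(NULL, c("lo", "hi"))))
  lo <- lo[keep]; hi <- hi[keep]
  o <- order(lo, hi)
  lo <- lo[o]; hi <- hi[o]
  out_lo <- lo[1]; out_hi <- hi[1]
  res <- list()
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= out_hi) out_hi <- max(out_hi, hi[i])
    else { res[[length(res) + 1L]] <- c(out_lo, out_hi)
           out_lo <- lo[i]; out_hi <- hi[i] }
  }
  res[[length(res) + 1L]] <- c(out_lo, out_hi)
  m <- do.call(rbind, res)
  colnames(m) <- c("lo", "hi")
  m
}

interval_measure <- function(u) if (!nrow(u)) 0 else sum(u[, 2] - u[, 1])

# Measure of the intersection of two interval unions (both normalized).
interval_intersection_measure <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1])
    hi <- pmin(a[i, 2], b[, 2])
    tot <- tot + sum(pmax(hi - lo, 0))
  }
  tot
}

# ---- taxon tier profiles ----

#' Per-taxon vertical tier profiles
#'
#' Summarises each taxon's use of vertical space on a surface: specimen
#' heights and the taxon's uptake zone, the exact union of its specimens'
#' uptake intervals (the vertical band occupied by the branching, i.e.
#' feeding, part).
#'
#' @param surface a `surface_map` with derived geometry.
#' @param level taxonomic level for grouping.
#' @param treatment an [effaced_treatment()]; default standard.
#' @param group_by optional column name overriding the level-derived label
#'   (used for morphogroup-level tiering).
#' @return named list of profiles: `n`, `heights`, `zone` (matrix of
#'   disjoint closed intervals), `zone_measure`, `mean_stem_length`.
#' @export
taxon_tier_profiles <- function(surface, level = "species",
                                treatment = effaced_treatment("standard"),
                                group_by = NULL) {
  sp <- surface$specimens
  if (is.null(sp$uptake_lo))
    stop("run derive_geometry() first", call. = FALSE)
  sp <- .apply_treatment(sp, treatment)
  lab <- if (is.null(group_by)) .label_at_level(sp, level) else
    sp[[group_by]]
  lapply(split(sp, lab), function(g) {
    u <- interval_union(g$uptake_lo, g$uptake_hi)
    list(n = nrow(g), heights = g$height, zone = u,
         zone_measure = interval_measure(u),
         mean_stem_length = mean(ifelse(is.na(g$stem_length), 0,
                                        g$stem_length)))
  })
}

#' Uptake-zone tiering score of one taxon (DVS-u)
#'
#' The proportion of a taxon's uptake zone that does not overlap the
#' uptake zone of any other taxon:
#' `1 - measure(zone_t intersect union(others)) / measure(zone_t)`,
#' computed with exact interval arithmetic.
#'
#' @param target profile of the focal taxon (see
#'   [taxon_tier_profiles()]).
#' @param others list of the remaining taxa's profiles.
#' @return score in `[0, 1]`, or `NA` (taxon excluded) when the focal zone
#'   has zero measure.
#' @export
taxon_dvs_u <- function(target, others) {
  if (target$zone_measure <= 0) return(NA_real_)
  all_other <- do.call(rbind, lapply(others, function(p) p$zone))
  if (is.null(all_other) || !nrow(all_other)) return(1)
  other_union <- interval_union(all_other[, 1], all_other[, 2])
  1 - interval_intersection_measure(target$zone, other_union) /
    target$zone_measure
}

#' Height tiering score of one taxon (DVS-h)
#'
#' The proportion of a taxon's specimens not matched in height by any
#' other taxon, a specimen being matched when its height falls inside the
#' closed `[min, max]` height envelope of at least one other taxon.
#'
#' @param target profile of the focal taxon.
#' @param others list of the remaining taxa's profiles.
#' @return score in `[0, 1]`.
#' @export
taxon_dvs_h <- function(target, others) {
  if (!target$n) return(NA_real_)
  envs <- lapply(others, function(p) range(p$heights))
  matched <- rep(FALSE, length(target$heights))
  for (e in envs)
    matched <- matched | (target$heights >= e[1] & target$heights <= e[2])
  mean(!matched)
}

.tier_class <- function(score) {
  ifelse(is.na(score), NA_character_,
         ifelse(score > 0.70, "high",
                ifelse(score >= 0.40, "medium", "low")))
}

#' Community tiering (DVS) metrics
#'
#' Computes per-taxon DVS-h and DVS-u scores and combines them into
#' community scores two ways: the unweighted mean across taxa (the classic
#' formulation restricted, if `min_n` is set, to abundant taxa) and the
#' abundance-weighted mean with weights `n_t / N` over eligible taxa,
#' which admits rare taxa while letting dominant taxa dominate the
#' community score. Communities are classed as highly tiered (> 0.70),
#' medium (0.40-0.70) or low (< 0.40) on each score.
#'
#' @param surface a `surface_map` with derived geometry.
#' @param level taxonomic level.
#' @param treatment an [effaced_treatment()].
#' @param min_n optional minimum specimen count per taxon (e.g. 30 to
#'   replicate abundant-taxa analyses); NULL includes every taxon.
#' @param group_by optional grouping column (see
#'   [taxon_tier_profiles()]).
#' @return object of class `tiering_result`: `per_taxon` data frame
#'   (taxon, n, dvs_h, dvs_u), `summary` data frame (metric, score,
#'   tier_class for dvs_h/dvs_u, weighted and unweighted),
#'   `stem_proportion` and `excluded` (taxa with undefined DVS-u).
#' @export
community_dvs <- function(surface, level = "species",
                          treatment = effaced_treatment("standard"),
                          min_n = NULL, group_by = NULL) {
  prof <- taxon_tier_profiles(surface, level, treatment, group_by)
  if (!is.null(min_n))
    prof <- prof[vapply(prof, function(p) p$n, 0L) >= min_n]
  if (length(prof) < 2)
    stop("fewer than 2 eligible taxa on '", surface$surface_id, "'",
         call. = FALSE)
  taxa <- names(prof)
  dvs_u <- vapply(taxa, function(t)
    taxon_dvs_u(prof[[t]], prof[setdiff(taxa, t)]), 0)
  dvs_h <- vapply(taxa, function(t)
    taxon_dvs_h(prof[[t]], prof[setdiff(taxa, t)]), 0)
  n <- vapply(prof, function(p) p$n, 0L)
  wmean <- function(score) {
    ok <- !is.na(score)
    if (!any(ok)) return(c(NA_real_, NA_real_))
    c(mean(score[ok]), sum(score[ok] * n[ok]) / sum(n[ok]))
  }
  mu <- wmean(dvs_u); mh <- wmean(dvs_h)
  summary <- data.frame(
    metric = c("dvs_h", "dvs_u", "dvs_h_weighted", "dvs_u_weighted"),
    score = c(mh[1], mu[1], mh[2], mu[2]))
  summary$tier_class <- .tier_class(summary$score)
  stemmed <- vapply(prof, function(p) p$mean_stem_length > 0, TRUE)
  structure(list(
    surface_id = surface$surface_id,
    per_taxon = data.frame(taxon = taxa, n = n, dvs_h = dvs_h,
                           dvs_u = dvs_u, row.names = NULL),
    summary = summary,
    stem_proportion = sum(n[stemmed]) / sum(n),
    excluded = taxa[is.na(dvs_u)]),
    class = "tiering_result")
}

#' @export
print.tiering_result <- function(x, ...) {
  cat("<tiering_result> ", x$surface_id, " (", nrow(x$per_taxon),
      " taxa)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Tiering between morphogroups
#'
#' Treats each gross morphogroup — the recliners, the bush-like forms, the
#' comb-like forms and the upright fronds — as a single taxon-unit and
#' computes DVS scores between them. Only groups abundant on the surface
#' (more than `min_n` specimens) count; a surface with fewer than three
#' such groups cannot support the analysis and returns NULL with a
#' message.
#'
#' @param surface a `surface_map` with derived geometry.
#' @param min_n abundance threshold per morphogroup (default 30).
#' @param treatment an [effaced_treatment()].
#' @return a `tiering_result` over morphogroups, or NULL when fewer than
#'   3 morphogroups qualify.
#' @export
morphogroup_dvs <- function(surface, min_n = 30,
                            treatment = effaced_treatment("standard")) {
  sp <- .apply_treatment(surface$specimens, treatment)
  groups <- c("reclining", "bradgatia", "pectinifrons", "upright_frond")
  tab <- table(sp$morphogroup[sp$morphogroup %in% groups])
  eligible <- names(tab)[tab > min_n]
  if (length(eligible) < 3) {
    message("surface '", surface$surface_id, "' excluded: only ",
            length(eligible), " morphogroup(s) with > ", min_n,
            " specimens")
    return(NULL)
  }
  s2 <- surface
  s2$specimens <-
    surface$specimens[surface$specimens$morphogroup %in% eligible, ,
                      drop = FALSE]
  community_dvs(s2, treatment = treatment, group_by = "morphogroup")
}

#' Associations between tiering, succession and stem prevalence
#'
#' Per-surface comparisons across a study: ordinary least-squares
#' regressions of each DVS score on the W statistic (is tiering linked to
#' successional stage?), and Spearman rank correlations of the proportion
#' of stemmed specimens against weighted DVS-u and of DVS-h against DVS-u.
#'
#' @param data data frame with one row per surface and columns `w`,
#'   `stem_proportion`, `dvs_u`, `dvs_h`, `dvs_u_weighted`,
#'   `dvs_h_weighted` (any DVS column subset works for the regressions).
#' @return list: `regressions` (data frame metric, n, F, df, p, adj_r2),
#'   `stem_vs_weighted_dvs_u` and `dvs_h_vs_dvs_u` (each rho, n, p).
#' @export
tiering_succession_association <- function(data) {
  if (nrow(data) < 3) stop("need at least 3 surfaces", call. = FALSE)
  dvs_cols <- intersect(c("dvs_u", "dvs_h", "dvs_u_weighted",
                          "dvs_h_weighted"), names(data))
  regs <- lapply(dvs_cols, function(cl) {
    if (stats::sd(data[[cl]]) == 0 || stats::sd(data$w) == 0)
      stop("constant input for regression of ", cl, call. = FALSE)
    sm <- summary(stats::lm(stats::reformulate("w", cl), data = data))
    data.frame(metric = cl, n = nrow(data),
               F = unname(sm$fstatistic[1]),
               df1 = unname(sm$fstatistic[2]),
               df2 = unname(sm$fstatistic[3]),
               p = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                             sm$fstatistic[3], lower.tail = FALSE),
               adj_r2 = sm$adj.r.squared)
  })
  sp_cor <- function(x, y) {
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), n = length(x), p = ct$p.value)
  }
  out <- list(regressions = do.call(rbind, regs))
  if (all(c("stem_proportion", "dvs_u_weighted") %in% names(data)))
    out$stem_vs_weighted_dvs_u <-
      sp_cor(data$stem_proportion, data$dvs_u_weighted)
  if (all(c("dvs_h", "dvs_u") %in% names(data)))
    out$dvs_h_vs_dvs_u <- sp_cor(data$dvs_h, data$dvs_u)
  out
}
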