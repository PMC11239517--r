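#' Abundance-biomass comparison curve and W statistic
#'
#' Builds the paired cumulative dominance curves of percent abundance (A)
#' and percent biomass (B), each over its own descending ranking, and the W
#' statistic
#' \deqn{W = \sum_{i=1}^{S} (A_i - B_i) / (50 (S - 1)),}
#' a number in `[-1, 1]` summarising the separation of the two curves.
#' Under the default orientation, positive W means abundance dominance —
#' many small individuals, an earlier successional (recently disturbed)
#' state — and negative W means biomass dominance (later succession). The
#' mirrored orientation (`"biomass_positive"`, the convention of some of
#' the disturbance-ecology literature) is available for comparison with
#' other work.
#'
#' Ranking ties are broken by taxon label (lexicographic), which leaves W
#' unchanged for exact ties.
#'
#' @param abundance named non-negative counts per taxon.
#' @param biomass named non-negative biomass per taxon (same names); here
#'   usually summed areal coverage, the biomass proxy.
#' @param orientation `"abundance_positive"` (default) or
#'   `"biomass_positive"`.
#' @return object of class `abc_curve`: `S`, `A`, `B` (cumulative percent
#'   at ranks 1..S), `abundance_rank`, `biomass_rank` (taxon orders) and
#'   `W`.
#' @export
abc_curve <- function(abundance, biomass,
                      orientation = c("abundance_positive",
                                      "biomass_positive")) {
  orientation <- match.arg(orientation)
  if (is.null(names(abundance)) || is.null(names(biomass)) ||
      !setequal(names(abundance), names(biomass)))
    stop("abundance and biomass must be named over the same taxa",
         call. = FALSE)
  biomass <- biomass[names(abundance)]
  pos <- abundance > 0
  abundance <- abundance[pos]
  biomass <- biomass[pos]
  S <- length(abundance)
  if (S < 2)
    stop("W statistic undefined for fewer than 2 taxa (S = ", S, ")",
         call. = FALSE)
  ord_a <- order(-abundance, names(abundance))
  ord_b <- order(-biomass, names(biomass))
  A <- cumsum(abundance[ord_a]) / sum(abundance) * 100
  B <- cumsum(biomass[ord_b]) / sum(biomass) * 100
  W <- sum(A - B) / (50 * (S - 1))
  if (orientation == "biomass_positive") W <- -W
  structure(list(S = S, A = unname(A), B = unname(B),
                 abundance_rank = names(abundance)[ord_a],
                 biomass_rank = names(biomass)[ord_b],
                 W = W, orientation = orientation),
            class = "abc_curve")
}

#' @export
print.abc_curve <- function(x, ...) {
  cat("<abc_curve> S = ", x$S, ", W = ", sprintf("%+.4f", x$W),
      " (", x$orientation, ")\n", sep = "")
  invisible(x)
}

#' W statistic of a community
#'
#' Aggregates specimen counts (abundance) and summed areal coverage
#' (biomass proxy) per taxon at the requested level and computes the
#' abundance-biomass W statistic via [abc_curve()]. Requires derived
#' geometry.
#'
#' @param surface a `surface_map` with derived geometry.
#' @param level taxonomic level (`"species"`, `"genus"`, `"morphogroup"`).
#' @param treatment an [effaced_treatment()] applied first.
#' @param members optional integer row subset (a jackknife replicate).
#' @param orientation W sign convention, see [abc_curve()].
#' @return an `abc_curve`.
#' @export
abc_w <- function(surface, level = "species",
                  treatment = effaced_treatment("standard"),
                  members = NULL, orientation = "abundance_positive") {
  sp <- surface$specimens
  if (is.null(sp$areal_coverage))
    stop("run derive_geometry() first", call. = FALSE)
  if (!is.null(members)) sp <- sp[members, , drop = FALSE]
  sp <- .apply_treatment(sp, treatment)
  lab <- .label_at_level(sp, level)
  counts <- tapply(rep(1L, nrow(sp)), lab, sum)
  biomass <- tapply(sp$areal_coverage, lab, sum)
  abc_curve(c(counts), c(biomass), orientation = orientation)
}

#' Jackknife distribution of the W statistic
#'
#' Computes W for every jackknife replicate of a surface. Replicates with
#' fewer than two taxa are dropped and counted; if more than half drop the
#' community is too sparse and an error is raised. The effaced treatment is
#' applied once to the full surface so replicate membership stays fixed.
#'
#' @param surface a `surface_map` with derived geometry.
#' @param samples matching [generate_jackknife_samples()] output.
#' @param level taxonomic level.
#' @param treatment an [effaced_treatment()].
#' @param orientation W sign convention.
#' @return numeric vector of per-replicate W values with attribute
#'   `n_dropped`.
#' @export
w_jackknife_distribution <- function(surface, samples, level = "species",
                                     treatment = effaced_treatment("standard"),
                                     orientation = "abundance_positive") {
  sp <- surface$specimens
  if (is.null(sp$areal_coverage))
    stop("run derive_geometry() first", call. = FALSE)
  if (treatment$mode == "proportional_relabel")
    set.seed(treatment$relabel_seed)
  spt <- .apply_treatment(sp, treatment)
  keep_rows <- match(spt$specimen_id, sp$specimen_id)
  lab <- .label_at_level(spt, level)
  cov <- spt$areal_coverage
  ws <- rep(NA_real_, length(samples$members))
  for (j in seq_along(samples$members)) {
    inside <- keep_rows %in% samples$members[[j]]
    if (!any(inside)) next
    counts <- tapply(rep(1L, sum(inside)), lab[inside], sum)
    if (sum(counts > 0) < 2) next
    biomass <- tapply(cov[inside], lab[inside], sum)
    ws[j] <- abc_curve(c(counts), c(biomass), orientation = orientation)$W
  }
  n_dropped <- sum(is.na(ws))
  if (n_dropped > length(ws) / 2)
    stop("surface '", surface$surface_id, "': ", n_dropped, " of ",
         length(ws), " replicates have fewer than 2 taxa; ",
         "community too sparse for a jackknife W distribution",
         call. = FALSE)
  structure(ws[!is.na(ws)], n_dropped = n_dropped)
}

#' Compare two jackknife W distributions
#'
#' Replicate-wise (index-matched) differences `a - b` with a percentile
#' confidence interval; the difference is significant when the interval
#' excludes zero. Excess replicates in the longer vector are truncated.
#'
#' @param dist_a,dist_b numeric W vectors.
#' @param alpha CI level (default 0.05 -> 95% interval).
#' @param pair identifiers of the two communities, e.g.
#'   `c("E Surface", "D Surface")`.
#' @return object of class `w_comparison`: `pair`, `diffs`, `ci_low`,
#'   `ci_high`, `mean_diff`, `significant`.
#' @export
compare_w <- function(dist_a, dist_b, alpha = 0.05,
                      pair = c("a", "b")) {
  if (!length(dist_a) || !length(dist_b))
    stop("empty W distribution", call. = FALSE)
  n <- min(length(dist_a), length(dist_b))
  d <- dist_a[seq_len(n)] - dist_b[seq_len(n)]
  ci <- unname(stats::quantile(d, c(alpha / 2, 1 - alpha / 2)))
  structure(list(pair = pair, diffs = d, ci_low = ci[1], ci_high = ci[2],
                 mean_diff = mean(d),
                 significant = ci[1] > 0 || ci[2] < 0),
            class = "w_comparison")
}

#' All pairwise W comparisons
#'
#' @param w_dists named list of jackknife W vectors, one per surface.
#' @param alpha CI level.
#' @return data frame: surface_a, surface_b, mean_diff, ci_low, ci_high,
#'   significant — one row per unordered pair.
#' @export
pairwise_w_comparisons <- function(w_dists, alpha = 0.05) {
  ids <- names(w_dists)
  if (length(ids) < 2) stop("need at least two surfaces", call. = FALSE)
  out <- list()
  for (i in seq_along(ids)[-length(ids)])
    for (j in seq((i + 1), length(ids))) {
      cmp <- compare_w(w_dists[[i]], w_dists[[j]], alpha,
                       pair = c(ids[i], ids[j]))
      out[[length(out) + 1L]] <- data.frame(
        surface_a = ids[i], surface_b = ids[j],
        mean_diff = cmp$mean_diff, ci_low = cmp$ci_low,
        ci_high = cmp$ci_high, significant = cmp$significant)
    }
  do.call(rbind, out)
}

#' Assign successional stages from pairwise W comparisons
#'
#' A surface whose significant comparisons all show a higher W than the
#' other surfaces is `earlier` succession; all lower, `later`; both
#' directions, `intermediate`. A surface with no significant comparison is
#' placed with the resolved stage whose mean-W range is nearest
#' (`resolution = "by_mean_w"`), as are surfaces that were never
#' jackknifed, placed by their full-surface W.
#'
#' @param comparisons output of [pairwise_w_comparisons()].
#' @param mean_w named vector of mean jackknife W per jackknifed surface.
#' @param full_w optional named vector of full-surface W for surfaces
#'   excluded from jackknifing.
#' @return data frame: surface_id, mean_w, stage
#'   (earlier/intermediate/later), resolution (significant/by_mean_w).
#' @export
assign_stages <- function(comparisons, mean_w, full_w = NULL) {
  ids <- names(mean_w)
  stage <- setNames(rep(NA_character_, length(ids)), ids)
  resolution <- setNames(rep("significant", length(ids)), ids)
  for (id in ids) {
    sig <- comparisons[comparisons$significant &
                       (comparisons$surface_a == id |
                        comparisons$surface_b == id), , drop = FALSE]
    if (!nrow(sig)) { resolution[id] <- "by_mean_w"; next }
    # orient each difference as (this surface) - (other surface)
    s <- ifelse(sig$surface_a == id, sign(sig$mean_diff),
                -sign(sig$mean_diff))
    stage[id] <- if (all(s > 0)) "earlier"
                 else if (all(s < 0)) "later"
                 else "intermediate"
  }
  resolved <- stage[!is.na(stage)]
  if (!length(resolved)) {
    warning("no significant pairwise W differences; all surfaces placed ",
            "by mean W as intermediate", call. = FALSE)
    stage[] <- "intermediate"
    resolution[] <- "by_mean_w"
  } else if (any(is.na(stage))) {
    ranges <- lapply(split(mean_w[names(resolved)], resolved), range)
    nearest <- function(w) {
      d <- vapply(ranges, function(r)
        if (w >= r[1] && w <= r[2]) 0 else min(abs(w - r)), 0)
      names(which.min(d))
    }
    for (id in names(stage)[is.na(stage)]) {
      stage[id] <- nearest(mean_w[id])
      resolution[id] <- "by_mean_w"
    }
  }
  out <- data.frame(surface_id = ids, mean_w = unname(mean_w[ids]),
                    stage = unname(stage[ids]),
                    resolution = unname(resolution[ids]))
  if (!is.null(full_w) && length(full_w)) {
    ranges <- lapply(split(out$mean_w, out$stage), range)
    nearest <- function(w) {
      d <- vapply(ranges, function(r)
        if (w >= r[1] && w <= r[2]) 0 else min(abs(w - r)), 0)
      names(which.min(d))
    }
    out <- rbind(out, data.frame(
      surface_id = names(full_w), mean_w = unname(full_w),
      stage = vapply(full_w, nearest, ""),
      resolution = "by_mean_w"))
  }
  rownames(out) <- NULL
  out
}

#' Regress mean W on community covariates
#'
#' Ordinary least-squares fit of per-surface mean W on each covariate
#' (e.g. specimen density, total areal coverage, mean and maximum specimen
#' height), reporting the F statistic, its degrees of freedom, p value and
#' adjusted R^2.
#'
#' @param data data frame of one row per surface.
#' @param response name of the W column (default `"mean_w"`).
#' @param covariates character vector of covariate column names.
#' @return data frame: covariate, n, F, df1, df2, p, adj_r2.
#' @export
regress_w_covariates <- function(data, response = "mean_w",
                                 covariates) {
  stopifnot(response %in% names(data), all(covariates %in% names(data)))
  if (nrow(data) < 3) stop("need at least 3 surfaces", call. = FALSE)
  out <- lapply(covariates, function(cv) {
    x <- data[[cv]]
    if (stats::sd(x) == 0)
      stop("covariate '", cv, "' is constant", call. = FALSE)
    fit <- stats::lm(stats::reformulate(cv, response), data = data)
    sm <- summary(fit)
    data.frame(covariate = cv, n = nrow(data),
               F = unname(sm$fstatistic[1]),
               df1 = unname(sm$fstatistic[2]),
               df2 = unname(sm$fstatistic[3]),
               p = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                             sm$fstatistic[3], lower.tail = FALSE),
               adj_r2 = sm$adj.r.squared)
  })
  do.call(rbind, out)
}
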