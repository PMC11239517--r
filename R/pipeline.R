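#' Pipeline configuration
#'
#' Study-level constants for an end-to-end run: the taxonomic level, the
#' effaced-frond treatment, jackknife settings, the significance level for
#' staging, the tier-class thresholds and the morphogroup abundance
#' threshold.
#'
#' @param level `"species"` or `"genus"`.
#' @param treatment an [effaced_treatment()].
#' @param jackknife a [jackknife_config()].
#' @param alpha CI level for W comparisons (default 0.05).
#' @param morphogroup_min_n abundance threshold for morphogroup tiering
#'   (default 30).
#' @param retrodeform apply [retrodeform()] to each surface first?
#' @param nmds_k NMDS embedding dimension (default 2).
#' @param seed master seed; stage-specific seeds derive from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(level = "species",
                            treatment = effaced_treatment("standard"),
                            jackknife = jackknife_config(),
                            alpha = 0.05, morphogroup_min_n = 30,
                            retrodeform = FALSE, nmds_k = 2,
                            seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(level = level, treatment = treatment,
                 jackknife = jackknife, alpha = alpha,
                 morphogroup_min_n = morphogroup_min_n,
                 retrodeform = retrodeform, nmds_k = nmds_k,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full community-analysis pipeline
#'
#' Orchestrates every stage over a set of surfaces: optional
#' retrodeformation, geometry derivation, spatial jackknifing, composition
#' tables and NMDS ordination of the jackknife replicates, hierarchical
#' clustering of full-surface relative abundances, jackknife W
#' distributions, pairwise comparisons and successional staging, W
#' regressions on community covariates, per-surface tiering and the
#' tiering/succession/stem associations. All tabular outputs are written
#' as CSV under `out_dir`, together with the dendrogram in Newick format,
#' a config echo (YAML) and a run log. Re-running with the same
#' configuration reproduces the same outputs.
#'
#' @param surfaces list of `surface_map`s, or a manifest path readable by
#'   [read_manifest()] (files resolved relative to the manifest).
#' @param out_dir output directory (created if absent).
#' @param cfg a [pipeline_config()].
#' @param jackknife_flags optional named logical vector marking which
#'   surfaces are jackknifed (manifest `jackknife` column plays this role
#'   for file input); default all.
#' @return invisibly, a list of the in-memory stage results (`stages`,
#'   `tiering`, `associations`, `regressions`, `nmds`, `hclust`, `paths`).
#' @export
run_pipeline <- function(surfaces, out_dir, cfg = pipeline_config(),
                         jackknife_flags = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), "  ", ..., "\n")
    cat(msg, file = log_path, append = TRUE)
    message(sub("\n$", "", msg))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(name, file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.character(surfaces)) {
    man <- read_manifest(surfaces)
    base <- dirname(surfaces)
    jackknife_flags <- stats::setNames(man$jackknife, man$surface_id)
    surfaces <- run_stage("read", lapply(seq_len(nrow(man)), function(i) {
      f <- man$file[i]
      if (!file.exists(f)) f <- file.path(base, man$file[i])
      read_surface_map(f, surface_id = man$surface_id[i],
                       area_m2 = if (!is.null(man$area_m2)) man$area_m2[i])
    }))
  }
  names(surfaces) <- vapply(surfaces, function(s) s$surface_id, "")
  if (is.null(jackknife_flags))
    jackknife_flags <- stats::setNames(rep(TRUE, length(surfaces)),
                                       names(surfaces))
  logf("pipeline start: ", length(surfaces), " surfaces, level=",
       cfg$level, ", treatment=", cfg$treatment$mode, ", seed=", cfg$seed)

  surfaces <- run_stage("geometry", lapply(surfaces, function(s) {
    if (cfg$retrodeform) s <- retrodeform(s)
    derive_geometry(s)
  }))

  jk_ids <- names(surfaces)[jackknife_flags[names(surfaces)]]
  samples <- run_stage("jackknife", {
    out <- list()
    for (i in seq_along(jk_ids)) {
      jc <- cfg$jackknife
      jc$seed <- cfg$seed + i
      out[[jk_ids[i]]] <-
        generate_jackknife_samples(surfaces[[jk_ids[i]]], jc)
    }
    out
  })
  logf("jackknife: ", length(samples), " surfaces x ",
       cfg$jackknife$n_samples, " replicates")

  comp_full <- run_stage("composition",
    composition_table(surfaces, cfg$level, cfg$treatment))
  utils::write.csv(cbind(attr(comp_full, "rows"), unclass(comp_full)),
                   file.path(out_dir, "composition_full.csv"),
                   row.names = FALSE)
  hc <- run_stage("clustering", hierarchical_cluster(comp_full))
  as_newick(hc, file.path(out_dir, "dendrogram.nwk"))

  comp_jk <- run_stage("composition",
    composition_table(surfaces[jk_ids], cfg$level, cfg$treatment,
                      samples = samples))
  ord <- run_stage("nmds",
    nmds(comp_jk, k = cfg$nmds_k, seed = cfg$seed))
  utils::write.csv(cbind(ord$rows, ord$points, stress = ord$stress),
                   file.path(out_dir, "nmds_coordinates.csv"),
                   row.names = FALSE)
  logf("nmds: k=", cfg$nmds_k, " stress=", signif(ord$stress, 4))

  w_dists <- run_stage("succession", {
    out <- list()
    for (id in jk_ids)
      out[[id]] <- w_jackknife_distribution(surfaces[[id]], samples[[id]],
                                            cfg$level, cfg$treatment)
    out
  })
  utils::write.csv(
    data.frame(surface_id = rep(names(w_dists), lengths(w_dists)),
               w = unlist(w_dists)),
    file.path(out_dir, "w_distributions.csv"), row.names = FALSE)
  comparisons <- run_stage("succession",
    pairwise_w_comparisons(w_dists, cfg$alpha))
  utils::write.csv(comparisons, file.path(out_dir, "w_comparisons.csv"),
                   row.names = FALSE)
  mean_w <- vapply(w_dists, mean, 0)
  full_w <- NULL
  excl <- setdiff(names(surfaces), jk_ids)
  if (length(excl))
    full_w <- vapply(surfaces[excl], function(s)
      abc_w(s, cfg$level, cfg$treatment)$W, 0)
  stages <- run_stage("staging", assign_stages(comparisons, mean_w, full_w))
  utils::write.csv(stages, file.path(out_dir, "stage_table.csv"),
                   row.names = FALSE)
  logf("stages: ", paste(table(stages$stage), names(table(stages$stage)),
                         collapse = ", "))

  covar <- run_stage("regressions", {
    df <- do.call(rbind, lapply(names(surfaces), function(id) {
      s <- surfaces[[id]]
      sp <- s$specimens
      data.frame(surface_id = id,
                 specimen_density = nrow(sp) / s$area_m2,
                 areal_coverage = sum(sp$areal_coverage),
                 mean_height = mean(sp$height),
                 max_height = max(sp$height))
    }))
    df$mean_w <- NA_real_
    df$mean_w[match(stages$surface_id, df$surface_id)] <- stages$mean_w
    df[!is.na(df$mean_w), , drop = FALSE]
  })
  regs <- run_stage("regressions",
    regress_w_covariates(covar, "mean_w",
                         c("specimen_density", "areal_coverage",
                           "mean_height", "max_height")))
  utils::write.csv(regs, file.path(out_dir, "w_regressions.csv"),
                   row.names = FALSE)

  tiering <- run_stage("tiering", lapply(surfaces, community_dvs,
                                         level = cfg$level,
                                         treatment = cfg$treatment))
  tier_tab <- do.call(rbind, lapply(tiering, function(tr) {
    s <- tr$summary
    data.frame(surface_id = tr$surface_id,
               dvs_h = s$score[s$metric == "dvs_h"],
               dvs_u = s$score[s$metric == "dvs_u"],
               dvs_h_weighted = s$score[s$metric == "dvs_h_weighted"],
               dvs_u_weighted = s$score[s$metric == "dvs_u_weighted"],
               dvs_u_weighted_class =
                 s$tier_class[s$metric == "dvs_u_weighted"],
               stem_proportion = tr$stem_proportion)
  }))
  utils::write.csv(tier_tab, file.path(out_dir, "tiering_table.csv"),
                   row.names = FALSE)

  assoc <- run_stage("associations", {
    df <- tier_tab
    df$w <- NA_real_
    df$w[match(stages$surface_id, df$surface_id)] <- stages$mean_w
    df <- df[!is.na(df$w), , drop = FALSE]
    tiering_succession_association(df)
  })
  utils::write.csv(assoc$regressions,
                   file.path(out_dir, "tiering_regressions.csv"),
                   row.names = FALSE)

  morpho <- run_stage("tiering", {
    res <- lapply(surfaces, morphogroup_dvs,
                  min_n = cfg$morphogroup_min_n,
                  treatment = cfg$treatment)
    res[!vapply(res, is.null, TRUE)]
  })
  if (length(morpho)) {
    mt <- do.call(rbind, lapply(morpho, function(tr)
      cbind(surface_id = tr$surface_id, tr$summary)))
    utils::write.csv(mt, file.path(out_dir, "morphogroup_tiering.csv"),
                     row.names = FALSE)
  }

  yaml::write_yaml(list(level = cfg$level,
                        treatment = cfg$treatment$mode,
                        jackknife = cfg$jackknife[c("fraction", "n_samples")],
                        alpha = cfg$alpha,
                        morphogroup_min_n = cfg$morphogroup_min_n,
                        nmds_k = cfg$nmds_k, seed = cfg$seed),
                   file.path(out_dir, "config_echo.yaml"))
  logf("pipeline complete")
  invisible(list(stages = stages, tiering = tier_tab,
                 associations = assoc, regressions = regs, nmds = ord,
                 hclust = hc, w_dists = w_dists, comparisons = comparisons,
                 paths = list.files(out_dir, full.names = TRUE)))
}
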