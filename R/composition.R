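#' Effaced-frond sensitivity treatment
#'
#' Many surfaces carry large numbers of effaced fronds — frondose specimens
#' too poorly preserved to identify below morphocategory. Four treatments
#' probe their influence on composition analyses:
#'
#' * `standard`: effaced fronds and taphomorphs removed (baseline for all
#'   analyses).
#' * `effaced_as_taxon`: effaced fronds kept as one extra pseudo-taxon
#'   `"Effaced frond"`; other taphomorphs removed.
#' * `proportional_relabel`: each effaced frond is relabelled to an
#'   identified taxon drawn with probability equal to that taxon's relative
#'   abundance among identified specimens of the same community (a
#'   community half-composed of one taxon relabels half its effaced fronds
#'   to it); total specimen count is conserved.
#' * `best_guess`: effaced fronds present in `best_guess_map` (named by
#'   `specimen_id`) take their mapped taxon; unmapped effaced fronds are
#'   removed.
#'
#' @param mode one of `"standard"`, `"effaced_as_taxon"`,
#'   `"proportional_relabel"`, `"best_guess"`.
#' @param relabel_seed RNG seed for `proportional_relabel`.
#' @param best_guess_map named character vector, `specimen_id` -> taxon.
#' @return object of class `effaced_treatment`.
#' @export
effaced_treatment <- function(mode = c("standard", "effaced_as_taxon",
                                       "proportional_relabel", "best_guess"),
                              relabel_seed = 1L, best_guess_map = NULL) {
  mode <- match.arg(mode)
  structure(list(mode = mode, relabel_seed = relabel_seed,
                 best_guess_map = best_guess_map),
            class = "effaced_treatment")
}

# Apply a treatment to one community's specimen table. RNG for
# proportional_relabel is seeded by the caller (once per table build).
.apply_treatment <- function(sp, treatment) {
  eff <- sp$effaced_frond | sp$tax_level == "taphomorph"
  switch(treatment$mode,
    standard = sp[!eff, , drop = FALSE],
    effaced_as_taxon = {
      out <- sp[!(sp$tax_level == "taphomorph" & !sp$effaced_frond), ,
                drop = FALSE]
      out$taxon[out$effaced_frond] <- "Effaced frond"
      out$tax_level[out$effaced_frond] <- "morphocategory"
      out
    },
    proportional_relabel = {
      out <- sp[!(sp$tax_level == "taphomorph" & !sp$effaced_frond), ,
                drop = FALSE]
      idx <- which(out$effaced_frond)
      pool <- out$taxon[!out$effaced_frond]
      if (length(idx) && length(pool)) {
        tab <- table(pool)
        out$taxon[idx] <- sample(names(tab), length(idx), replace = TRUE,
                                 prob = as.numeric(tab))
        out$tax_level[idx] <- "species"
        out$effaced_frond[idx] <- FALSE
      } else if (length(idx)) {
        out <- out[-idx, , drop = FALSE]  # nothing identified to draw from
      }
      out
    },
    best_guess = {
      out <- sp[!(sp$tax_level == "taphomorph" & !sp$effaced_frond), ,
                drop = FALSE]
      map <- treatment$best_guess_map
      idx <- which(out$effaced_frond)
      mapped <- idx[out$specimen_id[idx] %in% names(map)]
      out$taxon[mapped] <- unname(map[out$specimen_id[mapped]])
      out$tax_level[mapped] <- "species"
      out$effaced_frond[mapped] <- FALSE
      out[!out$effaced_frond, , drop = FALSE]
    })
}

# Aggregation label at a taxonomic level. Records unidentifiable at the
# requested level keep their finest available label.
.label_at_level <- function(sp, level) {
  switch(level,
    species = sp$taxon,
    genus = ifelse(sp$tax_level == "species",
                   vapply(strsplit(sp$taxon, "\\s+"), `[`, "", 1L),
                   sp$taxon),
    morphogroup = sp$morphogroup,
    stop("unknown taxonomic level: ", level, call. = FALSE))
}

#' Build a taxon composition table
#'
#' Tabulates specimen counts per community at a taxonomic level, after
#' applying an effaced-frond treatment within each community. Communities
#' are whole surfaces, or their jackknife replicates when `samples` is
#' supplied.
#'
#' @param surfaces a `surface_map` or list of them.
#' @param level `"species"`, `"genus"` or `"morphogroup"`. Records not
#'   identifiable at the level keep their finest available label (their own
#'   column).
#' @param treatment an [effaced_treatment()]; default standard.
#' @param samples optional named list of [generate_jackknife_samples()]
#'   results keyed by surface_id; when given, one row per
#'   (surface, replicate), with the treatment applied to the full surface
#'   before subsetting.
#' @return object of class `composition_table`: integer count matrix with a
#'   `rows` attribute (data frame surface_id, sample_index) and a `level`
#'   attribute.
#' @export
composition_table <- function(surfaces, level = "species",
                              treatment = effaced_treatment("standard"),
                              samples = NULL) {
  if (inherits(surfaces, "surface_map")) surfaces <- list(surfaces)
  if (!length(surfaces)) stop("no surfaces supplied", call. = FALSE)
  if (treatment$mode == "proportional_relabel")
    set.seed(treatment$relabel_seed)
  per_comm <- list()
  rows <- list()
  for (s in surfaces) {
    sp <- .apply_treatment(s$specimens, treatment)
    lab <- .label_at_level(sp, level)
    if (is.null(samples)) {
      per_comm[[length(per_comm) + 1L]] <- table(lab)
      rows[[length(rows) + 1L]] <- data.frame(surface_id = s$surface_id,
                                              sample_index = NA_integer_)
    } else {
      jk <- samples[[s$surface_id]]
      if (is.null(jk)) next
      keep <- match(sp$specimen_id, s$specimens$specimen_id)
      for (j in seq_along(jk$members)) {
        inside <- lab[keep %in% jk$members[[j]]]
        per_comm[[length(per_comm) + 1L]] <- table(inside)
        rows[[length(rows) + 1L]] <- data.frame(surface_id = s$surface_id,
                                                sample_index = j)
      }
    }
  }
  taxa <- sort(unique(unlist(lapply(per_comm, names))))
  m <- matrix(0L, length(per_comm), length(taxa),
              dimnames = list(NULL, taxa))
  for (i in seq_along(per_comm))
    m[i, names(per_comm[[i]])] <- as.integer(per_comm[[i]])
  rows <- do.call(rbind, rows)
  rownames(m) <- ifelse(is.na(rows$sample_index), rows$surface_id,
                        paste0(rows$surface_id, ":", rows$sample_index))
  structure(m, rows = rows, level = level, class = "composition_table")
}

#' Relative abundances of a composition table
#'
#' @param comp a [composition_table()] or count matrix.
#' @return matrix of row-wise relative abundances (rows sum to 1).
#' @export
relative_abundance <- function(comp) {
  m <- unclass(comp)
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("composition rows with zero total: ",
         paste(rownames(m)[tot == 0], collapse = ", "), call. = FALSE)
  sweep(m, 1, tot, "/")
}

#' Bray-Curtis dissimilarity between two composition rows
#'
#' `sum(|a - b|) / sum(a + b)`, in `[0, 1]`: 0 for identical rows, 1 for
#' disjoint supports.
#'
#' @param a,b non-negative numeric vectors over the same taxon set.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b))
    stop("rows must share the same column set", call. = FALSE)
  if (any(a < 0) || any(b < 0)) stop("negative abundances", call. = FALSE)
  tot <- sum(a) + sum(b)
  if (tot == 0)
    stop("Bray-Curtis undefined for two all-zero rows", call. = FALSE)
  sum(abs(a - b)) / tot
}

#' Bray-Curtis distance matrix
#'
#' @param comp composition table or non-negative matrix (rows with zero
#'   total are rejected).
#' @return `dist` object.
#' @export
bray_curtis_matrix <- function(comp) {
  m <- unclass(comp)
  if (any(rowSums(m) == 0))
    stop("composition rows with zero total", call. = FALSE)
  vegan::vegdist(m, method = "bray")
}

#' Non-metric multidimensional scaling of a composition table
#'
#' Kruskal NMDS (stress-1) on the Bray-Curtis distance matrix, restarted
#' from random configurations; the lowest-stress solution is kept.
#' Deterministic under a fixed seed. Rows with zero totals are dropped with
#' a warning.
#'
#' @param comp a [composition_table()] (counts are ordinated as-is; pass
#'   [relative_abundance()] output to ordinate proportions).
#' @param k embedding dimension (2 or 3).
#' @param seed RNG seed.
#' @param n_restarts random restarts (default 20).
#' @return object of class `nmds_result`: `points`, `stress` (in `[0, 1]`),
#'   `k`, `converged`, `rows`.
#' @export
nmds <- function(comp, k = 2, seed = 1L, n_restarts = 20) {
  m <- unclass(comp)
  rows <- attr(comp, "rows")
  keep <- rowSums(m) > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-total row(s) dropped before ordination",
            call. = FALSE)
    m <- m[keep, , drop = FALSE]
    if (!is.null(rows)) rows <- rows[keep, , drop = FALSE]
  }
  if (nrow(unique(m)) < k + 1)
    stop("need at least k + 1 distinct rows for a ", k,
         "-dimensional ordination", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(m, distance = "bray", k = k, trymax = n_restarts,
                        autotransform = FALSE, wascores = FALSE,
                        trace = 0)
  if (!isTRUE(fit$converged) && !is.numeric(fit$converged))
    warning("NMDS did not converge in ", n_restarts,
            " restarts; best stress ", signif(fit$stress, 4), call. = FALSE)
  structure(list(k = k, points = fit$points, stress = fit$stress,
                 n_restarts = n_restarts, seed = seed,
                 converged = fit$converged, rows = rows),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat("<nmds_result> k = ", x$k, ", stress = ", signif(x$stress, 4),
      " (", nrow(x$points), " communities)\n", sep = "")
  invisible(x)
}

#' Hierarchical clustering of community composition
#'
#' Agglomerative clustering of communities on Bray-Curtis distances between
#' relative-abundance rows (UPGMA/average linkage by default). Cut the tree
#' with [stats::cutree()]; export with [as_newick()].
#'
#' @param comp a [composition_table()] of full surfaces.
#' @param linkage linkage method passed to [stats::hclust()].
#' @param use_relative cluster on relative abundances (default TRUE) or raw
#'   counts.
#' @return an `hclust` object.
#' @export
hierarchical_cluster <- function(comp, linkage = "average",
                                 use_relative = TRUE) {
  m <- if (use_relative) relative_abundance(comp) else unclass(comp)
  if (nrow(m) < 2) stop("need at least 2 communities", call. = FALSE)
  stats::hclust(bray_curtis_matrix(m), method = linkage)
}

#' Export a dendrogram in Newick format
#'
#' @param hc an `hclust` object.
#' @param path optional file; when NULL the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
as_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) ape::write.tree(phy)
  else { ape::write.tree(phy, file = path); invisible(ape::write.tree(phy)) }
}

#' Predict successional stage from composition by linear discriminant
#' analysis
#'
#' Tests whether community composition carries a succession signal: per
#' repeat, the jackknife replicates of `n_holdout` randomly chosen surfaces
#' are held out, a linear discriminant is fitted on the remaining
#' replicates' relative abundances with the surface's successional stage as
#' the class, and held-out replicates are scored. A repeat whose training
#' fold lost a stage entirely is redrawn.
#'
#' @param comp a [composition_table()] of jackknife replicates.
#' @param stages named character vector, surface_id -> stage.
#' @param n_repeats train/test repeats (default 100).
#' @param n_holdout surfaces held out per repeat (default 3).
#' @param seed RNG seed.
#' @param prior `"uniform"` (default) fits the discriminant with equal
#'   class priors — the stage of an unseen surface is a priori unknown, and
#'   holding surfaces out would otherwise deplete their own stage's prior —
#'   or `"proportions"` for training-fold class frequencies.
#' @param permute_labels if TRUE, the surface-to-stage assignment is
#'   re-permuted at every repeat: a permutation null that calibrates the
#'   chance level of the procedure. Note that holding out whole surfaces
#'   leaves the held-out surface's own stage under-represented in
#'   training, so even the permutation null sits somewhat below the
#'   nominal 1/equal-classes level; report it alongside observed scores.
#' @return list with `median_correct` (median correct-stage fraction across
#'   repeats), `correct` (per-repeat fractions), `confusion` (summed
#'   confusion table) and `n_redraws`.
#' @export
lda_stage_prediction <- function(comp, stages, n_repeats = 100,
                                 n_holdout = 3, seed = 1L,
                                 prior = c("uniform", "proportions"),
                                 permute_labels = FALSE) {
  prior <- match.arg(prior)
  rows <- attr(comp, "rows")
  if (is.null(rows) || all(is.na(rows$sample_index)))
    stop("comp must be a composition table of jackknife replicates",
         call. = FALSE)
  m <- relative_abundance(comp)
  surf <- rows$surface_id
  stage <- stages[surf]
  if (length(unique(stages)) < 2)
    stop("need at least 2 stages", call. = FALSE)
  ids <- unique(surf)
  if (!is.null(seed)) set.seed(seed)
  correct <- numeric(n_repeats)
  lev <- sort(unique(stage))
  confusion <- matrix(0L, length(lev), length(lev),
                      dimnames = list(truth = lev, predicted = lev))
  n_redraws <- 0L
  for (r in seq_len(n_repeats)) {
    if (permute_labels) {
      perm <- stats::setNames(sample(stages[ids]), ids)
      stage <- perm[surf]
    }
    repeat {
      test_ids <- sample(ids, n_holdout)
      train <- !(surf %in% test_ids)
      if (length(unique(stage[train])) == length(unique(stage))) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > 1000L * n_repeats)
        stop("cannot draw a training fold containing every stage",
             call. = FALSE)
    }
    xtr <- m[train, , drop = FALSE]
    keep_col <- apply(xtr, 2, function(v) stats::sd(v) > 0)
    grp <- stage[train]
    pr <- if (prior == "uniform")
      rep(1 / length(unique(grp)), length(unique(grp))) else
      as.numeric(table(grp) / length(grp))
    fit <- suppressWarnings(
      MASS::lda(xtr[, keep_col, drop = FALSE], grouping = grp,
                prior = pr))
    pred <- stats::predict(fit, m[!train, keep_col, drop = FALSE])$class
    truth <- stage[!train]
    correct[r] <- mean(as.character(pred) == truth)
    tb <- table(factor(truth, lev), factor(as.character(pred), lev))
    confusion <- confusion + tb
  }
  list(median_correct = stats::median(correct), correct = correct,
       confusion = confusion, n_redraws = n_redraws)
}
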