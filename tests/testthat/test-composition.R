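toy_surface <- function(taxa_counts, effaced = 0, id = "toy") {
  taxa <- rep(names(taxa_counts), taxa_counts)
  n <- length(taxa) + effaced
  sp <- make_specimens(n, taxon = c(taxa, rep("Effaced frond", effaced)))
  sp$effaced_frond <- c(rep(FALSE, length(taxa)), rep(TRUE, effaced))
  sp$tax_level <- ifelse(sp$effaced_frond, "morphocategory", "species")
  surface_map(sp, surface_id = id, extent = c(0, 1, 0, 1))
}

test_that("composition tables aggregate counts and relative abundances", {
  s <- toy_surface(c(`Charnia masoni` = 10))
  comp <- composition_table(s)
  expect_equal(dim(comp), c(1L, 1L))
  expect_equal(relative_abundance(comp)[1, 1], 1.0)
  s2 <- toy_surface(c(`Charnia masoni` = 6, `Charnia sp` = 2,
                      `Fractofusus misrai` = 2))
  g <- composition_table(s2, level = "genus")
  expect_equal(sort(colnames(g)), c("Charnia", "Fractofusus"))
  expect_equal(unname(unclass(g)[1, ]), c(8L, 2L))
})

test_that("effaced treatments drop, keep or relabel effaced fronds", {
  s <- toy_surface(c(`Charnia masoni` = 5, `Fractofusus misrai` = 5),
                   effaced = 4)
  std <- composition_table(s, treatment = effaced_treatment("standard"))
  expect_equal(sum(std), 10)
  ast <- composition_table(s,
    treatment = effaced_treatment("effaced_as_taxon"))
  expect_equal(sum(ast), 14)
  expect_true("Effaced frond" %in% colnames(ast))
  expect_equal(unclass(ast)[, c("Charnia masoni", "Fractofusus misrai")],
               unclass(std)[, c("Charnia masoni", "Fractofusus misrai")])
})

test_that("proportional relabelling conserves totals and tracks the
           identified composition in expectation", {
  s <- toy_surface(c(`Charnia masoni` = 5, `Fractofusus misrai` = 5),
                   effaced = 4)
  rel <- composition_table(s,
    treatment = effaced_treatment("proportional_relabel",
                                  relabel_seed = 3))
  expect_equal(sum(rel), 14)
  expect_false("Effaced frond" %in% colnames(rel))
  # expectation: half the effaced relabel to each taxon
  big <- toy_surface(c(`Charnia masoni` = 3000,
                       `Fractofusus misrai` = 1000), effaced = 2000)
  relb <- composition_table(big,
    treatment = effaced_treatment("proportional_relabel",
                                  relabel_seed = 7))
  expect_equal(sum(relb), 6000)
  expect_equal(unclass(relb)[1, "Charnia masoni"] / 6000, 0.75,
               tolerance = 0.03)
})

test_that("best-guess treatment maps known specimens and drops the rest", {
  s <- toy_surface(c(`Charnia masoni` = 3), effaced = 2)
  eff_ids <- s$specimens$specimen_id[s$specimens$effaced_frond]
  bg <- composition_table(s, treatment = effaced_treatment(
    "best_guess",
    best_guess_map = setNames("Charnia masoni", eff_ids[1])))
  expect_equal(sum(bg), 4)
})

test_that("bray_curtis matches hand values and is a bounded symmetric
           dissimilarity", {
  expect_equal(bray_curtis(c(6, 4, 0), c(2, 4, 4)), 0.4)
  expect_equal(bray_curtis(c(1, 2), c(1, 2)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 3)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(1)
  for (i in 1:50) {
    a <- rpois(6, 4); b <- rpois(6, 4)
    if (sum(a) + sum(b) == 0) next
    d <- bray_curtis(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bray_curtis(b, a))
    if (sum(a) > 0) expect_equal(bray_curtis(a, a), 0)
  }
  # cross-check the scalar formula against the vegan distance matrix
  m <- matrix(rpois(24, 5) + 1, 4, 6)
  vd <- as.matrix(bray_curtis_matrix(m))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(vd[i, j], bray_curtis(m[i, ], m[j, ]))
})

test_that("NMDS embeds equidistant points exactly and never worsens with
           an extra dimension", {
  m <- rbind(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10), c(4, 3, 3))
  rownames(m) <- paste0("r", 1:4)
  o2 <- suppressWarnings(nmds(m, k = 2, seed = 1, n_restarts = 10))
  expect_lt(o2$stress, 0.01)
  fx <- generate_study_fixture(seed = 3)
  comp <- composition_table(fx$surfaces)
  s2 <- suppressWarnings(nmds(comp, k = 2, seed = 2,
                              n_restarts = 20))$stress
  s3 <- suppressWarnings(nmds(comp, k = 3, seed = 2,
                              n_restarts = 20))$stress
  # nested-model property, up to restart-optimizer tolerance
  expect_lte(s3, s2 + 0.01)
})

test_that("well-separated community types separate in ordination space", {
  fx <- generate_study_fixture(seed = 5)
  comp <- composition_table(fx$surfaces)
  ord <- nmds(comp, k = 2, seed = 3, n_restarts = 10)
  type <- fx$truth$community_type
  d <- as.matrix(dist(ord$points))
  same <- outer(type, type, "==") & upper.tri(d)
  diff <- outer(type, type, "!=") & upper.tri(d)
  expect_gt(mean(d[diff]), mean(d[same]))
})

test_that("hierarchical clustering recovers planted community types and
           merges identical communities at height zero", {
  s <- toy_surface(c(`Charnia masoni` = 5, `Fractofusus misrai` = 5))
  comp <- composition_table(list(s, {
    s2 <- s; s2$surface_id <- "toy2"; s2
  }))
  hc <- hierarchical_cluster(comp)
  expect_equal(min(hc$height), 0)
  fx <- generate_study_fixture(seed = 7)
  hc4 <- hierarchical_cluster(composition_table(fx$surfaces))
  cl <- cutree(hc4, 4)
  expect_equal(length(unique(paste(cl, fx$truth$community_type))), 4)
  nwk <- as_newick(hc4)
  expect_match(nwk, "^\\(.*\\);$")
})

test_that("duplicating a community merges it at height zero and, under
           single linkage, leaves every other merge height unchanged", {
  fx <- generate_study_fixture(seed = 9, n_surfaces = 4)
  comp <- relative_abundance(composition_table(fx$surfaces))
  comp2 <- rbind(comp, dup = comp[1, ])
  h2a <- hclust(bray_curtis_matrix(comp2), method = "average")
  expect_equal(min(h2a$height), 0)
  # single linkage ignores cluster sizes, so the duplicate is inert
  h1 <- hclust(bray_curtis_matrix(comp), method = "single")
  h2 <- hclust(bray_curtis_matrix(comp2), method = "single")
  expect_true(all(sapply(h1$height, function(x)
    any(abs(h2$height - x) < 1e-12))))
})

test_that("LDA recovers stages that composition determines and scores a
           single informative taxon", {
  mk <- function(id, dom, seed) {
    taxa <- planted_share_taxa(c(.7, .1, .1, .1), rep(.25, 4),
                               names = c(dom, "A", "B", "C"))
    derive_geometry(generate_surface(synthetic_surface_config(
      taxa, total_n = 300, surface_id = id, seed = seed)))
  }
  doms <- c(early = "E", intermediate = "I", late = "L")
  surfs <- list(); stages <- character()
  k <- 0
  for (st in names(doms)) for (r in 1:3) {
    k <- k + 1
    id <- paste0(st, r)
    surfs[[id]] <- mk(id, doms[[st]], 400 + k)
    stages[id] <- st
  }
  jk <- lapply(surfs, function(s)
    generate_jackknife_samples(s, jackknife_config(n_samples = 40,
                                                   seed = 4)))
  comp <- composition_table(surfs, samples = jk)
  res <- lda_stage_prediction(comp, stages, n_repeats = 30, seed = 6)
  expect_gte(res$median_correct, 0.9)
  # one taxon whose abundance orders the stages monotonically
  mk1 <- function(id, w, seed) {
    taxa <- planted_share_taxa(c(w, (1 - w) / 2, (1 - w) / 2),
                               rep(1 / 3, 3),
                               names = c("Marker", "A", "B"))
    derive_geometry(generate_surface(synthetic_surface_config(
      taxa, total_n = 300, surface_id = id, seed = seed)))
  }
  ws <- c(early = .7, intermediate = .4, late = .1)
  surfs1 <- list(); st1 <- character()
  k <- 0
  for (st in names(ws)) for (r in 1:3) {
    k <- k + 1
    id <- paste0(st, r)
    surfs1[[id]] <- mk1(id, ws[[st]], 500 + k)
    st1[id] <- st
  }
  jk1 <- lapply(surfs1, function(s)
    generate_jackknife_samples(s, jackknife_config(n_samples = 40,
                                                   seed = 4)))
  res1 <- lda_stage_prediction(composition_table(surfs1, samples = jk1),
                               st1, n_repeats = 30, seed = 6)
  expect_gte(res1$median_correct, 0.9)
})
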