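profile_of <- function(lo, hi, heights = (lo + hi) / 2, n = length(lo)) {
  u <- paleocomm:::interval_union(lo, hi)
  list(n = n, heights = heights, zone = u,
       zone_measure = paleocomm:::interval_measure(u),
       mean_stem_length = 0)
}

test_that("uptake-zone scores follow exact interval arithmetic", {
  t1 <- profile_of(0, 10)
  t2 <- profile_of(20, 50)
  expect_equal(taxon_dvs_u(t1, list(t2)), 1.0)
  expect_equal(taxon_dvs_u(t1, list(t1)), 0.0)
  t3 <- profile_of(5, 20)
  expect_equal(taxon_dvs_u(t1, list(t3)), 0.5)
  expect_equal(taxon_dvs_u(t3, list(t1)), 1 - 5 / 15)
  # zero-measure focal zone is undefined
  expect_true(is.na(taxon_dvs_u(profile_of(5, 5), list(t1))))
})

test_that("height scores count specimens outside every other envelope", {
  tall <- profile_of(0, 0, heights = c(30, 40), n = 2)
  low <- profile_of(0, 0, heights = c(10, 20), n = 2)
  expect_equal(taxon_dvs_h(tall, list(low)), 1.0)
  expect_equal(taxon_dvs_h(low, list(low)), 0.0)
  mid <- profile_of(0, 0, heights = c(5, 15, 25), n = 3)
  env <- profile_of(0, 0, heights = c(10, 20), n = 2)
  expect_equal(taxon_dvs_h(mid, list(env)), 2 / 3)
})

test_that("community DVS combines taxa by plain and abundance-weighted
           means", {
  s <- band_surface(c("A", "B", "B", "B"), lo = c(0, 5, 5, 5),
                    hi = c(10, 20, 20, 20))
  res <- community_dvs(s)
  su <- res$summary
  expect_equal(su$score[su$metric == "dvs_u"], (0.5 + 2 / 3) / 2,
               tolerance = 1e-12)
  expect_equal(su$score[su$metric == "dvs_u_weighted"],
               (1 * 0.5 + 3 * 2 / 3) / 4, tolerance = 1e-12)
  # equal abundances: weighted equals unweighted
  s2 <- band_surface(c("A", "B"), lo = c(0, 5), hi = c(10, 20))
  su2 <- community_dvs(s2)$summary
  expect_equal(su2$score[su2$metric == "dvs_u"],
               su2$score[su2$metric == "dvs_u_weighted"])
  # disjoint tiers score 1 and class high
  s3 <- band_surface(c("A", "B"), lo = c(0, 20), hi = c(10, 50))
  su3 <- community_dvs(s3)$summary
  expect_equal(su3$score[su3$metric == "dvs_u"], 1)
  expect_equal(su3$tier_class[su3$metric == "dvs_u"], "high")
})

test_that("tier classes split at 0.40 and 0.70", {
  expect_equal(paleocomm:::.tier_class(c(0.8, 0.70, 0.5, 0.40, 0.2)),
               c("high", "medium", "medium", "medium", "low"))
})

test_that("DVS-u is invariant to interval translation and DVS-h to
           uniform height scaling", {
  set.seed(4)
  lo <- runif(6, 0, 30); hi <- lo + runif(6, 1, 10)
  grp <- rep(1:3, each = 2)
  score <- function(shift, scale = 1) {
    profs <- lapply(1:3, function(g)
      profile_of(scale * (lo[grp == g] + shift),
                 scale * (hi[grp == g] + shift),
                 heights = scale * hi[grp == g], n = 2))
    list(u = sapply(1:3, function(g)
           taxon_dvs_u(profs[[g]], profs[-g])),
         h = sapply(1:3, function(g)
           taxon_dvs_h(profs[[g]], profs[-g])))
  }
  base <- score(0)
  expect_equal(score(17.3)$u, base$u)
  expect_equal(score(0, scale = 2.5)$h, base$h)
})

test_that("removing a taxon never decreases remaining DVS-u scores", {
  set.seed(6)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    profs <- lapply(seq_len(k), function(i) {
      m <- sample(1:4, 1)
      lo <- runif(m, 0, 40)
      profile_of(lo, lo + runif(m, 0.5, 15), n = m)
    })
    u_all <- sapply(seq_len(k), function(i)
      taxon_dvs_u(profs[[i]], profs[-i]))
    drop <- sample(k, 1)
    rest <- setdiff(seq_len(k), drop)
    u_red <- sapply(rest, function(i)
      taxon_dvs_u(profs[[i]], profs[setdiff(rest, i)]))
    expect_true(all(u_red >= u_all[rest] - 1e-12))
  }
})

test_that("exact DVS-u agrees with the occupancy-grid brute force on
           random communities", {
  set.seed(7)
  for (rep in 1:40) {
    k <- sample(2:5, 1)
    ints <- lapply(seq_len(k), function(i) {
      m <- sample(1:10, 1)
      lo <- runif(m, 0, 50)
      cbind(lo = lo, hi = lo + runif(m, 0.5, 20))
    })
    profs <- lapply(ints, function(m) profile_of(m[, 1], m[, 2],
                                                 n = nrow(m)))
    exact <- sapply(seq_len(k), function(i)
      taxon_dvs_u(profs[[i]], profs[-i]))
    grid <- grid_dvs_u(lapply(profs, function(p) p$zone))
    expect_equal(exact, grid, tolerance = 0.02)
  }
})

test_that("morphogroup tiering requires three abundant groups", {
  sp <- make_specimens(80,
    taxon = rep(c("Fractofusus misrai", "Charnia masoni"), each = 40),
    morphogroup = rep(c("reclining", "upright_frond"), each = 40),
    frond_length = 20, frond_width = 10,
    stem_length = rep(c(NA, 15), each = 40))
  s <- derive_geometry(surface_map(sp))
  expect_message(res <- morphogroup_dvs(s), "excluded")
  expect_null(res)
})

test_that("morphogroup tiering scores groups as single taxon-units", {
  n <- 40
  sp <- make_specimens(3 * n,
    taxon = rep(c("Fractofusus misrai", "Bradgatia sp", "Charnia masoni"),
                each = n),
    morphogroup = rep(c("reclining", "bradgatia", "upright_frond"),
                      each = n),
    frond_length = rep(c(30, 40, 60), each = n),
    frond_width = rep(c(15, 30, 25), each = n),
    stem_length = rep(c(NA, NA, 100), each = n))
  s <- derive_geometry(surface_map(sp))
  res <- morphogroup_dvs(s)
  expect_s3_class(res, "tiering_result")
  # recliners at [0, 5], bradgatia at [0, 40], fronds at [100, 160]:
  # fronds fully distinct, recliners swallowed by the bradgatia band
  pt <- res$per_taxon
  expect_equal(pt$dvs_u[pt$taxon == "upright_frond"], 1)
  expect_equal(pt$dvs_u[pt$taxon == "reclining"], 0)
  oracle <- grid_dvs_u(list(rbind(c(0, 5)), rbind(c(0, 40)),
                            rbind(c(100, 160))))
  expect_equal(sort(pt$dvs_u), sort(oracle), tolerance = 0.02)
})

test_that("tiering/succession associations recover planted monotone
           relationships", {
  df <- data.frame(w = c(0.2, 0.1, 0, -0.1, -0.2))
  df$dvs_u <- df$w                     # perfectly collinear
  df$dvs_h <- df$w
  df$dvs_u_weighted <- 1 - (df$w + 0.3)  # monotone inverse of stems
  df$dvs_h_weighted <- df$dvs_u_weighted
  df$stem_proportion <- 1 - df$dvs_u_weighted
  res <- suppressWarnings(tiering_succession_association(df))
  expect_equal(res$dvs_h_vs_dvs_u$rho, 1)
  expect_equal(res$stem_vs_weighted_dvs_u$rho, -1)
  expect_equal(res$regressions$adj_r2[res$regressions$metric == "dvs_u"],
               1)
})

test_that("independent tiering and succession show no association on
           average", {
  set.seed(11)
  rhos <- replicate(300, {
    x <- rnorm(18); y <- rnorm(18)
    suppressWarnings(cor.test(x, y, method = "spearman",
                              exact = FALSE)$estimate)
  })
  expect_lt(abs(mean(rhos)), 0.1)
})
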