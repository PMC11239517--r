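test_that("the ABC curves and W statistic match hand-worked values", {
  ab <- c(a = 70, b = 20, c = 10)
  bm <- c(a = 10, b = 30, c = 60)
  curve <- abc_curve(ab, bm)
  expect_equal(curve$A, c(70, 90, 100))
  expect_equal(curve$B, c(60, 90, 100))
  expect_equal(curve$W, 0.10)
  expect_equal(abc_curve(ab, ab)$W, 0)
  # swapping the roles of the share vectors flips the sign
  expect_equal(abc_curve(bm, ab)$W, -curve$W)
  # mirrored orientation for comparison with the classic convention
  expect_equal(abc_curve(ab, bm, orientation = "biomass_positive")$W,
               -0.10)
})

test_that("W is bounded, antisymmetric and invariant to biomass rescaling
           and taxon relabelling", {
  set.seed(2)
  for (i in 1:200) {
    S <- sample(2:8, 1)
    p <- setNames(rgamma(S, 1), paste0("t", 1:S))
    q <- setNames(rgamma(S, 1), paste0("t", 1:S))
    w <- abc_curve(p, q)$W
    expect_gte(w, -1); expect_lte(w, 1)
    expect_equal(abc_curve(q, p)$W, -w, tolerance = 1e-9)
    expect_equal(abc_curve(p, 7.3 * q)$W, w, tolerance = 1e-9)
    perm <- sample(S)
    expect_equal(abc_curve(setNames(p[perm], paste0("u", 1:S)),
                           setNames(q[perm], paste0("u", 1:S)))$W,
                 w, tolerance = 1e-9)
  }
})

test_that("a numerically dominant small-bodied taxon gives positive W", {
  # one abundant low-biomass taxon plus rare high-biomass taxa
  ab <- c(small = 900, big1 = 50, big2 = 50)
  bm <- c(small = 100, big1 = 4000, big2 = 3000)
  expect_gt(abc_curve(ab, bm)$W, 0)
})

test_that("abc_w aggregates counts and areal coverage per taxon and
           rejects single-taxon communities", {
  s <- band_surface(c("A", "A", "B"), lo = c(0, 0, 5), hi = c(10, 10, 20))
  curve <- abc_w(s)
  expect_equal(curve$S, 2)
  one <- band_surface("A", 0, 10)
  expect_error(abc_w(one), "fewer than 2 taxa")
})

test_that("the jackknife W distribution is centred on the full-surface W", {
  s <- planted_surface(c(.4, .25, .15, .12, .08),
                       c(.3, .22, .18, .16, .14), total_n = 1000,
                       seed = 31)
  jk <- generate_jackknife_samples(s, jackknife_config(n_samples = 1000,
                                                       seed = 32))
  wd <- w_jackknife_distribution(s, jk)
  expect_lt(abs(mean(wd) - abc_w(s)$W), 0.02)
  expect_equal(attr(wd, "n_dropped"), 0)
})

test_that("an early-succession configuration keeps the whole IQR above
           zero", {
  s <- planted_surface(c(.5, .2, .15, .1, .05), rep(.2, 5),
                       total_n = 800, seed = 33)
  jk <- generate_jackknife_samples(s, jackknife_config(n_samples = 300,
                                                       seed = 34))
  wd <- w_jackknife_distribution(s, jk)
  expect_gt(quantile(wd, 0.25), 0)
})

test_that("W comparisons use index-matched percentile intervals", {
  a <- rep(0.2, 100)
  cmp0 <- compare_w(a, a)
  expect_equal(cmp0$ci_low, 0)
  expect_equal(cmp0$ci_high, 0)
  expect_false(cmp0$significant)
  cmp1 <- compare_w(rep(0.2, 50), rep(-0.1, 80))
  expect_equal(cmp1$ci_low, 0.3)
  expect_equal(cmp1$ci_high, 0.3)
  expect_true(cmp1$significant)
  set.seed(5)
  cmp2 <- compare_w(rnorm(1000, 0.05, 0.01), rnorm(1000, -0.05, 0.01))
  expect_true(cmp2$significant)
  expect_gt(cmp2$ci_low, 0)
})

test_that("stage assignment follows the sign pattern of significant
           comparisons", {
  cmp <- data.frame(
    surface_a = c("hi", "hi", "mid"),
    surface_b = c("mid", "lo", "lo"),
    mean_diff = c(0.2, 0.4, 0.2),
    ci_low = c(0.15, 0.35, 0.15), ci_high = c(0.25, 0.45, 0.25),
    significant = TRUE)
  st <- assign_stages(cmp, c(hi = 0.2, mid = 0, lo = -0.2))
  expect_equal(st$stage[match(c("hi", "mid", "lo"), st$surface_id)],
               c("earlier", "intermediate", "later"))
  # no separation anywhere: everyone placed by mean W with a warning
  cmp0 <- cmp; cmp0$significant <- FALSE
  expect_warning(st0 <- assign_stages(cmp0, c(hi = 0.01, mid = 0,
                                              lo = -0.01)),
                 "no significant")
  expect_true(all(st0$resolution == "by_mean_w"))
  expect_equal(length(unique(st0$stage)), 1L)
})

test_that("silent surfaces and unjackknifed surfaces are placed by
           nearest mean-W group", {
  cmp <- data.frame(
    surface_a = c("hi", "quiet"), surface_b = c("lo", "hi"),
    mean_diff = c(0.4, -0.1), ci_low = c(0.35, -0.3),
    ci_high = c(0.45, 0.1), significant = c(TRUE, FALSE))
  st <- assign_stages(cmp, c(hi = 0.2, lo = -0.2, quiet = 0.19),
                      full_w = c(outsider = -0.25))
  expect_equal(st$stage[st$surface_id == "quiet"], "earlier")
  expect_equal(st$resolution[st$surface_id == "quiet"], "by_mean_w")
  expect_equal(st$stage[st$surface_id == "outsider"], "later")
})

test_that("W-covariate regressions report F, p and adjusted R2", {
  df <- data.frame(mean_w = c(0.2, 0.1, 0, -0.1, -0.2))
  df$perfect <- df$mean_w
  df$copy <- df$perfect
  set.seed(8); df$noise <- rnorm(5)
  res <- suppressWarnings(
    regress_w_covariates(df, covariates = c("perfect", "copy", "noise")))
  expect_equal(res$adj_r2[1], 1)
  expect_lt(res$p[1], 1e-6)
  expect_equal(res[1, -1], res[2, -1], ignore_attr = TRUE)
  df$flat <- 1
  expect_error(regress_w_covariates(df, covariates = "flat"), "constant")
})

test_that("null covariates give approximately uniform p values", {
  set.seed(9)
  p <- replicate(400, {
    df <- data.frame(mean_w = rnorm(16), cov = rnorm(16))
    regress_w_covariates(df, covariates = "cov")$p
  })
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})
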