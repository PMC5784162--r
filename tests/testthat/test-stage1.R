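test_that("balanced one-way REML matches the ANOVA closed form", {
  set.seed(21)
  g <- 200; r <- 2
  d <- data.frame(clone = factor(rep(seq_len(g), each = r)))
  u <- rnorm(g, 0, 1)
  d$y <- u[d$clone] + rnorm(g * r)
  fit <- reml_fit(d, "y", "one_way")
  a <- stats::anova(stats::lm(y ~ clone, d))
  s2c_anova <- (a[1, 3] - a[2, 3]) / r
  expect_equal(unname(fit$varcomps["clone"]), s2c_anova, tolerance = 1e-6)
  expect_equal(unname(fit$varcomps["residual"]), a[2, 3], tolerance = 1e-6)
})

test_that("constant response collapses to zero variance and zero BLUPs", {
  d <- data.frame(clone = factor(rep(1:30, each = 2)), y = 3)
  fit <- reml_fit(d, "y", "one_way")
  expect_true(all(fit$varcomps < 1e-10))
  expect_true(all(abs(fit$blups) < 1e-10))
  expect_equal(fit$H2, 0)
})

test_that("clone variance is recovered in a replicated design", {
  est <- vapply(1:10, function(s) {
    set.seed(s)
    g <- 500; r <- 2
    d <- data.frame(clone = factor(rep(seq_len(g), each = r)))
    u <- rnorm(g, 0, 1)
    d$y <- u[d$clone] + rnorm(g * r)
    unname(reml_fit(d, "y", "one_way")$varcomps["clone"])
  }, numeric(1))
  expect_lt(abs(mean(est) - 1), 0.15)
})

test_that("de-regression follows BLUP / (1 - PEV / s2c) with a reliability
          floor", {
  fit <- list(varcomps = c(clone = 1),
              blups = c(a = 1, b = 0.5, c = 0.3, d = 0.2, e = 0.1),
              pevs = c(a = 0, b = 0.5, c = 0.9, d = 0.97, e = 1.2))
  dg <- deregress(fit)
  expect_equal(dg$dereg[dg$clone == "a"], 1.0, tolerance = 1e-12)
  expect_equal(dg$dereg[dg$clone == "b"], 1.0, tolerance = 1e-12)
  expect_equal(dg$dereg[dg$clone == "c"], 3.0, tolerance = 1e-12)
  # reliability 0.03 < floor, and PEV > s2c: flagged, not returned
  expect_true(dg$excluded[dg$clone == "d"])
  expect_true(dg$excluded[dg$clone == "e"])
  expect_true(all(is.na(dg$dereg[dg$excluded])))
  expect_error(deregress(list(varcomps = c(clone = 0), blups = 1, pevs = 0)),
               "must be > 0")
})

test_that("de-regressed BLUPs are at least as dispersed as BLUPs", {
  cfg <- small_cfg(seed = 22)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$geno, sim$truth, cfg)
  fit <- reml_fit(ph[ph$panel == "panel1", ], "cbsd3s", "alpha_lattice")
  dg <- fit$dereg[!fit$dereg$excluded, ]
  expect_gte(stats::var(dg$dereg), stats::var(dg$blup))
  expect_true(all(fit$pevs >= 0 & fit$pevs <= fit$varcomps["clone"] + 1e-8))
})

test_that("entry-mean H2 follows the harmonic-mean formula", {
  fit <- list(varcomps = c(clone = 1, residual = 1),
              n_plots_per_clone = rep(2, 50))
  expect_equal(broad_sense_h2(fit), 1 / (1 + 1 / 2), tolerance = 1e-12)
  fit$varcomps <- c(clone = 0, residual = 1)
  expect_equal(broad_sense_h2(fit), 0)
  fit$varcomps <- c(clone = 1, residual = 0)
  expect_equal(broad_sense_h2(fit), 1)
  # unbalanced plot counts enter through the harmonic mean
  fit <- list(varcomps = c(clone = 1, residual = 1),
              n_plots_per_clone = c(1, 4, 4, 4))
  rbar <- 4 / (1 / 1 + 3 / 4)
  expect_equal(broad_sense_h2(fit), 1 / (1 + 1 / rbar), tolerance = 1e-12)
})

test_that("a constant covariate leaves the fit unchanged", {
  cfg <- small_cfg(seed = 23)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$geno, sim$truth, cfg)
  p1 <- ph[ph$panel == "panel1", ]
  p1$flat <- 1
  f0 <- reml_fit(p1, "cbsd3s", "alpha_lattice")
  f1 <- reml_fit(p1, "cbsd3s", "alpha_lattice", covariates = "flat")
  expect_equal(f0$varcomps, f1$varcomps, tolerance = 1e-10)
  expect_equal(f0$blups, f1$blups, tolerance = 1e-10)
})

test_that("the CMD covariate re-fit runs and changes the fixed part only
          modestly on independent traits", {
  cfg <- small_cfg(seed = 24)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$geno, sim$truth, cfg)
  p1 <- ph[ph$panel == "panel1", ]
  f0 <- reml_fit(p1, "cbsd6s", "alpha_lattice")
  f1 <- reml_fit(p1, "cbsd6s", "alpha_lattice", covariates = "cmds")
  expect_s3_class(f1, "stage1_fit")
  expect_gt(cor(f0$blups, f1$blups[names(f0$blups)]), 0.9)
})

test_that("trait correlations use the clone intersection", {
  x <- c(a = 1, b = 2, c = 3, d = 4)
  tab <- correlate_traits(list(s1 = x, s2 = x, s3 = -x))
  expect_equal(tab$correlation[tab$set1 == "s1" & tab$set2 == "s2"], 1)
  expect_equal(tab$correlation[tab$set1 == "s1" & tab$set2 == "s3"], -1)
  y <- c(q = 1, r = 2, s = 3)
  tab2 <- correlate_traits(list(s1 = x, s2 = y))
  expect_true(is.na(tab2$correlation))
  expect_equal(tab2$n, 0)
})

test_that("between-location correlation of de-regressed BLUPs is attenuated
          below the generating genetic correlation", {
  obs <- vapply(1:10, function(s) {
    cfg <- sim_config(n_clones_panel1 = 250, n_clones_panel2 = 0,
                      markers_per_chrom = 150, n_background = 60, seed = s,
                      introgression_spec = NULL, loc_corr = 0.6,
                      locations = list(panel1 = c("Namulonge", "Ngetta"),
                                       panel2 = character(0)),
                      h2_per_location = c(Namulonge = 0.5, Ngetta = 0.5),
                      traits = "cbsd3s", include_cmds = FALSE)
    sim <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(sim$geno, sim$truth, cfg)
    dsets <- lapply(c("Namulonge", "Ngetta"), function(loc) {
      f <- reml_fit(ph[ph$location == loc, ], "cbsd3s", "alpha_lattice")
      stats::setNames(f$dereg$dereg, f$dereg$clone)
    })
    names(dsets) <- c("A", "B")
    correlate_traits(dsets)$correlation
  }, numeric(1))
  expect_gt(mean(obs), 0)
  expect_lt(mean(obs), 0.6)
})
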