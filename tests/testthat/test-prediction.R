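test_that("identity kinship carries no information to untrained clones", {
  set.seed(51)
  n <- 60
  G <- diag(n)
  dimnames(G) <- list(paste0("c", 1:n), paste0("c", 1:n))
  y <- stats::setNames(rnorm(40), paste0("c", 1:40))
  fit <- gblup(y, G, predict_for = paste0("c", 41:60))
  expect_lt(max(abs(fit$gebv)), 1e-8)
  expect_equal(unname(fit$pred), rep(fit$pred[[1]], 20))
})

test_that("a duplicated training clone is predicted at the training clone's
          genetic effect", {
  set.seed(52)
  g <- quick_geno(n = 80, m = 300, seed = 52)
  M <- rbind(g$dosages, dup = g$dosages[1, ])
  rownames(M)[81] <- "dup"
  G <- grm_vanraden(M)
  y <- stats::setNames(rnorm(80, 0, 1), rownames(g$dosages))
  fit <- gblup(y, G, predict_for = c(rownames(g$dosages)[1], "dup"),
               allow_overlap = TRUE)
  expect_equal(fit$gebv[["dup"]], fit$gebv[[1]], tolerance = 1e-8)
  expect_error(gblup(y, G, predict_for = names(y)[1:10]), "overlap")
})

test_that("prediction accuracy increases with heritability and stays in a
          plausible band", {
  accs <- vapply(1:6, function(s) {
    cfg <- sim_config(n_clones_panel1 = 100, n_clones_panel2 = 200,
                      markers_per_chrom = 200, n_background = 120,
                      seed = s, introgression_spec = NULL)
    sim <- simulate_genotypes(cfg)
    g <- sim$truth$true_breeding_values[, 1]
    g <- (g - mean(g)) / sd(g)
    G <- grm_vanraden(sim$geno)
    test <- rownames(sim$geno$dosages)[251:300]
    train <- rownames(sim$geno$dosages)[1:250]
    one <- function(h2) {
      set.seed(1000 * s + round(100 * h2))
      y <- stats::setNames(g + rnorm(length(g), 0, sqrt((1 - h2) / h2)),
                           names(g))
      fit <- gblup(y[train], G, predict_for = test)
      cor(fit$pred[test], g[test])
    }
    one(0.4) - one(0.1)
  }, numeric(1))
  expect_gt(mean(accs), 0)
})

test_that("multi-kernel GBLUP collapses to single-kernel with a degenerate
          second kernel and decomposes exactly", {
  set.seed(53)
  g <- quick_geno(n = 120, m = 400, seed = 53)
  G <- grm_vanraden(g)
  yall <- stats::setNames(as.numeric(g$dosages %*% rnorm(400, 0, 0.05)) +
                            rnorm(120, 0, 0.5), rownames(g$dosages))
  train <- names(yall)[1:90]; test <- names(yall)[91:120]
  zero <- G * 0
  mk <- multikernel_gblup(yall[train], list(main = G, null = zero),
                          predict_for = test)
  single <- gblup(yall[train], G, predict_for = test)
  expect_lt(max(abs(mk$pred - single$pred)), 1e-6)
  expect_lt(max(abs(rowSums(mk$components) - mk$gebv)), 1e-8)
  Gbad <- G[1:100, 1:100]
  expect_error(multikernel_gblup(yall[train], list(G, Gbad)), "mismatched")
})

test_that("chromosome kernels conserve markers and reconstruct the
          whole-genome GRM", {
  g <- quick_geno(n = 80, m = 300, n_chrom = 3, seed = 54)
  ker <- build_chromosome_kernels(g, focal_chroms = c("1", "2"))
  expect_named(ker, c("chr1", "chr2", "rest"))
  expect_equal(sum(vapply(ker, attr, numeric(1), which = "n_markers")),
               ncol(g$dosages))
  w <- vapply(ker, attr, numeric(1), which = "scale")
  recon <- Reduce(`+`, Map(function(K, wk) K * wk, ker, w)) / sum(w)
  expect_equal(recon, grm_vanraden(g), tolerance = 1e-10,
               ignore_attr = TRUE)
  single <- build_chromosome_kernels(g)
  expect_equal(single$whole_genome, grm_vanraden(g), ignore_attr = TRUE)
  expect_error(build_chromosome_kernels(g, "99"), "absent")
})

test_that("Gaussian kernels follow exp(-d * theta)", {
  D <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "m1"))
  K <- rkhs_kernels(D, thetas = 0.05)[[1]]
  expect_equal(K["a", "b"], exp(-4 * 0.05), tolerance = 1e-12)
  expect_equal(diag(K), c(a = 1, b = 1))
  # identical clones: K = 1 for every theta
  D2 <- matrix(rbinom(20, 2, 0.5), 2, 10, byrow = TRUE,
               dimnames = list(c("a", "b"), paste0("m", 1:10)))
  D2[2, ] <- D2[1, ]
  for (K in rkhs_kernels(D2)) expect_equal(K["a", "b"], 1, tolerance = 1e-12)
  # theta -> 0 limit: flat kernel
  set.seed(55)
  D3 <- matrix(rbinom(100, 2, 0.5), 10, 10,
               dimnames = list(paste0("c", 1:10), paste0("m", 1:10)))
  Kflat <- rkhs_kernels(D3, thetas = 1e-12)[[1]]
  expect_lt(max(abs(Kflat - 1)), 1e-9)
  expect_error(rkhs_kernels(D3, thetas = -1))
})

test_that("all built kernels are PSD", {
  g <- quick_geno(n = 60, m = 200, n_chrom = 2, seed = 56)
  kers <- c(build_chromosome_kernels(g, "1"), rkhs_kernels(g))
  for (K in kers) {
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * sum(diag(K)) / nrow(K))
  }
})

test_that("Bayesian samplers are seed-reproducible and shrink null effects
          with sample size", {
  g <- quick_geno(n = 500, m = 150, seed = 57)
  M <- g$dosages
  set.seed(57)
  y <- rnorm(500)
  f1 <- bayes_regression(M[1:300, ], y[1:300], "BayesA", iters = 800,
                         burnin = 200, seed = 7)
  f2 <- bayes_regression(M[1:300, ], y[1:300], "BayesA", iters = 800,
                         burnin = 200, seed = 7)
  expect_identical(f1$effects, f2$effects)
  shrink <- vapply(1:5, function(s) {
    big <- bayes_regression(M, y, "BayesCpi", iters = 600, burnin = 150,
                            seed = s)
    small <- bayes_regression(M[1:50, ], y[1:50], "BayesCpi", iters = 600,
                              burnin = 150, seed = s)
    mean(abs(big$effects)) < mean(abs(small$effects))
  }, logical(1))
  expect_gte(sum(shrink), 4)
  expect_error(bayes_regression(M, y, "BayesA", iters = 100, burnin = 200))
})

test_that("BayesB concentrates posterior mass on a strong sparse signal", {
  hits <- vapply(1:5, function(s) {
    g <- quick_geno(n = 350, m = 400, seed = 600 + s)
    M <- g$dosages
    p <- colMeans(M) / 2
    j <- which(p > 0.35 & p < 0.65)[1]
    set.seed(s)
    beta <- sqrt(0.15 / (2 * p[j] * (1 - p[j])))
    gq <- beta * M[, j]
    y <- gq + rnorm(350, 0, sqrt(var(gq) * 0.85 / 0.15))
    fit <- bayes_regression(M, y, "BayesB", iters = 1500, burnin = 400,
                            seed = s)
    which.max(abs(fit$effects)) == j
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("Random Forest handles constants, clips mtry, and is
          reproducible", {
  g <- quick_geno(n = 100, m = 50, seed = 58)
  M <- g$dosages
  ycon <- rep(2, 80)
  # randomForest itself also warns about a low-cardinality response
  w <- capture_warnings(
    fit <- random_forest_gp(M[1:80, ], ycon, M[81:100, ], ntree = 100,
                            mtry = 300, seed = 1))
  expect_true(any(grepl("clipping", w)))
  expect_lt(max(abs(fit$pred - 2)), 1e-8)
  set.seed(58)
  y <- rnorm(80)
  f1 <- random_forest_gp(M[1:80, ], y, M[81:100, ], ntree = 100, mtry = 20,
                         seed = 3)
  f2 <- random_forest_gp(M[1:80, ], y, M[81:100, ], ntree = 100, mtry = 20,
                         seed = 3)
  expect_identical(f1$pred, f2$pred)
})

test_that("cross-validation is deterministic, accuracy is affine invariant,
          and permuted labels calibrate to zero", {
  cfg <- sim_config(n_clones_panel1 = 80, n_clones_panel2 = 160,
                    markers_per_chrom = 150, n_background = 80, seed = 59,
                    introgression_spec = NULL)
  sim <- simulate_genotypes(cfg)
  g <- sim$truth$true_breeding_values[, 1]
  set.seed(59)
  y <- stats::setNames(g + rnorm(length(g), 0, sd(g)),
                       rownames(sim$geno$dosages))
  a1 <- cross_validate("gblup", sim$geno, y,
                       scheme = list(type = "kfold", k = 5, reps = 1),
                       seed = 4)
  a2 <- cross_validate("gblup", sim$geno, y,
                       scheme = list(type = "kfold", k = 5, reps = 1),
                       seed = 4)
  expect_equal(a1, a2)
  a3 <- cross_validate("gblup", sim$geno, 10 + 3 * y,
                       scheme = list(type = "kfold", k = 5, reps = 1),
                       seed = 4)
  expect_equal(a1$accuracy, a3$accuracy, tolerance = 1e-6)
  null_acc <- vapply(1:10, function(s) {
    set.seed(700 + s)
    yp <- stats::setNames(sample(y), names(y))
    mean(cross_validate("gblup", sim$geno, yp,
                        scheme = list(type = "kfold", k = 5, reps = 1),
                        seed = s)$accuracy)
  }, numeric(1))
  expect_lt(abs(mean(null_acc)), 0.1)
  expect_error(
    cross_validate("gblup", sim$geno, y,
                   scheme = list(type = "kfold", k = 30, reps = 1), seed = 1),
    "fewer than")
})

test_that("cross-panel prediction trains on one panel and scores the other", {
  cfg <- sim_config(n_clones_panel1 = 80, n_clones_panel2 = 120,
                    markers_per_chrom = 150, n_background = 80, seed = 60,
                    introgression_spec = NULL)
  sim <- simulate_genotypes(cfg)
  g <- sim$truth$true_breeding_values[, 1]
  set.seed(60)
  y <- stats::setNames(g + rnorm(length(g), 0, sd(g)),
                       rownames(sim$geno$dosages))
  acc <- cross_validate("gblup", sim$geno, y,
                        scheme = list(type = "cross_panel",
                                      train = "panel1", test = "panel2"),
                        seed = 2)
  expect_equal(nrow(acc), 1)
  expect_equal(acc$n_test, 120)
  expect_gt(acc$accuracy, 0)
})
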