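test_that("generator is deterministic under a seed and varies across seeds", {
  a <- simulate_genotypes(small_cfg(seed = 11))
  b <- simulate_genotypes(small_cfg(seed = 11))
  c <- simulate_genotypes(small_cfg(seed = 12))
  expect_identical(a$geno$dosages, b$geno$dosages)
  expect_identical(a$truth$true_breeding_values, b$truth$true_breeding_values)
  expect_false(identical(a$geno$dosages, c$geno$dosages))
})

test_that("carrier frequency 0 and 1 bracket the ancestry truth", {
  cfg0 <- sim_config(n_clones_panel1 = 40, n_clones_panel2 = 80,
                     markers_per_chrom = 600, n_background = 100, seed = 2,
                     introgression_spec = list(chrom = "4", start_bp = 2e6,
                                               end_bp = 2.8e7,
                                               carrier_freq = 0, effect = 0))
  t0 <- simulate_genotypes(cfg0)$truth$true_ancestry
  expect_true(all(t0$truth == "EE"))

  cfg1 <- cfg0
  cfg1$introgression_spec$carrier_freq <- 1
  t1 <- simulate_genotypes(cfg1)$truth
  seg_windows <- unique(t1$true_ancestry$window[t1$true_ancestry$truth != "EE"])
  expect_gt(length(seg_windows), 0)
  inseg <- t1$true_ancestry[t1$true_ancestry$window %in% seg_windows, ]
  expect_true(all(inseg$truth == "GG"))  # all gametes donor => homozygous
})

test_that("an interval too narrow for a 20-AI-SNP window is refused", {
  cfg <- small_cfg(seed = 3)
  cfg$introgression_spec <- list(chrom = "4", start_bp = 1e6, end_bp = 1.4e6,
                                 carrier_freq = 0.2, effect = 0)
  expect_error(simulate_genotypes(cfg), "fewer than 20")
})

test_that("phenotypes respect the ordinal scale and the plot layout", {
  cfg <- small_cfg(seed = 4)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$geno, sim$truth, cfg)
  for (tr in c(cfg$traits, "cmds")) {
    expect_true(all(ph[[tr]] %in% 1:5))
  }
  expect_true(all(ph$clone %in% rownames(sim$geno$dosages)))
  p1 <- ph[ph$panel == "panel1", ]
  expect_setequal(unique(p1$rep), 1:2)
  p2 <- ph[ph$panel == "panel2", ]
  # every augmented block carries the full check set
  chk <- table(p2$clone[p2$is_check], p2$location[p2$is_check])
  expect_true(all(chk == max(p2$block)))
})

test_that("score thresholds saturate and inconsistent h2 is rejected", {
  cfg <- small_cfg(seed = 5,
                   score_thresholds = c(-1000, -999, -998, -997))
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$geno, sim$truth, cfg)
  expect_true(all(ph$cbsd3s == 5))

  cfg2 <- small_cfg(seed = 5, score_jitter = 0.5,
                    h2_per_location = c(Namulonge = 1, Ngetta = 1,
                                        Kasese = 1, Serere = 1, Kamuli = 1))
  sim2 <- simulate_genotypes(cfg2)
  expect_error(simulate_phenotypes(sim2$geno, sim2$truth, cfg2),
               "inconsistent")
})

test_that("with h2 = 1 and no location deviation, scores are a deterministic
          function of the genetic value", {
  cfg <- small_cfg(seed = 6, loc_corr = 1,
                   h2_per_location = c(Namulonge = 1, Ngetta = 1,
                                       Kasese = 1, Serere = 1, Kamuli = 1))
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$geno, sim$truth, cfg)
  p1 <- ph[ph$panel == "panel1" & ph$location == "Ngetta", ]
  reps <- split(p1$cbsd3s, p1$clone)
  expect_true(all(vapply(reps, function(v) length(unique(v)) == 1,
                         logical(1))))
})

test_that("realized allele frequencies track the generating frequencies", {
  cfg <- small_cfg(seed = 7, introgression_spec = NULL)
  sim <- simulate_genotypes(cfg)
  p_hat <- colMeans(sim$geno$dosages) / 2
  p_gen <- sim$truth$generating_freq
  # dominant sampling layer is the founder pool (n_founders haplotypes);
  # a 4-SE band should cover essentially every marker
  se <- sqrt(p_gen * (1 - p_gen) / cfg$n_founders +
               p_gen * (1 - p_gen) / nrow(sim$geno$dosages))
  cover <- mean(abs(p_hat - p_gen) <= 4 * se + 1e-9)
  expect_gte(cover, 0.98)
  expect_lt(mean(p_hat - p_gen), 0.02)  # no systematic bias
})

test_that("zero architecture yields no clone variance downstream", {
  cfg <- sim_config(n_clones_panel1 = 150, n_clones_panel2 = 0,
                    markers_per_chrom = 150, n_background = 50,
                    polygenic_var = 1e-12, seed = 8,
                    introgression_spec = NULL,
                    qtl_spec = data.frame(chrom = character(),
                                          bp = numeric(), add = numeric(),
                                          dom = numeric()),
                    locations = list(panel1 = "Namulonge",
                                     panel2 = character(0)),
                    traits = "cbsd3s", include_cmds = FALSE,
                    h2_per_location = c(Namulonge = 0.5))
  sim <- simulate_genotypes(cfg)
  g <- sim$truth$true_breeding_values[, 1]
  expect_lt(stats::var(g), 1e-10)
})

test_that("written outputs round-trip through the VCF reader", {
  cfg <- small_cfg(seed = 9)
  dir <- withr::local_tempdir()
  sim <- simulate_panel(cfg, dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("genotypes.vcf", "dosages.csv", "phenotypes.csv",
      "truth_breeding_values.csv", "ai_catalog.csv")))))
  geno2 <- read_vcf_dosages(file.path(dir, "genotypes.vcf"))
  expect_equal(unname(geno2$dosages), unname(sim$geno$dosages))
  expect_equal(geno2$map$pos, sim$geno$map$pos)
  expect_equal(round(geno2$map$ar2, 4), round(sim$geno$map$ar2, 4))
})
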