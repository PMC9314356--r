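test_that("reference panel obeys Hardy-Weinberg expectations and is deterministic", {
  cfg <- sim_config(n_studies = 1, n_cases_per_study = 10,
                    n_controls_per_study = 10, n_variants = 60,
                    maf_range = c(0.5, 0.5), major_locus_freq = 0.5,
                    n_risk_snps = 5, n_resilience_snps = 5,
                    ld_block_size = 1, seed = 42)
  n <- 4000
  panel <- simulate_reference_panel(cfg, n_samples = n)
  # at p = 0.5 the dosage mean is 1 with variance 2pq = 0.5
  z <- (colMeans(panel$dosages) - 1) / sqrt(0.5 / n)
  expect_lt(max(abs(z)), 4.5)          # per-variant, 60 variants
  expect_lt(abs(mean(z)), 3 / sqrt(60))  # grand mean within 3 SE

  panel2 <- simulate_reference_panel(cfg, n_samples = n)
  expect_identical(panel$dosages, panel2$dosages)
})

test_that("unlinked variants show null-level pairwise r2", {
  cfg <- sim_config(n_studies = 1, n_cases_per_study = 10,
                    n_controls_per_study = 10, n_variants = 40,
                    maf_range = c(0.2, 0.5), n_risk_snps = 2,
                    n_resilience_snps = 2, ld_block_size = 1, seed = 3)
  n <- 500
  panel <- simulate_reference_panel(cfg, n_samples = n)
  r2 <- cor(panel$dosages)^2
  mean_r2 <- mean(r2[upper.tri(r2)])
  # brute-force mean of pairwise r2 vs the theoretical null mean 1/(n-1)
  expect_equal(mean_r2, 1 / (n - 1), tolerance = 0.35)
})

test_that("block LD induces within-block but not between-block correlation", {
  cfg <- sim_config(n_studies = 1, n_cases_per_study = 10,
                    n_controls_per_study = 10, n_variants = 40,
                    maf_range = c(0.3, 0.5), n_risk_snps = 2,
                    n_resilience_snps = 2, ld_block_size = 4,
                    ld_block_r = 0.8, seed = 8)
  panel <- simulate_reference_panel(cfg, n_samples = 1500)
  map <- polyresilience:::variant_map(cfg)
  r2 <- cor(panel$dosages)^2
  same <- outer(map$block, map$block, "==") & upper.tri(r2)
  diff <- !outer(map$block, map$block, "==") & upper.tri(r2)
  expect_gt(mean(r2[same]), 0.2)
  expect_lt(mean(r2[diff]), 0.02)
})

test_that("cohort simulation is deterministic and fills requested counts", {
  cfg <- tiny_config(seed = 5)
  sim1 <- simulate_cohorts(cfg)
  sim2 <- simulate_cohorts(cfg)
  expect_identical(sim1$studies[[2]]$dosages, sim2$studies[[2]]$dosages)
  expect_identical(sim1$studies[[3]]$samples, sim2$studies[[3]]$samples)
  expect_identical(sim1$truth$liability_threshold,
                   sim2$truth$liability_threshold)
  for (st in sim1$studies) {
    expect_equal(sum(st$samples$status == "case"), 250)
    expect_equal(sum(st$samples$status == "control"), 250)
    expect_true(all(st$samples$age >= 60 & st$samples$age <= 90))
    expect_true(all(st$samples$sex %in% 1:2))
    expect_true(all(c("PC1", "PC4") %in% names(st$samples)))
  }
})

test_that("with no genetic effects the liability threshold matches qnorm(1-K)", {
  cfg <- tiny_config(seed = 9, n_risk_snps = 0, major_locus_beta = 0,
                     resilience_gamma = 0, disease_prevalence = 0.2)
  sim <- simulate_cohorts(cfg)
  # L = eps ~ N(0,1): threshold must be the (1-K) normal quantile, up to
  # Monte-Carlo error in the 50k-draw calibration
  expect_equal(sim$truth$liability_threshold, qnorm(0.8), tolerance = 0.03)
})

test_that("gamma = 0 makes affection independent of resilience dosage", {
  cfg <- tiny_config(seed = 11, n_cases_per_study = 600,
                     n_controls_per_study = 600, n_studies = 1,
                     resilience_gamma = 0)
  sim <- simulate_cohorts(cfg)
  st <- sim$studies[[1]]
  load <- rowSums(st$dosages[, sim$truth$resilience_snp_ids, drop = FALSE])
  fit <- summary(glm((st$samples$status == "case") ~ load,
                     family = binomial()))
  expect_lt(abs(fit$coefficients["load", "z value"]), 4)
})

test_that("gamma > 0 enriches resilience alleles in high-risk controls", {
  cfg <- tiny_config(seed = 13, n_cases_per_study = 1200,
                     n_controls_per_study = 1200, n_studies = 1,
                     resilience_gamma = 0.3)
  sim <- simulate_cohorts(cfg)
  st <- sim$studies[[1]]
  tr <- sim$truth$samples
  hi <- tr$high_risk
  load <- rowSums(st$dosages[, sim$truth$resilience_snp_ids, drop = FALSE])
  # brute-force contrast among samples above the risk quantile
  expect_gt(mean(load[hi & !tr$affected]), mean(load[hi & tr$affected]))
})

test_that("rejection sampling fails explicitly when counts are infeasible", {
  cfg <- tiny_config(seed = 2, n_studies = 1, n_cases_per_study = 50,
                     n_controls_per_study = 10, n_variants = 40,
                     n_risk_snps = 3, n_resilience_snps = 3,
                     disease_prevalence = 1e-4)
  expect_error(simulate_cohorts(cfg), "rejection sampling exhausted")
})

test_that("prior risk GWAS recovers true effects as n_effective grows", {
  cfg <- tiny_config(seed = 17, n_variants = 200, n_risk_snps = 20)
  map <- polyresilience:::variant_map(cfg)
  panel <- simulate_reference_panel(cfg, n_samples = 600)
  sim <- simulate_cohorts(tiny_config(seed = 17, n_variants = 200,
                                      n_risk_snps = 20, n_studies = 1,
                                      n_cases_per_study = 50,
                                      n_controls_per_study = 50))
  gw <- make_prior_risk_gwas(panel, sim$truth, n_effective = 1e12, seed = 4)
  expect_lt(max(abs(gw$beta - map$beta[match(gw$snp_id, map$snp_id)])), 1e-4)
  # and the noise SD matches the implied SE
  expect_equal(gw$se, 1 / sqrt(2 * colMeans(panel$dosages[, gw$snp_id]) / 2 *
                                 (1 - colMeans(panel$dosages[, gw$snp_id]) / 2) *
                                 1e12),
               ignore_attr = TRUE)
})

test_that("null variants yield uniform risk-GWAS P-values", {
  cfg <- sim_config(n_studies = 1, n_cases_per_study = 10,
                    n_controls_per_study = 10, n_variants = 500,
                    n_risk_snps = 0, major_locus_beta = 0,
                    n_resilience_snps = 0, ld_block_size = 1, seed = 21)
  panel <- simulate_reference_panel(cfg, n_samples = 800)
  sim_truth <- local({
    sim <- simulate_cohorts(sim_config(n_studies = 1, n_cases_per_study = 30,
                                       n_controls_per_study = 30,
                                       n_variants = 500, n_risk_snps = 0,
                                       major_locus_beta = 0,
                                       n_resilience_snps = 0,
                                       ld_block_size = 1, seed = 21))
    sim$truth
  })
  gw <- make_prior_risk_gwas(panel, sim_truth, n_effective = 5e4, seed = 31)
  ks <- suppressWarnings(stats::ks.test(gw$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the SE formula matches a brute-force regression oracle", {
  # independent oracle: OLS of a standardized-liability response on one
  # simulated variant, n = 20000, p = 0.3
  set.seed(77)
  n <- 20000; p <- 0.3
  g <- rbinom(n, 2, p)
  y <- 0.1 * g + rnorm(n)
  se_emp <- summary(lm(y ~ g))$coefficients["g", "Std. Error"]
  expect_equal(se_emp, 1 / sqrt(2 * p * (1 - p) * n), tolerance = 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_variants = 5), "exceed n_variants")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(disease_prevalence = 1.2), "disease_prevalence")
  expect_error(sim_config(n_studies = 0), "positive")
  expect_error(sim_config(ld_block_r = 1), "ld_block")
  expect_error(simulate_reference_panel(tiny_config(), n_samples = 0),
               "positive")
})

test_that("YAML configuration round-trips through read_sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_studies: 2", "n_cases_per_study: 40",
               "n_controls_per_study: 40", "n_variants: 100",
               "n_risk_snps: 5", "n_resilience_snps: 5", "seed: 12"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_studies, 2L)
  expect_equal(cfg$seed, 12L)
  writeLines("nonsense_key: 1", path)
  expect_error(read_sim_config(path), "unknown config keys")
})
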