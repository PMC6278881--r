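test_that("identical seeds reproduce every simulated object bit-for-bit", {
  cfg <- small_config(seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$effects, b$effects)
  expect_identical(a$sumstats, b$sumstats)
  expect_identical(as.data.frame(a$phenotypes), as.data.frame(b$phenotypes))
  d <- simulate_cohort(small_config(seed = 12))
  expect_false(identical(a$genotypes$dosage, d$genotypes$dosage))
})

test_that("dosages are 0/1/2 and allele frequencies track configured MAFs", {
  cfg <- sim_config(n_snps = 100, block_size = 10, n_target = 2000, seed = 2)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosage %in% 0:2))
  f_emp <- allele_freq(g)
  f_cfg <- g$snps$maf
  se <- sqrt(f_cfg * (1 - f_cfg) / (2 * nrow(g$dosage)))
  expect_true(all(abs(f_emp - f_cfg) < 3.5 * se))
})

test_that("maf = 0.5 gives mean dosage near 1 by symmetry", {
  cfg <- sim_config(n_snps = 20, block_size = 5, maf_range = c(0.5, 0.5),
                    n_target = 10000, seed = 3)
  g <- simulate_genotypes(cfg)
  expect_true(all(abs(colMeans(g$dosage) - 1) < 0.03))
})

test_that("zero within-block correlation yields independent SNPs", {
  cfg <- sim_config(n_snps = 100, block_size = 10, within_block_rho = 0,
                    n_target = 5000, seed = 4)
  g <- simulate_genotypes(cfg)
  cc <- cor(g$dosage)
  expect_lt(mean(abs(cc[upper.tri(cc)])), 3 / sqrt(5000))
})

test_that("adjacent-SNP LD matches a direct Monte-Carlo latent-model oracle", {
  rho <- 0.9; maf <- 0.3
  cfg <- sim_config(n_snps = 2, block_size = 2, within_block_rho = rho,
                    maf_range = c(maf, maf), n_target = 30000, seed = 5)
  g <- simulate_genotypes(cfg)
  emp_r2 <- cor(g$dosage[, 1], g$dosage[, 2])^2

  # oracle: direct simulation of the same latent model, 1e6 haplotypes
  set.seed(901)
  nh <- 1e6
  z1 <- rnorm(nh)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(nh)
  h1 <- as.integer(z1 < qnorm(maf)); h2 <- as.integer(z2 < qnorm(maf))
  half <- nh / 2
  d1 <- h1[1:half] + h1[(half + 1):nh]
  d2 <- h2[1:half] + h2[(half + 1):nh]
  oracle_r2 <- cor(d1, d2)^2
  expect_lt(abs(emp_r2 - oracle_r2), 0.02)
})

test_that("block layout keeps blocks inside and apart from the clump window", {
  cfg <- sim_config(n_snps = 100, block_size = 25, seed = 6)
  g <- simulate_genotypes(cfg, n_samples = 10)
  spans <- tapply(g$snps$bp, g$snps$block, function(x) max(x) - min(x))
  expect_true(all(spans < 250000))
  block_ends <- tapply(g$snps$bp, g$snps$block, max)
  block_starts <- tapply(g$snps$bp, g$snps$block, min)
  gaps <- block_starts[-1] - block_ends[-length(block_ends)]
  expect_true(all(gaps > 250000))
})

test_that("effect construction respects causal fraction and genetic correlation", {
  cfg <- small_config(seed = 7, prop_causal = 0.3)
  eff <- simulate_effects(cfg)
  expect_equal(sum(eff$causal), round(0.3 * 300))
  expect_true(all(eff$discovery[!eff$causal] == 0))
  expect_equal(sum(eff$discovery^2), cfg$h2_discovery)

  # r_g = 1 with equal h2: target effects equal discovery effects
  tr1 <- tibble::tibble(name = "t", type = "continuous", r_g = 1,
                        h2 = 0.22, prevalence = NA)
  e1 <- simulate_effects(small_config(seed = 8, traits = tr1))
  expect_equal(e1$t, e1$discovery, tolerance = 1e-12)

  # r_g = 0: effect vectors uncorrelated
  tr0 <- tibble::tibble(name = "t", type = "continuous", r_g = 0,
                        h2 = 0.2, prevalence = NA)
  cfg0 <- sim_config(n_snps = 4000, block_size = 10, prop_causal = 0.5, seed = 9,
                     traits = tr0)
  e0 <- simulate_effects(cfg0)
  ci <- e0$causal
  expect_lt(abs(cor(e0$discovery[ci], e0$t[ci])), 3 / sqrt(sum(ci)))
})

test_that("genetic-value correlation across seeds matches configured r_g", {
  tr <- tibble::tibble(name = "t", type = "continuous", r_g = 0.5,
                       h2 = 0.3, prevalence = NA)
  cors <- vapply(1:10, function(s) {
    cfg <- sim_config(n_snps = 2000, block_size = 10, within_block_rho = 0,
                      prop_causal = 1, n_target = 500, seed = 100 + s,
                      traits = tr)
    g <- simulate_genotypes(cfg)
    eff <- simulate_effects(cfg)
    X <- scale(g$dosage)
    cor(drop(X %*% eff$discovery), drop(X %*% eff$t))
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.5), 0.05)
})

test_that("null summary statistics give uniform p-values", {
  cfg <- sim_config(n_snps = 10000, block_size = 10, h2_discovery = 0,
                    seed = 10)
  eff <- simulate_effects(cfg)
  ss <- simulate_discovery_sumstats(eff, cfg)
  expect_true(all(ss$P > 0 & ss$P <= 1))
  ks <- suppressWarnings(stats::ks.test(ss$P, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("discovery estimates are consistent as the GWAS grows", {
  cfg <- small_config(seed = 11)
  cfg$n_discovery <- 1e8L
  eff <- simulate_effects(cfg)
  ss <- simulate_discovery_sumstats(eff, cfg)
  f <- prsct:::panel_metadata(cfg)$maf
  est <- log(ss$OR) * sqrt(2 * f * (1 - f))
  expect_true(all(abs(est - eff$discovery) < 1e-3))
})

test_that("mean chi-square of causal SNPs matches the generating equations", {
  cfg <- sim_config(n_snps = 5000, block_size = 10, prop_causal = 0.2,
                    h2_discovery = 0.22, n_discovery = 55374, seed = 12)
  eff <- simulate_effects(cfg)
  ss <- simulate_discovery_sumstats(eff, cfg)
  f <- prsct:::panel_metadata(cfg)$maf
  est <- log(ss$OR) * sqrt(2 * f * (1 - f))
  z2 <- (est * sqrt(cfg$n_discovery))^2
  ci <- eff$causal
  expected <- 1 + cfg$n_discovery * mean(eff$discovery[ci]^2)
  expect_lt(abs(mean(z2[ci]) - expected) / expected, 0.05)
})

test_that("liability thresholding reproduces configured prevalence", {
  tr <- tibble::tibble(name = "dx", type = "binary", r_g = 0.3,
                       h2 = 0.1, prevalence = 0.0214)
  cfg <- sim_config(n_snps = 50, block_size = 10, n_target = 100000,
                    seed = 13, traits = tr)
  coh <- simulate_cohort(cfg)
  expect_lt(abs(mean(coh$phenotypes$dx) - 0.0214), 0.0015)
})

test_that("zero-heritability traits carry no genetic signal", {
  tr <- tibble::tibble(name = "t", type = "continuous", r_g = 0.5,
                       h2 = 0, prevalence = NA)
  cfg <- sim_config(n_snps = 200, block_size = 10, n_target = 5000, seed = 14,
                    traits = tr)
  coh <- simulate_cohort(cfg)
  # the trait's own effects are zero; correlate against the discovery
  # polygenic value instead, which would pick up any leaked genetic signal
  g_disc <- drop(scale(coh$genotypes$dosage) %*% coh$effects$discovery)
  expect_lt(abs(cor(g_disc, coh$phenotypes$t)), 3 / sqrt(5000))
})

test_that("trait regression on true genetic value recovers sqrt(h2)", {
  tr <- tibble::tibble(name = "t", type = "continuous", r_g = 0.5,
                       h2 = 0.25, prevalence = NA)
  cfg <- sim_config(n_snps = 200, block_size = 10, n_target = 8000, seed = 15,
                    traits = tr)
  coh <- simulate_cohort(cfg)
  g <- attr(coh$phenotypes, "genetic_values")$t
  fit <- stats::lm(coh$phenotypes$t ~ g)
  slope <- coef(summary(fit))["g", ]
  expect_lt(abs(slope["Estimate"] - sqrt(0.25)), 3 * slope["Std. Error"])
})

test_that("missingness and relative injection behave as configured", {
  cfg <- sim_config(n_snps = 100, block_size = 10, n_target = 300, seed = 16)
  g <- simulate_genotypes(cfg)
  gm <- inject_missingness(g, rate = 0.05, seed = 2)
  rate <- mean(is.na(gm$dosage))
  expect_lt(abs(rate - 0.05), 0.01)

  gd <- inject_relatives(g, "duplicate", parents = 1L)
  expect_equal(nrow(gd$dosage), 301)
  expect_identical(unname(gd$dosage[301, ]), unname(g$dosage[1, ]))
  gp <- inject_relatives(g, "parent_child", parents = c(1L, 2L), seed = 3)
  expect_true(all(gp$dosage[301, ] %in% 0:2))
})
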