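test_that("linear fit degenerate cases behave (constant and exact responses)", {
  X <- cbind(`(Intercept)` = 1, x = rnorm(30))
  f_const <- fit_linear(rep(2, 30), X)
  expect_equal(f_const$r2, 0)
  expect_equal(f_const$coefficients$estimate[2], 0, tolerance = 1e-10)

  y_exact <- 3 + 2 * X[, "x"]
  f_exact <- fit_linear(y_exact, X)
  expect_equal(f_exact$r2, 1, tolerance = 1e-10)
})

test_that("linear coefficients match the normal-equations oracle", {
  set.seed(61)
  for (i in 1:10) {
    X <- cbind(1, matrix(rnorm(50 * 2), 50, 2))
    colnames(X) <- c("(Intercept)", "a", "b")
    y <- rnorm(50)
    fit <- fit_linear(y, X)
    oracle <- drop(solve(crossprod(X), crossprod(X, y)))
    expect_equal(fit$coefficients$estimate, unname(oracle), tolerance = 1e-8)
  }
})

test_that("collinear design columns are dropped and logged", {
  X <- cbind(`(Intercept)` = 1, a = rnorm(40))
  X <- cbind(X, dup = 2 * X[, "a"])
  fit <- fit_linear(rnorm(40), X)
  expect_equal(fit$dropped, "dup")
  expect_equal(nrow(fit$coefficients), 2)
})

test_that("intercept-only logistic fit equals the closed-form log-odds", {
  y <- c(rep(1, 30), rep(0, 70))
  fit <- fit_logistic(y, matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)")))
  expect_equal(fit$coefficients$estimate, log(30 / 70), tolerance = 1e-4)
  expect_equal(fit$loglik, fit$loglik_null, tolerance = 1e-8)
})

test_that("logistic slope on an independent predictor is null", {
  set.seed(62)
  n <- 10000
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.3)
  fit <- fit_logistic(y, cbind(`(Intercept)` = 1, x = x))
  row <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_lt(abs(row$estimate), 3 * row$se)
})

test_that("logistic log-likelihood matches a grid-search oracle", {
  # tiny printed fixture: 20 observations, one predictor
  y <- c(0, 1, 1, 0, 1, 0, 0, 0, 1, 1, 1, 0, 1, 0, 0, 1, 0, 1, 1, 0)
  x <- c(-1.2, -0.8, 0.5, -0.3, 1.1, 0.9, -1.5, 0.2, 0.7, -0.6,
         1.4, 0.3, 1.8, -1.0, -0.2, 0.6, -0.9, 1.2, 0.1, -0.4)
  fit <- fit_logistic(y, cbind(`(Intercept)` = 1, x = x))
  # oracle: maximize the Bernoulli log-likelihood over a 2-parameter lattice
  bgrid <- seq(-3, 3, by = 0.01)
  best <- -Inf
  for (b0 in bgrid) {
    eta <- b0 + outer(x, bgrid)
    mu <- 1 / (1 + exp(-eta))
    ll <- colSums(y * log(mu) + (1 - y) * log(1 - mu))
    best <- max(best, max(ll))
  }
  expect_equal(fit$loglik, best, tolerance = 1e-3)
})

test_that("single-class responses are rejected", {
  expect_error(fit_logistic(rep(1, 20), matrix(1, 20, 1)), "single class")
})

test_that("Nagelkerke R2 transcribes its formula and stays in range", {
  expect_equal(nagelkerke_r2(-50, -50, 100), 0)
  # hand-evaluated: ll_null = -13.46, ll_full = -10.2, n = 20
  ll_null <- -13.46; ll_full <- -10.2; n <- 20
  manual <- (1 - exp(2 * (ll_null - ll_full) / n)) / (1 - exp(2 * ll_null / n))
  expect_equal(nagelkerke_r2(ll_full, ll_null, n), manual)
  set.seed(63)
  for (i in 1:20) {
    lln <- -runif(1, 10, 500)
    llf <- lln + runif(1, 0, 50)
    v <- nagelkerke_r2(llf, lln, 1000)
    expect_true(v >= 0 && v <= 1)
  }
  expect_error(nagelkerke_r2(-60, -50, 100), "loglik_full")
})

test_that("incremental R2 recovers exact and null relationships", {
  set.seed(64)
  s <- rnorm(5000)
  res_exact <- incremental_r2(s, s, NULL, "linear")
  expect_equal(res_exact$delta_r2, 1, tolerance = 1e-10)

  y_null <- rnorm(5000)
  res_null <- incremental_r2(y_null, s, NULL, "linear")
  expect_lt(res_null$delta_r2, 2e-3)
})

test_that("listwise deletion drops the same rows from both fits", {
  set.seed(65)
  n <- 500
  y <- rnorm(n); s <- rnorm(n)
  covs <- data.frame(a = rnorm(n), b = rnorm(n))
  y[1:10] <- NA; covs$a[11:20] <- NA; s[21:25] <- NA
  res <- incremental_r2(y, s, covs, "linear")
  expect_equal(res$n, n - 25)
})

test_that("scan best equals an exhaustive per-threshold refit oracle", {
  cfg <- small_config(seed = 66)
  coh <- simulate_cohort(cfg)
  w <- tibble::tibble(snp_id = coh$sumstats$SNP,
                      effect = log(coh$sumstats$OR), p = coh$sumstats$P)
  grid <- make_threshold_grid(0, 0.5, 0.02)
  sc <- compute_prs(coh$genotypes, w, grid)
  ph <- coh$phenotypes
  covs <- cov_cols(ph)
  scan <- high_res_scan(ph$trait_cont, sc, covs, "linear", "trait_cont")

  oracle <- vapply(which(sc$usable), function(k) {
    incremental_r2(ph$trait_cont, sc$scores[, k], covs, "linear")$delta_r2
  }, numeric(1))
  expect_equal(scan$scan$delta_r2, oracle, tolerance = 1e-10)
  best_k <- which(oracle == max(oracle))[1]
  expect_equal(scan$best$best_threshold, sc$thresholds[sc$usable][best_k])
  expect_equal(scan$best$delta_r2, max(oracle), tolerance = 1e-10)
})

test_that("logistic scans agree with per-threshold incremental refits", {
  cfg <- sim_config(n_snps = 100, block_size = 10, n_target = 600, seed = 67,
                    traits = tibble::tibble(name = "dx", type = "binary",
                                            r_g = 0.5, h2 = 0.3,
                                            prevalence = 0.3))
  coh <- simulate_cohort(cfg)
  w <- tibble::tibble(snp_id = coh$sumstats$SNP,
                      effect = log(coh$sumstats$OR), p = coh$sumstats$P)
  grid <- make_threshold_grid(0, 0.5, 0.1)
  sc <- compute_prs(coh$genotypes, w, grid)
  covs <- coh$phenotypes[, c("age", "sex")]
  scan <- high_res_scan(coh$phenotypes$dx, sc, covs, "logistic", "dx")
  k1 <- which(sc$usable)[1]
  direct <- incremental_r2(coh$phenotypes$dx, sc$scores[, k1], covs, "logistic")
  expect_equal(scan$scan$delta_r2[1], direct$delta_r2, tolerance = 1e-10)
})

test_that("single usable threshold is returned as the best", {
  set.seed(68)
  g <- manual_geno(matrix(rbinom(600, 2, 0.3), 200, 3))
  w <- tibble::tibble(snp_id = g$snps$snp_id, effect = c(0.1, 0.2, -0.1),
                      p = c(0.04, 0.04, 0.04))
  grid <- make_threshold_grid(0, 0.05, 0.05)
  sc <- compute_prs(g, w, grid)
  expect_equal(sum(sc$usable), 1)
  scan <- high_res_scan(rnorm(200), sc, NULL, "linear")
  expect_equal(scan$best$best_threshold, 0.05)
})

test_that("standardizing the score changes neither p-value nor delta R2", {
  set.seed(69)
  n <- 1000
  s <- rnorm(n, 5, 7)
  covs <- data.frame(a = rnorm(n))
  y <- 0.1 * scale(s)[, 1] + 0.2 * covs$a + rnorm(n)
  r1 <- incremental_r2(y, s, covs, "linear")
  r2 <- incremental_r2(y, (s - mean(s)) / sd(s), covs, "linear")
  expect_equal(r1$delta_r2, r2$delta_r2, tolerance = 1e-12)
  expect_equal(r1$p_prs, r2$p_prs, tolerance = 1e-12)
})

test_that("interaction test recovers a male-only PRS effect", {
  set.seed(70)
  n <- 20000
  s <- rnorm(n)
  sex <- rbinom(n, 1, 0.5)
  y <- 0.1 * s * (sex == 0) + rnorm(n)
  res <- interaction_test(y, s, sex, NULL, "linear")
  expect_lt(abs(res$beta_male - 0.1), 3 * res$se_male)
  expect_lt(abs(res$beta_female - 0), 3 * res$se_female)
  expect_lt(res$p_interaction, 0.001)
})

test_that("single-sex data is rejected", {
  expect_error(interaction_test(rnorm(50), rnorm(50), rep(1, 50), NULL, "linear"),
               "both sexes")
})

test_that("significance flags use strict inequality at the study thresholds", {
  res <- tibble::tibble(p = c(2.1e-4, 1e-5, 0.5, 2.0999e-4))
  out <- apply_significance(res)
  expect_equal(out$significant, c(FALSE, TRUE, FALSE, TRUE))
  res_i <- tibble::tibble(p_interaction = c(4.5e-4, 4.4e-4))
  out_i <- apply_significance(res_i)
  expect_equal(out_i$significant_interaction, c(FALSE, TRUE))
})

test_that("analytic power has the right boundary and monotonicity behavior", {
  expect_equal(analytic_power(0, 1000, 0.05), 0.05, tolerance = 1e-12)
  expect_equal(analytic_power(0.01, 1e7, 0.05), 1, tolerance = 1e-6)
  pw_n <- analytic_power(0.002, c(1000, 5000, 20000, 100000), 0.05)
  expect_true(all(diff(pw_n) > 0))
  pw_r <- analytic_power(c(0.001, 0.002, 0.005, 0.01), 5000, 0.05)
  expect_true(all(diff(pw_r) > 0))
  expect_error(analytic_power(1, 100, 0.05), "r2")
})
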