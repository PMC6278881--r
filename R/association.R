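#' Ordinary least squares fit on a design matrix
#'
#' Thin wrapper over [stats::lm.fit()] that drops collinear columns (logged in
#' the result), and reports coefficients with standard errors, R-squared and
#' the Gaussian log-likelihood.
#'
#' @param response Numeric response vector.
#' @param design Numeric design matrix including an intercept column.
#' @return List with `coefficients` (tibble: term, estimate, se, statistic,
#'   p), `r2`, `loglik`, `n`, `df_residual`, `dropped`.
#' @export
fit_linear <- function(response, design) {
  keep <- qr(design)$pivot[seq_len(qr(design)$rank)]
  dropped <- colnames(design)[setdiff(seq_len(ncol(design)), keep)]
  X <- design[, sort(keep), drop = FALSE]
  n <- length(response)
  if (n <= ncol(X)) abort("fit_linear: n <= number of parameters.")
  fit <- lm.fit(X, response)
  rss <- sum(fit$residuals^2)
  has_intercept <- any(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0))
  tss <- if (has_intercept) sum((response - mean(response))^2) else sum(response^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  df <- n - ncol(X)
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(pmax(diag(XtX_inv), 0) * sigma2)
  est <- fit$coefficients
  stat <- est / se
  list(
    coefficients = tibble::tibble(
      term = colnames(X), estimate = unname(est), se = se,
      statistic = unname(stat),
      p = 2 * stats::pt(-abs(stat), df)
    ),
    r2 = r2, rss = rss,
    loglik = -n / 2 * (log(2 * pi) + log(rss / n) + 1),
    n = n, df_residual = df, dropped = dropped
  )
}

#' Logistic regression fit on a design matrix
#'
#' Iteratively reweighted least squares via [stats::glm.fit()] with
#' convergence when the deviance change is below `1e-8` (up to 100
#' iterations). Non-convergence and quasi-separation (fitted probabilities
#' pinned at 0/1) are flagged, not silently returned.
#'
#' @param response 0/1 response with both classes present.
#' @param design Numeric design matrix including an intercept column.
#' @return List with `coefficients` (tibble: term, estimate, se, statistic,
#'   p from the Wald test), `loglik`, `loglik_null`, `n`, `converged`,
#'   `separation`, `dropped`.
#' @export
fit_logistic <- function(response, design) {
  if (length(unique(response[!is.na(response)])) < 2L) {
    abort("fit_logistic: response has a single class.")
  }
  keep <- qr(design)$pivot[seq_len(qr(design)$rank)]
  dropped <- colnames(design)[setdiff(seq_len(ncol(design)), keep)]
  X <- design[, sort(keep), drop = FALSE]
  n <- length(response)
  if (n <= ncol(X)) abort("fit_logistic: n <= number of parameters.")
  fit <- suppressWarnings(glm.fit(
    X, response, family = binomial(),
    control = glm.control(epsilon = 1e-8, maxit = 100)
  ))
  mu <- fit$fitted.values
  separation <- any(mu < 1e-10 | mu > 1 - 1e-10)
  if (!fit$converged) warn("fit_logistic: IRLS did not converge in 100 iterations.")
  if (separation) warn("fit_logistic: fitted probabilities at 0/1 (possible separation).")
  w <- mu * (1 - mu)
  XtWX <- crossprod(X * sqrt(w))
  vcov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  est <- fit$coefficients
  se <- sqrt(pmax(diag(vcov), 0))
  stat <- est / se
  pbar <- mean(response)
  list(
    coefficients = tibble::tibble(
      term = colnames(X), estimate = unname(est), se = se,
      statistic = unname(stat), p = 2 * pnorm(-abs(stat))
    ),
    loglik = sum(dbinom(response, 1, pmax(pmin(mu, 1 - 1e-15), 1e-15), log = TRUE)),
    loglik_null = sum(dbinom(response, 1, pbar, log = TRUE)),
    n = n, converged = fit$converged, separation = separation,
    dropped = dropped
  )
}

#' Nagelkerke pseudo R-squared from two log-likelihoods
#'
#' `(1 - exp(2 (ll_null - ll_full) / n)) / (1 - exp(2 ll_null / n))`: the
#' Cox-Snell ratio rescaled to a 0-1 range.
#'
#' @param loglik_full,loglik_null Log-likelihoods of the full and null model
#'   (`loglik_full >= loglik_null`).
#' @param n Sample size (> 0).
#' @return A proportion in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(loglik_full, loglik_null, n) {
  if (n <= 0) abort("`n` must be positive.")
  if (any(loglik_full < loglik_null - 1e-8)) {
    abort("`loglik_full` must be >= `loglik_null`.")
  }
  cs <- 1 - exp(2 * (loglik_null - loglik_full) / n)
  cs_max <- 1 - exp(2 * loglik_null / n)
  pmin(pmax(cs / cs_max, 0), 1)
}

#' Incremental variance explained by a polygenic score
#'
#' Fits the baseline (covariates-only) and full (covariates + standardized
#' PRS) models and reports the difference in variance explained: plain
#' R-squared for linear models, Nagelkerke pseudo R-squared for logistic.
#' Rows with any missing value are dropped listwise before both fits, and the
#' score is standardized to mean 0, SD 1 on the analysis subset.
#'
#' @param phenotype Response vector (continuous, or 0/1 for logistic).
#' @param score Raw PRS vector.
#' @param covariates Covariate data frame (may be `NULL`).
#' @param family `"linear"` or `"logistic"`.
#' @return One-row tibble: `family, n, r2_null, r2_full, delta_r2, beta_prs`
#'   (per SD of score), `se_prs, p_prs`.
#' @export
incremental_r2 <- function(phenotype, score, covariates = NULL,
                           family = c("linear", "logistic")) {
  family <- match.arg(family)
  n_in <- length(phenotype)
  cc <- !is.na(phenotype) & !is.na(score)
  if (!is.null(covariates)) cc <- cc & stats::complete.cases(covariates)
  y <- phenotype[cc]
  s <- standardize(score[cc])
  X0 <- build_design(if (is.null(covariates)) NULL else covariates[cc, , drop = FALSE],
                     n = sum(cc))
  X1 <- cbind(X0, PRS = s)
  if (family == "linear") {
    f0 <- fit_linear(y, X0); f1 <- fit_linear(y, X1)
    r2_null <- f0$r2; r2_full <- f1$r2
  } else {
    f0 <- fit_logistic(y, X0); f1 <- fit_logistic(y, X1)
    r2_null <- nagelkerke_r2(f0$loglik, f0$loglik_null, f0$n)
    r2_full <- nagelkerke_r2(f1$loglik, f1$loglik_null, f1$n)
  }
  prs_row <- f1$coefficients[f1$coefficients$term == "PRS", ]
  tibble::tibble(
    family = family, n = length(y),
    r2_null = r2_null, r2_full = r2_full,
    delta_r2 = max(0, r2_full - r2_null),
    beta_prs = prs_row$estimate, se_prs = prs_row$se, p_prs = prs_row$p
  )
}

#' High-resolution threshold scan
#'
#' Fits the incremental model at every usable threshold of a score matrix and
#' selects the threshold maximizing incremental R-squared (ties broken by the
#' smaller threshold, for parsimony). For linear models the scan uses exact
#' residualization against the baseline design (one QR decomposition, then
#' closed-form per-threshold OLS — algebraically identical to refitting the
#' full model at each threshold); logistic models are refit per threshold.
#'
#' @param phenotype Response vector aligned with the score matrix rows.
#' @param scores A `prs_scores` object.
#' @param covariates Covariate data frame (may be `NULL`).
#' @param family `"linear"` or `"logistic"`.
#' @param phenotype_name Label carried into the result.
#' @return Object of class `prs_scan`: list with `scan` (tibble: threshold,
#'   n_snps, delta_r2, beta, se, p), `best` (one-row AssociationResult
#'   tibble), `family`, `n`, `phenotype`.
#' @export
high_res_scan <- function(phenotype, scores, covariates = NULL,
                          family = c("linear", "logistic"),
                          phenotype_name = "phenotype") {
  family <- match.arg(family)
  usable <- which(scores$usable)
  if (length(usable) == 0) abort("no usable threshold in the score matrix.")
  cc <- !is.na(phenotype)
  if (!is.null(covariates)) cc <- cc & stats::complete.cases(covariates)
  y <- phenotype[cc]
  S <- scores$scores[cc, usable, drop = FALSE]
  X0 <- build_design(if (is.null(covariates)) NULL else covariates[cc, , drop = FALSE],
                     n = sum(cc))
  n <- length(y)
  thr <- scores$thresholds[usable]

  if (family == "linear") {
    keep <- qr(X0)$pivot[seq_len(qr(X0)$rank)]
    X0 <- X0[, sort(keep), drop = FALSE]
    qr0 <- qr(X0)
    ry <- qr.resid(qr0, y)
    Ssd <- apply(S, 2, stats::sd)
    Ssd[Ssd == 0] <- 1
    S_std <- scale(S, center = TRUE, scale = Ssd)
    RS <- qr.resid(qr0, S_std)
    ss <- colSums(RS^2)
    sy <- colSums(RS * ry)
    beta <- ifelse(ss > 0, sy / ss, 0)
    rss0 <- sum(ry^2)
    rss1 <- rss0 - beta^2 * ss
    tss <- sum((y - mean(y))^2)
    r2_null <- 1 - rss0 / tss
    r2_full <- 1 - rss1 / tss
    df <- n - ncol(X0) - 1L
    se <- sqrt(rss1 / df / ss)
    tstat <- beta / se
    pval <- 2 * stats::pt(-abs(tstat), df)
    scan <- tibble::tibble(
      threshold = thr, n_snps = scores$n_snps[usable],
      delta_r2 = pmax(0, r2_full - r2_null),
      beta = beta, se = se, p = pval
    )
  } else {
    rows <- purrr::map(seq_along(usable), function(k) {
      res <- incremental_r2(y, S[, k], covariates =
                              if (is.null(covariates)) NULL else covariates[cc, , drop = FALSE],
                            family = "logistic")
      tibble::tibble(threshold = thr[k], n_snps = scores$n_snps[usable[k]],
                     delta_r2 = res$delta_r2, beta = res$beta_prs,
                     se = res$se_prs, p = res$p_prs)
    })
    scan <- dplyr::bind_rows(rows)
  }

  best_i <- which(scan$delta_r2 == max(scan$delta_r2))[1]  # ties: smaller p_T
  best <- tibble::tibble(
    phenotype = phenotype_name, family = family,
    best_threshold = scan$threshold[best_i],
    delta_r2 = scan$delta_r2[best_i],
    delta_r2_pct = 100 * scan$delta_r2[best_i],
    beta_prs = scan$beta[best_i], se_prs = scan$se[best_i],
    p = scan$p[best_i], n_snps = scan$n_snps[best_i], n = n
  )
  structure(
    list(scan = scan, best = best, family = family, n = n,
         phenotype = phenotype_name),
    class = "prs_scan"
  )
}

#' @export
print.prs_scan <- function(x, ...) {
  cat(sprintf(
    "<prs_scan> %s (%s, n=%d): best p_T=%.3f, delta-R2=%.4f%%, p=%.3g (%d SNPs)\n",
    x$phenotype, x$family, x$n, x$best$best_threshold,
    x$best$delta_r2_pct, x$best$p, x$best$n_snps
  ))
  invisible(x)
}

#' PRS-by-sex interaction test
#'
#' Fits the full model `covariates + PRS + sex + PRS:sex` and reports the Wald
#' p-value of the product term, the main sex effect, and sex-stratified PRS
#' coefficients from separate fits within each sex (sex coded 0 = male,
#' 1 = female). A `sex` column inside `covariates` is ignored in favour of the
#' explicit argument.
#'
#' @param phenotype Response vector.
#' @param score Raw PRS vector (standardized internally).
#' @param sex 0/1 vector; both values must be present.
#' @param covariates Covariate data frame without the sex term (a `sex`
#'   column, if present, is dropped).
#' @param family `"linear"` or `"logistic"`.
#' @param phenotype_name Label carried into the result.
#' @return One-row tibble: stratified PRS effects (`beta_male`, `beta_female`
#'   with SEs and p), `beta_interaction`, `p_interaction`, `beta_sex`,
#'   `p_sex`, `n`.
#' @export
interaction_test <- function(phenotype, score, sex, covariates = NULL,
                             family = c("linear", "logistic"),
                             phenotype_name = "phenotype") {
  family <- match.arg(family)
  cc <- !is.na(phenotype) & !is.na(score) & !is.na(sex)
  if (!is.null(covariates)) {
    covariates <- covariates[, setdiff(names(covariates), "sex"), drop = FALSE]
    if (ncol(covariates) == 0) covariates <- NULL
    if (!is.null(covariates)) cc <- cc & stats::complete.cases(covariates)
  }
  y <- phenotype[cc]; s <- standardize(score[cc]); sx <- sex[cc]
  if (length(unique(sx)) < 2L) abort("both sexes must be present.")
  cov_cc <- if (is.null(covariates)) NULL else covariates[cc, , drop = FALSE]
  X0 <- build_design(cov_cc, n = length(y))
  X <- cbind(X0, PRS = s, sex = sx, `PRS:sex` = s * sx)
  fit_fun <- if (family == "linear") fit_linear else fit_logistic
  full <- fit_fun(y, X)
  get_row <- function(fit, term) fit$coefficients[fit$coefficients$term == term, ]

  strat <- purrr::map(c(male = 0, female = 1), function(v) {
    sel <- sx == v
    Xs <- cbind(build_design(if (is.null(cov_cc)) NULL else cov_cc[sel, , drop = FALSE],
                             n = sum(sel)),
                PRS = s[sel])
    get_row(fit_fun(y[sel], Xs), "PRS")
  })
  int_row <- get_row(full, "PRS:sex")
  sex_row <- get_row(full, "sex")
  tibble::tibble(
    phenotype = phenotype_name, family = family,
    beta_male = strat$male$estimate, se_male = strat$male$se,
    p_male = strat$male$p,
    beta_female = strat$female$estimate, se_female = strat$female$se,
    p_female = strat$female$p,
    beta_interaction = int_row$estimate, p_interaction = int_row$p,
    beta_sex = sex_row$estimate, p_sex = sex_row$p,
    n = length(y)
  )
}

#' Flag results against study-wide significance thresholds
#'
#' Strict-inequality flags: a main-effect p-value equal to the threshold is
#' not significant. Defaults correspond to Bonferroni-style control for
#' testing the most predictive PRS across many phenotypes (main effects) and
#' for the interaction screen.
#'
#' @param results Tibble with a `p` column (main results) and/or a
#'   `p_interaction` column (interaction results).
#' @param alpha_main Main-analysis threshold (default 2.1e-4).
#' @param alpha_interaction Interaction threshold (default 4.5e-4).
#' @return `results` with `significant` (and `significant_interaction` where
#'   applicable) logical columns appended.
#' @export
apply_significance <- function(results, alpha_main = 2.1e-4,
                               alpha_interaction = 4.5e-4) {
  if (nrow(results) == 0) abort("`results` is empty.")
  if ("p" %in% names(results)) {
    results$significant <- results$p < alpha_main
  }
  if ("p_interaction" %in% names(results)) {
    results$significant_interaction <- results$p_interaction < alpha_interaction
  }
  results
}

#' Analytic power of a 1-df PRS association test
#'
#' A non-centrality approximation: the Wald chi-square of the PRS term under
#' a true incremental R-squared `r2` at sample size `n` is approximately
#' non-central chi-square with 1 df and `ncp = n r2 / (1 - r2)`; power is the
#' probability it exceeds the central critical value at level `alpha`.
#'
#' @param r2 Assumed true incremental R-squared, in `[0, 1)`.
#' @param n Analysis sample size.
#' @param alpha Significance level.
#' @return Power in `[alpha, 1]`. Vectorized over all arguments.
#' @export
analytic_power <- function(r2, n, alpha = 2.1e-4) {
  if (any(r2 < 0 | r2 >= 1)) abort("`r2` must be in [0, 1).")
  if (any(n <= 0)) abort("`n` must be positive.")
  if (any(alpha <= 0 | alpha >= 1)) abort("`alpha` must be in (0, 1).")
  crit <- qchisq(alpha, df = 1, lower.tail = FALSE)
  pchisq(crit, df = 1, ncp = n * r2 / (1 - r2), lower.tail = FALSE)
}
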