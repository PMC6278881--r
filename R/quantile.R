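#' Assign samples to score quantiles
#'
#' Rank-based assignment into K groups of near-equal size (sizes differ by at
#' most one; when n is not a multiple of K the lowest-index quantiles absorb
#' the remainder). Ties are broken by stable original order, so the
#' assignment depends on score ranks only.
#'
#' @param score Numeric score vector (`n >= K`).
#' @param K Number of quantiles (>= 2), default 20 (5% quantiles).
#' @return Integer vector of quantile indices `1..K`.
#' @export
assign_quantiles <- function(score, K = 20) {
  K <- assert_count(K, "K", min = 2L)
  n <- length(score)
  if (n < K) abort("need at least K observations.")
  r <- rank(score, ties.method = "first")
  base <- n %/% K
  rem <- n %% K
  sizes <- base + (seq_len(K) <= rem)
  findInterval(r, cumsum(sizes), left.open = TRUE) + 1L
}

#' Quantile-effect curve of a polygenic score
#'
#' For each non-reference quantile q, fits a regression of the phenotype on a
#' 0/1 indicator (1 = quantile q, 0 = reference quantile) restricted to the
#' samples of the two quantiles, with the full covariate set. Binary
#' phenotypes use logistic regression and report odds ratios. The reference
#' quantile is emitted as an exact-zero (OR 1) point.
#'
#' @param phenotype Response vector.
#' @param score Raw PRS vector.
#' @param covariates Covariate data frame (may be `NULL`).
#' @param K Number of quantiles, default 20.
#' @param reference Reference quantile index; defaults to `K/2` for even K
#'   (the lower-middle quantile), `(K+1)/2` for odd K.
#' @param family `"linear"` or `"logistic"`.
#' @param conf_level Confidence level for normal-approximation intervals on
#'   the link scale (exponentiated for odds ratios).
#' @param phenotype_name Label carried into the result.
#' @return Tibble of class `quantile_effects`: `phenotype, quantile, n,
#'   estimate, se, conf_low, conf_high` (+ `or, or_low, or_high` for
#'   logistic), `reference` flag. Quantiles whose subset cannot be fit (e.g. a
#'   single-class binary subset) appear with `NA` estimates.
#' @export
quantile_effect_curve <- function(phenotype, score, covariates = NULL,
                                  K = 20, reference = NULL,
                                  family = c("linear", "logistic"),
                                  conf_level = 0.95,
                                  phenotype_name = "phenotype") {
  family <- match.arg(family)
  K <- assert_count(K, "K", min = 2L)
  reference <- reference %||% (if (K %% 2 == 0) K %/% 2 else (K + 1) %/% 2)
  reference <- assert_count(reference, "reference")
  if (reference > K) abort("`reference` must be <= K.")
  cc <- !is.na(phenotype) & !is.na(score)
  if (!is.null(covariates)) cc <- cc & stats::complete.cases(covariates)
  y <- phenotype[cc]; s <- score[cc]
  cov_cc <- if (is.null(covariates)) NULL else covariates[cc, , drop = FALSE]
  q <- assign_quantiles(s, K)
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  fit_fun <- if (family == "linear") fit_linear else fit_logistic

  rows <- purrr::map(seq_len(K), function(k) {
    n_k <- sum(q == k)
    if (k == reference) {
      return(tibble::tibble(quantile = k, n = n_k, estimate = 0, se = NA_real_,
                            conf_low = NA_real_, conf_high = NA_real_,
                            reference = TRUE))
    }
    sel <- q %in% c(k, reference)
    ind <- as.numeric(q[sel] == k)
    fit <- tryCatch({
      Xs <- cbind(
        build_design(if (is.null(cov_cc)) NULL else cov_cc[sel, , drop = FALSE],
                     n = sum(sel)),
        quantile_ind = ind
      )
      fit_fun(y[sel], Xs)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(quantile = k, n = n_k, estimate = NA_real_,
                            se = NA_real_, conf_low = NA_real_,
                            conf_high = NA_real_, reference = FALSE))
    }
    row <- fit$coefficients[fit$coefficients$term == "quantile_ind", ]
    tibble::tibble(
      quantile = k, n = n_k, estimate = row$estimate, se = row$se,
      conf_low = row$estimate - zcrit * row$se,
      conf_high = row$estimate + zcrit * row$se,
      reference = FALSE
    )
  })
  out <- dplyr::bind_cols(
    tibble::tibble(phenotype = phenotype_name),
    dplyr::bind_rows(rows)
  )
  if (family == "logistic") {
    out$or <- exp(out$estimate)
    out$or_low <- exp(out$conf_low)
    out$or_high <- exp(out$conf_high)
  }
  attr(out, "K") <- K
  attr(out, "reference") <- reference
  attr(out, "family") <- family
  class(out) <- c("quantile_effects", class(out))
  out
}
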