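#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble as_tibble
#' @importFrom stats pnorm qnorm pchisq qchisq rnorm runif rbinom sd cor
#'   lm.fit glm.fit binomial glm.control dbinom complete.cases
NULL

# round half away from zero (printed tables use half-up, not banker's rounding)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# z-score a numeric vector; constant input is left centred at zero
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).", name,
      if (open_lower) "(" else "[", format(lower),
      format(upper), if (open_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}

#' Build a regression design matrix from a covariate table
#'
#' Numeric covariates enter as-is; character or factor columns (for example a
#' genotyping-batch label) are one-hot encoded with the first level as the
#' reference. An intercept column is always prepended. Identifier columns
#' (`fid`, `iid`) are dropped if present.
#'
#' @param covariates A data frame of covariates, or `NULL` for an
#'   intercept-only design.
#' @param n Number of rows when `covariates` is `NULL`.
#' @return A numeric matrix with an `(Intercept)` column.
#' @export
build_design <- function(covariates = NULL, n = NULL) {
  if (is.null(covariates)) {
    if (is.null(n)) abort("`n` is required when `covariates` is NULL.")
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  covariates <- as.data.frame(covariates)
  covariates <- covariates[, setdiff(names(covariates), c("fid", "iid")), drop = FALSE]
  if (ncol(covariates) == 0L) return(build_design(NULL, n = nrow(covariates)))
  for (j in names(covariates)) {
    if (is.character(covariates[[j]]) || is.logical(covariates[[j]])) {
      covariates[[j]] <- factor(covariates[[j]])
    }
  }
  X <- stats::model.matrix(~ ., data = covariates)
  storage.mode(X) <- "double"
  X
}

# complement map for strand flips
ALLELE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) {
  unname(ALLELE_COMPLEMENT[a1] == a2)
}
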