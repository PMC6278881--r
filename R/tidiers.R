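#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-threshold scan of a fitted PRS association
#' @param x A `prs_scan`.
#' @param ... Unused.
#' @return Tibble with one row per scanned threshold: `threshold, n_snps,
#'   delta_r2, beta, se, p`.
#' @export
tidy.prs_scan <- function(x, ...) {
  dplyr::mutate(x$scan, phenotype = x$phenotype, .before = 1)
}

#' One-row summary of a PRS threshold scan (the best-fitting model)
#' @param x A `prs_scan`.
#' @param ... Unused.
#' @return One-row tibble: phenotype, family, best threshold, incremental
#'   R-squared (proportion and percent), PRS coefficient per SD, p, SNP and
#'   sample counts.
#' @export
glance.prs_scan <- function(x, ...) {
  x$best
}

#' Tidy a quantile-effect curve
#' @param x A `quantile_effects` object.
#' @param ... Unused.
#' @return The underlying tibble (one row per quantile).
#' @export
tidy.quantile_effects <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "quantile_effects")
  out
}

#' One-row summary of a quantile-effect curve
#' @param x A `quantile_effects` object.
#' @param ... Unused.
#' @return One-row tibble: K, reference quantile, family, fitted points.
#' @export
glance.quantile_effects <- function(x, ...) {
  tibble::tibble(
    phenotype = x$phenotype[1],
    K = attr(x, "K"), reference = attr(x, "reference"),
    family = attr(x, "family"),
    n_points_fit = sum(!is.na(x$estimate) & !x$reference)
  )
}

#' Tidy a QC report (per-filter removal counts)
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return Tibble: filter, threshold, n_removed.
#' @export
tidy.qc_report <- function(x, ...) {
  dplyr::mutate(x$filters, level = x$level, .before = 1)
}

#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    level = x$level,
    n_input = length(x$surviving) + nrow(x$removed),
    n_removed = nrow(x$removed),
    n_surviving = length(x$surviving)
  )
}
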