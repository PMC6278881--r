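#' Cohort descriptive summary
#'
#' Per-phenotype descriptives in the style of a cohort table: case counts and
#' percentages (two decimals, rounded half-up) for binary phenotypes, mean and
#' SD for continuous ones. Missing values are excluded per phenotype, so each
#' row carries its own assessed n.
#'
#' @param phenotypes Phenotype table (tibble); identifier and covariate
#'   columns are ignored.
#' @param traits Character vector of phenotype columns to summarise. Defaults
#'   to the `traits` attribute a simulated table carries, else every column
#'   not in the standard id/covariate set.
#' @return Tibble of class `cohort_summary`: `phenotype, type, n_assessed,
#'   cases, pct, mean, sd`.
#' @export
cohort_summary <- function(phenotypes, traits = NULL) {
  if (is.null(traits)) {
    tr_attr <- attr(phenotypes, "traits")
    traits <- if (!is.null(tr_attr)) {
      tr_attr$name
    } else {
      std <- c("fid", "iid", "age", "sex", "birth_lat", "birth_lon", "batch")
      setdiff(names(phenotypes)[!grepl("^pc[0-9]+$", names(phenotypes))], std)
    }
  }
  missing_tr <- setdiff(traits, names(phenotypes))
  if (length(missing_tr) > 0) {
    abort(paste0("phenotype column(s) not found: ", paste(missing_tr, collapse = ", ")))
  }
  rows <- purrr::map(traits, function(tr) {
    x <- phenotypes[[tr]]
    x <- x[!is.na(x)]
    n <- length(x)
    binary <- all(x %in% c(0, 1))
    if (binary) {
      cases <- sum(x == 1)
      tibble::tibble(
        phenotype = tr, type = "binary", n_assessed = n,
        cases = cases,
        pct = if (n > 0) round_half_up(100 * cases / n, 2) else NA_real_,
        mean = NA_real_, sd = NA_real_
      )
    } else {
      tibble::tibble(
        phenotype = tr, type = "continuous", n_assessed = n,
        cases = NA_integer_, pct = NA_real_,
        mean = mean(x), sd = stats::sd(x)
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Render a cohort summary as plain text
#' @param summary A [cohort_summary()].
#' @return Character vector of lines (invisibly printed).
#' @export
format_cohort_summary <- function(summary) {
  lines <- c("Phenotype                     Value              Total n")
  for (i in seq_len(nrow(summary))) {
    r <- summary[i, ]
    val <- if (r$type == "binary") {
      sprintf("%d (%.2f%%)", r$cases, r$pct)
    } else {
      sprintf("%.2f +/- %.2f", round_half_up(r$mean, 2), round_half_up(r$sd, 2))
    }
    lines <- c(lines, sprintf("%-29s %-18s %s", r$phenotype, val,
                              format(r$n_assessed, big.mark = ",")))
  }
  lines
}

#' Ordered association results table
#'
#' Binds the best-threshold rows of one or more scans, sorts ascending by
#' p-value, and applies the study-wide significance flag — the layout of a
#' "prediction of PRS on target phenotypes" table: phenotype, p, best p_T,
#' incremental R-squared in percent, number of SNPs.
#'
#' @param results List of `prs_scan` objects, or a tibble of their `best`
#'   rows.
#' @param alpha_main Significance threshold passed to
#'   [apply_significance()].
#' @return Tibble sorted by `p` with a `significant` column.
#' @export
results_table <- function(results, alpha_main = 2.1e-4) {
  tbl <- if (inherits(results, "data.frame")) {
    tibble::as_tibble(results)
  } else {
    dplyr::bind_rows(purrr::map(results, function(r) {
      if (inherits(r, "prs_scan")) r$best else tibble::as_tibble(r)
    }))
  }
  if (nrow(tbl) == 0) abort("`results` is empty.")
  tbl <- dplyr::arrange(tbl, .data$p)
  apply_significance(tbl, alpha_main = alpha_main)
}

#' Run provenance block
#'
#' A record of what produced a set of results: configuration hash, seed,
#' package and R versions, and the analysis thresholds in force.
#'
#' @param config Optional configuration object (hashed with [rlang::hash()]).
#' @param seed Seed used for the run.
#' @param thresholds Optional named list of analysis thresholds.
#' @return One-row tibble.
#' @export
provenance <- function(config = NULL, seed = NA_integer_, thresholds = NULL) {
  tibble::tibble(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("prsct")),
    r_version = as.character(getRversion()),
    seed = as.integer(seed),
    config_hash = if (is.null(config)) NA_character_ else rlang::hash(config),
    thresholds = if (is.null(thresholds)) NA_character_ else
      paste(names(thresholds), unlist(thresholds), sep = "=", collapse = ";")
  )
}
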