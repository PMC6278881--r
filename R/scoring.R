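#' High-resolution p-value threshold grid
#'
#' An arithmetic sequence of inclusion thresholds computed in integer steps
#' (`threshold = k * step`) so that 501 grid points accumulate no floating
#' drift. The default grid, 0 to 0.5 in increments of 0.001, is the standard
#' high-resolution scoring grid. The lower endpoint `p_T = 0` formally
#' includes no SNPs (p-values are strictly positive); it stays in the grid but
#' is flagged unusable for model scans.
#'
#' @param lower,upper Grid endpoints in `[0, 1]`, `lower < upper`.
#' @param step Positive increment.
#' @return Tibble of class `threshold_grid` with column `threshold`, plus
#'   attributes `lower`, `upper`, `step`.
#' @export
make_threshold_grid <- function(lower = 0, upper = 0.5, step = 0.001) {
  assert_scalar_num(lower, "lower", 0, 1)
  assert_scalar_num(upper, "upper", 0, 1)
  if (step <= 0) abort("`step` must be positive.")
  if (lower >= upper) abort("empty threshold range: `lower` must be < `upper`.")
  k0 <- round(lower / step)
  if (abs(k0 * step - lower) > 1e-12) abort("`lower` must be a multiple of `step`.")
  k1 <- floor(upper / step + 1e-9)
  out <- tibble::tibble(threshold = (k0:k1) * step)
  attr(out, "lower") <- lower
  attr(out, "upper") <- upper
  attr(out, "step") <- step
  class(out) <- c("threshold_grid", class(out))
  out
}

#' Greedy LD clumping
#'
#' SNPs are processed in ascending p-value order (ties broken by chromosome,
#' then position, then id). Each SNP not already removed becomes an index SNP;
#' every unprocessed SNP on the same chromosome within `window_kb` whose
#' squared dosage correlation with the index reaches `r2_threshold` is
#' removed. LD is the squared Pearson correlation of dosages in the target
#' panel, with pairwise-complete handling of missing genotypes.
#'
#' @param records Harmonized records with `snp_id, chr, bp, p` (e.g.
#'   [harmonized_weights()] output).
#' @param geno Target `geno_matrix` containing every SNP in `records`.
#' @param r2_threshold Squared-correlation threshold in `(0, 1]`, default 0.1.
#' @param window_kb Physical window in kilobases, default 250.
#' @return Character vector of index SNP ids in genomic order.
#' @export
ld_clump <- function(records, geno, r2_threshold = 0.1, window_kb = 250) {
  assert_scalar_num(r2_threshold, "r2_threshold", 0, 1, open_lower = TRUE)
  assert_scalar_num(window_kb, "window_kb", 0, Inf, open_lower = TRUE)
  missing_snps <- setdiff(records$snp_id, geno$snps$snp_id)
  if (length(missing_snps) > 0) {
    abort(sprintf("SNP(s) absent from genotypes (harmonize first): %s ...",
                  missing_snps[1]))
  }
  ord <- order(records$p, records$chr, records$bp, records$snp_id)
  rec <- records[ord, ]
  X <- geno$dosage[, rec$snp_id, drop = FALSE]
  storage.mode(X) <- "double"
  window_bp <- window_kb * 1000
  m <- nrow(rec)
  removed <- rep(FALSE, m)
  is_index <- rep(FALSE, m)
  for (i in seq_len(m)) {
    if (removed[i]) next
    is_index[i] <- TRUE
    if (i == m) break
    later <- (i + 1):m
    cand <- later[!removed[later] &
                    rec$chr[later] == rec$chr[i] &
                    abs(rec$bp[later] - rec$bp[i]) <= window_bp]
    if (length(cand) == 0) next
    r <- suppressWarnings(
      cor(X[, i], X[, cand, drop = FALSE], use = "pairwise.complete.obs")
    )
    r[is.na(r)] <- 0
    removed[cand[r^2 >= r2_threshold]] <- TRUE
  }
  idx <- rec[is_index, ]
  idx$snp_id[order(idx$chr, idx$bp, idx$snp_id)]
}

#' Compute polygenic scores across a threshold grid
#'
#' The score of sample i at threshold `p_T` is the sum over SNPs with
#' `p <= p_T` of `effect * dosage` (the raw weighted sum; downstream
#' association standardizes scores, so the convention does not affect p-values
#' or incremental R-squared). Missing dosages are imputed as twice the
#' in-sample effect-allele frequency. Scores are accumulated in one pass per
#' SNP over the sorted grid, so SNP sets are nested across thresholds by
#' construction.
#'
#' @param geno Target `geno_matrix` (QC'd).
#' @param weights Tibble with `snp_id, effect, p` restricted to clumped index
#'   SNPs.
#' @param grid A [make_threshold_grid()].
#' @return Object of class `prs_scores`: list with `scores` (samples x
#'   thresholds matrix), `thresholds`, `n_snps` (per-threshold included-SNP
#'   counts), `usable` (thresholds with at least one SNP and `p_T > 0`),
#'   `samples`, and `weight_convention`.
#' @export
compute_prs <- function(geno, weights, grid) {
  missing_snps <- setdiff(weights$snp_id, geno$snps$snp_id)
  if (length(missing_snps) > 0) {
    abort(sprintf("weight for SNP(s) not in genotypes: %s ...", missing_snps[1]))
  }
  if (any(!is.finite(weights$effect))) abort("non-finite effect weights.")
  thr <- grid$threshold
  K <- length(thr)
  X <- geno$dosage[, weights$snp_id, drop = FALSE]
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    f <- colMeans(X, na.rm = TRUE) / 2
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- 2 * f[na_idx[, 2]]
  }
  # first grid index at which each SNP qualifies (p <= threshold; a tiny
  # tolerance absorbs binary representation error of grid points, but the
  # zero threshold stays empty because p-values are strictly positive)
  eff_thr <- ifelse(thr > 0, thr + 1e-12, thr)
  first_bin <- vapply(weights$p, function(p) {
    k <- which(p <= eff_thr)
    if (length(k) > 0) k[1] else K + 1L
  }, integer(1))

  n <- nrow(X)
  scores <- matrix(0, n, K)
  running <- numeric(n)
  counts <- integer(K)
  by_bin <- split(seq_len(nrow(weights)), factor(first_bin, levels = seq_len(K + 1L)))
  n_run <- 0L
  for (k in seq_len(K)) {
    sel <- by_bin[[k]]
    if (length(sel) > 0) {
      running <- running + drop(X[, sel, drop = FALSE] %*% weights$effect[sel])
      n_run <- n_run + length(sel)
    }
    scores[, k] <- running
    counts[k] <- n_run
  }
  dimnames(scores) <- list(geno$samples$iid, sprintf("%.3f", thr))
  structure(
    list(
      scores = scores, thresholds = thr, n_snps = counts,
      usable = counts > 0 & thr > 0,
      samples = geno$samples,
      weight_convention = "sum(dosage x effect)"
    ),
    class = "prs_scores"
  )
}

#' @export
print.prs_scores <- function(x, ...) {
  cat(sprintf(
    "<prs_scores> %d samples x %d thresholds [%g..%g], %d usable; SNPs at top threshold: %d\n",
    nrow(x$scores), length(x$thresholds), min(x$thresholds),
    max(x$thresholds), sum(x$usable), max(x$n_snps)
  ))
  invisible(x)
}

#' @export
as_tibble.prs_scores <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(FID = x$samples$fid, IID = x$samples$iid),
    tibble::as_tibble(x$scores)
  )
}

#' Write a score matrix as TSV (FID, IID, one column per threshold)
#' @param scores A `prs_scores`.
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  readr::write_tsv(as_tibble.prs_scores(scores), path)
  invisible(path)
}
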