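#' Quality-control thresholds
#'
#' Defaults follow common GWAS target-panel practice: drop SNPs with minor
#' allele frequency below 0.01, Hardy-Weinberg exact p below 1e-8, or
#' missingness above 0.02; drop samples with missingness above 0.01 or a
#' pairwise relatedness coefficient above 0.088 (which flags pairs at or above
#' roughly third-degree relatedness on the r-scale where a parent-offspring
#' pair is 0.5).
#'
#' @param maf_min Minimum minor allele frequency.
#' @param hwe_p_min Minimum Hardy-Weinberg exact-test p-value.
#' @param snp_missing_max Maximum per-SNP missingness fraction.
#' @param sample_missing_max Maximum per-sample missingness fraction.
#' @param kinship_max Maximum pairwise relatedness coefficient.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, hwe_p_min = 1e-8,
                          snp_missing_max = 0.02, sample_missing_max = 0.01,
                          kinship_max = 0.088) {
  for (nm in c("maf_min", "hwe_p_min", "snp_missing_max",
               "sample_missing_max", "kinship_max")) {
    assert_scalar_num(get(nm), nm, 0, 1)
  }
  structure(
    list(maf_min = maf_min, hwe_p_min = hwe_p_min,
         snp_missing_max = snp_missing_max,
         sample_missing_max = sample_missing_max, kinship_max = kinship_max),
    class = "qc_thresholds"
  )
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test of the heterozygote count conditional on the allele
#' counts: the p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count (the
#' plain exact sum, not the mid-p variant). Monomorphic genotype counts return
#' 1. All three arguments are vectorized.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total > 0).
#' @return Exact p-value(s) in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  k <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(n_AA, k); n_Aa <- rep_len(n_Aa, k); n_aa <- rep_len(n_aa, k)
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0, na.rm = TRUE)) {
    abort("genotype counts must be non-negative.")
  }
  if (any(n_AA + n_Aa + n_aa <= 0)) abort("total genotype count must be > 0.")
  vapply(seq_len(k), function(i) {
    hwe_exact_one(n_AA[i], n_Aa[i], n_aa[i])
  }, numeric(1))
}

hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1.0)
  n <- n_AA + n_Aa + n_aa
  n_rare <- min(nA, na)
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- hets * log(2) +
    lfactorial(n) + lfactorial(nA) + lfactorial(na) -
    lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2) - lfactorial(2 * n)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_Aa, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

# per-SNP genotype counts and summaries
snp_stats <- function(geno) {
  d <- geno$dosage
  n_obs <- colSums(!is.na(d))
  n2 <- colSums(d == 2L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n0 <- colSums(d == 0L, na.rm = TRUE)
  f <- (2 * n2 + n1) / (2 * pmax(n_obs, 1L))
  tibble::tibble(
    snp_id = geno$snps$snp_id,
    n_obs = n_obs, n_hom_a1 = n2, n_het = n1, n_hom_a2 = n0,
    freq_a1 = f, maf = pmin(f, 1 - f),
    missing_rate = 1 - n_obs / nrow(d)
  )
}

#' SNP-level quality control
#'
#' Applies, in order, the minor-allele-frequency, Hardy-Weinberg and
#' missingness filters of `thresholds`, logging the number of SNPs each filter
#' removes from the survivors of the previous one.
#'
#' @param geno A `geno_matrix`.
#' @param thresholds A [qc_thresholds()].
#' @return A list of class `qc_report` with `filters` (tibble of per-filter
#'   removal counts), `surviving` (SNP ids), `removed` (tibble snp_id, filter),
#'   and `stats` (per-SNP summaries).
#' @export
snp_qc <- function(geno, thresholds = qc_thresholds()) {
  if (ncol(geno$dosage) == 0L) abort("genotype matrix has no SNPs.")
  st <- snp_stats(geno)
  alive <- rep(TRUE, nrow(st))
  removed <- character(0); removed_by <- character(0)

  drop_filter <- function(fail, label) {
    idx <- which(alive & fail)
    alive[idx] <<- FALSE
    removed <<- c(removed, st$snp_id[idx])
    removed_by <<- c(removed_by, rep(label, length(idx)))
    length(idx)
  }
  n_maf <- drop_filter(st$maf < thresholds$maf_min, "maf")
  hwe_p <- rep(NA_real_, nrow(st))
  if (any(alive)) {
    hwe_p[alive] <- hwe_exact_test(st$n_hom_a1[alive], st$n_het[alive],
                                   st$n_hom_a2[alive])
  }
  n_hwe <- drop_filter(!is.na(hwe_p) & hwe_p < thresholds$hwe_p_min, "hwe")
  n_miss <- drop_filter(st$missing_rate > thresholds$snp_missing_max, "missingness")

  surviving <- st$snp_id[alive]
  if (length(surviving) == 0L) warn("SNP QC removed every SNP.")
  structure(
    list(
      level = "snp",
      filters = tibble::tibble(
        filter = c("maf", "hwe", "missingness"),
        threshold = c(thresholds$maf_min, thresholds$hwe_p_min,
                      thresholds$snp_missing_max),
        n_removed = c(n_maf, n_hwe, n_miss)
      ),
      surviving = surviving,
      removed = tibble::tibble(snp_id = removed, filter = removed_by),
      stats = dplyr::mutate(st, hwe_p = hwe_p)
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report: %s level>\n", x$level))
  print(x$filters)
  cat(sprintf("surviving: %d\n", length(x$surviving)))
  invisible(x)
}

#' Method-of-moments kinship estimation
#'
#' The standardized estimator: the mean over SNPs of
#' `(x_i - 2f)(x_j - 2f) / (2f(1 - f))` with `f` the in-sample effect-allele
#' frequency; missing dosages are excluded pairwise. On this r-scale a
#' duplicate pair is near 1 and a parent-offspring pair near 0.5.
#'
#' @param geno A `geno_matrix` with at least two samples and no monomorphic
#'   SNPs (run [snp_qc()] first).
#' @param thin_step Use every `thin_step`-th SNP (speed knob; 1 = all SNPs).
#' @return Symmetric n x n matrix with sample iids as dimnames.
#' @export
estimate_kinship <- function(geno, thin_step = 1L) {
  if (nrow(geno$dosage) < 2L) abort("kinship needs at least 2 samples.")
  thin_step <- assert_count(thin_step, "thin_step")
  d <- geno$dosage[, seq(1L, ncol(geno$dosage), by = thin_step), drop = FALSE]
  f <- colMeans(d, na.rm = TRUE) / 2
  if (any(f <= 0 | f >= 1)) {
    abort("monomorphic SNPs present; apply SNP QC before kinship estimation.")
  }
  Z <- sweep(d, 2, 2 * f, "-")
  Z <- sweep(Z, 2, sqrt(2 * f * (1 - f)), "/")
  obs <- !is.na(Z)
  Z[!obs] <- 0
  M <- tcrossprod(obs * 1)
  K <- tcrossprod(Z) / pmax(M, 1)
  dimnames(K) <- list(geno$samples$iid, geno$samples$iid)
  K
}

#' Greedy relatedness pruning
#'
#' While any pair exceeds `kinship_max`, removes the individual involved in
#' the most such pairs; ties are broken by lower call rate, then by larger
#' sample index. The survivors contain no pair above the threshold, and the
#' result is deterministic.
#'
#' @param kinship Square symmetric relatedness matrix with id dimnames.
#' @param kinship_max Relatedness threshold (strictly-exceeds rule).
#' @param call_rates Optional per-sample genotype call rates (same order as
#'   `kinship`); defaults to 1 for all samples.
#' @return Character vector of surviving sample ids.
#' @export
prune_related <- function(kinship, kinship_max = 0.088, call_rates = NULL) {
  if (!is.matrix(kinship) || nrow(kinship) != ncol(kinship)) {
    abort("`kinship` must be a square matrix.")
  }
  n <- nrow(kinship)
  ids <- rownames(kinship) %||% as.character(seq_len(n))
  call_rates <- call_rates %||% rep(1, n)
  A <- kinship > kinship_max
  diag(A) <- FALSE
  alive <- rep(TRUE, n)
  repeat {
    deg <- rowSums(A[, alive, drop = FALSE]) * alive
    if (max(deg) == 0) break
    cand <- which(deg == max(deg))
    cand <- cand[call_rates[cand] == min(call_rates[cand])]
    drop <- max(cand)
    alive[drop] <- FALSE
    A[drop, ] <- FALSE
    A[, drop] <- FALSE
  }
  ids[alive]
}

#' Sample-level quality control
#'
#' Applies, in order: the per-sample missingness filter, relatedness pruning
#' on the kinship estimate, and an external exclusion list (the hook used for
#' checks that need data outside the panel, such as reported-sex mismatch or
#' ancestry outliers).
#'
#' @param geno A `geno_matrix` (SNP-QC'd for the kinship step).
#' @param thresholds A [qc_thresholds()].
#' @param kinship Optional precomputed kinship matrix; computed from `geno`
#'   when `NULL`.
#' @param exclude Character vector of sample iids to drop unconditionally.
#' @return A `qc_report` for the sample level.
#' @export
sample_qc <- function(geno, thresholds = qc_thresholds(), kinship = NULL,
                      exclude = character(0)) {
  d <- geno$dosage
  miss <- rowMeans(is.na(d))
  call_rates <- 1 - miss
  alive <- miss <= thresholds$sample_missing_max
  n_miss <- sum(!alive)
  removed <- geno$samples$iid[!alive]
  removed_by <- rep("missingness", n_miss)

  g_alive <- subset_geno(geno, samples = geno$samples$iid[alive])
  if (nrow(g_alive$dosage) < 2L) {
    keep_rel <- g_alive$samples$iid
  } else if (is.null(kinship)) {
    keep_rel <- prune_related(estimate_kinship(g_alive), thresholds$kinship_max,
                              call_rates = call_rates[alive])
  } else {
    keep_rel <- prune_related(
      kinship[g_alive$samples$iid, g_alive$samples$iid, drop = FALSE],
      thresholds$kinship_max, call_rates = call_rates[alive]
    )
  }
  rel_removed <- setdiff(g_alive$samples$iid, keep_rel)
  removed <- c(removed, rel_removed)
  removed_by <- c(removed_by, rep("relatedness", length(rel_removed)))

  excl_removed <- intersect(keep_rel, exclude)
  surviving <- setdiff(keep_rel, exclude)
  removed <- c(removed, excl_removed)
  removed_by <- c(removed_by, rep("external_exclusion", length(excl_removed)))

  structure(
    list(
      level = "sample",
      filters = tibble::tibble(
        filter = c("missingness", "relatedness", "external_exclusion"),
        threshold = c(thresholds$sample_missing_max, thresholds$kinship_max, NA),
        n_removed = c(n_miss, length(rel_removed), length(excl_removed))
      ),
      surviving = surviving,
      removed = tibble::tibble(sample_id = removed, filter = removed_by),
      stats = tibble::tibble(iid = geno$samples$iid, missing_rate = miss)
    ),
    class = "qc_report"
  )
}

#' Full QC pass over a genotype panel
#' @inheritParams sample_qc
#' @return List with `genotypes` (the filtered panel), `snp_report`,
#'   `sample_report`.
#' @export
run_qc <- function(geno, thresholds = qc_thresholds(), exclude = character(0)) {
  snp_rep <- snp_qc(geno, thresholds)
  g <- subset_geno(geno, snps = snp_rep$surviving)
  sample_rep <- sample_qc(g, thresholds, exclude = exclude)
  list(
    genotypes = subset_geno(g, samples = sample_rep$surviving),
    snp_report = snp_rep,
    sample_report = sample_rep
  )
}
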