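#' Read GWAS summary statistics
#'
#' Accepts a whitespace- or tab-delimited file with a header containing
#' `SNP CHR BP A1 A2 P` and either `OR` (converted to `log(OR)`) or `BETA`.
#' When both effect columns are present `OR` takes precedence with a warning.
#' Rows with `p <= 0`, `p > 1`, non-ACGT alleles, identical alleles, or a
#' non-positive odds ratio are rejected and counted.
#'
#' @param path Path to the summary statistics file.
#' @return Tibble with columns `snp_id, chr, bp, a1, a2, effect, p`; the
#'   number of rejected rows (with per-reason counts) is attached as
#'   attributes `n_rejected` and `rejected_reasons`.
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_table(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  names(raw) <- toupper(names(raw))
  needed <- c("SNP", "CHR", "BP", "A1", "A2", "P")
  missing_cols <- setdiff(needed, names(raw))
  has_or <- "OR" %in% names(raw)
  has_beta <- "BETA" %in% names(raw)
  if (!has_or && !has_beta) missing_cols <- c(missing_cols, "OR (or BETA)")
  if (length(missing_cols) > 0) {
    abort(paste0("summary statistics file is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (has_or && has_beta) {
    warn("both OR and BETA present; using OR.")
  }

  p <- suppressWarnings(as.numeric(raw$P))
  a1 <- toupper(raw$A1); a2 <- toupper(raw$A2)
  if (has_or) {
    or <- suppressWarnings(as.numeric(raw$OR))
    effect <- suppressWarnings(log(or))  # invalid ORs are rejected below
    bad_effect <- is.na(or) | or <= 0
  } else {
    effect <- suppressWarnings(as.numeric(raw$BETA))
    bad_effect <- !is.finite(effect)
  }
  acgt <- c("A", "C", "G", "T")
  reasons <- dplyr::case_when(
    is.na(p) | p <= 0 | p > 1 ~ "invalid_p",
    !(a1 %in% acgt) | !(a2 %in% acgt) ~ "non_acgt_allele",
    a1 == a2 ~ "identical_alleles",
    bad_effect ~ "invalid_effect",
    TRUE ~ "ok"
  )
  keep <- reasons == "ok"
  n_rej <- sum(!keep)
  if (n_rej > 0) {
    inform(sprintf("read_sumstats: rejected %d of %d rows.", n_rej, nrow(raw)))
  }
  out <- tibble::tibble(
    snp_id = raw$SNP[keep], chr = as.character(raw$CHR[keep]),
    bp = as.integer(raw$BP[keep]), a1 = a1[keep], a2 = a2[keep],
    effect = effect[keep], p = p[keep]
  )
  attr(out, "n_rejected") <- n_rej
  attr(out, "rejected_reasons") <- table(reasons[!keep])
  out
}

#' Harmonize summary statistics with a target genotype panel
#'
#' Aligns effect alleles between the discovery summary statistics and the
#' target panel's `(A1, A2)`. Each target SNP receives exactly one
#' disposition:
#' * `matched` — alleles agree as stated;
#' * `sign_flipped` — alleles swapped, effect negated;
#' * `strand_flipped` — alleles agree after complementing both, effect kept;
#' * `strand_flipped_and_sign_flipped` — swapped after complementing, negated;
#' * `dropped_ambiguous` — palindromic (A/T or C/G) SNPs, unconditionally;
#' * `dropped_mismatch` — any other allele configuration;
#' * `dropped_absent` — target SNP absent from the summary statistics.
#'
#' @param records Summary statistics tibble from [read_sumstats()] (or the
#'   same columns).
#' @param target_snps Target SNP metadata: tibble with `snp_id, chr, bp, a1,
#'   a2` (e.g. `geno$snps`).
#' @param match_by `"id"` (default) or `"pos"` (match on `chr:bp`, for panels
#'   whose id spaces differ).
#' @return Tibble of class `harmonized_panel`, one row per target SNP, in
#'   target orientation: `snp_id, chr, bp, a1, a2, effect, p, disposition`.
#'   Effects and p of dropped SNPs are `NA`.
#' @export
harmonize <- function(records, target_snps, match_by = c("id", "pos")) {
  match_by <- match.arg(match_by)
  if (match_by == "id") {
    if (anyDuplicated(records$snp_id)) abort("duplicate snp_id in `records`.")
    if (anyDuplicated(target_snps$snp_id)) abort("duplicate snp_id in `target_snps`.")
    idx <- match(target_snps$snp_id, records$snp_id)
  } else {
    key_r <- paste(records$chr, records$bp)
    key_t <- paste(target_snps$chr, target_snps$bp)
    if (anyDuplicated(key_r)) abort("duplicate chr:bp in `records`.")
    if (anyDuplicated(key_t)) abort("duplicate chr:bp in `target_snps`.")
    idx <- match(key_t, key_r)
  }
  n <- nrow(target_snps)
  s_a1 <- records$a1[idx]; s_a2 <- records$a2[idx]
  t_a1 <- target_snps$a1; t_a2 <- target_snps$a2
  c_a1 <- unname(ALLELE_COMPLEMENT[s_a1]); c_a2 <- unname(ALLELE_COMPLEMENT[s_a2])

  disposition <- dplyr::case_when(
    is.na(idx) ~ "dropped_absent",
    is_palindromic(s_a1, s_a2) | is_palindromic(t_a1, t_a2) ~ "dropped_ambiguous",
    s_a1 == t_a1 & s_a2 == t_a2 ~ "matched",
    s_a1 == t_a2 & s_a2 == t_a1 ~ "sign_flipped",
    c_a1 == t_a1 & c_a2 == t_a2 ~ "strand_flipped",
    c_a1 == t_a2 & c_a2 == t_a1 ~ "strand_flipped_and_sign_flipped",
    TRUE ~ "dropped_mismatch"
  )
  sign <- dplyr::case_when(
    disposition %in% c("matched", "strand_flipped") ~ 1,
    disposition %in% c("sign_flipped", "strand_flipped_and_sign_flipped") ~ -1,
    TRUE ~ NA_real_
  )
  out <- tibble::tibble(
    snp_id = target_snps$snp_id, chr = target_snps$chr, bp = target_snps$bp,
    a1 = t_a1, a2 = t_a2,
    effect = sign * records$effect[idx],
    p = ifelse(is.na(sign), NA_real_, records$p[idx]),
    disposition = factor(disposition, levels = c(
      "matched", "sign_flipped", "strand_flipped",
      "strand_flipped_and_sign_flipped", "dropped_ambiguous",
      "dropped_mismatch", "dropped_absent"
    ))
  )
  class(out) <- c("harmonized_panel", class(out))
  out
}

#' Kept rows of a harmonized panel (aligned, usable weights)
#' @param harmonized A `harmonized_panel`.
#' @return Tibble restricted to matched/flipped SNPs.
#' @export
harmonized_weights <- function(harmonized) {
  kept <- harmonized$disposition %in% c(
    "matched", "sign_flipped", "strand_flipped",
    "strand_flipped_and_sign_flipped"
  )
  out <- harmonized[kept, ]
  class(out) <- setdiff(class(out), "harmonized_panel")
  out
}

#' Disposition counts of a harmonized panel
#' @param harmonized A `harmonized_panel`.
#' @return Tibble `disposition, n` covering every target SNP exactly once.
#' @export
harmonization_report <- function(harmonized) {
  dplyr::count(tibble::as_tibble(harmonized), .data$disposition,
               .drop = FALSE, name = "n")
}
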