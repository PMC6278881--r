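# Shared fixtures: small simulated cohorts and hand-built genotype panels.

small_config <- function(seed = 1, ...) {
  sim_config(n_snps = 300, block_size = 10, within_block_rho = 0.5,
             n_target = 400, seed = seed, ...)
}

# genotype panel built directly from a dosage matrix (bypasses the simulator)
manual_geno <- function(dosage, chr = NULL, bp = NULL, a1 = NULL, a2 = NULL) {
  m <- ncol(dosage)
  snps <- tibble::tibble(
    snp_id = colnames(dosage) %||% sprintf("snp%03d", seq_len(m)),
    chr = chr %||% rep("1", m),
    bp = bp %||% (seq_len(m) * 1000L),
    a1 = a1 %||% rep("A", m),
    a2 = a2 %||% rep("G", m)
  )
  samples <- tibble::tibble(
    fid = sprintf("F%03d", seq_len(nrow(dosage))),
    iid = sprintf("I%03d", seq_len(nrow(dosage)))
  )
  prsct:::new_geno_matrix(dosage, snps, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# covariate columns of a simulated phenotype table
cov_cols <- function(pheno) {
  pheno[, c("age", "sex", "birth_lat", "birth_lon", "batch",
            grep("^pc[0-9]+$", names(pheno), value = TRUE))]
}

# independent greedy clumping oracle: straight re-derivation from an r2
# matrix, p-values and positions, no shared code with ld_clump()
clump_oracle <- function(r2, p, chr, bp, snp_id, r2_threshold, window_bp) {
  ord <- order(p, chr, bp, snp_id)
  removed <- rep(FALSE, length(p))
  index <- logical(length(p))
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    if (removed[i]) next
    index[i] <- TRUE
    if (pos < length(ord)) {
      for (j in ord[(pos + 1):length(ord)]) {
        if (!removed[j] && chr[j] == chr[i] &&
            abs(bp[j] - bp[i]) <= window_bp && r2[i, j] >= r2_threshold) {
          removed[j] <- TRUE
        }
      }
    }
  }
  snp_id[index][order(chr[index], bp[index], snp_id[index])]
}
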