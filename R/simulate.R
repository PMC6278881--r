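#' Configure a synthetic GWAS + target-cohort simulation
#'
#' Defines the generative model for a discovery GWAS and a target cohort with
#' known ground truth: LD-blocked biallelic genotypes, a point-normal polygenic
#' architecture, target traits with configurable SNP-heritability and genetic
#' correlation to the discovery trait, binary traits via a liability threshold,
#' and the standard covariates (age, sex, birthplace coordinates, genotyping
#' batch, principal components).
#'
#' Genotypes are generated from a haplotype-level latent-Gaussian model: each of
#' the two haplotypes of an individual is derived from a latent Gaussian vector
#' with AR1 correlation `within_block_rho` inside an LD block, thresholded at
#' the quantile of each SNP's allele frequency. Blocks are independent and
#' placed further apart than any clumping window, so inter-block LD is exactly
#' zero by construction.
#'
#' @param n_snps Number of SNPs in the panel.
#' @param block_size SNPs per LD block (the last block may be truncated).
#' @param within_block_rho AR1 latent correlation between adjacent SNPs within
#'   a block, in `[0, 1)`.
#' @param maf_range Range of effect-allele frequencies, in `(0, 0.5]`.
#' @param prop_causal Fraction of SNPs with non-zero effect, in `(0, 1]`.
#' @param h2_discovery SNP-heritability of the (liability-scale) discovery
#'   trait, in `[0, 1)`. Default 0.22, the SNP-heritability scale typical of
#'   ADHD-like psychiatric traits.
#' @param n_discovery Discovery GWAS sample size. Default 55374
#'   (a 20,183-case / 35,191-control mega-GWAS).
#' @param n_target Target cohort sample size.
#' @param traits Data frame with one row per target trait: columns `name`,
#'   `type` (`"continuous"` or `"binary"`), `r_g` (genetic correlation to the
#'   discovery trait, in `[-1, 1]`), `h2` (SNP-heritability of the target
#'   trait), and `prevalence` (for binary traits; `NA` otherwise).
#' @param covariate_spec List with `age_range`, `p_female`, `n_batches`,
#'   `n_pcs`, `birth_lat_range`, `birth_lon_range`.
#' @param palindromic_frac Fraction of SNPs given strand-ambiguous (A/T or C/G)
#'   allele pairs. Default 0: ambiguous SNPs are dropped during harmonization,
#'   so a lossless panel keeps ground truth simple; raise to exercise that path.
#' @param seed Integer seed; the same seed reproduces every simulated object
#'   bit-for-bit.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 2000,
                       block_size = 20,
                       within_block_rho = 0.7,
                       maf_range = c(0.05, 0.5),
                       prop_causal = 0.2,
                       h2_discovery = 0.22,
                       n_discovery = 55374,
                       n_target = 2000,
                       traits = default_traits(),
                       covariate_spec = default_covariate_spec(),
                       palindromic_frac = 0,
                       seed = 1L) {
  n_snps <- assert_count(n_snps, "n_snps")
  block_size <- assert_count(block_size, "block_size")
  assert_scalar_num(within_block_rho, "within_block_rho", 0, 1, open_upper = TRUE)
  if (length(maf_range) != 2L) abort("`maf_range` must have two elements.")
  assert_scalar_num(maf_range[1], "maf_range[1]", 0, 0.5, open_lower = TRUE)
  assert_scalar_num(maf_range[2], "maf_range[2]", maf_range[1], 0.5)
  assert_scalar_num(prop_causal, "prop_causal", 0, 1, open_lower = TRUE)
  assert_scalar_num(h2_discovery, "h2_discovery", 0, 1, open_upper = TRUE)
  n_discovery <- assert_count(n_discovery, "n_discovery")
  n_target <- assert_count(n_target, "n_target", min = 2L)
  assert_scalar_num(palindromic_frac, "palindromic_frac", 0, 1)
  seed <- assert_count(seed, "seed", min = 0L)

  traits <- tibble::as_tibble(traits)
  req <- c("name", "type", "r_g", "h2", "prevalence")
  if (!all(req %in% names(traits))) {
    abort(paste0("`traits` must have columns: ", paste(req, collapse = ", ")))
  }
  if (!all(traits$type %in% c("continuous", "binary"))) {
    abort("trait `type` must be 'continuous' or 'binary'.")
  }
  if (any(abs(traits$r_g) > 1)) abort("|r_g| must be <= 1.")
  if (any(traits$h2 < 0 | traits$h2 >= 1)) abort("trait h2 must be in [0, 1).")
  bad_prev <- traits$type == "binary" &
    (is.na(traits$prevalence) | traits$prevalence <= 0 | traits$prevalence >= 1)
  if (any(bad_prev)) abort("binary traits need `prevalence` in (0, 1).")
  if (anyDuplicated(traits$name)) abort("trait names must be unique.")

  structure(
    list(
      n_snps = n_snps, block_size = block_size,
      within_block_rho = within_block_rho, maf_range = as.numeric(maf_range),
      prop_causal = prop_causal, h2_discovery = h2_discovery,
      n_discovery = n_discovery, n_target = n_target, traits = traits,
      covariate_spec = covariate_spec, palindromic_frac = palindromic_frac,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_traits <- function() {
  tibble::tribble(
    ~name,            ~type,         ~r_g, ~h2,  ~prevalence,
    "trait_cont",     "continuous",  0.35, 0.25, NA,
    "trait_binary",   "binary",      0.35, 0.10, 0.0214
  )
}

#' @rdname sim_config
#' @export
default_covariate_spec <- function() {
  list(
    age_range = c(40, 73), p_female = 0.53, n_batches = 3, n_pcs = 15,
    birth_lat_range = c(50, 58), birth_lon_range = c(-6, 2)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d SNPs (blocks of %d, rho=%.2f), discovery n=%d (h2=%.2f), target n=%d, %d trait(s), seed=%d\n",
    x$n_snps, x$block_size, x$within_block_rho, x$n_discovery,
    x$h2_discovery, x$n_target, nrow(x$traits), x$seed
  ))
  invisible(x)
}

# Deterministic SNP panel metadata (MAFs, positions, alleles) shared by the
# genotype and summary-statistic generators so both see the same panel.
panel_metadata <- function(config) {
  m <- config$n_snps
  bs <- config$block_size
  block <- rep(seq_len(ceiling(m / bs)), each = bs)[seq_len(m)]
  within <- stats::ave(seq_len(m), block, FUN = seq_along)
  out <- withr::with_seed(config$seed, {
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    # non-palindromic ordered pairs keep harmonization lossless by default
    safe <- rbind(
      c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
      c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
    )
    pal <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    pick <- sample(nrow(safe), m, replace = TRUE)
    a1 <- safe[pick, 1]; a2 <- safe[pick, 2]
    if (config$palindromic_frac > 0) {
      n_pal <- round(config$palindromic_frac * m)
      if (n_pal > 0) {
        idx <- sample(m, n_pal)
        pp <- sample(nrow(pal), n_pal, replace = TRUE)
        a1[idx] <- pal[pp, 1]; a2[idx] <- pal[pp, 2]
      }
    }
    list(maf = maf, a1 = a1, a2 = a2)
  })
  # one block spans far less than a 250-kb clumping window; consecutive
  # blocks sit 1 Mb apart so inter-block distance always exceeds it
  bp <- (block - 1L) * 1000000L + (within - 1L) * 100L + 1L
  tibble::tibble(
    snp_id = sprintf("rs%06d", seq_len(m)),
    chr = "1", bp = bp, a1 = out$a1, a2 = out$a2,
    maf = out$maf, block = block
  )
}

#' Simulate an LD-blocked genotype panel
#'
#' Draws `n_samples` individuals as two haplotypes each from the latent
#' AR1-Gaussian block model of [sim_config()]. Dosages count copies of the
#' effect allele A1 and take values 0/1/2 (no missingness unless injected with
#' [inject_missingness()]).
#'
#' @param config A [sim_config()].
#' @param n_samples Number of individuals (>= 2). Defaults to
#'   `config$n_target`.
#' @param seed_offset Internal offset separating the RNG streams of the
#'   different generator stages.
#' @return A `geno_matrix`: list with `dosage` (n x m integer matrix),
#'   `snps` (SNP metadata tibble) and `samples` (id tibble).
#' @export
simulate_genotypes <- function(config, n_samples = config$n_target,
                               seed_offset = 1000L) {
  n_samples <- assert_count(n_samples, "n_samples", min = 2L)
  snps <- panel_metadata(config)
  m <- nrow(snps)
  rho <- config$within_block_rho
  thr <- qnorm(snps$maf)
  dosage <- withr::with_seed(config$seed + seed_offset, {
    H <- matrix(0L, 2L * n_samples, m)
    for (b in unique(snps$block)) {
      cols <- which(snps$block == b)
      B <- length(cols)
      Z <- matrix(rnorm(2L * n_samples * B), 2L * n_samples, B)
      if (rho > 0 && B > 1L) {
        for (j in 2:B) Z[, j] <- rho * Z[, j - 1L] + sqrt(1 - rho^2) * Z[, j]
      }
      H[, cols] <- (Z < rep(thr[cols], each = 2L * n_samples)) + 0L
    }
    H[seq(1L, 2L * n_samples, by = 2L), ] + H[seq(2L, 2L * n_samples, by = 2L), ]
  })
  samples <- tibble::tibble(
    fid = sprintf("F%05d", seq_len(n_samples)),
    iid = sprintf("I%05d", seq_len(n_samples))
  )
  new_geno_matrix(dosage, snps, samples)
}

new_geno_matrix <- function(dosage, snps, samples) {
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(samples$iid, snps$snp_id)
  structure(list(dosage = dosage, snps = snps, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$dosage))
  cat(sprintf("<geno_matrix> %d samples x %d SNPs (%s missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              format(nmiss, big.mark = ",")))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype panel by sample and/or SNP ids
#' @param geno A `geno_matrix`.
#' @param samples,snps Character vectors of ids to keep (`NULL` keeps all).
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(geno, samples = NULL, snps = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(geno$dosage)) else match(samples, geno$samples$iid)
  vi <- if (is.null(snps)) seq_len(ncol(geno$dosage)) else match(snps, geno$snps$snp_id)
  if (anyNA(si)) abort("unknown sample id(s) in `samples`.")
  if (anyNA(vi)) abort("unknown SNP id(s) in `snps`.")
  new_geno_matrix(geno$dosage[si, vi, drop = FALSE],
                 geno$snps[vi, ], geno$samples[si, ])
}

#' @export
as_tibble.geno_matrix <- function(x, ...) {
  dplyr::bind_cols(x$samples, tibble::as_tibble(x$dosage))
}

#' Empirical effect-allele frequencies of a panel
#' @param geno A `geno_matrix`.
#' @return Named numeric vector of allele frequencies (dosage mean / 2).
#' @export
allele_freq <- function(geno) {
  colMeans(geno$dosage, na.rm = TRUE) / 2
}

#' Simulate true per-SNP effects under a point-normal architecture
#'
#' A fraction `prop_causal` of SNPs receives i.i.d. normal effects on the
#' standardized-genotype scale, rescaled so the genetic variance equals
#' `h2_discovery`. Each target trait's effects are built as
#' `r_g * discovery + sqrt(1 - r_g^2) * independent`, rescaled to the trait's
#' own `h2`; non-causal SNPs have exactly zero effect everywhere.
#'
#' @param config A [sim_config()].
#' @return A tibble of class `true_effects`: `snp_id`, `causal`, `discovery`,
#'   and one column per target trait.
#' @export
simulate_effects <- function(config) {
  snps <- panel_metadata(config)
  m <- nrow(snps)
  m_causal <- max(1L, round(config$prop_causal * m))
  withr::with_seed(config$seed + 2000L, {
    causal_idx <- sort(sample.int(m, m_causal))
    unit_vec <- function(v) v / sqrt(sum(v^2))
    d_unit <- unit_vec(rnorm(m_causal))
    discovery <- numeric(m)
    discovery[causal_idx] <- d_unit * sqrt(config$h2_discovery)
    out <- tibble::tibble(
      snp_id = snps$snp_id,
      causal = seq_len(m) %in% causal_idx,
      discovery = discovery
    )
    for (i in seq_len(nrow(config$traits))) {
      tr <- config$traits[i, ]
      indep <- unit_vec(rnorm(m_causal))
      t_unit <- tr$r_g * d_unit + sqrt(1 - tr$r_g^2) * indep
      eff <- numeric(m)
      if (tr$h2 > 0) eff[causal_idx] <- unit_vec(t_unit) * sqrt(tr$h2)
      out[[tr$name]] <- eff
    }
    class(out) <- c("true_effects", class(out))
    out
  })
}

#' Simulate discovery GWAS summary statistics
#'
#' Marginal effect estimates are the true standardized effects plus normal
#' noise with variance `1 / n_discovery`; two-sided Wald p-values come from
#' `z = estimate * sqrt(n_discovery)`. Effects are emitted on the allelic
#' scale as odds ratios, `OR = exp(estimate / sqrt(2 f (1 - f)))`, with A1 the
#' effect allele.
#'
#' @param effects A `true_effects` tibble from [simulate_effects()].
#' @param config The same [sim_config()] used to generate `effects`.
#' @return Tibble with columns `SNP, CHR, BP, A1, A2, OR, P` (the summary
#'   statistics dialect written by [write_sumstats()]).
#' @export
simulate_discovery_sumstats <- function(effects, config) {
  snps <- panel_metadata(config)
  if (nrow(effects) != nrow(snps) || !all(effects$snp_id == snps$snp_id)) {
    abort("`effects` does not match the SNP panel of `config`.")
  }
  n <- config$n_discovery
  withr::with_seed(config$seed + 3000L, {
    est <- effects$discovery + rnorm(nrow(snps)) / sqrt(n)
    z <- est * sqrt(n)
    p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
    f <- snps$maf
    tibble::tibble(
      SNP = snps$snp_id, CHR = snps$chr, BP = snps$bp,
      A1 = snps$a1, A2 = snps$a2,
      OR = exp(est / sqrt(2 * f * (1 - f))), P = p
    )
  })
}

#' Simulate target phenotypes and covariates
#'
#' Continuous traits are `sqrt(h2) * standardized genetic value + covariate
#' effects + normal residual`, with total variance 1. Binary traits apply a
#' liability threshold at `qnorm(1 - prevalence)` to the same construction.
#' Covariates (age, sex, birthplace coordinates, batch, principal components)
#' each carry a small fixed effect (0.5% of variance), so baseline-model
#' adjustment matters without dominating.
#'
#' @param genotypes A `geno_matrix` on the config's panel.
#' @param effects A `true_effects` tibble.
#' @param config The shared [sim_config()].
#' @return A tibble with `fid`, `iid`, covariate columns (`age`, `sex` with
#'   0 = male / 1 = female, `birth_lat`, `birth_lon`, `batch`, `pc1..`), and
#'   one column per trait. True standardized genetic values are attached as
#'   attribute `"genetic_values"` for validation.
#' @export
simulate_phenotypes <- function(genotypes, effects, config) {
  if (!identical(genotypes$snps$snp_id, effects$snp_id)) {
    abort("`genotypes` and `effects` are not on the same SNP panel.")
  }
  n <- nrow(genotypes$dosage)
  cs <- config$covariate_spec
  withr::with_seed(config$seed + 4000L, {
    cov_tbl <- tibble::tibble(
      age = runif(n, cs$age_range[1], cs$age_range[2]),
      sex = rbinom(n, 1, cs$p_female),
      birth_lat = runif(n, cs$birth_lat_range[1], cs$birth_lat_range[2]),
      birth_lon = runif(n, cs$birth_lon_range[1], cs$birth_lon_range[2]),
      batch = paste0("batch", sample.int(cs$n_batches, n, replace = TRUE))
    )
    pcs <- matrix(rnorm(n * cs$n_pcs), n, cs$n_pcs,
                  dimnames = list(NULL, paste0("pc", seq_len(cs$n_pcs))))
    cov_tbl <- dplyr::bind_cols(cov_tbl, tibble::as_tibble(pcs))

    # small fixed covariate effects: age, sex, birthplace, first three PCs,
    # each explaining 0.5% of phenotypic variance, alternating sign
    cov_cols <- c("age", "sex", "birth_lat", "birth_lon", "pc1", "pc2", "pc3")
    cov_lin <- vapply(cov_cols, function(j) standardize(cov_tbl[[j]]), numeric(n))
    b_cov <- sqrt(0.005) * rep(c(1, -1), length.out = length(cov_cols))
    cov_part <- drop(cov_lin %*% b_cov)
    var_cov <- sum(b_cov^2)

    X_std <- scale(genotypes$dosage)
    X_std[is.na(X_std)] <- 0
    out <- dplyr::bind_cols(genotypes$samples, cov_tbl)
    gvals <- list()
    for (i in seq_len(nrow(config$traits))) {
      tr <- config$traits[i, ]
      g <- unname(drop(X_std %*% effects[[tr$name]]))
      g_std <- if (stats::sd(g) > 0) standardize(g) else g
      resid_var <- max(0, 1 - tr$h2 - var_cov)
      liab <- sqrt(tr$h2) * g_std + cov_part + rnorm(n, sd = sqrt(resid_var))
      out[[tr$name]] <- if (tr$type == "binary") {
        as.integer(liab > qnorm(1 - tr$prevalence))
      } else {
        liab
      }
      gvals[[tr$name]] <- g_std
    }
    attr(out, "genetic_values") <- tibble::as_tibble(gvals)
    attr(out, "traits") <- config$traits
    out
  })
}

#' Simulate a complete cohort (genotypes, effects, summary stats, phenotypes)
#' @param config A [sim_config()].
#' @return List with elements `genotypes`, `effects`, `sumstats`, `phenotypes`.
#' @export
simulate_cohort <- function(config) {
  genotypes <- simulate_genotypes(config)
  effects <- simulate_effects(config)
  sumstats <- simulate_discovery_sumstats(effects, config)
  phenotypes <- simulate_phenotypes(genotypes, effects, config)
  list(genotypes = genotypes, effects = effects,
       sumstats = sumstats, phenotypes = phenotypes)
}

#' Inject uniform random missingness into a genotype panel
#' @param geno A `geno_matrix`.
#' @param rate Per-genotype missingness probability.
#' @param snps Optional SNP ids to restrict the injection to.
#' @param seed Integer seed.
#' @return A `geno_matrix` with `NA` dosages at the injected positions.
#' @export
inject_missingness <- function(geno, rate, snps = NULL, seed = 1L) {
  assert_scalar_num(rate, "rate", 0, 1)
  cols <- if (is.null(snps)) seq_len(ncol(geno$dosage)) else match(snps, geno$snps$snp_id)
  if (anyNA(cols)) abort("unknown SNP id(s) in `snps`.")
  d <- geno$dosage
  withr::with_seed(seed, {
    mask <- matrix(runif(nrow(d) * length(cols)) < rate, nrow(d), length(cols))
    d[, cols][mask] <- NA_integer_
  })
  new_geno_matrix(d, geno$snps, geno$samples)
}

#' Append related individuals to a genotype panel
#'
#' `"duplicate"` copies an existing sample; `"parent_child"` draws a child by
#' Mendelian transmission (one allele from each of two parents, a transmitted
#' allele being a Bernoulli draw with probability dosage/2).
#'
#' @param geno A `geno_matrix`.
#' @param type `"duplicate"` or `"parent_child"`.
#' @param parents Indices of the source sample(s): one for a duplicate, two
#'   for a parent-child trio completion.
#' @param seed Integer seed.
#' @return A `geno_matrix` with one appended sample (iid prefixed `REL`).
#' @export
inject_relatives <- function(geno, type = c("duplicate", "parent_child"),
                             parents = c(1L, 2L), seed = 1L) {
  type <- match.arg(type)
  d <- geno$dosage
  new_row <- if (type == "duplicate") {
    d[parents[1], ]
  } else {
    withr::with_seed(seed, {
      t1 <- rbinom(ncol(d), 1, d[parents[1], ] / 2)
      t2 <- rbinom(ncol(d), 1, d[parents[2], ] / 2)
      t1 + t2
    })
  }
  iid_new <- sprintf("REL%05d", nrow(d) + 1L)
  samples <- dplyr::bind_rows(geno$samples,
                              tibble::tibble(fid = iid_new, iid = iid_new))
  new_geno_matrix(rbind(d, new_row), geno$snps, samples)
}
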