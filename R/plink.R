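#' Read and write PLINK 1 binary genotype triplets
#'
#' The `.bed` file is SNP-major with magic bytes `0x6C 0x1B 0x01` and two bits
#' per genotype (`00` = homozygous A1, `10` = heterozygous, `11` = homozygous
#' A2, `01` = missing; samples packed four per byte, first sample in the lowest
#' bits). Dosages count copies of A1. `.bim` columns are chromosome, id,
#' genetic distance (written as 0), base-pair position, A1, A2; `.fam` is the
#' standard six-column pedigree stub.
#'
#' @param geno A `geno_matrix`.
#' @param prefix Path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return `write_plink()` returns `prefix` invisibly; `read_plink()` returns
#'   a `geno_matrix`.
#' @export
write_plink <- function(geno, prefix) {
  n <- nrow(geno$dosage); m <- ncol(geno$dosage)
  # 2-bit codes indexed by dosage: 0 -> 11, 1 -> 10, 2 -> 00, NA -> 01
  code <- c(3L, 2L, 0L)
  g <- geno$dosage
  codes <- matrix(code[g + 1L], n, m)
  codes[is.na(g)] <- 1L
  bytes_per_snp <- ceiling(n / 4)
  pad <- bytes_per_snp * 4L - n
  if (pad > 0) codes <- rbind(codes, matrix(0L, pad, m))
  shift <- c(1L, 4L, 16L, 64L)
  byte_mat <- matrix(0L, bytes_per_snp, m)
  for (k in 1:4) {
    byte_mat <- byte_mat + codes[seq(k, nrow(codes), by = 4L), , drop = FALSE] * shift[k]
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  writeBin(as.raw(byte_mat), con)

  bim <- geno$snps
  readr::write_tsv(
    tibble::tibble(chr = bim$chr, snp_id = bim$snp_id, cm = 0,
                   bp = bim$bp, a1 = bim$a1, a2 = bim$a2),
    paste0(prefix, ".bim"), col_names = FALSE
  )
  fam <- geno$samples
  readr::write_tsv(
    tibble::tibble(fid = fam$fid, iid = fam$iid, pat = 0, mat = 0,
                   sex = 0, pheno = -9),
    paste0(prefix, ".fam"), col_names = FALSE
  )
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  bim <- readr::read_tsv(
    paste0(prefix, ".bim"),
    col_names = c("chr", "snp_id", "cm", "bp", "a1", "a2"),
    col_types = "ccidcc", progress = FALSE
  )
  fam <- readr::read_tsv(
    paste0(prefix, ".fam"),
    col_names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
    col_types = "cccccc", progress = FALSE
  )
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6CL, 0x1BL, 0x01L))) {
    abort("not a SNP-major PLINK .bed file (bad magic bytes).")
  }
  raw <- readBin(con, "raw", bytes_per_snp * m)
  if (length(raw) != bytes_per_snp * m) abort(".bed file truncated.")
  b <- as.integer(raw)
  # unpack 2-bit fields: sample k of a byte sits at bits 2(k-1)..2k-1
  codes <- matrix(0L, bytes_per_snp * 4L, m)
  bmat <- matrix(b, bytes_per_snp, m)
  for (k in 1:4) {
    codes[seq(k, nrow(codes), by = 4L), ] <- bmat %% 4L
    bmat <- bmat %/% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2, 10 -> 1, 11 -> 0, 01 -> NA
  lut <- c(2L, NA_integer_, 1L, 0L)
  dosage <- matrix(lut[codes + 1L], n, m)
  snps <- tibble::tibble(snp_id = bim$snp_id, chr = bim$chr, bp = bim$bp,
                         a1 = bim$a1, a2 = bim$a2)
  new_geno_matrix(dosage, snps, fam[, c("fid", "iid")])
}

#' Read and write the plain-text dosage dialect
#'
#' A dosage table is a TSV with columns `FID`, `IID`, then one column per SNP
#' (header = SNP id, values 0/1/2 or `NA`), accompanied by a `<path>.snps.tsv`
#' sidecar with columns `snp_id, chr, bp, a1, a2`.
#'
#' @param geno A `geno_matrix`.
#' @param path Path of the dosage TSV.
#' @return `write_dosage_tsv()` returns `path` invisibly; `read_dosage_tsv()`
#'   returns a `geno_matrix`.
#' @export
write_dosage_tsv <- function(geno, path) {
  tbl <- dplyr::bind_cols(
    tibble::tibble(FID = geno$samples$fid, IID = geno$samples$iid),
    tibble::as_tibble(geno$dosage)
  )
  readr::write_tsv(tbl, path)
  readr::write_tsv(geno$snps[, c("snp_id", "chr", "bp", "a1", "a2")],
                   paste0(path, ".snps.tsv"))
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    FID = "c", IID = "c", .default = "i"
  ), progress = FALSE)
  snps <- readr::read_tsv(paste0(path, ".snps.tsv"),
                          col_types = "ccicc", progress = FALSE)
  dosage <- as.matrix(tbl[, -(1:2)])
  new_geno_matrix(dosage, snps,
                 tibble::tibble(fid = tbl$FID, iid = tbl$IID))
}

#' Write summary statistics in the `SNP CHR BP A1 A2 OR P` dialect
#' @param sumstats Tibble as produced by [simulate_discovery_sumstats()].
#' @param path Output TSV path.
#' @export
write_sumstats <- function(sumstats, path) {
  readr::write_tsv(sumstats, path)
  invisible(path)
}

#' Write a phenotype/covariate table as `FID IID <columns...>` TSV
#' @param phenotypes Tibble with `fid` and `iid` columns.
#' @param path Output TSV path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  out <- dplyr::rename(phenotypes, FID = "fid", IID = "iid")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  dplyr::rename(tbl, fid = "FID", iid = "IID")
}
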