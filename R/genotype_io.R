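#' Open a PLINK 1 binary genotype fileset
#'
#' Creates a read-only, out-of-core handle over a variant-major `.bed` file
#' and its companion `.bim` (variant) and `.fam` (sample) tables. Only the
#' header and the two metadata tables are read; genotype bytes are accessed
#' lazily by [load_block()], [variant_stats()] and [sparse_inner_products()].
#'
#' Dosages count the A1 allele of the `.bim` file (bit-pair `00` decodes to
#' dosage 2), so effect signs of downstream models follow A1. This is the
#' PLINK 1 counted-allele convention; be aware of it when comparing signs
#' with tools that count A2.
#'
#' @param bed_path path to the `.bed` file, or a fileset prefix.
#' @param bim_path,fam_path paths to the `.bim`/`.fam` files; derived from
#'   `bed_path` when `NULL`.
#' @return An object of class `genotype_store` with elements `bed_path`,
#'   `n_samples`, `n_variants`, `variant_meta` (data.frame with columns
#'   `variant_id`, `chromosome`, `position`, `allele1`, `allele2`), and
#'   `sample_ids`.
#' @examples
#' g <- simulate_genotypes(simulation_spec(n_samples = 6, n_variants = 3))
#' prefix <- file.path(tempdir(), "toy")
#' write_plink_fixture(g$dosage, out_prefix = prefix)
#' store <- open_store(prefix)
#' store$n_samples
#' @export
open_store <- function(bed_path, bim_path = NULL, fam_path = NULL) {
  if (!grepl("\\.bed$", bed_path)) {
    bim_path <- bim_path %||% paste0(bed_path, ".bim")
    fam_path <- fam_path %||% paste0(bed_path, ".fam")
    bed_path <- paste0(bed_path, ".bed")
  } else {
    stem <- sub("\\.bed$", "", bed_path)
    bim_path <- bim_path %||% paste0(stem, ".bim")
    fam_path <- fam_path %||% paste0(stem, ".fam")
  }
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) stop("file not found: ", f)

  bim <- data.table::fread(bim_path, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  if (ncol(bim) != 6L) stop(".bim must have 6 columns, found ", ncol(bim))
  names(bim) <- c("chromosome", "variant_id", "cm", "position", "allele1", "allele2")
  fam <- data.table::fread(fam_path, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  if (ncol(fam) != 6L) stop(".fam must have 6 columns, found ", ncol(fam))
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")

  n_samples <- nrow(fam)
  n_variants <- nrow(bim)
  hdr <- readBin(bed_path, "raw", n = 3L)
  if (length(hdr) < 3L || hdr[1] != as.raw(0x6c) || hdr[2] != as.raw(0x1b))
    stop("not a PLINK 1 .bed file (bad magic bytes): ", bed_path)
  if (hdr[3] == as.raw(0x00))
    stop("sample-major .bed layout is not supported: ", bed_path)
  if (hdr[3] != as.raw(0x01))
    stop("unrecognized .bed mode byte: ", as.integer(hdr[3]))
  expected <- 3 + n_variants * ceiling(n_samples / 4)
  actual <- file.size(bed_path)
  if (actual != expected)
    stop(sprintf(".bed file is truncated or inconsistent: %d bytes, expected %d (n=%d, p=%d)",
                 actual, expected, n_samples, n_variants))

  structure(list(
    bed_path = normalizePath(bed_path),
    n_samples = n_samples,
    n_variants = n_variants,
    variant_meta = data.frame(
      variant_id = bim$variant_id, chromosome = bim$chromosome,
      position = as.integer(bim$position), allele1 = bim$allele1,
      allele2 = bim$allele2, stringsAsFactors = FALSE),
    sample_ids = fam$iid,
    fam = fam
  ), class = "genotype_store")
}

#' @exportS3Method base::print
print.genotype_store <- function(x, ...) {
  cat(sprintf("genotype_store: %d samples x %d variants\n  %s\n",
              x$n_samples, x$n_variants, x$bed_path))
  invisible(x)
}

#' Decode one .bed byte into dosage codes
#'
#' Reads up to four 2-bit genotype codes from a byte, least-significant
#' bit-pair first: `00` is dosage 2 (homozygous A1), `10` is 1, `11` is 0,
#' and `01` is missing (returned as `NA`).
#'
#' @param byte integer in 0..255.
#' @param n_remaining number of samples encoded in this byte (1..4); the
#'   final byte of a variant row may carry fewer than 4.
#' @return numeric vector of length `n_remaining` with values in
#'   `c(0, 1, 2, NA)`.
#' @examples
#' decode_bed_byte(0x1b) # 0b00011011 -> 0, 1, NA, 2
#' @export
decode_bed_byte <- function(byte, n_remaining = 4L) {
  stopifnot(length(byte) == 1L, byte >= 0, byte <= 255,
            n_remaining >= 1L, n_remaining <= 4L)
  codes <- bitwAnd(bitwShiftR(as.integer(byte), 2L * (seq_len(n_remaining) - 1L)), 3L)
  c(2, NA, 1, 0)[codes + 1L]
}

check_variant_indices <- function(store, indices) {
  indices <- as.integer(indices)
  if (length(indices) && (min(indices) < 1L || max(indices) > store$n_variants))
    stop("variant index out of range 1..", store$n_variants)
  indices
}

#' Per-variant QC statistics
#'
#' Computes the counted-allele (A1) frequency, minor allele frequency,
#' missing rate, and mean-imputation value of each requested variant,
#' using non-missing entries only. A variant with all entries missing gets
#' `impute_value = 0`, `maf = 0` and `missing_rate = 1`.
#'
#' @param store a `genotype_store`.
#' @param indices variant indices (default all).
#' @param sample_idx sample indices over which to compute the statistics
#'   (default all samples). Pass the training subset when imputation means
#'   must not leak from validation or test data.
#' @return data.frame with columns `variant_id`, `maf`, `missing_rate`,
#'   `impute_value`.
#' @export
variant_stats <- function(store, indices = seq_len(store$n_variants),
                          sample_idx = NULL) {
  indices <- check_variant_indices(store, indices)
  sample_idx <- if (is.null(sample_idx)) seq_len(store$n_samples)
                else as.integer(sample_idx)
  if (length(sample_idx) == 0L || min(sample_idx) < 1L ||
      max(sample_idx) > store$n_samples)
    stop("sample index out of range 1..", store$n_samples)
  if (length(indices) == 0L)
    return(data.frame(variant_id = character(0), maf = numeric(0),
                      missing_rate = numeric(0), impute_value = numeric(0)))
  cnt <- cpp_bed_counts(store$bed_path, store$n_samples,
                        indices - 1L, sample_idx - 1L)
  n <- length(sample_idx)
  n_obs <- n - cnt[, 3L]
  freq <- ifelse(n_obs > 0, (cnt[, 1L] + 2 * cnt[, 2L]) / (2 * n_obs), 0)
  data.frame(
    variant_id = store$variant_meta$variant_id[indices],
    maf = pmin(freq, 1 - freq),
    missing_rate = cnt[, 3L] / n,
    impute_value = ifelse(n_obs > 0, (cnt[, 1L] + 2 * cnt[, 2L]) / n_obs, 0),
    stringsAsFactors = FALSE)
}

#' Variant quality-control filter
#'
#' Keeps variant `j` iff `missing_rate_j <= max_missing_rate` and
#' `maf_j >= min_maf`, preserving order. Defaults follow the common
#' biobank-scale convention of excluding variants with more than 10%
#' missingness or minor allele frequency below 0.1%.
#'
#' @param stats data.frame as returned by [variant_stats()].
#' @param max_missing_rate,min_maf thresholds in `[0, 1]`.
#' @return integer vector of kept row indices into `stats`.
#' @export
qc_filter <- function(stats, max_missing_rate = 0.10, min_maf = 0.001) {
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  which(stats$missing_rate <= max_missing_rate & stats$maf >= min_maf)
}

#' Load a dense dosage block
#'
#' Materializes the requested variants as a dense `n_samples x k` matrix.
#' Missing genotypes are replaced by each variant's mean-imputation value
#' (computed over all samples unless `impute_values` is supplied, e.g. with
#' training-set means), or kept as `NA` when `raw = TRUE`.
#'
#' @param store a `genotype_store`.
#' @param indices variant indices; column order follows this argument.
#' @param impute_values per-variant imputation values aligned with
#'   `indices`; computed from the store when `NULL`.
#' @param raw if `TRUE`, return raw dosages with `NA` for missing.
#' @return numeric matrix with `length(indices)` columns, with variant ids
#'   as column names.
#' @export
load_block <- function(store, indices, impute_values = NULL, raw = FALSE) {
  indices <- check_variant_indices(store, indices)
  if (length(indices) == 0L)
    return(matrix(numeric(0), nrow = store$n_samples, ncol = 0L))
  if (is.null(impute_values) && !raw)
    impute_values <- variant_stats(store, indices)$impute_value
  if (raw) impute_values <- rep(NA_real_, length(indices))
  stopifnot(length(impute_values) == length(indices))
  out <- cpp_bed_block(store$bed_path, store$n_samples, indices - 1L,
                       as.numeric(impute_values), raw)
  colnames(out) <- store$variant_meta$variant_id[indices]
  out
}

#' SNP-optimized inner products with the genotype matrix
#'
#' Computes `t(X[, indices]) %*% R` in one sequential pass over the
#' requested variants' bytes, without materializing the dense genotype
#' matrix. Because a dosage vector takes only the values
#' `{0, 1, 2, mu}` (with `mu` the imputation value for missing entries),
#' the dot product with a residual vector reduces to three accumulator
#' registers -- the samples with dosage 1, dosage 2 and missing -- and
#' zero-dosage entries contribute nothing:
#' `x^T r = 1 * sum_{x=1} r + 2 * sum_{x=2} r + mu * sum_{x=miss} r`.
#' This is the kernel behind both batch screening and the KKT check.
#'
#' @param store a `genotype_store`.
#' @param R numeric matrix (or vector) with `n_samples` rows.
#' @param indices variant indices; rows of the result follow this order.
#' @param chunk_size number of variants whose bytes are buffered per read;
#'   the result is independent of it up to floating summation order.
#' @param impute_values per-variant imputation values aligned with
#'   `indices`; computed from the store when `NULL`.
#' @return numeric matrix `length(indices) x ncol(R)`.
#' @export
sparse_inner_products <- function(store, R, indices = seq_len(store$n_variants),
                                  chunk_size = 256L, impute_values = NULL) {
  indices <- check_variant_indices(store, indices)
  if (is.vector(R)) R <- matrix(R, ncol = 1L)
  if (nrow(R) != store$n_samples)
    stop("R has ", nrow(R), " rows; expected ", store$n_samples)
  stopifnot(chunk_size >= 1L)
  if (length(indices) == 0L) return(matrix(numeric(0), 0L, ncol(R)))
  if (is.null(impute_values))
    impute_values <- variant_stats(store, indices)$impute_value
  stopifnot(length(impute_values) == length(indices))
  ord <- order(indices)
  out <- cpp_bed_xtr(store$bed_path, store$n_samples, indices[ord] - 1L,
                     R, as.numeric(impute_values)[ord], as.integer(chunk_size))
  out[order(ord), , drop = FALSE]
}
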