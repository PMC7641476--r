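#' Simulation specification
#'
#' Generative parameters for synthetic biallelic SNP dosages and
#' phenotypes with known ground truth. Genotypes are independent across
#' variants (no linkage disequilibrium) unless `ld_block_size > 1`, in
#' which case adjacent variants within blocks share a latent allele count
#' with autoregressive correlation `ld_rho`, emulating the grouped
#' correlated predictors that motivate the elastic net.
#'
#' @param n_samples,n_variants dimensions.
#' @param maf_low,maf_high uniform range of the minor allele frequencies.
#' @param missing_rate i.i.d. per-entry missingness probability.
#' @param n_causal number of variants with nonzero effects.
#' @param effect_sd standard deviation of the causal effect sizes.
#' @param heritability fraction of phenotypic variance explained by the
#'   genetic signal (latent scale for the binomial family).
#' @param n_covariates number of standard-normal adjustment covariates
#'   with their own effects.
#' @param family response model: `"gaussian"`, `"binomial"`, `"cox"`.
#' @param baseline_hazard,censoring_rate Cox family: exponential baseline
#'   hazard and target censored fraction (independent exponential
#'   censoring is tuned to match it).
#' @param ld_block_size,ld_rho optional block-correlated genotype mode.
#' @param seed RNG seed; the whole generator is deterministic given it.
#' @export
simulation_spec <- function(n_samples = 400L, n_variants = 1000L,
                            maf_low = 0.05, maf_high = 0.5,
                            missing_rate = 0.01, n_causal = 20L,
                            effect_sd = 1, heritability = 0.5,
                            n_covariates = 0L, family = "gaussian",
                            baseline_hazard = 0.1, censoring_rate = 0.3,
                            ld_block_size = 1L, ld_rho = 0,
                            seed = 1L) {
  stopifnot(n_causal <= n_variants, maf_low > 0, maf_high <= 0.5,
            maf_low <= maf_high, missing_rate >= 0, missing_rate < 1,
            heritability > 0, heritability < 1, effect_sd > 0,
            ld_block_size >= 1L, ld_rho >= 0, ld_rho < 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 maf_low = maf_low, maf_high = maf_high,
                 missing_rate = missing_rate, n_causal = as.integer(n_causal),
                 effect_sd = effect_sd, heritability = heritability,
                 n_covariates = as.integer(n_covariates), family = family,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate biallelic SNP dosages
#'
#' Draws `dosage_ij ~ Binomial(2, maf_j)` with
#' `maf_j ~ Uniform(maf_low, maf_high)`, then masks entries missing i.i.d.
#' with probability `missing_rate`. In block-correlated mode the two
#' allele draws of each variant are thresholded latent Gaussians with
#' autoregressive correlation `ld_rho` within blocks.
#'
#' @param spec a [simulation_spec()].
#' @return list with `dosage` (n x p matrix over `{0, 1, 2, NA}`) and
#'   `maf` (the true generating frequencies).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; p <- spec$n_variants
  maf <- runif(p, spec$maf_low, spec$maf_high)
  if (spec$ld_block_size > 1L && spec$ld_rho > 0) {
    dosage <- matrix(0L, n, p)
    for (hap in 1:2) {
      lat <- matrix(0, n, p)
      for (j in seq_len(p)) {
        e <- rnorm(n)
        lat[, j] <- if ((j - 1L) %% spec$ld_block_size == 0L) e
                    else spec$ld_rho * lat[, j - 1L] + sqrt(1 - spec$ld_rho^2) * e
      }
      thr <- qnorm(maf)
      dosage <- dosage + (lat < rep(thr, each = n))
    }
  } else {
    dosage <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), n, p)
  }
  storage.mode(dosage) <- "double"
  if (spec$missing_rate > 0) {
    miss <- matrix(runif(n * p) < spec$missing_rate, n, p)
    dosage[miss] <- NA_real_
  }
  list(dosage = dosage, maf = maf)
}

#' Simulate a phenotype with a sparse genetic signal
#'
#' Chooses `n_causal` causal variants with effects
#' `beta* ~ N(0, effect_sd^2)` and builds the genetic signal from the
#' mean-imputed dosage matrix. Gaussian: `y = Z gamma + X beta* + eps`
#' with the noise variance set so `var(X beta*) / var(X beta* + eps)`
#' equals `heritability`. Binomial: `y ~ Bernoulli(plogis(eta))` with the
#' signal rescaled so it explains `heritability` of the latent logistic
#' variance (`pi^2 / 3`). Cox: times `~ Exponential(h0 * exp(eta))` with
#' independent exponential censoring tuned so the expected censored
#' fraction equals `censoring_rate`.
#'
#' @param genotypes output of [simulate_genotypes()] (or a dosage matrix).
#' @param spec a [simulation_spec()].
#' @return list with `y`, `status` (Cox only; `TRUE` = event), `beta`
#'   (full-length true coefficients), `causal` (indices), `covariates`,
#'   `gamma`, and `eta_genetic`.
#' @export
simulate_phenotype <- function(genotypes, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  dosage <- if (is.list(genotypes)) genotypes$dosage else genotypes
  n <- nrow(dosage); p <- ncol(dosage)
  set.seed(spec$seed + 1L)
  X <- apply(dosage, 2L, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x[is.na(x)] <- 0  # all-missing column
    x
  })
  causal <- sort(sample.int(p, spec$n_causal))
  beta <- numeric(p)
  beta[causal] <- rnorm(spec$n_causal, 0, spec$effect_sd)
  eta_g <- drop(X %*% beta)
  q <- spec$n_covariates
  Z <- if (q) matrix(rnorm(n * q), n, q,
                     dimnames = list(NULL, paste0("covar", seq_len(q))))
       else NULL
  gam <- if (q) rnorm(q, 0, 0.5) else numeric(0)
  eta_c <- if (q) drop(Z %*% gam) else 0
  h2 <- spec$heritability
  vg <- var(eta_g)
  out <- list(beta = beta, causal = causal, covariates = Z, gamma = gam,
              eta_genetic = eta_g)
  if (spec$family == "gaussian") {
    sigma <- if (vg > 0) sqrt(vg * (1 - h2) / h2) else 1
    out$y <- eta_c + eta_g + rnorm(n, 0, sigma)
  } else if (spec$family == "binomial") {
    scl <- if (vg > 0) sqrt(h2 / (1 - h2) * pi^2 / 3 / vg) else 0
    eta <- eta_c + scl * (eta_g - mean(eta_g))
    out$beta <- beta * scl
    out$eta_genetic <- eta_g * scl
    out$y <- rbinom(n, 1L, plogis(eta))
  } else if (spec$family == "cox") {
    rate <- spec$baseline_hazard * exp(eta_c + eta_g - mean(eta_g))
    t_event <- rexp(n, rate)
    cr <- spec$censoring_rate
    if (cr > 0) {
      # P(censored_i) = c / (c + rate_i); tune c to the target mean
      croot <- uniroot(function(cc) mean(cc / (cc + rate)) - cr,
                       interval = c(1e-10, 1e10), tol = 1e-12)$root
      t_cens <- rexp(n, croot)
      out$y <- pmin(t_event, t_cens)
      out$status <- t_event <= t_cens
    } else {
      out$y <- t_event
      out$status <- rep(TRUE, n)
    }
  } else stop("unknown family: ", spec$family)
  out
}

#' Write a PLINK 1 fileset from a dosage matrix
#'
#' Encodes dosages over `{0, 1, 2, NA}` into the variant-major 2-bit
#' `.bed` format (magic bytes `0x6C 0x1B`, mode `0x01`), with companion
#' `.bim` and `.fam` tables. Trailing padding bits of each variant row are
#' written as `00` and ignored on read. The files round-trip exactly
#' through [open_store()] and [load_block()].
#'
#' @param dosage numeric matrix, samples x variants, values in
#'   `{0, 1, 2, NA}`.
#' @param out_prefix output path prefix (writes `prefix.bed/.bim/.fam`).
#' @param variant_ids,sample_ids identifiers; generated when `NULL`.
#' @param chromosome,positions optional `.bim` fields.
#' @return the prefix, invisibly.
#' @export
write_plink_fixture <- function(dosage, out_prefix, variant_ids = NULL,
                                sample_ids = NULL, chromosome = "1",
                                positions = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); p <- ncol(dosage)
  vals <- dosage[!is.na(dosage)]
  if (!all(vals %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA")
  variant_ids <- variant_ids %||% sprintf("snp%06d", seq_len(p))
  sample_ids <- sample_ids %||% sprintf("id%06d", seq_len(n))
  positions <- positions %||% seq_len(p)

  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  codes <- matrix(3L, n, p)
  codes[!is.na(dosage) & dosage == 2] <- 0L
  codes[!is.na(dosage) & dosage == 1] <- 2L
  codes[is.na(dosage)] <- 1L
  n_pad <- (4L - n %% 4L) %% 4L
  if (n_pad) codes <- rbind(codes, matrix(0L, n_pad, p))  # padding bits 00
  i1 <- seq(1L, nrow(codes), by = 4L)
  bytes <- codes[i1, , drop = FALSE] + 4L * codes[i1 + 1L, , drop = FALSE] +
    16L * codes[i1 + 2L, , drop = FALSE] + 64L * codes[i1 + 3L, , drop = FALSE]
  con <- file(paste0(out_prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)  # column-major = variant-major

  bim <- data.frame(chromosome, variant_ids, 0L, positions, "A", "B")
  data.table::fwrite(bim, paste0(out_prefix, ".bim"), sep = "\t",
                     col.names = FALSE)
  fam <- data.frame(sample_ids, sample_ids, 0L, 0L, 0L, -9L)
  data.table::fwrite(fam, paste0(out_prefix, ".fam"), sep = "\t",
                     col.names = FALSE)
  invisible(out_prefix)
}

#' Deterministic train/validation/test split
#'
#' @param n number of samples.
#' @param fractions length-3 nonnegative fractions summing to 1
#'   (default 60/20/20).
#' @param seed RNG seed.
#' @return list with `train`, `validation`, `test` index vectors.
#' @export
split_samples <- function(n, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  set.seed(seed)
  perm <- sample.int(n)
  n_tr <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  list(train = sort(perm[seq_len(n_tr)]),
       validation = sort(perm[n_tr + seq_len(n_val)]),
       test = sort(perm[(n_tr + n_val + 1L):n]))
}

#' Simulate a complete dataset with known ground truth
#'
#' Convenience wrapper: simulates genotypes and a phenotype, optionally
#' writes the PLINK triplet (plus a tab-delimited phenotype/covariate
#' table and a ground-truth coefficient table) under `out_prefix`, and
#' returns everything including a 60/20/20 sample split.
#'
#' @param spec a [simulation_spec()].
#' @param out_prefix file prefix; when `NULL` nothing is written.
#' @return list with `genotypes`, `phenotype` (the [simulate_phenotype()]
#'   output), `split`, and — when written — `prefix` and a ready
#'   [open_store()] handle `store`.
#' @export
simulate_dataset <- function(spec, out_prefix = NULL) {
  g <- simulate_genotypes(spec)
  ph <- simulate_phenotype(g, spec)
  sp <- split_samples(spec$n_samples, seed = spec$seed + 2L)
  out <- list(genotypes = g, phenotype = ph, split = sp)
  if (!is.null(out_prefix)) {
    write_plink_fixture(g$dosage, out_prefix)
    tab <- data.frame(iid = sprintf("id%06d", seq_len(spec$n_samples)),
                      response = ph$y)
    if (!is.null(ph$status)) tab$status <- as.integer(ph$status)
    if (!is.null(ph$covariates)) tab <- cbind(tab, ph$covariates)
    data.table::fwrite(tab, paste0(out_prefix, ".pheno.tsv"), sep = "\t")
    truth <- data.frame(variant_id = sprintf("snp%06d", seq_len(spec$n_variants)),
                        beta_true = ph$beta)
    data.table::fwrite(truth, paste0(out_prefix, ".truth.tsv"), sep = "\t")
    out$prefix <- out_prefix
    out$store <- open_store(out_prefix)
  }
  out
}
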