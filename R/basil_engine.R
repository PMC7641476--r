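#' BASIL run configuration
#'
#' Collects the tunable parameters of the batch screening iterative lasso.
#'
#' @param family model family: `"gaussian"`, `"binomial"`, or `"cox"`.
#' @param L number of penalty values on the path (default 100).
#' @param lambda_min_ratio ratio `lambda_L / lambda_1`; defaults to 0.01
#'   when there are more variants than training samples, else 1e-4.
#' @param batch_M screening batch size `M`: how many currently inactive
#'   variants with the largest gradient magnitudes join the strong set at
#'   each screening. `NULL` uses [initial_batch_heuristic()].
#' @param delta_M batch enlargement when an entire iteration fails the KKT
#'   check; defaults to `batch_M`.
#' @param lambdas_per_iteration how many pending penalty values are fitted
#'   per iteration (the batch `Lambda^(k)`); the pending list is refilled
#'   to this size from the global sequence after each iteration.
#' @param kkt_tolerance relative slack on the KKT threshold
#'   `lambda * alpha * c_j` (floating-point arithmetic needs a nonzero
#'   tolerance; default 1e-6).
#' @param early_stop_patience stop after this many consecutive validated
#'   penalty values without improvement of the validation metric.
#' @param alpha_mix elastic-net mixing parameter in `(0, 1]`.
#' @param standardize see [penalty_spec()].
#' @param max_missing_rate,min_maf QC thresholds applied before fitting.
#' @param chunk_size variants buffered per read in the full-data pass.
#' @param tol,maxit inner coordinate-descent control, see [solver_control()].
#' @param min_batch floor for the heuristic batch size.
#' @param seed seed for any randomized subsampling; the path computation
#'   itself is deterministic.
#' @return an object of class `basil_config`.
#' @export
basil_config <- function(family = "gaussian", L = 100L, lambda_min_ratio = NULL,
                         batch_M = NULL, delta_M = NULL,
                         lambdas_per_iteration = 10L, kkt_tolerance = 1e-6,
                         early_stop_patience = 2L, alpha_mix = 1,
                         standardize = FALSE, max_missing_rate = 0.10,
                         min_maf = 0.001, chunk_size = 256L, tol = 1e-7,
                         maxit = 10000L, min_batch = 1000L, seed = 1L) {
  stopifnot(L >= 2L, lambdas_per_iteration >= 1L, kkt_tolerance >= 0,
            early_stop_patience >= 1L, alpha_mix > 0, alpha_mix <= 1,
            is.null(batch_M) || batch_M >= 1L,
            is.null(delta_M) || delta_M >= 1L,
            is.null(lambda_min_ratio) ||
              (lambda_min_ratio > 0 && lambda_min_ratio < 1))
  structure(list(family = family, L = as.integer(L),
                 lambda_min_ratio = lambda_min_ratio,
                 batch_M = batch_M, delta_M = delta_M,
                 lambdas_per_iteration = as.integer(lambdas_per_iteration),
                 kkt_tolerance = kkt_tolerance,
                 early_stop_patience = as.integer(early_stop_patience),
                 alpha_mix = alpha_mix, standardize = standardize,
                 max_missing_rate = max_missing_rate, min_maf = min_maf,
                 chunk_size = as.integer(chunk_size), tol = tol,
                 maxit = as.integer(maxit), min_batch = as.integer(min_batch),
                 seed = as.integer(seed)),
            class = "basil_config")
}

#' Log-spaced penalty sequence
#'
#' Builds the decreasing sequence `lambda_1 = lambda_max` down to
#' `lambda_L = lambda_max * lambda_min_ratio`, equally spaced on the log
#' scale. `lambda_max` is the screening statistic at the covariate-only
#' fit, `max_j (1/n)|x_j^T r^(0)| / c_j` (further divided by `alpha` for
#' the elastic net): the smallest penalty at which every penalized
#' coefficient is zero.
#'
#' @param lambda_max positive scalar.
#' @param L sequence length.
#' @param lambda_min_ratio ratio of the last to the first value.
#' @export
lambda_sequence <- function(lambda_max, L = 100L, lambda_min_ratio = 0.01) {
  if (!is.finite(lambda_max) || lambda_max <= 0)
    stop("lambda_max must be a positive number")
  stopifnot(L >= 2L, lambda_min_ratio > 0, lambda_min_ratio < 1)
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio), length.out = L))
}

#' Batch screening of the strong set
#'
#' Returns the union of the active set with the `M` variants outside it
#' that have the largest screening statistic. Ties are broken by ascending
#' variant index for determinism.
#'
#' @param stats per-variant screening statistics
#'   (`(1/n) |x_j^T r| / c_j`, family-scaled).
#' @param active_set indices that are always retained.
#' @param M batch size (positive).
#' @return sorted integer vector of strong-set indices.
#' @export
screen_strong_set <- function(stats, active_set = integer(0), M) {
  if (M <= 0) stop("screening batch size M must be positive")
  p <- length(stats)
  active_set <- as.integer(active_set)
  if (length(active_set) >= p) return(sort(unique(active_set)))
  ord <- order(stats, seq_len(p), decreasing = c(TRUE, FALSE), method = "radix")
  cand <- ord[!(ord %in% active_set)]
  sort(unique(c(active_set, head(cand, M))))
}

#' KKT certification of candidate solutions
#'
#' Given the full-universe gradient statistics of each candidate solution
#' in a batch (computed by [sparse_inner_products()] in a single pass),
#' finds the longest prefix of the decreasing penalty batch whose
#' solutions are exact for the full problem: a solution at `lambda` passes
#' iff `stat_j < lambda * alpha * (1 + tolerance)` for every variant `j`
#' outside the strong set, where `stat_j = (1/n)|x_j^T r(lambda)| / c_j`.
#'
#' @param stats numeric matrix, `p x L`: screening statistics per variant
#'   (rows) and candidate penalty value (columns).
#' @param lambda the decreasing penalty values of the batch.
#' @param strong_set indices (rows of `stats`) fitted in memory.
#' @param alpha elastic-net mixing parameter (KKT threshold is
#'   `lambda * alpha`).
#' @param tolerance relative slack, see [basil_config()].
#' @return list with `pass` (logical per penalty), `n_passed` (length of
#'   the passing prefix), `lambda_bar_index` (equal to `n_passed`; 0
#'   signals total failure and triggers the batch-enlargement fallback),
#'   and `violations` (per failed penalty, the violating variant indices
#'   sorted by violation magnitude).
#' @export
kkt_check <- function(stats, lambda, strong_set, alpha = 1, tolerance = 1e-6) {
  stats <- as.matrix(stats)
  if (ncol(stats) != length(lambda))
    stop("stats columns must match the number of penalty values")
  outside <- setdiff(seq_len(nrow(stats)), strong_set)
  L <- length(lambda)
  pass <- logical(L)
  violations <- vector("list", L)
  for (l in seq_len(L)) {
    thr <- lambda[l] * alpha * (1 + tolerance)
    if (length(outside) == 0L) { pass[l] <- TRUE; next }
    v <- stats[outside, l]
    bad <- v >= thr
    pass[l] <- !any(bad)
    if (!pass[l])
      violations[[l]] <- outside[bad][order(v[bad], decreasing = TRUE)]
  }
  n_passed <- if (all(pass)) L else which(!pass)[1] - 1L
  list(pass = pass, n_passed = n_passed, lambda_bar_index = n_passed,
       violations = violations)
}

#' Heuristic initial screening batch size
#'
#' Sets the initial batch size to the number of variants whose screening
#' statistic exceeds the strong-rule threshold for the `target_index`-th
#' penalty value, `2 * lambda_target - lambda_1` -- i.e. large enough that
#' the first iteration can plausibly cover the first `target_index`
#' penalty values -- floored at `min_batch` and capped at the number of
#' variants.
#'
#' @param stats per-variant screening statistics at the covariate-only
#'   fit, on the same scale as `lambda` (divided by `alpha` and the
#'   penalty factors).
#' @param lambda the global penalty sequence.
#' @param target_index which penalty value the first iteration should
#'   reach (default 10).
#' @param min_batch lower bound on the returned size (default 1000).
#' @export
initial_batch_heuristic <- function(stats, lambda, target_index = 10L,
                                    min_batch = 1000L) {
  stopifnot(target_index >= 1L, target_index < length(lambda))
  thr <- 2 * lambda[target_index] - lambda[1]
  m <- sum(stats > thr)
  min(max(m, min_batch), length(stats))
}

#' Fit the full regularization path with batch screening
#'
#' The main driver. Iterates screening, in-memory strong-set fitting, and
#' full-data KKT certification until the penalty sequence is exhausted or
#' the validation metric stops improving. Every returned solution is exact
#' for the full variant universe: coefficients outside the strong set are
#' certified zero by the KKT condition. Exactly one sequential pass over
#' the on-disk genotypes is made per iteration; the same pass serves the
#' KKT check of the current batch and the screening of the next.
#'
#' QC statistics and imputation means are computed on the training samples
#' and reused for validation and prediction.
#'
#' @param store a [open_store()] handle.
#' @param phenotype numeric response aligned with the store's samples
#'   (observed times for `family = "cox"`).
#' @param covariates optional numeric matrix of unpenalized adjustment
#'   covariates (e.g. age, sex, principal components), `n_samples` rows.
#' @param status for the Cox family: event indicators, `TRUE`/1 = failure
#'   observed, `FALSE`/0 = right-censored.
#' @param train,validation disjoint sample index vectors; `train` defaults
#'   to all samples. Without a validation set no early stopping occurs and
#'   the whole path is fitted.
#' @param config a [basil_config()].
#' @param penalty_factor optional per-variant penalty multipliers over the
#'   full variant universe (must be positive; unpenalized adjustment
#'   variables belong in `covariates`).
#' @param relaxed also compute the relaxed (debiased) refit at each
#'   validated penalty value.
#' @param qc apply [qc_filter()] with the thresholds in `config`.
#' @param verbose print per-iteration progress.
#' @return An object of class `basil_path`; see [path_summary()],
#'   [predict.basil_path()], [coef.basil_path()].
#' @export
basil_fit <- function(store, phenotype, covariates = NULL, status = NULL,
                      train = NULL, validation = NULL,
                      config = basil_config(), penalty_factor = NULL,
                      relaxed = FALSE, qc = TRUE, verbose = FALSE) {
  stopifnot(inherits(store, "genotype_store"), inherits(config, "basil_config"))
  fam <- as_family(config$family)
  n <- store$n_samples
  if (length(phenotype) != n)
    stop("phenotype length (", length(phenotype),
         ") does not match the store's sample count (", n, ")")
  train <- if (is.null(train)) seq_len(n) else sort(as.integer(train))
  validation <- if (is.null(validation)) integer(0) else sort(as.integer(validation))
  if (length(intersect(train, validation)))
    stop("train and validation sample sets must be disjoint")
  if (fam$requires_status && is.null(status))
    stop("family 'cox' requires the status argument (TRUE = event observed)")
  Zall <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(Zall) && nrow(Zall) != n)
    stop("covariates must have one row per store sample")
  if (!is.null(Zall) && is.null(colnames(Zall)))
    colnames(Zall) <- paste0("covar", seq_len(ncol(Zall)))
  q <- if (is.null(Zall)) 0L else ncol(Zall)

  resp_of <- function(idx) {
    if (fam$name == "cox") survival_response(phenotype[idx], status[idx])
    else phenotype[idx]
  }
  y_tr <- resp_of(train)
  n_tr <- length(train)
  has_val <- length(validation) > 0L
  y_val <- if (has_val) resp_of(validation) else NULL
  Z_tr <- if (q) Zall[train, , drop = FALSE] else NULL
  Z_val <- if (q && has_val) Zall[validation, , drop = FALSE] else NULL

  ## QC and imputation on the training samples
  stats_all <- variant_stats(store, sample_idx = train)
  keep <- if (qc) qc_filter(stats_all, config$max_missing_rate, config$min_maf)
          else seq_len(store$n_variants)
  if (length(keep) == 0L) stop("no variants pass QC")
  impute <- stats_all$impute_value[keep]
  p <- length(keep)
  pf <- if (is.null(penalty_factor)) rep(1, p)
        else {
          stopifnot(length(penalty_factor) == store$n_variants)
          pfk <- penalty_factor[keep]
          if (any(pfk <= 0))
            stop("penalty factors must be positive; put unpenalized variables in covariates")
          pfk
        }
  grad_scale <- if (fam$name == "cox") 1 else 1 / n_tr

  ## covariate-only fit, initial residual and screening pass (pass 1)
  cov0 <- covariate_only_fit(Z_tr, y_tr, fam)
  r_full <- numeric(n); r_full[train] <- cov0$residual
  n_passes <- 1L
  raw0 <- abs(drop(sparse_inner_products(store, r_full, keep,
                                         config$chunk_size, impute))) * grad_scale
  screen_stat <- raw0 / pf
  alpha <- config$alpha_mix
  lambda_max <- max(screen_stat) / alpha
  lmr <- config$lambda_min_ratio %||% (if (p > n_tr) 0.01 else 1e-4)
  lambdas <- lambda_sequence(lambda_max, config$L, lmr)

  M <- config$batch_M %||%
    initial_batch_heuristic(screen_stat / alpha, lambdas,
                            min_batch = min(config$min_batch, p))
  delta_M <- config$delta_M %||% M
  lpi <- config$lambdas_per_iteration
  control <- solver_control(tol = config$tol, maxit = config$maxit)

  ## column cache over the keep-universe (all sample rows, training means)
  cache <- new.env(parent = emptyenv())
  cache$cols <- matrix(numeric(0), n, 0L)
  cache$idx <- integer(0)  # keep-universe positions of cached columns
  fetch_cols <- function(S) {
    need <- setdiff(S, cache$idx)
    if (length(need)) {
      blk <- load_block(store, keep[need], impute_values = impute[need])
      cache$cols <- cbind(cache$cols, blk)
      cache$idx <- c(cache$idx, need)
    }
    cache$cols[, match(S, cache$idx), drop = FALSE]
  }

  ever_active <- integer(0)
  S <- screen_strong_set(screen_stat, ever_active, M)
  pending <- seq_len(min(lpi, config$L))  # global lambda indices
  # start at the exact covariate-only solution: lambda_1 = lambda_max, so the
  # all-zero penalized block is already stationary there
  warm <- if (fam$name == "cox")
    list(beta = setNames(numeric(0), character(0)),
         gamma = unname(cov0$coefficients), b0 = 0)
  else
    list(beta = setNames(numeric(0), character(0)),
         gamma = unname(cov0$coefficients[-1]),
         b0 = unname(cov0$coefficients[1]))
  lambda_bar_global <- 0L  # global index of the last validated lambda

  val_beta <- list(); val_gamma <- list(); val_a0 <- numeric(0)
  val_idx <- integer(0); val_iter <- integer(0)
  val_train_metric <- numeric(0); val_val_metric <- numeric(0)
  relaxed_coefs <- list(); relaxed_val_metric <- numeric(0)
  best_metric <- -Inf; best_l <- NA_integer_; n_no_improve <- 0L
  early_stopped <- FALSE
  iter_log <- list()
  k <- 0L

  repeat {
    k <- k + 1L
    Xs_all <- fetch_cols(S)
    X_tr <- Xs_all[train, , drop = FALSE]
    warm_vec <- NULL
    if (!is.null(warm)) {
      b <- setNames(numeric(length(S)), as.character(S))
      common <- intersect(names(warm$beta), names(b))
      b[common] <- warm$beta[common]
      warm_vec <- list(beta = unname(b), gamma = warm$gamma, b0 = warm$b0)
    }
    fit <- fit_path_on_strong_set(
      X_tr, Z_tr, y_tr, fam,
      penalty_spec(alpha, lambdas[pending], pf[S], config$standardize),
      warm_start = warm_vec, control = control)

    ## one full-data pass: KKT stats for this batch, screening for the next
    G <- matrix(0, n, length(pending))
    for (l in seq_along(pending))
      G[train, l] <- fam$residual(y_tr, fit$linear_predictor[, l])
    raw <- abs(sparse_inner_products(store, G, keep, config$chunk_size,
                                     impute)) * grad_scale
    stat_mat <- raw / pf
    n_passes <- n_passes + 1L
    kkt <- kkt_check(stat_mat, lambdas[pending], S, alpha, config$kkt_tolerance)
    n_ok <- kkt$n_passed

    iter_log[[k]] <- data.frame(
      iteration = k, strong_size = length(S), M = M,
      n_pending = length(pending), n_validated = n_ok,
      lambda_bar_index = if (n_ok) pending[n_ok] else lambda_bar_global)
    if (verbose)
      message(sprintf("iter %d: |S|=%d M=%d pending=%d validated=%d",
                      k, length(S), M, length(pending), n_ok))

    if (n_ok == 0L) {
      ## total failure: enlarge the batch and re-screen from the residual
      ## at the last validated lambda (screen_stat is still that gradient)
      if (length(S) >= p)
        stop("KKT certification failed with the full variant set in memory")
      M <- M + delta_M
      S <- screen_strong_set(screen_stat, ever_active, M)
      next
    }

    for (l in seq_len(n_ok)) {
      gl <- pending[l]
      b <- fit$coefficients[, l]
      nz <- which(b != 0)
      val_beta[[length(val_beta) + 1L]] <- setNames(b[nz], as.character(S[nz]))
      val_gamma[[length(val_gamma) + 1L]] <- fit$covariate_coefficients[, l]
      val_a0 <- c(val_a0, fit$intercept[l])
      val_idx <- c(val_idx, gl)
      val_iter <- c(val_iter, k)
      val_train_metric <- c(val_train_metric,
                            eval_metric(fam, y_tr, fit$linear_predictor[, l]))
      act <- S[nz]
      ever_active <- union(ever_active, act)
      if (has_val) {
        eta_v <- rep(fit$intercept[l], length(validation))
        if (q) eta_v <- eta_v + drop(Z_val %*% fit$covariate_coefficients[, l])
        if (length(nz))
          eta_v <- eta_v + drop(Xs_all[validation, nz, drop = FALSE] %*% b[nz])
        mv <- eval_metric(fam, y_val, eta_v)
        val_val_metric <- c(val_val_metric, mv)
        if (mv > best_metric + 1e-12) {
          best_metric <- mv; best_l <- length(val_val_metric); n_no_improve <- 0L
        } else n_no_improve <- n_no_improve + 1L
      }
      if (relaxed) {
        rr_ok <- length(act) + q + 1L <= n_tr
        if (rr_ok) {
          rf <- relaxed_refit(X_tr[, nz, drop = FALSE], Z_tr, y_tr, fam)
          relaxed_coefs[[length(relaxed_coefs) + 1L]] <-
            list(intercept = rf$intercept,
                 covariate_coefficients = rf$covariate_coefficients,
                 beta = setNames(rf$active_coefficients, as.character(act)))
          if (has_val) {
            eta_v <- rep(rf$intercept, length(validation))
            if (q) eta_v <- eta_v + drop(Z_val %*% rf$covariate_coefficients)
            if (length(nz))
              eta_v <- eta_v +
                drop(Xs_all[validation, nz, drop = FALSE] %*% rf$active_coefficients)
            relaxed_val_metric <- c(relaxed_val_metric,
                                    eval_metric(fam, y_val, eta_v))
          }
        } else {
          relaxed_coefs[[length(relaxed_coefs) + 1L]] <- NULL
          if (has_val) relaxed_val_metric <- c(relaxed_val_metric, NA_real_)
        }
      }
      if (has_val && n_no_improve >= config$early_stop_patience) {
        early_stopped <- TRUE
        break
      }
    }

    lambda_bar_global <- val_idx[length(val_idx)]
    l_bar <- match(lambda_bar_global, pending)
    warm <- list(beta = setNames(fit$coefficients[, l_bar], as.character(S)),
                 gamma = fit$covariate_coefficients[, l_bar], b0 = fit$intercept[l_bar])
    screen_stat <- stat_mat[, l_bar]

    if (early_stopped || lambda_bar_global >= config$L) break
    remaining <- (lambda_bar_global + 1L):config$L
    pending <- head(remaining, lpi)
    S <- screen_strong_set(screen_stat, ever_active, M)
  }

  nv <- length(val_idx)
  beta_sparse <- Matrix::sparseMatrix(
    i = unlist(lapply(val_beta, function(b) as.integer(names(b)))),
    j = rep(seq_len(nv), vapply(val_beta, length, 1L)),
    x = unlist(lapply(val_beta, unname), use.names = FALSE),
    dims = c(p, nv),
    dimnames = list(store$variant_meta$variant_id[keep], NULL))
  gamma_mat <- if (q) do.call(cbind, val_gamma) else matrix(numeric(0), 0L, nv)
  if (q) rownames(gamma_mat) <- colnames(Zall)

  structure(list(
    family = fam$name, alpha = alpha,
    lambda = lambdas[val_idx], lambda_index = val_idx,
    lambda_sequence = lambdas,
    beta = beta_sparse, a0 = val_a0, gamma = gamma_mat,
    n_active = vapply(val_beta, length, 1L),
    train_metric = val_train_metric,
    validation_metric = if (has_val) val_val_metric else rep(NA_real_, nv),
    metric_name = metric_name(fam),
    best = if (has_val) best_l else NA_integer_,
    relaxed = if (relaxed) list(coefficients = relaxed_coefs,
                                validation_metric = relaxed_val_metric)
              else NULL,
    iteration = val_iter,
    keep = keep, variant_ids = store$variant_meta$variant_id[keep],
    impute = impute, penalty_factor = pf,
    train = train, validation = validation,
    n_full_passes = n_passes,
    iterations = do.call(rbind, iter_log),
    early_stopped = early_stopped,
    M_final = M,
    config = config,
    bed_path = store$bed_path
  ), class = "basil_path")
}

#' @exportS3Method base::print
print.basil_path <- function(x, ...) {
  cat(sprintf("basil_path (%s, alpha = %g): %d validated lambdas, %d iterations, %d full-data passes\n",
              x$family, x$alpha, length(x$lambda), nrow(x$iterations),
              x$n_full_passes))
  if (!is.na(x$best))
    cat(sprintf("best validation %s = %.4f at lambda index %d (%d active variants)\n",
                x$metric_name, x$validation_metric[x$best],
                x$lambda_index[x$best], x$n_active[x$best]))
  invisible(x)
}

#' Per-lambda path summary
#'
#' @param object a `basil_path`.
#' @return data.frame with one row per validated penalty value.
#' @export
path_summary <- function(object) {
  data.frame(lambda_index = object$lambda_index, lambda = object$lambda,
             n_active = object$n_active,
             train_metric = object$train_metric,
             validation_metric = object$validation_metric,
             kkt_pass = TRUE, iteration = object$iteration)
}

#' Extract path coefficients
#'
#' @param object a `basil_path`.
#' @param lambda_index `"best"`, `"all"`, or integer positions into the
#'   validated path.
#' @param ... unused.
#' @return list with `a0`, `gamma`, and the sparse variant coefficient
#'   matrix `beta` (variants x selected lambdas).
#' @export
coef.basil_path <- function(object, lambda_index = "all", ...) {
  sel <- resolve_lambda_sel(object, lambda_index)
  list(a0 = object$a0[sel],
       gamma = object$gamma[, sel, drop = FALSE],
       beta = object$beta[, sel, drop = FALSE])
}

resolve_lambda_sel <- function(object, lambda_index) {
  nv <- length(object$lambda)
  if (identical(lambda_index, "best")) {
    if (is.na(object$best))
      stop("no validation set was used; pass explicit lambda_index")
    return(object$best)
  }
  if (identical(lambda_index, "all")) return(seq_len(nv))
  sel <- as.integer(lambda_index)
  if (any(sel < 1L) || any(sel > nv))
    stop("lambda_index out of range 1..", nv)
  sel
}

#' Predict from a fitted BASIL path
#'
#' Computes per-sample predictions at one or more validated penalty
#' values. Missing genotypes are imputed with the training-set means
#' stored in the path object. The store's variant universe must contain
#' the model's variants (matched by variant id at the recorded positions).
#'
#' @param object a `basil_path`.
#' @param store a `genotype_store` (or a dense dosage matrix over the
#'   model's QC'd variant universe, `n x length(object$keep)`).
#' @param covariates covariate matrix aligned with the store's samples;
#'   required when the model was fit with covariates.
#' @param lambda_index `"best"` (default), `"all"`, or integer positions.
#' @param type `"link"` for the linear predictor; `"response"` applies the
#'   inverse link (probability for binomial, relative risk `exp(eta)` for
#'   Cox).
#' @param sample_idx optional subset of samples to predict for.
#' @param ... unused.
#' @return numeric matrix, samples x selected lambdas.
#' @export
predict.basil_path <- function(object, store, covariates = NULL,
                               lambda_index = "best",
                               type = c("link", "response"),
                               sample_idx = NULL, ...) {
  type <- match.arg(type)
  sel <- resolve_lambda_sel(object, lambda_index)
  beta <- object$beta[, sel, drop = FALSE]
  nzrow <- which(Matrix::rowSums(beta != 0) > 0)
  if (inherits(store, "genotype_store")) {
    ids <- store$variant_meta$variant_id[object$keep[nzrow]]
    missing_ids <- object$variant_ids[nzrow][ids != object$variant_ids[nzrow]]
    if (length(missing_ids))
      stop("store variant universe does not match the model; mismatched ids: ",
           paste(head(missing_ids, 5L), collapse = ", "))
    n <- store$n_samples
    X <- if (length(nzrow))
      load_block(store, object$keep[nzrow], impute_values = object$impute[nzrow])
    else matrix(numeric(0), n, 0L)
  } else {
    Xfull <- as.matrix(store)
    if (ncol(Xfull) != length(object$keep))
      stop("dense input must have one column per model variant (",
           length(object$keep), ")")
    n <- nrow(Xfull)
    X <- Xfull[, nzrow, drop = FALSE]
  }
  rows <- if (is.null(sample_idx)) seq_len(n) else as.integer(sample_idx)
  q <- nrow(object$gamma)
  if (q > 0L) {
    if (is.null(covariates))
      stop("the model was fit with covariates; supply them for prediction")
    Zm <- as.matrix(covariates)
    if (nrow(Zm) != n) stop("covariates must have one row per sample")
  }
  eta <- matrix(rep(object$a0[sel], each = length(rows)), length(rows))
  if (q > 0L)
    eta <- eta + Zm[rows, , drop = FALSE] %*% object$gamma[, sel, drop = FALSE]
  if (length(nzrow))
    eta <- eta + X[rows, , drop = FALSE] %*% beta[nzrow, , drop = FALSE]
  eta <- as.matrix(eta)
  if (type == "response")
    eta <- switch(object$family, gaussian = eta, binomial = plogis(eta),
                  cox = exp(eta))
  eta
}
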