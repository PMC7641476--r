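#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - gamma, 0)`, the scalar update at the heart of
#' coordinate descent for l1 penalties.
#'
#' @param z numeric.
#' @param gamma nonnegative threshold.
#' @export
soft_threshold <- function(z, gamma) {
  stopifnot(all(gamma >= 0))
  sign(z) * pmax(abs(z) - gamma, 0)
}

#' Elastic-net penalty specification
#'
#' @param alpha mixing parameter in `(0, 1]`: 1 is the lasso, values below
#'   1 add an l2 component that stabilizes groups of correlated variants.
#' @param lambda strictly decreasing positive penalty values.
#' @param penalty_factor nonnegative per-column multipliers `c_j` of the
#'   penalty (0 = unpenalized); recycled to the design at fit time when
#'   `NULL`. At least one factor must be positive.
#' @param standardize scale columns to unit variance before fitting and
#'   back-transform the coefficients. Defaults to `FALSE`: hard-call
#'   dosages already share the 0..2 scale, and standardization would
#'   inflate rare variants by shrinking their effective penalty.
#' @export
penalty_spec <- function(alpha = 1, lambda, penalty_factor = NULL,
                         standardize = FALSE) {
  stopifnot(alpha > 0, alpha <= 1, all(lambda > 0))
  if (length(lambda) > 1L && any(diff(lambda) >= 0))
    stop("lambda values must be strictly decreasing")
  if (!is.null(penalty_factor)) {
    stopifnot(all(penalty_factor >= 0))
    if (!any(penalty_factor > 0)) stop("at least one penalty_factor must be > 0")
  }
  structure(list(alpha = alpha, lambda = as.numeric(lambda),
                 penalty_factor = penalty_factor, standardize = standardize),
            class = "penalty_spec")
}

#' Solver control parameters
#'
#' @param tol coordinate-descent convergence: maximum absolute coefficient
#'   change per sweep, relative to `max(1, sd(working response))`.
#' @param maxit maximum coordinate-descent sweeps per penalty value.
#' @param irls_maxit maximum outer quadratic-approximation iterations for
#'   the binomial and Cox families.
#' @param irls_tol relative change in penalized objective declaring the
#'   outer loop converged.
#' @export
solver_control <- function(tol = 1e-7, maxit = 10000L, irls_maxit = 25L,
                           irls_tol = 1e-9) {
  list(tol = tol, maxit = as.integer(maxit),
       irls_maxit = as.integer(irls_maxit), irls_tol = irls_tol)
}

penalty_value <- function(beta, lambda, alpha, pf) {
  lambda * sum(pf * (alpha * abs(beta) + 0.5 * (1 - alpha) * beta^2))
}

response_n <- function(y) {
  if (inherits(y, "survival_response")) length(y$time) else length(y)
}

#' Fit the elastic-net path on an in-memory strong set
#'
#' Solves, for each penalty value `lambda` (warm-started from the previous
#' one),
#' `min f(b0, gamma, beta) + lambda * sum_j c_j (alpha |beta_j| + (1-alpha) beta_j^2 / 2)`
#' where `f` is the family loss, the intercept `b0` and the adjustment
#' covariates `Z` are never penalized, and `X` holds the screened
#' (mean-imputed) variant columns. The Gaussian family is solved by cyclic
#' coordinate descent; binomial and Cox wrap an outer quadratic
#' approximation (IRLS with step-halving on objective increase) around
#' weighted Gaussian coordinate descent.
#'
#' @param X dense numeric matrix of penalized columns (may have 0 columns).
#' @param Z covariate matrix or `NULL`.
#' @param y numeric response, or a [survival_response()] for `family = "cox"`.
#' @param family family name or [family_spec()].
#' @param penalty a [penalty_spec()].
#' @param warm_start optional list with `beta`, `gamma`, `b0` to initialize
#'   the first penalty value.
#' @param intercept include an unpenalized intercept (default `TRUE`;
#'   ignored for the Cox family, whose partial likelihood has none).
#' @param control a [solver_control()].
#' @return A `strong_fit` list: `coefficients` (`ncol(X) x L`),
#'   `covariate_coefficients`, `intercept`, `linear_predictor` (`n x L`),
#'   `converged`, `objective` (loss + penalty, per lambda),
#'   `objective_trace` (per-sweep surrogate objectives), `lambda`, `alpha`,
#'   `penalty_factor`.
#' @export
fit_path_on_strong_set <- function(X, Z = NULL, y, family = "gaussian",
                                   penalty, warm_start = NULL,
                                   intercept = TRUE,
                                   control = solver_control()) {
  fam <- as_family(family)
  n <- response_n(y)
  X <- as.matrix(X)
  if (nrow(X) != n && ncol(X) > 0L) stop("X row count differs from response")
  if (ncol(X) == 0L) X <- matrix(numeric(0), nrow = n, ncol = 0L)
  Zm <- if (is.null(Z)) matrix(numeric(0), n, 0L) else as.matrix(Z)
  if (nrow(Zm) != n) stop("Z row count differs from response")
  if (anyNA(X) || any(!is.finite(X))) stop("X contains non-finite values")
  if (anyNA(Zm) || any(!is.finite(Zm))) stop("Z contains non-finite values")
  p <- ncol(X); q <- ncol(Zm)
  lambda <- penalty$lambda
  alpha <- penalty$alpha
  pf <- penalty$penalty_factor %||% rep(1, p)
  if (length(pf) != p) stop("penalty_factor length differs from ncol(X)")
  if (p > 0L && !any(pf > 0)) stop("at least one penalty_factor must be > 0")

  col_scale <- rep(1, p)
  if (isTRUE(penalty$standardize) && p > 0L) {
    col_scale <- apply(X, 2L, function(x) sqrt(mean((x - mean(x))^2)))
    col_scale[col_scale <= 0] <- 1
    X <- sweep(X, 2L, col_scale, "/")
  }

  L <- length(lambda)
  beta <- matrix(0, p, L, dimnames = list(colnames(X), NULL))
  gamma <- matrix(0, q, L, dimnames = list(colnames(Zm), NULL))
  a0 <- numeric(L)
  eta <- matrix(0, n, L)
  converged <- logical(L)
  objective <- numeric(L)
  traces <- vector("list", L)

  cur_beta <- rep(0, p); cur_gamma <- rep(0, q); cur_b0 <- 0
  if (is.null(warm_start)) {
    # cold start at the covariate-only optimum, so that at lambda >= the
    # entry penalty the all-zero penalized block is already stationary
    cov0 <- covariate_only_fit(Zm, y, fam)
    if (fam$name == "cox") {
      if (q > 0L) cur_gamma <- unname(cov0$coefficients)
    } else {
      cur_b0 <- unname(cov0$coefficients[1])
      if (q > 0L) cur_gamma <- unname(cov0$coefficients[-1])
    }
  }
  if (!is.null(warm_start)) {
    if (!is.null(warm_start$beta)) {
      stopifnot(length(warm_start$beta) == p)
      cur_beta <- warm_start$beta * col_scale
    }
    if (!is.null(warm_start$gamma) && q > 0L) cur_gamma <- warm_start$gamma
    if (!is.null(warm_start$b0)) cur_b0 <- warm_start$b0
  }
  use_intercept <- isTRUE(intercept) && fam$has_intercept

  lin_pred <- function(b, g, b0) {
    e <- rep(if (use_intercept) b0 else 0, n)
    if (q > 0L) e <- e + drop(Zm %*% g)
    if (p > 0L) e <- e + drop(X %*% b)
    e
  }

  for (l in seq_len(L)) {
    lam <- lambda[l]
    if (fam$name == "gaussian") {
      w <- rep(1 / n, n)
      tolval <- control$tol * max(1, sd(y))
      fit <- cpp_cd_elnet(X, Zm, w, y, lam, alpha, pf,
                          cur_beta, cur_gamma, cur_b0, use_intercept,
                          tolval, control$maxit)
      cur_beta <- fit$beta; cur_gamma <- fit$gamma; cur_b0 <- fit$b0
      eta[, l] <- y - fit$residual
      converged[l] <- fit$converged
      traces[[l]] <- fit$objective_trace
      objective[l] <- fam$loss(y, eta[, l]) +
        penalty_value(cur_beta, lam, alpha, pf)
    } else {
      irls <- irls_solve(X, Zm, y, fam, lam, alpha, pf,
                         cur_beta, cur_gamma, cur_b0, use_intercept, control)
      cur_beta <- irls$beta; cur_gamma <- irls$gamma; cur_b0 <- irls$b0
      eta[, l] <- lin_pred(cur_beta, cur_gamma, cur_b0)
      converged[l] <- irls$converged
      traces[[l]] <- irls$objective_trace
      objective[l] <- irls$objective
    }
    beta[, l] <- cur_beta
    if (q > 0L) gamma[, l] <- cur_gamma
    a0[l] <- if (use_intercept) cur_b0 else 0
  }

  if (isTRUE(penalty$standardize) && p > 0L)
    beta <- beta / col_scale

  structure(list(coefficients = beta, covariate_coefficients = gamma,
                 intercept = a0, linear_predictor = eta,
                 converged = converged, objective = objective,
                 objective_trace = traces, lambda = lambda, alpha = alpha,
                 penalty_factor = pf, family = fam$name),
            class = "strong_fit")
}

# Outer quadratic-approximation loop for binomial/cox: at the current eta,
# form IRLS weights w and working response z so that the weighted Gaussian
# surrogate (1/2) sum w (z - eta)^2 shares gradient and (diagonal)
# curvature with the family loss, solve the penalized surrogate by
# coordinate descent, and step-halve if the true penalized objective rises.
irls_solve <- function(X, Zm, y, fam, lam, alpha, pf,
                       beta, gamma, b0, use_intercept, control) {
  n <- response_n(y)
  p <- ncol(X); q <- ncol(Zm)
  lin_pred <- function(b, g, b00) {
    e <- rep(if (use_intercept) b00 else 0, n)
    if (q > 0L) e <- e + drop(Zm %*% g)
    if (p > 0L) e <- e + drop(X %*% b)
    e
  }
  eta <- lin_pred(beta, gamma, b0)
  obj <- fam$loss(y, eta) + penalty_value(beta, lam, alpha, pf)
  trace <- obj
  converged <- FALSE
  inner_ok <- TRUE
  for (it in seq_len(control$irls_maxit)) {
    if (fam$name == "binomial") {
      pr <- plogis(eta)
      pr <- pmin(pmax(pr, 1e-5), 1 - 1e-5)
      w <- pr * (1 - pr) / n
      z <- eta + (y - pr) / (pr * (1 - pr))
    } else { # cox
      g <- cox_residual(y, eta)
      w <- pmax(cox_curvature(y, eta), 1e-10)
      z <- eta - g / w
    }
    tolval <- control$tol * max(1, sd(z))
    fit <- cpp_cd_elnet(X, Zm, w, z, lam, alpha, pf, beta, gamma, b0,
                        use_intercept, tolval, control$maxit)
    inner_ok <- inner_ok && fit$converged
    nb <- fit$beta; ng <- fit$gamma; nb0 <- fit$b0
    step <- 1
    repeat {
      tb <- beta + step * (nb - beta)
      tg <- if (q > 0L) gamma + step * (ng - gamma) else gamma
      tb0 <- b0 + step * (nb0 - b0)
      teta <- lin_pred(tb, tg, tb0)
      tobj <- fam$loss(y, teta) + penalty_value(tb, lam, alpha, pf)
      if (tobj <= obj + 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    if (tobj > obj + 1e-12) break  # no descent even with tiny step
    delta <- abs(obj - tobj)
    beta <- tb; gamma <- tg; b0 <- tb0; eta <- teta; obj <- tobj
    trace <- c(trace, obj)
    if (delta <= control$irls_tol * (abs(obj) + 1)) { converged <- TRUE; break }
  }
  list(beta = beta, gamma = gamma, b0 = b0, objective = obj,
       objective_trace = trace, converged = converged && inner_ok)
}

check_full_rank <- function(D) {
  dec <- qr(D)
  if (dec$rank < ncol(D)) {
    bad <- colnames(D)[dec$pivot[(dec$rank + 1L):ncol(D)]]
    stop("collinear columns in covariate/design matrix: ",
         paste(bad, collapse = ", "))
  }
}

#' Unpenalized covariate-only fit and initial residual
#'
#' Fits the family model on the intercept and adjustment covariates alone
#' and returns the family residual at that fit: the `r^(0)` that seeds the
#' penalty sequence and the first screening pass. With no covariates this
#' reduces to centering for the Gaussian family (`r^(0) = y - mean(y)`),
#' the base rate for the binomial family, and the null score for Cox.
#'
#' @param Z covariate matrix or `NULL`.
#' @param y response (or [survival_response()]).
#' @param family family name or [family_spec()].
#' @return list with `coefficients` (intercept first, except Cox),
#'   `eta`, and `residual`.
#' @export
covariate_only_fit <- function(Z, y, family = "gaussian") {
  fam <- as_family(family)
  n <- response_n(y)
  Zm <- if (is.null(Z)) matrix(numeric(0), n, 0L) else as.matrix(Z)
  if (nrow(Zm) != n) stop("Z row count differs from response")
  if (is.null(colnames(Zm)) && ncol(Zm) > 0L)
    colnames(Zm) <- paste0("covar", seq_len(ncol(Zm)))

  if (fam$name == "cox") {
    if (ncol(Zm) == 0L) {
      eta <- rep(0, n)
      cf <- numeric(0)
    } else {
      check_full_rank(Zm)
      sfit <- survival::coxph(
        survival::Surv(y$time, y$event) ~ Zm, ties = "breslow")
      cf <- unname(coef(sfit))
      names(cf) <- colnames(Zm)
      eta <- drop(Zm %*% cf)
    }
    return(list(coefficients = cf, eta = eta, residual = fam$residual(y, eta)))
  }

  D <- cbind(`(Intercept)` = rep(1, n), Zm)
  check_full_rank(D)
  if (fam$name == "gaussian") {
    fit <- lm.fit(D, y)
    cf <- fit$coefficients
  } else {
    fit <- suppressWarnings(glm.fit(D, y, family = binomial()))
    cf <- fit$coefficients
  }
  eta <- drop(D %*% cf)
  list(coefficients = cf, eta = eta, residual = fam$residual(y, eta))
}

#' Relaxed (debiased) refit on the active set
#'
#' Refits the family model without penalty on the intercept, the
#' adjustment covariates, and the active variant columns, undoing the
#' shrinkage of the penalized fit. Coefficients of inactive variants
#' remain exactly zero. Rank-deficient designs are resolved by dropping
#' the aliased columns (their coefficients are set to 0) with a warning.
#'
#' @param X_A dense matrix of active variant columns (may have 0 columns).
#' @param Z covariate matrix or `NULL`.
#' @param y response (or [survival_response()]).
#' @param family family name or [family_spec()].
#' @return list with `intercept`, `covariate_coefficients`,
#'   `active_coefficients`.
#' @export
relaxed_refit <- function(X_A, Z, y, family = "gaussian") {
  fam <- as_family(family)
  n <- response_n(y)
  X_A <- if (is.null(X_A)) matrix(numeric(0), n, 0L) else as.matrix(X_A)
  Zm <- if (is.null(Z)) matrix(numeric(0), n, 0L) else as.matrix(Z)
  q <- ncol(Zm); a <- ncol(X_A)
  if (a + q + 1L > n)
    stop("active set plus covariates exceed the sample size; cannot refit")
  if (a == 0L && fam$name != "cox") {
    base <- covariate_only_fit(Zm, y, fam)
    return(list(intercept = unname(base$coefficients[1]),
                covariate_coefficients = base$coefficients[-1],
                active_coefficients = numeric(0)))
  }
  if (fam$name == "cox") {
    D <- cbind(Zm, X_A)
    if (ncol(D) == 0L)
      return(list(intercept = 0, covariate_coefficients = numeric(0),
                  active_coefficients = numeric(0)))
    sfit <- survival::coxph(survival::Surv(y$time, y$event) ~ D,
                            ties = "breslow")
    cf <- unname(coef(sfit))
    if (anyNA(cf)) {
      warning("rank-deficient relaxed refit; aliased coefficients set to 0")
      cf[is.na(cf)] <- 0
    }
    return(list(intercept = 0,
                covariate_coefficients = if (q) cf[seq_len(q)] else numeric(0),
                active_coefficients = if (a) cf[q + seq_len(a)] else numeric(0)))
  }
  D <- cbind(`(Intercept)` = rep(1, n), Zm, X_A)
  fit <- if (fam$name == "gaussian") lm.fit(D, y)
         else suppressWarnings(glm.fit(D, y, family = binomial()))
  cf <- fit$coefficients
  if (anyNA(cf)) {
    warning("rank-deficient relaxed refit; aliased coefficients set to 0")
    cf[is.na(cf)] <- 0
  }
  list(intercept = unname(cf[1]),
       covariate_coefficients = if (q) cf[1 + seq_len(q)] else numeric(0),
       active_coefficients = if (a) unname(cf[1 + q + seq_len(a)]) else numeric(0))
}
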