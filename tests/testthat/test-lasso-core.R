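test_that("soft thresholding", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(-3, 1), -2)
})

test_that("single-variable fit matches the closed form", {
  set.seed(1)
  for (alpha in c(1, 0.5)) {
    for (rep in 1:5) {
      n <- 40
      x <- matrix(rnorm(n), n, 1)
      y <- rnorm(n)
      lam <- abs(sum(x * y) / n) * runif(1, 0.2, 0.9)
      fit <- fit_path_on_strong_set(x, NULL, y, "gaussian",
                                    penalty_spec(alpha, lam),
                                    intercept = FALSE,
                                    control = solver_control(tol = 1e-12))
      want <- soft_threshold(sum(x * y) / n, lam * alpha) /
        (sum(x^2) / n + lam * (1 - alpha))
      expect_lt(abs(fit$coefficients[1, 1] - want), 1e-10)
    }
  }
})

test_that("at lambda >= lambda_max all penalized coefficients are exactly zero", {
  set.seed(2)
  n <- 50; p <- 20
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  r0 <- y - mean(y)
  lam_max <- max(abs(crossprod(X, r0))) / n
  fit <- fit_path_on_strong_set(X, NULL, y, "gaussian",
                                penalty_spec(1, lam_max))
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept[1], mean(y))
})

test_that("gaussian solutions beat a proximal-gradient reference and satisfy KKT", {
  set.seed(3)
  n <- 60; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:3] %*% c(1, -1, 0.5)) + rnorm(n)
  lam_max <- max(abs(crossprod(X, y))) / n
  for (alpha in c(1, 0.5)) {
    lam <- lam_max * 0.3
    fit <- fit_path_on_strong_set(X, NULL, y, "gaussian",
                                  penalty_spec(alpha, lam),
                                  intercept = FALSE,
                                  control = solver_control(tol = 1e-12))
    b <- fit$coefficients[, 1]
    bref <- prox_lasso(X, y, lam, alpha)
    expect_lte(elnet_objective(X, y, b, lam, alpha),
               elnet_objective(X, y, bref, lam, alpha) + 1e-8)
    # KKT: |(1/n) x_j^T r - lam(1-a) b_j| = lam*a*sign(b_j) on the active set,
    # <= lam*a off it
    r <- y - X %*% b
    grad <- drop(crossprod(X, r)) / n - lam * (1 - alpha) * b
    expect_lt(max(abs(grad[b != 0] - lam * alpha * sign(b[b != 0]))), 1e-8)
    expect_lt(max(abs(grad[b == 0])), lam * alpha + 1e-8)
  }
})

test_that("path fits agree with glmnet for gaussian and binomial with covariates", {
  library(glmnet)
  set.seed(4)
  n <- 150; p <- 40
  X <- matrix(rnorm(n * p), n, p)
  Z <- cbind(age = rnorm(n), sexm = rbinom(n, 1, 0.5))
  eta <- drop(X[, 1:4] %*% c(1, -1, 0.8, -0.6)) + 0.5 * Z[, 1]
  for (family in c("gaussian", "binomial")) {
    y <- if (family == "gaussian") eta + rnorm(n) else rbinom(n, 1, plogis(eta))
    # glmnet applies the l2 term on an internally y-standardized scale;
    # compare on unit-variance y so both conventions coincide
    if (family == "gaussian") y <- y / sqrt(mean((y - mean(y))^2))
    r0 <- covariate_only_fit(Z, y, family)$residual
    lam_max <- max(abs(crossprod(X, r0))) / n
    lams <- lambda_sequence(lam_max, 20, 0.05)
    for (alpha in c(1, 0.5)) {
      fit <- fit_path_on_strong_set(X, Z, y, family,
                                    penalty_spec(alpha, lams / alpha),
                                    control = solver_control(tol = 1e-10))
      # glmnet rescales penalty factors to sum to nvars, making the
      # effective factor (p+2)/p on the penalized block; compensate by
      # shrinking lambda so the effective per-column penalty is c_j = 1
      g <- glmnet(cbind(Z, X), y, family = family, alpha = alpha,
                  lambda = lams / alpha * p / (p + 2), standardize = FALSE,
                  thresh = 1e-13, penalty.factor = c(0, 0, rep(1, p)))
      B <- as.matrix(g$beta)
      expect_lt(max(abs(fit$coefficients - B[-(1:2), ])), 2e-5)
      expect_lt(max(abs(fit$covariate_coefficients - B[1:2, ])), 2e-4)
      expect_lt(max(abs(fit$intercept - g$a0)), 2e-4)
    }
  }
})

test_that("objective is non-increasing over coordinate-descent sweeps", {
  set.seed(5)
  n <- 80; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  lams <- lambda_sequence(max(abs(crossprod(X, y - mean(y)))) / n, 10, 0.05)
  fit <- fit_path_on_strong_set(X, NULL, y, "gaussian", penalty_spec(1, lams))
  for (tr in fit$objective_trace)
    expect_true(all(diff(tr) <= 1e-12))
})

test_that("warm-started and cold path fits coincide", {
  set.seed(6)
  n <- 70; p <- 25
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:2] %*% c(1, -1)) + rnorm(n)
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / n
  lams <- c(lam_max * 0.5, lam_max * 0.2)
  ctl <- solver_control(tol = 1e-12)
  warm <- fit_path_on_strong_set(X, NULL, y, "gaussian",
                                 penalty_spec(1, lams), control = ctl)
  for (l in 1:2) {
    cold <- fit_path_on_strong_set(X, NULL, y, "gaussian",
                                   penalty_spec(1, lams[l]), control = ctl)
    expect_lt(max(abs(warm$coefficients[, l] - cold$coefficients[, 1])), 1e-8)
  }
})

test_that("unpenalized covariates are block-stationary at the solution", {
  set.seed(7)
  n <- 90; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  Z <- matrix(rnorm(n * 2), n, 2)
  y <- rnorm(n) + Z[, 1]
  lam <- max(abs(crossprod(X, y - mean(y)))) / n * 0.4
  fit <- fit_path_on_strong_set(X, Z, y, "gaussian", penalty_spec(1, lam),
                                control = solver_control(tol = 1e-12))
  # refit intercept + covariates by OLS with the penalized part fixed
  part <- y - drop(X %*% fit$coefficients[, 1])
  ols <- lm.fit(cbind(1, Z), part)$coefficients
  expect_lt(abs(ols[1] - fit$intercept[1]), 1e-8)
  expect_lt(max(abs(ols[-1] - fit$covariate_coefficients[, 1])), 1e-8)
})

test_that("covariate-only fits return the family residual at the null model", {
  expect_equal(covariate_only_fit(NULL, c(1, 2, 3), "gaussian")$residual,
               c(-1, 0, 1))
  set.seed(8)
  Z <- cbind(rbinom(40, 1, 0.5))
  y <- rnorm(40) + Z[, 1]
  r0 <- covariate_only_fit(Z, y, "gaussian")$residual
  expect_lt(abs(sum(r0)), 1e-10)
  expect_lt(abs(sum(r0 * Z[, 1])), 1e-10)

  yb <- rep(c(1, 0, 0, 0), 10)
  expect_equal(covariate_only_fit(NULL, yb, "binomial")$residual, yb - 0.25)

  Zc <- cbind(a = rnorm(40), b = rnorm(40))
  Zc <- cbind(Zc, c = Zc[, 1] + Zc[, 2])
  expect_error(covariate_only_fit(Zc, y, "gaussian"), "collinear.*c")
})

test_that("relaxed refit equals the normal-equations solution", {
  set.seed(9)
  n <- 60
  XA <- matrix(rnorm(n * 5), n, 5)
  Z <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("z1", "z2")))
  y <- rnorm(n)
  rf <- relaxed_refit(XA, Z, y, "gaussian")
  D <- cbind(1, Z, XA)
  want <- solve(crossprod(D), crossprod(D, y))
  expect_lt(abs(rf$intercept - want[1]), 1e-8)
  expect_lt(max(abs(rf$covariate_coefficients - want[2:3])), 1e-8)
  expect_lt(max(abs(rf$active_coefficients - want[4:8])), 1e-8)

  # orthonormal active columns, no covariates: coefficients are X^T y
  Q <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  yc <- y - mean(y)
  rfq <- relaxed_refit(Q, NULL, yc, "gaussian")
  # OLS with intercept on near-centered Q; compare against lm
  want2 <- lm.fit(cbind(1, Q), yc)$coefficients[-1]
  expect_lt(max(abs(rfq$active_coefficients - want2)), 1e-10)

  # empty active set reduces to the covariate-only fit
  rf0 <- relaxed_refit(NULL, Z, y, "gaussian")
  c0 <- covariate_only_fit(Z, y, "gaussian")$coefficients
  expect_equal(rf0$intercept, unname(c0[1]))
  expect_equal(unname(rf0$covariate_coefficients), unname(c0[-1]))
})

test_that("relaxed refit does not increase the in-sample loss", {
  set.seed(10)
  n <- 100; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:3] %*% c(1, -1, 2)) + rnorm(n)
  lam <- max(abs(crossprod(X, y - mean(y)))) / n * 0.3
  fit <- fit_path_on_strong_set(X, NULL, y, "gaussian", penalty_spec(1, lam))
  act <- which(fit$coefficients[, 1] != 0)
  rf <- relaxed_refit(X[, act, drop = FALSE], NULL, y, "gaussian")
  loss_lasso <- sum((y - fit$linear_predictor[, 1])^2)
  loss_relax <- sum((y - rf$intercept - X[, act] %*% rf$active_coefficients)^2)
  expect_lte(loss_relax, loss_lasso + 1e-10)
})

test_that("binomial and cox path fits reach family-specific stationary points", {
  set.seed(11)
  n <- 120; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  eta <- drop(X[, 1:2] %*% c(1.2, -1))
  # binomial: KKT at the solution, checked through the residual
  yb <- rbinom(n, 1, plogis(eta))
  r0 <- covariate_only_fit(NULL, yb, "binomial")$residual
  lam <- max(abs(crossprod(X, r0))) / n * 0.4
  fb <- fit_path_on_strong_set(X, NULL, yb, "binomial", penalty_spec(1, lam),
                               control = solver_control(tol = 1e-11))
  rb <- binomial_residual(yb, fb$linear_predictor[, 1])
  grad <- drop(crossprod(X, rb)) / n
  b <- fb$coefficients[, 1]
  expect_lt(max(abs(grad[b != 0] - lam * sign(b[b != 0]))), 1e-6)
  expect_lt(max(abs(grad[b == 0])), lam * (1 + 1e-6))
  # cox
  resp <- rand_survival(n, seed = 12)
  r0c <- cox_residual(resp, 0)
  lamc <- max(abs(crossprod(X, r0c))) * 0.4
  fc <- fit_path_on_strong_set(X, NULL, resp, "cox", penalty_spec(1, lamc),
                               control = solver_control(tol = 1e-11))
  gc <- cox_residual(resp, fc$linear_predictor[, 1])
  gradc <- abs(drop(crossprod(X, gc)))
  bc <- fc$coefficients[, 1]
  expect_lt(max(gradc[bc == 0]), lamc * (1 + 1e-6))
  if (any(bc != 0))
    expect_lt(max(abs(gradc[bc != 0] - lamc)), 1e-6)
})
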