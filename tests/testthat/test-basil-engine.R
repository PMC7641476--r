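test_that("lambda sequences are log-spaced from lambda_max", {
  expect_equal(lambda_sequence(1, 3, 0.01), c(1, 0.1, 0.01))
  expect_error(lambda_sequence(-1, 10, 0.01), "positive")
  # lambda_1 from the inner-product definition
  x <- c(1, -1); r0 <- c(1, -1)
  expect_equal(max(abs(sum(x * r0))) / 2, 1)
})

test_that("screening takes the top-M of the inactive complement, ties by index", {
  expect_equal(screen_strong_set(c(0.9, 0.1, 0.5, 0.7), active_set = 3, M = 2),
               c(1L, 3L, 4L))
  expect_equal(screen_strong_set(c(0.2, 0.2, 0.1), integer(0), M = 1), 1L)  # tie
  expect_equal(screen_strong_set(runif(5), integer(0), M = 10), 1:5)       # M >= p
  expect_equal(screen_strong_set(runif(5), 1:5, M = 2), 1:5)               # A = universe
  expect_error(screen_strong_set(runif(5), integer(0), M = 0), "positive")
})

test_that("kkt_check finds the passing prefix and reports violators", {
  lam <- c(0.5, 0.4, 0.3)
  stats <- matrix(0.01, 4, 3)
  stats[2, 3] <- 0.3 + 0.1  # variant 2 violates at lambda = 0.3
  out <- kkt_check(stats, lam, strong_set = c(1L), alpha = 1)
  expect_equal(out$pass, c(TRUE, TRUE, FALSE))
  expect_equal(out$n_passed, 2L)
  expect_equal(out$violations[[3]], 2L)
  # empty complement passes vacuously
  expect_equal(kkt_check(stats, lam, 1:4)$n_passed, 3L)
})

test_that("batch heuristic equals a direct count and is monotone", {
  set.seed(1)
  stats <- abs(rnorm(500))
  lam <- lambda_sequence(max(stats), 50, 0.01)
  for (ti in c(5, 10, 20)) {
    want <- sum(stats > 2 * lam[ti] - lam[1])
    expect_equal(initial_batch_heuristic(stats, lam, ti, min_batch = 1),
                 min(max(want, 1), 500))
  }
  ms <- vapply(2:30, function(ti)
    initial_batch_heuristic(stats, lam, ti, min_batch = 1), numeric(1))
  expect_true(all(diff(ms) >= 0))
  # at target 1 the threshold is lambda_max itself: count 0, floored
  expect_equal(initial_batch_heuristic(stats, lam, 1, min_batch = 17), 17)
})

make_sim <- function(n = 250, p = 400, seed = 21, family = "gaussian",
                     n_covariates = 0, h2 = 0.5, n_causal = 8) {
  spec <- simulation_spec(n_samples = n, n_variants = p, n_causal = n_causal,
                          heritability = h2, missing_rate = 0.02,
                          n_covariates = n_covariates, family = family,
                          seed = seed)
  simulate_dataset(spec, out_prefix = tempfile("eng"))
}

test_that("a single-batch run (p <= M) equals the plain in-memory path fit", {
  sim <- make_sim()
  st <- sim$store
  cfg <- basil_config(L = 20, lambda_min_ratio = 0.05, batch_M = 400,
                      lambdas_per_iteration = 20, tol = 1e-10)
  path <- basil_fit(st, sim$phenotype$y, config = cfg)
  expect_equal(nrow(path$iterations), 1L)
  expect_equal(path$n_full_passes, 2L)
  tr <- seq_len(st$n_samples)
  Xf <- load_block(st, seq_len(st$n_variants))
  direct <- fit_path_on_strong_set(Xf, NULL, sim$phenotype$y, "gaussian",
                                   penalty_spec(1, path$lambda),
                                   control = solver_control(tol = 1e-10))
  expect_lt(max(abs(as.matrix(path$beta) - direct$coefficients)), 1e-7)
})

test_that("the batched path matches the full-matrix fit and certifies KKT", {
  sim <- make_sim(n_covariates = 2)
  st <- sim$store
  y <- sim$phenotype$y; Z <- sim$phenotype$covariates
  cfg <- basil_config(L = 25, lambda_min_ratio = 0.05, batch_M = 40,
                      lambdas_per_iteration = 5, tol = 1e-10)
  path <- basil_fit(st, y, covariates = Z, config = cfg)
  expect_equal(length(path$lambda), 25L)
  Xf <- load_block(st, seq_len(st$n_variants))
  direct <- fit_path_on_strong_set(Xf, Z, y, "gaussian",
                                   penalty_spec(1, path$lambda),
                                   control = solver_control(tol = 1e-10))
  expect_lt(max(abs(as.matrix(path$beta) - direct$coefficients)), 1e-5)
  # full-universe KKT at every validated lambda
  B <- as.matrix(path$beta)
  eta <- matrix(path$a0, nrow(Xf), 25, byrow = TRUE) + Z %*% path$gamma + Xf %*% B
  for (l in seq_len(25)) {
    stat <- abs(crossprod(Xf, y - eta[, l])) / nrow(Xf)
    expect_lt(max(stat[B[, l] == 0, ]), path$lambda[l] * (1 + 1e-6))
  }
  # one full-data scan per outer iteration (including the initial screen)
  expect_equal(path$n_full_passes, nrow(path$iterations) + 1L)
})

test_that("the engine respects validation-based early stopping", {
  sim <- make_sim(n = 300, h2 = 0.4, seed = 5)
  st <- sim$store
  cfg <- basil_config(L = 100, batch_M = 50, lambdas_per_iteration = 10)
  path <- basil_fit(st, sim$phenotype$y, train = sim$split$train,
                    validation = sim$split$validation, config = cfg)
  expect_true(path$early_stopped)
  expect_lt(length(path$lambda), 100L)
  expect_false(is.na(path$best))
  expect_equal(path$validation_metric[path$best], max(path$validation_metric))
})

test_that("adversarial batching (M = 1, delta_M = 1) still completes exactly", {
  spec <- simulation_spec(n_samples = 120, n_variants = 50, n_causal = 5,
                          heritability = 0.6, missing_rate = 0, seed = 13)
  sim <- simulate_dataset(spec, out_prefix = tempfile("adv"))
  st <- sim$store
  cfg <- basil_config(L = 15, lambda_min_ratio = 0.05, batch_M = 1, delta_M = 1,
                      lambdas_per_iteration = 3, tol = 1e-10)
  path <- basil_fit(st, sim$phenotype$y, config = cfg)
  expect_equal(length(path$lambda), 15L)
  Xf <- load_block(st, seq_len(st$n_variants))
  y <- sim$phenotype$y
  B <- as.matrix(path$beta)
  for (l in seq_along(path$lambda)) {
    r <- y - path$a0[l] - Xf %*% B[, l]
    stat <- abs(crossprod(Xf, r)) / nrow(Xf)
    expect_lt(max(stat[B[, l] == 0, ]), path$lambda[l] * (1 + 1e-6))
  }
})

test_that("validated lambdas form a prefix of the global sequence", {
  sim <- make_sim(seed = 31)
  cfg <- basil_config(L = 30, batch_M = 30, lambdas_per_iteration = 4)
  path <- basil_fit(sim$store, sim$phenotype$y, train = sim$split$train,
                    validation = sim$split$validation, config = cfg)
  expect_equal(path$lambda_index, seq_along(path$lambda))
  expect_equal(path$lambda, path$lambda_sequence[path$lambda_index])
  expect_true(all(diff(path$lambda) < 0))
})

test_that("relaxed refits ride along the path and never lose in-sample", {
  sim <- make_sim(seed = 41, n = 200, p = 150)
  cfg <- basil_config(L = 15, lambda_min_ratio = 0.05, batch_M = 50,
                      lambdas_per_iteration = 5)
  path <- basil_fit(sim$store, sim$phenotype$y, config = cfg, relaxed = TRUE)
  expect_equal(length(path$relaxed$coefficients), length(path$lambda))
  l <- length(path$lambda)
  rc <- path$relaxed$coefficients[[l]]
  act <- as.integer(names(rc$beta))
  expect_equal(sort(act), sort(unname(which(as.matrix(path$beta)[, l] != 0))))
})

test_that("prediction matches a dense matrix-product oracle", {
  sim <- make_sim(seed = 51, n_covariates = 2)
  st <- sim$store
  y <- sim$phenotype$y; Z <- sim$phenotype$covariates
  cfg <- basil_config(L = 15, lambda_min_ratio = 0.05, batch_M = 100,
                      lambdas_per_iteration = 5)
  path <- basil_fit(st, y, covariates = Z, train = sim$split$train,
                    validation = sim$split$validation, config = cfg)
  sel <- length(path$lambda)
  pred <- predict(path, st, covariates = Z, lambda_index = sel)
  Xf <- load_block(st, path$keep, impute_values = path$impute)
  want <- path$a0[sel] + drop(Z %*% path$gamma[, sel]) +
    drop(Xf %*% as.matrix(path$beta)[, sel])
  expect_lt(max(abs(pred[, 1] - want)), 1e-10)
  # all-zero model predicts the intercept
  p1 <- predict(path, st, covariates = Z, lambda_index = 1)
  expect_lt(max(abs(p1 - (path$a0[1] + drop(Z %*% path$gamma[, 1])))), 1e-10)
  # binomial response transform
  expect_equal(plogis(pred), 1 / (1 + exp(-pred)))
})

test_that("alignment errors are raised for mismatched inputs", {
  sim <- make_sim(seed = 61)
  st <- sim$store
  expect_error(basil_fit(st, sim$phenotype$y[-1]), "does not match")
  expect_error(basil_fit(st, sim$phenotype$y, train = 1:100, validation = 90:120),
               "disjoint")
  expect_error(basil_fit(st, sim$phenotype$y,
                         config = basil_config(family = "cox")),
               "status")
})
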