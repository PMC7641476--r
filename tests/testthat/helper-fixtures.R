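# Shared fixture builders and independent oracles for the test suite.

# random dosage matrix over {0, 1, 2, NA}
rand_dosage <- function(n, p, missing_rate = 0.05, seed = 1) {
  set.seed(seed)
  maf <- runif(p, 0.05, 0.5)
  d <- matrix(rbinom(n * p, 2, rep(maf, each = n)), n, p)
  storage.mode(d) <- "double"
  if (missing_rate > 0) d[matrix(runif(n * p) < missing_rate, n, p)] <- NA
  d
}

# write a dosage matrix to a temporary PLINK fileset and open it
fixture_store <- function(dosage, ...) {
  prefix <- tempfile("fix")
  write_plink_fixture(dosage, prefix, ...)
  open_store(prefix)
}

# dense column-mean imputation (the oracle counterpart of load_block)
dense_impute <- function(dosage) {
  apply(dosage, 2, function(x) {
    m <- mean(x, na.rm = TRUE)
    x[is.na(x)] <- if (is.nan(m)) 0 else m
    x
  })
}

# central finite-difference gradient of a scalar function
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# proximal-gradient (ISTA) reference for the interceptless Gaussian
# elastic net: min 1/(2n)||y - Xb||^2 + lambda(a||b||_1 + (1-a)||b||^2/2)
prox_lasso <- function(X, y, lambda, alpha = 1, maxit = 200000, tol = 1e-12) {
  n <- nrow(X)
  L <- max(eigen(crossprod(X) / n, symmetric = TRUE, only.values = TRUE)$values) +
    lambda * (1 - alpha)
  b <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    g <- crossprod(X, X %*% b - y) / n + lambda * (1 - alpha) * b
    bn <- soft_threshold(b - g / L, lambda * alpha / L)
    if (max(abs(bn - b)) < tol) { b <- bn; break }
    b <- bn
  }
  b
}

elnet_objective <- function(X, y, b, lambda, alpha) {
  sum((y - X %*% b)^2) / (2 * nrow(X)) +
    lambda * sum(alpha * abs(b) + (1 - alpha) / 2 * b^2)
}

# exhaustive O(m*n) AUC by pair enumeration (ties count 1/2)
auc_bruteforce <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# random survival data with tied event times
rand_survival <- function(n, seed, tie_prob = 0.5) {
  set.seed(seed)
  tm <- sample(1:ceiling(n * (1 - tie_prob)), n, replace = TRUE) +
    runif(n) * 0  # integer times force ties
  ev <- runif(n) < 0.7
  if (!any(ev)) ev[1] <- TRUE
  survival_response(tm, ev)
}
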