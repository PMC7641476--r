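#' Model families for penalized genotype regression
#'
#' A family bundles the convex loss `f` and the residual-like vector `g`
#' with `grad_beta f = X^T g`, which drives both batch screening and the
#' KKT check. Losses are scaled so the penalty sequence is sample-size
#' stable: Gaussian `1/(2n) * RSS`, binomial `1/n` times the negative
#' Bernoulli log-likelihood, Cox `1/m` times the negative log partial
#' likelihood (`m` = number of events).
#'
#' @param name one of `"gaussian"`, `"binomial"`, `"cox"`.
#' @return a `family_spec` list with elements `name`, `requires_status`,
#'   and functions `residual(y, eta)`, `loss(y, eta)`.
#' @export
family_spec <- function(name = c("gaussian", "binomial", "cox")) {
  name <- match.arg(name)
  spec <- switch(name,
    gaussian = list(
      residual = function(y, eta) gaussian_residual(y, eta),
      loss = function(y, eta) sum((y - eta)^2) / (2 * length(y)),
      requires_status = FALSE, has_intercept = TRUE),
    binomial = list(
      residual = function(y, eta) binomial_residual(y, eta),
      loss = function(y, eta) {
        # -loglik_i = log(1 + exp(eta)) - y * eta, computed stably
        mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
      },
      requires_status = FALSE, has_intercept = TRUE),
    cox = list(
      residual = function(y, eta) cox_residual(y, eta),
      loss = function(y, eta) cox_neg_log_partial_likelihood(y, eta),
      requires_status = TRUE, has_intercept = FALSE))
  structure(c(list(name = name), spec), class = "family_spec")
}

as_family <- function(family) {
  if (inherits(family, "family_spec")) family else family_spec(family)
}

#' Gaussian residual
#'
#' Returns `y - eta`. The screening/KKT statistic of variant `j` is
#' `(1/n) |x_j^T (y - eta)|`.
#'
#' @param y numeric response.
#' @param eta linear predictor (recycled scalar allowed).
#' @export
gaussian_residual <- function(y, eta = 0) {
  if (length(eta) == 1L) eta <- rep(eta, length(y))
  if (length(y) != length(eta)) stop("y and eta lengths differ")
  y - eta
}

#' Binomial residual
#'
#' Returns `y - p` with `p = plogis(eta)`, the gradient-generating vector
#' of the (per-n) negative Bernoulli log-likelihood.
#'
#' @param y 0/1 response.
#' @param eta linear predictor.
#' @export
binomial_residual <- function(y, eta = 0) {
  if (length(eta) == 1L) eta <- rep(eta, length(y))
  if (length(y) != length(eta)) stop("y and eta lengths differ")
  if (!all(y %in% c(0, 1))) stop("binomial response must be 0/1")
  y - plogis(eta)
}

#' Right-censored survival response
#'
#' Packages observed times and event indicators for the Cox family.
#' `event = TRUE` means the failure was observed; `event = FALSE` means the
#' observation was right-censored. Note that some datasets code censoring
#' with an indicator `delta` where `delta = 0` marks failure; map such data
#' with `event = (delta == 0)` at ingestion.
#'
#' @param time positive observation times.
#' @param event logical (or 0/1) event indicators; `TRUE` = failure.
#' @export
survival_response <- function(time, event) {
  time <- as.numeric(time)
  event <- as.logical(event)
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) stop("times must be strictly positive")
  if (anyNA(event)) stop("event indicators must not be NA")
  if (!any(event)) stop("degenerate survival response: no events observed")
  structure(list(time = time, event = event), class = "survival_response")
}

# Risk-set bookkeeping shared by the Cox loss, residual and curvature.
# Ties are handled with the Breslow convention: tied events share the risk
# set taken at their common time. Returns, per sample i (original order):
#   d       event indicator (0/1)
#   chaz    sum over unique event times t_k <= time_i of d_k / S_k
#   chaz2   same with d_k / S_k^2
#   logS    per event: log S at its event time (for the loss)
# where S_k = sum_{j : time_j >= t_k} exp(eta_j) and m = total events.
cox_parts <- function(response, eta) {
  stopifnot(inherits(response, "survival_response"))
  n <- length(response$time)
  if (length(eta) == 1L) eta <- rep(eta, n)
  if (length(eta) != n) stop("eta length differs from response")
  o <- order(response$time)
  tt <- response$time[o]
  dd <- as.numeric(response$event[o])
  ee <- exp(eta[o])
  # suffix sums of exp(eta) over the time-sorted samples
  suffix <- rev(cumsum(rev(ee)))
  grp <- cumsum(!duplicated(tt))             # tie group id, ascending time
  first <- which(!duplicated(tt))            # first index of each group
  S_grp <- suffix[first]                     # risk-set sum at each unique time
  d_grp <- as.numeric(rowsum(dd, grp))       # events per unique time
  ev <- d_grp > 0
  # cumulative hazard increments up to and including each sample's time
  inc1 <- ifelse(ev, d_grp / S_grp, 0)
  inc2 <- ifelse(ev, d_grp / S_grp^2, 0)
  chaz_grp <- cumsum(inc1)
  chaz2_grp <- cumsum(inc2)
  m <- sum(dd)
  out_chaz <- numeric(n); out_chaz2 <- numeric(n)
  out_chaz[o] <- chaz_grp[grp]
  out_chaz2[o] <- chaz2_grp[grp]
  logS_sorted <- log(S_grp)[grp]
  loss <- -(sum(eta[o][dd > 0]) - sum(logS_sorted[dd > 0])) / m
  list(m = m, d = as.numeric(response$event), chaz = out_chaz,
       chaz2 = out_chaz2, loss = loss)
}

#' Cox negative log partial likelihood
#'
#' Evaluates `-(1/m) * sum_over_events (eta_i - log sum_{j in R_i} exp(eta_j))`
#' with `R_i` the risk set at event time `i` and `m` the number of events.
#' Tied event times use the Breslow convention (shared risk-set denominator).
#'
#' @param response a [survival_response()].
#' @param eta linear predictor.
#' @export
cox_neg_log_partial_likelihood <- function(response, eta = 0) {
  cox_parts(response, eta)$loss
}

#' Cox gradient-generating residual
#'
#' Returns the vector `g` with `grad_beta f = X^T g` exactly, where `f` is
#' [cox_neg_log_partial_likelihood()]:
#' `g_i = -(1/m) (event_i - exp(eta_i) * sum_{k: t_k <= y_i} d_k / S_k)`.
#' Screening and KKT checking use `|x_j^T g|`. The entries always sum to
#' zero (the score is orthogonal to the intercept direction), which is why
#' the Cox model carries no intercept.
#'
#' @inheritParams cox_neg_log_partial_likelihood
#' @export
cox_residual <- function(response, eta = 0) {
  pp <- cox_parts(response, eta)
  n <- length(response$time)
  if (length(eta) == 1L) eta <- rep(eta, n)
  -(pp$d - exp(eta) * pp$chaz) / pp$m
}

# Diagonal curvature of the Cox loss, used as IRLS weights.
cox_curvature <- function(response, eta) {
  pp <- cox_parts(response, eta)
  n <- length(response$time)
  if (length(eta) == 1L) eta <- rep(eta, n)
  ee <- exp(eta)
  (ee * pp$chaz - ee^2 * pp$chaz2) / pp$m
}
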