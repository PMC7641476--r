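#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2)`, with the total sum
#' of squares taken about the mean of `y` on the evaluated split. Can be
#' negative when the prediction does worse than the mean.
#'
#' @param y observed quantitative response.
#' @param prediction predicted values.
#' @export
r_squared <- function(y, prediction) {
  if (length(y) != length(prediction)) stop("y and prediction lengths differ")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("degenerate response: y is constant")
  1 - sum((y - prediction)^2) / ss_tot
}

#' Area under the ROC curve
#'
#' Computed exactly as the Mann-Whitney rank statistic
#' `(#{case score > control score} + 0.5 * #ties) / (m * n)`, which equals
#' trapezoidal integration of the ROC curve but is tie-exact and
#' `O(n log n)`.
#'
#' @param y 0/1 class labels (1 = case).
#' @param score real-valued classifier scores; any strictly increasing
#'   transformation gives the same AUC.
#' @export
auc <- function(y, score) {
  if (length(y) != length(score)) stop("y and score lengths differ")
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  m <- sum(y == 1); n0 <- sum(y == 0)
  if (m == 0 || n0 == 0) stop("degenerate response: both classes required")
  r <- rank(score)  # midranks handle ties
  (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n0)
}

#' Standard errors for the evaluation metrics
#'
#' For the AUC, the distribution-free upper bound
#' `sqrt(1 / (4 * min(m, n)))` with `m`, `n` the case and control counts.
#' For R-squared, a delta-method standard error from the influence
#' function of `1 - mean(e^2) / mean(d^2)`.
#'
#' @param y observed response (0/1 for `auc_se_bound`).
#' @param prediction predictions (only for `r_squared_se`).
#' @export
auc_se_bound <- function(y) {
  m <- sum(y == 1); n0 <- sum(y == 0)
  if (m == 0 || n0 == 0) stop("degenerate response: both classes required")
  sqrt(1 / (4 * min(m, n0)))
}

#' @rdname auc_se_bound
#' @export
r_squared_se <- function(y, prediction) {
  n <- length(y)
  e2 <- (y - prediction)^2
  d2 <- (y - mean(y))^2
  me <- mean(e2); md <- mean(d2)
  if (md == 0) stop("degenerate response: y is constant")
  infl <- -(e2 - me) / md + me * (d2 - md) / md^2
  sd(infl) / sqrt(n)
}

# Per-family validation metric; larger is better for all families
# (Cox uses the negated validation partial likelihood).
eval_metric <- function(fam, y, eta) {
  switch(fam$name,
         gaussian = r_squared(y, eta),
         binomial = auc(y, eta),
         cox = -cox_neg_log_partial_likelihood(y, eta))
}

metric_name <- function(fam) {
  switch(fam$name, gaussian = "r_squared", binomial = "auc",
         cox = "neg_log_partial_lik")
}
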