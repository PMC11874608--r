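# Statistical layer: lambda-weighted dependent-measures contrasts,
# Holm-Bonferroni correction, proportion of transfer, and the exponential
# learning-curve fit with its derivative-based learning rate.

#' Dependent-measures contrast test
#'
#' Tests a hypothesised pattern of change across repeated measures with a
#' single test. For each participant `i`, a contrast score
#' `L_i = sum_j x_ij * lambda_j` is computed with zero-sum weights; the test
#' statistic is `t = mean(L) / sqrt(var(L) / n)` on `n - 1` degrees of
#' freedom, with a two-sided p value. The standardized effect size is
#' `g = mean(L) / sd(L) = t / sqrt(n)`.
#'
#' @param data Matrix or data frame, participants in rows and conditions
#'   (e.g. sessions) in columns. No missing cells.
#' @param lambdas Numeric contrast weights, one per column, summing to zero.
#' @return An object of class `contrast_result` with fields `L_scores`,
#'   `L_mean`, `L_var`, `n`, `t`, `df`, `p`, `g`, `lambdas`.
#' @examples
#' x <- rbind(c(0.1, 0.5, 0.4), c(0.2, 0.6, 0.5), c(0.3, 0.6, 0.6))
#' contrast_test(x, lambda_weights("ya_action"))
#' @export
contrast_test <- function(data, lambdas) {
  x <- as.matrix(data)
  if (!is.numeric(x)) stop("data must be numeric")
  if (anyNA(x)) stop("no missing cells allowed")
  if (ncol(x) != length(lambdas)) {
    stop("need one lambda weight per column")
  }
  if (abs(sum(lambdas)) > 1e-8) stop("lambda weights must sum to zero")
  n <- nrow(x)
  if (n < 2) stop("need at least 2 participants")
  L <- as.vector(x %*% lambdas)
  L_mean <- mean(L)
  L_var <- stats::var(L)
  if (L_var <= 0 || !is.finite(L_var)) {
    stop("degenerate contrast: zero variance of the L scores")
  }
  t_stat <- L_mean / sqrt(L_var / n)
  df <- n - 1
  structure(list(L_scores = L, L_mean = L_mean, L_var = L_var, n = n,
                 t = t_stat, df = df,
                 p = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE),
                 g = L_mean / sqrt(L_var),
                 lambdas = lambdas),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> t(%d) = %.3f, p = %.4g, g = %.3f\n",
              x$df, x$t, x$p, x$g))
  cat("  lambdas:", paste(x$lambdas, collapse = ", "), "\n")
  invisible(x)
}

#' Standard contrast weights for the three assessment sessions
#'
#' The action patterns encode the learning-and-retention shapes observed at
#' the trained phase (Baseline, Post-training, Retention); the judgement
#' patterns are sign-reversed because improvement there is a *decrease* in
#' threshold.
#'
#' @param pattern One of `"ya_action"` (-3, 2, 1), `"oa_action"` (-2, 1, 1),
#'   `"ya_judgement"` (3, -2, -1), `"oa_judgement"` (2, -1, -1).
#' @return Numeric weight vector (sums to zero).
#' @export
lambda_weights <- function(pattern) {
  switch(pattern,
         ya_action = c(-3, 2, 1),
         oa_action = c(-2, 1, 1),
         ya_judgement = c(3, -2, -1),
         oa_judgement = c(2, -1, -1),
         stop("unknown pattern: ", pattern))
}

#' Holm-Bonferroni sequential correction
#'
#' Step-down multiple-testing correction over a family of p values: sorted
#' ascending, `p_(k)` is compared with `alpha / (m - k + 1)`, rejecting
#' until the first failure. Implemented via [stats::p.adjust()].
#'
#' @param p_values Named numeric vector of p values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Named logical vector: reject the null for this phase/test?
#'   Adjusted p values are attached as attribute `adjusted`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p values must be in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "holm")
  structure(adj <= alpha, adjusted = adj)
}

#' Proportion of transfer
#'
#' Change at each transfer phase from Baseline to Post-training divided by
#' the change at the trained (criterion) phase, as a signed fraction: 1 at
#' the criterion phase by definition, positive when performance moved the
#' same way as at the criterion phase.
#'
#' @param baseline,post Named numeric vectors of mean performance per phase
#'   (names are phases, e.g. `"60"`); same names in both.
#' @param criterion_phase Name of the trained phase (e.g. `"90"`).
#' @return An object of class `transfer_report`: the named proportion vector
#'   plus the criterion phase.
#' @examples
#' b <- c(`60` = 0.30, `90` = 0.20)
#' p <- c(`60` = 0.50, `90` = 0.61)
#' proportion_of_transfer(b, p, "90")
#' @export
proportion_of_transfer <- function(baseline, post, criterion_phase) {
  criterion_phase <- as.character(criterion_phase)
  if (!setequal(names(baseline), names(post))) {
    stop("baseline and post must cover the same phases")
  }
  if (!criterion_phase %in% names(baseline)) {
    stop("criterion phase not present in the data")
  }
  post <- post[names(baseline)]
  denom <- post[[criterion_phase]] - baseline[[criterion_phase]]
  if (denom == 0) stop("criterion phase did not change; proportion undefined")
  structure(list(proportion = (post - baseline) / denom,
                 criterion_phase = criterion_phase),
            class = "transfer_report")
}

#' @export
print.transfer_report <- function(x, ...) {
  cat(sprintf("<transfer_report> criterion phase %s\n", x$criterion_phase))
  print(round(x$proportion, 3))
  invisible(x)
}

#' Fit the exponential learning curve
#'
#' Fits `PTT20 = a * exp(-b / S)` to per-session mean performance by
#' bounded nonlinear least squares (`a` in `[0, 1.5]`, `b` in `[0, 20]`,
#' started at `a = max(session_means)`, `b = 1`), and reports the learning
#' rate as the first derivative of the fitted curve evaluated at the first
#' session, `a * b * exp(-b)`.
#'
#' @param session_means Ordered per-session mean scores, proportions in
#'   `[0, 1]`; at least 3 sessions.
#' @param session_index Session numbers (default `1..length(session_means)`,
#'   with 1 = Baseline).
#' @return An object of class `learning_fit` with fields `a`, `b`,
#'   `r_squared`, `session_means`, `session_index`, `fitted`, and
#'   `learning_rate_S1`.
#' @examples
#' s <- 1:10
#' fit_learning_curve(0.66 * exp(-1.1 / s))
#' @export
fit_learning_curve <- function(session_means,
                               session_index = seq_along(session_means)) {
  y <- as.numeric(session_means)
  S <- as.numeric(session_index)
  if (length(y) < 3) stop("need at least 3 sessions")
  if (length(S) != length(y)) stop("session_index must match session_means")
  if (any(!is.finite(y)) || any(y < 0) || any(y > 1)) {
    stop("session means must be proportions in [0, 1]")
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-b / S),
                      data = data.frame(y = y, S = S),
                      start = list(a = max(y), b = 1),
                      lower = c(0, 0), upper = c(1.5, 20)),
    error = function(e) {
      stop("learning-curve fit failed to converge: ", conditionMessage(e))
    })
  cf <- stats::coef(fit)
  a <- unname(cf["a"])
  b <- unname(cf["b"])
  resid <- y - a * exp(-b / S)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  structure(list(a = a, b = b, r_squared = r2,
                 session_means = y, session_index = S,
                 fitted = a * exp(-b / S),
                 learning_rate_S1 = learning_rate(a, b, 1)),
            class = "learning_fit")
}

#' @export
print.learning_fit <- function(x, ...) {
  cat(sprintf(
    "<learning_fit> a = %.4f, b = %.4f, r^2 = %.3f, learning rate (S=1) = %.4f\n",
    x$a, x$b, x$r_squared, x$learning_rate_S1))
  invisible(x)
}

#' Learning rate of the exponential session curve
#'
#' The first derivative of `a * exp(-b / S)` with respect to session,
#' `(a * b) / S^2 * exp(-b / S)`. Evaluated at `S = 1` this is the standard
#' learning-rate summary for this task.
#'
#' @param a,b Curve parameters.
#' @param S Session number, `> 0` (conventionally evaluated at 1).
#' @return The derivative value. Vectorised over `S`.
#' @examples
#' learning_rate(0.6599, 1.1, 1) # ~0.2416
#' @export
learning_rate <- function(a, b, S = 1) {
  if (any(!is.finite(c(a, b, S)))) stop("arguments must be finite")
  if (any(S <= 0)) stop("S must be positive")
  (a * b) / S^2 * exp(-b / S)
}
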