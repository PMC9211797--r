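#' Likelihood-ratio test of nested restrictions
#'
#' Tests extra equality/fixed-value restrictions against a base model:
#' both the base model (restrictions `base`) and the restricted model
#' (restrictions `base` plus `extra`) are fitted, and
#' \eqn{\Delta G^2 = G^2_{restricted} - G^2_{base}} is referred to the
#' central chi-square distribution with degrees of freedom equal to the
#' number of free parameters lost.  The associated effect size is Cohen's
#' \eqn{w = \sqrt{\Delta G^2 / N}} with \eqn{N} the total number of analyzed
#' responses.
#'
#' @param model An [mpt_model()].
#' @param data A frequency table.
#' @param base Restrictions defining the base model.
#' @param extra Additional restrictions to be tested (must be non-empty and
#'   actually reduce the number of free parameters).
#' @param N Total observation count used for the effect size; defaults to the
#'   sum of all counts.
#' @param name Optional label for the hypothesis.
#' @param ... Passed on to [fit_mpt()] (backend, starts, seed, control).
#' @return An object of class `mpt_lr_test` with `delta_G2`, `df`, `p`, `w`
#'   and the two component fits (`base_fit`, `restricted_fit`).
#' @export
lr_test <- function(model, data, base = list(), extra, N = NULL,
                    name = NULL, ...) {
  if (inherits(extra, "mpt_restriction")) extra <- list(extra)
  if (is.character(extra)) extra <- parse_restrictions(extra)
  if (inherits(base, "mpt_restriction")) base <- list(base)
  if (is.character(base)) base <- parse_restrictions(base)
  if (length(extra) == 0) stop("no extra restrictions to test")

  base_fit <- fit_mpt(model, data, restrictions = base, ...)
  restricted_fit <- fit_mpt(model, data, restrictions = c(base, extra), ...)
  df <- length(base_fit$free_params) - length(restricted_fit$free_params)
  if (df <= 0) {
    stop("extra restrictions do not reduce the free parameter count; ",
         "the models are not properly nested")
  }
  if (is.null(N)) N <- base_fit$N

  delta <- restricted_fit$G2 - base_fit$G2
  if (delta < -1e-6) {
    warning("restricted fit beat the base fit by ", format(-delta),
            "; check convergence")
  }
  delta <- max(delta, 0)
  structure(
    list(delta_G2 = delta, df = df,
         p = stats::pchisq(delta, df, lower.tail = FALSE),
         w = sqrt(delta / N), N = N, name = name,
         base_fit = base_fit, restricted_fit = restricted_fit),
    class = "mpt_lr_test"
  )
}

#' @export
print.mpt_lr_test <- function(x, ...) {
  if (!is.null(x$name)) cat("Hypothesis:", x$name, "\n")
  cat(sprintf("Delta G2(%d) = %.2f, p %s, w = %.2f\n", x$df, x$delta_G2,
              format_p(x$p), x$w))
  invisible(x)
}

format_p <- function(p) {
  if (p < .001) "< .001" else paste0("= ", sub("^0", "", sprintf("%.3f", p)))
}

#' Cohen's effect size w for chi-square statistics
#'
#' Converts a (delta) \eqn{G^2} statistic into Cohen's
#' \eqn{w = \sqrt{G^2 / N}}, the effect-size convention under which the
#' noncentrality parameter of the chi-square test is \eqn{\lambda = N w^2}.
#'
#' @param G2 Nonnegative chi-square / \eqn{G^2} statistic.
#' @param N Total observation count (> 0).
#' @return The effect size `w`.
#' @examples
#' effect_size_w(26.06, 17600)  # 0.04 at two decimals
#' @export
effect_size_w <- function(G2, N) {
  stopifnot(is.numeric(G2), G2 >= 0, is.numeric(N), N > 0)
  sqrt(G2 / N)
}

#' Power of the chi-square test at effect size w
#'
#' Power of an \eqn{\alpha}-level chi-square test with `df` degrees of
#' freedom against the alternative with effect size `w` at total sample size
#' `N`: the upper-tail probability of the noncentral chi-square distribution
#' with noncentrality \eqn{\lambda = N w^2} beyond the central critical
#' value.
#'
#' @param w Effect size (Cohen's w, >= 0).
#' @param N Total observation count.
#' @param df Degrees of freedom of the test.
#' @param alpha Significance level.
#' @return The power (a probability; equals `alpha` when `w = 0`).
#' @export
chi2_power <- function(w, N, df = 1, alpha = 0.05) {
  stopifnot(w >= 0, N > 0, df >= 1, alpha > 0, alpha < 1)
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = N * w^2, lower.tail = FALSE)
}

#' Noncentrality required for target power
#'
#' Root-finds the noncentrality parameter \eqn{\lambda^*} at which the
#' noncentral chi-square test with `df` degrees of freedom attains the target
#' power at level `alpha`.  For `df = 1`, `alpha = .05`, `power = .95` this
#' is approximately 12.995.
#'
#' @param df Degrees of freedom.
#' @param alpha Significance level.
#' @param power Target power, with `alpha < power < 1`.
#' @return The noncentrality \eqn{\lambda^*}.
#' @export
noncentrality_for_power <- function(df = 1, alpha = 0.05, power = 0.95) {
  stopifnot(alpha > 0, alpha < power, power < 1)
  crit <- stats::qchisq(1 - alpha, df)
  f <- function(lambda) {
    stats::pchisq(crit, df, ncp = lambda, lower.tail = FALSE) - power
  }
  upper <- 10
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}

#' Minimal detectable effect size (sensitivity analysis)
#'
#' The smallest effect size \eqn{w} that a chi-square test with `df` degrees
#' of freedom detects with the target power at level `alpha` given `N` total
#' observations, i.e. \eqn{w = \sqrt{\lambda^*/N}} with \eqn{\lambda^*} from
#' [noncentrality_for_power()].
#'
#' @inheritParams noncentrality_for_power
#' @param N Total observation count.
#' @return The minimal detectable `w`, with the underlying noncentrality in
#'   attribute `"lambda"`.
#' @examples
#' minimal_detectable_w(17600)  # about 0.027, i.e. 0.03 at two decimals
#' @export
minimal_detectable_w <- function(N, df = 1, alpha = 0.05, power = 0.95) {
  stopifnot(N > 0)
  lambda <- noncentrality_for_power(df = df, alpha = alpha, power = power)
  structure(sqrt(lambda / N), lambda = lambda)
}
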