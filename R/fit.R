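#' Maximum-likelihood estimation for MPT models
#'
#' Fits an MPT model to a frequency table by maximizing the
#' product-multinomial log-likelihood
#' \deqn{\ell(\theta) = \sum_{j} \sum_{c} n_{jc} \log p_{jc}(\theta),}
#' optionally after applying equality/fixed-value restrictions.  Two
#' interchangeable backends are provided: the classical MPT
#' expectation-maximization update on expected branch frequencies
#' (`backend = "em"`) and quasi-Newton (BFGS) maximization after a logit
#' transform of each free parameter (`backend = "optim"`).  Both use multiple
#' starting points (the parameter-space midpoint plus `n_starts` random
#' draws) and keep the best solution.
#'
#' Goodness of fit is the likelihood-ratio statistic
#' \eqn{G^2 = 2 \sum n_{jc} \log(n_{jc}/\hat n_{jc})} (with
#' \eqn{0 \log 0 := 0}) on \eqn{df = \sum_j (C_j - 1) - k} degrees of
#' freedom, where \eqn{k} is the number of free parameters; the p-value is
#' the upper-tail central chi-square probability (defined as 1 when
#' \eqn{df = 0}).
#'
#' @param model An [mpt_model()].
#' @param data A frequency table (see [frequency_table()]).
#' @param restrictions Restrictions applied before fitting (list of
#'   [restr_equate()] / [restr_fix()], a restriction string, or an
#'   `mpt_restricted` object).
#' @param backend `"em"` or `"optim"`.
#' @param n_starts Number of random starting points in addition to the
#'   midpoint start.
#' @param seed Integer seed for the random starts.
#' @param control List of optional settings: `tol` (log-likelihood
#'   improvement declaring EM convergence, default `1e-10`), `maxit`
#'   (default 20000 EM iterations / 500 BFGS iterations), `stage1_iters`
#'   (EM iterations spent on each start before the best start is polished,
#'   default 100).
#' @return An object of class `mpt_fit` with the reduced-space `estimates`,
#'   the `expanded` full-space parameter values, `se` (see
#'   [standard_errors()]), `loglik`, `G2`, `df`, `p`, a `converged` flag with
#'   `iterations`, and the fitted cell table `cells` (observed and expected
#'   counts).
#' @examples
#' fs <- build_four_states()
#' fx <- fixture_experiment1()
#' fit <- fit_mpt(fs$model, fx$data, restrictions = fx$base_restrictions,
#'                n_starts = 2)
#' round(fit$expanded, 2)
#' @export
fit_mpt <- function(model, data, restrictions = list(),
                    backend = c("em", "optim"), n_starts = 10,
                    seed = 20220621, control = list()) {
  backend <- match.arg(backend)
  red <- if (inherits(restrictions, "mpt_restricted")) restrictions
         else apply_restrictions(model, restrictions)
  compiled <- compile_mpt(red$model)
  counts <- align_counts(compiled, data)
  core <- fit_mle_core(compiled, counts, backend = backend,
                       n_starts = n_starts, seed = seed, control = control)

  estimates <- core$theta
  expanded <- expand_params(red, estimates)
  se <- tryCatch(
    se_from_information(compiled, counts, estimates),
    error = function(e) {
      warning("standard errors unavailable: ", conditionMessage(e))
      stats::setNames(rep(NA_real_, length(estimates)), names(estimates))
    })

  df <- sum(compiled$cats_per_tree - 1L) - length(estimates)
  p <- if (df > 0) stats::pchisq(core$G2, df, lower.tail = FALSE) else 1

  structure(
    list(estimates = estimates, expanded = expanded, se = se,
         se_expanded = expand_se(red, se),
         loglik = core$loglik, G2 = core$G2, df = df, p = p,
         converged = core$converged, iterations = core$iterations,
         backend = backend, n_starts = n_starts, seed = seed,
         free_params = red$free_params, restricted = red,
         cells = data.frame(tree = compiled$cells$tree,
                            category = compiled$cells$category,
                            observed = counts, expected = core$expected),
         N = sum(counts)),
    class = "mpt_fit"
  )
}

#' @export
print.mpt_fit <- function(x, digits = 3, ...) {
  cat("MPT maximum-likelihood fit (", x$backend, " backend)\n", sep = "")
  cat(sprintf("  G2(%d) = %.*f, p = %.3f, logLik = %.*f\n",
              x$df, digits, x$G2, x$p, digits, x$loglik))
  if (!x$converged) cat("  WARNING: optimization did not converge\n")
  est <- data.frame(estimate = round(x$estimates, digits),
                    se = round(x$se, digits))
  print(est)
  invisible(x)
}

# core fitting on a compiled reduced model and a numeric cell-count vector
fit_mle_core <- function(compiled, counts, backend = "em", n_starts = 10,
                         seed = 20220621, control = list()) {
  tol <- control$tol %||% 1e-10
  maxit <- control$maxit %||% if (backend == "em") 20000L else 500L
  stage1 <- control$stage1_iters %||% 100L
  np <- length(compiled$model$params)
  totals <- drop(rowsum(counts, compiled$tree_of_cell))
  total_of_cell <- totals[compiled$tree_of_cell]

  if (np == 0) {
    pc <- cell_probs(compiled, numeric(0))
    expected <- total_of_cell * pc
    return(list(theta = stats::setNames(numeric(0), character(0)),
                loglik = ll_of_probs(counts, pc), G2 = g2_stat(counts, expected),
                expected = expected, converged = TRUE, iterations = 0L))
  }

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  starts <- c(list(rep(0.5, np)),
              lapply(seq_len(max(0, n_starts)),
                     function(i) stats::runif(np, 0.05, 0.95)))

  if (backend == "em") {
    # stage 1: a short EM run from every start; stage 2: converge the best
    stage1_runs <- lapply(starts, function(s) {
      em_run(compiled, counts, s, maxit = stage1, tol = tol)
    })
    best <- stage1_runs[[which.max(vapply(stage1_runs, `[[`, numeric(1), "loglik"))]]
    run <- em_run(compiled, counts, best$theta, maxit = maxit, tol = tol)
    run$iterations <- run$iterations + best$iterations
  } else {
    runs <- lapply(starts, function(s) {
      bfgs_run(compiled, counts, s, maxit = maxit)
    })
    run <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
  }

  if (!run$converged) {
    warning("MPT fit did not converge after all starts; result is flagged")
  }
  theta <- stats::setNames(run$theta, compiled$model$params)
  pc <- cell_probs(compiled, theta)
  expected <- total_of_cell * pc
  list(theta = theta, loglik = ll_of_probs(counts, pc),
       G2 = g2_stat(counts, expected),
       expected = expected, converged = run$converged,
       iterations = run$iterations)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

EPS_BOUND <- 1e-8

ll_of_probs <- function(counts, pc) {
  pos <- counts > 0
  if (any(pos & pc <= 0)) return(-Inf)
  sum(counts[pos] * log(pc[pos]))
}

g2_stat <- function(counts, expected) {
  pos <- counts > 0
  if (any(pos & expected <= 0)) return(Inf)
  2 * sum(counts[pos] * log(counts[pos] / expected[pos]))
}

# One EM trajectory: E-step distributes each cell count over its branches in
# proportion to the branch probabilities; M-step is the closed-form update
# theta_s = E[#direct occurrences of s] / E[#occurrences of s].
em_run <- function(compiled, counts, theta, maxit, tol) {
  theta <- pmin(pmax(theta, EPS_BOUND), 1 - EPS_BOUND)
  AB <- compiled$A + compiled$B
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    pb <- branch_probs(compiled, theta)
    pc <- numeric(compiled$n_cells)
    agg <- rowsum(pb, compiled$branch_cell)
    pc[as.integer(rownames(agg))] <- agg
    ll <- ll_of_probs(counts, pc)
    if (is.finite(ll) && ll - ll_old < tol && it > 1) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    cellcount_b <- counts[compiled$branch_cell]
    cellprob_b <- pc[compiled$branch_cell]
    m <- ifelse(cellprob_b > 0, cellcount_b * pb / cellprob_b, 0)
    num <- drop(crossprod(compiled$A, m))
    den <- drop(crossprod(AB, m))
    theta <- ifelse(den > 0, num / den, theta)
    theta <- pmin(pmax(theta, EPS_BOUND), 1 - EPS_BOUND)
  }
  list(theta = theta, loglik = ll_old, converged = converged, iterations = it)
}

# negative log-likelihood and analytic gradient in logit space
bfgs_run <- function(compiled, counts, theta0, maxit) {
  eta0 <- stats::qlogis(pmin(pmax(theta0, 1e-6), 1 - 1e-6))
  nll <- function(eta) {
    theta <- stats::plogis(eta)
    theta <- pmin(pmax(theta, EPS_BOUND), 1 - EPS_BOUND)
    -ll_of_probs(counts, cell_probs(compiled, theta))
  }
  grad <- function(eta) {
    theta <- stats::plogis(eta)
    theta <- pmin(pmax(theta, EPS_BOUND), 1 - EPS_BOUND)
    -ll_gradient(compiled, counts, theta) * theta * (1 - theta)
  }
  res <- stats::optim(eta0, nll, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  theta <- pmin(pmax(stats::plogis(res$par), EPS_BOUND), 1 - EPS_BOUND)
  list(theta = theta, loglik = -res$value,
       converged = res$convergence == 0,
       iterations = unname(res$counts[1]))
}

# gradient of the log-likelihood in probability space
ll_gradient <- function(compiled, counts, theta) {
  pb <- branch_probs(compiled, theta)
  pc <- numeric(compiled$n_cells)
  agg <- rowsum(pb, compiled$branch_cell)
  pc[as.integer(rownames(agg))] <- agg
  w <- ifelse(pc[compiled$branch_cell] > 0,
              counts[compiled$branch_cell] / pc[compiled$branch_cell], 0) * pb
  drop(crossprod(compiled$A, w)) / theta -
    drop(crossprod(compiled$B, w)) / (1 - theta)
}

#' Standard errors from the observed Fisher information
#'
#' Computes per-parameter standard errors as the square roots of the diagonal
#' of the inverse observed Fisher information (the negative Hessian of the
#' log-likelihood) in the reduced parameter space.  Estimates on the boundary
#' of the unit interval — where the information matrix is undefined — are
#' reported as `NA` with a warning, as are all parameters when the
#' information matrix is singular.
#'
#' @param model An [mpt_model()].
#' @param data A frequency table.
#' @param estimates Named numeric vector of (reduced-space) MLEs.
#' @param restrictions Restrictions under which `estimates` were obtained.
#' @return Named numeric vector of standard errors (possibly `NA`).
#' @export
standard_errors <- function(model, data, estimates, restrictions = list()) {
  red <- if (inherits(restrictions, "mpt_restricted")) restrictions
         else apply_restrictions(model, restrictions)
  compiled <- compile_mpt(red$model)
  counts <- align_counts(compiled, data)
  se_from_information(compiled, counts, check_param_vector(red$model, estimates))
}

se_from_information <- function(compiled, counts, theta, boundary_tol = 1e-6) {
  np <- length(theta)
  if (np == 0) return(stats::setNames(numeric(0), character(0)))
  se <- stats::setNames(rep(NA_real_, np), names(theta))
  interior <- theta > boundary_tol & theta < 1 - boundary_tol
  if (!all(interior)) {
    warning("boundary estimate(s): ",
            paste(names(theta)[!interior], collapse = ", "),
            "; standard errors reported as NA")
  }
  if (!any(interior)) return(se)
  # observed information: finite differences of the analytic gradient
  h <- 1e-5
  H <- matrix(0, np, np)
  for (k in seq_len(np)) {
    tp <- theta; tm <- theta
    tp[k] <- min(theta[k] + h, 1 - EPS_BOUND)
    tm[k] <- max(theta[k] - h, EPS_BOUND)
    H[, k] <- (ll_gradient(compiled, counts, tp) -
                 ll_gradient(compiled, counts, tm)) / (tp[k] - tm[k])
  }
  H <- (H + t(H)) / 2
  info <- -H[interior, interior, drop = FALSE]
  inv <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(inv)) {
    warning("singular information matrix; standard errors reported as NA")
    return(se)
  }
  d <- diag(inv)
  d[d < 0] <- NA_real_
  se[interior] <- sqrt(d)
  se
}

expand_se <- function(restricted, se) {
  out <- vapply(restricted$map, function(m) {
    if (m$type == "fixed") NA_real_ else unname(se[m$source])
  }, numeric(1))
  stats::setNames(out, names(restricted$map))
}
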