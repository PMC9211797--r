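#' Specify a multinomial MPT simulation
#'
#' A simulation spec fixes everything a reproducible study needs: the model,
#' the generating parameter values, the per-tree response totals, the number
#' of replicates and the seed.  Sampling is pooled multinomial per tree —
#' the same homogeneity assumption the analysis model makes.
#'
#' @param model An [mpt_model()].
#' @param true_params Named numeric vector covering all model parameters.
#' @param tree_totals Named numeric vector of positive per-tree totals
#'   (names matching the model's trees), or a single total recycled to all
#'   trees.
#' @param reps Number of replicates (>= 1).
#' @param seed Integer master seed; each replicate derives its own stream
#'   from `(seed, rep_index)`.
#' @return An object of class `mpt_sim_spec`.
#' @export
simulation_spec <- function(model, true_params, tree_totals, reps = 1,
                            seed = 20220621) {
  true_params <- check_param_vector(model, true_params)
  if (length(tree_totals) == 1 && is.null(names(tree_totals))) {
    tree_totals <- stats::setNames(rep(tree_totals, length(model$trees)),
                                   names(model$trees))
  }
  missing <- setdiff(names(model$trees), names(tree_totals))
  if (length(missing)) {
    stop("missing tree total(s): ", paste(missing, collapse = ", "))
  }
  tree_totals <- tree_totals[names(model$trees)]
  stopifnot(all(tree_totals > 0), reps >= 1)
  structure(list(model = model, true_params = true_params,
                 tree_totals = tree_totals, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "mpt_sim_spec")
}

rep_seed <- function(seed, rep_index) {
  as.integer((as.double(seed) + 104729 * as.double(rep_index)) %% 2147483647)
}

#' Sample a frequency table from an MPT model
#'
#' Draws, independently for each tree, a multinomial sample of the tree's
#' total over its category probabilities at the generating parameter values.
#' The draw is a pure function of `(spec$seed, rep_index)`.
#'
#' @param spec An [simulation_spec()] object.
#' @param rep_index Replicate index (1-based).
#' @return A frequency table ([frequency_table()]).
#' @export
sample_frequencies <- function(spec, rep_index = 1) {
  stopifnot(inherits(spec, "mpt_sim_spec"), rep_index >= 1)
  probs <- category_probabilities(spec$model, spec$true_params)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(rep_seed(spec$seed, rep_index))
  rows <- lapply(names(spec$model$trees), function(tn) {
    counts <- drop(stats::rmultinom(1, spec$tree_totals[[tn]], probs[[tn]]))
    data.frame(tree = tn, category = names(probs[[tn]]), count = counts,
               stringsAsFactors = FALSE)
  })
  frequency_table(do.call(rbind, rows))
}

#' Parameter-recovery study
#'
#' Fits the (restricted) model to each simulated replicate and summarizes,
#' per free parameter, the mean estimate, bias, root-mean-square error and
#' the coverage of the Wald 95% interval (estimate +/- 1.96 SE) for the
#' generating value.  Replicates that fail to converge are excluded and
#' counted.
#'
#' @param spec A [simulation_spec()].
#' @param restrictions Restrictions under which each replicate is fitted;
#'   the generating parameter values must satisfy any equates for bias to be
#'   interpretable.
#' @param ... Passed to [fit_mpt()] (`backend`, `n_starts`, `seed` is taken
#'   from the spec per replicate).
#' @return An object of class `mpt_recovery`: a list with the per-parameter
#'   `summary` data frame, `n_reps`, `n_converged` and `n_excluded`.
#' @export
recovery_study <- function(spec, restrictions = list(), ...) {
  stopifnot(inherits(spec, "mpt_sim_spec"))
  red <- apply_restrictions(spec$model, restrictions)
  truth <- reduce_truth(red, spec$true_params)
  est <- matrix(NA_real_, spec$reps, length(truth),
                dimnames = list(NULL, names(truth)))
  ses <- est
  converged <- logical(spec$reps)
  for (i in seq_len(spec$reps)) {
    tab <- sample_frequencies(spec, i)
    fit <- suppressWarnings(
      fit_mpt(spec$model, tab, restrictions = red,
              seed = rep_seed(spec$seed, i), ...))
    converged[i] <- fit$converged
    if (fit$converged) {
      est[i, ] <- fit$estimates[names(truth)]
      ses[i, ] <- fit$se[names(truth)]
    }
  }
  use <- which(converged)
  cover <- colMeans(abs(est[use, , drop = FALSE] -
                          rep(truth, each = length(use))) <=
                      1.96 * ses[use, , drop = FALSE], na.rm = TRUE)
  mean_est <- colMeans(est[use, , drop = FALSE])
  bias <- mean_est - truth
  rmse <- sqrt(colMeans((est[use, , drop = FALSE] -
                           rep(truth, each = length(use)))^2))
  structure(
    list(summary = data.frame(param = names(truth), true = unname(truth),
                              mean_est = unname(mean_est),
                              bias = unname(bias), rmse = unname(rmse),
                              coverage = unname(cover),
                              stringsAsFactors = FALSE),
         n_reps = spec$reps, n_converged = length(use),
         n_excluded = spec$reps - length(use)),
    class = "mpt_recovery"
  )
}

#' @export
print.mpt_recovery <- function(x, digits = 4, ...) {
  cat("Parameter recovery over", x$n_converged, "of", x$n_reps,
      "replicates\n")
  s <- x$summary
  s[-1] <- lapply(s[-1], round, digits)
  print(s, row.names = FALSE)
  invisible(x)
}

# generating values mapped into the reduced space; errors if equated
# parameters disagree in the truth
reduce_truth <- function(restricted, true_params) {
  out <- stats::setNames(rep(NA_real_, length(restricted$free_params)),
                         restricted$free_params)
  for (p in names(restricted$map)) {
    m <- restricted$map[[p]]
    if (m$type != "free") next
    v <- unname(true_params[[p]])
    if (is.na(out[m$source])) out[m$source] <- v
    else if (abs(out[m$source] - v) > 1e-12) {
      stop("generating values violate the equate on '", m$source,
           "'; reduced-space truth is undefined")
    }
  }
  out
}

#' Empirical power of a nested likelihood-ratio test
#'
#' Simulates data from the generating parameters and records how often the
#' [lr_test()] of the extra restrictions rejects at level `alpha`.  With
#' generating values that satisfy the extra restrictions this estimates the
#' type-I error; otherwise the power.
#'
#' @param spec A [simulation_spec()].
#' @param base Restrictions of the base model.
#' @param extra Extra restrictions under test.
#' @param alpha Significance level.
#' @param ... Passed to [fit_mpt()] via [lr_test()].
#' @return A list of class `mpt_empirical_power` with the rejection `rate`,
#'   the replicate p-values, and convergence bookkeeping.
#' @export
empirical_power <- function(spec, base = list(), extra, alpha = 0.05, ...) {
  stopifnot(inherits(spec, "mpt_sim_spec"))
  pvals <- rep(NA_real_, spec$reps)
  ok <- logical(spec$reps)
  for (i in seq_len(spec$reps)) {
    tab <- sample_frequencies(spec, i)
    tst <- suppressWarnings(
      lr_test(spec$model, tab, base = base, extra = extra,
              N = sum(spec$tree_totals), seed = rep_seed(spec$seed, i), ...))
    ok[i] <- tst$base_fit$converged && tst$restricted_fit$converged
    if (ok[i]) pvals[i] <- tst$p
  }
  structure(list(rate = mean(pvals[ok] < alpha), alpha = alpha,
                 p_values = pvals, n_reps = spec$reps,
                 n_used = sum(ok), n_excluded = sum(!ok)),
            class = "mpt_empirical_power")
}

#' @export
print.mpt_empirical_power <- function(x, ...) {
  cat(sprintf("Empirical rejection rate at alpha = %.3g: %.3f (%d of %d replicates)\n",
              x$alpha, x$rate, x$n_used, x$n_reps))
  invisible(x)
}

#' Population effect size of a restriction violation
#'
#' Computes the population-level Cohen's w implied by generating parameter
#' values that violate a set of restrictions: the restricted model (base plus
#' extra restrictions) is fitted to the exact expected cell counts (an
#' "infinite-N" fit at the scenario's totals), its base-model counterpart
#' likewise, and the per-observation \eqn{\Delta G^2} is converted to
#' \eqn{w = \sqrt{\Delta G^2 / N}}.  This is the standard noncentrality
#' construction against which empirical power is compared.
#'
#' @param model An [mpt_model()].
#' @param true_params Named generating parameter values.
#' @param tree_totals Named per-tree totals of the scenario.
#' @param base Restrictions of the base model.
#' @param extra Extra restrictions whose violation carries the effect.
#' @param ... Passed to the internal fits.
#' @return The population `w`.
#' @export
population_w <- function(model, true_params, tree_totals, base = list(),
                         extra, ...) {
  true_params <- check_param_vector(model, true_params)
  probs <- category_probabilities(model, true_params)
  fit_expected <- function(restrictions) {
    red <- apply_restrictions(model, restrictions)
    compiled <- compile_mpt(red$model)
    expected <- unlist(lapply(seq_along(model$trees), function(i) {
      tn <- names(model$trees)[i]
      tree_totals[[tn]] * probs[[tn]]
    }), use.names = FALSE)
    fit_mle_core(compiled, expected, ...)
  }
  g2_base <- fit_expected(base)$G2
  g2_restricted <- fit_expected(c(base, extra))$G2
  sqrt(max(g2_restricted - g2_base, 0) / sum(unlist(tree_totals)))
}
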