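# scenario used throughout: the first experiment's base-model solution as the
# generating truth
exp1_generator <- function(reps, seed, truth_override = NULL) {
  fx <- fixture_experiment1()
  fit <- fit_mpt(fx$model, fx$data, fx$base_restrictions, n_starts = 2)
  truth <- fit$expanded
  if (!is.null(truth_override)) truth[names(truth_override)] <- truth_override
  list(fx = fx,
       spec = simulation_spec(fx$model, truth, tree_totals = 4400,
                              reps = reps, seed = seed),
       truth = truth)
}

test_that("multinomial sampling preserves totals and is reproducible", {
  g <- exp1_generator(reps = 3, seed = 101)
  tab1 <- sample_frequencies(g$spec, 1)
  expect_true(all(tree_totals(tab1) == 4400))
  expect_equal(as.data.frame(sample_frequencies(g$spec, 1)),
               as.data.frame(tab1))
  expect_false(identical(sample_frequencies(g$spec, 2)$count, tab1$count))
})

test_that("sampled proportions concentrate at the binomial rate", {
  # old tree with P(recollect) = .525 at total 10,000: 3 binomial SEs = .015
  fs <- build_four_states()
  theta <- example_params_fs()
  spec <- simulation_spec(fs$model, theta, tree_totals = 10000, reps = 40,
                          seed = 77)
  hits <- vapply(1:40, function(i) {
    tab <- sample_frequencies(spec, i)
    prop <- tab$count[tab$tree == "old_animate" & tab$category == "recollect"] / 10000
    abs(prop - .525) <= .015
  }, logical(1))
  expect_gte(mean(hits), 37 / 40)
})

test_that("recovery studies are reproducible and well calibrated", {
  g <- exp1_generator(reps = 1, seed = 55)
  r1 <- recovery_study(g$spec, restrictions = g$fx$base_restrictions,
                       n_starts = 1)
  r2 <- recovery_study(g$spec, restrictions = g$fx$base_restrictions,
                       n_starts = 1)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$n_converged, 1L)

  g <- exp1_generator(reps = 300, seed = 56)
  rec <- recovery_study(g$spec, restrictions = g$fx$base_restrictions,
                        backend = "optim", n_starts = 1)
  expect_true(all(rec$summary$rmse >= abs(rec$summary$bias)))
  # Wald 95% intervals cover interior truths at roughly nominal rate
  expect_true(all(rec$summary$coverage >= .90 & rec$summary$coverage <= .99))
})

test_that("recovery error shrinks as the per-tree totals grow", {
  fx <- fixture_experiment1()
  fit <- fit_mpt(fx$model, fx$data, fx$base_restrictions, n_starts = 2)
  err <- vapply(c(500, 4400), function(total) {
    spec <- simulation_spec(fx$model, fit$expanded, tree_totals = total,
                            reps = 60, seed = 99)
    rec <- recovery_study(spec, restrictions = fx$base_restrictions,
                          backend = "optim", n_starts = 1)
    mean(rec$summary$rmse)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("empirical power tracks the analytic noncentral chi-square curve", {
  fx <- fixture_experiment1()
  fit <- fit_mpt(fx$model, fx$data, fx$base_restrictions, n_starts = 2)
  truth0 <- fit$expanded
  rbar <- (truth0[["r_a"]] + truth0[["r_i"]]) / 2
  totals <- stats::setNames(rep(4400, 4), names(fx$model$trees))
  extra <- fx$hypotheses$recollection
  make_truth <- function(delta) {
    t <- truth0
    t[["r_a"]] <- rbar + delta
    t[["r_i"]] <- rbar - delta
    t
  }
  w_of_delta <- function(delta) {
    population_w(fx$model, make_truth(delta), totals,
                 base = fx$base_restrictions, extra = extra, n_starts = 0)
  }
  delta_for_w <- function(w) {
    if (w == 0) return(0)
    stats::uniroot(function(d) w_of_delta(d) - w, c(1e-4, .2),
                   tol = 1e-7)$root
  }

  reps <- 120
  rates <- analytic <- numeric(0)
  for (w in c(0, .02, .03, .05)) {
    truth <- make_truth(delta_for_w(w))
    spec <- simulation_spec(fx$model, truth, tree_totals = 4400,
                            reps = reps, seed = 400 + round(1000 * w))
    ep <- empirical_power(spec, base = fx$base_restrictions, extra = extra,
                          backend = "optim", n_starts = 1)
    target <- if (w == 0) .05 else chi2_power(w, 17600, df = 1, alpha = .05)
    mc3 <- 3 * sqrt(max(target * (1 - target), .05 * .95) / reps)
    expect_lt(abs(ep$rate - target), mc3)
    rates <- c(rates, ep$rate)
    analytic <- c(analytic, target)
  }
  # rejection rate non-decreasing in the size of the violation
  expect_true(all(diff(rates) >= -.05))
})

test_that("generating values that violate an equate are rejected for recovery", {
  fx <- fixture_experiment1()
  fit <- fit_mpt(fx$model, fx$data, fx$base_restrictions, n_starts = 1)
  spec <- simulation_spec(fx$model, fit$expanded, tree_totals = 100,
                          reps = 1, seed = 1)
  expect_error(
    recovery_study(spec, restrictions = c(fx$base_restrictions,
                                          fx$hypotheses$recollection),
                   n_starts = 1),
    "violate the equate"
  )
})
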