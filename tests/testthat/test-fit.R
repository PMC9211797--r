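test_that("the saturated model reproduces observed proportions with G2 ~ 0", {
  fx <- fixture_experiment1()
  fit <- fit_mpt(fx$model, fx$data, n_starts = 2)
  expect_lt(fit$G2, 1e-8)
  expect_identical(fit$df, 0L)
  expect_equal(fit$p, 1)
  obs_prop <- with(fit$cells, observed / ave(observed, tree, FUN = sum))
  fit_prop <- with(fit$cells, expected / ave(expected, tree, FUN = sum))
  expect_equal(fit_prop, obs_prop, tolerance = 1e-6)
})

test_that("estimates match an exhaustive grid search on a toy model", {
  m <- one_ht_model()
  tab <- one_ht_table()
  fit <- fit_mpt(m, tab, n_starts = 3)
  grid <- one_ht_grid_mle(tab)
  expect_equal(unname(fit$estimates[c("r", "g")]), unname(grid),
               tolerance = 2e-3)
  # closed form for these counts: g = 20/100, r solves .7 = r + (1-r) g
  expect_equal(unname(fit$estimates["g"]), .2, tolerance = 1e-6)
  expect_equal(unname(fit$estimates["r"]), .625, tolerance = 1e-6)
})

test_that("binomial standard errors equal the closed form and scale with N", {
  m <- binomial_model()
  fit <- fit_mpt(m, binomial_table(70, 30), n_starts = 1)
  expect_equal(unname(fit$se["p"]), sqrt(.7 * .3 / 100), tolerance = 1e-6)

  fit4 <- fit_mpt(m, binomial_table(280, 120), n_starts = 1)
  expect_equal(unname(fit4$se["p"] / fit$se["p"]), 0.5, tolerance = 1e-6)
})

test_that("EM and logit-space quasi-Newton backends agree", {
  fx1 <- fixture_experiment1()
  fx2 <- fixture_experiment2()
  for (fx in list(fx1, fx2)) {
    em <- fit_mpt(fx$model, fx$data, fx$base_restrictions,
                  backend = "em", n_starts = 3)
    qn <- fit_mpt(fx$model, fx$data, fx$base_restrictions,
                  backend = "optim", n_starts = 3)
    expect_lt(max(abs(em$estimates - qn$estimates[names(em$estimates)])), 1e-4)
    expect_equal(em$loglik, qn$loglik, tolerance = 1e-8)
  }
})

test_that("estimates are invariant to row order of the data and branch order", {
  fx <- fixture_experiment1()
  fit <- fit_mpt(fx$model, fx$data, fx$base_restrictions, n_starts = 2)

  shuffled <- fx$data[rev(seq_len(nrow(fx$data))), ]
  fit2 <- fit_mpt(fx$model, shuffled, fx$base_restrictions, n_starts = 2)
  expect_equal(fit$estimates, fit2$estimates, tolerance = 1e-10)

  perm <- rev(seq_along(fx$model$branches))
  m2 <- mpt_model(fx$model$params, fx$model$trees,
                  lapply(fx$model$branches[perm], function(b) {
                    list(tree = b$tree, category = b$category,
                         terms = data.frame(param = b$params,
                                            complement = b$comp))
                  }))
  fit3 <- fit_mpt(m2, fx$data, fx$base_restrictions, n_starts = 2)
  expect_equal(fit$estimates, fit3$estimates, tolerance = 1e-8)
})

test_that("zero observed cells follow the 0 log 0 convention", {
  m <- one_ht_model()
  tab <- frequency_table(data.frame(
    tree = c("old", "old", "new", "new"),
    category = c("hit", "miss", "fa", "cr"),
    count = c(100, 0, 20, 80)
  ))
  fit <- suppressWarnings(fit_mpt(m, tab, n_starts = 2))  # r at boundary
  expect_true(is.finite(fit$G2))
  expect_gte(fit$G2, 0)
})

test_that("boundary estimates yield NA standard errors with a warning", {
  m <- binomial_model()
  expect_warning(fit <- fit_mpt(m, binomial_table(100, 0), n_starts = 1),
                 "boundary")
  expect_true(is.na(fit$se["p"]))
})

test_that("model/data mismatches are rejected", {
  fx <- fixture_experiment1()
  bad <- fx$data
  bad$tree[1] <- "phantom_tree"
  expect_error(fit_mpt(fx$model, bad, n_starts = 1), "does not define")
  expect_error(fit_mpt(one_ht_model(),
                       binomial_table(1, 2), n_starts = 1),
               "does not define|no observations")
})

test_that("restricted fits never beat the unrestricted fit", {
  fx <- fixture_experiment1()
  sat <- fit_mpt(fx$model, fx$data, n_starts = 2)
  base <- fit_mpt(fx$model, fx$data, fx$base_restrictions, n_starts = 2)
  more <- fit_mpt(fx$model, fx$data,
                  c(fx$base_restrictions, fx$hypotheses$recollection),
                  n_starts = 2)
  expect_gte(base$G2, sat$G2 - 1e-6)
  expect_gte(more$G2, base$G2 - 1e-6)
})
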