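test_that("the four-states build has the published structure", {
  fs <- build_four_states()
  expect_length(fs$model$params, 12)
  expect_setequal(grep("_a$", fs$model$params, value = TRUE),
                  c("r_a", "f_a", "d_a", "gr_a", "gf_a", "gg_a"))
  expect_length(fs$model$trees, 4)
  expect_length(fs$model$branches, 22)

  data_df <- sum(vapply(fs$model$trees,
                        function(t) length(t$categories) - 1L, integer(1)))
  expect_identical(data_df, 12L)
  # saturated without restrictions, df 3 under the guessing equates
  expect_identical(data_df - length(fs$model$params), 0L)
  base <- apply_restrictions(fs$model, fs$base)
  expect_identical(data_df - length(base$free_params), 3L)
})

test_that("the process-dissociation build has the published structure", {
  pd <- build_pd_two_ht()
  expect_length(pd$model$params, 10)
  expect_length(pd$model$trees, 8)
  # analysis covers Phase-1 and new words only
  expect_true(all(grepl("^(inclusion|exclusion)_(old|new)_", names(pd$model$trees))))
  expect_true(all(vapply(pd$model$trees,
                         function(t) identical(t$categories, c("old", "new")),
                         logical(1))))

  alias <- apply_restrictions(pd$model, pd$rd_alias)
  expect_length(alias$free_params, 8)          # saturated: 8 free on 8 df
  base <- apply_restrictions(pd$model, pd$base)
  expect_identical(8L - length(base$free_params), 2L)
})

test_that("both built-in models are complete and the bases identified", {
  for (b in list(build_four_states(), build_pd_two_ht())) {
    expect_true(structural_check(b$model, n_points = 30, seed = 5)$pass)
    expect_true(identifiability_check(b$model, b$base, n_points = 3,
                                      seed = 5)$identified)
  }
})

test_that("largest-remainder reconstruction conserves the total", {
  expect_identical(reconstruct_counts(c(.53, .23, .06, .19), 4400),
                   c(2309L, 1002L, 261L, 828L))
  expect_identical(reconstruct_counts(c(.25, .25, .25, .25), 100),
                   rep(25L, 4))
  set.seed(8)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    p <- stats::runif(k)
    total <- sample(10:5000, 1)
    counts <- reconstruct_counts(p, total)
    expect_identical(sum(counts), as.integer(total))
    expect_true(all(counts >= 0))
  }
  expect_error(reconstruct_counts(c(0, 0), 10), "zero")
  expect_error(reconstruct_counts(c(-.1, 1.1), 10), "nonnegative")
})

test_that("experiment fixtures carry the design totals", {
  fx1 <- fixture_experiment1()
  expect_identical(nrow(fx1$data), 16L)
  expect_true(all(tree_totals(fx1$data) == 4400))
  expect_identical(fx1$N_total, 17600L)
  oi <- fx1$data[fx1$data$tree == "old_inanimate", ]
  expect_identical(oi$count, reconstruct_counts(c(.48, .25, .07, .20), 4400))

  fx2 <- fixture_experiment2()
  expect_identical(nrow(fx2$data), 16L)
  tot <- tree_totals(fx2$data)
  expect_true(all(tot[grepl("^inclusion", names(tot))] == 2106))
  expect_true(all(tot[grepl("^exclusion", names(tot))] == 2132))
  expect_identical(fx2$N_total, 16952L)
  ni <- fx2$data[fx2$data$tree == "exclusion_new_inanimate", ]
  expect_identical(ni$count, reconstruct_counts(c(.13, .87), 2132))
})

test_that("saturated fits reproduce the fixture proportions exactly", {
  for (fx in list(fixture_experiment1(), fixture_experiment2())) {
    fit <- fit_mpt(fx$model, fx$data, n_starts = 2)
    expect_lt(fit$G2, 1e-8)
    prop_hat <- with(fit$cells, expected / ave(expected, tree, FUN = sum))
    prop_obs <- with(fit$cells, observed / ave(observed, tree, FUN = sum))
    expect_equal(prop_hat, prop_obs, tolerance = 1e-6)
  }
})

test_that("the base fit stays within .01 of the fixture proportions per cell", {
  fx <- fixture_experiment1()
  fit <- fit_mpt(fx$model, fx$data, fx$base_restrictions, n_starts = 3)
  p <- category_probabilities(fx$model, fit$expanded)
  for (tn in rownames(fx$proportions)) {
    raw <- fx$proportions[tn, ]
    expect_lt(max(abs(p[[tn]][names(raw)] - raw / sum(raw))), .01)
  }
})

test_that("frequency CSV round-trips and rejects bad input", {
  fx <- fixture_experiment1()
  path <- withr::local_tempfile(fileext = ".csv")
  write_frequency_csv(fx$data, path)
  back <- read_frequency_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(fx$data))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tree,category,count", "t,a,5", "t,b,-3"), bad)
  expect_error(read_frequency_csv(bad), "row 2")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tree,category,count", "t,a,5", "t,a,2"), dup)
  expect_error(read_frequency_csv(dup), "duplicate")
})

test_that("shipped model and data files match the built-in constructors", {
  eqn1 <- system.file("extdata", "four_states.eqn", package = "mptmem")
  expect_true(mpt_structural_equal(read_eqn(eqn1), build_four_states()$model))
  eqn2 <- system.file("extdata", "pd_two_ht.eqn", package = "mptmem")
  expect_true(mpt_structural_equal(read_eqn(eqn2), build_pd_two_ht()$model))

  csv1 <- system.file("extdata", "exp1_counts.csv", package = "mptmem")
  expect_equal(as.data.frame(read_frequency_csv(csv1)),
               as.data.frame(fixture_experiment1()$data))
  csv2 <- system.file("extdata", "exp2_counts.csv", package = "mptmem")
  expect_equal(as.data.frame(read_frequency_csv(csv2)),
               as.data.frame(fixture_experiment2()$data))
})
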