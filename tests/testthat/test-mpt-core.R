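test_that("category probabilities equal hand-enumerated branch products", {
  fs <- build_four_states()
  # old-word tree: r + (1-r)(1-f)g_r, (1-r)f + (1-r)(1-f)(1-g_r)g_f, ...
  theta <- stats::setNames(rep(c(.5, .5, .6, .1, .3, .4), 2), fs$model$params)
  p <- category_probabilities(fs$model, theta)
  expect_equal(unname(p$old_animate),
               c(.525, .3175, .063, .0945), tolerance = 1e-12)
  expect_equal(sum(p$old_animate), 1, tolerance = 1e-12)

  # degenerate recollection: every old word yields detailed recollection
  theta["r_a"] <- 1
  p1 <- category_probabilities(fs$model, theta)
  expect_equal(unname(p1$old_animate[["recollect"]]), 1)

  # process-dissociation exclusion tree: (1-r)f + (1-r)(1-f)g_e for "old"
  pd <- build_pd_two_ht()
  th2 <- stats::setNames(rep(c(.5, .4, .3, .6, .2), 2), pd$model$params)
  p2 <- category_probabilities(pd$model, th2)
  expect_equal(unname(p2$exclusion_old_animate),
               c(.26, .74), tolerance = 1e-12)
})

test_that("missing parameter values are reported by name", {
  fs <- build_four_states()
  theta <- stats::setNames(rep(.5, 11), fs$model$params[-3])
  expect_error(category_probabilities(fs$model, theta), "d_a")
})

test_that("tree probabilities sum to one at random parameter points", {
  for (build in list(build_four_states, build_pd_two_ht)) {
    m <- build()$model
    chk <- structural_check(m, n_points = 50, seed = 3)
    expect_true(chk$pass)
    expect_lt(chk$max_abs_dev, 1e-12)
  }
})

test_that("structural check flags an incomplete tree and is deterministic", {
  broken <- mpt_model(
    params = "p",
    trees = list(flip = c("heads", "tails")),
    branches = list(list(tree = "flip", category = "heads", terms = "p"))
  )
  chk <- structural_check(broken, n_points = 20, seed = 9)
  expect_false(chk$pass)
  expect_identical(chk$failed_trees, "flip")
  chk2 <- structural_check(broken, n_points = 20, seed = 9)
  expect_identical(chk, chk2)
})

test_that("identifiability check recovers the known rank structure", {
  pd <- build_pd_two_ht()
  # 10 free parameters but only 8 independent category cells
  unres <- identifiability_check(pd$model, n_points = 3, seed = 2)
  expect_identical(unres$max_rank, 8L)
  expect_identical(unres$n_free, 10L)
  expect_false(unres$identified)

  fs <- build_four_states()
  sat <- identifiability_check(fs$model, n_points = 3, seed = 2)
  expect_identical(sat$max_rank, 12L)
  expect_true(sat$identified)

  bin <- identifiability_check(binomial_model(), n_points = 2, seed = 1)
  expect_identical(bin$max_rank, 1L)
})

test_that("branch and term order do not change probabilities", {
  fs <- build_four_states()
  theta <- example_params_fs()
  p0 <- category_probabilities(fs$model, theta)

  set.seed(4)
  perm <- sample(length(fs$model$branches))
  shuffled_branches <- lapply(fs$model$branches[perm], function(b) {
    tperm <- sample(length(b$params))
    list(tree = b$tree, category = b$category,
         terms = data.frame(param = b$params[tperm],
                            complement = b$comp[tperm]))
  })
  m2 <- mpt_model(fs$model$params, fs$model$trees, shuffled_branches)
  expect_equal(category_probabilities(m2, theta), p0, tolerance = 1e-14)
  expect_true(mpt_structural_equal(fs$model, m2))
})

test_that("model validation rejects dangling references", {
  expect_error(mpt_model("p", list(flip = c("a", "b")),
                         list(list(tree = "nope", category = "a", terms = "p"))),
               "unknown tree")
  expect_error(mpt_model("p", list(flip = c("a", "b")),
                         list(list(tree = "flip", category = "c", terms = "p"))),
               "unknown category")
  expect_error(mpt_model("p", list(flip = c("a", "b")),
                         list(list(tree = "flip", category = "a", terms = "q"))),
               "undeclared parameter")
  expect_error(mpt_model("p", list(flip = "a"), list()), "at least 2")
})
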