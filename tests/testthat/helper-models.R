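# Small models and tables shared across tests.

binomial_model <- function() {
  mpt_model(
    params = "p",
    trees = list(flip = c("heads", "tails")),
    branches = list(
      list(tree = "flip", category = "heads", terms = "p"),
      list(tree = "flip", category = "tails", terms = "(1-p)")
    )
  )
}

binomial_table <- function(heads, tails) {
  frequency_table(data.frame(tree = "flip",
                             category = c("heads", "tails"),
                             count = c(heads, tails)))
}

# one-high-threshold recognition model: old items are detected with
# probability r or guessed old with g; new items can only be guessed old
one_ht_model <- function() {
  mpt_model(
    params = c("r", "g"),
    trees = list(old = c("hit", "miss"), new = c("fa", "cr")),
    branches = list(
      list(tree = "old", category = "hit", terms = "r"),
      list(tree = "old", category = "hit", terms = "(1-r)*g"),
      list(tree = "old", category = "miss", terms = "(1-r)*(1-g)"),
      list(tree = "new", category = "fa", terms = "g"),
      list(tree = "new", category = "cr", terms = "(1-g)")
    )
  )
}

one_ht_table <- function() {
  frequency_table(data.frame(
    tree = c("old", "old", "new", "new"),
    category = c("hit", "miss", "fa", "cr"),
    count = c(70, 30, 20, 80)
  ))
}

# exhaustive grid-search MLE for the one-high-threshold model, step 1e-3
one_ht_grid_mle <- function(tab, step = 1e-3) {
  counts <- stats::setNames(tab$count, paste(tab$tree, tab$category))
  g <- seq(step, 1 - step, by = step)
  r <- seq(step, 1 - step, by = step)
  best <- c(r = NA, g = NA)
  best_ll <- -Inf
  for (ri in r) {
    p_hit <- ri + (1 - ri) * g
    ll <- counts[["old hit"]] * log(p_hit) +
      counts[["old miss"]] * log(1 - p_hit) +
      counts[["new fa"]] * log(g) +
      counts[["new cr"]] * log(1 - g)
    k <- which.max(ll)
    if (ll[k] > best_ll) {
      best_ll <- ll[k]
      best <- c(r = ri, g = g[k])
    }
  }
  best
}

example_params_fs <- function() {
  fs <- build_four_states()
  stats::setNames(rep(c(.5, .5, .6, .1, .3, .4), 2), fs$model$params)
}
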