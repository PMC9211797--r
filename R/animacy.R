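#' The four-states remember-know-guess model, duplicated over animacy
#'
#' Builds the four-states MPT model of recognition-memory retrieval
#' experiences with one set of trees for animate and one for inanimate words.
#' Each animacy set has an old-word tree and a new-word tree over the
#' categories `recollect` ("detailed recollection"), `familiar` ("feeling of
#' familiarity"), `guess` ("guessing") and `new`, governed by six parameters:
#' recollection `r`, conditional familiarity `f`, new-word detection `d`, and
#' the state-of-uncertainty guessing chain `g_r`, `g_f`, `g_g` (shared
#' between the old- and new-word trees of an animacy set).
#'
#' Restriction sets returned alongside the model:
#' \describe{
#'   \item{`base`}{the three guessing equates across animacy
#'     (\eqn{g_r, g_f, g_g}) that define the base model (3 model df).}
#'   \item{`hypotheses$recollection`}{equate `r` across animacy.}
#'   \item{`hypotheses$familiarity`}{equate `f` across animacy.}
#'   \item{`hypotheses$detection`}{equate `d` across animacy.}
#' }
#'
#' @return A list with elements `model`, `base` and `hypotheses`.
#' @export
build_four_states <- function() {
  suffixes <- c(animate = "a", inanimate = "i")
  params <- character(0)
  trees <- list()
  branches <- list()
  for (an in names(suffixes)) {
    s <- suffixes[[an]]
    r <- paste0("r_", s); f <- paste0("f_", s); d <- paste0("d_", s)
    gr <- paste0("gr_", s); gf <- paste0("gf_", s); gg <- paste0("gg_", s)
    params <- c(params, stats::setNames(
      c(paste("recollection,", an, "words"),
        paste("conditional familiarity,", an, "words"),
        paste("detection of new", an, "words"),
        paste("guess 'detailed recollection',", an, "words"),
        paste("guess 'feeling of familiarity',", an, "words"),
        paste("guess 'guessing',", an, "words")),
      c(r, f, d, gr, gf, gg)))
    cats <- c("recollect", "familiar", "guess", "new")
    old_tree <- paste0("old_", an)
    new_tree <- paste0("new_", an)
    trees[[old_tree]] <- list(name = old_tree, categories = cats,
                              item_type = paste("old", an))
    trees[[new_tree]] <- list(name = new_tree, categories = cats,
                              item_type = paste("new", an))
    b <- function(tree, category, terms) list(tree = tree, category = category,
                                              terms = terms)
    branches <- c(branches, list(
      b(old_tree, "recollect", r),
      b(old_tree, "familiar", sprintf("(1-%s)*%s", r, f)),
      b(old_tree, "recollect", sprintf("(1-%s)*(1-%s)*%s", r, f, gr)),
      b(old_tree, "familiar", sprintf("(1-%s)*(1-%s)*(1-%s)*%s", r, f, gr, gf)),
      b(old_tree, "guess",
        sprintf("(1-%s)*(1-%s)*(1-%s)*(1-%s)*%s", r, f, gr, gf, gg)),
      b(old_tree, "new",
        sprintf("(1-%s)*(1-%s)*(1-%s)*(1-%s)*(1-%s)", r, f, gr, gf, gg)),
      b(new_tree, "new", d),
      b(new_tree, "recollect", sprintf("(1-%s)*%s", d, gr)),
      b(new_tree, "familiar", sprintf("(1-%s)*(1-%s)*%s", d, gr, gf)),
      b(new_tree, "guess", sprintf("(1-%s)*(1-%s)*(1-%s)*%s", d, gr, gf, gg)),
      b(new_tree, "new", sprintf("(1-%s)*(1-%s)*(1-%s)*(1-%s)", d, gr, gf, gg))
    ))
  }
  model <- mpt_model(params, trees, branches)
  list(
    model = model,
    base = list(restr_equate("gr_a", "gr_i"),
                restr_equate("gf_a", "gf_i"),
                restr_equate("gg_a", "gg_i")),
    hypotheses = list(
      recollection = list(restr_equate("r_a", "r_i")),
      familiarity = list(restr_equate("f_a", "f_i")),
      detection = list(restr_equate("d_a", "d_i"))
    )
  )
}

#' The two-high-threshold process-dissociation model, duplicated over animacy
#'
#' Builds the two-high-threshold variant of the multinomial
#' process-dissociation model with one set of trees for animate and one for
#' inanimate words.  Each animacy set has four binomial trees (inclusion /
#' exclusion instructions crossed with Phase-1 old words / new words;
#' categories `old` and `new`) governed by five parameters: recollection `r`,
#' conditional familiarity `f`, new-word detection `d`, and guessing "old"
#' under inclusion (`g_i`) and exclusion (`g_e`) instructions.  Under
#' exclusion instructions recollection leads to a correct "new" response to
#' Phase-1 words, which is what dissociates recollection from familiarity.
#'
#' Without additional restrictions this model has 10 parameters for 8
#' independent data cells and is not identifiable (see
#' [identifiability_check()]).  Restriction sets returned alongside the
#' model:
#' \describe{
#'   \item{`rd_alias`}{equate `r = d` within each animacy set (the validated
#'     identifying assumption; yields a saturated model).}
#'   \item{`base`}{`rd_alias` plus the guessing equates \eqn{g_i, g_e} across
#'     animacy (the base model, 2 model df).}
#'   \item{`hypotheses$recollection` / `hypotheses$familiarity`}{equate `r`
#'     resp. `f` across animacy.}
#' }
#'
#' @return A list with elements `model`, `rd_alias`, `base` and `hypotheses`.
#' @export
build_pd_two_ht <- function() {
  suffixes <- c(animate = "a", inanimate = "i")
  params <- character(0)
  trees <- list()
  branches <- list()
  for (an in names(suffixes)) {
    s <- suffixes[[an]]
    r <- paste0("r_", s); f <- paste0("f_", s); d <- paste0("d_", s)
    gi <- paste0("gi_", s); ge <- paste0("ge_", s)
    params <- c(params, stats::setNames(
      c(paste("recollection,", an, "words"),
        paste("conditional familiarity,", an, "words"),
        paste("detection of new", an, "words"),
        paste("guess 'old' under inclusion,", an, "words"),
        paste("guess 'old' under exclusion,", an, "words")),
      c(r, f, d, gi, ge)))
    b <- function(tree, category, terms) list(tree = tree, category = category,
                                              terms = terms)
    io <- paste0("inclusion_old_", an)
    in_ <- paste0("inclusion_new_", an)
    eo <- paste0("exclusion_old_", an)
    en <- paste0("exclusion_new_", an)
    for (tn in c(io, in_, eo, en)) {
      trees[[tn]] <- list(name = tn, categories = c("old", "new"),
                          item_type = gsub("_", " ", tn))
    }
    branches <- c(branches, list(
      # inclusion, Phase-1 old words: recollection and familiarity both help
      b(io, "old", r),
      b(io, "old", sprintf("(1-%s)*%s", r, f)),
      b(io, "old", sprintf("(1-%s)*(1-%s)*%s", r, f, gi)),
      b(io, "new", sprintf("(1-%s)*(1-%s)*(1-%s)", r, f, gi)),
      # exclusion, Phase-1 old words: recollection excludes, familiarity hurts
      b(eo, "new", r),
      b(eo, "old", sprintf("(1-%s)*%s", r, f)),
      b(eo, "old", sprintf("(1-%s)*(1-%s)*%s", r, f, ge)),
      b(eo, "new", sprintf("(1-%s)*(1-%s)*(1-%s)", r, f, ge)),
      # new words: detected as new, otherwise guessed
      b(in_, "new", d),
      b(in_, "old", sprintf("(1-%s)*%s", d, gi)),
      b(in_, "new", sprintf("(1-%s)*(1-%s)", d, gi)),
      b(en, "new", d),
      b(en, "old", sprintf("(1-%s)*%s", d, ge)),
      b(en, "new", sprintf("(1-%s)*(1-%s)", d, ge))
    ))
  }
  model <- mpt_model(params, trees, branches)
  rd_alias <- list(restr_equate("r_a", "d_a"), restr_equate("r_i", "d_i"))
  g_equates <- list(restr_equate("gi_a", "gi_i"), restr_equate("ge_a", "ge_i"))
  list(
    model = model,
    rd_alias = rd_alias,
    base = c(rd_alias, g_equates),
    hypotheses = list(
      recollection = list(restr_equate("r_a", "r_i")),
      familiarity = list(restr_equate("f_a", "f_i"))
    )
  )
}

#' Reconstruct integer counts from rounded proportions
#'
#' Published tables report category proportions rounded to two decimals; this
#' rebuilds integer counts for a known per-tree total.  The proportions are
#' first renormalized to sum to 1 (rounded rows can print to sums slightly
#' off 1), multiplied by the total, and integerized by the largest-remainder
#' method, so the result always sums exactly to `total`.  Ties in the
#' fractional parts are broken by category order.
#'
#' @param proportions Nonnegative numeric vector, at least one positive.
#' @param total Positive integer total.
#' @return Integer vector of the same length as `proportions` summing to
#'   `total`.
#' @examples
#' reconstruct_counts(c(.53, .23, .06, .19), 4400)
#' @export
reconstruct_counts <- function(proportions, total) {
  stopifnot(is.numeric(proportions), length(proportions) >= 1,
            is.numeric(total), length(total) == 1, total > 0)
  if (any(!is.finite(proportions)) || any(proportions < 0)) {
    stop("proportions must be nonnegative")
  }
  if (sum(proportions) <= 0) stop("all proportions are zero")
  x <- proportions / sum(proportions) * total
  counts <- floor(x)
  remainder <- round(total - sum(counts))
  if (remainder > 0) {
    pick <- order(-(x - counts), seq_along(x))[seq_len(remainder)]
    counts[pick] <- counts[pick] + 1
  }
  as.integer(counts)
}

# Published mean proportions (judgment categories by item type), and the
# design constants the per-tree totals derive from.
exp1_proportions <- function() {
  rbind(
    old_animate   = c(recollect = .53, familiar = .23, guess = .06, new = .19),
    old_inanimate = c(recollect = .48, familiar = .25, guess = .07, new = .20),
    new_animate   = c(recollect = .02, familiar = .07, guess = .05, new = .86),
    new_inanimate = c(recollect = .03, familiar = .09, guess = .06, new = .82)
  )
}

exp2_proportions <- function() {
  rbind(
    inclusion_old_animate   = c(old = .84, new = .16),
    inclusion_old_inanimate = c(old = .80, new = .20),
    inclusion_new_animate   = c(old = .15, new = .85),
    inclusion_new_inanimate = c(old = .16, new = .84),
    exclusion_old_animate   = c(old = .28, new = .72),
    exclusion_old_inanimate = c(old = .30, new = .70),
    exclusion_new_animate   = c(old = .12, new = .88),
    exclusion_new_inanimate = c(old = .13, new = .87)
  )
}

proportions_to_table <- function(props, totals) {
  rows <- lapply(rownames(props), function(tn) {
    data.frame(tree = tn, category = colnames(props),
               count = reconstruct_counts(props[tn, ], totals[[tn]]),
               stringsAsFactors = FALSE)
  })
  frequency_table(do.call(rbind, rows))
}

#' Built-in experiment fixtures
#'
#' Bundles each experiment's model, restriction sets, and the aggregate
#' frequency table reconstructed from the published mean proportions.
#'
#' `fixture_experiment1()`: the four-states model with counts rebuilt from
#' the remember-know-guess judgment proportions at 4,400 responses per tree
#' (110 participants times 40 words per item type), 17,600 responses in
#' total.  `fixture_experiment2()`: the process-dissociation model with
#' counts rebuilt from the "old"/"new" judgment proportions at 2,106
#' responses per inclusion tree (81 participants times 26 analyzed words) and
#' 2,132 per exclusion tree (82 times 26), 16,952 in total.
#'
#' @return An object of class `mpt_experiment`: a list with `label`, `model`,
#'   `base_restrictions`, `hypotheses` (named lists of extra restrictions,
#'   in analysis order), `data`, `N_total` and the source `proportions`.
#' @export
fixture_experiment1 <- function() {
  fs <- build_four_states()
  props <- exp1_proportions()
  totals <- stats::setNames(rep(4400, nrow(props)), rownames(props))
  data <- proportions_to_table(props, totals)
  structure(
    list(label = "exp1", model = fs$model, base_restrictions = fs$base,
         hypotheses = fs$hypotheses, data = data,
         N_total = sum(data$count), proportions = props),
    class = "mpt_experiment"
  )
}

#' @rdname fixture_experiment1
#' @export
fixture_experiment2 <- function() {
  pd <- build_pd_two_ht()
  props <- exp2_proportions()
  totals <- ifelse(grepl("^inclusion", rownames(props)), 81 * 26, 82 * 26)
  names(totals) <- rownames(props)
  data <- proportions_to_table(props, totals)
  structure(
    list(label = "exp2", model = pd$model, base_restrictions = pd$base,
         hypotheses = pd$hypotheses, data = data,
         N_total = sum(data$count), proportions = props),
    class = "mpt_experiment"
  )
}

#' @export
print.mpt_experiment <- function(x, ...) {
  cat("MPT experiment fixture '", x$label, "': ", sep = "")
  cat(length(x$model$trees), "trees,", x$N_total, "total responses\n")
  cat("  hypotheses:", paste(names(x$hypotheses), collapse = ", "), "\n")
  invisible(x)
}
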