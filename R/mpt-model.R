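#' Construct a multinomial processing tree (MPT) model
#'
#' An MPT model explains the probabilities of observable response categories
#' as sums over latent processing branches, where each branch probability is a
#' product of parameters \eqn{\theta} and complements \eqn{1-\theta}.  Each
#' tree corresponds to one item-type condition (for example, old animate words
#' in a recognition test) and its category probabilities must sum to one
#' identically in the parameters.
#'
#' @param params Character vector of parameter names, or a named character
#'   vector mapping parameter names to free-text descriptions.  All parameters
#'   are probabilities in \eqn{[0, 1]}.
#' @param trees Named list mapping tree names to their ordered category names
#'   (each a character vector of length >= 2), or a list of lists with fields
#'   `name`, `categories` and optionally `item_type`.
#' @param branches List of branches.  Each branch is a list with fields
#'   `tree`, `category` and `terms`, where `terms` is either a product string
#'   such as `"(1-r)*(1-f)*gr"` or a two-column data frame with columns
#'   `param` and `complement`.  An empty product (written `"1"`) has
#'   probability 1.
#'
#' @return An object of class `mpt_model`.
#' @examples
#' m <- mpt_model(
#'   params = c("p"),
#'   trees = list(flip = c("heads", "tails")),
#'   branches = list(
#'     list(tree = "flip", category = "heads", terms = "p"),
#'     list(tree = "flip", category = "tails", terms = "(1-p)")
#'   )
#' )
#' category_probabilities(m, c(p = 0.25))
#' @export
mpt_model <- function(params, trees, branches) {
  if (is.null(names(params))) {
    descriptions <- stats::setNames(rep("", length(params)), params)
  } else {
    descriptions <- params
    params <- names(params)
  }
  if (anyDuplicated(params)) {
    stop("duplicate parameter names: ",
         paste(unique(params[duplicated(params)]), collapse = ", "))
  }

  trees <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    if (is.character(tr)) {
      tr <- list(name = names(trees)[i], categories = tr, item_type = NA_character_)
    }
    if (is.null(tr$item_type)) tr$item_type <- NA_character_
    if (is.null(tr$name) || !nzchar(tr$name)) stop("every tree needs a name")
    if (length(tr$categories) < 2) {
      stop("tree '", tr$name, "' needs at least 2 categories")
    }
    if (anyDuplicated(tr$categories)) {
      stop("duplicate categories in tree '", tr$name, "'")
    }
    tr[c("name", "categories", "item_type")]
  })
  names(trees) <- vapply(trees, `[[`, character(1), "name")
  if (anyDuplicated(names(trees))) stop("duplicate tree names")

  branches <- lapply(branches, function(b) {
    terms <- b$terms
    if (is.character(terms)) terms <- parse_term_product(terms)
    if (is.null(b$const)) b$const <- 1
    list(tree = b$tree, category = b$category,
         params = as.character(terms$param),
         comp = as.logical(terms$complement),
         const = as.numeric(b$const))
  })

  model <- structure(
    list(params = params, descriptions = descriptions,
         trees = trees, branches = branches),
    class = "mpt_model"
  )
  validate_mpt_model(model)
  model
}

validate_mpt_model <- function(model) {
  for (b in model$branches) {
    if (!b$tree %in% names(model$trees)) {
      stop("branch references unknown tree '", b$tree, "'")
    }
    cats <- model$trees[[b$tree]]$categories
    if (!b$category %in% cats) {
      stop("branch references unknown category '", b$category,
           "' in tree '", b$tree, "'")
    }
    unknown <- setdiff(b$params, model$params)
    if (length(unknown)) {
      stop("branch references undeclared parameter(s): ",
           paste(unknown, collapse = ", "))
    }
    if (!is.finite(b$const) || b$const < 0 || b$const > 1) {
      stop("branch constant must lie in [0, 1]")
    }
  }
  invisible(model)
}

#' @export
print.mpt_model <- function(x, ...) {
  cat("MPT model:", length(x$params), "parameters,",
      length(x$trees), "trees,", length(x$branches), "branches\n")
  cat("  parameters:", paste(x$params, collapse = ", "), "\n")
  for (tr in x$trees) {
    cat("  tree", tr$name, "->", paste(tr$categories, collapse = ", "), "\n")
  }
  invisible(x)
}

# Compiled representation used by all numeric code: branch probabilities are
# exp(A %*% log(theta) + B %*% log(1 - theta)) * const, with A/B the per-branch
# exponents of direct and complement occurrences.
compile_mpt <- function(model) {
  np <- length(model$params)
  nb <- length(model$branches)
  A <- matrix(0L, nb, np, dimnames = list(NULL, model$params))
  B <- matrix(0L, nb, np, dimnames = list(NULL, model$params))
  const <- numeric(nb)
  cells <- do.call(rbind, lapply(model$trees, function(tr) {
    data.frame(tree = tr$name, category = tr$categories,
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  cell_key <- paste(cells$tree, cells$category, sep = "\r")
  branch_cell <- integer(nb)
  for (i in seq_len(nb)) {
    b <- model$branches[[i]]
    for (j in seq_along(b$params)) {
      k <- match(b$params[j], model$params)
      if (b$comp[j]) B[i, k] <- B[i, k] + 1L else A[i, k] <- A[i, k] + 1L
    }
    const[i] <- b$const
    branch_cell[i] <- match(paste(b$tree, b$category, sep = "\r"), cell_key)
  }
  tree_of_cell <- match(cells$tree, names(model$trees))
  list(model = model, A = A, B = B, const = const, cells = cells,
       branch_cell = branch_cell, n_cells = nrow(cells),
       tree_of_cell = tree_of_cell, n_trees = length(model$trees),
       cats_per_tree = vapply(model$trees, function(t) length(t$categories),
                              integer(1)))
}

# Branch probabilities at theta (named or positional, model order).
branch_probs <- function(compiled, theta) {
  th <- pmin(pmax(as.numeric(theta), 0), 1)
  if (length(th) != ncol(compiled$A)) stop("parameter vector has wrong length")
  lt <- log(th)
  lc <- log1p(-th)
  lt[th == 0] <- -Inf
  lc[th == 1] <- -Inf
  lp <- drop(compiled$A %*% ifelse(is.finite(lt), lt, 0) +
             compiled$B %*% ifelse(is.finite(lc), lc, 0))
  pb <- exp(lp) * compiled$const
  # zero out branches whose log terms hit -Inf
  zero <- (compiled$A %*% (th == 0)) + (compiled$B %*% (th == 1)) > 0
  pb[zero] <- 0
  pb
}

cell_probs <- function(compiled, theta) {
  pb <- branch_probs(compiled, theta)
  pc <- numeric(compiled$n_cells)
  agg <- rowsum(pb, compiled$branch_cell)
  pc[as.integer(rownames(agg))] <- agg
  pc
}

check_param_vector <- function(model, params) {
  if (is.null(names(params))) {
    if (length(params) != length(model$params)) {
      stop("unnamed parameter vector must have length ", length(model$params))
    }
    names(params) <- model$params
  }
  missing <- setdiff(model$params, names(params))
  if (length(missing)) {
    stop("missing parameter value(s): ", paste(missing, collapse = ", "))
  }
  params <- params[model$params]
  if (any(!is.finite(params)) || any(params < 0) || any(params > 1)) {
    stop("all parameter values must lie in [0, 1]")
  }
  params
}

#' Category probabilities of an MPT model
#'
#' Evaluates, for every tree, the probability of each response category at the
#' given parameter values by summing branch products.
#'
#' @param model An [mpt_model()].
#' @param params Named numeric vector of parameter values in \eqn{[0, 1]}
#'   covering all model parameters.
#' @return A named list mapping each tree name to a named numeric vector of
#'   category probabilities (summing to 1).
#' @export
category_probabilities <- function(model, params) {
  params <- check_param_vector(model, params)
  compiled <- compile_mpt(model)
  pc <- cell_probs(compiled, params)
  out <- lapply(seq_along(model$trees), function(i) {
    idx <- which(compiled$tree_of_cell == i)
    stats::setNames(pc[idx], compiled$cells$category[idx])
  })
  names(out) <- names(model$trees)
  out
}

#' Numerically check that tree probabilities sum to one
#'
#' Draws random parameter vectors and verifies that, for every tree, the
#' category probabilities sum to 1.  A tree whose branch set is incomplete
#' (a deleted branch, a mistyped complement) fails at generic parameter
#' points.
#'
#' @param model An [mpt_model()].
#' @param n_points Number of random parameter points to test.
#' @param seed Integer seed for the random points.
#' @param tol Tolerance on the deviation of the per-tree sum from 1.
#' @return A list of class `mpt_structural_check` with the maximum absolute
#'   deviation overall (`max_abs_dev`), per tree (`tree_max_dev`), the flagged
#'   trees (`failed_trees`) and a `pass` flag.
#' @export
structural_check <- function(model, n_points = 100, seed = 1, tol = 1e-9) {
  stopifnot(n_points >= 1)
  compiled <- compile_mpt(model)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  np <- length(model$params)
  dev <- matrix(0, n_points, compiled$n_trees)
  for (i in seq_len(n_points)) {
    theta <- stats::runif(np)
    pc <- cell_probs(compiled, theta)
    sums <- rowsum(pc, compiled$tree_of_cell)
    dev[i, ] <- abs(drop(sums) - 1)
  }
  tree_max <- apply(dev, 2, max)
  names(tree_max) <- names(model$trees)
  failed <- names(tree_max)[tree_max > tol]
  structure(list(max_abs_dev = max(tree_max), tree_max_dev = tree_max,
                 failed_trees = failed, pass = length(failed) == 0,
                 n_points = n_points, seed = seed, tol = tol),
            class = "mpt_structural_check")
}

#' @export
print.mpt_structural_check <- function(x, ...) {
  cat("Structural check over", x$n_points, "random points:",
      if (x$pass) "PASS" else "FAIL", "\n")
  cat("  max |sum - 1| =", format(x$max_abs_dev), "\n")
  if (!x$pass) cat("  incomplete trees:", paste(x$failed_trees, collapse = ", "), "\n")
  invisible(x)
}

#' Local identifiability check via the Jacobian rank
#'
#' Evaluates the numerical Jacobian of the map from free parameters to the
#' stacked category probabilities at random interior parameter points and
#' compares its maximal rank to the number of free parameters.  A model whose
#' rank falls short of the free-parameter count is not locally identifiable;
#' the classical example here is the process-dissociation model without the
#' recollection/detection equates.
#'
#' @param model An [mpt_model()].
#' @param restrictions Optional list of restrictions (see [restr_equate()])
#'   applied before the check.
#' @param n_points Number of random interior points.
#' @param seed Integer seed.
#' @return A list of class `mpt_identifiability` with `max_rank`, `n_free`,
#'   `identified`, and the data degrees of freedom `data_df`
#'   (\eqn{\sum_j (C_j - 1)}).
#' @export
identifiability_check <- function(model, restrictions = list(),
                                  n_points = 5, seed = 1) {
  stopifnot(n_points >= 1)
  red <- apply_restrictions(model, restrictions)
  compiled <- compile_mpt(red$model)
  np <- length(red$model$params)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  max_rank <- 0L
  for (i in seq_len(n_points)) {
    theta <- stats::runif(np, 0.15, 0.85)
    J <- num_jacobian(function(th) cell_probs(compiled, th), theta)
    r <- qr(J, tol = 1e-8)$rank
    if (r > max_rank) max_rank <- r
  }
  data_df <- sum(compiled$cats_per_tree - 1L)
  structure(list(max_rank = max_rank, n_free = np,
                 identified = max_rank == np, data_df = data_df,
                 n_points = n_points, seed = seed),
            class = "mpt_identifiability")
}

#' @export
print.mpt_identifiability <- function(x, ...) {
  cat("Identifiability check: rank", x$max_rank, "of", x$n_free,
      "free parameters (data df =", paste0(x$data_df, ")"), "->",
      if (x$identified) "locally identified" else "NOT identifiable", "\n")
  invisible(x)
}

#' Structural equality of two MPT models
#'
#' Compares two models up to renaming of trees, categories and parameters
#' (by order of appearance) and up to the order of branches and of terms
#' within a branch.  This is the equality notion under which reading back a
#' written EQN file reproduces the model.
#'
#' @param a,b Two [mpt_model()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
mpt_structural_equal <- function(a, b) {
  canon <- function(m, rename) {
    if (rename) {
      # identifiers renumbered by first appearance in the branch list, since
      # that is all a serialized model preserves
      br_trees <- vapply(m$branches, `[[`, character(1), "tree")
      br_params <- unlist(lapply(m$branches, `[[`, "params"),
                          use.names = FALSE)
      pmap <- stats::setNames(paste0("P", seq_along(unique(br_params))),
                              unique(br_params))
      tmap <- stats::setNames(paste0("T", seq_along(unique(br_trees))),
                              unique(br_trees))
      cmaps <- lapply(names(m$trees), function(tn) {
        seen <- unique(vapply(Filter(function(b) b$tree == tn, m$branches),
                              `[[`, character(1), "category"))
        cats <- c(seen, setdiff(m$trees[[tn]]$categories, seen))
        stats::setNames(paste0("C", seq_along(cats)), cats)
      })
      names(cmaps) <- names(m$trees)
    } else {
      pmap <- stats::setNames(m$params, m$params)
      tmap <- stats::setNames(names(m$trees), names(m$trees))
      cmaps <- lapply(m$trees, function(tr) {
        stats::setNames(tr$categories, tr$categories)
      })
    }
    br <- vapply(m$branches, function(b) {
      terms <- paste0(ifelse(b$comp, "~", ""), pmap[b$params])
      paste(tmap[b$tree], cmaps[[b$tree]][b$category],
            paste(sort(terms), collapse = "*"), format(b$const), sep = " ")
    }, character(1))
    ncats <- sort(vapply(m$trees, function(tr) length(tr$categories),
                         integer(1)))
    list(np = length(m$params), ncats = unname(ncats), branches = sort(br))
  }
  # equal either with identifiers taken at face value (invariant to branch
  # and term permutation) or after renaming by order of appearance (how a
  # serialized EQN file comes back)
  identical(canon(a, FALSE), canon(b, FALSE)) ||
    identical(canon(a, TRUE), canon(b, TRUE))
}

# numerical central-difference Jacobian
num_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (k in seq_along(x)) {
    xp <- x; xm <- x
    xp[k] <- x[k] + h
    xm[k] <- x[k] - h
    J[, k] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
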