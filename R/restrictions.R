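#' Parameter restrictions
#'
#' Equality and fixed-value restrictions on MPT model parameters.  An
#' equality restriction `restr_equate(a, b)` merges two parameters into one
#' free parameter (chains are resolved transitively); `restr_fix(a, value)`
#' pins a parameter to a constant in \eqn{[0, 1]}.  Restrictions are how
#' substantive hypotheses are expressed: equating, say, the recollection
#' parameter across animacy states yields the nested model whose fit loss is
#' the test of an animacy effect on recollection.
#'
#' @param a,b Parameter names.
#' @param value Constant in \eqn{[0, 1]}.
#' @return An object of class `mpt_restriction`.
#' @seealso [apply_restrictions()]
#' @export
restr_equate <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  structure(list(kind = "equate", a = a, b = b), class = "mpt_restriction")
}

#' @rdname restr_equate
#' @export
restr_fix <- function(a, value) {
  stopifnot(is.character(a), length(a) == 1, is.numeric(value),
            length(value) == 1)
  if (!is.finite(value) || value < 0 || value > 1) {
    stop("fixed value must lie in [0, 1]")
  }
  structure(list(kind = "fix", a = a, value = value),
            class = "mpt_restriction")
}

#' @export
print.mpt_restriction <- function(x, ...) {
  if (x$kind == "equate") cat(x$a, "=", x$b, "\n")
  else cat(x$a, "=", format(x$value), "\n")
  invisible(x)
}

#' Parse a restriction string
#'
#' Parses a compact textual restriction syntax, e.g.
#' `"r_a = r_i; d_a = 0.5"`: each `;`- or `,`-separated clause equates two
#' parameters or fixes one parameter to a numeric constant.
#'
#' @param text Character scalar.
#' @return A list of `mpt_restriction` objects.
#' @export
parse_restrictions <- function(text) {
  if (!nzchar(trimws(text))) return(list())
  clauses <- trimws(strsplit(text, "[;,]")[[1]])
  clauses <- clauses[nzchar(clauses)]
  lapply(clauses, function(cl) {
    parts <- trimws(strsplit(cl, "=", fixed = TRUE)[[1]])
    if (length(parts) != 2 || !all(nzchar(parts))) {
      stop("cannot parse restriction clause '", cl, "'")
    }
    rhs_num <- suppressWarnings(as.numeric(parts[2]))
    if (!is.na(rhs_num)) restr_fix(parts[1], rhs_num)
    else restr_equate(parts[1], parts[2])
  })
}

#' Apply restrictions to an MPT model
#'
#' Produces the reduced model in which equated parameters are merged into a
#' single representative (the earliest-declared member of each equivalence
#' class) and fixed parameters are folded into constant branch multipliers,
#' together with an expansion map that recovers full-space parameter values
#' from reduced-space values.
#'
#' @param model An [mpt_model()].
#' @param restrictions List of [restr_equate()] / [restr_fix()] objects (a
#'   single restriction or a restriction string are also accepted).
#' @return A list of class `mpt_restricted` with elements `model` (the
#'   reduced [mpt_model()]), `map` (per full parameter, either
#'   `list(type = "free", source = <reduced name>)` or
#'   `list(type = "fixed", value = <constant>)`) and `free_params`.
#' @examples
#' fs <- build_four_states()
#' red <- apply_restrictions(fs$model, fs$base)
#' length(red$free_params)  # 12 parameters minus 3 guessing equates
#' @export
apply_restrictions <- function(model, restrictions = list()) {
  if (inherits(restrictions, "mpt_restriction")) restrictions <- list(restrictions)
  if (is.character(restrictions)) restrictions <- parse_restrictions(restrictions)
  for (r in restrictions) {
    if (!inherits(r, "mpt_restriction")) stop("not an mpt_restriction object")
    refs <- if (r$kind == "equate") c(r$a, r$b) else r$a
    unknown <- setdiff(refs, model$params)
    if (length(unknown)) {
      stop("restriction references unknown parameter(s): ",
           paste(unknown, collapse = ", "))
    }
  }

  # union-find over equates; representative = earliest parameter in model order
  parent <- stats::setNames(seq_along(model$params), model$params)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (r in restrictions) {
    if (r$kind != "equate") next
    ra <- find(match(r$a, model$params))
    rb <- find(match(r$b, model$params))
    root <- min(ra, rb)
    parent[ra] <- root
    parent[rb] <- root
  }
  rep_idx <- vapply(seq_along(model$params), find, numeric(1))

  fixed <- list()
  for (r in restrictions) {
    if (r$kind != "fix") next
    root <- model$params[rep_idx[match(r$a, model$params)]]
    if (!is.null(fixed[[root]]) && fixed[[root]] != r$value) {
      stop("contradictory fixed values for parameter class of '", root, "': ",
           fixed[[root]], " vs ", r$value)
    }
    fixed[[root]] <- r$value
  }

  rep_name <- model$params[rep_idx]
  free_params <- setdiff(unique(rep_name), names(fixed))

  map <- lapply(seq_along(model$params), function(i) {
    root <- rep_name[i]
    if (!is.null(fixed[[root]])) list(type = "fixed", value = fixed[[root]])
    else list(type = "free", source = root)
  })
  names(map) <- model$params

  new_branches <- lapply(model$branches, function(b) {
    const <- b$const
    keep <- logical(length(b$params))
    pars <- b$params
    for (j in seq_along(pars)) {
      root <- rep_name[match(pars[j], model$params)]
      if (!is.null(fixed[[root]])) {
        v <- if (b$comp[j]) 1 - fixed[[root]] else fixed[[root]]
        const <- const * v
      } else {
        pars[j] <- root
        keep[j] <- TRUE
      }
    }
    list(tree = b$tree, category = b$category,
         params = pars[keep], comp = b$comp[keep], const = const)
  })

  reduced <- structure(
    list(params = free_params,
         descriptions = model$descriptions[free_params],
         trees = model$trees, branches = new_branches),
    class = "mpt_model"
  )
  validate_mpt_model(reduced)
  structure(list(model = reduced, map = map, free_params = free_params,
                 restrictions = restrictions, full_params = model$params),
            class = "mpt_restricted")
}

#' Expand reduced-space parameter values to the full parameter space
#'
#' @param restricted An `mpt_restricted` object from [apply_restrictions()].
#' @param values Named numeric vector over the reduced model's free
#'   parameters.
#' @return Named numeric vector over the full model's parameters: equated
#'   parameters share their representative's value, fixed parameters take
#'   their constant.
#' @export
expand_params <- function(restricted, values) {
  stopifnot(inherits(restricted, "mpt_restricted"))
  missing <- setdiff(restricted$free_params, names(values))
  if (length(missing)) {
    stop("missing reduced-space value(s): ", paste(missing, collapse = ", "))
  }
  out <- vapply(restricted$map, function(m) {
    if (m$type == "fixed") m$value else unname(values[m$source])
  }, numeric(1))
  stats::setNames(out, names(restricted$map))
}
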