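#' Read and write EQN model files
#'
#' The EQN format is the de-facto interchange format of the MPT software
#' ecosystem (multiTree, MPTinR, GPT): the first line is a header (commonly a
#' line count or comment) and every following non-empty line holds three
#' whitespace-separated fields — tree, category, and a branch product such as
#' `(1-r)*(1-f)*gr`.  Multiple lines with the same tree/category pair
#' accumulate as distinct branches of that category.
#'
#' Tree and category fields may be classical 1-based integers (mapped to the
#' stable identifiers `T<k>` / `C<k>`) or arbitrary non-numeric labels, which
#' are kept as-is.  `write_eqn()` emits the model's own tree/category/
#' parameter names, so `parse_eqn(write_eqn(m))` is structurally identical to
#' `m` (see [mpt_structural_equal()]).
#'
#' @param text Character scalar (possibly multi-line) or character vector of
#'   lines.
#' @param path File path.
#' @param model An [mpt_model()].  Models with constant branch multipliers
#'   (from fixed-value restrictions) cannot be serialized.
#' @return `parse_eqn()`/`read_eqn()` return an [mpt_model()];
#'   `write_eqn()` returns the EQN text invisibly (and writes it to `path`
#'   if given).
#' @examples
#' m <- parse_eqn(c("2", "1 1 p", "1 2 (1-p)"))
#' cat(write_eqn(m))
#' @export
parse_eqn <- function(text) {
  if (length(text) == 1 && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  if (length(text) < 1) stop("empty EQN input")
  lines <- text[-1]  # header line ignored by convention
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("EQN input has no content lines")

  tree_tok <- character(0)
  cat_tok <- character(0)
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    lineno <- keep[i] + 1L
    fields <- strsplit(trimws(lines[keep[i]]), "[[:space:]]+")[[1]]
    if (length(fields) != 3) {
      stop("EQN line ", lineno,
           ": expected 'tree category product', got '",
           trimws(lines[keep[i]]), "'")
    }
    terms <- tryCatch(parse_term_product(fields[3]),
                      error = function(e) {
                        stop("EQN line ", lineno, ": ", conditionMessage(e),
                             call. = FALSE)
                      })
    rows[[i]] <- list(tree = fields[1], category = fields[2], terms = terms)
  }

  map_ids <- function(tokens, prefix) {
    if (all(grepl("^[0-9]+$", tokens))) {
      stats::setNames(paste0(prefix, tokens), tokens)
    } else {
      stats::setNames(unique(tokens), unique(tokens))
    }
  }
  tree_ids <- map_ids(vapply(rows, `[[`, character(1), "tree"), "T")
  cat_ids <- map_ids(vapply(rows, `[[`, character(1), "category"), "C")

  params <- character(0)
  for (r in rows) params <- union(params, r$terms$param)

  tree_names <- unique(unname(tree_ids[vapply(rows, `[[`, character(1), "tree")]))
  trees <- lapply(tree_names, function(tn) {
    cats <- unique(vapply(
      Filter(function(r) tree_ids[[r$tree]] == tn, rows),
      function(r) unname(cat_ids[[r$category]]), character(1)))
    list(name = tn, categories = cats, item_type = NA_character_)
  })

  branches <- lapply(rows, function(r) {
    list(tree = unname(tree_ids[[r$tree]]),
         category = unname(cat_ids[[r$category]]),
         terms = r$terms)
  })
  mpt_model(params = params, trees = trees, branches = branches)
}

#' @rdname parse_eqn
#' @export
read_eqn <- function(path) parse_eqn(readLines(path, warn = FALSE))

#' @rdname parse_eqn
#' @export
write_eqn <- function(model, path = NULL) {
  stopifnot(inherits(model, "mpt_model"))
  lines <- vapply(model$branches, function(b) {
    if (b$const != 1) {
      stop("cannot write EQN for a model with constant branch multipliers; ",
           "serialize the unrestricted model instead")
    }
    prod <- if (length(b$params) == 0) "1" else {
      paste(ifelse(b$comp, paste0("(1-", b$params, ")"), b$params),
            collapse = "*")
    }
    paste(b$tree, b$category, prod)
  }, character(1))
  text <- paste(c(length(lines), lines), collapse = "\n")
  text <- paste0(text, "\n")
  if (!is.null(path)) writeLines(text, path, sep = "")
  invisible(text)
}

# Parse a branch product like "(1-r)*(1-f)*gr" into a data frame with columns
# param / complement.  "1" denotes the empty product.
parse_term_product <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s)) stop("empty branch product")
  n_open <- lengths(regmatches(s, gregexpr("(", s, fixed = TRUE)))
  n_close <- lengths(regmatches(s, gregexpr(")", s, fixed = TRUE)))
  if (n_open != n_close) stop("unbalanced parentheses in '", text, "'")
  factors <- strsplit(s, "*", fixed = TRUE)[[1]]
  if (any(!nzchar(factors))) stop("malformed product '", text, "'")
  param <- character(0)
  complement <- logical(0)
  id_rx <- "^[A-Za-z_][A-Za-z0-9_.]*$"
  for (f in factors) {
    if (f == "1") next
    m <- regmatches(f, regexec("^\\((1-)([^()]+)\\)$", f))[[1]]
    if (length(m) == 3) {
      if (!grepl(id_rx, m[3])) stop("unknown token '", m[3], "' in '", text, "'")
      param <- c(param, m[3])
      complement <- c(complement, TRUE)
    } else if (grepl(id_rx, f)) {
      param <- c(param, f)
      complement <- c(complement, FALSE)
    } else {
      stop("unknown token '", f, "' in '", text, "'")
    }
  }
  data.frame(param = param, complement = complement, stringsAsFactors = FALSE)
}
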