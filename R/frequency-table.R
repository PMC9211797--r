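#' Frequency tables of category counts
#'
#' A frequency table holds the observed nonnegative integer response counts
#' per tree and category — the data format all fitting functions consume.
#'
#' @param x A data frame with columns `tree`, `category`, `count`.
#' @return An object of class `mpt_freq` (a data frame).
#' @export
frequency_table <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("tree", "category", "count")
  if (!all(need %in% names(x))) {
    stop("frequency table needs columns: ", paste(need, collapse = ", "))
  }
  x <- as.data.frame(x)[need]
  x$tree <- as.character(x$tree)
  x$category <- as.character(x$category)
  bad <- which(!is.finite(x$count) | x$count < 0 |
                 abs(x$count - round(x$count)) > 1e-8)
  if (length(bad)) {
    stop("invalid count in row ", bad[1], ": ", x$count[bad[1]],
         " (counts must be nonnegative integers)")
  }
  x$count <- as.integer(round(x$count))
  key <- paste(x$tree, x$category, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (tree, category) pair in row ", which(duplicated(key))[1])
  }
  class(x) <- c("mpt_freq", "data.frame")
  x
}

#' @rdname frequency_table
#' @param table An `mpt_freq` object.
#' @return `tree_totals()` returns a named numeric vector of per-tree totals.
#' @export
tree_totals <- function(table) {
  tab <- frequency_table(table)
  tapply(tab$count, factor(tab$tree, levels = unique(tab$tree)), sum)
}

#' Read or write a frequency CSV file
#'
#' The CSV has columns `tree`, `category`, `count`.  Writing orders rows by
#' tree, then category (each in order of first appearance), so output is
#' deterministic; a read/write round trip is lossless.
#'
#' @param path File path.
#' @param table An `mpt_freq` object (or coercible data frame).
#' @export
read_frequency_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tryCatch(frequency_table(x), error = function(e) {
    stop("in '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  tab
}

#' @rdname read_frequency_csv
#' @export
write_frequency_csv <- function(table, path) {
  tab <- frequency_table(table)
  ord <- order(match(tab$tree, unique(tab$tree)),
               match(tab$category, unique(tab$category)))
  utils::write.csv(tab[ord, ], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Align a frequency table with a model: returns the count vector over the
# model's canonical cell order (missing cells count 0), erroring on cells the
# model does not define and on empty trees.
align_counts <- function(compiled, data, require_positive_totals = TRUE) {
  tab <- frequency_table(data)
  cell_key <- paste(compiled$cells$tree, compiled$cells$category, sep = "\r")
  data_key <- paste(tab$tree, tab$category, sep = "\r")
  unknown <- which(!data_key %in% cell_key)
  if (length(unknown)) {
    stop("data contain cell (", tab$tree[unknown[1]], ", ",
         tab$category[unknown[1]], ") that the model does not define")
  }
  counts <- numeric(compiled$n_cells)
  counts[match(data_key, cell_key)] <- tab$count
  if (require_positive_totals) {
    totals <- rowsum(counts, compiled$tree_of_cell)
    if (any(totals <= 0)) {
      empty <- names(compiled$model$trees)[which(totals <= 0)]
      stop("tree(s) with no observations: ", paste(empty, collapse = ", "))
    }
  }
  counts
}
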