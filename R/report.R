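#' Run a complete model-based analysis
#'
#' Reproduces the full hypothesis-testing ladder for a built-in experiment
#' fixture (or any `mpt_experiment` object): the base-model fit, one
#' likelihood-ratio test per hypothesis (each tested as extra restrictions on
#' top of the base model), and the sensitivity analysis (minimal detectable
#' effect size at the experiment's total N).  Aborts if the base-restricted
#' model is not locally identifiable.
#'
#' @param experiment `"exp1"`, `"exp2"`, or an `mpt_experiment` object (see
#'   [fixture_experiment1()]).
#' @param alpha Significance level used in the sensitivity analysis.
#' @param power Target power of the sensitivity analysis.
#' @param ... Passed to [fit_mpt()] (`backend`, `n_starts`, `seed`, ...).
#' @return An object of class `mpt_analysis`: the base `fit`, the named list
#'   of `tests`, the `sensitivity` result, and provenance (options, seed,
#'   a checksum of the analyzed counts).
#' @examples
#' \donttest{
#' report <- run_analysis("exp1", n_starts = 2)
#' print(report)
#' }
#' @export
run_analysis <- function(experiment, alpha = 0.05, power = 0.95, ...) {
  if (is.character(experiment)) {
    experiment <- switch(match.arg(experiment, c("exp1", "exp2")),
                         exp1 = fixture_experiment1(),
                         exp2 = fixture_experiment2())
  }
  stopifnot(inherits(experiment, "mpt_experiment"))
  dots <- list(...)
  seed <- dots$seed %||% 20220621

  ident <- identifiability_check(experiment$model,
                                 restrictions = experiment$base_restrictions)
  if (!ident$identified) {
    print(ident)
    stop("base-restricted model is not locally identifiable; aborting")
  }

  fit <- fit_mpt(experiment$model, experiment$data,
                 restrictions = experiment$base_restrictions, ...)
  tests <- lapply(names(experiment$hypotheses), function(h) {
    lr_test(experiment$model, experiment$data,
            base = experiment$base_restrictions,
            extra = experiment$hypotheses[[h]],
            N = experiment$N_total, name = h, ...)
  })
  names(tests) <- names(experiment$hypotheses)

  w_min <- minimal_detectable_w(experiment$N_total, df = 1,
                                alpha = alpha, power = power)
  structure(
    list(label = experiment$label, fit = fit, tests = tests,
         sensitivity = list(N = experiment$N_total, df = 1, alpha = alpha,
                            power = power, w = as.numeric(w_min),
                            lambda = attr(w_min, "lambda")),
         provenance = list(seed = seed, backend = fit$backend,
                           n_starts = fit$n_starts,
                           n_total = experiment$N_total,
                           counts_checksum = counts_checksum(experiment$data),
                           multiple_testing = "none (unadjusted tests)")),
    class = "mpt_analysis"
  )
}

# order-independent FNV-style hash of the (tree, category, count) triples
counts_checksum <- function(data) {
  tab <- frequency_table(data)
  keys <- sort(paste(tab$tree, tab$category, tab$count, sep = ":"))
  h <- 2166136261
  for (ch in utf8ToInt(paste(keys, collapse = "|"))) {
    h <- (xor(h, ch) * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}

#' @export
print.mpt_analysis <- function(x, ...) {
  cat("=== Model-based analysis:", x$label, "===\n")
  cat(sprintf("Base model fit: G2(%d) = %.2f, p %s\n",
              x$fit$df, x$fit$G2, format_p(x$fit$p)))
  cat("Parameter estimates (full space):\n")
  est <- round(x$fit$expanded, 2)
  se <- round(x$fit$se_expanded, 2)
  for (p in names(est)) {
    cat(sprintf("  %-6s %.2f%s\n", p, est[[p]],
                if (is.na(se[[p]])) "" else sprintf(" (SE = %.2f)", se[[p]])))
  }
  cat("Hypothesis tests (extra restriction vs base model):\n")
  for (h in names(x$tests)) {
    t <- x$tests[[h]]
    cat(sprintf("  %-13s Delta G2(%d) = %.2f, p %s, w = %.2f\n",
                h, t$df, t$delta_G2, format_p(t$p), t$w))
  }
  s <- x$sensitivity
  cat(sprintf(paste0("Sensitivity: w = %.2f detectable with power %.2f at ",
                     "alpha = %.2f (N = %d, df = %d, lambda = %.3f)\n"),
              s$w, s$power, s$alpha, s$N, s$df, s$lambda))
  cat("Note: tests are reported unadjusted for multiple comparisons.\n")
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Writes (or returns) a machine-readable JSON report with the base-fit
#' estimates and standard errors, goodness of fit, every hypothesis test
#' (delta G2, df, p, w), the sensitivity analysis, and provenance.  The
#' serialization is deterministic, so serialize-deserialize-serialize is
#' byte-identical.
#'
#' @param analysis An `mpt_analysis` object.
#' @param path Optional output file.
#' @return The JSON string, invisibly if `path` is given.
#' @export
analysis_to_json <- function(analysis, path = NULL) {
  stopifnot(inherits(analysis, "mpt_analysis"))
  fit <- analysis$fit
  payload <- list(
    label = analysis$label,
    base_fit = list(
      estimates = as.list(round(fit$estimates, 6)),
      expanded = as.list(round(fit$expanded, 6)),
      se = as.list(round(fit$se, 6)),
      loglik = round(fit$loglik, 6),
      G2 = round(fit$G2, 6), df = fit$df, p = round(fit$p, 6),
      converged = fit$converged, iterations = fit$iterations,
      backend = fit$backend, n_starts = fit$n_starts, seed = fit$seed
    ),
    tests = lapply(analysis$tests, function(t) {
      list(delta_G2 = round(t$delta_G2, 6), df = t$df, p = round(t$p, 6),
           w = round(t$w, 6), N = t$N)
    }),
    sensitivity = lapply(analysis$sensitivity, function(v) {
      if (is.numeric(v)) round(v, 6) else v
    }),
    provenance = analysis$provenance
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' @rdname analysis_to_json
#' @export
analysis_from_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

# re-serialize a deserialized report with the writer's settings (used to
# verify lossless round trips)
reserialize_report <- function(parsed) {
  as.character(jsonlite::toJSON(parsed, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null", pretty = TRUE))
}
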