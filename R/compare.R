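#' Run one inference engine on a problem
#'
#' Thin dispatcher over the three exact engines. All three return the
#' same [posterior_result()] and, being exact, the same numbers; they
#' differ only in cost: enumeration is exponential (the oracle), the
#' chain is quadratic in time and space, the convolution tree is
#' sub-quadratic in time and near-linear in space.
#'
#' @param problem An [adder_problem()].
#' @param engine `"convtree"` (default), `"chain"`, or `"enumeration"`.
#' @param ... Passed on to the engine function.
#' @return A [posterior_result()].
#' @export
infer_posteriors <- function(problem,
                             engine = c("convtree", "chain", "enumeration"),
                             ...) {
  engine <- match.arg(engine)
  switch(engine,
    convtree = posteriors_convtree(problem, ...),
    chain = posteriors_chain(problem, ...),
    enumeration = posteriors_by_enumeration(problem, ...))
}

#' Compare the exact engines on one problem
#'
#' Runs the requested engines and measures the largest absolute
#' difference between any pair of posteriors (over every leaf-posterior
#' entry and the count posterior). Because all engines are exact, the
#' differences reflect only floating-point round-off; agreement is also
#' expressed as decimal places, `floor(-log10(max diff))`. An engine that
#' cannot run at the problem's size (enumeration beyond its cap) is
#' skipped with a warning, never silently.
#'
#' @param problem An [adder_problem()].
#' @param engines Character vector from
#'   `c("enumeration", "chain", "convtree")`.
#' @param tolerance Maximum acceptable pairwise difference; `$ok` reports
#'   whether it held.
#' @param cap Enumeration state-space cap (see
#'   [posteriors_by_enumeration()]).
#' @return An `engine_comparison`: `results` (named list of
#'   [posterior_result()]), `pairs` (tibble of pairwise max differences),
#'   `max_diff`, `decimal_places`, `log_evidence_spread`, `ok`, and
#'   structural `counters`.
#' @examples
#' cmp <- compare_engines(generate_problem(6, seed = 3))
#' cmp$decimal_places
#' @export
compare_engines <- function(problem,
                            engines = c("enumeration", "chain", "convtree"),
                            tolerance = 1e-8, cap = 2^22) {
  engines <- match.arg(engines, several.ok = TRUE)
  results <- list()
  timings <- numeric(0)
  for (eng in engines) {
    if (eng == "enumeration" && prod(.leaf_sizes(problem)) > cap) {
      rlang::warn(sprintf(
        "skipping enumeration: %g joint configurations exceed the oracle cap %g.",
        prod(.leaf_sizes(problem)), cap))
      next
    }
    t0 <- proc.time()[["elapsed"]]
    results[[eng]] <- infer_posteriors(problem, engine = eng)
    timings[[eng]] <- proc.time()[["elapsed"]] - t0
  }
  if (length(results) < 2L) {
    rlang::abort("need at least two runnable engines to compare.",
      class = "convtree_invalid")
  }
  nms <- names(results)
  pairs <- tidyr::expand_grid(a = nms, b = nms) |>
    dplyr::filter(.data$a < .data$b) |>
    dplyr::mutate(
      max_diff = purrr::map2_dbl(.data$a, .data$b,
        ~ .result_max_diff(results[[.x]], results[[.y]])),
      log_evidence_diff = purrr::map2_dbl(.data$a, .data$b,
        ~ abs(results[[.x]]$log_evidence - results[[.y]]$log_evidence)))
  max_diff <- max(pairs$max_diff)
  counters <- tibble::tibble(
    engine = nms,
    seconds = unname(timings[nms]),
    detail = purrr::map_chr(results, function(r) {
      ex <- r$extra
      if (!is.null(ex$configurations))
        sprintf("%g configurations", ex$configurations)
      else if (!is.null(ex$table_cells))
        sprintf("%g table cells", ex$table_cells)
      else if (!is.null(ex$message_cells))
        sprintf("%g message cells, %g conv ops", ex$message_cells, ex$conv_ops)
      else ""
    }))
  structure(list(
    results = results,
    pairs = pairs,
    max_diff = max_diff,
    decimal_places = if (max_diff == 0) Inf else floor(-log10(max_diff)),
    log_evidence_spread = max(pairs$log_evidence_diff),
    tolerance = tolerance,
    ok = max_diff <= tolerance,
    counters = counters),
    class = "engine_comparison")
}

#' @export
print.engine_comparison <- function(x, ...) {
  cat(sprintf("<engine_comparison> %s\n",
    paste(names(x$results), collapse = " vs ")))
  cat(sprintf("  max |posterior difference| = %.3g (%s decimal places)\n",
    x$max_diff,
    if (is.infinite(x$decimal_places)) "all" else x$decimal_places))
  cat(sprintf("  tolerance %.3g: %s\n", x$tolerance,
    if (x$ok) "agreement" else "DISAGREEMENT"))
  print(x$counters)
  invisible(x)
}

#' @method tidy engine_comparison
#' @export
tidy.engine_comparison <- function(x, ...) x$pairs

#' Structural benchmark of the scalable engines
#'
#' Generates one problem per size and runs the requested engines,
#' recording the convolution-work counter and stored message/table sizes.
#' Wall-clock seconds are included for information only; the structural
#' counters are what the complexity claims are checked against.
#'
#' @param sizes Integer vector of problem sizes.
#' @param seed Base RNG seed (size index is added to it).
#' @param engines Subset of `c("chain", "convtree")`.
#' @return A tibble with one row per (size, engine).
#' @export
bench_engines <- function(sizes, seed = 1L,
                          engines = c("chain", "convtree")) {
  engines <- match.arg(engines, several.ok = TRUE)
  purrr::map_dfr(seq_along(sizes), function(k) {
    n <- sizes[k]
    problem <- generate_problem(n, seed = seed + k - 1L)
    purrr::map_dfr(engines, function(eng) {
      conv_ops_reset()
      t0 <- proc.time()[["elapsed"]]
      res <- infer_posteriors(problem, engine = eng)
      secs <- proc.time()[["elapsed"]] - t0
      tibble::tibble(
        n = n, engine = eng,
        conv_ops = conv_ops(),
        stored_cells = res$extra$message_cells %||%
          res$extra$table_cells %||% NA_real_,
        seconds = secs,
        log_evidence = res$log_evidence)
    })
  })
}
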