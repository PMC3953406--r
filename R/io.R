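.problem_format_version <- "1.0"

.io_fail <- function(path, msg) {
  rlang::abort(sprintf("problem file invalid at %s: %s", path, msg),
    class = "convtree_schema")
}

.check_num_vec <- function(x, where, min_len = 1L) {
  if (is.null(x)) .io_fail(where, "missing required field")
  x <- unlist(x, use.names = FALSE)
  if (!is.numeric(x) || length(x) < min_len || anyNA(x)) {
    .io_fail(where, "must be a numeric array")
  }
  x
}

#' Read and write problem files
#'
#' Problems are stored as JSON with fields `version`, `rng`, `leaves`
#' (array of `{name, prior, unique_likelihood}`), `shared_likelihood`, and
#' `generator` (seed and configuration, or null). Numbers are written with
#' full precision so that write-then-read reproduces the problem exactly.
#' Schema violations are reported with the JSON path of the offending
#' field.
#'
#' @param problem An [adder_problem()].
#' @param path File path.
#' @return `read_problem()` returns an [adder_problem()];
#'   `write_problem()` invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_problem(generate_problem(3, seed = 1), f)
#' read_problem(f)
#' @export
write_problem <- function(problem, path) {
  stopifnot(is_adder_problem(problem))
  obj <- list(
    version = .problem_format_version,
    rng = .rng_kind,
    leaves = purrr::pmap(problem$leaves, function(name, prior, unique_likelihood) {
      list(name = name, prior = prior, unique_likelihood = unique_likelihood)
    }),
    shared_likelihood = problem$shared_likelihood,
    generator = problem$generator)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
    null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_problem
#' @export
read_problem <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("no such problem file: %s", path),
      class = "convtree_schema")
  }
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(obj)) .io_fail("$", "top level must be an object")
  if (is.null(obj$leaves) || !is.list(obj$leaves) || length(obj$leaves) < 1L) {
    .io_fail("$.leaves", "must be a non-empty array of leaf objects")
  }
  leaves <- purrr::imap(obj$leaves, function(lf, i) {
    where <- sprintf("$.leaves[%d]", i)
    if (!is.list(lf) || is.null(lf$name)) .io_fail(where, "missing 'name'")
    prior <- .check_num_vec(lf$prior, paste0(where, ".prior"))
    uniq <- .check_num_vec(lf$unique_likelihood,
      paste0(where, ".unique_likelihood"))
    if (any(prior < 0)) .io_fail(paste0(where, ".prior"),
      "entries must be nonnegative")
    if (length(uniq) != length(prior)) {
      .io_fail(paste0(where, ".unique_likelihood"), sprintf(
        "length %d does not match prior length %d",
        length(uniq), length(prior)))
    }
    tryCatch(leaf_variable(lf$name, prior, uniq),
      convtree_invalid = function(e) .io_fail(where, conditionMessage(e)))
  })
  shared <- .check_num_vec(obj$shared_likelihood, "$.shared_likelihood")
  expected <- sum(purrr::map_int(leaves, ~ length(.x$prior) - 1L)) + 1L
  if (length(shared) != expected) {
    .io_fail("$.shared_likelihood", sprintf(
      "length %d does not match sum of leaf state spans (expected %d)",
      length(shared), expected))
  }
  gen <- obj$generator
  if (!is.null(gen)) {
    gen <- lapply(gen, function(x) if (is.list(x)) lapply(x, unlist) else unlist(x))
  }
  tryCatch(adder_problem(leaves, shared, generator = gen),
    convtree_invalid = function(e) .io_fail("$", conditionMessage(e)))
}
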