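#' One input variable of an adder problem
#'
#' A leaf couples a normalized prior over its states `0 .. s - 1` (for
#' protein inference `s = 2`: absent/present, with prior parameter gamma)
#' with the likelihood vector of its unique evidence, already folded into a
#' single product over that leaf's unique peptides.
#'
#' @param name Identifier for the leaf.
#' @param prior Numeric vector (or [count_pmf()]) of state prior
#'   probabilities, summing to 1.
#' @param unique_likelihood Numeric likelihood vector of the same length,
#'   nonnegative and not all zero. Defaults to the uninformative vector of
#'   ones.
#' @return A `leaf_variable` object.
#' @examples
#' leaf_variable("P1", prior = c(0.2, 0.8),
#'               unique_likelihood = c(0.65, 0.35))
#' @export
leaf_variable <- function(name, prior, unique_likelihood = NULL) {
  if (is_count_pmf(prior)) prior <- prior$weights
  prior <- as.numeric(prior)
  if (is.null(unique_likelihood)) unique_likelihood <- rep(1, length(prior))
  unique_likelihood <- as.numeric(unique_likelihood)
  if (length(prior) < 1L || anyNA(prior) || any(prior < 0)) {
    rlang::abort(sprintf("leaf '%s': prior must be nonnegative.", name),
      class = "convtree_invalid")
  }
  if (abs(sum(prior) - 1) > 1e-8) {
    rlang::abort(sprintf("leaf '%s': prior must sum to 1 (got %.17g).",
      name, sum(prior)), class = "convtree_invalid")
  }
  if (length(unique_likelihood) != length(prior)) {
    rlang::abort(sprintf(
      "leaf '%s': unique_likelihood length (%d) must match prior length (%d).",
      name, length(unique_likelihood), length(prior)),
      class = "convtree_invalid")
  }
  if (anyNA(unique_likelihood) || any(unique_likelihood < 0) ||
      all(unique_likelihood == 0)) {
    rlang::abort(sprintf(
      "leaf '%s': unique_likelihood must be nonnegative and not all zero.",
      name), class = "convtree_invalid")
  }
  structure(list(name = as.character(name), prior = prior,
                 unique_likelihood = unique_likelihood),
    class = "leaf_variable")
}

#' An inference problem over the sum of discrete leaves
#'
#' Bundles an ordered set of leaves with the likelihood of the shared
#' evidence, which depends on the leaves only through their total count
#' (or sum). Entry `k + 1` of `shared_likelihood` is the likelihood of the
#' shared data given total `k`, for `k = 0 .. sum(s_i - 1)`.
#'
#' @param leaves A list of [leaf_variable()] objects, or a data frame /
#'   tibble with columns `name`, `prior` (list-column), and
#'   `unique_likelihood` (list-column).
#' @param shared_likelihood Numeric vector over totals, nonnegative, not
#'   all zero, of length `sum(s_i - 1) + 1`.
#' @param generator Optional metadata (seed, configuration) recorded by
#'   [generate_problem()] and preserved by the file format.
#' @return An `adder_problem` object; its `$leaves` element is a tibble
#'   with one row per leaf.
#' @examples
#' p <- adder_problem(
#'   list(leaf_variable("A", c(0.2, 0.8), c(0.65, 0.35)),
#'        leaf_variable("B", c(0.5, 0.5))),
#'   shared_likelihood = c(0.2, 0.5, 0.3))
#' p
#' @export
adder_problem <- function(leaves, shared_likelihood, generator = NULL) {
  if (is.data.frame(leaves)) {
    leaves <- purrr::pmap(leaves[c("name", "prior", "unique_likelihood")],
      leaf_variable)
  }
  if (!is.list(leaves) || length(leaves) < 1L ||
      !all(purrr::map_lgl(leaves, inherits, "leaf_variable"))) {
    rlang::abort("`leaves` must be a non-empty list of leaf_variable objects.",
      class = "convtree_invalid")
  }
  nms <- purrr::map_chr(leaves, "name")
  if (anyDuplicated(nms)) {
    rlang::abort("leaf names must be unique.", class = "convtree_invalid")
  }
  max_count <- sum(purrr::map_int(leaves, ~ length(.x$prior) - 1L))
  shared_likelihood <- as.numeric(shared_likelihood)
  if (length(shared_likelihood) != max_count + 1L) {
    rlang::abort(sprintf(
      "shared_likelihood must have %d entries (totals 0..%d), got %d.",
      max_count + 1L, max_count, length(shared_likelihood)),
      class = "convtree_invalid")
  }
  if (anyNA(shared_likelihood) || any(shared_likelihood < 0) ||
      all(shared_likelihood == 0)) {
    rlang::abort("shared_likelihood must be nonnegative and not all zero.",
      class = "convtree_invalid")
  }
  structure(
    list(
      leaves = tibble::tibble(
        name = nms,
        prior = purrr::map(leaves, "prior"),
        unique_likelihood = purrr::map(leaves, "unique_likelihood")),
      shared_likelihood = shared_likelihood,
      generator = generator),
    class = "adder_problem")
}

#' @rdname adder_problem
#' @param x Object to test.
#' @export
is_adder_problem <- function(x) inherits(x, "adder_problem")

#' Number of leaves of a problem
#' @param problem An [adder_problem()].
#' @return Integer count of leaf variables.
#' @export
n_leaves <- function(problem) {
  stopifnot(is_adder_problem(problem))
  nrow(problem$leaves)
}

# state-space sizes s_i and per-leaf local weights prior * unique
.leaf_sizes <- function(problem) {
  purrr::map_int(problem$leaves$prior, length)
}

.leaf_weights <- function(problem) {
  purrr::map2(problem$leaves$prior, problem$leaves$unique_likelihood, `*`)
}

.max_count <- function(problem) {
  sum(.leaf_sizes(problem) - 1L)
}

#' @export
print.adder_problem <- function(x, ...) {
  s <- .leaf_sizes(x)
  cat(sprintf("<adder_problem> %d leaves (states %s), totals 0..%d\n",
    nrow(x$leaves),
    if (length(unique(s)) == 1L) as.character(s[1]) else paste(range(s), collapse = "-"),
    .max_count(x)))
  if (!is.null(x$generator)) {
    cat(sprintf("  generated: seed %s, mode %s, rng %s\n",
      x$generator$seed %||% "?", x$generator$mode %||% "?",
      x$generator$rng %||% "?"))
  }
  invisible(x)
}

#' @method tidy adder_problem
#' @export
tidy.adder_problem <- function(x, ...) {
  tidyr::unnest(
    dplyr::mutate(x$leaves,
      state = purrr::map(.data$prior, ~ seq_along(.x) - 1L)),
    c("state", "prior", "unique_likelihood"))
}
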