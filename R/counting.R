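#' Count integer tuples with a prescribed weighted sum
#'
#' Runs the convolution tree with unnormalized all-ones weight vectors
#' (a probabilistic generating function used non-probabilistically): the
#' root then holds, for every total `t`, the exact number of integer
#' tuples `(x_1, ..., x_k)` with `0 <= x_i <= max_counts[i]` and
#' `sum_i coefficients[i] * x_i = t`. This answers coin-change questions
#' (how many ways to make change) and the counting version of bounded
#' linear Diophantine equations. Given a `target`, an up pass conditioned
#' on that total also yields per-variable solution counts. All
#' convolutions take the direct (exact integer) path.
#'
#' @param coefficients Integer coefficients `c_i`, one per variable.
#' @param max_counts Integer upper bounds; variable `i` ranges over
#'   `0 .. max_counts[i]`.
#' @param target Optional target total `t`.
#' @return A list of class `tuple_counts`: `totals` (tibble of `total`,
#'   `count` over all achievable totals) and, when `target` is given,
#'   `target`, `count` (tuples hitting it), and `marginals` (tibble of
#'   `variable`, `value`, `count` of solutions per variable value).
#' @examples
#' # coins worth 1 and 2, up to two of each: ways to total 4
#' count_tuples(c(1, 2), c(2, 2), target = 4)
#' @export
count_tuples <- function(coefficients, max_counts, target = NULL) {
  coefficients <- as.integer(coefficients)
  max_counts <- as.integer(max_counts)
  k <- length(coefficients)
  if (k < 1L || length(max_counts) != k || anyNA(coefficients) ||
      anyNA(max_counts) || any(max_counts < 0L)) {
    rlang::abort("`coefficients` and `max_counts` must be equal-length integer vectors with nonnegative bounds.",
      class = "convtree_invalid")
  }
  wl <- purrr::map(max_counts, ~ rep(1, .x + 1L))
  nms <- paste0("x", seq_len(k))

  shared <- if (is.null(target)) count_pmf(1, offset = 0L)
    else count_pmf(1, offset = as.integer(target))
  tree <- .build_tree_impl(wl, nms, coefficients, shared,
    normalize = FALSE, method = "direct")
  tree <- pass_down(tree)

  L <- tree$depth
  root <- round(tree$above[[L + 1L]][[1L]])
  root_off <- tree$offsets[[L + 1L]][1L]
  totals <- tibble::tibble(
    total = root_off + seq_along(root) - 1L,
    count = root)

  out <- list(totals = totals)
  if (!is.null(target)) {
    target <- as.integer(target)
    out$target <- target
    ti <- target - root_off + 1L
    if (ti < 1L || ti > length(root) || root[ti] == 0) {
      out$count <- 0
      out$marginals <- tibble::tibble(
        variable = rep(nms, times = max_counts + 1L),
        value = unlist(purrr::map(max_counts, ~ 0:.x), use.names = FALSE),
        count = 0)
    } else {
      out$count <- root[ti]
      tree <- pass_up(tree)
      marg <- purrr::map(seq_len(k), function(i) {
        lf <- tree$leaves[[i]]
        b <- tree$below[[1L]][[i]]
        # works for detached (coef 0) variables too: the collapsed leaf's
        # below-message is the completion count shared by every value
        round(lf$w0 * b[lf$perm])
      })
      out$marginals <- tibble::tibble(
        variable = rep(nms, times = max_counts + 1L),
        value = unlist(purrr::map(max_counts, ~ 0:.x), use.names = FALSE),
        count = unlist(marg, use.names = FALSE))
    }
  }
  structure(out, class = "tuple_counts")
}

#' @export
print.tuple_counts <- function(x, ...) {
  if (!is.null(x$target)) {
    cat(sprintf("<tuple_counts> %g tuples reach target %d\n",
      x$count, x$target))
  } else {
    cat("<tuple_counts> counts per total:\n")
  }
  print(x$totals, n = Inf)
  invisible(x)
}
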