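#' A two-dimensional adder problem
#'
#' Each leaf carries a joint distribution over an integer *pair* (e.g.
#' discretized mass in the rows and valence in the columns), stored as a
#' [grid_pmf()] prior and an optional grid of unique-evidence
#' likelihoods; the shared evidence is a likelihood over the pairwise
#' total (row sum, column sum).
#'
#' @param leaves A list; each element is a list with `name`, `prior`
#'   (a [grid_pmf()]), and optional `unique_likelihood` (a [grid_pmf()]
#'   or matrix of the same dimensions; default uninformative).
#' @param shared_likelihood A [grid_pmf()] over achievable totals.
#' @return An `adder_problem_2d` object.
#' @export
adder_problem_2d <- function(leaves, shared_likelihood) {
  if (!is.list(leaves) || length(leaves) < 1L) {
    rlang::abort("`leaves` must be a non-empty list.", class = "convtree_invalid")
  }
  if (!is_grid_pmf(shared_likelihood)) {
    rlang::abort("`shared_likelihood` must be a grid_pmf.",
      class = "convtree_invalid")
  }
  leaves <- purrr::imap(leaves, function(lf, i) {
    nm <- lf$name %||% paste0("X", i)
    if (!is_grid_pmf(lf$prior)) {
      rlang::abort(sprintf("leaf '%s': prior must be a grid_pmf.", nm),
        class = "convtree_invalid")
    }
    u <- lf$unique_likelihood
    if (is.null(u)) {
      u <- grid_pmf(matrix(1, nrow(lf$prior$weights), ncol(lf$prior$weights)),
        lf$prior$row_offset, lf$prior$col_offset)
    } else if (!is_grid_pmf(u)) {
      u <- grid_pmf(as.matrix(u), lf$prior$row_offset, lf$prior$col_offset)
    }
    if (!identical(dim(u$weights), dim(lf$prior$weights))) {
      rlang::abort(sprintf(
        "leaf '%s': dimension mismatch between prior (%dx%d) and unique likelihood (%dx%d).",
        nm, nrow(lf$prior$weights), ncol(lf$prior$weights),
        nrow(u$weights), ncol(u$weights)), class = "convtree_invalid")
    }
    list(name = nm, prior = lf$prior, unique_likelihood = u)
  })
  structure(list(leaves = leaves, shared_likelihood = shared_likelihood),
    class = "adder_problem_2d")
}

.align_grid <- function(lik, row_off, col_off, nr, nc) {
  out <- matrix(0, nr, nc)
  ri <- (row_off + seq_len(nr) - 1L) - lik$row_offset + 1L
  ci <- (col_off + seq_len(nc) - 1L) - lik$col_offset + 1L
  okr <- which(ri >= 1L & ri <= nrow(lik$weights))
  okc <- which(ci >= 1L & ci <= ncol(lik$weights))
  if (length(okr) && length(okc)) {
    out[okr, okc] <- lik$weights[ri[okr], ci[okc], drop = FALSE]
  }
  out
}

#' Exact posteriors for a 2-D adder problem
#'
#' The message schedule is identical to [posteriors_convtree()] in every
#' dimension: leaves are paired into a balanced binary tree, down-messages
#' are two-dimensional convolutions of the parents' messages, up-messages
#' are 2-D correlations from which a contiguous submatrix is sliced, and
#' each posterior is the normalized entrywise product of a node's above-
#' and below-messages.
#'
#' @param problem2d An [adder_problem_2d()].
#' @param method Convolution method for [grid_convolve()].
#' @return A list of class `posterior_result_2d` with `leaf_posteriors`
#'   (normalized [grid_pmf()] per leaf), `count_posterior` (normalized
#'   [grid_pmf()] over the total), and `log_evidence`.
#' @export
posteriors_convtree_2d <- function(problem2d, method = "auto") {
  stopifnot(inherits(problem2d, "adder_problem_2d"))
  leaves <- problem2d$leaves

  st <- new.env(parent = emptyenv())
  st$log_scale <- 0
  st$leaf_post <- list()
  norm_tracked <- function(w, what) {
    z <- sum(w)
    if (z <= 0) {
      rlang::abort(sprintf(
        "zero total probability at %s: the model contradicts the evidence.",
        what), class = "convtree_contradiction")
    }
    st$log_scale <- st$log_scale + log(z)
    w / z
  }

  build <- function(lo, hi) {
    if (lo == hi) {
      lf <- leaves[[lo]]
      w <- lf$prior$weights * lf$unique_likelihood$weights
      return(list(leaf = lo,
        contrib = norm_tracked(w, sprintf("leaf '%s'", lf$name)),
        row_off = lf$prior$row_offset, col_off = lf$prior$col_offset))
    }
    mid <- lo + (hi - lo) %/% 2L
    left <- build(lo, mid)
    right <- build(mid + 1L, hi)
    w <- .conv2_raw(left$contrib, right$contrib, method)
    w[w < 0] <- 0
    list(left = left, right = right,
      contrib = norm_tracked(w, "an internal adder"),
      row_off = left$row_off + right$row_off,
      col_off = left$col_off + right$col_off)
  }

  up <- function(node, msg) {
    if (!is.null(node$leaf)) {
      lf <- leaves[[node$leaf]]
      post <- node$contrib * msg
      z <- sum(post)
      if (z <= 0) {
        rlang::abort(sprintf(
          "zero total probability at leaf '%s': the model contradicts the evidence.",
          lf$name), class = "convtree_contradiction")
      }
      st$leaf_post[[lf$name]] <- grid_pmf(post / z,
        row_offset = node$row_off, col_offset = node$col_off)
      return(invisible(NULL))
    }
    msg_l <- grid_backward_message(msg, node$right$contrib, method = method)
    msg_r <- grid_backward_message(msg, node$left$contrib, method = method)
    zl <- sum(msg_l); zr <- sum(msg_r)
    if (zl <= 0 || zr <= 0) {
      rlang::abort("zero total probability in a 2-D up-message: the model contradicts the evidence.",
        class = "convtree_contradiction")
    }
    up(node$left, msg_l / zl)
    up(node$right, msg_r / zr)
    invisible(NULL)
  }

  root <- build(1L, length(leaves))
  aligned <- .align_grid(problem2d$shared_likelihood,
    root$row_off, root$col_off, nrow(root$contrib), ncol(root$contrib))
  ev <- sum(root$contrib * aligned)
  if (ev <= 0) {
    rlang::abort("zero total probability at the root: the shared likelihood excludes every achievable total.",
      class = "convtree_contradiction")
  }
  log_evidence <- log(ev) + st$log_scale

  up(root, aligned)

  structure(list(
    leaf_posteriors = st$leaf_post[purrr::map_chr(leaves, "name")],
    count_posterior = grid_pmf(root$contrib * aligned / ev,
      row_offset = root$row_off, col_offset = root$col_off),
    log_evidence = log_evidence,
    engine = "convtree2d"),
    class = "posterior_result_2d")
}

#' @export
print.posterior_result_2d <- function(x, ...) {
  cat(sprintf("<posterior_result_2d> %d leaves, log P(data) = %.6f\n",
    length(x$leaf_posteriors), x$log_evidence))
  invisible(x)
}
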