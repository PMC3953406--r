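#' Build a probabilistic convolution tree
#'
#' Arranges the leaves of a problem into a layered binary tree of adder
#' nodes: leaves are paired left-to-right, their pairwise sums are paired
#' again, and so on up to the root, which carries the total. When the
#' number of leaves is not a power of two, dummy leaves - point masses at
#' 0 with no evidence - pad it to the next power, which provably leaves
#' every real posterior and the count distribution unchanged (a point
#' mass at 0 is the identity of convolution). Integer `coefficients`
#' attach a scaling node to each leaf, so the root carries
#' `sum_i c_i * X_i`; a zero coefficient detaches its leaf from the sum.
#'
#' @param problem An [adder_problem()].
#' @param coefficients Optional integer vector, one per leaf.
#' @param shared Optional replacement for the problem's shared likelihood:
#'   a [count_pmf()] over the achievable (scaled) sum. Required when
#'   negative coefficients shift the root support below zero.
#' @param normalize Normalize every message, tracking the scale in log
#'   space (the default; raw mode is used for unnormalized counting).
#' @param method Convolution method passed to [pmf_convolve()].
#' @return A `conv_tree` object; run [pass_down()] and [pass_up()] to fill
#'   its messages, or use [posteriors_convtree()] directly.
#' @export
build_tree <- function(problem, coefficients = NULL, shared = NULL,
                       normalize = TRUE, method = "auto") {
  stopifnot(is_adder_problem(problem))
  wl <- .leaf_weights(problem)
  if (is.null(shared)) {
    shared <- count_pmf(problem$shared_likelihood, offset = 0L)
  } else if (!is_count_pmf(shared)) {
    shared <- count_pmf(as.numeric(shared), offset = 0L)
  }
  .build_tree_impl(wl, problem$leaves$name, coefficients, shared,
    normalize, method)
}

.build_tree_impl <- function(wl, leaf_names, coefficients, shared,
                             normalize, method) {
  n <- length(wl)
  if (!is.null(coefficients)) {
    coefficients <- as.integer(coefficients)
    if (length(coefficients) != n) {
      rlang::abort("`coefficients` must supply one integer per leaf.",
        class = "convtree_invalid")
    }
  }
  depth <- if (n == 1L) 0L else ceiling(log2(n))
  N <- 2L^depth

  leaves <- vector("list", N)
  for (i in seq_len(N)) {
    if (i <= n) {
      w0 <- wl[[i]]
      ci <- if (is.null(coefficients)) 1L else coefficients[i]
      sc <- pmf_scale_support(count_pmf(w0, 0L), ci)
      leaves[[i]] <- list(
        dummy = FALSE, w0 = w0, coef = ci,
        scaled = sc$weights, offset = sc$offset,
        perm = .scale_permutation(length(w0), ci))
    } else {
      leaves[[i]] <- list(dummy = TRUE, w0 = 1, coef = 1L,
        scaled = 1, offset = 0L, perm = 1L)
    }
  }
  structure(
    list(n = n, N = N, depth = depth,
         leaf_names = leaf_names,
         leaves = leaves, shared = shared,
         normalize = normalize, method = method,
         above = NULL, below = NULL, offsets = NULL,
         log_scale = 0),
    class = "conv_tree")
}

#' @export
print.conv_tree <- function(x, ...) {
  cat(sprintf("<conv_tree> %d leaves (padded to %d), depth %d, messages %s\n",
    x$n, x$N, x$depth,
    if (is.null(x$above)) "not yet passed"
    else if (is.null(x$below)) "down only" else "down+up"))
  invisible(x)
}

#' Step 1: pass above-messages down the tree
#'
#' Computes, for every node, the joint probability of its value with all
#' data above it. The base case is each leaf's `prior * unique_likelihood`
#' (scaled if a coefficient is attached); each internal node's
#' above-message is the convolution of its two parents' messages. With
#' `normalize = TRUE` messages are rescaled layer by layer and the total
#' scale is tracked in log space, so the root message is the normalized
#' distribution of the total given all above-data.
#'
#' @param tree A `conv_tree` from [build_tree()].
#' @return The tree with `$above` (per-layer message lists), `$offsets`,
#'   and `$log_scale` filled in.
#' @export
pass_down <- function(tree) {
  stopifnot(inherits(tree, "conv_tree"))
  L <- tree$depth
  above <- vector("list", L + 1L)
  offs <- vector("list", L + 1L)
  log_scale <- 0

  lw <- vector("list", tree$N)
  lo <- integer(tree$N)
  for (i in seq_len(tree$N)) {
    w <- tree$leaves[[i]]$scaled
    if (tree$normalize) {
      z <- sum(w)
      if (z <= 0) {
        rlang::abort(sprintf(
          "zero total probability at leaf %d: the model contradicts the evidence.", i),
          class = "convtree_contradiction")
      }
      log_scale <- log_scale + log(z)
      w <- w / z
    }
    lw[[i]] <- w
    lo[i] <- tree$leaves[[i]]$offset
  }
  above[[1]] <- lw
  offs[[1]] <- lo

  if (L > 0L) for (l in seq_len(L)) {
    m <- length(above[[l]]) %/% 2L
    cur <- vector("list", m)
    co <- integer(m)
    for (j in seq_len(m)) {
      a <- .conv_raw(above[[l]][[2L * j - 1L]], above[[l]][[2L * j]],
        tree$method)
      a <- .clip_fft_negatives(a)
      if (tree$normalize) {
        z <- sum(a)
        if (z <= 0) {
          rlang::abort(sprintf(
            "zero total probability at node %d of layer %d.", j, l),
            class = "convtree_contradiction")
        }
        log_scale <- log_scale + log(z)
        a <- a / z
      }
      cur[[j]] <- a
      co[j] <- offs[[l]][2L * j - 1L] + offs[[l]][2L * j]
    }
    above[[l + 1L]] <- cur
    offs[[l + 1L]] <- co
  }
  tree$above <- above
  tree$offsets <- offs
  tree$log_scale <- log_scale
  tree
}

# align a count_pmf likelihood onto a node support given by (offset, len):
# values outside the likelihood's range have zero likelihood
.align_likelihood <- function(lik, offset, len) {
  out <- numeric(len)
  idx <- (offset + seq_len(len) - 1L) - lik$offset + 1L
  ok <- idx >= 1L & idx <= length(lik$weights)
  out[ok] <- lik$weights[idx[ok]]
  out
}

#' Step 2: pass below-messages up the tree
#'
#' Initializes the root's below-message with the shared-data likelihood
#' (aligned to the root's support) and propagates likelihood-given-data-
#' below messages toward the leaves: the message to the left parent is the
#' backward message of the node's below-message against the right parent's
#' above-message, and symmetrically. Messages are normalized with a
#' tracked scale; an all-zero message signals contradictory evidence and
#' aborts with the offending node named.
#'
#' @param tree A `conv_tree` on which [pass_down()] has been run.
#' @return The tree with `$below` filled in.
#' @export
pass_up <- function(tree) {
  stopifnot(inherits(tree, "conv_tree"))
  if (is.null(tree$above)) {
    rlang::abort("run pass_down() before pass_up().", class = "convtree_invalid")
  }
  L <- tree$depth
  below <- vector("list", L + 1L)
  root <- tree$above[[L + 1L]][[1L]]
  aligned <- .align_likelihood(tree$shared, tree$offsets[[L + 1L]][1L],
    length(root))
  if (all(aligned == 0)) {
    rlang::abort("zero total probability at the root: the shared likelihood excludes every achievable total.",
      class = "convtree_contradiction")
  }
  below[[L + 1L]] <- list(aligned)

  if (L > 0L) for (l in L:1L) {
    m <- length(tree$above[[l]])
    cur <- vector("list", m)
    for (j in seq_len(m %/% 2L)) {
      b <- below[[l + 1L]][[j]]
      left <- 2L * j - 1L; right <- 2L * j
      for (side in c(left, right)) {
        sib <- if (side == left) right else left
        msg <- pmf_backward_message(b, tree$above[[l]][[sib]],
          method = tree$method)
        if (tree$normalize) {
          z <- sum(msg)
          if (z <= 0) {
            rlang::abort(sprintf(
              "zero total probability in the message to node %d of layer %d.",
              side, l - 1L), class = "convtree_contradiction")
          }
          msg <- msg / z
        }
        cur[[side]] <- msg
      }
    }
    below[[l]] <- cur
  }
  tree$below <- below
  tree
}

#' Exact posteriors via the probabilistic convolution tree
#'
#' Runs [build_tree()], [pass_down()], and [pass_up()], then reads each
#' node's posterior off the product of its above- and below-messages
#' (normalized). Sub-quadratic time and `O(n log n)` message storage, so
#' it scales to tens of thousands of leaves where the quadratic chain
#' engine runs out of memory.
#'
#' @inheritParams build_tree
#' @param keep_tree Attach the message-filled tree to `$extra$tree`.
#' @return A [posterior_result()]. `$extra` records the padded size,
#'   total stored message length, and the convolution work counter used
#'   by the structural complexity checks.
#' @examples
#' p <- generate_problem(6, seed = 1)
#' posteriors_convtree(p)
#' @export
posteriors_convtree <- function(problem, coefficients = NULL, shared = NULL,
                                method = "auto", keep_tree = FALSE) {
  ops0 <- conv_ops()
  tree <- build_tree(problem, coefficients = coefficients, shared = shared,
    normalize = TRUE, method = method)
  tree <- pass_up(pass_down(tree))
  res <- .tree_posteriors(tree)
  res$extra$conv_ops <- conv_ops() - ops0
  if (keep_tree) res$extra$tree <- tree
  res
}

.tree_posteriors <- function(tree) {
  L <- tree$depth
  root_above <- tree$above[[L + 1L]][[1L]]
  root_below <- tree$below[[L + 1L]][[1L]]
  ev <- sum(root_above * root_below)
  if (ev <= 0) {
    rlang::abort("zero total probability: the model contradicts the evidence.",
      class = "convtree_contradiction")
  }
  log_evidence <- log(ev) + tree$log_scale

  leaf_post <- vector("list", tree$n)
  for (i in seq_len(tree$n)) {
    lf <- tree$leaves[[i]]
    b <- tree$below[[1L]][[i]]
    post <- if (lf$coef == 0L) lf$w0 else lf$w0 * b[lf$perm]
    leaf_post[[i]] <- count_pmf(
      pmf_normalize(post, what = sprintf("leaf '%s'", tree$leaf_names[i])),
      normalized = TRUE)
  }
  names(leaf_post) <- tree$leaf_names

  count_post <- pmf_normalize(root_above * root_below)

  posterior_result(
    leaf_posteriors = leaf_post,
    count_posterior = count_pmf(count_post,
      offset = tree$offsets[[L + 1L]][1L], normalized = TRUE),
    log_evidence = log_evidence,
    engine = "convtree",
    extra = list(
      padded_n = tree$N,
      message_cells = tree_message_cells(tree)))
}

#' Structural size of a tree's stored messages
#'
#' Total length of all stored above- and below-messages, the quantity
#' bounded by `4 * N * (log2(N) + 1)` for binary leaves - the near-linear
#' space behaviour that distinguishes the convolution tree from the
#' quadratic chain table.
#'
#' @param tree A message-filled `conv_tree`.
#' @return Total stored message length (double).
#' @export
tree_message_cells <- function(tree) {
  stopifnot(inherits(tree, "conv_tree"))
  cells <- 0
  if (!is.null(tree$above)) {
    cells <- cells + sum(vapply(tree$above, function(l) sum(lengths(l)), 0))
  }
  if (!is.null(tree$below)) {
    cells <- cells + sum(vapply(tree$below, function(l) sum(lengths(l)), 0))
  }
  cells
}

#' Posterior distributions of the internal adder nodes
#'
#' Each internal node's posterior over its partial sum is the normalized
#' product of its above- and below-messages.
#'
#' @param tree A `conv_tree` after [pass_down()] and [pass_up()].
#' @return A list over layers `1 .. depth`; each element is a list of
#'   normalized [count_pmf()] objects for the nodes of that layer
#'   (layer `depth` holds the root).
#' @export
tree_node_posteriors <- function(tree) {
  stopifnot(inherits(tree, "conv_tree"))
  if (is.null(tree$below)) {
    rlang::abort("run pass_down() and pass_up() first.",
      class = "convtree_invalid")
  }
  purrr::map(seq_len(tree$depth), function(l) {
    purrr::map(seq_along(tree$above[[l + 1L]]), function(j) {
      count_pmf(
        pmf_normalize(tree$above[[l + 1L]][[j]] * tree$below[[l + 1L]][[j]],
          what = sprintf("node %d of layer %d", j, l)),
        offset = tree$offsets[[l + 1L]][j], normalized = TRUE)
    })
  })
}
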