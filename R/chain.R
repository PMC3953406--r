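#' Quadratic forward-backward inference over partial sums
#'
#' The chain engine unrolls the sum one leaf at a time (Heckerman's
#' temporal transform): layer `i` holds a weight vector over the partial
#' sum of the first `i` leaves. `chain_forward()` computes the left pass
#' `l_i`, starting from a point mass at 0 and propagating
#' `l_{i+1}(k) = sum_x l_i(k - x) * w_{i+1}(x)` with the per-leaf edge
#' weights `w_i(x) = prior_i(x) * unique_i(x)` (out-of-bound indices are
#' zero). `chain_backward()` computes the right pass `r_i`, initialized at
#' the final layer with the shared-data likelihood and propagated by
#' `r_i(k) = sum_x r_{i+1}(k + x) * w_{i+1}(x)`. Time and table space are
#' quadratic in the number of (binary) leaves.
#'
#' With `renormalize = TRUE` (the default for [posteriors_chain()]) each
#' layer is rescaled to sum to one and the scale is tracked in log space,
#' so the engine survives thousands of leaves; raw mode keeps the
#' unnormalized tables, for which `sum_k l_i(k) r_i(k)` is the same total
#' evidence at every layer.
#'
#' @param problem An [adder_problem()].
#' @param renormalize Rescale each layer, tracking the log scale factor.
#' @return For the passes, a list with `layers` (list of numeric vectors,
#'   layer 0 first for the forward pass, layer n last for the backward
#'   pass) and `log_scale`. [posteriors_chain()] returns a
#'   [posterior_result()].
#' @examples
#' p <- generate_problem(6, seed = 1)
#' posteriors_chain(p)
#' @export
chain_forward <- function(problem, renormalize = FALSE) {
  stopifnot(is_adder_problem(problem))
  wl <- .leaf_weights(problem)
  layers <- vector("list", length(wl) + 1L)
  layers[[1]] <- 1
  log_scale <- 0
  for (i in seq_along(wl)) {
    w <- wl[[i]]
    prev <- layers[[i]]
    np <- length(prev)
    li <- numeric(np + length(w) - 1L)
    for (x in seq_along(w)) {
      if (w[x] != 0) {
        li[x:(x + np - 1L)] <- li[x:(x + np - 1L)] + w[x] * prev
      }
    }
    if (renormalize) {
      z <- sum(li)
      if (z <= 0) {
        rlang::abort(sprintf(
          "zero total probability at forward layer %d: the model contradicts the evidence.", i),
          class = "convtree_contradiction")
      }
      log_scale <- log_scale + log(z)
      li <- li / z
    }
    layers[[i + 1L]] <- li
  }
  list(layers = layers, log_scale = log_scale)
}

#' @rdname chain_forward
#' @export
chain_backward <- function(problem, renormalize = FALSE) {
  stopifnot(is_adder_problem(problem))
  wl <- .leaf_weights(problem)
  n <- length(wl)
  sizes <- lengths(wl)
  len <- cumsum(c(1L, sizes - 1L))  # layer i has len[i + 1] cells
  layers <- vector("list", n + 1L)
  layers[[n + 1L]] <- problem$shared_likelihood
  log_scale <- 0
  for (i in n:1) {
    w <- wl[[i]]
    nxt <- layers[[i + 1L]]
    np <- len[i]
    ri <- numeric(np)
    for (x in seq_along(w)) {
      if (w[x] != 0) ri <- ri + w[x] * nxt[x:(x + np - 1L)]
    }
    if (renormalize) {
      z <- sum(ri)
      if (z <= 0) {
        rlang::abort(sprintf(
          "zero total probability at backward layer %d: the model contradicts the evidence.", i - 1L),
          class = "convtree_contradiction")
      }
      log_scale <- log_scale + log(z)
      ri <- ri / z
    }
    layers[[i]] <- ri
  }
  list(layers = layers, log_scale = log_scale)
}

#' @rdname chain_forward
#' @export
posteriors_chain <- function(problem, renormalize = TRUE) {
  stopifnot(is_adder_problem(problem))
  fwd <- chain_forward(problem, renormalize = renormalize)
  bwd <- chain_backward(problem, renormalize = renormalize)
  wl <- .leaf_weights(problem)
  n <- length(wl)

  ln <- fwd$layers[[n + 1L]]
  ev <- sum(ln * problem$shared_likelihood)
  if (ev <= 0) {
    rlang::abort("zero total probability: the model contradicts the evidence.",
      class = "convtree_contradiction")
  }
  log_evidence <- log(ev) + fwd$log_scale

  # posterior by the three-factor path sum l_{i-1}(k) w_i(x) r_i(k + x);
  # no division by priors anywhere, so states with zero prior stay exact
  leaf_post <- vector("list", n)
  for (i in seq_len(n)) {
    w <- wl[[i]]
    lprev <- fwd$layers[[i]]
    rnext <- bwd$layers[[i + 1L]]
    np <- length(lprev)
    post <- vapply(seq_along(w), function(x) {
      w[x] * sum(lprev * rnext[x:(x + np - 1L)])
    }, numeric(1))
    leaf_post[[i]] <- count_pmf(
      pmf_normalize(post, what = sprintf("leaf '%s'", problem$leaves$name[i])),
      normalized = TRUE)
  }
  names(leaf_post) <- problem$leaves$name

  count_post <- pmf_normalize(ln * problem$shared_likelihood)

  cells <- sum(lengths(fwd$layers)) + sum(lengths(bwd$layers))
  posterior_result(
    leaf_posteriors = leaf_post,
    count_posterior = count_pmf(count_post, normalized = TRUE),
    log_evidence = log_evidence,
    engine = "chain",
    extra = list(table_cells = cells))
}
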