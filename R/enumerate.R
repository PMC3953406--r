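#' Exact posteriors by power-set / product-space enumeration
#'
#' The brute-force correctness oracle: every joint configuration of the
#' leaves is visited once, with weight
#' `prod_i prior_i(x_i) * unique_i(x_i) * shared(sum_i x_i)`. A single
#' pass accumulates the total (the evidence, i.e. the denominator of the
#' posterior) and every per-leaf constrained sum (the numerators)
#' simultaneously. Exponential in the number of leaves; refuses problems
#' whose joint state space exceeds `cap`.
#'
#' Per-leaf weights are normalized with a tracked log scale factor so the
#' joint table cannot underflow near the cap.
#'
#' @param problem An [adder_problem()].
#' @param cap Maximum allowed number of joint configurations
#'   (default `2^22`).
#' @return A [posterior_result()]; `$extra$configurations` records how
#'   many joint states were enumerated.
#' @examples
#' p <- generate_problem(4, seed = 7)
#' posteriors_by_enumeration(p)
#' @export
posteriors_by_enumeration <- function(problem, cap = 2^22) {
  stopifnot(is_adder_problem(problem))
  s <- .leaf_sizes(problem)
  n_config <- prod(s)
  if (n_config > cap) {
    rlang::abort(sprintf(
      "problem too large for oracle: %g joint configurations exceed cap %g.",
      n_config, cap), class = "convtree_too_large")
  }
  wl <- .leaf_weights(problem)

  # expand the joint table leaf by leaf; leaf 1 varies fastest, so the
  # 0-based configuration index decomposes in mixed radix over (s_1, s_2, ...)
  w <- 1
  sums <- 0L
  log_scale <- 0
  for (i in seq_along(wl)) {
    zi <- sum(wl[[i]])
    log_scale <- log_scale + log(zi)
    w <- as.vector(outer(w, wl[[i]] / zi))
    sums <- as.vector(outer(sums, seq_along(wl[[i]]) - 1L, `+`))
  }
  joint <- w * problem$shared_likelihood[sums + 1L]
  total <- sum(joint)
  if (total <= 0) {
    rlang::abort("zero total probability: the model contradicts the evidence.",
      class = "convtree_contradiction")
  }

  kmax <- .max_count(problem)
  count_post <- vapply(0:kmax, function(k) sum(joint[sums == k]), numeric(1))

  idx <- seq_len(n_config) - 1
  base <- 1
  leaf_post <- vector("list", length(s))
  for (i in seq_along(s)) {
    xi <- (idx %/% base) %% s[i]
    post <- vapply(0:(s[i] - 1L), function(x) sum(joint[xi == x]), numeric(1))
    leaf_post[[i]] <- count_pmf(post / total, normalized = TRUE)
    base <- base * s[i]
  }
  names(leaf_post) <- problem$leaves$name

  posterior_result(
    leaf_posteriors = leaf_post,
    count_posterior = count_pmf(count_post / total, normalized = TRUE),
    log_evidence = log(total) + log_scale,
    engine = "enumeration",
    extra = list(configurations = n_config))
}

#' 2-D posteriors by joint-state enumeration
#'
#' Brute-force oracle for problems whose leaves carry two additive
#' quantities (a [grid_pmf()] prior and unique likelihood each): every
#' joint assignment of (row, col) pairs to leaves is weighted by the
#' product of local weights times the shared likelihood of the total
#' (row sum, col sum).
#'
#' @param problem2d An [adder_problem_2d()].
#' @param cap Maximum joint configurations.
#' @return A list with `leaf_posteriors` (list of normalized
#'   [grid_pmf()]), `count_posterior` (normalized [grid_pmf()] over
#'   totals), and `log_evidence`.
#' @export
posteriors_by_enumeration_2d <- function(problem2d, cap = 2^20) {
  stopifnot(inherits(problem2d, "adder_problem_2d"))
  leaves <- problem2d$leaves
  sizes <- purrr::map_int(leaves, ~ length(.x$prior$weights))
  n_config <- prod(sizes)
  if (n_config > cap) {
    rlang::abort(sprintf(
      "problem too large for oracle: %g joint configurations exceed cap %g.",
      n_config, cap), class = "convtree_too_large")
  }
  shared <- problem2d$shared_likelihood

  w <- 1; sr <- 0L; sc <- 0L
  for (lf in leaves) {
    lw <- as.vector(lf$prior$weights * lf$unique_likelihood$weights)
    nr <- nrow(lf$prior$weights); nc <- ncol(lf$prior$weights)
    vr <- rep(lf$prior$row_offset + seq_len(nr) - 1L, times = nc)
    vc <- rep(lf$prior$col_offset + seq_len(nc) - 1L, each = nr)
    w <- as.vector(outer(w, lw))
    sr <- as.vector(outer(sr, vr, `+`))
    sc <- as.vector(outer(sc, vc, `+`))
  }
  ri <- sr - shared$row_offset + 1L
  ci <- sc - shared$col_offset + 1L
  ok <- ri >= 1L & ri <= nrow(shared$weights) & ci >= 1L & ci <= ncol(shared$weights)
  sw <- numeric(length(w))
  sw[ok] <- shared$weights[cbind(ri[ok], ci[ok])]
  joint <- w * sw
  total <- sum(joint)
  if (total <= 0) {
    rlang::abort("zero total probability: the model contradicts the evidence.",
      class = "convtree_contradiction")
  }

  idx <- seq_len(n_config) - 1
  base <- 1
  leaf_post <- vector("list", length(leaves))
  for (i in seq_along(leaves)) {
    pr <- leaves[[i]]$prior
    si <- sizes[i]
    xi <- (idx %/% base) %% si
    post <- vapply(0:(si - 1L), function(x) sum(joint[xi == x]), numeric(1))
    leaf_post[[i]] <- grid_pmf(
      matrix(post / total, nrow(pr$weights), ncol(pr$weights)),
      row_offset = pr$row_offset, col_offset = pr$col_offset)
    base <- base * si
  }
  names(leaf_post) <- purrr::map_chr(leaves, "name")

  ro <- min(sr); co <- min(sc)
  cp <- matrix(0, max(sr) - ro + 1L, max(sc) - co + 1L)
  for (j in seq_along(joint)) {
    cp[sr[j] - ro + 1L, sc[j] - co + 1L] <-
      cp[sr[j] - ro + 1L, sc[j] - co + 1L] + joint[j]
  }
  list(
    leaf_posteriors = leaf_post,
    count_posterior = grid_pmf(cp / total, row_offset = ro, col_offset = co),
    log_evidence = log(total))
}
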