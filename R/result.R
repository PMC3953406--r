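#' Posterior inference result
#'
#' The common return type of the three engines: per-leaf posterior
#' distributions, the posterior distribution of the total count at the
#' root, and the log of the total probability of the data.
#'
#' @param leaf_posteriors Named list of normalized [count_pmf()] objects,
#'   one per leaf, in problem order.
#' @param count_posterior Normalized [count_pmf()] over the total.
#' @param log_evidence Log of P(all data).
#' @param engine Character tag of the engine that produced the result.
#' @param extra Optional engine-specific diagnostics (counters, tables).
#' @return An object of class `posterior_result`.
#' @export
posterior_result <- function(leaf_posteriors, count_posterior, log_evidence,
                             engine, extra = list()) {
  stopifnot(is.list(leaf_posteriors),
            all(purrr::map_lgl(leaf_posteriors, is_count_pmf)),
            is_count_pmf(count_posterior))
  structure(
    list(leaf_posteriors = leaf_posteriors,
         count_posterior = count_posterior,
         log_evidence = log_evidence,
         engine = engine,
         extra = extra),
    class = "posterior_result")
}

#' @export
print.posterior_result <- function(x, ...) {
  cat(sprintf("<posterior_result> engine = %s, %d leaves, log P(data) = %.6f\n",
    x$engine, length(x$leaf_posteriors), x$log_evidence))
  cat("P(present) per leaf (1 - P(state 0)):\n")
  p <- purrr::map_dbl(x$leaf_posteriors, ~ 1 - .x$weights[1])
  print(round(p, 6))
  invisible(x)
}

#' Tidy a posterior result into one row per leaf state
#'
#' @param x A `posterior_result`.
#' @param ... Unused.
#' @return A tibble with columns `leaf`, `state`, and `posterior`.
#' @method tidy posterior_result
#' @export
tidy.posterior_result <- function(x, ...) {
  tibble::tibble(
    leaf = rep(names(x$leaf_posteriors),
               times = purrr::map_int(x$leaf_posteriors, ~ length(.x$weights))),
    state = unlist(purrr::map(x$leaf_posteriors, pmf_support), use.names = FALSE),
    posterior = unlist(purrr::map(x$leaf_posteriors, "weights"),
                       use.names = FALSE))
}

#' One-row summary of a posterior result
#'
#' @param x A `posterior_result`.
#' @param ... Unused.
#' @return A tibble with `engine`, `n_leaves`, `log_evidence`, and the
#'   posterior expectation of the total count.
#' @method glance posterior_result
#' @export
glance.posterior_result <- function(x, ...) {
  cp <- x$count_posterior
  tibble::tibble(
    engine = x$engine,
    n_leaves = length(x$leaf_posteriors),
    log_evidence = x$log_evidence,
    expected_count = sum(pmf_support(cp) * cp$weights))
}

#' Plot leaf posteriors and the posterior count distribution
#'
#' @param object A `posterior_result`.
#' @param ... Unused.
#' @return A ggplot: per-leaf posterior bars faceted over leaves, or, via
#'   [plot_count_posterior()], the distribution of the total.
#' @method autoplot posterior_result
#' @export
autoplot.posterior_result <- function(object, ...) {
  td <- tidy(object)
  td$leaf <- factor(td$leaf, levels = unique(td$leaf))
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$state), y = .data$posterior)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~leaf) +
    ggplot2::labs(x = "state", y = "posterior probability",
      title = sprintf("Leaf posteriors (%s engine)", object$engine)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.posterior_result
#' @export
plot_count_posterior <- function(object, ...) {
  stopifnot(inherits(object, "posterior_result"))
  td <- tidy(object$count_posterior)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$value, y = .data$weight)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "total count / sum", y = "posterior probability",
      title = "Posterior distribution of the total") +
    ggplot2::theme_minimal()
}

# largest absolute difference between two results over all leaf-posterior
# entries and the count posterior (supports must match)
.result_max_diff <- function(a, b) {
  d <- max(purrr::map2_dbl(a$leaf_posteriors, b$leaf_posteriors,
    ~ max(abs(.x$weights - .y$weights))))
  max(d, max(abs(a$count_posterior$weights - b$count_posterior$weights)))
}
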