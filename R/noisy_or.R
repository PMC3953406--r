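#' Noisy-or peptide evidence
#'
#' In the Bayesian protein-inference model, each peptide is generated by a
#' noisy-or: every present parent protein independently emits the peptide
#' with probability `alpha`, and a noise process creates it with
#' probability `beta`, so the peptide is absent with probability
#' `(1 - beta) * (1 - alpha)^x` when `x` parents are present. The PSM
#' `score` is the probability that the peptide matched an observed
#' spectrum.
#'
#' @param alpha Emission probability in `[0, 1]`.
#' @param beta Noise probability in `[0, 1]`.
#' @param score Probability the peptide matched observed spectra, in
#'   `[0, 1]`.
#' @return An object of class `noisy_or_peptide`.
#' @examples
#' noisy_or_peptide(alpha = 1, beta = 0, score = 0.35)
#' @export
noisy_or_peptide <- function(alpha, beta, score) {
  for (nm in c("alpha", "beta", "score")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      rlang::abort(sprintf("`%s` must be a single probability in [0, 1].", nm),
        class = "convtree_invalid")
    }
  }
  structure(list(alpha = alpha, beta = beta, score = score),
    class = "noisy_or_peptide")
}

#' @export
print.noisy_or_peptide <- function(x, ...) {
  cat(sprintf("<noisy_or_peptide> alpha = %g, beta = %g, score = %g\n",
    x$alpha, x$beta, x$score))
  invisible(x)
}

# P(peptide data | x present parents): the peptide is absent iff it came
# from neither the noise model nor any of the x present parents.
.noisy_or_data_lik <- function(p, x) {
  absent <- (1 - p$beta) * (1 - p$alpha)^x
  p$score * (1 - absent) + (1 - p$score) * absent
}

#' Likelihood of a unique peptide's data over its protein's states
#'
#' For a peptide adjacent to a single protein with `states` possible copy
#' numbers `0 .. states - 1`, returns the likelihood vector entry
#' `x = score * (1 - (1 - beta) * (1 - alpha)^x) +
#' (1 - score) * (1 - beta) * (1 - alpha)^x`. Several unique peptides for
#' the same protein combine by entrywise product (conditionally
#' independent PSMs).
#'
#' @param p A [noisy_or_peptide()].
#' @param states Number of states of the parent variable (2 for
#'   present/absent protein inference).
#' @return Numeric likelihood vector of length `states`.
#' @examples
#' # a certain emitter with score 0.35: relative likelihoods 0.65 vs 0.35
#' noisy_or_unique_likelihood(noisy_or_peptide(1, 0, 0.35), states = 2)
#' @export
noisy_or_unique_likelihood <- function(p, states = 2L) {
  stopifnot(inherits(p, "noisy_or_peptide"), states >= 1L)
  .noisy_or_data_lik(p, seq_len(states) - 1)
}

#' Likelihood of a shared peptide's data over the number of present parents
#'
#' A peptide shared by `n` proteins with identical emission parameters
#' depends on its parents only through how many are present: marginalizing
#' over *which* proteins are present can be replaced by marginalizing over
#' the count. Entry `k` (for `k = 0 .. n`) is the same closed form as
#' [noisy_or_unique_likelihood()] evaluated at `k`. Multiple shared
#' peptides combine by entrywise product.
#'
#' @param p A [noisy_or_peptide()].
#' @param n Number of parent proteins (>= 1).
#' @return Numeric likelihood vector of length `n + 1` over counts `0..n`.
#' @export
noisy_or_count_likelihood <- function(p, n) {
  stopifnot(inherits(p, "noisy_or_peptide"), n >= 1L)
  .noisy_or_data_lik(p, 0:n)
}
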