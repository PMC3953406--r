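# Run code under a private, named RNG stream without disturbing the
# caller's .Random.seed. The algorithm identifier is recorded in generated
# problems so files reproduce across runs.
.rng_kind <- "Mersenne-Twister"

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = .rng_kind)
  force(code)
}

.check_range <- function(r, nm, lo = 0, hi = 1) {
  if (!is.numeric(r) || length(r) != 2L || anyNA(r) || r[1] > r[2] ||
      r[1] < lo || r[2] > hi) {
    rlang::abort(sprintf("`%s` must be an ordered range within [%g, %g].",
      nm, lo, hi), class = "convtree_invalid")
  }
}

#' Generate a random benchmark problem
#'
#' Draws a splice-variant-style inference problem over `n` binary leaves
#' (proteins). Each protein gets one unique noisy-or peptide with emission
#' probability `alpha`, noise probability `beta`, and PSM score drawn
#' uniformly from their ranges, folded into the leaf's unique-evidence
#' likelihood, and a protein-specific prior drawn uniformly from
#' `prior_range`. The shared evidence is, by default, an arbitrary
#' categorical likelihood over the number of present proteins `0 .. n`
#' (entries uniform on (0, 1), normalized to sum to one) - the
#' configuration used for engine benchmarking. In `"shared-peptides"` mode
#' it is instead the entrywise product of the count likelihoods of between
#' 1 and 9 shared noisy-or peptides, the model-faithful construction.
#'
#' The same `seed` always reproduces the identical problem; the RNG
#' algorithm identifier is recorded in the problem's generator metadata
#' and in files written by [write_problem()].
#'
#' @param n Number of leaves (>= 1).
#' @param seed Integer RNG seed; if `NULL` one is drawn and recorded.
#' @param mode `"categorical"` (default) or `"shared-peptides"`.
#' @param alpha_range,beta_range,score_range Uniform ranges in `[0, 1]`
#'   for the peptide parameters.
#' @param prior_range Uniform range for protein priors; bounded away from
#'   0 and 1 by default so that no state is a priori impossible.
#' @param shared_peptides_range Integer range for the number of shared
#'   peptides in `"shared-peptides"` mode.
#' @return An [adder_problem()] with generator metadata attached.
#' @examples
#' generate_problem(4, seed = 7)
#' @export
generate_problem <- function(n, seed = NULL,
                             mode = c("categorical", "shared-peptides"),
                             alpha_range = c(0, 1),
                             beta_range = c(0, 1),
                             score_range = c(0, 1),
                             prior_range = c(1e-6, 1 - 1e-6),
                             shared_peptides_range = c(1L, 9L)) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) {
    rlang::abort("`n` must be an integer >= 1.", class = "convtree_invalid")
  }
  .check_range(alpha_range, "alpha_range")
  .check_range(beta_range, "beta_range")
  .check_range(score_range, "score_range")
  .check_range(prior_range, "prior_range")
  if (shared_peptides_range[1] < 1 ||
      shared_peptides_range[1] > shared_peptides_range[2]) {
    rlang::abort("`shared_peptides_range` must be an ordered integer range >= 1.",
      class = "convtree_invalid")
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)

  .with_seed(seed, {
    runifr <- function(k, r) stats::runif(k, r[1], r[2])
    leaves <- purrr::map(seq_len(n), function(i) {
      pep <- noisy_or_peptide(runifr(1, alpha_range), runifr(1, beta_range),
                              runifr(1, score_range))
      gamma <- runifr(1, prior_range)
      leaf_variable(paste0("X", i), prior = c(1 - gamma, gamma),
        unique_likelihood = noisy_or_unique_likelihood(pep, 2L))
    })
    shared <- if (mode == "categorical") {
      w <- stats::runif(n + 1L)
      w / sum(w)
    } else {
      k <- sample(seq.int(shared_peptides_range[1], shared_peptides_range[2]), 1L)
      lik <- rep(1, n + 1L)
      for (j in seq_len(k)) {
        pep <- noisy_or_peptide(runifr(1, alpha_range), runifr(1, beta_range),
                                runifr(1, score_range))
        lik <- lik * noisy_or_count_likelihood(pep, n)
      }
      lik
    }
    adder_problem(leaves, shared, generator = list(
      seed = seed, mode = mode, rng = .rng_kind,
      config = list(
        n = n, alpha_range = alpha_range, beta_range = beta_range,
        score_range = score_range, prior_range = prior_range,
        shared_peptides_range = as.integer(shared_peptides_range))))
  })
}
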