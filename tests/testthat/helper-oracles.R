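# Brute-force oracles, kept deliberately naive and independent of the
# package's convolution/message-passing code paths.

# direct double-sum convolution
conv_oracle <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
    }
  }
  out
}

# quadruple-loop 2-D convolution
conv2_oracle <- function(a, b) {
  out <- matrix(0, nrow(a) + nrow(b) - 1L, ncol(a) + ncol(b) - 1L)
  for (i1 in seq_len(nrow(a))) for (j1 in seq_len(ncol(a))) {
    for (i2 in seq_len(nrow(b))) for (j2 in seq_len(ncol(b))) {
      out[i1 + i2 - 1L, j1 + j2 - 1L] <-
        out[i1 + i2 - 1L, j1 + j2 - 1L] + a[i1, j1] * b[i2, j2]
    }
  }
  out
}

# full product-space enumeration with an arbitrary joint-likelihood
# function over the state vector; wl is the list of per-leaf local
# weights prior * unique. Returns normalized per-leaf posteriors and the
# total evidence.
enum_oracle <- function(wl, lik_fn) {
  grid <- expand.grid(lapply(wl, function(w) seq_along(w) - 1L),
    KEEP.OUT.ATTRS = FALSE)
  w <- apply(grid, 1L, function(x) {
    prod(mapply(function(wi, xi) wi[xi + 1L], wl, x)) * lik_fn(as.numeric(x))
  })
  total <- sum(w)
  post <- lapply(seq_along(wl), function(i) {
    vapply(seq_along(wl[[i]]) - 1L,
      function(s) sum(w[grid[[i]] == s]), numeric(1)) / total
  })
  list(posteriors = post, total = total)
}

# random problem with arbitrary per-leaf state counts
random_problem <- function(n, seed, sizes = rep(2L, n)) {
  set.seed(seed)
  leaves <- lapply(seq_len(n), function(i) {
    pr <- runif(sizes[i]) + 0.05
    leaf_variable(paste0("X", i), pr / sum(pr),
      unique_likelihood = runif(sizes[i]) + 0.05)
  })
  k <- sum(sizes - 1L) + 1L
  sh <- runif(k)
  adder_problem(leaves, sh / sum(sh))
}

max_posterior_diff <- function(a, b) {
  d <- max(mapply(function(x, y) max(abs(x$weights - y$weights)),
    a$leaf_posteriors, b$leaf_posteriors))
  max(d, max(abs(a$count_posterior$weights - b$count_posterior$weights)))
}
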