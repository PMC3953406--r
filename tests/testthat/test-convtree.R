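test_that("tree structure is forced by the leaf count", {
  p <- generate_problem(4, seed = 1)
  tr <- build_tree(p)
  expect_equal(tr$depth, 2L)
  expect_equal(tr$N, 4L)

  p3 <- generate_problem(3, seed = 1)
  tr3 <- build_tree(p3)
  expect_equal(tr3$N, 4L)
  expect_true(tr3$leaves[[4]]$dummy)

  p1 <- generate_problem(1, seed = 1)
  expect_equal(build_tree(p1)$depth, 0L)
})

test_that("down-messages are the layered convolutions", {
  # two even priors, no evidence: root above is the binomial
  p <- adder_problem(list(leaf_variable("A", c(0.5, 0.5)),
                          leaf_variable("B", c(0.5, 0.5))), rep(1, 3))
  tr <- pass_down(build_tree(p, normalize = FALSE))
  expect_equal(tr$above[[2]][[1]], c(0.25, 0.5, 0.25))

  # leaf above-message is prior * unique, the printed 0.13 / 0.28 case
  p <- adder_problem(list(leaf_variable("A", c(0.2, 0.8), c(0.65, 0.35)),
                          leaf_variable("B", c(0.5, 0.5))), rep(1, 3))
  tr <- pass_down(build_tree(p, normalize = FALSE))
  expect_equal(tr$above[[1]][[1]], c(0.13, 0.28))
})

test_that("the normalized root above-message equals the chain's final layer", {
  for (seed in 1:10) {
    n <- sample(2:20, 1)
    p <- generate_problem(n, seed = 900 + seed)
    tr <- pass_down(build_tree(p))
    root <- tr$above[[tr$depth + 1L]][[1]]
    ln <- chain_forward(p)$layers[[n + 1L]]
    expect_lt(max(abs(root / sum(root) - ln / sum(ln))), 1e-10)
  }
})

test_that("up-messages recover independence and forced counts", {
  # uninformative shared data: posteriors collapse to prior * unique
  p <- random_problem(4, seed = 31)
  p$shared_likelihood <- rep(1, 5)
  r <- posteriors_convtree(p)
  for (i in 1:4) {
    w <- p$leaves$prior[[i]] * p$leaves$unique_likelihood[[i]]
    expect_equal(r$leaf_posteriors[[i]]$weights, w / sum(w),
      tolerance = 1e-12)
  }

  # count forced to 2 with two binary leaves: both present
  p <- adder_problem(list(leaf_variable("A", c(0.2, 0.8), c(0.65, 0.35)),
                          leaf_variable("B", c(0.5, 0.5))), c(0, 0, 1))
  r <- posteriors_convtree(p)
  expect_equal(r$leaf_posteriors$A$weights, c(0, 1))
  expect_equal(r$leaf_posteriors$B$weights, c(0, 1))
  expect_equal(r$count_posterior$weights, c(0, 0, 1))
})

test_that("convolution-tree posteriors equal the enumeration oracle", {
  worst <- 0
  for (seed in 1:50) {
    n <- sample(2:12, 1)
    sizes <- sample(2:3, n, replace = TRUE)
    p <- random_problem(n, seed = 1200 + seed, sizes = sizes)
    d <- max_posterior_diff(posteriors_convtree(p),
      posteriors_by_enumeration(p))
    worst <- max(worst, d)
    expect_equal(posteriors_convtree(p)$log_evidence,
      posteriors_by_enumeration(p)$log_evidence, tolerance = 1e-8)
  }
  expect_lt(worst, 1e-8)
})

test_that("convolution tree and chain agree at larger sizes", {
  for (n in c(64L, 128L, 256L)) {
    p <- generate_problem(n, seed = n)
    expect_lt(max_posterior_diff(posteriors_convtree(p), posteriors_chain(p)),
      1e-8)
  }
})

test_that("dummy padding leaves real posteriors unchanged", {
  for (n in c(3L, 5L, 6L, 7L, 9L)) {
    p <- generate_problem(n, seed = 50 + n)
    r <- posteriors_convtree(p)
    expect_equal(r$extra$padded_n, 2^ceiling(log2(n)))
    expect_length(r$leaf_posteriors, n)
    expect_length(r$count_posterior$weights, n + 1L)
    expect_lt(max_posterior_diff(r, posteriors_by_enumeration(p)), 1e-10)
  }
})

test_that("a single leaf reduces to direct Bayes", {
  p <- adder_problem(list(leaf_variable("A", c(0.2, 0.8), c(0.65, 0.35))),
    c(0.9, 0.1))
  r <- posteriors_convtree(p)
  w <- c(0.2 * 0.65 * 0.9, 0.8 * 0.35 * 0.1)
  expect_equal(r$leaf_posteriors$A$weights, w / sum(w))
  expect_equal(r$log_evidence, log(sum(w)))
})

test_that("contradictory evidence aborts with a named node", {
  p <- adder_problem(
    list(leaf_variable("A", c(0, 1)), leaf_variable("B", c(0, 1))),
    c(1, 0, 0))  # both leaves surely present but the count must be 0
  expect_error(posteriors_convtree(p), class = "convtree_contradiction")
})

test_that("internal-node posteriors are exposed and consistent", {
  p <- generate_problem(4, seed = 11)
  r <- posteriors_convtree(p, keep_tree = TRUE)
  np <- tree_node_posteriors(r$extra$tree)
  # the root node's posterior is the count posterior
  expect_equal(np[[2]][[1]]$weights, r$count_posterior$weights)
  # a first-layer node's posterior is the pairwise-sum posterior from
  # enumeration of the joint table
  wl <- Map(`*`, p$leaves$prior, p$leaves$unique_likelihood)
  grid <- expand.grid(0:1, 0:1, 0:1, 0:1)
  w <- apply(grid, 1, function(x)
    prod(mapply(function(wi, xi) wi[xi + 1], wl, x)) *
      p$shared_likelihood[sum(x) + 1L])
  pair_sum <- grid[[1]] + grid[[2]]
  want <- vapply(0:2, function(s) sum(w[pair_sum == s]), numeric(1))
  expect_equal(np[[1]][[1]]$weights, want / sum(want), tolerance = 1e-12)
})

test_that("message storage is near-linear and work is sub-quadratic", {
  for (n in c(64L, 256L, 1024L)) {
    p <- generate_problem(n, seed = n + 1L)
    r <- posteriors_convtree(p)
    expect_lte(r$extra$message_cells, 4 * n * (log2(n) + 1))
  }
  conv_ops_reset()
  invisible(posteriors_convtree(generate_problem(1024L, seed = 21)))
  ops1 <- conv_ops_reset()
  invisible(posteriors_convtree(generate_problem(2048L, seed = 22)))
  ops2 <- conv_ops_reset()
  expect_lt(ops2 / ops1, 3)
})
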