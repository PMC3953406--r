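test_that("unit coefficients reproduce the unscaled engine", {
  p <- generate_problem(5, seed = 4)
  a <- posteriors_convtree(p)
  b <- posteriors_convtree(p, coefficients = rep(1L, 5))
  expect_equal(max_posterior_diff(a, b), 0)
})

test_that("a weighted sum with point evidence forces the right states", {
  # Y = X1 + 2 X2, binary leaves, Y observed equal to 2: only (0, 1) fits
  leaves <- list(leaf_variable("X1", c(0.5, 0.5), c(0.8, 0.2)),
                 leaf_variable("X2", c(0.7, 0.3), c(0.4, 0.6)))
  p <- adder_problem(leaves, rep(1, 3))
  sh <- count_pmf(c(0, 0, 1, 0), offset = 0L)  # support 0..3
  r <- posteriors_convtree(p, coefficients = c(1L, 2L), shared = sh)
  expect_equal(r$leaf_posteriors$X1$weights, c(1, 0))
  expect_equal(r$leaf_posteriors$X2$weights, c(0, 1))
})

test_that("a negative coefficient realizes subtraction", {
  # Y = X1 - X2 for independent binary leaves with uninformative evidence:
  # the root posterior is the difference distribution
  leaves <- list(leaf_variable("X1", c(0.4, 0.6)),
                 leaf_variable("X2", c(0.25, 0.75)))
  p <- adder_problem(leaves, rep(1, 3))
  sh <- count_pmf(rep(1, 3), offset = -1L)  # uninformative over -1..1
  r <- posteriors_convtree(p, coefficients = c(1L, -1L), shared = sh)
  diff_dist <- c(`-1` = 0.4 * 0.75, `0` = 0.4 * 0.25 + 0.6 * 0.75,
                 `1` = 0.6 * 0.25)
  expect_equal(unname(r$count_posterior$weights), unname(diff_dist))
  expect_equal(pmf_support(r$count_posterior), -1:1)
})

test_that("scaled-sum posteriors match exhaustive enumeration", {
  set.seed(71)
  for (rep in 1:12) {
    n <- sample(2:8, 1)
    coefs <- sample(c(-2:-1, 1:3), n, replace = TRUE)
    if (rep > 8) coefs[sample(n, 1)] <- 0L  # exercise detached inputs
    p <- random_problem(n, seed = 7000 + rep,
      sizes = sample(2:3, n, replace = TRUE))
    sizes <- lengths(p$leaves$prior)
    lo <- sum(pmin(coefs * (sizes - 1L), 0L))
    hi <- sum(pmax(coefs * (sizes - 1L), 0L))
    shw <- runif(hi - lo + 1L) + 0.05
    sh <- count_pmf(shw, offset = lo)

    r <- posteriors_convtree(p, coefficients = coefs, shared = sh)
    wl <- Map(`*`, p$leaves$prior, p$leaves$unique_likelihood)
    o <- enum_oracle(wl, function(x) shw[sum(coefs * x) - lo + 1L])
    d <- max(mapply(function(a, b) max(abs(a$weights - b)),
      r$leaf_posteriors, o$posteriors))
    expect_lt(d, 1e-10)
    expect_equal(r$log_evidence, log(o$total), tolerance = 1e-10)
  }
})

test_that("a single adder over all leaves equals the plain engine", {
  p <- generate_problem(6, seed = 13)
  lv <- purrr::pmap(p$leaves, leaf_variable)
  spec <- cascade_spec(list(
    Y = list(inputs = p$leaves$name, evidence = p$shared_likelihood)))
  a <- posteriors_cascade(spec, lv)
  b <- posteriors_convtree(p)
  expect_lt(max_posterior_diff(a, b), 1e-12)
  expect_equal(a$log_evidence, b$log_evidence, tolerance = 1e-12)
})

test_that("chained evidence on nested sums matches enumeration", {
  # D1 depends on X1 + X2; D2 depends on (X1 + X2) + X3
  lv <- list(leaf_variable("X1", c(0.3, 0.7), c(0.6, 0.4)),
             leaf_variable("X2", c(0.5, 0.5), c(0.2, 0.8)),
             leaf_variable("X3", c(0.9, 0.1), c(0.5, 0.5)))
  e1 <- c(0.1, 0.6, 0.3); e2 <- c(0.25, 0.25, 0.2, 0.3)
  spec <- cascade_spec(list(
    Y1 = list(inputs = c("X1", "X2"), evidence = e1),
    Y2 = list(inputs = c("Y1", "X3"), evidence = e2)))
  r <- posteriors_cascade(spec, lv)

  wl <- lapply(lv, function(l) l$prior * l$unique_likelihood)
  o <- enum_oracle(wl, function(x)
    e1[x[1] + x[2] + 1L] * e2[x[1] + x[2] + x[3] + 1L])
  d <- max(mapply(function(a, b) max(abs(a$weights - b)),
    r$leaf_posteriors, o$posteriors))
  expect_lt(d, 1e-10)
  expect_equal(r$log_evidence, log(o$total), tolerance = 1e-12)

  # the intermediate adder's posterior is exposed and sums to one
  expect_named(r$extra$adder_posteriors, c("Y2", "Y1"), ignore.order = TRUE)
  expect_equal(sum(r$extra$adder_posteriors$Y1$weights), 1)
})

test_that("cascades with coefficients and deep nesting match enumeration", {
  set.seed(99)
  lv <- lapply(1:5, function(i) {
    pr <- runif(2) + 0.05
    leaf_variable(paste0("X", i), pr / sum(pr), runif(2) + 0.05)
  })
  e1 <- runif(4) + 0.05          # Y1 = X1 + 2 X2, support 0..3
  e2 <- runif(6) + 0.05          # Y2 = Y1 + X3 + X4, support 0..5
  e3 <- runif(8) + 0.05          # Y3 = Y2 - X5, support -1..5 (8 values... 7)
  e3 <- e3[1:7]
  spec <- cascade_spec(list(
    Y1 = list(inputs = c("X1", "X2"), coefficients = c(1L, 2L),
              evidence = e1),
    Y2 = list(inputs = c("Y1", "X3", "X4"), evidence = e2),
    Y3 = list(inputs = c("Y2", "X5"), coefficients = c(1L, -1L),
              evidence = count_pmf(e3, offset = -1L))))
  r <- posteriors_cascade(spec, lv)

  wl <- lapply(lv, function(l) l$prior * l$unique_likelihood)
  o <- enum_oracle(wl, function(x) {
    y1 <- x[1] + 2 * x[2]
    y2 <- y1 + x[3] + x[4]
    y3 <- y2 - x[5]
    e1[y1 + 1L] * e2[y2 + 1L] * e3[y3 + 2L]
  })
  d <- max(mapply(function(a, b) max(abs(a$weights - b)),
    r$leaf_posteriors, o$posteriors))
  expect_lt(d, 1e-10)
  expect_equal(r$log_evidence, log(o$total), tolerance = 1e-12)
})

test_that("non-tree and cyclic cascades are rejected", {
  lv <- list(leaf_variable("X1", c(0.5, 0.5)),
             leaf_variable("X2", c(0.5, 0.5)),
             leaf_variable("X3", c(0.5, 0.5)))

  # X1 feeds two adders: a loop after moralization
  spec <- cascade_spec(list(
    Y1 = list(inputs = c("X1", "X2")),
    Y2 = list(inputs = c("X1", "X3")),
    Y3 = list(inputs = c("Y1", "Y2"))))
  expect_error(posteriors_cascade(spec, lv), "X1",
    class = "convtree_not_tree")

  # adder cycle
  spec <- cascade_spec(list(
    Y1 = list(inputs = c("X1", "Y2")),
    Y2 = list(inputs = c("X2", "Y1")),
    Y3 = list(inputs = c("Y1", "X3"))))
  expect_error(posteriors_cascade(spec, lv), class = "convtree_not_tree")

  # unknown input
  spec <- cascade_spec(list(Y1 = list(inputs = c("X1", "X9"))))
  expect_error(posteriors_cascade(spec,
    list(leaf_variable("X1", c(0.5, 0.5)))), "X9",
    class = "convtree_invalid")
})
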