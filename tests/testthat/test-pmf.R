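test_that("convolution matches hand and oracle values", {
  # identity element: point mass at zero
  b <- count_pmf(c(0.1, 0.2, 0.7))
  r <- pmf_convolve(count_pmf(1), b)
  expect_equal(r$weights, b$weights)
  expect_equal(r$offset, 0L)

  # two fair coins
  r <- pmf_convolve(count_pmf(c(0.5, 0.5)), count_pmf(c(0.5, 0.5)))
  expect_equal(r$weights, c(0.25, 0.5, 0.25))

  # protein prior 0.8 with a unique-peptide likelihood 0.65/0.35:
  # expected values frozen from the double-sum oracle
  a <- c(0.2, 0.8); b <- c(0.65, 0.35)
  expect_equal(conv_oracle(a, b), c(0.13, 0.59, 0.28))
  expect_equal(pmf_convolve(count_pmf(a), count_pmf(b))$weights,
    c(0.13, 0.59, 0.28))

  # offsets add, totals multiply
  x <- count_pmf(c(1, 2, 3), offset = -2)
  y <- count_pmf(c(4, 5), offset = 3)
  r <- pmf_convolve(x, y)
  expect_equal(r$offset, 1L)
  expect_equal(sum(r$weights), sum(x$weights) * sum(y$weights))
  expect_equal(r$weights, conv_oracle(x$weights, y$weights))
})

test_that("FFT and direct convolution agree over a range of lengths", {
  set.seed(11)
  for (len in c(1L, 2L, 3L, 5L, 17L, 63L, 64L, 128L, 257L, 512L)) {
    a <- runif(len)
    b <- runif(sample(len, 1L))
    d <- pmf_convolve(a, b, method = "direct")
    f <- pmf_convolve(a, b, method = "fft")
    expect_lt(max(abs(d - f)), 1e-10)
    expect_true(all(f >= 0))
    # independent library oracle
    expect_lt(max(abs(d - stats::convolve(a, rev(b), type = "open"))), 1e-10)
  }
})

test_that("convolution is commutative and associative", {
  set.seed(5)
  for (rep in 1:20) {
    a <- runif(sample(1:40, 1))
    b <- runif(sample(1:40, 1))
    c_ <- runif(sample(1:40, 1))
    expect_lt(max(abs(pmf_convolve(a, b) - pmf_convolve(b, a))), 1e-10)
    lhs <- pmf_convolve(pmf_convolve(a, b), c_)
    rhs <- pmf_convolve(a, pmf_convolve(b, c_))
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("backward messages implement the shifted correlation", {
  # sibling with no uncertainty contributes no shift
  cb <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(pmf_backward_message(cb, 1), cb)

  # uniform child makes every target state equally likely
  out <- pmf_backward_message(rep(0.2, 5), c(0.3, 0.7))
  expect_equal(out, rep(0.2 * 1.0, 4))

  # explicit correlation sum
  expect_equal(pmf_backward_message(c(1, 0, 0), c(0.3, 0.7)), c(0.3, 0))

  # mismatched lengths are rejected
  expect_error(pmf_backward_message(c(1, 0), c(0.3, 0.3, 0.4)),
    class = "convtree_invalid")
})

test_that("backward message conserves total evidence", {
  # sum_l aL[l] * bwd(c, aR)[l] == sum_k c[k] * (aL conv aR)[k]
  set.seed(21)
  for (rep in 1:25) {
    nl <- sample(1:12, 1); nr <- sample(1:12, 1)
    aL <- runif(nl); aR <- runif(nr)
    cb <- runif(nl + nr - 1L)
    lhs <- sum(aL * pmf_backward_message(cb, aR))
    rhs <- sum(cb * pmf_convolve(aL, aR))
    expect_lt(abs(lhs - rhs), 1e-10)
  }
})

test_that("normalization rescales and rejects contradictions", {
  expect_equal(pmf_normalize(c(2, 2)), c(0.5, 0.5))
  expect_equal(pmf_normalize(c(0.13, 0.59, 0.28)), c(0.13, 0.59, 0.28))
  expect_error(pmf_normalize(c(0, 0)), "zero total probability",
    class = "convtree_contradiction")
  expect_error(pmf_normalize(c(0, 0), what = "node 'A'"), "node 'A'")
  p <- pmf_normalize(count_pmf(c(1, 3)))
  expect_true(isTRUE(attr(p, "normalized")))
})

test_that("support scaling pads, reverses, and composes", {
  a <- count_pmf(c(0.3, 0.7))
  expect_equal(pmf_scale_support(a, 1), a)
  r <- pmf_scale_support(a, 2)
  expect_equal(r$weights, c(0.3, 0, 0.7))
  expect_equal(r$offset, 0L)
  r <- pmf_scale_support(a, -1)
  expect_equal(r$weights, c(0.7, 0.3))
  expect_equal(r$offset, -1L)
  r <- pmf_scale_support(a, 0)
  expect_equal(r$weights, 1)
  expect_equal(r$offset, 0L)

  # composition: scaling by c1 then c2 is scaling by c1 * c2
  set.seed(3)
  b <- count_pmf(runif(4), offset = -1L)
  for (c1 in setdiff(-3:3, 0)) for (c2 in setdiff(-3:3, 0)) {
    two <- pmf_scale_support(pmf_scale_support(b, c1), c2)
    one <- pmf_scale_support(b, c1 * c2)
    expect_equal(two$offset, one$offset)
    expect_equal(two$weights, one$weights)
  }
})

test_that("count_pmf invariants are enforced", {
  expect_error(count_pmf(numeric(0)), class = "convtree_invalid")
  expect_error(count_pmf(c(0.5, -0.1)), class = "convtree_invalid")
  expect_error(count_pmf(c(0.5, 0.6), normalized = TRUE),
    class = "convtree_invalid")
  expect_silent(count_pmf(c(0.5, 0.5), normalized = TRUE))
  expect_equal(tidy(count_pmf(c(0.2, 0.8), offset = 2L))$value, c(2L, 3L))
})

test_that("2-D convolution matches the quadruple-loop oracle", {
  # point mass at (0, 0) is the identity
  b <- grid_pmf(matrix(runif(6), 2, 3))
  r <- grid_convolve(grid_pmf(matrix(1, 1, 1)), b)
  expect_equal(r$weights, b$weights)

  # outer product of two 1-D fair-coin cases
  u <- grid_pmf(matrix(0.25, 2, 2))
  r <- grid_convolve(u, u)
  expect_equal(r$weights,
    outer(c(0.25, 0.5, 0.25), c(0.25, 0.5, 0.25)))

  set.seed(8)
  a <- matrix(runif(6), 2, 3); b <- matrix(runif(6), 3, 2)
  r <- grid_convolve(grid_pmf(a, 1L, -2L), grid_pmf(b, -1L, 4L))
  expect_equal(r$weights, conv2_oracle(a, b))
  expect_equal(c(r$row_offset, r$col_offset), c(0L, 2L))

  # fft path agrees with the oracle too
  a2 <- matrix(runif(20 * 18), 20, 18); b2 <- matrix(runif(17 * 19), 17, 19)
  f <- grid_convolve(grid_pmf(a2), grid_pmf(b2), method = "fft")
  expect_lt(max(abs(f$weights - conv2_oracle(a2, b2))), 1e-9)
})

test_that("2-D backward message slices the correct submatrix", {
  set.seed(13)
  aL <- matrix(runif(6), 2, 3)
  aR <- matrix(runif(4), 2, 2)
  cb <- matrix(runif(3 * 4), 3, 4)  # child dims: (2+2-1) x (3+2-1)
  out <- grid_backward_message(cb, aR)
  # oracle: entry (l1, l2) = sum over (r1, r2) of cb[l+r] * aR[r]
  want <- matrix(0, 2, 3)
  for (l1 in 1:2) for (l2 in 1:3) for (r1 in 1:2) for (r2 in 1:2) {
    want[l1, l2] <- want[l1, l2] + cb[l1 + r1 - 1L, l2 + r2 - 1L] * aR[r1, r2]
  }
  expect_equal(out, want)
  # evidence conservation against the forward convolution
  lhs <- sum(aL * grid_backward_message(cb, aR))
  rhs <- sum(cb * conv2_oracle(aL, aR))
  expect_lt(abs(lhs - rhs), 1e-10)
})
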