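#' Finite discrete distributions over consecutive integers
#'
#' A `count_pmf` is a dense vector of nonnegative weights over a contiguous
#' integer support: entry `j` of `weights` is the weight of the value
#' `offset + j - 1`. It represents either a probability mass function (when
#' normalized) or an unnormalized nonnegative weight vector, e.g. a
#' likelihood over a count. All message passing in the package is arithmetic
#' on these objects.
#'
#' @param weights Numeric vector of nonnegative weights, length >= 1.
#' @param offset Integer, the smallest value in the support (default 0).
#' @param normalized Logical; if `TRUE` the weights are checked to sum to 1
#'   within `1e-12` and the object is flagged as a proper distribution.
#'
#' @return An object of class `count_pmf`.
#' @examples
#' count_pmf(c(0.2, 0.8))            # P(X = 0) = 0.2, P(X = 1) = 0.8
#' count_pmf(c(0.5, 0.5), offset = -1)
#' @export
count_pmf <- function(weights, offset = 0L, normalized = FALSE) {
  weights <- as.numeric(weights)
  if (length(weights) < 1L) {
    rlang::abort("`weights` must have length >= 1.", class = "convtree_invalid")
  }
  if (anyNA(weights) || any(weights < 0)) {
    rlang::abort("`weights` must be nonnegative and free of NA.",
      class = "convtree_invalid")
  }
  if (normalized && abs(sum(weights) - 1) > 1e-12) {
    rlang::abort(
      sprintf("normalized pmf must sum to 1 within 1e-12 (got %.17g).",
        sum(weights)),
      class = "convtree_invalid")
  }
  structure(
    list(offset = as.integer(offset), weights = weights),
    normalized = normalized,
    class = "count_pmf")
}

#' @rdname count_pmf
#' @param x Object to test or print.
#' @export
is_count_pmf <- function(x) inherits(x, "count_pmf")

#' @export
print.count_pmf <- function(x, ...) {
  cat(sprintf("<count_pmf> support %d..%d%s\n", x$offset,
    x$offset + length(x$weights) - 1L,
    if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""))
  v <- x$weights
  names(v) <- pmf_support(x)
  print(v, ...)
  invisible(x)
}

#' Integer support of a count pmf
#' @param x A `count_pmf`.
#' @return Integer vector `offset .. offset + length - 1`.
#' @export
pmf_support <- function(x) {
  stopifnot(is_count_pmf(x))
  x$offset + seq_along(x$weights) - 1L
}

#' @method tidy count_pmf
#' @export
tidy.count_pmf <- function(x, ...) {
  tibble::tibble(value = pmf_support(x), weight = x$weights)
}

## ---- operation counter ------------------------------------------------
## Structural work accounting: every convolution adds its scalar
## multiply-add count (direct path) or an FFT-equivalent 3*m*log2(m)
## (transform path). Used to assert sub-quadratic growth without timing.
.conv_state <- new.env(parent = emptyenv())
.conv_state$ops <- 0

#' Convolution work counter
#'
#' The package keeps a global counter of the scalar work performed by
#' convolutions: a direct convolution of lengths `p` and `q` adds `p * q`
#' multiply-adds; an FFT convolution of padded length `m` adds
#' `3 * m * log2(m)` (three transforms). The counter underlies the
#' structural complexity checks (sub-quadratic growth of the convolution
#' tree) without resorting to wall-clock timing.
#'
#' @return `conv_ops()` returns the current counter (a double);
#'   `conv_ops_reset()` zeroes it and invisibly returns the previous value.
#' @export
conv_ops <- function() .conv_state$ops

#' @rdname conv_ops
#' @export
conv_ops_reset <- function() {
  old <- .conv_state$ops
  .conv_state$ops <- 0
  invisible(old)
}

.count_ops <- function(n) {
  .conv_state$ops <- .conv_state$ops + n
  invisible(NULL)
}

## ---- convolution ------------------------------------------------------

.conv_direct <- function(x, y) {
  nx <- length(x); ny <- length(y)
  .count_ops(nx * ny)
  out <- numeric(nx + ny - 1L)
  # accumulate shifted copies of the longer vector, one per entry of the
  # shorter one: O(nx * ny) multiply-adds either way
  if (nx > ny) { tmp <- x; x <- y; y <- tmp; nx <- length(x); ny <- length(y) }
  for (i in seq_len(nx)) {
    if (x[i] != 0) out[i:(i + ny - 1L)] <- out[i:(i + ny - 1L)] + x[i] * y
  }
  out
}

.conv_fft <- function(x, y) {
  n <- length(x) + length(y) - 1L
  m <- stats::nextn(n, 2L)
  .count_ops(3 * m * log2(m))
  fx <- stats::fft(c(x, numeric(m - length(x))))
  fy <- stats::fft(c(y, numeric(m - length(y))))
  out <- Re(stats::fft(fx * fy, inverse = TRUE))[seq_len(n)] / m
  .clip_fft_negatives(out)
}

# FFT hygiene: round-off can produce tiny negative "probabilities"; clip
# them, but a structurally negative entry signals an internal error.
.clip_fft_negatives <- function(out) {
  neg <- out < 0
  if (any(neg)) {
    tol <- 1e-12 * max(abs(out), 1e-300)
    if (any(out < -tol)) {
      rlang::abort("internal consistency error: convolution produced a negative weight beyond round-off.",
        class = "convtree_internal")
    }
    out[neg] <- 0
  }
  out
}

.use_direct <- function(x, y) {
  if (min(length(x), length(y)) < 64L) return(TRUE)
  dx <- mean(x != 0); dy <- mean(y != 0)
  dx < 0.1 || dy < 0.1
}

.conv_raw <- function(x, y, method = "auto") {
  switch(method,
    direct = .conv_direct(x, y),
    fft = .conv_fft(x, y),
    auto = if (.use_direct(x, y)) .conv_direct(x, y) else .conv_fft(x, y),
    rlang::abort(sprintf("unknown convolution method '%s'.", method)))
}

#' Convolve two count pmfs
#'
#' The distribution of `X + Y` for independent `X ~ a`, `Y ~ b` (for
#' unnormalized inputs, the weight of each sum). Offsets add; the result has
#' length `|a| + |b| - 1`; total weight multiplies. Small or sparse operands
#' take the direct O(pq) path, large dense operands the FFT path; the two
#' agree entrywise to round-off.
#'
#' @param a,b `count_pmf` objects (or bare numeric weight vectors, treated
#'   as offset-0 pmfs).
#' @param method `"auto"` (default heuristic), `"direct"`, or `"fft"`.
#' @return A `count_pmf` (a numeric vector if both inputs were numeric).
#' @examples
#' pmf_convolve(count_pmf(c(0.5, 0.5)), count_pmf(c(0.5, 0.5)))
#' @export
pmf_convolve <- function(a, b, method = c("auto", "direct", "fft")) {
  method <- match.arg(method)
  ap <- is_count_pmf(a); bp <- is_count_pmf(b)
  wa <- if (ap) a$weights else as.numeric(a)
  wb <- if (bp) b$weights else as.numeric(b)
  if (length(wa) < 1L || length(wb) < 1L) {
    rlang::abort("cannot convolve an empty weight vector.",
      class = "convtree_invalid")
  }
  out <- .conv_raw(wa, wb, method)
  if (!ap && !bp) return(out)
  oa <- if (ap) a$offset else 0L
  ob <- if (bp) b$offset else 0L
  count_pmf(out, offset = oa + ob)
}

#' Backward (up-pass) message: correlate a child's likelihood with a sibling
#'
#' Given the likelihood `child_below` of the data below an adder node,
#' indexed by the node's sum, and the above-message `other_above` of one
#' parent, returns the likelihood over the *other* parent's states: entry
#' `l` (0-based) is `sum_r child_below[l + r] * other_above[r]`. This is the
#' convolution of `child_below` with the reversal of `other_above`, sliced
#' to drop the shift (start `|R| - 1`, length `|L| = |child| - |R| + 1`):
#' the up-pass represents subtraction, so one operand's indices reverse.
#'
#' @param child_below Numeric weight vector over the child's sums (length
#'   `|L| + |R| - 1`).
#' @param other_above A `count_pmf` or numeric vector with `|R|` entries.
#' @param method Convolution method, as in [pmf_convolve()].
#' @return Numeric weight vector with `|L|` entries, all nonnegative.
#' @export
pmf_backward_message <- function(child_below, other_above,
                                 method = c("auto", "direct", "fft")) {
  method <- match.arg(method)
  cb <- if (is_count_pmf(child_below)) child_below$weights else as.numeric(child_below)
  oa <- if (is_count_pmf(other_above)) other_above$weights else as.numeric(other_above)
  nr <- length(oa)
  nl <- length(cb) - nr + 1L
  if (nl < 1L) {
    rlang::abort(sprintf(
      "length mismatch: child vector (%d) shorter than sibling message (%d).",
      length(cb), nr), class = "convtree_invalid")
  }
  full <- .conv_raw(cb, rev(oa), method)
  out <- full[nr:(nr + nl - 1L)]
  # correlation of nonnegative vectors; clip transform round-off only
  .clip_fft_negatives(out)
}

#' Normalize a weight vector into a probability distribution
#'
#' @param v A `count_pmf` or numeric weight vector with at least one
#'   strictly positive entry.
#' @param what Optional label (e.g. a node name) used in the error message
#'   when the total weight is zero, which signals contradictory evidence.
#' @return The input rescaled to sum to 1 (same type as the input;
#'   `count_pmf` inputs come back flagged as normalized).
#' @export
pmf_normalize <- function(v, what = NULL) {
  w <- if (is_count_pmf(v)) v$weights else as.numeric(v)
  s <- sum(w)
  if (s <= 0 || !is.finite(s)) {
    lab <- if (is.null(what)) "" else sprintf(" at %s", what)
    rlang::abort(
      sprintf("zero total probability%s: the model contradicts the evidence.", lab),
      class = "convtree_contradiction")
  }
  if (is_count_pmf(v)) count_pmf(w / s, offset = v$offset, normalized = TRUE)
  else w / s
}

#' Distribution of an integer multiple of a variable
#'
#' Returns the pmf of `c * X` for integer `c` and `X ~ a`. For `c > 0` the
#' support stretches: `|c| - 1` zeros are padded between consecutive
#' entries and the offset becomes `c * offset`. For `c < 0` the vector is
#' additionally reversed and the offset becomes `c * (offset + |a| - 1)`
#' (the minimum value reached). `c = 0` collapses to a point mass at 0
#' carrying the total weight.
#'
#' @param a A `count_pmf`.
#' @param c An integer scaling factor.
#' @return A `count_pmf` for `c * X`.
#' @examples
#' pmf_scale_support(count_pmf(c(0.3, 0.7)), 2)   # support {0, 2}
#' pmf_scale_support(count_pmf(c(0.3, 0.7)), -1)  # support {-1, 0}
#' @export
pmf_scale_support <- function(a, c) {
  stopifnot(is_count_pmf(a))
  c <- as.integer(c)
  n <- length(a$weights)
  if (c == 0L) return(count_pmf(sum(a$weights), offset = 0L))
  if (c == 1L) return(a)
  w <- a$weights
  if (c < 0L) w <- rev(w)
  out <- numeric(abs(c) * (n - 1L) + 1L)
  out[seq(1L, length(out), by = abs(c))] <- w
  off <- if (c > 0L) c * a$offset else c * (a$offset + n - 1L)
  count_pmf(out, offset = off)
}

# Index permutation realised by pmf_scale_support: entry j of the original
# support lands at 1-based position perm[j] of the scaled vector. Stored by
# scaling nodes so the backward pass is a table lookup, not a convolution.
.scale_permutation <- function(n, c) {
  if (c == 0L) rep(1L, n)
  else if (c > 0L) as.integer(abs(c) * (seq_len(n) - 1L) + 1L)
  else as.integer(abs(c) * (n - seq_len(n)) + 1L)
}
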