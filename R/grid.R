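#' Two-dimensional count pmfs
#'
#' A `grid_pmf` is the 2-D analogue of [count_pmf()]: a matrix of
#' nonnegative weights over a rectangle of integer pairs. Entry `(i, j)` is
#' the weight of `(row_offset + i - 1, col_offset + j - 1)`. Used when each
#' variable carries two additive quantities at once (e.g. a discretized
#' mass in the rows and a valence in the columns of an elemental
#' decomposition).
#'
#' @param weights Numeric matrix of nonnegative weights (both dims >= 1).
#' @param row_offset,col_offset Smallest value per dimension.
#' @return An object of class `grid_pmf`.
#' @export
grid_pmf <- function(weights, row_offset = 0L, col_offset = 0L) {
  weights <- as.matrix(weights)
  if (nrow(weights) < 1L || ncol(weights) < 1L) {
    rlang::abort("`weights` must have both dimensions >= 1.",
      class = "convtree_invalid")
  }
  if (anyNA(weights) || any(weights < 0)) {
    rlang::abort("`weights` must be nonnegative and free of NA.",
      class = "convtree_invalid")
  }
  structure(
    list(row_offset = as.integer(row_offset),
         col_offset = as.integer(col_offset),
         weights = weights),
    class = "grid_pmf")
}

#' @rdname grid_pmf
#' @param x Object to test.
#' @export
is_grid_pmf <- function(x) inherits(x, "grid_pmf")

#' @export
print.grid_pmf <- function(x, ...) {
  cat(sprintf("<grid_pmf> rows %d..%d, cols %d..%d\n",
    x$row_offset, x$row_offset + nrow(x$weights) - 1L,
    x$col_offset, x$col_offset + ncol(x$weights) - 1L))
  print(x$weights, ...)
  invisible(x)
}

#' @method tidy grid_pmf
#' @export
tidy.grid_pmf <- function(x, ...) {
  tibble::tibble(
    row = rep(x$row_offset + seq_len(nrow(x$weights)) - 1L,
              times = ncol(x$weights)),
    col = rep(x$col_offset + seq_len(ncol(x$weights)) - 1L,
              each = nrow(x$weights)),
    weight = as.vector(x$weights))
}

.conv2_direct <- function(a, b) {
  na <- dim(a); nb <- dim(b)
  .count_ops(prod(na) * prod(nb))
  out <- matrix(0, na[1] + nb[1] - 1L, na[2] + nb[2] - 1L)
  for (i in seq_len(na[1])) {
    for (j in seq_len(na[2])) {
      if (a[i, j] != 0) {
        ri <- i:(i + nb[1] - 1L); cj <- j:(j + nb[2] - 1L)
        out[ri, cj] <- out[ri, cj] + a[i, j] * b
      }
    }
  }
  out
}

.conv2_fft <- function(a, b) {
  d1 <- nrow(a) + nrow(b) - 1L
  d2 <- ncol(a) + ncol(b) - 1L
  m1 <- stats::nextn(d1, 2L); m2 <- stats::nextn(d2, 2L)
  .count_ops(3 * m1 * m2 * log2(m1 * m2))
  pad <- function(m) {
    out <- matrix(0, m1, m2)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  fa <- stats::fft(pad(a)); fb <- stats::fft(pad(b))
  out <- Re(stats::fft(fa * fb, inverse = TRUE))[seq_len(d1), seq_len(d2), drop = FALSE] / (m1 * m2)
  neg <- out < 0
  if (any(neg)) {
    tol <- 1e-12 * max(abs(out), 1e-300)
    if (any(out < -tol)) {
      rlang::abort("internal consistency error: 2-D convolution produced a negative weight beyond round-off.",
        class = "convtree_internal")
    }
    out[neg] <- 0
  }
  out
}

.conv2_raw <- function(a, b, method = "auto") {
  switch(method,
    direct = .conv2_direct(a, b),
    fft = .conv2_fft(a, b),
    auto = if (min(prod(dim(a)), prod(dim(b))) < 256L ||
               mean(a != 0) < 0.1 || mean(b != 0) < 0.1)
      .conv2_direct(a, b) else .conv2_fft(a, b))
}

#' Convolve two 2-D pmfs
#'
#' Full two-dimensional convolution: the distribution of the entrywise sum
#' of two independent integer pairs. Offsets add per dimension; the total
#' weight multiplies.
#'
#' @param a,b `grid_pmf` objects.
#' @param method `"auto"`, `"direct"`, or `"fft"`.
#' @return A `grid_pmf`.
#' @export
grid_convolve <- function(a, b, method = c("auto", "direct", "fft")) {
  method <- match.arg(method)
  stopifnot(is_grid_pmf(a), is_grid_pmf(b))
  out <- .conv2_raw(a$weights, b$weights, method)
  grid_pmf(out,
    row_offset = a$row_offset + b$row_offset,
    col_offset = a$col_offset + b$col_offset)
}

#' 2-D backward message: correlate a child's likelihood with a sibling grid
#'
#' The two-dimensional analogue of [pmf_backward_message()]: convolve the
#' child's likelihood matrix with the 180-degree rotation of the sibling's
#' above-message and retrieve the contiguous submatrix corresponding to the
#' target parent's support (rows `nrow(R) - 1 ..`, cols `ncol(R) - 1 ..`,
#' 0-based).
#'
#' @param child_below Numeric matrix over the child's sums
#'   (`nrow(L) + nrow(R) - 1` by `ncol(L) + ncol(R) - 1`).
#' @param other_above A `grid_pmf` or matrix for the sibling parent.
#' @param method Convolution method.
#' @return Numeric matrix with the target parent's dimensions.
#' @export
grid_backward_message <- function(child_below, other_above,
                                  method = c("auto", "direct", "fft")) {
  method <- match.arg(method)
  cb <- if (is_grid_pmf(child_below)) child_below$weights else as.matrix(child_below)
  oa <- if (is_grid_pmf(other_above)) other_above$weights else as.matrix(other_above)
  nr <- dim(oa)
  nl <- dim(cb) - nr + 1L
  if (any(nl < 1L)) {
    rlang::abort("dimension mismatch between child matrix and sibling message.",
      class = "convtree_invalid")
  }
  rot <- oa[rev(seq_len(nr[1])), rev(seq_len(nr[2])), drop = FALSE]
  full <- .conv2_raw(cb, rot, method)
  out <- full[nr[1]:(nr[1] + nl[1] - 1L), nr[2]:(nr[2] + nl[2] - 1L), drop = FALSE]
  out[out < 0] <- 0
  out
}
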