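#' Describe a cascade of adder nodes
#'
#' A cascade is a directed acyclic arrangement of adder nodes, each
#' summing a subset of the leaves and/or other adders, optionally with an
#' integer coefficient per input edge and an evidence likelihood attached
#' to the adder's value. Cascades express shared evidence over *nested*
#' sums (e.g. evidence on `X1 + X2` and further evidence on
#' `X1 + X2 + X3`). Exact inference requires the cascaded structure to be
#' a tree: every leaf and adder may feed into at most one other adder,
#' and exactly one adder (the root) feeds into none.
#'
#' @param adders A named list; each element describes one adder as a list
#'   with `inputs` (character vector of leaf or adder names),
#'   optional `coefficients` (integers, one per input, default 1), and
#'   optional `evidence` (a [count_pmf()] or numeric likelihood vector
#'   over the adder's value, numeric meaning offset 0).
#' @return A `cascade_spec` object.
#' @examples
#' cascade_spec(list(
#'   Y1 = list(inputs = c("X1", "X2"), evidence = c(0.1, 0.6, 0.3)),
#'   Y2 = list(inputs = c("Y1", "X3"), evidence = c(0.2, 0.2, 0.2, 0.4))))
#' @export
cascade_spec <- function(adders) {
  if (!is.list(adders) || length(adders) < 1L || is.null(names(adders)) ||
      any(names(adders) == "")) {
    rlang::abort("`adders` must be a non-empty named list.",
      class = "convtree_invalid")
  }
  if (anyDuplicated(names(adders))) {
    rlang::abort("adder names must be unique.", class = "convtree_invalid")
  }
  adders <- purrr::imap(adders, function(a, nm) {
    if (is.null(a$inputs) || length(a$inputs) < 1L) {
      rlang::abort(sprintf("adder '%s' must have at least one input.", nm),
        class = "convtree_invalid")
    }
    a$inputs <- as.character(a$inputs)
    if (is.null(a$coefficients)) a$coefficients <- rep(1L, length(a$inputs))
    a$coefficients <- as.integer(a$coefficients)
    if (length(a$coefficients) != length(a$inputs)) {
      rlang::abort(sprintf(
        "adder '%s': need one coefficient per input.", nm),
        class = "convtree_invalid")
    }
    if (!is.null(a$evidence) && !is_count_pmf(a$evidence)) {
      a$evidence <- count_pmf(as.numeric(a$evidence), offset = 0L)
    }
    a
  })
  structure(list(adders = adders), class = "cascade_spec")
}

#' @export
print.cascade_spec <- function(x, ...) {
  cat(sprintf("<cascade_spec> %d adders\n", length(x$adders)))
  for (nm in names(x$adders)) {
    a <- x$adders[[nm]]
    cat(sprintf("  %s = %s%s\n", nm,
      paste(ifelse(a$coefficients == 1L, a$inputs,
        paste0(a$coefficients, "*", a$inputs)), collapse = " + "),
      if (is.null(a$evidence)) "" else "  [evidence]"))
  }
  invisible(x)
}

# validate the cascade against the leaf set; returns the root adder name
.cascade_root <- function(spec, leaf_names) {
  adders <- spec$adders
  all_names <- c(leaf_names, names(adders))
  consumed <- integer(length(all_names))
  names(consumed) <- all_names
  for (nm in names(adders)) {
    for (inp in adders[[nm]]$inputs) {
      if (!inp %in% all_names) {
        rlang::abort(sprintf(
          "adder '%s' refers to unknown input '%s'.", nm, inp),
          class = "convtree_invalid")
      }
      consumed[inp] <- consumed[inp] + 1L
    }
  }
  multi <- names(consumed)[consumed > 1L]
  if (length(multi)) {
    rlang::abort(sprintf(
      "cascade is not a tree: node '%s' feeds more than one adder (loopy cascades need junction-tree machinery, which this engine does not provide).",
      multi[1]), class = "convtree_not_tree")
  }
  unused_leaf <- leaf_names[consumed[leaf_names] == 0L]
  if (length(unused_leaf)) {
    rlang::abort(sprintf("leaf '%s' is not an input of any adder.",
      unused_leaf[1]), class = "convtree_invalid")
  }
  roots <- names(adders)[consumed[names(adders)] == 0L]
  if (length(roots) != 1L) {
    rlang::abort(sprintf(
      "cascade must have exactly one root adder (found %d): it likely contains a cycle or a disconnected component.",
      length(roots)), class = "convtree_not_tree")
  }
  # reachability from the root catches cycles among consumed adders
  seen <- character(0)
  stack <- roots
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    seen <- c(seen, cur)
    kids <- spec$adders[[cur]]$inputs
    stack <- c(stack, kids[kids %in% names(adders)])
  }
  missing <- setdiff(names(adders), seen)
  if (length(missing)) {
    rlang::abort(sprintf(
      "cascade contains a cycle: adder '%s' is not reachable from the root '%s'.",
      missing[1], roots), class = "convtree_not_tree")
  }
  roots
}

#' Exact posteriors on a cascaded adder tree
#'
#' Runs the convolution-tree message-passing schedule over an arbitrary
#' tree-shaped cascade: adders over subsets of leaves (and other adders),
#' integer coefficients on input edges, and evidence likelihoods attached
#' to any adder's value. Adders with more than two inputs are expanded
#' into balanced pairwise sums internally; posteriors equal brute-force
#' enumeration of the original cascaded network. An adder over all leaves
#' with its evidence as the shared likelihood reproduces
#' [posteriors_convtree()] exactly.
#'
#' @param spec A [cascade_spec()].
#' @param leaves A list of [leaf_variable()] objects (every leaf must feed
#'   exactly one adder), or the `$leaves` tibble of an [adder_problem()].
#' @return A [posterior_result()]; `$extra$adder_posteriors` holds the
#'   posterior [count_pmf()] of every named adder's value.
#' @export
posteriors_cascade <- function(spec, leaves) {
  stopifnot(inherits(spec, "cascade_spec"))
  if (is.data.frame(leaves)) {
    leaves <- purrr::pmap(leaves[c("name", "prior", "unique_likelihood")],
      leaf_variable)
  }
  stopifnot(all(purrr::map_lgl(leaves, inherits, "leaf_variable")))
  leaf_names <- purrr::map_chr(leaves, "name")
  names(leaves) <- leaf_names
  root <- .cascade_root(spec, leaf_names)

  st <- new.env(parent = emptyenv())
  st$log_scale <- 0
  st$leaf_post <- list()
  st$adder_post <- list()

  norm_tracked <- function(w, what) {
    z <- sum(w)
    if (z <= 0) {
      rlang::abort(sprintf(
        "zero total probability at %s: the model contradicts the evidence.",
        what), class = "convtree_contradiction")
    }
    st$log_scale <- st$log_scale + log(z)
    w / z
  }

  ## -- down pass: each structural node carries `contrib`, the normalized
  ##    joint of its (possibly scaled) value with all data in its subtree
  build <- function(name) {
    if (name %in% leaf_names) {
      lf <- leaves[[name]]
      w0 <- lf$prior * lf$unique_likelihood
      return(list(kind = "leaf", name = name, w0 = w0, coef = 1L,
        perm = seq_along(w0),
        contrib = norm_tracked(w0, sprintf("leaf '%s'", name)),
        offset = 0L))
    }
    a <- spec$adders[[name]]
    kids <- purrr::map2(a$inputs, a$coefficients,
      function(inp, cf) .edge_scale(build(inp), cf))
    node <- .pair_balanced(kids, norm_tracked, name)
    if (node$kind != "pair") {
      # single-input adder: give it an addressable wrapper
      node <- list(kind = "wrap", inner = node, edge_coef = 1L,
        perm = seq_along(node$contrib),
        contrib = node$contrib, offset = node$offset)
    }
    node$name <- name
    if (!is.null(a$evidence)) {
      ev <- .align_likelihood(a$evidence, node$offset, length(node$contrib))
      node$evidence <- ev
      node$contrib <- norm_tracked(node$contrib * ev,
        sprintf("adder '%s'", name))
    }
    node
  }

  ## -- up pass: `msg` is the likelihood of all data outside the node's
  ##    subtree, index-aligned to the node's external support
  up <- function(node, msg) {
    nm <- node$name
    if (!is.null(nm) && !(node$kind == "leaf")) {
      st$adder_post[[nm]] <- count_pmf(
        pmf_normalize(node$contrib * msg, what = sprintf("adder '%s'", nm)),
        offset = node$offset, normalized = TRUE)
    }
    if (!is.null(node$evidence)) msg <- msg * node$evidence
    if (node$kind == "leaf") {
      post <- if (node$coef == 0L) node$w0 else node$w0 * msg[node$perm]
      st$leaf_post[[nm]] <- count_pmf(
        pmf_normalize(post, what = sprintf("leaf '%s'", nm)),
        normalized = TRUE)
    } else if (node$kind == "wrap") {
      inner_msg <- if (node$edge_coef == 0L)
        rep(1, length(node$inner$contrib)) else msg[node$perm]
      up(node$inner, inner_msg)
    } else {
      msg_l <- pmf_backward_message(msg, node$right$contrib)
      msg_r <- pmf_backward_message(msg, node$left$contrib)
      up(node$left, pmf_normalize(msg_l,
        what = sprintf("message into '%s'", node$left$name %||% "a pair node")))
      up(node$right, pmf_normalize(msg_r,
        what = sprintf("message into '%s'", node$right$name %||% "a pair node")))
    }
    invisible(NULL)
  }

  root_node <- build(root)
  up(root_node, rep(1, length(root_node$contrib)))

  posterior_result(
    leaf_posteriors = st$leaf_post[leaf_names],
    count_posterior = st$adder_post[[root]],
    log_evidence = st$log_scale,
    engine = "cascade",
    extra = list(adder_posteriors = st$adder_post))
}

# apply an integer edge coefficient to a built node; the stored index
# permutation makes the up pass a table lookup, not another convolution
.edge_scale <- function(node, cf) {
  cf <- as.integer(cf)
  if (cf == 1L) return(node)
  sc <- pmf_scale_support(count_pmf(node$contrib, node$offset), cf)
  if (node$kind == "leaf") {
    node$coef <- cf
    node$perm <- .scale_permutation(length(node$w0), cf)
    node$contrib <- sc$weights
    node$offset <- sc$offset
    node
  } else {
    list(kind = "wrap", inner = node, edge_coef = cf,
         perm = .scale_permutation(length(node$contrib), cf),
         contrib = sc$weights, offset = sc$offset,
         name = NULL)
  }
}

# fold a list of built nodes into a balanced binary structure; internal
# pair nodes convolve their children's contribs
.pair_balanced <- function(nodes, norm_tracked, where) {
  k <- length(nodes)
  if (k == 1L) return(nodes[[1]])
  half <- ceiling(k / 2)
  left <- .pair_balanced(nodes[seq_len(half)], norm_tracked, where)
  right <- .pair_balanced(nodes[(half + 1L):k], norm_tracked, where)
  w <- .clip_fft_negatives(.conv_raw(left$contrib, right$contrib, "auto"))
  list(kind = "pair", name = NULL, left = left, right = right,
       contrib = norm_tracked(w, sprintf("a pairwise sum inside '%s'", where)),
       offset = left$offset + right$offset)
}
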