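#' Ladderize an annotated tree with deterministic tiebreaking
#'
#' Establishes the canonical traversal order used by the encoder. Sibling
#' subtrees are ordered by their root node's time, then by the time of the
#' immediate ancestral node, then by the root node's affinity. Any remaining
#' tie recurses into the (already canonically ordered) child subtrees and
#' compares their key sequences; two subtrees identical in every key raise a
#' tie error naming the nodes, since they make the encoding ambiguous.
#'
#' @param tree An [annotated_tree()].
#' @param on_tie `"error"` (default): raise on any full-key tie.
#'   `"keep"`: keep the input order for fully tied siblings. A full-key tie
#'   means the two subtrees are observationally identical (same times and
#'   affinities throughout), so the resulting encoding is provably the same
#'   either way; the encoder therefore uses `"keep"`, which matters for
#'   sampled trees where several copies of one genotype form ultrametric
#'   cherries.
#' @return Integer vector of tip ids in canonical (ladderized) traversal
#'   order, with the per-node ordered-children list as attribute
#'   `"children"`.
#' @export
ladderize_order <- function(tree, on_tie = c("error", "keep")) {
  on_tie <- match.arg(on_tie)
  stopifnot(inherits(tree, "annotated_tree"))
  ch <- children_list(tree)
  tm <- tree$node_time; af <- tree$affinity
  parent <- integer(n_nodes(tree))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent[tree_root(tree)] <- NA_integer_
  cmp <- function(a, b) {
    if (tm[a] != tm[b]) return(sign(tm[a] - tm[b]))
    pa <- parent[a]; pb <- parent[b]
    pta <- if (is.na(pa)) -Inf else tm[pa]
    ptb <- if (is.na(pb)) -Inf else tm[pb]
    if (pta != ptb) return(sign(pta - ptb))
    if (af[a] != af[b]) return(sign(af[a] - af[b]))
    ka <- ordered[[a]]; kb <- ordered[[b]]
    if (length(ka) != length(kb)) return(sign(length(ka) - length(kb)))
    for (i in seq_along(ka)) {
      c0 <- cmp(ka[i], kb[i])
      if (c0 != 0L) return(c0)
    }
    0L
  }
  ordered <- vector("list", n_nodes(tree))
  # canonical child order must exist before parents compare subtrees:
  # process nodes in decreasing time (children before parents is implied
  # for equal times only at the zero-time expansion, where recursion into
  # already-ordered deeper nodes still terminates because 'ordered' is
  # filled lazily below)
  order_kids <- function(v) {
    if (!is.null(ordered[[v]])) return(ordered[[v]])
    kids <- ch[[v]]
    for (k in kids) order_kids(k)
    res <- if (length(kids) <= 1L) kids else {
      c0 <- cmp(kids[1L], kids[2L])
      if (c0 == 0L && on_tie == "error")
        stop("ladderization tie between nodes ", kids[1L], " and ", kids[2L],
             " (equal times, ancestor times, affinities, and subtrees)")
      if (c0 > 0L) rev(kids) else kids
    }
    ordered[[v]] <<- res
    res
  }
  root <- tree_root(tree)
  order_kids(root)
  # iterative DFS collecting tips in canonical order
  tips <- integer(tree$n_tip); nt <- 0L
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- ordered[[v]]
    if (!length(kids)) {
      nt <- nt + 1L
      tips[nt] <- v
    } else {
      stack <- c(stack, rev(kids))
    }
  }
  structure(tips[seq_len(nt)], children = ordered)
}

#' Scale a tree to mean unit depth
#'
#' Divides every branch length (and hence node time) by the mean root-to-tip
#' depth, so that trees of different absolute depths are comparable before
#' encoding. Affinities are untouched.
#'
#' @param tree An [annotated_tree()].
#' @return The rescaled [annotated_tree()].
#' @export
scale_tree <- function(tree) {
  stopifnot(inherits(tree, "annotated_tree"))
  d <- mean(tree$node_time[seq_len(tree$n_tip)])
  if (d <= 0) stop("mean leaf depth is zero; cannot scale")
  tree$edge_length <- tree$edge_length / d
  tree$node_time <- tree$node_time / d
  tree
}

#' Encode an annotated tree as a 4 x W matrix
#'
#' The compact bijective ladderized vector (CBLV) encoding augmented with
#' affinities. Tips are visited in canonical ladderized order; column `j`
#' holds, top to bottom: the j-th tip's height (time from the root); the
#' height of the internal node where that tip's subtree attaches to the
#' previously traversed part of the tree (0 for the first tip, whose
#' attachment is the root); the tip's affinity; and the attachment node's
#' affinity. Columns beyond the number of tips are zero padding.
#'
#' @param tree An [annotated_tree()] (typically after [scale_tree()]).
#' @param width Number of columns W (default 200); must be >= the tip count.
#' @return A 4 x `width` numeric matrix of class `encoded_tree` with
#'   attribute `n_tip`.
#' @export
encode_tree <- function(tree, width = 200L) {
  stopifnot(inherits(tree, "annotated_tree"))
  if (tree$n_tip > width)
    stop("tree has ", tree$n_tip, " tips but the encoding width is ", width)
  tips <- ladderize_order(tree, on_tie = "keep")
  ordered <- attr(tips, "children")
  root <- tree_root(tree)
  tm <- tree$node_time; af <- tree$affinity
  M <- matrix(0, 4L, width)
  j <- 0L
  # DFS carrying the pending attachment node: entering a non-first child of
  # v makes v the attachment point of that subtree's first tip
  stack <- list(list(v = root, pend = root))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    kids <- ordered[[fr$v]]
    if (!length(kids)) {
      j <- j + 1L
      M[, j] <- c(tm[fr$v], tm[fr$pend], af[fr$v], af[fr$pend])
    } else {
      frames <- c(list(list(v = kids[1L], pend = fr$pend)),
                  lapply(kids[-1L], function(k) list(v = k, pend = fr$v)))
      stack <- c(stack, rev(frames))
    }
  }
  structure(M, n_tip = tree$n_tip, class = c("encoded_tree", "matrix", "array"))
}

#' Feature standardization for encoded trees and auxiliary inputs
#'
#' Fits per-feature-type statistics over a training set: one (mean, sd) pair
#' for all height entries (encoding rows 1-2), one for all affinity entries
#' (rows 3-4), and one per auxiliary (non-sigmoid) input column. Structural
#' padding zeros are excluded from the statistics and restored to exactly 0
#' after transformation.
#'
#' @param encodings List of [encode_tree()] matrices.
#' @param aux Optional numeric matrix (trees x auxiliary inputs) of
#'   non-sigmoid parameter values.
#' @return `fit_tree_scaler`: an object of class `tree_scaler`.
#' @export
fit_tree_scaler <- function(encodings, aux = NULL) {
  stopifnot(length(encodings) >= 2L)
  hs <- unlist(lapply(encodings, function(e) e[1:2, seq_len(attr(e, "n_tip"))]))
  as <- unlist(lapply(encodings, function(e) e[3:4, seq_len(attr(e, "n_tip"))]))
  sc <- list(h_mean = mean(hs), h_sd = sd(hs),
             a_mean = mean(as), a_sd = sd(as))
  if (sc$h_sd == 0) stop("zero variance in feature 'heights'")
  if (sc$a_sd == 0) stop("zero variance in feature 'affinities'")
  if (!is.null(aux)) {
    aux <- as.matrix(aux)
    sc$aux_mean <- colMeans(aux)
    sc$aux_sd <- apply(aux, 2L, sd)
    zv <- sc$aux_sd == 0
    if (any(zv))
      stop("zero variance in auxiliary feature(s): ",
           paste(colnames(aux)[zv] %||% which(zv), collapse = ", "))
  }
  structure(sc, class = "tree_scaler")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname fit_tree_scaler
#' @param scaler A fitted `tree_scaler`.
#' @param inverse Undo the transformation instead of applying it.
#' @return `apply_tree_scaler`: a list with standardized `encodings` and
#'   (if given) `aux`. The transform is not idempotent; apply it exactly
#'   once, with the scaler fitted on the training set.
#' @export
apply_tree_scaler <- function(scaler, encodings, aux = NULL,
                              inverse = FALSE) {
  stopifnot(inherits(scaler, "tree_scaler"))
  tf <- function(x, m, s) if (inverse) x * s + m else (x - m) / s
  enc <- lapply(encodings, function(e) {
    n <- attr(e, "n_tip")
    cols <- seq_len(n)
    e[1:2, cols] <- tf(e[1:2, cols], scaler$h_mean, scaler$h_sd)
    e[3:4, cols] <- tf(e[3:4, cols], scaler$a_mean, scaler$a_sd)
    if (n < ncol(e)) e[, (n + 1L):ncol(e)] <- 0
    e
  })
  out <- list(encodings = enc)
  if (!is.null(aux)) {
    aux <- as.matrix(aux)
    out$aux <- if (inverse)
      sweep(sweep(aux, 2L, scaler$aux_sd, "*"), 2L, scaler$aux_mean, "+")
    else
      sweep(sweep(aux, 2L, scaler$aux_mean, "-"), 2L, scaler$aux_sd, "/")
  }
  out
}

#' @rdname fit_tree_scaler
#' @return `standardize_features`: list with standardized `encodings`,
#'   `aux`, and the fitted `scaler` (for reuse at prediction time).
#' @export
standardize_features <- function(encodings, aux = NULL) {
  scaler <- fit_tree_scaler(encodings, aux)
  c(apply_tree_scaler(scaler, encodings, aux), list(scaler = scaler))
}

#' Save / load a tree scaler as JSON
#'
#' @param scaler A `tree_scaler`.
#' @param path JSON file path.
#' @export
write_tree_scaler <- function(scaler, path) {
  jsonlite::write_json(unclass(scaler), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tree_scaler
#' @export
read_tree_scaler <- function(path) {
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(sc, class = "tree_scaler")
}
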