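#' Affinity-annotated phylogenetic tree
#'
#' A rooted tree in ape-style numbering (tips `1..n_tip`, root `n_tip + 1`,
#' further internal nodes after that) carrying, for every node, its time
#' (distance from the root along branch lengths) and its affinity. This is
#' the container consumed by the tree encoder.
#'
#' @param edge Two-column integer matrix of (parent, child) node ids.
#' @param edge_length Numeric branch lengths, one per edge row.
#' @param n_tip Number of tips.
#' @param affinity Numeric vector, one affinity per node id.
#' @param tip_label Optional tip labels (default `"t1"..."tn"`).
#' @param node_time Optional node times; derived from `edge_length` if
#'   omitted.
#' @return An object of class `annotated_tree`.
#' @export
annotated_tree <- function(edge, edge_length, n_tip, affinity,
                           tip_label = NULL, node_time = NULL) {
  edge <- matrix(as.integer(edge), ncol = 2L)
  n_nodes <- max(edge, n_tip)
  if (nrow(edge) != length(edge_length))
    stop("edge and edge_length disagree")
  if (length(affinity) != n_nodes)
    stop("need one affinity per node (", n_nodes, "), got ", length(affinity))
  if (any(!is.finite(affinity)))
    stop("all node affinities must be finite")
  if (is.null(node_time)) {
    node_time <- rep(NA_real_, n_nodes)
    root <- setdiff(edge[, 1], edge[, 2])
    if (length(root) != 1L) stop("tree must have exactly one root")
    node_time[root] <- 0
    # edges in parent-before-child order via repeated sweeps
    remaining <- seq_len(nrow(edge))
    while (length(remaining)) {
      ready <- remaining[!is.na(node_time[edge[remaining, 1]])]
      if (!length(ready)) stop("edges do not form a rooted tree")
      node_time[edge[ready, 2]] <- node_time[edge[ready, 1]] +
        edge_length[ready]
      remaining <- setdiff(remaining, ready)
    }
  }
  if (is.null(tip_label)) tip_label <- paste0("t", seq_len(n_tip))
  structure(list(edge = edge, edge_length = as.numeric(edge_length),
                 n_tip = as.integer(n_tip), node_time = as.numeric(node_time),
                 affinity = as.numeric(affinity),
                 tip_label = as.character(tip_label)),
            class = "annotated_tree")
}

n_nodes <- function(tree) max(tree$edge, tree$n_tip)

tree_root <- function(tree) setdiff(tree$edge[, 1], tree$edge[, 2])

# children list indexed by node id
children_list <- function(tree) {
  split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(n_nodes(tree))))
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat(sprintf(
    "<annotated_tree> %d tips, %d nodes, depth range [%.3g, %.3g], affinity range [%.3g, %.3g]\n",
    x$n_tip, n_nodes(x), min(x$node_time[seq_len(x$n_tip)]),
    max(x$node_time[seq_len(x$n_tip)]), min(x$affinity), max(x$affinity)))
  invisible(x)
}

#' Convert an annotated tree to an ape "phylo" object
#'
#' Affinities and times are attached as `node.affinity` / `node.time`
#' attributes (full node-id order).
#'
#' @param tree An [annotated_tree()].
#' @return An `ape::phylo` object.
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "annotated_tree"))
  ph <- structure(list(edge = tree$edge, edge.length = tree$edge_length,
                       Nnode = n_nodes(tree) - tree$n_tip,
                       tip.label = tree$tip_label),
                  class = "phylo")
  attr(ph, "node.affinity") <- tree$affinity
  attr(ph, "node.time") <- tree$node_time
  ph
}

# parent-array representation (0-based parents, -1 root) -> annotated_tree
parent_to_tree <- function(parent, time, affinity, labels = NULL) {
  n <- length(parent)
  if (n == 1L) stop("degenerate single-node tree")
  is_tip <- !(seq_len(n) - 1L) %in% parent[parent >= 0L]
  tip_ids <- which(is_tip)
  root0 <- which(parent == -1L)
  int_ids <- c(root0, setdiff(which(!is_tip), root0))
  new_id <- integer(n)
  new_id[tip_ids] <- seq_along(tip_ids)
  new_id[int_ids] <- length(tip_ids) + seq_along(int_ids)
  child <- which(parent >= 0L)
  edge <- cbind(new_id[parent[child] + 1L], new_id[child])
  el <- time[child] - time[parent[child] + 1L]
  nt <- numeric(n); af <- numeric(n)
  nt[new_id] <- time; af[new_id] <- affinity
  tl <- if (is.null(labels)) NULL else {
    out <- character(length(tip_ids))
    out[new_id[tip_ids]] <- labels[tip_ids]
    out[!nzchar(out)] <- paste0("t", which(!nzchar(out)))
    out
  }
  annotated_tree(edge, el, length(tip_ids), af, tip_label = tl,
                 node_time = nt)
}

format_num <- function(x) formatC(x, digits = 10, format = "g")

#' Write an annotated tree as Newick with node comments
#'
#' BEAST-style bracketed comments `[&time=...,affinity=...]` follow each
#' node; branch lengths are written after the comment. Iterative (no
#' recursion), so arbitrarily deep trees are safe.
#'
#' @param tree An [annotated_tree()].
#' @param path Output file path; if `NULL` the Newick string is returned.
#' @return The path (invisibly) or the Newick string.
#' @export
write_annotated_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "annotated_tree"))
  ch <- children_list(tree)
  root <- tree_root(tree)
  brlen <- rep(NA_real_, n_nodes(tree))
  brlen[tree$edge[, 2]] <- tree$edge_length
  lab <- function(v) {
    nm <- if (v <= tree$n_tip) tree$tip_label[v] else ""
    com <- sprintf("[&time=%s,affinity=%s]", format_num(tree$node_time[v]),
                   format_num(tree$affinity[v]))
    bl <- if (is.na(brlen[v])) "" else paste0(":", format_num(brlen[v]))
    paste0(nm, com, bl)
  }
  # explicit-stack DFS emitting tokens
  buf <- vector("list", 4096L); nb <- 0L
  emit <- function(s) {
    nb <<- nb + 1L
    if (nb > length(buf)) length(buf) <<- 2L * length(buf)
    buf[[nb]] <<- s
  }
  stack <- list(list(v = root, i = 0L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    kids <- ch[[fr$v]]
    if (length(kids) == 0L) {
      emit(lab(fr$v))
      stack[[length(stack)]] <- NULL
    } else if (fr$i == 0L) {
      emit("(")
      stack[[length(stack)]]$i <- 1L
      stack[[length(stack) + 1L]] <- list(v = kids[1L], i = 0L)
    } else if (fr$i < length(kids)) {
      emit(",")
      stack[[length(stack)]]$i <- fr$i + 1L
      stack[[length(stack) + 1L]] <- list(v = kids[fr$i + 1L], i = 0L)
    } else {
      emit(")")
      emit(lab(fr$v))
      stack[[length(stack)]] <- NULL
    }
  }
  out <- paste0(paste0(unlist(buf[seq_len(nb)]), collapse = ""), ";")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}

#' Read a Newick tree with affinity node comments
#'
#' Parses Newick with optional `[&key=value,...]` comments on every node.
#' Node times are derived from branch lengths (root at time 0); every node
#' must carry an `affinity` comment.
#'
#' @param path Path to a Newick file, or a Newick string containing `";"`.
#' @return An [annotated_tree()].
#' @export
read_annotated_newick <- function(path) {
  txt <- if (grepl(";", path, fixed = TRUE)) path else
    paste0(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("[[:space:]]", "", txt)
  txt <- sub(";.*$", "", txt)
  chars <- strsplit(txt, "")[[1]]
  n_ch <- length(chars)
  parent <- integer(0); label <- character(0)
  brlen <- numeric(0); affin <- numeric(0)
  new_node <- function(p) {
    parent[length(parent) + 1L] <<- p
    label[length(label) + 1L] <<- ""
    brlen[length(brlen) + 1L] <<- NA_real_
    affin[length(affin) + 1L] <<- NA_real_
    length(parent)
  }
  pos <- 1L
  peek <- function() if (pos <= n_ch) chars[pos] else ""
  read_upto <- function(stopset) {
    start <- pos
    while (pos <= n_ch && !(chars[pos] %in% stopset)) pos <<- pos + 1L
    if (pos > start) paste0(chars[start:(pos - 1L)], collapse = "") else ""
  }
  # attach label / [&comment] / :length to node v
  read_meta <- function(v) {
    label[v] <<- read_upto(c("[", ":", ",", ")", "("))
    if (peek() == "[") {
      pos <<- pos + 1L
      com <- read_upto("]")
      if (peek() != "]") stop("unterminated comment at position ", pos)
      pos <<- pos + 1L
      com <- sub("^&", "", com)
      for (kv in strsplit(com, ",", fixed = TRUE)[[1]]) {
        p <- strsplit(kv, "=", fixed = TRUE)[[1]]
        if (length(p) == 2L && p[1] == "affinity")
          affin[v] <<- as.numeric(p[2])
      }
    }
    if (peek() == ":") {
      pos <<- pos + 1L
      brlen[v] <<- as.numeric(read_upto(c(",", ")", "(")))
    }
  }
  if (peek() != "(") { # single-leaf "tree"
    v <- new_node(-1L)
    read_meta(v)
    stop("Newick describes a single node, not a tree")
  }
  stack <- integer(0)
  repeat {
    c0 <- peek()
    if (c0 == "(") {
      pos <- pos + 1L
      v <- new_node(if (length(stack)) stack[length(stack)] else -1L)
      stack <- c(stack, v)
    } else if (c0 == ",") {
      pos <- pos + 1L
    } else if (c0 == ")") {
      pos <- pos + 1L
      if (!length(stack))
        stop("malformed Newick: unbalanced ')' at position ", pos)
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      read_meta(v)
      if (!length(stack)) break
    } else if (c0 == "") {
      stop("malformed Newick: unbalanced parentheses at position ", pos)
    } else {
      v <- new_node(stack[length(stack)])
      read_meta(v)
    }
  }
  if (pos <= n_ch)
    stop("malformed Newick: trailing characters at position ", pos)
  if (anyNA(affin)) {
    bad <- which(is.na(affin))
    stop("node(s) missing an affinity comment: ",
         paste(ifelse(nzchar(label[bad]), label[bad], paste0("#", bad)),
               collapse = ", "))
  }
  brlen[is.na(brlen)] <- 0
  n <- length(parent)
  time <- rep(NA_real_, n); time[parent == -1L] <- 0
  for (v in seq_len(n)) # nodes are created parent-before-child
    if (parent[v] > 0L) time[v] <- time[parent[v]] + brlen[v]
  parent_to_tree(ifelse(parent > 0L, parent - 1L, -1L), time, affin,
                 labels = label)
}
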