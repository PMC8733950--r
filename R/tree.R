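#' Parse a Newick tree with validation
#'
#' Reads a rooted phylogenetic tree from Newick text and enforces the
#' structural requirements of the clade-divergence analyses: pairwise-distinct
#' leaf labels and a branch length on every non-root edge. Bracketed comments
#' are stripped; internal node labels are retained as plain labels (they are
#' names, never support values, as far as this package is concerned). Single
#' quotes around labels are carried verbatim as part of the label, so quoted
#' labels round-trip unchanged through [write_newick()].
#'
#' Negative branch lengths (as can arise from neighbour-joining) are accepted
#' with a warning and enter downstream samples as-is; zero lengths are legal
#' values. An unrooted Newick with a basal multifurcation is accepted and its
#' basal node treated as the root.
#'
#' @param text A single Newick string (terminated by `;`).
#' @return An object of class `phylo` (see \pkg{ape}).
#' @examples
#' tr <- parse_newick("((A:1,B:2):3,C:4);")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  .newick_prescan(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: no tree could be read", call. = FALSE)
  validate_tree(tree)
  tree
}

# Cheap structural pre-scan so that the most common syntax errors are
# reported with a character position (ape's parser does not give one).
.newick_prescan <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  in_quote <- FALSE
  in_comment <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_comment) {
      if (ch == "]") in_comment <- FALSE
      next
    }
    if (ch == "'") {
      in_quote <- !in_quote
      next
    }
    if (in_quote) next
    if (ch == "[") in_comment <- TRUE
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unbalanced ')' at character ", i, call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at end of input", call. = FALSE)
  if (!any(chars == ";"))
    stop("Newick parse error: missing ';' terminator at character ",
         length(chars) + 1L, call. = FALSE)
  invisible(TRUE)
}

#' @keywords internal
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L)
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "), call. = FALSE)
  n_edge <- nrow(tree$edge)
  if (n_edge > 0L) {
    el <- tree$edge.length
    if (is.null(el))
      stop("missing branch lengths: tree has no edge lengths at all", call. = FALSE)
    bad <- which(is.na(el) | is.nan(el))
    if (length(bad) > 0L) {
      nodes <- vapply(tree$edge[bad, 2L], function(nd) node_name(tree, nd), character(1L))
      stop("missing branch length on the edge into node(s): ",
           paste(nodes, collapse = ", "), call. = FALSE)
    }
    if (any(el < 0))
      warning("tree contains ", sum(el < 0),
              " negative branch length(s); they are kept as-is", call. = FALSE)
  }
  invisible(tree)
}

# Human-readable name for a node number.
node_name <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  lbl <- tree$node.label[node - ntip]
  if (!is.null(lbl) && !is.na(lbl) && nzchar(lbl)) lbl else paste0("node#", node)
}

#' Serialize a tree to Newick
#'
#' Writes at full double precision so that `parse_newick(write_newick(t))`
#' reproduces `t` with identical labels and branch lengths.
#'
#' @param tree A `phylo` object.
#' @return A single Newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  # ape's writer rewrites spaces in labels as underscores; shield them with a
  # placeholder so quoted labels survive the round trip verbatim
  tok <- "\x01"
  shield <- function(l) if (is.null(l)) l else gsub(" ", tok, l, fixed = TRUE)
  tree$tip.label <- shield(tree$tip.label)
  tree$node.label <- shield(tree$node.label)
  gsub(tok, " ", ape::write.tree(tree, digits = 17), fixed = TRUE)
}

#' Most recent common ancestor of a set of leaves
#'
#' @param tree A `phylo` object.
#' @param leaf_names Nonempty character vector of leaf labels.
#' @return The node number of the deepest node whose subtree contains all
#'   named leaves (the tip number itself for a single leaf).
#' @export
find_mrca <- function(tree, leaf_names) {
  stopifnot(inherits(tree, "phylo"))
  leaf_names <- unique(as.character(leaf_names))
  if (length(leaf_names) == 0L) stop("leaf set is empty", call. = FALSE)
  missing <- setdiff(leaf_names, tree$tip.label)
  if (length(missing) > 0L)
    stop("unknown leaf name(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(leaf_names) == 1L)
    return(match(leaf_names, tree$tip.label))
  ape::getMRCA(tree, leaf_names)
}

#' Designate a clade of a tree
#'
#' A clade is an internal node together with its whole subtree; it is one of
#' the two comparison units of the divergence analysis and must contain at
#' least two leaves.
#'
#' @param tree A `phylo` object.
#' @param node Node number of the clade root (e.g. from [find_mrca()]), or an
#'   internal node label present in `tree$node.label`.
#' @return An object of class `clade_ref` with elements `tree` and `node`.
#' @export
clade_ref <- function(tree, node) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (is.character(node)) {
    if (is.null(tree$node.label))
      stop("tree has no internal node labels; cannot resolve '", node, "'", call. = FALSE)
    hit <- match(node, tree$node.label)
    if (is.na(hit))
      stop("no internal node labelled '", node, "'", call. = FALSE)
    node <- ntip + hit
  }
  node <- as.integer(node)
  if (node < 1L || node > ntip + tree$Nnode)
    stop("node ", node, " is not a node of the tree", call. = FALSE)
  lv <- subtree_leaves(tree, node)
  if (length(lv) < 2L)
    stop("clade must contain at least 2 leaves (node ", node, " has ",
         length(lv), ")", call. = FALSE)
  structure(list(tree = tree, node = node), class = "clade_ref")
}

#' @export
print.clade_ref <- function(x, ...) {
  cat("<clade_ref> root node ", x$node, ", ", length(clade_leaves(x)),
      " leaves\n", sep = "")
  invisible(x)
}

# Parent lookup vector: parent[i] is the parent node of node i (NA for root).
parent_vector <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  p <- rep(NA_integer_, n)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

# All node numbers in the subtree rooted at `node` (including `node`).
subtree_nodes <- function(tree, node) {
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  out <- integer(0)
  stack <- node
  while (length(stack) > 0L) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, nd)
    ch <- kids[[as.character(nd)]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  out
}

# Tip numbers below `node`.
subtree_leaves <- function(tree, node) {
  ntip <- length(tree$tip.label)
  nds <- subtree_nodes(tree, node)
  sort(nds[nds <= ntip])
}

#' Leaf labels of a clade
#' @param clade A `clade_ref`.
#' @return Character vector of leaf labels in the clade's subtree.
#' @export
clade_leaves <- function(clade) {
  stopifnot(inherits(clade, "clade_ref"))
  clade$tree$tip.label[subtree_leaves(clade$tree, clade$node)]
}

#' Path distance from the clade root to a leaf
#'
#' Sum of branch lengths on the unique path from the clade's root node down
#' to the named leaf. This is the "divergence from the root" used to pick the
#' least-diverged representative when a species contributes several leaves.
#'
#' @param clade A `clade_ref`.
#' @param leaf A leaf label inside the clade.
#' @return Nonnegative real (can be negative only if the tree carries
#'   negative branch lengths).
#' @export
distance_to_clade_root <- function(clade, leaf) {
  stopifnot(inherits(clade, "clade_ref"), is.character(leaf), length(leaf) == 1L)
  tree <- clade$tree
  tip <- match(leaf, tree$tip.label)
  if (is.na(tip)) stop("unknown leaf '", leaf, "'", call. = FALSE)
  par <- parent_vector(tree)
  # edge length into each node
  elen <- rep(NA_real_, length(par))
  elen[tree$edge[, 2L]] <- tree$edge.length
  d <- 0
  nd <- tip
  while (!is.na(nd) && nd != clade$node) {
    d <- d + elen[nd]
    nd <- par[nd]
  }
  if (is.na(nd))
    stop("leaf '", leaf, "' is not inside the clade", call. = FALSE)
  d
}
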