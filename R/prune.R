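#' Prune a clade to a kept leaf set, preserving path lengths
#'
#' Restricts the clade's subtree to `keep`: all other leaves are removed,
#' internal nodes left with a single child are suppressed and their two
#' incident edges merged into one edge carrying the summed length, and the
#' result is rooted at the most recent common ancestor of the kept leaves.
#' Consequently the patristic distance between any two kept leaves is exactly
#' the same before and after pruning — the module's defining contract.
#'
#' This is the "common species" restriction step of the divergence analysis:
#' after representatives are chosen, each clade is pruned to the
#' representatives of the species shared by both clades, and the tests run on
#' the updated branch lengths.
#'
#' @param clade A `clade_ref`.
#' @param keep Character vector of leaf labels to retain (at least 2, all
#'   inside the clade).
#' @return An object of class `pruned_clade`: `tree` (a standalone `phylo`
#'   rooted at the kept MRCA), `keep`, `removed_length` (total branch length
#'   discarded), and `stem_length` (the original clade stem plus any path
#'   between the old clade root and the new root; `NA` when the clade root
#'   was the tree root and nothing was collapsed above the kept MRCA).
#' @export
prune_to_leaves <- function(clade, keep) {
  stopifnot(inherits(clade, "clade_ref"))
  keep <- unique(as.character(keep))
  lv <- clade_leaves(clade)
  outside <- setdiff(keep, lv)
  if (length(outside) > 0L)
    stop("leaves not in clade: ", paste(outside, collapse = ", "), call. = FALSE)
  if (length(keep) < 2L)
    stop("need at least 2 kept leaves to define within-clade divergence",
         call. = FALSE)
  sub <- clade_subtree(clade)
  stem <- clade_stem_length(clade)
  pruned <- ape::keep.tip(sub, keep)
  extra <- if (!is.null(pruned$root.edge)) pruned$root.edge else 0
  pruned$root.edge <- NULL
  removed <- sum(sub$edge.length) - sum(pruned$edge.length)
  stem_out <- if (is.na(stem) && extra == 0) NA_real_
              else sum(c(if (!is.na(stem)) stem, extra))
  structure(list(tree = pruned,
                 keep = sort(keep, method = "radix"),
                 removed_length = removed,
                 stem_length = stem_out),
            class = "pruned_clade")
}

#' @export
print.pruned_clade <- function(x, ...) {
  cat("<pruned_clade> ", length(x$tree$tip.label), " leaves kept, ",
      format(x$removed_length), " total length removed\n", sep = "")
  invisible(x)
}

# Standalone phylo for the clade's subtree.
clade_subtree <- function(clade) {
  tree <- clade$tree
  root <- root_node(tree)
  if (clade$node == root) tree else ape::extract.clade(tree, clade$node)
}

root_node <- function(tree) {
  setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])[1L]
}

# Length of the edge into the clade root; NA when the clade root is the
# tree root (no stem edge exists).
clade_stem_length <- function(clade) {
  i <- match(clade$node, clade$tree$edge[, 2L])
  if (is.na(i)) NA_real_ else clade$tree$edge.length[i]
}

#' Within-clade branch-length sample
#'
#' Collects the lengths of every edge strictly inside the clade's subtree as
#' a multiset (duplicate values retained). The stem edge — the edge
#' connecting the clade root to its parent, typically the duplication node —
#' is excluded by default: it measures the pre-speciation divergence of the
#' duplicate itself, not divergence within the clade during speciation. Set
#' `include_stem = TRUE` to add it.
#'
#' @param clade A `clade_ref` or a `pruned_clade`.
#' @param include_stem Include the stem edge length in the sample?
#' @return Numeric vector of branch lengths (length at least 2).
#' @export
branch_lengths <- function(clade, include_stem = FALSE) {
  if (inherits(clade, "pruned_clade")) {
    vals <- clade$tree$edge.length
    stem <- clade$stem_length
  } else if (inherits(clade, "clade_ref")) {
    tree <- clade$tree
    inside <- setdiff(subtree_nodes(tree, clade$node), clade$node)
    vals <- tree$edge.length[tree$edge[, 2L] %in% inside]
    stem <- clade_stem_length(clade)
  } else stop("expected a clade_ref or pruned_clade", call. = FALSE)
  if (include_stem) {
    if (is.na(stem))
      stop("clade has no stem edge (its root is the tree root)", call. = FALSE)
    vals <- c(vals, stem)
  }
  if (length(vals) < 2L)
    stop("fewer than 2 branch lengths; sample too small for any test",
         call. = FALSE)
  vals
}
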