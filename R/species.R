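#' Species extractor rule
#'
#' Leaf labels of gene trees often embed a species identifier (for instance a
#' taxonomic id such as `taxid_9606`). A `species_extractor` is a regular
#' expression applied to each leaf label; the substring of the *first* match
#' is the species id. Leaves with no match are handled according to
#' `unmatched`: excluded with a warning (default) or treated as an error.
#'
#' @param pattern Regular expression (POSIX extended, as `regexpr`).
#' @param unmatched `"exclude"` (drop non-matching leaves, with a warning at
#'   map construction) or `"error"`.
#' @return An object of class `species_extractor`.
#' @examples
#' ex <- species_extractor("taxid.[0-9]+")
#' extract_species("NPC1_taxid_9606", ex)
#' @export
species_extractor <- function(pattern, unmatched = c("exclude", "error")) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  unmatched <- match.arg(unmatched)
  ok <- tryCatch({ regexpr(pattern, "x"); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("invalid regular expression: ", pattern, call. = FALSE)
  structure(list(pattern = pattern, unmatched = unmatched),
            class = "species_extractor")
}

#' Extract species ids from leaf labels
#'
#' Vectorized first-match extraction; returns `NA` where the pattern does not
#' match.
#'
#' @param labels Character vector of leaf labels.
#' @param extractor A [species_extractor()].
#' @return Character vector of species ids (`NA` for non-matching labels).
#' @export
extract_species <- function(labels, extractor) {
  stopifnot(inherits(extractor, "species_extractor"))
  m <- regexpr(extractor$pattern, labels)
  out <- rep(NA_character_, length(labels))
  hit <- m != -1L
  out[hit] <- substring(labels[hit], m[hit], m[hit] + attr(m, "match.length")[hit] - 1L)
  out
}

#' Species-to-leaves map of a clade
#'
#' Groups the clade's leaves by extracted species id and records leaves whose
#' label does not match the pattern.
#'
#' @param clade A `clade_ref` (or `pruned_clade`).
#' @param extractor A [species_extractor()].
#' @return An object of class `species_map`: a list with `species` (named list
#'   mapping species id to leaf labels), `unmatched` (character vector) and
#'   `pattern`.
#' @export
clade_species_map <- function(clade, extractor) {
  stopifnot(inherits(extractor, "species_extractor"))
  leaves <- if (inherits(clade, "pruned_clade")) clade$tree$tip.label
            else clade_leaves(clade)
  ids <- extract_species(leaves, extractor)
  unmatched <- leaves[is.na(ids)]
  if (length(unmatched) > 0L) {
    if (extractor$unmatched == "error")
      stop("leaves with no species match for pattern '", extractor$pattern,
           "': ", paste(unmatched, collapse = ", "), call. = FALSE)
    warning("excluding ", length(unmatched), " leaf/leaves with no species match: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(ids)
  sp <- split(leaves[keep], ids[keep])
  structure(list(species = sp, unmatched = unmatched,
                 pattern = extractor$pattern),
            class = "species_map")
}

#' @export
print.species_map <- function(x, ...) {
  cat("<species_map> ", length(x$species), " species, ",
      sum(lengths(x$species)), " leaves mapped, ",
      length(x$unmatched), " unmatched\n", sep = "")
  invisible(x)
}

#' Least-diverged representative leaf
#'
#' When a species contributes several leaves to a clade (in-paralogs,
#' isoforms), the analysis keeps one representative: the leaf with the
#' smallest path distance to the clade root, i.e. the least diverged copy.
#' Ties are broken by lexicographic leaf label (C-locale).
#'
#' @param clade A `clade_ref`.
#' @param leaves Nonempty character vector of leaf labels inside the clade.
#' @return A single leaf label.
#' @export
select_representative <- function(clade, leaves) {
  stopifnot(inherits(clade, "clade_ref"), length(leaves) >= 1L)
  d <- vapply(leaves, function(l) distance_to_clade_root(clade, l), numeric(1L))
  cand <- leaves[d <= min(d) + 0]
  sort(cand, method = "radix")[1L]
}

#' Species-set (Venn/superset) analysis of two clades
#'
#' Compares the species content of the two clades: intersection and
#' per-clade unique counts, plus a qualitative relation. A clade is declared
#' a superset of the other only when the other side has no unique species
#' *and* the shared set is nonempty — a superset relation over an empty
#' intersection would be biologically meaningless here. A superset pattern is
#' the package's signal that the superset clade's gene is the more likely
#' essential duplicate (retained across lineages).
#'
#' @param map_a,map_b `species_map` objects built with the same pattern.
#' @return An object of class `species_set_summary`: counts `common`,
#'   `unique_a`, `unique_b`, the explicit id sets, and
#'   `relation` in `c("A_superset","B_superset","equal","overlap","disjoint")`.
#' @export
species_set_analysis <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "species_map"), inherits(map_b, "species_map"))
  if (!identical(map_a$pattern, map_b$pattern))
    stop("species maps were built with different patterns", call. = FALSE)
  a <- names(map_a$species)
  b <- names(map_b$species)
  if (length(a) == 0L && length(b) == 0L)
    stop("both species maps are empty; nothing to compare", call. = FALSE)
  common <- intersect(a, b)
  ua <- setdiff(a, b)
  ub <- setdiff(b, a)
  relation <-
    if (length(common) == 0L) "disjoint"
    else if (length(ua) == 0L && length(ub) == 0L) "equal"
    else if (length(ub) == 0L) "A_superset"
    else if (length(ua) == 0L) "B_superset"
    else "overlap"
  structure(list(common = length(common),
                 unique_a = length(ua),
                 unique_b = length(ub),
                 common_species = sort(common, method = "radix"),
                 unique_a_species = sort(ua, method = "radix"),
                 unique_b_species = sort(ub, method = "radix"),
                 relation = relation),
            class = "species_set_summary")
}

#' @export
print.species_set_summary <- function(x, ...) {
  cat("<species_set_summary> common ", x$common, " | unique A ", x$unique_a,
      " | unique B ", x$unique_b, " | relation ", x$relation, "\n", sep = "")
  invisible(x)
}
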