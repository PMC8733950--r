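#' Analysis configuration
#'
#' Bundles the user choices for one clade-divergence comparison. Clades are
#' designated either by a set of leaf labels (their MRCA defines the clade)
#' or by a single internal node label.
#'
#' @param clade_a,clade_b Character vector of leaf labels, or a single
#'   internal node label.
#' @param species_pattern Optional regular expression extracting a species id
#'   from each leaf label (e.g. `"taxid.[0-9]+"`). When given, the comparison
#'   is restricted to the species common to both clades, one representative
#'   leaf per species.
#' @param unmatched Policy for leaves the pattern does not match:
#'   `"exclude"` (with a warning) or `"error"`.
#' @param include_stem Include each clade's stem edge in its branch-length
#'   sample? Default `FALSE`: the stem measures divergence of the duplicate
#'   itself, not within-clade divergence during speciation.
#' @param seed Optional integer seed recorded for provenance and used by any
#'   downstream simulation calls.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(clade_a, clade_b, species_pattern = NULL,
                            unmatched = c("exclude", "error"),
                            include_stem = FALSE, seed = NULL) {
  stopifnot(length(clade_a) >= 1L, length(clade_b) >= 1L)
  unmatched <- match.arg(unmatched)
  structure(list(clade_a = as.character(clade_a),
                 clade_b = as.character(clade_b),
                 species_pattern = species_pattern,
                 unmatched = unmatched,
                 include_stem = isTRUE(include_stem),
                 seed = seed),
            class = "analysis_config")
}

#' Resolve the two clade designators against a tree
#'
#' Each designator is resolved to a clade: a single string matching an
#' internal node label selects that node; otherwise the designator is taken
#' as leaf labels and the clade is their MRCA. The two clades must be
#' disjoint (no shared leaves, neither nested in the other). They are not
#' required to be sister groups, but a warning is raised when their roots are
#' not siblings, since the comparison is meant for the two sides of a gene
#' duplication node.
#'
#' @param tree A `phylo` object.
#' @param config An [analysis_config()].
#' @return List with elements `a` and `b`, both `clade_ref`.
#' @export
resolve_clades <- function(tree, config) {
  stopifnot(inherits(config, "analysis_config"))
  a <- resolve_one(tree, config$clade_a)
  b <- resolve_one(tree, config$clade_b)
  if (length(intersect(clade_leaves(a), clade_leaves(b))) > 0L)
    stop("clades must be disjoint paralogous sister groups ",
         "(the resolved clades share leaves or one contains the other)",
         call. = FALSE)
  par <- parent_vector(tree)
  if (!identical(par[a$node], par[b$node]))
    warning("clade roots are not siblings; make sure both descend from ",
            "the intended gene duplication node", call. = FALSE)
  list(a = a, b = b)
}

resolve_one <- function(tree, designator) {
  if (length(designator) == 1L && !is.null(tree$node.label) &&
      designator %in% tree$node.label)
    return(clade_ref(tree, designator))
  clade_ref(tree, find_mrca(tree, designator))
}

#' Compare the internal divergence of two paralogous clades
#'
#' Runs the full analysis: clade resolution, species extraction,
#' representative selection, common-species pruning, branch-length sampling,
#' the three two-sample tests, and the species-set summary.
#'
#' With a species pattern the pipeline is, in fixed order: (1) build the
#' species-to-leaves map of each clade; (2) within each clade pick, per
#' species, the least-diverged representative leaf; (3) intersect the two
#' species sets; (4) prune each clade to the representatives of the common
#' species, updating branch lengths; (5) extract the within-clade
#' branch-length samples; (6) run the three tests; (7) summarize the species
#' sets of the *unpruned* clades (the Venn reflects full clade content);
#' (8) assemble the report. Without a pattern, steps 1-4 are skipped and all
#' leaves are used.
#'
#' @param tree A `phylo` object (see [parse_newick()]).
#' @param config An [analysis_config()].
#' @return An object of class `divergence_report`; see [write_report()].
#' @examples
#' tr <- parse_newick(
#'   "((g1_sp1:0.1,g1_sp2:0.2):0.05,(g2_sp1:0.4,g2_sp2:0.6):0.05);")
#' cfg <- analysis_config(clade_a = c("g1_sp1", "g1_sp2"),
#'                        clade_b = c("g2_sp1", "g2_sp2"),
#'                        species_pattern = "sp[0-9]+")
#' rep <- compare_clades(tr, cfg)
#' rep$tests$student_t
#' @export
compare_clades <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "analysis_config"))
  clades <- resolve_clades(tree, config)
  a <- clades$a; b <- clades$b
  species_summary <- NULL
  reps <- list(a = NULL, b = NULL)
  pruned_n <- c(a = length(clade_leaves(a)), b = length(clade_leaves(b)))
  n_species <- c(a = NA_integer_, b = NA_integer_)

  if (!is.null(config$species_pattern)) {
    ex <- species_extractor(config$species_pattern, config$unmatched)
    map_a <- clade_species_map(a, ex)
    map_b <- clade_species_map(b, ex)
    n_species <- c(a = length(map_a$species), b = length(map_b$species))
    reps$a <- vapply(map_a$species, function(lv) select_representative(a, lv),
                     character(1L))
    reps$b <- vapply(map_b$species, function(lv) select_representative(b, lv),
                     character(1L))
    common <- intersect(names(map_a$species), names(map_b$species))
    if (length(common) < 2L)
      stop("fewer than 2 common species between the clades; ",
           "clade A species: {", paste(names(map_a$species), collapse = ", "),
           "}; clade B species: {", paste(names(map_b$species), collapse = ", "),
           "}", call. = FALSE)
    dropped_a <- setdiff(clade_leaves(a), reps$a[common])
    dropped_b <- setdiff(clade_leaves(b), reps$b[common])
    if (length(c(dropped_a, dropped_b)) > 0L)
      message("excluded from the pruned comparison (non-representative or ",
              "non-common species): ",
              paste(sort(c(dropped_a, dropped_b), method = "radix"),
                    collapse = ", "))
    pa <- prune_to_leaves(a, unname(reps$a[common]))
    pb <- prune_to_leaves(b, unname(reps$b[common]))
    pruned_n <- c(a = length(pa$tree$tip.label), b = length(pb$tree$tip.label))
    sample_a <- branch_lengths(pa, include_stem = config$include_stem)
    sample_b <- branch_lengths(pb, include_stem = config$include_stem)
    species_summary <- species_set_analysis(map_a, map_b)
  } else {
    sample_a <- branch_lengths(a, include_stem = config$include_stem)
    sample_b <- branch_lengths(b, include_stem = config$include_stem)
  }

  tests <- run_all_tests(sample_a, sample_b)
  newick <- write_newick(tree)
  structure(list(
    clades = list(
      a = clade_summary(a, n_species[["a"]], reps$a, pruned_n[["a"]], sample_a),
      b = clade_summary(b, n_species[["b"]], reps$b, pruned_n[["b"]], sample_b)),
    tests = tests,
    species = species_summary,
    samples = list(a = sample_a, b = sample_b),
    provenance = list(
      species_pattern = config$species_pattern,
      unmatched_policy = config$unmatched,
      include_stem = config$include_stem,
      tool = "cladediv",
      version = as.character(utils::packageVersion("cladediv")),
      input_md5 = text_md5(newick))),
    class = "divergence_report")
}

clade_summary <- function(clade, n_species, representatives, n_pruned, sample) {
  list(n_leaves = length(clade_leaves(clade)),
       n_species = n_species,
       representatives = if (is.null(representatives)) NULL
                         else as.list(representatives),
       n_pruned_leaves = n_pruned,
       sample_size = length(sample),
       mean_length = mean(sample),
       median_length = stats::median(sample))
}

text_md5 <- function(text) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(text, f)
  unname(tools::md5sum(f))
}

#' @export
print.divergence_report <- function(x, ...) {
  cat("Clade divergence report\n")
  cat(sprintf("  clade A: %d leaves, sample of %d branch lengths (mean %.4g)\n",
              x$clades$a$n_leaves, x$clades$a$sample_size, x$clades$a$mean_length))
  cat(sprintf("  clade B: %d leaves, sample of %d branch lengths (mean %.4g)\n",
              x$clades$b$n_leaves, x$clades$b$sample_size, x$clades$b$mean_length))
  for (t in x$tests) {
    if (inherits(t, "divergence_test_error"))
      cat(sprintf("  %-15s failed: %s\n", t$test, t$error))
    else
      cat(sprintf("  %-15s statistic = %9.5g  p = %s\n",
                  t$test, t$statistic, format_p(t$p_value)))
  }
  if (!is.null(x$species))
    cat(sprintf("  species sets: common %d, unique A %d, unique B %d (%s)\n",
                x$species$common, x$species$unique_a, x$species$unique_b,
                x$species$relation))
  invisible(x)
}
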