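#' Specification of a simulated duplicated gene tree
#'
#' Describes one simulation scenario: a gene duplication at the root
#' producing two paralogous clades with matched species content and
#' controlled per-clade divergence rates. The defaults emulate a desk-scale
#' duplication scenario: branch lengths drawn i.i.d. from an exponential
#' distribution with mean 0.1 substitutions/site (positive and right-skewed,
#' like real gene-tree branch lengths), equal rates in both clades, and no
#' species loss.
#'
#' @param k Number of species (at least 3).
#' @param rate_a,rate_b Positive divergence-rate multipliers applied to all
#'   edges of clade A and clade B respectively; their ratio is the simulated
#'   effect size.
#' @param mean_length Mean of the exponential base branch-length
#'   distribution (substitutions/site).
#' @param fixed_length If non-`NULL`, every base edge length is this constant
#'   instead of an exponential draw (deterministic mode for unit checks).
#' @param dropout_b Probability that each species is lost from clade B
#'   (models the essentiality asymmetry in which a dispensable duplicate is
#'   absent from some lineages); at least 2 species always survive.
#' @param seed Integer seed; identical specs yield byte-identical trees.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(k, rate_a = 1, rate_b = 1, mean_length = 0.1,
                     fixed_length = NULL, dropout_b = 0, seed = 1L) {
  if (k < 3L) stop("k must be >= 3", call. = FALSE)
  if (rate_a <= 0 || rate_b <= 0) stop("rate multipliers must be > 0", call. = FALSE)
  if (dropout_b < 0 || dropout_b >= 1)
    stop("dropout_b must be in [0, 1)", call. = FALSE)
  if (!is.null(fixed_length) && fixed_length < 0)
    stop("fixed_length must be >= 0", call. = FALSE)
  structure(list(k = as.integer(k), rate_a = rate_a, rate_b = rate_b,
                 mean_length = mean_length, fixed_length = fixed_length,
                 dropout_b = dropout_b, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a duplicated gene tree with known ground truth
#'
#' Builds one random species topology on `k` leaves by uniform random joins,
#' instantiates it twice under a common root — the duplication node — and
#' draws every edge length i.i.d. from the base distribution, multiplying
#' clade A edges (stem included) by `rate_a` and clade B edges by `rate_b`.
#' Species dropout is applied to clade B only. Leaves are labelled
#' `gA_sp<i>` / `gB_sp<i>`, so the default species pattern `"sp[0-9]+"`
#' recovers the species matching between the two clades.
#'
#' @param spec A [sim_spec()].
#' @return List with `tree` (a `phylo`; root = duplication node), and
#'   `truth`: `ratio` (true rate ratio rate_b/rate_a), `dropped_species`
#'   (species ids absent from clade B) and `species` (all ids).
#' @examples
#' sim <- simulate_duplicated_tree(sim_spec(k = 5, rate_b = 3, seed = 42))
#' sim$truth$ratio
#' @export
simulate_duplicated_tree <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  species <- paste0("sp", seq_len(spec$k))
  topo <- random_join_topology(species)

  clade_a <- ape::read.tree(text = paste0(topo, ";"))
  clade_a$tip.label <- paste0("gA_", clade_a$tip.label)

  clade_b <- ape::read.tree(text = paste0(topo, ";"))
  dropped <- character(0)
  if (spec$dropout_b > 0) {
    dropped <- species[stats::runif(spec$k) < spec$dropout_b]
    while (spec$k - length(dropped) < 2L)          # keep B analysable
      dropped <- dropped[-1L]
    if (length(dropped) > 0L)
      clade_b <- ape::drop.tip(clade_b, dropped)
  }
  clade_b$tip.label <- paste0("gB_", clade_b$tip.label)

  clade_a$edge.length <- draw_lengths(nrow(clade_a$edge), spec) * spec$rate_a
  clade_b$edge.length <- draw_lengths(nrow(clade_b$edge), spec) * spec$rate_b
  stem_a <- draw_lengths(1L, spec) * spec$rate_a
  stem_b <- draw_lengths(1L, spec) * spec$rate_b

  newick <- paste0("(", strip_semicolon(ape::write.tree(clade_a, digits = 17)),
                   ":", format(stem_a, digits = 17),
                   ",", strip_semicolon(ape::write.tree(clade_b, digits = 17)),
                   ":", format(stem_b, digits = 17), ");")
  tree <- parse_newick(newick)
  list(tree = tree,
       truth = list(ratio = spec$rate_b / spec$rate_a,
                    dropped_species = sort(dropped, method = "radix"),
                    species = species))
}

# Random rooted binary topology by uniform pairwise joins; returns a Newick
# fragment (no branch lengths, no terminator).
random_join_topology <- function(labels) {
  items <- as.list(labels)
  while (length(items) > 1L) {
    i <- sample.int(length(items), 2L)
    merged <- paste0("(", items[[i[1L]]], ",", items[[i[2L]]], ")")
    items <- c(items[-i], list(merged))
  }
  items[[1L]]
}

draw_lengths <- function(n, spec) {
  if (!is.null(spec$fixed_length)) rep(spec$fixed_length, n)
  else stats::rexp(n, rate = 1 / spec$mean_length)
}

strip_semicolon <- function(s) sub(";$", "", s)

#' Rejection-rate sweep over simulation scenarios
#'
#' For each scenario, repeatedly simulates a duplicated tree, runs the full
#' clade comparison (species pattern `"sp[0-9]+"`) and records the fraction
#' of replicates in which each test rejects at level `alpha`. With
#' `rate_a == rate_b` this measures the empirical type-I error; with unequal
#' rates, power. Per-replicate seeds are derived deterministically from each
#' spec's seed, so the sweep is reproducible.
#'
#' @param specs A `sim_spec` or list of them.
#' @param replicates Replicates per scenario (at least 50 for stable rates).
#' @param alpha Significance level in (0, 1).
#' @return A data frame with one row per scenario x test: `k`, `rate_a`,
#'   `rate_b`, `dropout_b`, `test`, `replicates`, `n_valid`,
#'   `rejection_rate`, `mean_statistic`.
#' @export
power_sweep <- function(specs, replicates, alpha = 0.05) {
  if (inherits(specs, "sim_spec")) specs <- list(specs)
  stopifnot(replicates >= 50L, alpha > 0, alpha < 1)
  tests <- c("student_t", "welch_t", "mann_whitney_u")
  out <- lapply(specs, function(sp) {
    pmat <- matrix(NA_real_, nrow = replicates, ncol = 3L,
                   dimnames = list(NULL, tests))
    smat <- pmat
    for (i in seq_len(replicates)) {
      sp_i <- sp
      sp_i$seed <- (sp$seed + i * 1000003L) %% 2147483647L
      sim <- simulate_duplicated_tree(sp_i)
      leaves <- sim$tree$tip.label
      cfg <- analysis_config(clade_a = leaves[startsWith(leaves, "gA_")],
                             clade_b = leaves[startsWith(leaves, "gB_")],
                             species_pattern = "sp[0-9]+")
      rep_i <- suppressMessages(suppressWarnings(compare_clades(sim$tree, cfg)))
      for (tn in tests) {
        t <- rep_i$tests[[tn]]
        if (!inherits(t, "divergence_test_error")) {
          pmat[i, tn] <- t$p_value
          smat[i, tn] <- t$statistic
        }
      }
    }
    do.call(rbind, lapply(tests, function(tn) {
      valid <- !is.na(pmat[, tn])
      data.frame(k = sp$k, rate_a = sp$rate_a, rate_b = sp$rate_b,
                 dropout_b = sp$dropout_b, test = tn,
                 replicates = replicates, n_valid = sum(valid),
                 rejection_rate = mean(pmat[valid, tn] < alpha),
                 mean_statistic = mean(smat[valid, tn]))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
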