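micro_tree <- function() parse_newick(
  "((g1_sp1:0.1,g1_sp2:0.2):0.05,(g2_sp1:0.4,g2_sp2:0.6):0.05);")

micro_config <- function(...) analysis_config(
  clade_a = c("g1_sp1", "g1_sp2"), clade_b = c("g2_sp1", "g2_sp2"),
  species_pattern = "sp[0-9]+", ...)

test_that("resolve_clades handles leaf sets, labels and rejects nesting", {
  tr <- parse_newick("((a1:1,a2:1)dupL:1,(b1:1,b2:1)dupR:1);")
  cfg <- analysis_config(c("a1", "a2"), c("b1", "b2"))
  cl <- resolve_clades(tr, cfg)
  expect_setequal(clade_leaves(cl$a), c("a1", "a2"))
  expect_setequal(clade_leaves(cl$b), c("b1", "b2"))

  by_label <- resolve_clades(tr, analysis_config("dupL", c("b1", "b2")))
  expect_equal(by_label$a$node, cl$a$node)

  # MRCA of {a1, b1} is the root, which contains clade B: nesting error
  expect_error(resolve_clades(tr, analysis_config(c("a1", "b1"), c("b1", "b2"))),
               "disjoint")

  # non-sibling clades warn but do not fail
  deep <- parse_newick("(((a1:1,a2:1):1,c:1):1,(b1:1,b2:1):1);")
  expect_warning(resolve_clades(deep, analysis_config(c("a1", "a2"), c("b1", "b2"))),
                 "not siblings")
})

test_that("compare_clades reproduces the worked micro-example", {
  rep <- compare_clades(micro_tree(), micro_config())
  expect_setequal(rep$samples$a, c(0.1, 0.2))
  expect_setequal(rep$samples$b, c(0.4, 0.6))
  st <- rep$tests$student_t
  expect_equal(st$statistic, -3.1304951685, tolerance = 1e-9)
  expect_equal(st$df, 2)
  expect_equal(st$p_value, 0.0886776231, tolerance = 1e-9)
  expect_equal(rep$species$common, 2)
  expect_equal(rep$species$relation, "equal")

  # pattern is a no-op when every species appears once and all are shared
  no_pat <- compare_clades(micro_tree(), analysis_config(
    c("g1_sp1", "g1_sp2"), c("g2_sp1", "g2_sp2")))
  expect_setequal(no_pat$samples$a, rep$samples$a)
  expect_setequal(no_pat$samples$b, rep$samples$b)
  expect_equal(no_pat$tests$student_t$statistic, st$statistic, tolerance = 1e-12)

  # swapping the clades negates every t and preserves every p
  swapped <- compare_clades(micro_tree(), analysis_config(
    clade_a = c("g2_sp1", "g2_sp2"), clade_b = c("g1_sp1", "g1_sp2"),
    species_pattern = "sp[0-9]+"))
  for (nm in c("student_t", "welch_t")) {
    expect_equal(swapped$tests[[nm]]$statistic, -rep$tests[[nm]]$statistic,
                 tolerance = 1e-12)
    expect_equal(swapped$tests[[nm]]$p_value, rep$tests[[nm]]$p_value,
                 tolerance = 1e-12)
  }
  expect_equal(swapped$tests$mann_whitney_u$p_value,
               rep$tests$mann_whitney_u$p_value, tolerance = 1e-12)
})

test_that("an extra in-paralog is replaced by its least-diverged representative", {
  # sp1 contributes two leaves to clade A; the closer one (g1_sp1) is kept
  tr <- parse_newick(paste0(
    "(((g1_sp1:0.05,g1b_sp1:0.9):0.05,g1_sp2:0.2):0.05,",
    "(g2_sp1:0.4,g2_sp2:0.6):0.05);"))
  cfg <- analysis_config(c("g1_sp1", "g1b_sp1", "g1_sp2"),
                         c("g2_sp1", "g2_sp2"),
                         species_pattern = "sp[0-9]+")
  rep <- suppressMessages(compare_clades(tr, cfg))
  expect_equal(rep$clades$a$representatives$sp1, "g1_sp1")
  expect_equal(rep$clades$a$sample_size, 2L)
  expect_equal(rep$clades$a$n_pruned_leaves, 2L)
  # pruned sample: g1_sp1 at 0.05+0.05 = 0.1 from the pruned root, g1_sp2 at 0.2
  expect_setequal(rep$samples$a, c(0.1, 0.2))
})

test_that("too few common species is an informative error", {
  tr <- parse_newick("((g1_sp1:0.1,g1_sp2:0.2):0.1,(g2_sp3:0.4,g2_sp4:0.6):0.1);")
  cfg <- analysis_config(c("g1_sp1", "g1_sp2"), c("g2_sp3", "g2_sp4"),
                         species_pattern = "sp[0-9]+")
  expect_error(compare_clades(tr, cfg), "fewer than 2 common species.*sp1.*sp3")
})

test_that("sample size is 2k-2 for a pruned binary clade of k kept leaves", {
  set.seed(41)
  sim <- simulate_duplicated_tree(sim_spec(k = 12, seed = 77))
  leaves <- sim$tree$tip.label
  cfg <- analysis_config(leaves[startsWith(leaves, "gA_")],
                         leaves[startsWith(leaves, "gB_")],
                         species_pattern = "sp[0-9]+")
  rep <- compare_clades(sim$tree, cfg)
  expect_equal(rep$clades$a$sample_size, 2L * 12L - 2L)
  expect_equal(rep$clades$b$sample_size, 2L * 12L - 2L)
})

test_that("reports serialize to schema-valid JSON and round-trip", {
  rep <- compare_clades(micro_tree(), micro_config())
  json <- tempfile(fileext = ".json")
  tsv <- tempfile(fileext = ".tsv")
  write_report(rep, json, tsv = tsv)
  doc <- read_report(json)
  expect_true(validate_report(doc))
  expect_equal(doc$tests$statistic[1], rep$tests$student_t$p_value * 0 +
                 rep$tests$student_t$statistic, tolerance = 1e-12)
  expect_equal(sort(doc$samples$a), sort(rep$samples$a))
  expect_equal(doc$species$common, 2)
  expect_equal(doc$provenance$species_pattern, "sp[0-9]+")
  tab <- utils::read.delim(tsv)
  expect_equal(tab$test, c("student_t", "welch_t", "mann_whitney_u"))

  # display floor for vanishing p-values
  tiny <- rep
  tiny$tests$student_t$p_value <- 1e-20
  write_report(tiny, json)
  doc2 <- read_report(json)
  expect_equal(doc2$tests$p_display[1], "< 1e-15")
  expect_equal(doc2$tests$p_value[1], 1e-20)
})
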