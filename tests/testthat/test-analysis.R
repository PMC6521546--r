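test_that("the overlap coefficient follows the smaller-set definition", {
  expect_equal(overlap_coefficient(c("a", "b", "c"), c("b", "c", "d")), 2 / 3)
  expect_equal(overlap_coefficient(c("a", "b"), c("a", "b", "c", "d")), 1)
  expect_equal(overlap_coefficient(character(), "a"), 0)
  expect_equal(overlap_coefficient("a", "a"), 1)
  expect_equal(overlap_coefficient(c("a", "a", "b"), c("b", "b")), 1)  # set semantics
})

test_that("overlap coefficient and modality ratios match brute-force oracles", {
  set.seed(11)
  universe <- sprintf("e%03d", 1:100)
  for (trial in 1:1000) {
    x <- sample(universe, sample(0:20, 1))
    y <- sample(universe, sample(0:20, 1))
    # oracle: direct membership counting
    inter <- sum(vapply(unique(x), function(e) e %in% y, logical(1)))
    expected <- if (min(length(x), length(y)) == 0) 0 else
      inter / min(length(x), length(y))
    expect_identical(overlap_coefficient(x, y), expected)
  }
  for (trial in 1:1000) {
    a <- sample(universe, sample(1:15, 1))
    b <- sample(universe, sample(0:15, 1))
    c <- sample(universe, sample(0:15, 1))
    u <- unique(c(a, b, c))
    counts <- vapply(u, function(e) (e %in% a) + (e %in% b) + (e %in% c), 0)
    got <- modality_overlap(a, b, c)
    expect_identical(got[["shared"]], sum(counts == 3) / length(u))
    expect_identical(got[["partial"]], sum(counts == 2) / length(u))
    expect_identical(got[["exclusive"]], sum(counts == 1) / length(u))
    expect_lt(abs(sum(got) - 1), 1e-12)
  }
})

test_that("the similarity index averages the three pairwise coefficients", {
  expect_equal(similarity_index(c("1", "2", "3"), c("2", "3", "4"),
                                c("3", "4", "5")), 5 / 9)
  s <- c("a", "b")
  expect_equal(similarity_index(s, s, s), 1)
  expect_equal(similarity_index("a", "b", "c"), 0)
  # empty-set convention: a database with no convertible content scores 0
  expect_equal(similarity_index(character(), "a", "b"), 0)
})

test_that("similarity index and modality ratios are permutation invariant and bounded", {
  set.seed(13)
  universe <- sprintf("e%02d", 1:40)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (trial in 1:50) {
    sets <- lapply(1:3, function(i) sample(universe, sample(0:12, 1)))
    if (!length(unique(unlist(sets)))) next
    ref <- do.call(similarity_index, sets)
    expect_gte(ref, 0); expect_lte(ref, 1)
    for (p in perms) {
      expect_identical(do.call(similarity_index, sets[p]), ref)
      if (length(unlist(sets[p])))
        expect_identical(sort(do.call(modality_overlap, sets[p])),
                         sort(do.call(modality_overlap, sets)))
    }
  }
  expect_error(modality_overlap(character(), character(), character()), "empty")
})

test_that("modality overlap handles the worked partitions", {
  expect_equal(unname(modality_overlap("x", "x", "x")), c(1, 0, 0))
  expect_equal(unname(modality_overlap(c("1", "2"), c("2", "3"), "4")),
               c(0, 0.25, 0.75))
  expect_equal(unname(modality_overlap("x", "x", "y")), c(0, 0.5, 0.5))
})

test_that("the maximum-overlap bound is min over max", {
  expect_equal(round(100 * max_pairwise_overlap_bound(4048, 655), 2), 16.18)
  expect_equal(max_pairwise_overlap_bound(7, 7), 1)
  expect_equal(max_pairwise_overlap_bound(10, 0), 0)
  expect_error(max_pairwise_overlap_bound(0, 0), "zero")
})

test_that("merging unites node sets and keeps per-database provenance", {
  a <- tiny_graph()
  b <- tiny_graph()
  b$nodes$key <- c("protein|hgnc:2", "abundance|chebi:2")
  b$nodes$identifier <- c("2", "2")
  b$edges$subject <- "protein|hgnc:2"; b$edges$object <- "abundance|chebi:2"
  b$edges$database <- "wikipathways"; b$edges$pathway_id <- "WP1"
  b$metadata$database <- "wikipathways"; b$metadata$pathway_id <- "WP1"
  m <- merge_graphs(list(a, b))
  expect_identical(n_nodes(m), 4L)
  expect_identical(n_edges(m), 2L)
  expect_setequal(m$metadata$database, c("kegg", "wikipathways"))

  # idempotent on nodes
  expect_identical(n_nodes(merge_graphs(list(a, a))), n_nodes(a))

  # shared node appears once; edges remain queryable by database
  c_ <- tiny_graph()
  c_$edges$database <- "wikipathways"; c_$edges$pathway_id <- "WP2"
  c_$metadata$database <- "wikipathways"; c_$metadata$pathway_id <- "WP2"
  m2 <- merge_graphs(list(a, c_))
  expect_identical(n_nodes(m2), 2L)
  expect_identical(sort(unique(m2$edges$database)), c("kegg", "wikipathways"))
})

test_that("collapse_to_genes pools gene, RNA and protein nodes at the gene level", {
  nodes <- tibble::tibble(
    key = c("protein|hgnc:391", "rna|hgnc:391", "gene|hgnc:391",
            "protein|hgnc:391|protein_modification:p-Y641",
            "abundance|chebi:1"),
    class = c("protein", "rna", "gene", "protein", "abundance"),
    prefix = c("hgnc", "hgnc", "hgnc", "hgnc", "chebi"),
    identifier = c("391", "391", "391", "391", "1"),
    label = "x",
    mods = list(character(), character(), character(),
                modification("protein_modification", "p-Y641"), character()),
    members = rep(list(character()), 5))
  g <- pathway_graph(nodes, empty_edges())
  collapsed <- collapse_to_genes(g)
  expect_setequal(collapsed$nodes$key, c("gene|hgnc:391", "abundance|chebi:1"))

  metab_only <- pathway_graph(nodes[5, ], empty_edges())
  expect_identical(collapse_to_genes(metab_only)$nodes$key, "abundance|chebi:1")
})

test_that("entity sets exclude groups and reactions and split by modality", {
  nodes <- tibble::tibble(
    key = c("protein|hgnc:391", "rna|hgnc:391", "abundance|chebi:1",
            "mirna|mirbase:MI1", "bioprocess|kegg.pathway:hsa1",
            "complex|n:c", "reaction|reaction:abc"),
    class = c("protein", "rna", "abundance", "mirna", "bioprocess",
              "complex", "reaction"),
    prefix = c("hgnc", "hgnc", "chebi", "mirbase", "kegg.pathway", "n",
               "reaction"),
    identifier = c("391", "391", "1", "MI1", "hsa1", "c", "abc"),
    label = "", mods = rep(list(character()), 7),
    members = c(rep(list(character()), 5), list("protein|hgnc:391"),
                list(character())))
  g <- pathway_graph(nodes, empty_edges())
  sets <- entity_sets_by_modality(g)
  expect_identical(sets$genes, "gene|hgnc:391")     # protein + rna pooled
  expect_identical(sets$metabolites, "abundance|chebi:1")
  expect_identical(sets$mirnas, "mirna|mirbase:MI1")
  expect_identical(sets$biological_processes, "bioprocess|kegg.pathway:hsa1")
  expect_false(any(grepl("complex|reaction", unlist(sets), fixed = FALSE)))

  groups_only <- pathway_graph(nodes[6, ], empty_edges())
  expect_true(all(lengths(entity_sets_by_modality(groups_only)) == 0))
  empty <- pathway_graph()
  expect_true(all(lengths(entity_sets_by_modality(empty)) == 0))
})

test_that("consensus detection separates agreeing from contradicting sources", {
  base <- tiny_graph()
  e <- base$edges
  agree <- e; agree$database <- "wikipathways"; agree$pathway_id <- "WP1"
  oppose <- e; oppose$database <- "reactome"; oppose$pathway_id <- "R1"
  oppose$relation <- "decreases"

  g_cons <- pathway_graph(base$nodes, rbind(e, agree))
  rec <- detect_consensus(g_cons)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$verdict, "consensus")

  g_contra <- pathway_graph(base$nodes, rbind(e, oppose))
  rec2 <- detect_consensus(g_contra)
  expect_identical(rec2$verdict, "contradictory")

  # single source: nothing to compare
  expect_identical(nrow(detect_consensus(base)), 0L)

  # non-polar relations are ignored
  assoc <- e; assoc$relation <- "association"
  assoc2 <- assoc; assoc2$database <- "wikipathways"; assoc2$pathway_id <- "WP1"
  expect_identical(nrow(detect_consensus(pathway_graph(base$nodes,
                                                       rbind(assoc, assoc2)))), 0L)

  # direct and indirect increases count as the same polarity by default...
  direct <- agree; direct$relation <- "directly_increases"
  g_mixed <- pathway_graph(base$nodes, rbind(e, direct))
  expect_identical(detect_consensus(g_mixed)$verdict, "consensus")
  # ...but not in relation-exact mode
  expect_identical(detect_consensus(g_mixed, relation_exact = TRUE)$verdict,
                   "contradictory")
})

test_that("consensus detection never reports pairs with fewer than two polar edges", {
  set.seed(5)
  for (trial in 1:20) {
    n <- sample(3:6, 1)
    keys <- paste0("protein|hgnc:", seq_len(n))
    nodes <- tibble::tibble(key = keys, class = "protein", prefix = "hgnc",
                            identifier = as.character(seq_len(n)), label = "",
                            mods = rep(list(character()), n),
                            members = rep(list(character()), n))
    m <- sample(1:8, 1)
    edges <- tibble::tibble(
      subject = sample(keys, m, TRUE), object = sample(keys, m, TRUE),
      relation = sample(c("increases", "decreases", "association"), m, TRUE),
      database = sample(c("kegg", "reactome", "wikipathways"), m, TRUE),
      pathway_id = sample(c("p1", "p2"), m, TRUE), pathway_name = "p",
      source_relation = "x")
    g <- pathway_graph(nodes, edges)
    rec <- detect_consensus(g)
    if (nrow(rec)) for (i in seq_len(nrow(rec))) {
      expect_gte(length(rec$polarities[[i]]), 2)
      expect_gte(rec$n_sources[i], 2)
    }
  }
})

test_that("summaries count nodes and edges by class and relation", {
  s <- summarize_graph(tiny_graph())
  expect_identical(s$nodes, 2L)
  expect_identical(s$edges, 1L)
  expect_identical(unname(s$by_class[["protein"]]), 1L)
  expect_identical(unname(s$by_relation[["increases"]]), 1L)

  s0 <- summarize_graph(pathway_graph())
  expect_identical(s0$nodes, 0L)
  expect_identical(sum(s0$by_class), 0L)

  # merged trio totals = sum of parts minus shared nodes
  trio <- generate_trio(trio_plan(seed = 9))
  gs <- convert_trio(trio)
  merged <- merge_graphs(gs)
  shared_correction <- sum(lengths(lapply(gs, function(g) g$nodes$key))) -
    length(unique(unlist(lapply(gs, function(g) g$nodes$key))))
  expect_identical(summarize_graph(merged)$nodes,
                   sum(vapply(gs, n_nodes, integer(1))) - shared_correction)
})

test_that("compare_pathways reports the comparison-row layout", {
  trio <- generate_trio(trio_plan(seed = 21))
  gs <- convert_trio(trio)
  row <- compare_pathways(gs$kegg, gs$reactome, gs$wikipathways)
  expect_named(row, c("s_kegg_reactome", "s_kegg_wikipathways",
                      "s_reactome_wikipathways", "similarity_index"))
  expect_equal(row$similarity_index, trio$expected$index)
  expect_equal(row$s_kegg_reactome, unname(trio$expected$coefficients["kr"]))
})

test_that("venn counts partition the union", {
  v <- venn_counts(c("a", "b", "c"), c("b", "c", "d"), c("c", "d", "e"))
  expect_identical(sum(v), 5L)
  expect_identical(unname(v[["kegg_reactome_wikipathways"]]), 1L)
  expect_identical(unname(v[["kegg"]]), 1L)
})
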