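test_that("a minimal KGML pathway converts to two molecular nodes and one increases edge", {
  g <- to_unified(parse_kgml(minimal_kgml()))
  expect_identical(n_nodes(g), 2L)
  expect_identical(n_edges(g), 1L)
  expect_identical(g$edges$relation, "increases")
  expect_identical(g$edges$source_relation, "activation")
  expect_identical(g$edges$database, "kegg")
  expect_setequal(g$nodes$class, c("protein", "abundance"))
})

test_that("untranslatable relations are dropped and tallied, not emitted", {
  g <- to_unified(parse_kgml(kgml_with_relation("missing interaction")))
  expect_identical(n_nodes(g), 2L)
  expect_identical(n_edges(g), 0L)
  expect_identical(skipped_relations(g), c("missing interaction" = 1L))
  # only closed-set relation types ever appear on edges
  zoo <- to_unified(parse_kgml(kgml_relation_zoo()))
  expect_true(all(zoo$edges$relation %in% relation_types()))
  expect_identical(sum(skipped_relations(zoo)), 4L)
})

test_that("count_skipped tallies per raw label without converting", {
  zoo <- parse_kgml(kgml_relation_zoo())
  sk <- count_skipped(zoo)
  expect_identical(sort(names(sk)), sort(c("hidden compound", "state change",
                                           "dissociation", "missing interaction")))
  expect_true(all(sk == 1L))
  expect_length(count_skipped(parse_kgml(minimal_kgml())), 0)

  twice <- '<pathway name="path:hsa1"><entry id="1" name="hsa:1" type="gene"/>
    <entry id="2" name="hsa:2" type="gene"/>
    <relation entry1="1" entry2="2"><subtype name="dissociation" value="x"/></relation>
    <relation entry1="2" entry2="1"><subtype name="dissociation" value="x"/></relation>
  </pathway>'
  expect_identical(count_skipped(parse_kgml(twice)), c(dissociation = 2L))
})

test_that("unknown raw types or relations are hard errors", {
  sp <- parse_kgml(minimal_kgml())
  sp$entities$raw_type[1] <- "martian"
  expect_error(to_unified(sp), "martian")
  sp2 <- parse_kgml(minimal_kgml())
  sp2$interactions$raw_relations[[1]] <- "telepathy"
  expect_error(to_unified(sp2), "telepathy")
})

test_that("untyped GPML DataNodes become abundance nodes", {
  gpml <- '<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="x">
    <DataNode GraphId="d1" TextLabel="mystery"/>
  </Pathway>'
  g <- to_unified(parse_gpml(gpml))
  expect_identical(g$nodes$class, "abundance")
})

test_that("the genes-as switch types KEGG gene entries as genes instead of proteins", {
  sp <- parse_kgml(minimal_kgml())
  expect_identical(sort(to_unified(sp)$nodes$class), c("abundance", "protein"))
  expect_identical(sort(to_unified(sp, genes_as = "genes")$nodes$class),
                   c("abundance", "gene"))
})

test_that("normalization inside conversion harmonizes node identity across databases", {
  tab <- demo_mapping()
  gk <- to_unified(parse_kgml(minimal_kgml()), tab)
  gb <- to_unified(parse_biopax(minimal_biopax()), tab)
  # kegg hsa:207 and uniprot P31749 both land on protein|hgnc:391
  expect_true("protein|hgnc:391" %in% gk$nodes$key)
  expect_true("protein|hgnc:391" %in% gb$nodes$key)
})

test_that("miRNA entities are classed as mirna regardless of source typing", {
  gpml <- '<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="x">
    <DataNode GraphId="d1" TextLabel="hsa-miR-21" Type="GeneProduct">
      <Xref Database="miRBase" ID="MI0000077"/></DataNode>
  </Pathway>'
  g <- to_unified(parse_gpml(gpml))
  expect_identical(g$nodes$class, "mirna")
})

test_that("reactions are reified with participant edges and catalyst edges", {
  g <- to_unified(parse_biopax(minimal_biopax()))
  rxn_key <- g$nodes$key[g$nodes$class == "reaction"]
  expect_length(rxn_key, 1)
  e <- g$edges
  expect_identical(e$object[e$relation == "has_reactant"], "abundance|chebi:15422")
  expect_identical(e$object[e$relation == "has_product"], "abundance|chebi:16761")
  expect_identical(e$subject[e$relation == "increases"], "protein|uniprot:P31749")
  expect_identical(e$object[e$relation == "increases"], rxn_key)
})

test_that("identical reactions from different databases share one reaction node", {
  # KEGG writes the same ATP -> ADP conversion with KEGG compound ids;
  # a mapping table normalizes both sides to ChEBI
  tab <- load_mapping_table(tibble::tibble(
    source_prefix = c("kegg.compound", "kegg.compound"),
    source_id = c("C00002", "C00008"),
    target_prefix = c("chebi", "chebi"),
    target_id = c("15422", "16761")))
  kgml <- '<pathway name="path:hsa00999">
    <entry id="1" name="cpd:C00002" type="compound"/>
    <entry id="2" name="cpd:C00008" type="compound"/>
    <reaction id="9" name="rn:R00001" type="irreversible">
      <substrate id="1" name="cpd:C00002"/><product id="2" name="cpd:C00008"/>
    </reaction>
  </pathway>'
  gk <- to_unified(parse_kgml(kgml), tab)
  gb <- to_unified(parse_biopax(minimal_biopax()), tab)
  expect_identical(gk$nodes$key[gk$nodes$class == "reaction"],
                   gb$nodes$key[gb$nodes$class == "reaction"])
})

test_that("flatten_groups replicates incident edges onto members and is pure", {
  nodes <- tibble::tibble(
    key = c("protein|hgnc:1", "protein|hgnc:2", "protein|hgnc:3",
            "complex|kegg.local:g1"),
    class = c("protein", "protein", "protein", "complex"),
    prefix = c("hgnc", "hgnc", "hgnc", "kegg.local"),
    identifier = c("1", "2", "3", "g1"),
    label = c("P1", "P2", "X", "G"),
    mods = rep(list(character()), 4),
    members = list(character(), character(), character(),
                   c("protein|hgnc:1", "protein|hgnc:2")))
  edges <- tibble::tibble(
    subject = c("protein|hgnc:3", "complex|kegg.local:g1",
                "complex|kegg.local:g1"),
    object = c("complex|kegg.local:g1", "protein|hgnc:1", "protein|hgnc:2"),
    relation = c("increases", "has_component", "has_component"),
    database = "kegg", pathway_id = "p", pathway_name = "p",
    source_relation = c("activation", "membership", "membership"))
  g <- pathway_graph(nodes, edges)
  flat <- flatten_groups(g)
  expect_identical(n_nodes(g), 4L)            # input untouched
  expect_false(any(flat$nodes$class %in% group_classes()))
  expect_setequal(paste(flat$edges$subject, flat$edges$object),
                  c("protein|hgnc:3 protein|hgnc:1",
                    "protein|hgnc:3 protein|hgnc:2"))
  expect_true(all(flat$edges$relation == "increases"))
  # no-op on group-free graphs, idempotent otherwise
  expect_identical(flatten_groups(tiny_graph())$nodes, tiny_graph()$nodes)
  expect_identical(flatten_groups(flat)$edges, flat$edges)
})

test_that("nested groups flatten to the fixpoint against a closure oracle", {
  # family F = {P1, complex C}, C = {P2, P3}; edge X -> F
  keys <- c(P1 = "protein|hgnc:1", P2 = "protein|hgnc:2", P3 = "protein|hgnc:3",
            X = "protein|hgnc:4", C = "complex|n:c", F = "family|n:f")
  nodes <- tibble::tibble(
    key = unname(keys),
    class = c("protein", "protein", "protein", "protein", "complex", "family"),
    prefix = c("hgnc", "hgnc", "hgnc", "hgnc", "n", "n"),
    identifier = c("1", "2", "3", "4", "c", "f"),
    label = names(keys),
    mods = rep(list(character()), 6),
    members = list(character(), character(), character(), character(),
                   unname(keys[c("P2", "P3")]), unname(keys[c("P1", "C")])))
  edges <- tibble::tibble(
    subject = keys[["X"]], object = keys[["F"]], relation = "increases",
    database = "kegg", pathway_id = "p", pathway_name = "p",
    source_relation = "activation")
  flat <- flatten_groups(pathway_graph(nodes, edges))
  expect_setequal(flat$edges$object, unname(keys[c("P1", "P2", "P3")]))

  # cyclic membership terminates and keeps the non-group leaves
  nodes2 <- nodes
  nodes2$members[[5]] <- c(unname(keys[["P2"]]), unname(keys[["F"]]))  # C -> F cycle
  flat2 <- flatten_groups(pathway_graph(nodes2, edges))
  expect_setequal(flat2$edges$object, unname(keys[c("P1", "P2")]))
})

test_that("flattening random group hierarchies matches a transitive-closure oracle", {
  set.seed(7)
  for (trial in 1:20) {
    n_prot <- sample(2:5, 1); n_grp <- sample(1:3, 1)
    prot_keys <- paste0("protein|hgnc:", seq_len(n_prot))
    grp_keys <- paste0("complex|n:g", seq_len(n_grp))
    members <- lapply(seq_len(n_grp), function(i)
      unique(sample(c(prot_keys, grp_keys), sample(1:3, 1), replace = TRUE)))
    nodes <- tibble::tibble(
      key = c(prot_keys, grp_keys),
      class = c(rep("protein", n_prot), rep("complex", n_grp)),
      prefix = c(rep("hgnc", n_prot), rep("n", n_grp)),
      identifier = c(as.character(seq_len(n_prot)), paste0("g", seq_len(n_grp))),
      label = "", mods = rep(list(character()), n_prot + n_grp),
      members = c(rep(list(character()), n_prot), members))
    src <- prot_keys[1]; tgt <- grp_keys[n_grp]
    edges <- tibble::tibble(subject = src, object = tgt,
                            relation = "increases", database = "kegg",
                            pathway_id = "p", pathway_name = "p",
                            source_relation = "activation")
    g <- pathway_graph(nodes, edges)

    # oracle: iterate set substitution until stable (bounded)
    closure <- list(tgt)
    for (it in 1:10) {
      nxt <- unique(unlist(lapply(closure[[length(closure)]], function(k) {
        if (k %in% grp_keys) members[[match(k, grp_keys)]] else k
      })))
      closure <- c(closure, list(nxt))
      if (setequal(nxt, closure[[length(closure) - 1]])) break
    }
    expected <- setdiff(closure[[length(closure)]], grp_keys)

    flat <- suppressWarnings(flatten_groups(g))
    expect_setequal(flat$edges$object, expected)
    expect_false(any(flat$nodes$class %in% group_classes()))
  }
})

test_that("groups with no members are dropped with a warning", {
  nodes <- tibble::tibble(key = "complex|n:g", class = "complex", prefix = "n",
                          identifier = "g", label = "",
                          mods = list(character()), members = list(character()))
  g <- pathway_graph(nodes, empty_edges())
  expect_warning(flat <- flatten_groups(g), "no resolvable members")
  expect_identical(n_nodes(flat), 0L)
})

test_that("edge provenance always carries the source database", {
  trio <- generate_trio(trio_plan(seed = 3))
  gs <- convert_trio(trio)
  for (db in names(gs))
    if (n_edges(gs[[db]])) expect_true(all(gs[[db]]$edges$database ==
                                             gs[[db]]$metadata$database))
})
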