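# Synthetic fixture generation: KGML/GPML/BioPAX file trios with a
# planned overlap structure, written in real dialect syntax so the
# actual parser code paths are exercised, plus a KGML document
# containing every relation subtype ("relation zoo"). The trio's
# analytic similarity index follows from the planned counts alone, so
# the whole parse -> normalize -> convert -> collapse -> compare
# pipeline has an exact end-to-end oracle.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Plan for a synthetic fixture trio
#'
#' Controls the entity overlap structure of one pathway represented in
#' all three dialects: `shared` entities appear in all three files,
#' `pairwise` (named kr/kw/rw) in exactly one database pair, and
#' `exclusive` (named k/r/w) in one database only. Every file carries
#' one positive-polarity relation per consecutive entity pair (its
#' database's default polar label); with `contradict = TRUE` the two
#' first shared entities additionally receive an opposite-polarity
#' duplicate edge in KEGG vs WikiPathways (requires `shared >= 2`).
#'
#' @param shared entities present in all three databases
#' @param pairwise named counts c(kr=, kw=, rw=) per database pair
#' @param exclusive named counts c(k=, r=, w=) per database
#' @param contradict emit one contradictory edge pair
#' @param seed integer seed driving identifier sampling
#' @return a `trio_plan` list
#' @export
trio_plan <- function(shared = 2, pairwise = c(kr = 1, kw = 1, rw = 1),
                      exclusive = c(k = 1, r = 1, w = 1),
                      contradict = FALSE, seed = 1) {
  pairwise <- pairwise[c("kr", "kw", "rw")]
  exclusive <- exclusive[c("k", "r", "w")]
  stopifnot(!anyNA(pairwise), !anyNA(exclusive),
            shared >= 0, all(pairwise >= 0), all(exclusive >= 0))
  if (shared + sum(pairwise) + sum(exclusive) == 0)
    stop("trio plan has no entities")
  if (contradict && shared < 2)
    stop("contradict = TRUE requires at least 2 shared entities")
  structure(list(shared = as.integer(shared),
                 pairwise = as.integer(pairwise) |> stats::setNames(c("kr", "kw", "rw")),
                 exclusive = as.integer(exclusive) |> stats::setNames(c("k", "r", "w")),
                 contradict = isTRUE(contradict), seed = as.integer(seed)),
            class = "trio_plan")
}

#' Analytic expectations implied by a trio plan
#'
#' Set sizes, the three pairwise overlap coefficients, the similarity
#' index, and the shared/partial/exclusive ratios that the pipeline
#' must recover from the generated files — computed from the planned
#' counts alone, independently of any parsing.
#'
#' @param plan a [trio_plan()]
#' @return list(sizes, coefficients, index, overlap)
#' @export
trio_expectations <- function(plan) {
  s <- plan$shared; pw <- plan$pairwise; ex <- plan$exclusive
  sizes <- c(k = s + pw[["kr"]] + pw[["kw"]] + ex[["k"]],
             r = s + pw[["kr"]] + pw[["rw"]] + ex[["r"]],
             w = s + pw[["kw"]] + pw[["rw"]] + ex[["w"]])
  pair_coeff <- function(inter, a, b) if (min(a, b) == 0) 0 else inter / min(a, b)
  coeff <- c(
    kr = pair_coeff(s + pw[["kr"]], sizes[["k"]], sizes[["r"]]),
    kw = pair_coeff(s + pw[["kw"]], sizes[["k"]], sizes[["w"]]),
    rw = pair_coeff(s + pw[["rw"]], sizes[["r"]], sizes[["w"]]))
  u <- s + sum(pw) + sum(ex)
  # canonical (sorted) summation order, exactly permutation invariant
  list(sizes = sizes, coefficients = coeff, index = sum(sort(coeff)) / 3,
       overlap = c(shared = s / u, partial = sum(pw) / u,
                   exclusive = sum(ex) / u))
}

# entity table: one row per planned entity with its per-database ids
trio_entities <- function(plan) {
  n <- plan$shared + sum(plan$pairwise) + sum(plan$exclusive)
  membership <- c(rep("krw", plan$shared),
                  rep("kr", plan$pairwise[["kr"]]),
                  rep("kw", plan$pairwise[["kw"]]),
                  rep("rw", plan$pairwise[["rw"]]),
                  rep("k", plan$exclusive[["k"]]),
                  rep("r", plan$exclusive[["r"]]),
                  rep("w", plan$exclusive[["w"]]))
  with_local_seed(plan$seed, {
    base <- sample(10000:99999, n)
    tibble::tibble(
      idx = seq_len(n), membership = membership,
      hgnc = as.character(base),
      ncbigene = as.character(base + 100000L),
      uniprot = sprintf("P%05d", base %% 100000L),
      kegg = paste0("hsa:", base + 100000L),
      symbol = paste0("SYN", base))
  })
}

trio_mapping_table <- function(entities) {
  tibble::tibble(
    source_prefix = rep(c("kegg", "ncbigene", "uniprot"),
                        each = nrow(entities)),
    source_id = c(entities$kegg, entities$ncbigene, entities$uniprot),
    target_prefix = rep(c("ncbigene", "hgnc", "hgnc"), each = nrow(entities)),
    target_id = c(entities$ncbigene, entities$hgnc, entities$hgnc))
}

trio_kgml_text <- function(ent, plan) {
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<pathway name="path:hsa90001" org="hsa" title="Synthetic pathway (KEGG)">')
  for (i in seq_len(nrow(ent)))
    lines <- c(lines, sprintf(
      '  <entry id="%d" name="%s" type="gene"><graphics name="%s"/></entry>',
      i, ent$kegg[i], xml_escape(ent$symbol[i])))
  add_rel <- function(a, b, subtype) sprintf(
    '  <relation entry1="%d" entry2="%d" type="PPrel"><subtype name="%s" value="--&gt;"/></relation>',
    a, b, subtype)
  if (nrow(ent) >= 2)
    for (i in seq_len(nrow(ent) - 1))
      lines <- c(lines, add_rel(i, i + 1, "activation"))
  if (plan$contradict) lines <- c(lines, add_rel(2, 1, "activation"))
  c(lines, "</pathway>")
}

trio_gpml_text <- function(ent, plan) {
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="Synthetic pathway (WikiPathways)" Organism="Homo sapiens">')
  for (i in seq_len(nrow(ent)))
    lines <- c(lines, sprintf(paste0(
      '  <DataNode GraphId="n%d" TextLabel="%s" Type="GeneProduct">',
      '<Xref Database="Entrez Gene" ID="%s"/></DataNode>'),
      i, xml_escape(ent$symbol[i]), ent$ncbigene[i]))
  add_edge <- function(a, b, arrow) c(
    '  <Interaction><Graphics>',
    sprintf('    <Point GraphRef="n%d"/>', a),
    sprintf('    <Point GraphRef="n%d" ArrowHead="%s"/>', b, arrow),
    '  </Graphics></Interaction>')
  if (nrow(ent) >= 2)
    for (i in seq_len(nrow(ent) - 1))
      lines <- c(lines, add_edge(i, i + 1, "Arrow"))
  if (plan$contradict) lines <- c(lines, add_edge(2, 1, "TBar"))
  c(lines, "</Pathway>")
}

trio_biopax_text <- function(ent, plan) {
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#">',
    '  <bp:Pathway rdf:ID="SyntheticPathway">',
    '    <bp:displayName>Synthetic pathway (Reactome)</bp:displayName>',
    '    <bp:xref rdf:resource="#PathwayXref"/>',
    '  </bp:Pathway>',
    '  <bp:UnificationXref rdf:ID="PathwayXref">',
    '    <bp:db>Reactome</bp:db><bp:id>R-HSA-90001</bp:id>',
    '  </bp:UnificationXref>')
  for (i in seq_len(nrow(ent))) lines <- c(lines,
    sprintf('  <bp:Protein rdf:ID="Protein%d">', i),
    sprintf('    <bp:displayName>%s</bp:displayName>', xml_escape(ent$symbol[i])),
    sprintf('    <bp:entityReference rdf:resource="#ProteinReference%d"/>', i),
    '  </bp:Protein>',
    sprintf('  <bp:ProteinReference rdf:ID="ProteinReference%d">', i),
    sprintf('    <bp:xref rdf:resource="#Xref%d"/>', i),
    '  </bp:ProteinReference>',
    sprintf('  <bp:UnificationXref rdf:ID="Xref%d">', i),
    sprintf('    <bp:db>UniProt</bp:db><bp:id>%s</bp:id>', ent$uniprot[i]),
    '  </bp:UnificationXref>')
  if (nrow(ent) >= 2) for (i in seq_len(nrow(ent) - 1)) lines <- c(lines,
    sprintf('  <bp:Control rdf:ID="Control%d">', i),
    sprintf('    <bp:controller rdf:resource="#Protein%d"/>', i),
    sprintf('    <bp:controlled rdf:resource="#Protein%d"/>', i + 1),
    '    <bp:controlType>ACTIVATION</bp:controlType>',
    '  </bp:Control>')
  c(lines, '</rdf:RDF>')
}

#' Generate a synthetic KGML/GPML/BioPAX trio with planned overlap
#'
#' Emits one pathway in all three source dialects with the entity
#' overlap structure of the plan. Entities are genes drawn from a
#' synthetic HGNC-like namespace; each dialect carries a different
#' identifier type (KEGG gene accessions, Entrez Gene ids, UniProt
#' accessions) so normalization through the accompanying mapping table
#' (KEGG -> NCBI Gene -> HGNC, UniProt -> HGNC) is genuinely
#' exercised. Deterministic given the plan's seed: the same plan twice
#' yields byte-identical files.
#'
#' @param plan a [trio_plan()]
#' @return list with `kgml`/`gpml`/`biopax` file texts, the
#'   `mapping_table` tibble, the entity table, and `expected`
#'   ([trio_expectations()])
#' @export
generate_trio <- function(plan = trio_plan()) {
  stopifnot(inherits(plan, "trio_plan"))
  ent <- trio_entities(plan)
  in_db <- function(db) ent[grepl(db, ent$membership), ]
  list(plan = plan,
       entities = ent,
       kgml = paste0(paste(trio_kgml_text(in_db("k"), plan), collapse = "\n"), "\n"),
       gpml = paste0(paste(trio_gpml_text(in_db("w"), plan), collapse = "\n"), "\n"),
       biopax = paste0(paste(trio_biopax_text(in_db("r"), plan), collapse = "\n"), "\n"),
       mapping_table = trio_mapping_table(ent),
       expected = trio_expectations(plan))
}

#' Run the full pipeline over a generated trio
#'
#' Parses the three generated files, normalizes and converts them with
#' the trio's mapping table, and returns the three unified graphs —
#' the end-to-end path whose similarity output must reproduce the
#' plan's analytic expectations.
#'
#' @param trio a [generate_trio()] result
#' @return named list of three [pathway_graph()]s (kegg, reactome,
#'   wikipathways)
#' @export
convert_trio <- function(trio) {
  table <- load_mapping_table(trio$mapping_table)
  list(kegg = to_unified(parse_kgml(trio$kgml), table),
       reactome = to_unified(parse_biopax(trio$biopax), table),
       wikipathways = to_unified(parse_gpml(trio$gpml), table))
}

#' Write a trio plus its expectations to a directory
#'
#' @param trio a [generate_trio()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_trio <- function(trio, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("kegg.kgml", "wikipathways.gpml",
                            "reactome.owl", "mapping.tsv",
                            "expectations.json"))
  writeLines(trio$kgml, paths[1], sep = "")
  writeLines(trio$gpml, paths[2], sep = "")
  writeLines(trio$biopax, paths[3], sep = "")
  utils::write.table(trio$mapping_table, paths[4], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(trio$expected, paths[5], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' KGML document containing every relation subtype
#'
#' A fixed KGML text whose relations carry each of the 16 KGML
#' relation subtypes exactly once (the `compound` subtype is mediated
#' by a compound entry, as in real KEGG files). Converting it drops
#' exactly the four subtypes with no unified-edge equivalent: hidden
#' compound, state change, dissociation and missing interaction.
#'
#' @return KGML text, stable across calls
#' @export
kgml_relation_zoo <- function() {
  subtypes <- c("activation", "inhibition", "expression", "repression",
                "binding/association", "phosphorylation", "dephosphorylation",
                "ubiquitination", "glycosylation", "methylation",
                "indirect effect", "hidden compound", "state change",
                "dissociation", "missing interaction")
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<pathway name="path:hsa99999" org="hsa" title="Relation subtype zoo">')
  n_genes <- length(subtypes) + 2
  for (i in seq_len(n_genes))
    lines <- c(lines, sprintf(
      '  <entry id="%d" name="hsa:%d" type="gene"><graphics name="Z%d"/></entry>',
      i, 1000 + i, i))
  cid <- n_genes + 1
  lines <- c(lines, sprintf(
    '  <entry id="%d" name="cpd:C%05d" type="compound"><graphics name="ZC"/></entry>',
    cid, 1))
  for (k in seq_along(subtypes))
    lines <- c(lines, sprintf(
      '  <relation entry1="%d" entry2="%d" type="PPrel"><subtype name="%s" value="?"/></relation>',
      k, k + 1, xml_escape(subtypes[k])))
  lines <- c(lines, sprintf(
    '  <relation entry1="%d" entry2="%d" type="PCrel"><subtype name="compound" value="%d"/></relation>',
    1, n_genes, cid))
  paste0(paste(c(lines, "</pathway>"), collapse = "\n"), "\n")
}
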