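# Bundled entity-class and relation mappings from each source
# database's vocabulary into the unified model, overridable via
# 3-column TSVs. The KEGG tables are reconstructions of the published
# mapping (the four untranslatable KEGG relations map to SKIP).

#' Default entity-class map
#'
#' Maps each (database, raw_type) pair emitted by the parsers to a
#' unified node class. KEGG `gene` entries default to `protein` (KEGG
#' signalling arrows act between gene products); see the `genes_as`
#' switch of [to_unified()]. WikiPathways' abstract `DataNode` maps to
#' `abundance`, the class for unspecified physical entities.
#'
#' @return tibble with columns database, raw, target
#' @export
default_class_map <- function() {
  tibble::tribble(
    ~database,       ~raw,             ~target,
    "kegg",          "gene",           "protein",
    "kegg",          "compound",       "abundance",
    "kegg",          "map",            "bioprocess",
    "kegg",          "group",          "complex",
    "kegg",          "ortholog",       "protein",
    "kegg",          "enzyme",         "protein",
    "wikipathways",  "GeneProduct",    "protein",
    "wikipathways",  "Protein",        "protein",
    "wikipathways",  "Rna",            "rna",
    "wikipathways",  "Metabolite",     "abundance",
    "wikipathways",  "Pathway",        "bioprocess",
    "wikipathways",  "Complex",        "complex",
    "wikipathways",  "Group",          "complex",
    "wikipathways",  "DataNode",       "abundance",
    "reactome",      "Protein",        "protein",
    "reactome",      "Rna",            "rna",
    "reactome",      "Dna",            "gene",
    "reactome",      "SmallMolecule",  "abundance",
    "reactome",      "PhysicalEntity", "abundance",
    "reactome",      "Complex",        "complex",
    "reactome",      "EntitySet",      "family",
    "reactome",      "Pathway",        "bioprocess")
}

#' Default relation map
#'
#' Maps each (database, raw_relation) pair to a unified relation type,
#' or to `SKIP` for relations with no causal/correlative equivalent.
#' Exactly four KEGG relation subtypes map to SKIP: hidden compound,
#' state change, dissociation and missing interaction — non-causal
#' labels with no unified-edge equivalent.
#'
#' @return tibble with columns database, raw, target
#' @export
default_relation_map <- function() {
  tibble::tribble(
    ~database,       ~raw,                  ~target,
    "kegg",          "activation",          "increases",
    "kegg",          "expression",          "increases",
    "kegg",          "inhibition",          "decreases",
    "kegg",          "repression",          "decreases",
    "kegg",          "phosphorylation",     "directly_increases",
    "kegg",          "dephosphorylation",   "directly_decreases",
    "kegg",          "ubiquitination",      "directly_increases",
    "kegg",          "glycosylation",       "directly_increases",
    "kegg",          "methylation",         "directly_increases",
    "kegg",          "binding/association", "association",
    "kegg",          "indirect effect",     "regulates",
    "kegg",          "compound_mediated",   "association",
    "kegg",          "hidden compound",     "SKIP",
    "kegg",          "state change",        "SKIP",
    "kegg",          "dissociation",        "SKIP",
    "kegg",          "missing interaction", "SKIP",
    "wikipathways",  "Arrow",               "increases",
    "wikipathways",  "mim-stimulation",     "increases",
    "wikipathways",  "mim-conversion",      "increases",
    "wikipathways",  "TBar",                "decreases",
    "wikipathways",  "mim-inhibition",      "decreases",
    "wikipathways",  "mim-catalysis",       "increases",
    "wikipathways",  "mim-binding",         "association",
    "wikipathways",  "Line",                "association",
    "reactome",      "ACTIVATION",          "increases",
    "reactome",      "INHIBITION",          "decreases")
}

# KEGG subtypes that imply a protein modification on the target; the
# modification annotation is attached to the edge (KGML does not say
# which residue state results).
kegg_modification_subtypes <- c("phosphorylation", "dephosphorylation",
                                "ubiquitination", "glycosylation",
                                "methylation")

load_map_tsv <- function(path, defaults, target_domain) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*(#|$)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 3))
    stop_format("map file ", path, ": expected 3 tab-separated columns ",
                "(database, raw, target)")
  m <- do.call(rbind, fields)
  if (identical(tolower(trimws(m[1, ])), c("database", "raw", "target")))
    m <- m[-1, , drop = FALSE]
  overrides <- tibble::tibble(database = tolower(trimws(m[, 1])),
                              raw = trimws(m[, 2]), target = trimws(m[, 3]))
  bad <- setdiff(overrides$target, target_domain)
  if (length(bad)) stop_format("map file ", path, ": unknown target token(s): ",
                               paste(bad, collapse = ", "))
  keep <- !(paste(defaults$database, defaults$raw) %in%
              paste(overrides$database, overrides$raw))
  rbind(overrides, defaults[keep, ])
}

#' Load a class or relation map, layered over the bundled defaults
#'
#' 3-column tab-separated text (database, raw token, target token);
#' rows override the matching default entries, unknown pairs extend the
#' map.
#'
#' @param path TSV file path
#' @return tibble with columns database, raw, target
#' @export
load_class_map <- function(path)
  load_map_tsv(path, default_class_map(), node_classes())

#' @rdname load_class_map
#' @export
load_relation_map <- function(path)
  load_map_tsv(path, default_relation_map(), c(relation_types(), "SKIP"))

map_lookup <- function(map, database, raw) {
  hit <- map$target[map$database == database & map$raw == raw]
  if (length(hit)) hit[1] else NA_character_
}
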