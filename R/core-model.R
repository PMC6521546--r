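# Unified graph data model: namespace-qualified identifiers (CURIEs),
# BEL-style node classes, typed relations with polarity, and the
# provenance-carrying directed multigraph shared by every other module.

#' Closed set of node classes
#'
#' The unified model recognises nine node classes mirroring BEL terms:
#' gene, rna, mirna, protein, abundance (metabolites and unspecified
#' physical entities), complex, family, bioprocess and reaction.
#' `complex` and `family` are the only *group* classes: they aggregate
#' member nodes and are excluded from similarity sets.
#'
#' @return character vector of class tokens
#' @export
node_classes <- function() {
  c("gene", "rna", "mirna", "protein", "abundance",
    "complex", "family", "bioprocess", "reaction")
}

#' Group node classes (aggregating classes)
#' @return character vector, subset of [node_classes()]
#' @export
group_classes <- function() c("complex", "family")

#' Closed set of relation types
#'
#' BEL-style relation vocabulary used on unified edges. Causal relations
#' carry polarity (see [relation_polarity()]); structural relations
#' (component/member/reactant/product) and correlative ones do not.
#'
#' @return character vector of relation tokens
#' @export
relation_types <- function() {
  c("increases", "decreases", "directly_increases", "directly_decreases",
    "regulates", "association", "has_component", "has_member",
    "has_reactant", "has_product", "transcribed_to", "translated_to")
}

#' Polarity of a relation type
#'
#' `increases`/`directly_increases` have polarity +1,
#' `decreases`/`directly_decreases` have polarity -1, every other member
#' of the closed relation set has polarity 0. Total over
#' [relation_types()]; unknown tokens are an error.
#'
#' @param relation character vector of relation tokens
#' @return integer vector in \{-1, 0, 1\}
#' @export
relation_polarity <- function(relation) {
  bad <- setdiff(relation, relation_types())
  if (length(bad)) stop("unknown relation type(s): ", paste(bad, collapse = ", "))
  p <- integer(length(relation))
  p[relation %in% c("increases", "directly_increases")] <- 1L
  p[relation %in% c("decreases", "directly_decreases")] <- -1L
  p
}

#' Construct a namespace-qualified identifier (CURIE)
#'
#' The atom of harmonization: a lowercase namespace prefix (hgnc,
#' uniprot, chebi, ...), a namespace-local accession (case preserved),
#' and an optional human-readable label. The label never participates in
#' identity.
#'
#' @param prefix namespace token; lowercased
#' @param identifier namespace-local accession, preserved verbatim
#' @param label optional display name
#' @return a `curie` list with fields prefix, identifier, label
#' @examples
#' curie("HGNC", "391", "AKT1")
#' @export
curie <- function(prefix, identifier, label = "") {
  prefix <- tolower(trimws(prefix))
  identifier <- trimws(as.character(identifier))
  if (!nzchar(prefix)) stop("curie prefix must be non-empty")
  if (!nzchar(identifier)) stop("curie identifier must be non-empty")
  structure(list(prefix = prefix, identifier = identifier,
                 label = as.character(label %||% "")),
            class = "curie")
}

#' Canonical string form of a CURIE
#' @param x a `curie` or a list with prefix/identifier fields
#' @return "prefix:identifier"
#' @export
curie_string <- function(x) paste0(tolower(x$prefix), ":", x$identifier)

#' @export
format.curie <- function(x, ...) curie_string(x)

#' @export
print.curie <- function(x, ...) {
  cat(curie_string(x), if (nzchar(x$label)) paste0(" (", x$label, ")"), "\n", sep = "")
  invisible(x)
}

#' Construct a node modification
#'
#' Modifications participate in node identity: a phosphorylated protein
#' is a distinct node from its unmodified form, mirroring how curators
#' record specific protein events.
#'
#' @param mod_type one of "protein_modification", "fragment", "variant"
#' @param detail free-text qualifier (residue/position, "spliced", ...)
#' @return canonical "mod_type:detail" token
#' @export
modification <- function(mod_type, detail = "") {
  mod_type <- match.arg(mod_type, c("protein_modification", "fragment", "variant"))
  paste0(mod_type, ":", detail)
}

#' Canonical node key
#'
#' Deterministic identity for a unified node:
#' `class|prefix:identifier` with the sorted modification tokens appended
#' (`|mod1,mod2`) when present. Labels are deliberately excluded —
#' identifiers are the harmonized handle, labels vary across databases.
#'
#' @param node_class one of [node_classes()]
#' @param prefix,identifier the node's resolved CURIE
#' @param mods character vector of modification tokens (see
#'   [modification()]); order-insensitive
#' @return character scalar key
#' @examples
#' node_key("protein", "hgnc", "391")           # "protein|hgnc:391"
#' @export
node_key <- function(node_class, prefix, identifier, mods = character()) {
  node_class <- match.arg(node_class, node_classes())
  key <- paste0(node_class, "|", tolower(prefix), ":", identifier)
  mods <- sort(unique(as.character(mods)))
  if (length(mods)) key <- paste0(key, "|", paste(mods, collapse = ","))
  key
}

empty_nodes <- function() {
  tibble::tibble(key = character(), class = character(), prefix = character(),
                 identifier = character(), label = character(),
                 mods = list(), members = list())
}

empty_edges <- function() {
  tibble::tibble(subject = character(), object = character(),
                 relation = character(), database = character(),
                 pathway_id = character(), pathway_name = character(),
                 source_relation = character())
}

#' Construct a unified pathway graph
#'
#' A directed multigraph: a keyed node table, an edge multiset where
#' every edge carries provenance (source database, pathway id/name, raw
#' source relation), and pathway-level metadata. Parallel edges are kept
#' when provenance differs; exact duplicates on
#' (subject, object, relation, database, pathway_id) are stored once.
#'
#' @param nodes tibble with columns key, class, prefix, identifier,
#'   label, mods (list), members (list)
#' @param edges tibble with columns subject, object, relation, database,
#'   pathway_id, pathway_name, source_relation
#' @param metadata tibble (database, pathway_id, pathway_name); derived
#'   from edges and node provenance when NULL
#' @return object of class `pathway_graph`
#' @export
pathway_graph <- function(nodes = empty_nodes(), edges = empty_edges(),
                          metadata = NULL) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  if (nrow(nodes)) {
    if (anyDuplicated(nodes$key)) nodes <- nodes[!duplicated(nodes$key), ]
    bad <- setdiff(nodes$class, node_classes())
    if (length(bad)) stop("unknown node class(es): ", paste(bad, collapse = ", "))
  }
  if (nrow(edges)) {
    bad <- setdiff(edges$relation, relation_types())
    if (length(bad)) stop("unknown relation type(s): ", paste(bad, collapse = ", "))
    missing <- setdiff(c(edges$subject, edges$object), nodes$key)
    if (length(missing)) stop("edge endpoint(s) missing from node table: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    dup <- duplicated(edges[, c("subject", "object", "relation",
                                "database", "pathway_id")])
    edges <- edges[!dup, ]
  }
  if (is.null(metadata)) {
    metadata <- unique(edges[, c("database", "pathway_id", "pathway_name")])
  } else {
    metadata <- unique(tibble::as_tibble(metadata)[, c("database", "pathway_id",
                                                       "pathway_name")])
  }
  structure(list(nodes = nodes, edges = edges, metadata = metadata),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %d nodes, %d edges, %d source pathway(s)\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$metadata)))
  if (nrow(x$metadata)) {
    cat(paste0("  ", x$metadata$database, ":", x$metadata$pathway_id,
               " (", x$metadata$pathway_name, ")", collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Number of nodes/edges in a pathway graph
#' @param g a `pathway_graph`
#' @return integer
#' @export
n_nodes <- function(g) nrow(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

# Row-bind node tables, keeping the first occurrence of each key.
bind_nodes <- function(...) {
  nodes <- do.call(rbind, lapply(list(...), tibble::as_tibble))
  nodes[!duplicated(nodes$key), ]
}
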