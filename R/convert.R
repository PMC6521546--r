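# Conversion of the parser intermediate representation into the
# unified graph model: identifier resolution, class and relation
# mapping, group reification and reaction reification.

modality_for_class <- function(node_class, mirna = FALSE) {
  if (mirna) return("mirnas")
  switch(node_class,
         gene = , rna = , protein = "genes",
         abundance = "metabolites",
         mirna = "mirnas",
         bioprocess = "bioprocess",
         "genes")
}

reaction_node <- function(reactant_keys, product_keys, reversible, label) {
  canonical <- paste0(paste(sort(reactant_keys), collapse = "+"), ">>",
                      paste(sort(product_keys), collapse = "+"))
  ref <- curie("reaction", str_hash31(canonical), label)
  list(key = node_key("reaction", ref$prefix, ref$identifier), ref = ref,
       members = c(sort(reactant_keys), sort(product_keys)),
       label = if (reversible) paste0(label, " (reversible)") else label)
}

#' Convert a source pathway to a unified pathway graph
#'
#' The harmonization step: every entity's cross-references are resolved
#' through the mapping table and priority cascade, its raw source type
#' is mapped to a unified node class, raw relations are mapped to
#' unified relation types (relations mapped to `SKIP` are dropped and
#' tallied — retrievable with [skipped_relations()] or
#' [count_skipped()]), group entities become complex/family nodes with
#' `has_component`/`has_member` edges, and reactions are reified as
#' reaction nodes with `has_reactant`/`has_product` edges plus
#' `increases` edges from their catalysts. Every edge carries
#' provenance (database, pathway id and name, raw source relation). A
#' raw type or relation missing from the maps is a hard error, keeping
#' the maps total over the parsers' output.
#'
#' Reaction node identifiers are deterministic digests of the sorted
#' reactant/product keys, so identical reactions from two databases
#' unify on merge.
#'
#' @param sp a [source_pathway()]
#' @param table a [load_mapping_table()] result
#' @param config a priority configuration
#' @param class_map,relation_map mapping tibbles (see
#'   [default_class_map()], [default_relation_map()])
#' @param genes_as `"proteins"` (default) or `"genes"`: the class given
#'   to KEGG `gene` entries. The genes modality pools genes, RNAs and
#'   gene products, so the choice is invisible to the similarity layer.
#' @return a [pathway_graph()] with a `"skipped"` attribute tallying
#'   dropped raw relations
#' @export
to_unified <- function(sp, table = empty_mapping_table(),
                       config = default_priority_config(),
                       class_map = default_class_map(),
                       relation_map = default_relation_map(),
                       genes_as = c("proteins", "genes")) {
  genes_as <- match.arg(genes_as)
  db <- sp$database
  ents <- sp$entities

  key_of <- character()        # local_id -> node key
  nodes <- empty_nodes()
  group_rows <- integer()

  if (nrow(ents)) for (i in seq_len(nrow(ents))) {
    raw_type <- ents$raw_type[i]
    cls <- map_lookup(class_map, db, raw_type)
    if (is.na(cls)) stop("no class mapping for (", db, ", ", raw_type, ")")
    if (db == "kegg" && raw_type == "gene" && genes_as == "genes") cls <- "gene"
    mirna <- !(cls %in% group_classes()) &&
      is_mirna(ents$xrefs[[i]], ents$label[i])
    if (mirna) cls <- "mirna"
    ref <- resolve_xrefs(ents$xrefs[[i]], modality_for_class(cls, mirna),
                         table, config, database = db, label = ents$label[i])
    key <- node_key(cls, ref$prefix, ref$identifier)
    key_of[ents$local_id[i]] <- key
    nodes <- rbind(nodes, tibble::tibble(
      key = key, class = cls, prefix = ref$prefix, identifier = ref$identifier,
      label = ref$label, mods = list(character()), members = list(character())))
    if (cls %in% group_classes()) group_rows <- c(group_rows, nrow(nodes))
  }

  edges <- empty_edges()
  add_edge <- function(s, t, relation, source_relation) {
    edges <<- rbind(edges, tibble::tibble(
      subject = unname(s), object = unname(t), relation = relation, database = db,
      pathway_id = sp$pathway_id, pathway_name = sp$pathway_name,
      source_relation = source_relation))
  }

  # group membership edges (node row i corresponds to entity row i here)
  if (length(group_rows)) for (i in group_rows) {
    members <- ents$member_ids[[i]]
    member_keys <- unique(unname(key_of[intersect(members, names(key_of))]))
    nodes$members[[i]] <- member_keys
    rel <- if (nodes$class[i] == "complex") "has_component" else "has_member"
    for (m in member_keys) add_edge(nodes$key[i], m, rel, "membership")
  }

  # reified reactions (before interactions: controls may target them)
  if (nrow(sp$reactions)) for (i in seq_len(nrow(sp$reactions))) {
    rx <- sp$reactions[i, ]
    reactants <- unique(unname(key_of[intersect(rx$reactant_ids[[1]], names(key_of))]))
    products <- unique(unname(key_of[intersect(rx$product_ids[[1]], names(key_of))]))
    rn <- reaction_node(reactants, products, rx$reversible, rx$reaction_id)
    key_of[rx$reaction_id] <- rn$key
    nodes <- rbind(nodes, tibble::tibble(
      key = rn$key, class = "reaction", prefix = rn$ref$prefix,
      identifier = rn$ref$identifier, label = rn$label,
      mods = list(character()), members = list(rn$members)))
    for (m in reactants) add_edge(rn$key, m, "has_reactant", "reaction")
    for (m in products) add_edge(rn$key, m, "has_product", "reaction")
    for (m in unique(unname(key_of[intersect(rx$modifier_ids[[1]], names(key_of))])))
      add_edge(m, rn$key, "increases", "reaction_modifier")
  }

  skipped <- integer()
  if (nrow(sp$interactions)) for (i in seq_len(nrow(sp$interactions))) {
    s <- key_of[sp$interactions$source_id[i]]
    t <- key_of[sp$interactions$target_id[i]]
    if (is.na(s) || is.na(t)) next
    for (raw in sp$interactions$raw_relations[[i]]) {
      target <- map_lookup(relation_map, db, raw)
      if (is.na(target)) stop("no relation mapping for (", db, ", ", raw, ")")
      if (target == "SKIP") {
        skipped[raw] <- (skipped[raw] %||% 0L) + 1L
        next
      }
      add_edge(s, t, target, raw)
    }
  }

  g <- pathway_graph(nodes, edges,
                     metadata = tibble::tibble(database = db,
                                               pathway_id = sp$pathway_id,
                                               pathway_name = sp$pathway_name))
  attr(g, "skipped") <- skipped
  g
}

#' Skipped-relation tally of a converted graph
#' @param g a graph returned by [to_unified()]
#' @return named integer: raw relation label -> dropped count
#' @export
skipped_relations <- function(g) attr(g, "skipped") %||% integer()

#' Count relations a conversion would skip
#'
#' Tallies, per raw relation label, the interactions of a source
#' pathway whose label maps to `SKIP` under the relation map, without
#' performing the conversion.
#'
#' @param sp a [source_pathway()]
#' @param relation_map relation mapping tibble
#' @return named integer (empty when nothing would be skipped)
#' @export
count_skipped <- function(sp, relation_map = default_relation_map()) {
  skipped <- integer()
  if (nrow(sp$interactions)) for (i in seq_len(nrow(sp$interactions))) {
    for (raw in sp$interactions$raw_relations[[i]]) {
      target <- map_lookup(relation_map, sp$database, raw)
      if (!is.na(target) && target == "SKIP")
        skipped[raw] <- (skipped[raw] %||% 0L) + 1L
    }
  }
  skipped
}

# Cycle-safe transitive closure of group membership: the non-group leaf
# members of each group node.
group_leaf_members <- function(nodes) {
  is_group <- stats::setNames(nodes$class %in% group_classes(), nodes$key)
  members <- stats::setNames(nodes$members, nodes$key)
  leaves_of <- function(key, visited = character()) {
    if (key %in% visited) return(character())
    visited <- c(visited, key)
    out <- character()
    for (m in members[[key]] %||% character()) {
      if (!m %in% names(is_group)) next
      if (is_group[[m]]) out <- c(out, leaves_of(m, visited))
      else out <- c(out, m)
    }
    unique(out)
  }
  stats::setNames(lapply(nodes$key[nodes$class %in% group_classes()], leaves_of),
                  nodes$key[nodes$class %in% group_classes()])
}

#' Flatten group nodes into their members
#'
#' Removes every complex/family node and replicates each of its
#' incident edges onto each (transitively resolved, cycle-safe) leaf
#' member; membership edges (`has_component`/`has_member`) are removed.
#' Pure function: the input graph is untouched. Idempotent. Groups with
#' no resolvable members are dropped with a warning.
#'
#' @param g a [pathway_graph()]
#' @return a new `pathway_graph` with no group nodes
#' @export
flatten_groups <- function(g) {
  group_keys <- g$nodes$key[g$nodes$class %in% group_classes()]
  if (!length(group_keys)) return(g)
  leaves <- group_leaf_members(g$nodes)
  empty <- names(leaves)[lengths(leaves) == 0]
  if (length(empty))
    warn_beltway(length(empty), " group node(s) with no resolvable members dropped")

  edges <- g$edges
  edges <- edges[!(edges$relation %in% c("has_component", "has_member") &
                     edges$subject %in% group_keys), ]
  out <- empty_edges()
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    subs <- if (edges$subject[i] %in% group_keys)
      leaves[[edges$subject[i]]] else edges$subject[i]
    objs <- if (edges$object[i] %in% group_keys)
      leaves[[edges$object[i]]] else edges$object[i]
    for (s in subs) for (t in objs) {
      row <- edges[i, ]; row$subject <- s; row$object <- t
      out <- rbind(out, row)
    }
  }
  nodes <- g$nodes[!g$nodes$key %in% group_keys, ]
  # membership lists may still cite removed groups inside reaction nodes
  nodes$members <- lapply(nodes$members, setdiff, group_keys)
  pathway_graph(nodes, out, metadata = g$metadata)
}
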